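#' Discretize one expression vector into expression states
#'
#' Exact minimum within-cluster-variance partition of a continuous vector
#' into at most `n_states` contiguous bins (1-D k-means solved by dynamic
#' programming over the sorted unique values). Deterministic: identical
#' values always share a state and no randomness is involved. If the vector
#' has fewer distinct values than `n_states`, each distinct value becomes
#' its own state.
#'
#' @param x Numeric vector.
#' @param n_states Maximum number of states (default 3).
#' @return Integer vector of state labels in `1..k`, `k <= n_states`,
#'   ordered by increasing expression.
#' @examples
#' discretize_1d(c(1, 1, 1, 9, 9, 9), n_states = 2)
#' @export
discretize_1d <- function(x, n_states = 3) {
  stopifnot(is.numeric(x), length(x) >= 1, n_states >= 1)
  if (anyNA(x)) abort("x must not contain missing values")
  u <- sort(unique(x))
  m <- length(u)
  if (m <= n_states) {
    return(match(x, u))
  }
  w <- as.numeric(tabulate(match(x, u), nbins = m))
  cs_w <- cumsum(w)
  cs_wu <- cumsum(w * u)
  cs_wu2 <- cumsum(w * u^2)
  # weighted within-bin sum of squares of u[a..b]
  cost <- function(a, b) {
    W <- cs_w[b] - if (a > 1) cs_w[a - 1] else 0
    S1 <- cs_wu[b] - if (a > 1) cs_wu[a - 1] else 0
    S2 <- cs_wu2[b] - if (a > 1) cs_wu2[a - 1] else 0
    S2 - S1^2 / W
  }
  k <- n_states
  D <- matrix(Inf, k, m)      # D[j, i]: best cost of u[1..i] in j bins
  B <- matrix(1L, k, m)       # start index of the last bin
  for (i in 1:m) D[1, i] <- cost(1, i)
  for (j in 2:k) {
    for (i in j:m) {
      best <- Inf; barg <- j
      for (a in j:i) {
        cand <- D[j - 1, a - 1] + cost(a, i)
        if (cand < best - 1e-12) { best <- cand; barg <- a }
      }
      D[j, i] <- best
      B[j, i] <- barg
    }
  }
  # backtrack bin boundaries
  breaks <- integer(k + 1)
  breaks[k + 1] <- m
  i <- m
  for (j in k:1) {
    breaks[j] <- B[j, i]
    i <- breaks[j] - 1L
  }
  state_of_u <- integer(m)
  for (j in 1:k) {
    hi <- if (j < k) breaks[j + 1] - 1L else m
    state_of_u[breaks[j]:hi] <- j
  }
  state_of_u[match(x, u)]
}

#' Discretize a gene pair into joint expression states
#'
#' Two schemes for turning a pair of continuous expression vectors into at
#' most `n_states^2` joint states:
#' \describe{
#'   \item{grid (default)}{the product of the two 1-D minimum-variance
#'     partitions ([discretize_1d()]). Because the joint partition refines
#'     both marginal partitions, the estimated joint mutual information can
#'     never fall below either marginal one, which makes the synergy score
#'     bounds (and the non-positivity of fully redundant pairs) hold by
#'     construction. Deterministic.}
#'   \item{cluster}{k-means on the standardized pairs into `n_states^2`
#'     clusters (10 restarts, seeded).}
#' }
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_states Number of marginal states (default 3, i.e. up to 9 joint
#'   states).
#' @param method `"grid"` or `"cluster"`.
#' @param seed Seed for the k-means restarts (ignored by `"grid"`).
#' @return Integer vector of joint state labels.
#' @export
discretize_2d <- function(x, y, n_states = 3,
                          method = c("grid", "cluster"), seed = 1) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (method == "grid") {
    sx <- discretize_1d(x, n_states)
    sy <- discretize_1d(y, n_states)
    joint <- (sx - 1L) * max(sy) + sy
    return(match(joint, sort(unique(joint))))
  }
  z <- cbind(std_or_zero(x), std_or_zero(y))
  pts <- unique(z)
  centers <- min(n_states^2, nrow(pts))
  if (centers == nrow(pts)) {
    return(match(paste(z[, 1], z[, 2]), paste(pts[, 1], pts[, 2])))
  }
  fit <- with_substream(seed, kmeans(z, centers = centers, nstart = 10,
                                     iter.max = 100))
  as.integer(fit$cluster)
}

std_or_zero <- function(v) {
  s <- sd(v)
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}
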