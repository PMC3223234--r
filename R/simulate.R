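#' Simulation configuration
#'
#' Describes a synthetic phenotype-labelled expression experiment mirroring
#' the three-condition (BSA control / palmitate / oleate) toxic-vs-nontoxic
#' design: background noise genes, planted cooperative gene pairs with a
#' gap, substitute or on/off joint pattern, individually phenotype-correlated
#' ("redundant") genes, metabolite-trend condition profiles, and planted
#' pathway memberships with an optional hub neighbor gene.
#'
#' Toxic samples are assigned to the palmitate (`PA`) condition; nontoxic
#' samples are split evenly between `BSA` and `OA`, mirroring the study
#' design where palmitate induces the toxic phenotype.
#'
#' @param n_genes Total number of genes.
#' @param n_toxic,n_nontoxic Samples per phenotype class.
#' @param pairs Optional data frame of planted pairs, one row each, with
#'   columns `pattern` (`"gap"`, `"substitute"`, `"onoff"`), `delta`
#'   (phenotype effect size, log2 units, `>= 0`) and `sigma_c2` (shared
#'   latent variance). Optional `gene1`/`gene2` columns pin the pair to
#'   specific gene ids; by default pairs take the first unassigned genes.
#' @param n_redundant Number of genes with an individual mean shift
#'   `redundant_delta` between phenotypes (marginally informative genes).
#' @param redundant_delta Mean shift (log2 units) for redundant genes.
#' @param pathways Optional list of planted pathways; each element is a list
#'   with `name`, `n_members` and logical `hub`. When `hub` is `TRUE` an
#'   extra (non-member) hub gene is planted whose pairing with every member
#'   follows the gap pattern, so the hub becomes a cooperative neighbor of
#'   the pathway in the reconstructed network.
#' @param pathway_delta,pathway_sigma_c2 Effect size and latent variance of
#'   the hub-member gap construction.
#' @param trends Metabolite-trend assignment: a character vector of trend
#'   codes (`"I"`–`"IV"`) named by gene id, or an unnamed vector of length
#'   `n_genes`. Assigned genes receive additive per-condition mean offsets
#'   realizing the trend (scaled by `trend_effect`).
#' @param trend_effect Scale of the trend condition offsets (log2 units).
#' @param noise_sd Standard deviation of i.i.d. measurement noise
#'   (log2 units, `> 0`).
#' @param seed Root seed; all randomness flows from it through fixed
#'   per-role substreams, so identical configurations reproduce bit-identical
#'   datasets.
#' @return A `sim_config` object.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 50, n_toxic = 30, n_nontoxic = 30,
                       pairs = NULL, n_redundant = 0, redundant_delta = 1,
                       pathways = NULL, pathway_delta = 2,
                       pathway_sigma_c2 = 4,
                       trends = NULL, trend_effect = 1,
                       noise_sd = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, n_toxic >= 1, n_nontoxic >= 1, noise_sd > 0,
            n_redundant >= 0, redundant_delta >= 0, pathway_delta >= 0,
            pathway_sigma_c2 >= 0)
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    req <- c("pattern", "delta", "sigma_c2")
    if (!all(req %in% names(pairs))) {
      abort("`pairs` needs columns pattern, delta, sigma_c2")
    }
    bad <- setdiff(unique(pairs$pattern), c("gap", "substitute", "onoff"))
    if (length(bad)) abort(paste0("unknown pair pattern: ", bad[1]))
    if (any(pairs$delta < 0)) abort("pair delta must be >= 0")
    if (any(pairs$sigma_c2 < 0)) abort("pair sigma_c2 must be >= 0")
  }
  if (!is.null(pathways)) {
    stopifnot(is.list(pathways))
    for (pw in pathways) {
      stopifnot(is.character(pw$name), pw$n_members >= 1)
    }
    if (anyDuplicated(vapply(pathways, `[[`, "", "name"))) {
      abort("duplicate pathway name in `pathways`")
    }
  }
  if (!is.null(trends)) {
    bad <- setdiff(unique(trends), c("I", "II", "III", "IV"))
    if (length(bad)) abort(paste0("unknown trend code: ", bad[1]))
    if (is.null(names(trends)) && length(trends) != n_genes) {
      abort("unnamed `trends` must have length n_genes")
    }
  }
  structure(list(n_genes = n_genes, n_toxic = n_toxic,
                 n_nontoxic = n_nontoxic, pairs = pairs,
                 n_redundant = n_redundant, redundant_delta = redundant_delta,
                 pathways = pathways, pathway_delta = pathway_delta,
                 pathway_sigma_c2 = pathway_sigma_c2,
                 trends = trends, trend_effect = trend_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted-pair specification helper
#'
#' Convenience constructor for the `pairs` argument of [sim_config()].
#' Defaults put gap/substitute pairs in the marginally-quiet regime the
#' patterns emulate: the shared latent variance dominates the squared
#' per-gene phenotype shift (`sigma_c2 >= 4 * (delta/2)^2`), so each gene
#' alone is a weak phenotype marker while the pair jointly separates the
#' classes.
#'
#' @param n Number of pairs.
#' @param pattern `"gap"`, `"substitute"` or `"onoff"` (recycled).
#' @param delta Phenotype effect size in log2 units (recycled).
#' @param sigma_c2 Shared latent variance (recycled).
#' @return A tibble suitable for `sim_config(pairs = ...)`.
#' @export
planted_pairs <- function(n = 5, pattern = "gap", delta = 2, sigma_c2 = 4) {
  tibble(pattern = rep_len(pattern, n),
         delta = rep_len(delta, n),
         sigma_c2 = rep_len(sigma_c2, n))
}

# per-condition mean offsets realizing each metabolite trend (unit scale);
# chosen so every required strict inequality holds with margin 1
trend_offsets <- function(code) {
  switch(code,
         I   = c(BSA = 0, PA = 1, OA = 0),
         II  = c(BSA = 1, PA = 0, OA = 1),
         III = c(BSA = 0, PA = 1, OA = 2),
         IV  = c(BSA = 2, PA = 1, OA = 0),
         abort(paste0("unknown trend code: ", code)))
}

#' Simulate a phenotype-labelled expression dataset
#'
#' Generates log2-scale expression under the design described by a
#' [sim_config()]. Gene roles are laid out deterministically: planted pair
#' members first, then redundant genes, then pathway members and hubs, then
#' i.i.d. background genes. Ground truth (role, pair id, pattern, pathway,
#' trend) is stored in the `genes` tibble of the returned dataset, and
#' planted pathway memberships are attached as a named list in
#' `attr(, "gene_sets")`.
#'
#' Planted patterns, with `s = +1` for toxic and `-1` for nontoxic samples,
#' shared latent `C ~ N(0, sigma_c2)` and noise `e ~ N(0, noise_sd^2)`:
#' \describe{
#'   \item{gap}{`G1 = C + s*delta/2 + e`, `G2 = C - s*delta/2 + e`: the genes
#'     are positively correlated and the phenotype separates along the
#'     difference axis while each marginal stays comparatively
#'     uninformative.}
#'   \item{substitute}{`G1 = C + s*delta/2 + e`, `G2 = -C + s*delta/2 + e`:
#'     negative correlation, separation along the sum axis.}
#'   \item{onoff}{nontoxic samples tightly around the joint origin
#'     (`N(0, 0.1 I)`), toxic samples uniform over an annulus of radius 2-3:
#'     both genes jointly silent in one phenotype, jointly active in the
#'     other.}
#' }
#'
#' @param config A [sim_config()].
#' @return An [expr_dataset()] with ground-truth gene annotation.
#' @examples
#' cfg <- sim_config(n_genes = 10,
#'                   pairs = data.frame(pattern = "gap", delta = 2, sigma_c2 = 1),
#'                   seed = 1)
#' ds <- simulate_dataset(cfg)
#' ds
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_s <- cfg$n_toxic + cfg$n_nontoxic
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_s))

  # toxic samples carry the palmitate condition; nontoxic split BSA/OA
  n_bsa <- ceiling(cfg$n_nontoxic / 2)
  samples <- tibble(
    sample_id = sample_ids,
    condition = c(rep("PA", cfg$n_toxic),
                  rep("BSA", n_bsa), rep("OA", cfg$n_nontoxic - n_bsa)),
    phenotype = c(rep("toxic", cfg$n_toxic), rep("nontoxic", cfg$n_nontoxic))
  )
  s_sign <- ifelse(samples$phenotype == "toxic", 1, -1)

  # --- gene role layout -------------------------------------------------
  role <- rep("background", cfg$n_genes)
  pair_id <- rep(NA_integer_, cfg$n_genes)
  pattern <- rep(NA_character_, cfg$n_genes)
  pathway <- rep(NA_character_, cfg$n_genes)
  names(role) <- gene_ids
  next_free <- 1L
  take <- function(k) {
    free <- which(role == "background" & seq_along(role) >= next_free)
    if (length(free) < k) abort("n_genes too small for the requested roles")
    free[seq_len(k)]
  }
  claim <- function(idx, what) {
    conflict <- idx[role[idx] != "background"]
    if (length(conflict)) {
      abort(paste0("conflicting gene-role assignment for gene ",
                   gene_ids[conflict[1]], " (already ",
                   role[conflict[1]], ", requested ", what, ")"))
    }
  }

  pair_rows <- if (is.null(cfg$pairs)) tibble() else cfg$pairs
  pair_members <- list()
  if (nrow(pair_rows)) {
    for (i in seq_len(nrow(pair_rows))) {
      if (all(c("gene1", "gene2") %in% names(pair_rows)) &&
          !is.na(pair_rows$gene1[i])) {
        idx <- match(c(pair_rows$gene1[i], pair_rows$gene2[i]), gene_ids)
        if (anyNA(idx)) abort("planted pair names an unknown gene")
        claim(idx, "planted pair")
      } else {
        idx <- take(2)
      }
      role[idx] <- "pair"
      pair_id[idx] <- i
      pattern[idx] <- pair_rows$pattern[i]
      pair_members[[i]] <- idx
    }
  }
  if (cfg$n_redundant > 0) {
    idx <- take(cfg$n_redundant)
    claim(idx, "redundant")
    role[idx] <- "redundant"
  }
  gene_sets <- list()
  hub_of <- character()
  if (!is.null(cfg$pathways)) {
    for (pw in cfg$pathways) {
      m_idx <- take(pw$n_members)
      role[m_idx] <- "pathway_member"
      pathway[m_idx] <- pw$name
      gene_sets[[pw$name]] <- gene_ids[m_idx]
      if (isTRUE(pw$hub)) {
        h_idx <- take(1)
        role[h_idx] <- "pathway_hub"
        pathway[h_idx] <- pw$name
        hub_of[pw$name] <- gene_ids[h_idx]
      }
    }
  }

  # --- trend assignment -------------------------------------------------
  trend <- rep(NA_character_, cfg$n_genes)
  if (!is.null(cfg$trends)) {
    if (is.null(names(cfg$trends))) {
      trend <- as.character(cfg$trends)
    } else {
      idx <- match(names(cfg$trends), gene_ids)
      if (anyNA(idx)) {
        abort(paste0("trend assigned to unknown gene: ",
                     names(cfg$trends)[is.na(idx)][1]))
      }
      trend[idx] <- unname(cfg$trends)
    }
  }

  # --- expression -------------------------------------------------------
  # base measurement noise for every gene (background role = noise only)
  values <- with_substream(cfg$seed + 11L, {
    matrix(rnorm(cfg$n_genes * n_s, sd = cfg$noise_sd),
           nrow = cfg$n_genes, dimnames = list(gene_ids, sample_ids))
  })

  if (nrow(pair_rows)) {
    values <- with_substream(cfg$seed + 13L, {
      for (i in seq_len(nrow(pair_rows))) {
        idx <- pair_members[[i]]
        d <- pair_rows$delta[i]
        v <- pair_rows$sigma_c2[i]
        pat <- pair_rows$pattern[i]
        if (pat == "onoff") {
          # joint silent state vs dispersed active state; base noise replaced
          quiet <- matrix(rnorm(2 * n_s, sd = sqrt(0.1)), nrow = 2)
          r <- sqrt(runif(n_s, 4, 9))
          th <- runif(n_s, 0, 2 * pi)
          loud <- rbind(r * cos(th), r * sin(th))
          on <- if (d > 0) s_sign > 0 else rep(FALSE, n_s)
          values[idx, ] <- quiet
          values[idx[1], on] <- loud[1, on]
          values[idx[2], on] <- loud[2, on]
        } else {
          C <- rnorm(n_s, sd = sqrt(v))
          values[idx[1], ] <- values[idx[1], ] + C + s_sign * d / 2
          if (pat == "gap") {
            # positive correlation, phenotype on the difference axis
            values[idx[2], ] <- values[idx[2], ] + C - s_sign * d / 2
          } else {
            # negative correlation, phenotype on the sum axis
            values[idx[2], ] <- values[idx[2], ] - C + s_sign * d / 2
          }
        }
      }
      values
    })
  }

  if (cfg$n_redundant > 0) {
    idx <- which(role == "redundant")
    values[idx, ] <- values[idx, , drop = FALSE] +
      matrix(rep(s_sign * cfg$redundant_delta / 2, each = length(idx)),
             nrow = length(idx))
  }

  if (length(hub_of)) {
    values <- with_substream(cfg$seed + 19L, {
      for (pw_name in names(hub_of)) {
        h <- match(hub_of[pw_name], gene_ids)
        m <- match(gene_sets[[pw_name]], gene_ids)
        C <- rnorm(n_s, sd = sqrt(cfg$pathway_sigma_c2))
        # every hub-member pair is a gap pair sharing the hub's latent level
        values[h, ] <- values[h, ] + C + s_sign * cfg$pathway_delta / 2
        values[m, ] <- values[m, , drop = FALSE] +
          matrix(rep(C - s_sign * cfg$pathway_delta / 2, each = length(m)),
                 nrow = length(m))
      }
      values
    })
  }

  assigned <- which(!is.na(trend))
  for (i in assigned) {
    off <- trend_offsets(trend[i]) * cfg$trend_effect
    values[i, ] <- values[i, ] + off[samples$condition]
  }

  genes <- tibble(gene_id = gene_ids, role = unname(role),
                  pair_id = pair_id, pattern = pattern,
                  pathway = pathway, trend = trend)
  ds <- expr_dataset(values, samples, genes)
  attr(ds, "gene_sets") <- if (length(gene_sets)) gene_sets else NULL
  attr(ds, "config") <- cfg
  ds
}

#' Simulate a network with a planted pathway hub
#'
#' Network-level testbed for pathway-neighbor association ranking: an
#' Erdos-Renyi background graph in which a designated pathway gene set is
#' embedded, plus one planted hub gene adjacent to a fixed number of pathway
#' genes and only a few others. Chance neighbors of the pathway acquire
#' comparable pathway adjacency but higher overall degree, so the hub should
#' rank first by the hypergeometric association test (low degree, same
#' overlap) -- the structure a top-neighbor
#' association analysis is meant to detect.
#'
#' The background graph is kept sparse (default mean degree about 2.4) so
#' that adjacency to three or more pathway genes essentially only arises by
#' planting, mirroring the reported regime where over 90 percent of a
#' pathway's network neighbors touch at most two of its genes.
#'
#' @param n_genes Background graph size (pathway genes included).
#' @param n_pathway Number of pathway genes.
#' @param edge_prob Erdos-Renyi edge probability of the background graph.
#' @param hub_connections Planted hub-to-pathway edges.
#' @param hub_extra Planted hub edges to non-pathway genes.
#' @param seed Seed.
#' @return A list with `network` (a `gene_network`), `pathway_genes`, and
#'   `hub` (the planted hub's gene id).
#' @export
simulate_hub_network <- function(n_genes = 60, n_pathway = 10,
                                 edge_prob = 0.04, hub_connections = 3,
                                 hub_extra = 1, seed = 1) {
  stopifnot(n_pathway + 1 < n_genes, hub_connections <= n_pathway)
  ids <- sprintf("g%03d", seq_len(n_genes + 1L))
  hub <- ids[n_genes + 1L]
  pathway_genes <- ids[seq_len(n_pathway)]
  g <- with_substream(seed, {
    base <- igraph::sample_gnp(n_genes, edge_prob)
    igraph::V(base)$name <- ids[seq_len(n_genes)]
    base <- igraph::add_vertices(base, 1, name = hub)
    to <- c(sample(pathway_genes, hub_connections),
            sample(ids[(n_pathway + 1):n_genes], hub_extra))
    igraph::add_edges(base, as.vector(rbind(hub, to)))
  })
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  list(network = new_gene_network(g, type = "simulated"),
       pathway_genes = intersect(pathway_genes, igraph::V(g)$name),
       hub = hub)
}

#' Write a dataset and gene sets as plain-text fixture files
#'
#' Writes the expression matrix (TSV, first column `gene_id`, one column per
#' sample), the sample metadata (TSV: `sample_id`, `condition`, `phenotype`)
#' and, when available, the gene sets (GMT). Round-trips losslessly through
#' [read_expression()] / [read_gmt()].
#'
#' @param dataset An `expr_dataset`.
#' @param dir Output directory (created if missing).
#' @param gene_sets Named list of gene sets; defaults to the simulator's
#'   planted sets attached to `dataset`, if any.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(dataset, dir, gene_sets = attr(dataset, "gene_sets")) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_expression(dataset, paths[["expression"]], paths[["samples"]])
  if (!is.null(gene_sets)) {
    paths[["gene_sets"]] <- file.path(dir, "gene_sets.gmt")
    write_gmt(gene_sets, paths[["gene_sets"]])
  }
  invisible(paths)
}
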