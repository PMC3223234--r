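make_ds <- function(values, cond, ph = NULL) {
  if (is.null(ph)) ph <- ifelse(cond == "PA", "toxic", "nontoxic")
  expr_dataset(values,
               tibble::tibble(sample_id = sprintf("s%02d", seq_along(cond)),
                              condition = cond, phenotype = ph))
}

test_that("preprocess averages probes, logs, and drops blacklisted genes", {
  cond <- rep(c("BSA", "PA", "OA"), each = 2)
  vals <- rbind(p1 = 2^(1:6), p2 = 2^(2:7), p3 = 2^(4:9))
  ds <- make_ds(vals, cond)
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("gA", "gA", "gB"))
  out <- preprocess(ds, probe_map = pm, log2_transform = TRUE)
  # log2 rows: p1 = 1..6, p2 = 2..7 -> gA averages to 1.5..6.5; gB = p3
  expect_equal(unname(out$values["gA", ]), (1:6) + 0.5)
  expect_equal(unname(out$values["gB", 2]), 5)
  # identity map leaves the matrix unchanged (row order by gene id)
  idm <- data.frame(probe_id = rownames(vals), gene_id = rownames(vals))
  out2 <- preprocess(ds, probe_map = idm)
  expect_equal(out2$values[rownames(vals), ], ds$values)
  # blacklist
  out3 <- preprocess(ds, drop_genes = "p2")
  expect_setequal(rownames(out3$values), c("p1", "p3"))
  # non-positive values cannot be logged, error names the cell
  vals[2, 3] <- 0
  expect_error(preprocess(make_ds(vals, cond), log2_transform = TRUE),
               "non-positive value at gene p2")
})

test_that("trend matching implements the four strict orderings", {
  expect_identical(match_trend(1, 2, 3), "III")
  expect_identical(match_trend(1, 3, 2), "I")
  expect_identical(match_trend(3, 1, 2), "II")
  expect_identical(match_trend(3, 2, 1), "IV")
  expect_identical(match_trend(2, 2, 3), NA_character_)
  expect_identical(match_trend(2, 2, 2), NA_character_)
  # vectorized, and mutually exclusive over a mean grid
  g <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  codes <- match_trend(g$a, g$b, g$c)
  hit <- vapply(seq_len(nrow(g)), function(i) {
    sum(c(g$a[i] < g$b[i] & g$b[i] > g$c[i],
          g$a[i] > g$b[i] & g$b[i] < g$c[i],
          g$a[i] < g$b[i] & g$b[i] < g$c[i],
          g$a[i] > g$b[i] & g$b[i] > g$c[i]))
  }, 0)
  expect_true(all(hit <= 1))
  expect_identical(!is.na(codes), hit == 1)
  # tolerance band turns near-ties into no-match
  expect_identical(match_trend(1, 1.05, 0, tol = 0.1), NA_character_)
  expect_identical(match_trend(1, 1.05, 0, tol = 0), "I")
})

test_that("selection keeps trend-matched differentially expressed genes", {
  cond <- rep(c("BSA", "PA", "OA"), each = 10)
  set.seed(5)
  strong <- rnorm(30, mean = rep(c(0, 3, 0), each = 10), sd = 0.1)
  flat <- rep(1, 30)
  noise <- rnorm(30, sd = 0.1)
  vals <- rbind(strong = strong, flat = flat, noise = noise)
  ds <- make_ds(vals, cond)
  rep_tbl <- select_genes(ds, alpha = 0.05)
  expect_true(rep_tbl$kept[rep_tbl$gene == "strong"])
  expect_identical(rep_tbl$trend[rep_tbl$gene == "strong"], "I")
  # oracle: direct Welch t-test on the same split
  expect_equal(rep_tbl$p_BSA_PA[rep_tbl$gene == "strong"],
               t.test(strong[1:10], strong[11:20])$p.value)
  expect_false(rep_tbl$kept[rep_tbl$gene == "flat"])
  # alpha = 0 keeps nothing
  expect_equal(sum(select_genes(ds, alpha = 0)$kept), 0)
})

test_that("selection is invariant to gene and sample order and monotone in alpha", {
  ds <- simulate_dataset(sim_config(n_genes = 30, n_toxic = 15,
                                    n_nontoxic = 15,
                                    trends = rep(c("I", "IV", NA), 10)[1:30] |>
                                      (\(x) replace(x, is.na(x), "II"))(),
                                    trend_effect = 0.4, seed = 8))
  r1 <- select_genes(ds, alpha = 0.2)
  # permute genes and samples
  gp <- sample(nrow(ds$values)); sp <- sample(ncol(ds$values))
  ds2 <- expr_dataset(ds$values[gp, sp], ds$samples[sp, ])
  r2 <- select_genes(ds2, alpha = 0.2)
  r2 <- r2[match(r1$gene, r2$gene), ]
  expect_equal(r1$kept, r2$kept)
  expect_equal(r1$p_BSA_PA, r2$p_BSA_PA)
  # monotone: raising alpha never shrinks the kept set
  k1 <- r1$gene[r1$kept]
  k0 <- with(select_genes(ds, alpha = 0.01), gene[kept])
  expect_true(all(k0 %in% k1))
})

test_that("trend-assigned genes with strong condition effects are recalled", {
  recall <- vapply(1:5, function(seed) {
    trends <- rep(c("I", "II", "III", "IV"), 5)
    ds <- simulate_dataset(sim_config(n_genes = 40, n_toxic = 15,
                                      n_nontoxic = 15,
                                      trends = c(setNames(trends,
                                                          sprintf("g%03d", 1:20))),
                                      seed = seed))
    rep_tbl <- select_genes(ds)
    mean(rep_tbl$kept[1:20])
  }, 1)
  expect_gte(mean(recall), 0.9)
})

test_that("a condition with fewer than two samples is an error", {
  cond <- c("BSA", "PA", "PA", "OA", "OA")
  vals <- matrix(rnorm(10), 2, 5, dimnames = list(c("a", "b"), NULL))
  expect_error(select_genes(make_ds(vals, cond)), "BSA.*fewer than 2")
})
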