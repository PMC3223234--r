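test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- sim_config(n_genes = 20, n_toxic = 10, n_nontoxic = 10,
                    pairs = planted_pairs(2, c("gap", "onoff")),
                    n_redundant = 2, trends = c(g015 = "III"), seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$samples, d2$samples)
  d3 <- simulate_dataset(sim_config(n_genes = 20, n_toxic = 10,
                                    n_nontoxic = 10, seed = 43))
  expect_false(identical(d1$values, d3$values))
})

test_that("sample layout ties toxic samples to the palmitate condition", {
  ds <- simulate_dataset(sim_config(n_genes = 5, n_toxic = 12,
                                    n_nontoxic = 11, seed = 1))
  s <- ds$samples
  expect_setequal(unique(s$condition[s$phenotype == "toxic"]), "PA")
  expect_setequal(unique(s$condition[s$phenotype == "nontoxic"]),
                  c("BSA", "OA"))
  expect_equal(sum(s$phenotype == "toxic"), 12)
  expect_equal(nrow(s), 23)
})

test_that("gap pairs separate on the difference axis, not the marginals", {
  # oracle: direct Welch t statistics on the generated samples
  for (seed in 1:5) {
    cfg <- sim_config(n_genes = 50,
                      pairs = tibble::tibble(pattern = "gap", delta = 2,
                                             sigma_c2 = 1)[rep(1, 5), ],
                      noise_sd = 0.3, seed = seed)
    ds <- simulate_dataset(cfg)
    tox <- ds$samples$phenotype == "toxic"
    for (pr in planted_gene_ids(ds)) {
      g1 <- ds$values[pr[1], ]; g2 <- ds$values[pr[2], ]
      t_diff <- welch_t_abs((g1 - g2)[tox], (g1 - g2)[!tox])
      t_m1 <- welch_t_abs(g1[tox], g1[!tox])
      t_m2 <- welch_t_abs(g2[tox], g2[!tox])
      expect_gt(t_diff, t_m1)
      expect_gt(t_diff, t_m2)
    }
  }
})

test_that("at the default latent variance the marginals are much weaker than the joint axis", {
  # marginal near-uninformativeness regime: sigma_c2 >= 4 * (delta/2)^2
  ratios <- vapply(1:20, function(seed) {
    ds <- simulate_dataset(sim_config(n_genes = 2,
                                      pairs = planted_pairs(1), seed = seed))
    tox <- ds$samples$phenotype == "toxic"
    g1 <- ds$values[1, ]; g2 <- ds$values[2, ]
    t_diff <- welch_t_abs((g1 - g2)[tox], (g1 - g2)[!tox])
    t_marg <- max(welch_t_abs(g1[tox], g1[!tox]),
                  welch_t_abs(g2[tox], g2[!tox]))
    t_diff / t_marg
  }, 1)
  expect_true(all(ratios > 2))
  expect_gt(median(ratios), 4)
})

test_that("zero effect size yields a phenotype-null dataset", {
  cfg <- sim_config(n_genes = 10,
                    pairs = planted_pairs(3, c("gap", "substitute", "onoff"),
                                          delta = 0),
                    seed = 7)
  ds <- simulate_dataset(cfg)
  sc <- synergy_scan(ds, B = 100, seed = 11)
  expect_equal(sum(sc$pairs$p_adj < 0.05 & sc$pairs$syn > 0), 0)
})

test_that("on/off pairs are jointly silent in one phenotype and dispersed in the other", {
  ds <- simulate_dataset(sim_config(n_genes = 2,
                                    pairs = planted_pairs(1, "onoff"),
                                    seed = 3))
  tox <- ds$samples$phenotype == "toxic"
  radius <- sqrt(ds$values[1, ]^2 + ds$values[2, ]^2)
  expect_true(all(radius[tox] >= 2 & radius[tox] <= 3))
  expect_lt(max(radius[!tox]), 2)
})

test_that("trend-assigned genes realize their condition ordering", {
  # trend fidelity: >= 95% of assigned genes satisfy the strict inequalities
  hits <- unlist(lapply(1:5, function(seed) {
    trends <- rep(c("I", "II", "III", "IV"), each = 10)
    ds <- simulate_dataset(sim_config(n_genes = 40, n_toxic = 20,
                                      n_nontoxic = 20, trends = trends,
                                      seed = seed))
    cond <- ds$samples$condition
    m <- vapply(c("BSA", "PA", "OA"), function(cc) {
      rowMeans(ds$values[, cond == cc, drop = FALSE])
    }, numeric(40))
    match_trend(m[, "BSA"], m[, "PA"], m[, "OA"]) == trends
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("conflicting explicit gene-role assignments are rejected by name", {
  pr <- tibble::tibble(pattern = c("gap", "gap"), delta = 2, sigma_c2 = 4,
                       gene1 = c("g001", "g002"), gene2 = c("g002", "g003"))
  expect_error(simulate_dataset(sim_config(n_genes = 10, pairs = pr)),
               "g002")
  expect_error(
    simulate_dataset(sim_config(n_genes = 3, pairs = planted_pairs(2))),
    "n_genes too small")
})

test_that("fixtures round-trip through the io layer and stay small", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 50, n_toxic = 10, n_nontoxic = 10,
                    pathways = list(list(name = "PW1", n_members = 4,
                                         hub = TRUE)),
                    seed = 2)
  ds <- simulate_dataset(cfg)
  paths <- write_fixture(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_lt(sum(file.size(paths)), 1e6)
  back <- read_expression(paths[["expression"]], paths[["samples"]])
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_equal(back$samples, ds$samples)
  sets <- read_gmt(paths[["gene_sets"]])
  expect_identical(sets$PW1, attr(ds, "gene_sets")$PW1)
})
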