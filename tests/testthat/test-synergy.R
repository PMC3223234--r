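test_that("normalized mutual information matches the direct double-sum", {
  expect_equal(mutual_information(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_equal(mutual_information(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(mutual_information(matrix(c(30, 10, 10, 30), 2)),
               0.18872, tolerance = 1e-4)
  set.seed(10)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    tab <- matrix(rpois(2 * k, 4), k, 2)
    if (any(colSums(tab) == 0) || sum(tab) == 0) next
    a <- mutual_information(tab)
    b <- mi_oracle(tab)
    expect_lt(abs(a - b), 1e-12 * max(1, abs(b)))
  }
  expect_error(mutual_information(matrix(c(3, 4, 0, 0), 2)),
               "degenerate phenotype")
})

test_that("fully redundant pairs never score positive synergy", {
  set.seed(11)
  ph <- rep(c("toxic", "nontoxic"), each = 20)
  for (rep in 1:10) {
    g <- rnorm(40) + 2 * (ph == "toxic") * runif(1)
    s <- synergy_score(g, g, ph)
    expect_equal(s$I12, s$I1)
    expect_equal(s$syn, -s$I2)
    expect_lte(s$syn, 0)
  }
})

test_that("phenotype-independent pairs have mean synergy near zero", {
  # oracle: Monte-Carlo null distribution across 200 re-draws
  set.seed(12)
  ph <- rep(c("toxic", "nontoxic"), each = 30)
  syn <- replicate(200, synergy_score(rnorm(60), rnorm(60), ph)$syn)
  se <- sd(syn) / sqrt(length(syn))
  # plug-in estimation biases the joint MI upward more than the marginals,
  # so the null mean sits slightly above zero; 3 SE around the bias-free
  # value must still cover it once the analytic Miller-Madow offset
  # (extra joint cells vs marginal cells) / (2 n ln 2) is removed
  bias <- (8 - 2 - 2) / (2 * 60 * log(2))
  expect_lt(abs(mean(syn) - bias), 3 * se + 0.02)
  expect_true(all(syn >= -1 & syn <= 1))
})

test_that("planted gap pairs score positive synergy across seeds", {
  gap_syn <- function(sigma_c2) {
    vapply(1:20, function(seed) {
      ds <- simulate_dataset(sim_config(n_genes = 2,
                                        pairs = planted_pairs(1, "gap",
                                                              delta = 2,
                                                              sigma_c2 = sigma_c2),
                                        seed = seed))
      synergy_score(ds$values[1, ], ds$values[2, ],
                    ds$samples$phenotype)$syn
    }, 1)
  }
  # marginally-quiet regime (sigma_c2 >= delta^2): synergy always positive
  quiet <- gap_syn(4)
  expect_true(all(quiet > 0))
  # marginally-informative regime (sigma_c2 = 1): the joint axis still wins
  # on average, but individual seeds can dip to zero
  loud <- gap_syn(1)
  expect_gt(mean(loud), 0)
  expect_gt(mean(loud > 0), 0.5)
})

test_that("every estimate respects the normalization bounds", {
  for (seed in 1:5) {
    ds <- simulate_dataset(sim_config(
      n_genes = 12, pairs = planted_pairs(3, c("gap", "substitute", "onoff")),
      n_redundant = 2, seed = seed))
    sc <- synergy_scan(ds, B = 20, seed = seed)
    p <- sc$pairs
    expect_true(all(p$I1 >= 0 & p$I1 <= 1))
    expect_true(all(p$I2 >= 0 & p$I2 <= 1))
    expect_true(all(p$I12 >= 0 & p$I12 <= 1))
    expect_true(all(p$syn >= -1 & p$syn <= 1))
    expect_true(all(p$I12 >= pmax(p$I1, p$I2) - 1e-10))
    expect_true(all(p$p_adj >= p$p_raw))
  }
})

test_that("permutation p-values hit their extreme-case values", {
  # a planted pair that beats every permutation sits at the p floor
  ds <- simulate_dataset(sim_config(n_genes = 2, pairs = planted_pairs(1),
                                    seed = 6))
  strong <- permutation_test(ds$values[1, ], ds$values[2, ],
                             ds$samples$phenotype, B = 99, seed = 2)
  expect_gt(strong$syn, 0)
  expect_equal(strong$p_raw, 1 / 100)
  # identical separated vectors: observed synergy is minimal, p = 1
  ph <- rep(c("toxic", "nontoxic"), each = 15)
  g1 <- withr::with_seed(8, c(rnorm(15, 5), rnorm(15, -5)))
  flat <- permutation_test(g1, g1, ph, B = 99, seed = 2)
  expect_equal(flat$p_raw, 1)
})

test_that("permuting labels beforehand reproduces the null scores", {
  # exchangeability: the identity column of a pre-permuted run equals the
  # corresponding permutation column of the original run
  ds <- null_dataset(4, seed = 21, n_toxic = 10, n_nontoxic = 10)
  g1 <- ds$values[1, ]; g2 <- ds$values[2, ]
  ph <- ds$samples$phenotype
  perm <- withr::with_seed(33, sample(seq_along(ph)))
  obs_perm <- permutation_test(g1, g2, ph[perm], B = 1, seed = 5)
  obs_orig <- permutation_test(g1, g2, ph, B = 1, seed = 5)
  # same pair, same discretization: only the labels moved, so both runs
  # draw their synergy values from the same exchangeable null
  s12 <- discretize_2d(g1, g2)
  s1 <- discretize_1d(g1); s2 <- discretize_1d(g2)
  mi_of <- function(labels) {
    mutual_information(table(s12, labels)) -
      mutual_information(table(s1, labels)) -
      mutual_information(table(s2, labels))
  }
  expect_equal(obs_perm$syn, mi_of(ph[perm]))
  expect_equal(obs_orig$syn, mi_of(ph))
})

test_that("BH adjustment matches the direct step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("planted joint patterns are recognized", {
  hits <- sapply(1:20, function(seed) {
    ds <- simulate_dataset(sim_config(
      n_genes = 6, pairs = planted_pairs(3, c("gap", "substitute", "onoff")),
      seed = seed))
    ph <- ds$samples$phenotype
    v <- ds$values
    c(classify_pattern(v[1, ], v[2, ], ph) == "gap",
      classify_pattern(v[3, ], v[4, ], ph) == "substitute",
      classify_pattern(v[5, ], v[6, ], ph) == "onoff")
  })
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
  expect_gte(mean(hits[3, ]), 0.9)
})

test_that("network assembly keeps only significant positive-synergy pairs", {
  res <- tibble::tibble(gene1 = c("a", "a", "b", "c"),
                        gene2 = c("b", "c", "c", "d"),
                        syn = c(0.5, -0.3, 0.2, 0.4),
                        p_adj = c(0.01, 0.001, 0.2, 0.04))
  net <- build_network(res, alpha = 0.05)
  expect_setequal(edge_keys(net), c("a|b", "c|d"))
  expect_setequal(network_genes(net), c("a", "b", "c", "d"))
  # isolated genes never appear
  net2 <- build_network(res[1, ], alpha = 0.05)
  expect_setequal(network_genes(net2), c("a", "b"))
  # no significant pair: empty network
  net3 <- build_network(dplyr::mutate(res, p_adj = 1), alpha = 0.05)
  expect_equal(igraph::ecount(net3$graph), 0)
  # duplicate pairs are rejected whatever the order
  dup <- tibble::tibble(gene1 = c("a", "b"), gene2 = c("b", "a"),
                        syn = 0.1, p_adj = 0.01)
  expect_error(build_network(dup), "duplicate gene pair")
})

test_that("topology report contrasts the degree sequence with a size-matched random graph", {
  star <- tibble::tibble(gene1 = "hub", gene2 = sprintf("leaf%02d", 1:10),
                         syn = 0.5, p_adj = 0.01)
  net <- build_network(star, alpha = 0.05)
  rep <- topology_report(net, seed = 4)
  h <- dplyr::filter(rep$histogram, graph == "network")
  expect_equal(h$n[h$degree == 10], 1)
  expect_equal(h$n[h$degree == 1], 10)
  expect_gt(rep$ks_statistic, 0)

  # an ER graph compared against an identically-seeded ER replica: KS = 0
  g <- withr::with_seed(6, igraph::sample_gnm(20, 60))
  igraph::V(g)$name <- sprintf("g%02d", 1:20)
  el <- igraph::as_edgelist(g)
  er_net <- build_network(tibble::tibble(gene1 = el[, 1], gene2 = el[, 2],
                                         syn = 0.1, p_adj = 0.01))
  expect_equal(topology_report(er_net, seed = 6)$ks_statistic, 0)

  empty <- build_network(dplyr::mutate(star, p_adj = 1))
  expect_error(topology_report(empty), "empty network")
})

test_that("scan results expose tidy, glance and plots", {
  ds <- simulate_dataset(sim_config(n_genes = 8,
                                    pairs = planted_pairs(2), seed = 14))
  sc <- synergy_scan(ds, B = 50, seed = 3)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), choose(8, 2))
  gl <- glance(sc)
  expect_equal(gl$n_pairs, 28)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(plot_pair(ds, "g001", "g002"), "ggplot")
})
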