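test_that("all_pairs enumerates C(n,2) records and matches the naive reference", {
  x4 <- random_expr(4, 12, seed = 31)
  expect_equal(nrow(all_pairs(x4)), 6)

  x <- random_expr(12, 20, seed = 32, zeros = 6)
  got <- all_pairs(x)
  ref <- oracle_all_pairs(x)
  expect_equal(nrow(got), 66)
  expect_equal(got$gene_a, ref$gene_a)
  expect_equal(got$gene_b, ref$gene_b)
  for (col in c("cv_ab", "cv_ba", "delta_cv", "mean_ab", "mean_ba",
                "pearson_r", "pearson_r2", "spearman_r2", "mi")) {
    expect_equal(got[[col]], ref[[col]], tolerance = 1e-10, label = col)
  }
  expect_equal(got$n_used, ref$n_used)
  expect_equal(got$ra_evaluable, ref$ra_evaluable)

  # determinism: identical input, identical table
  expect_identical(tidy(all_pairs(x)), tidy(got))
  # block size must not affect the result
  expect_equal(tidy(all_pairs(x, block_size = 3L)), tidy(got))

  expect_error(all_pairs(x[1, ]), "two genes")
})

test_that("rank_pairs orders deterministically per method and gates RA", {
  fx <- generate_fixture(n_samples = 50, n_ratiometric = 3, n_wide = 3,
                         n_two_regime = 0, n_independent = 10, seed = 33)
  pt <- all_pairs(fx$matrix)
  ra <- rank_pairs(pt, "RA")
  cfg <- measure_config()
  expect_lte(nrow(ra), nrow(pt))
  expect_true(all(ra$delta_cv < cfg$delta_cv_threshold))
  expect_true(!is.unsorted(ra$stability))
  # the planted proportional pairs head the RA list
  expect_true(all(grepl("^RAT", ra$gene_a[1:3])))

  pe <- rank_pairs(pt, "PE")
  expect_true(!is.unsorted(-pe$pearson_r2))
  mi <- rank_pairs(pt, "MI")
  expect_true(!is.unsorted(-mi$mi))

  # sorting the brute-force table gives the same order
  ref <- oracle_all_pairs(fx$matrix)
  ref_pe <- ref[order(-ref$pearson_r2, -abs(ref$pearson_r), ref$gene_a, ref$gene_b), ]
  expect_equal(pe$gene_a, ref_pe$gene_a)
  expect_equal(pe$gene_b, ref_pe$gene_b)
})

test_that("stringency sweeps are nested with edge counts matching direct enumeration", {
  x <- random_expr(10, 24, seed = 34)
  pt <- all_pairs(x)
  for (method in c("PE", "MI", "SP")) {
    sw <- stringency_sweep(pt, method, n_steps = 50)
    stat <- switch(method, PE = pt$pearson_r2, SP = pt$spearman_r2, MI = pt$mi)
    hi <- switch(method, PE = 1, SP = 1, MI = 2)
    for (i in c(1, 10, 25, 50)) {
      thr <- hi * (1 - i / 50)
      expect_equal(sw$steps$n_edges[i], sum(stat >= thr),
                   label = paste(method, "step", i))
      g <- graph_at(sw, i)
      expect_equal(nrow(g), sw$steps$n_edges[i])
      expect_equal(length(graph_vertices(g)), sw$steps$n_vertices[i])
    }
    # nestedness: sizes non-decreasing as thresholds relax
    expect_true(!is.unsorted(sw$steps$n_edges))
    expect_true(!is.unsorted(sw$steps$n_vertices))
  }
  # final PE step accepts every pair (R^2 >= 0)
  sw <- stringency_sweep(pt, "PE")
  expect_equal(sw$steps$n_edges[100], nrow(pt))

  # RA delta-CV sweep against direct counting
  swra <- stringency_sweep(pt, "RA", n_steps = 50, ra_sweep_mode = "delta_cv")
  for (i in c(5, 25, 50)) {
    expect_equal(swra$steps$n_edges[i],
                 sum(pt$ra_evaluable & pt$delta_cv <= i / 50, na.rm = TRUE))
  }
  # gated-CV sweep only ever contains gate-passing pairs
  swg <- stringency_sweep(pt, "RA", ra_sweep_mode = "gated_cv")
  expect_equal(swg$steps$n_edges[100],
               sum(pt$ra_evaluable & pt$delta_cv < measure_config()$delta_cv_threshold,
                   na.rm = TRUE))
})

test_that("inclusion profile reports percentages and the coverage step", {
  x <- random_expr(10, 24, seed = 35)
  pt <- all_pairs(x)
  sw <- stringency_sweep(pt, "PE")
  prof <- inclusion_profile(sw, total_genes = 10, target_percent = 95)
  expect_equal(prof$percent_genes, 100 * prof$n_vertices / 10)
  expect_equal(prof$percent_genes[100], 100)   # all genes enter at R^2 >= 0
  cs <- attr(prof, "coverage_step")
  expect_true(prof$percent_genes[cs] >= 95)
  expect_true(cs == 1 || prof$percent_genes[cs - 1] < 95)
})

test_that("method overlap partitions match explicit set algebra", {
  g1 <- tibble::tibble(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"))
  same <- method_overlap(list(RA = g1, PE = g1, MI = g1), match_on = "pairs")
  expect_equal(same$count[same$region == "RA&PE&MI"], 3)
  expect_equal(sum(same$count), 3)
  expect_equal(sum(same$fraction), 1)

  g2 <- tibble::tibble(gene_a = c("e", "f"), gene_b = c("f", "g"))
  g3 <- tibble::tibble(gene_a = "x", gene_b = "y")
  disj <- method_overlap(list(RA = g1, PE = g2, MI = g3), match_on = "pairs")
  expect_equal(disj$count[grepl("&", disj$region)], rep(0, 4))
  expect_equal(sum(disj$count), 6)

  # mixed case checked against explicit sets, on genes
  mix <- method_overlap(list(RA = g1, PE = g2, MI = g1), match_on = "genes")
  v1 <- c("a", "b", "c", "d"); v2 <- c("e", "f", "g")
  expect_equal(mix$count[mix$region == "RA&MI"], length(v1))
  expect_equal(mix$count[mix$region == "PE"], length(v2))
  expect_equal(sum(mix$count), length(union(v1, v2)))
})

test_that("the measure correlation grid is symmetric with unit diagonal", {
  x <- random_expr(15, 30, seed = 36)
  pt <- all_pairs(x)
  cm <- measure_correlation_matrix(pt)
  expect_equal(dim(cm), c(6, 6))
  expect_equal(diag(cm), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_equal(cm["I", "R2"], cor(pt$mi, pt$pearson_r2))
  # duplicated statistics correlate perfectly
  pt2 <- pt
  pt2$mi <- pt2$pearson_r2
  expect_equal(measure_correlation_matrix(pt2)["I", "R2"], 1)
})

test_that("invariance diagnostic relates gene CV to best pair stability", {
  fx <- generate_fixture(n_samples = 80, n_ratiometric = 10, n_wide = 0,
                         n_two_regime = 0, n_independent = 10, seed = 37)
  pt <- all_pairs(fx$matrix)
  diag <- invariance_diagnostic(fx$matrix, pt, top_k = 10)
  expect_equal(nrow(diag), 10)
  expect_true(!is.unsorted(diag$best_stability))

  # direct recomputation of both quantities for the reported genes
  v <- as.matrix(fx$matrix[-1]); rownames(v) <- fx$matrix$gene_id
  ra <- rank_pairs(pt, "RA")
  for (i in c(1, 5, 10)) {
    g <- diag$gene_id[i]
    expect_equal(diag$gene_cv[i], sd(v[g, ]) / mean(v[g, ]))
    expect_equal(diag$best_stability[i],
                 min(ra$stability[ra$gene_a == g | ra$gene_b == g]))
  }
  r2 <- attr(diag, "r_squared")
  expect_equal(r2, cor(diag$gene_cv, diag$best_stability)^2)
  expect_error(invariance_diagnostic(fx$matrix, pt, top_k = 1e6), "top_k")
})

test_that("two-regime pairs are flagged while homogeneous correlated pairs are not", {
  set.seed(38)
  b <- rlnorm(100, log(100), 0.5)
  a <- 2 * b * (1 + rnorm(100, 0, 0.05))
  expect_false(two_regime_flag(a, b)$flagged)

  # 90 near-independent low samples plus 10 jointly high ones
  a2 <- rlnorm(100, log(10), 0.3)
  b2 <- rlnorm(100, log(10), 0.3)
  a2[1:10] <- 500 * exp(rnorm(10, 0, 0.05))
  b2[1:10] <- 500 * exp(rnorm(10, 0, 0.05))
  res <- two_regime_flag(a2, b2)
  expect_true(res$flagged)
  expect_gt(res$r2_full - res$r2_reduced, 0.5)
  # invariant to gene order
  expect_equal(two_regime_flag(b2, a2)$flagged, res$flagged)
})

test_that("ranking consistency equals top-k overlap with Monte-Carlo behaviour", {
  pairs <- tidyr::expand_grid(gene_a = sprintf("g%02d", 1:10),
                              gene_b = sprintf("g%02d", 1:10)) |>
    dplyr::filter(gene_a < gene_b)
  rc <- ranking_consistency(pairs, pairs, depths = c(1, 5, 20))
  expect_equal(rc$fraction, c(1, 1, 1))

  rev <- pairs[rev(seq_len(nrow(pairs))), ]
  rc2 <- ranking_consistency(pairs, rev, depths = 10)
  expect_equal(rc2$fraction, 0)   # 45 pairs, disjoint top-10 vs bottom-10

  # independent random rankings over N pairs: expected overlap k/N
  set.seed(39)
  N <- nrow(pairs); k <- 10
  fr <- replicate(300, {
    ranking_consistency(pairs[sample(N), ], pairs[sample(N), ], depths = k)$fraction
  })
  expect_equal(mean(fr), k / N, tolerance = 0.12)
})
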