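make_gmt <- function(sets) {
  tf <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, paste(id, "desc"), sets[[id]]), collapse = "\t")
  }, ""), tf)
  tf
}

test_that("GMT collections round-trip as long tibbles", {
  tf <- make_gmt(list(P1 = c("a", "b", "c"), P2 = c("c", "d")))
  sets <- read_gmt(tf)
  expect_equal(sort(unique(sets$set_id)), c("P1", "P2"))
  expect_setequal(sets$gene_id[sets$set_id == "P1"], c("a", "b", "c"))
  expect_equal(sets$description[sets$set_id == "P2"][1], "P2 desc")
})

test_that("annotated edge and pair fractions match enumeration", {
  g <- tibble::tibble(gene_a = c("a", "a", "x", "p"),
                      gene_b = c("b", "c", "y", "q"))
  sets <- tibble::tibble(set_id = "S", description = "",
                         gene_id = c("a", "b", "c"))
  # 2 of 4 edges have both endpoints annotated
  expect_equal(annotated_edge_fraction(g, sets), 50)
  allsets <- tibble::tibble(set_id = "S", description = "",
                            gene_id = c("a", "b", "c", "x", "y", "p", "q"))
  expect_equal(annotated_edge_fraction(g, allsets), 100)
  none <- tibble::tibble(set_id = "S", description = "", gene_id = "zz")
  expect_equal(annotated_edge_fraction(g, none), 0)

  # same-set reading: a-b and a-c annotated together, x-y split across sets
  two <- tibble::tibble(set_id = c("S1", "S1", "S1", "S2", "S3"),
                        description = "",
                        gene_id = c("a", "b", "c", "x", "y"))
  expect_equal(annotated_edge_fraction(g, two, same_set = TRUE), 50)

  ann <- tibble::tibble(gene_a = c("a", "x", "m"), gene_b = c("b", "y", "n"))
  expect_equal(annotated_pair_fraction(g, ann), 50)
  expect_equal(annotated_pair_fraction(g, g), 100)
  expect_equal(annotated_pair_fraction(g, ann[3, ]), 0)

  # edge order is irrelevant
  expect_equal(annotated_edge_fraction(g[c(3, 1, 4, 2), ], sets), 50)
})

test_that("within-pathway recovery counts edges by direct enumeration", {
  fx <- generate_fixture(n_samples = 60, n_ratiometric = 0, n_wide = 0,
                         n_two_regime = 0, n_independent = 30,
                         n_pathway_tight = 10, seed = 41)
  pt <- all_pairs(fx$matrix)
  sw <- stringency_sweep(pt, "RA", ra_sweep_mode = "gated_cv")
  sizes <- c(10, 20, 30)
  rec <- within_pathway_recovery(sw, fx$gene_sets, "tight_pathway", sizes)
  genes <- fx$gene_sets$gene_id
  for (i in seq_along(sizes)) {
    g <- graph_at(sw, rec$step[i])
    expect_equal(rec$n_edges_within[i],
                 sum(g$gene_a %in% genes & g$gene_b %in% genes))
    expect_equal(rec$pct_pathway_genes[i],
                 100 * mean(genes %in% graph_vertices(g)))
  }
  expect_true(!is.unsorted(rec$n_edges_within))   # nested graphs

  missing <- tibble::tibble(set_id = "off", gene_id = c("zz1", "zz2"))
  expect_equal(within_pathway_recovery(sw, missing, "off", sizes)$n_edges_within,
               rep(0L, 3))
})

test_that("permutation nulls are seeded, reproducible, and sit below a planted pathway", {
  fx <- generate_fixture(n_samples = 80, n_ratiometric = 0, n_wide = 0,
                         n_two_regime = 0, n_independent = 60,
                         n_pathway_tight = 12, seed = 42)
  pt <- all_pairs(fx$matrix)
  sw <- stringency_sweep(pt, "RA", ra_sweep_mode = "gated_cv")
  sizes <- c(15, 30)
  nl <- permuted_pathway_null(fx$matrix, sw, fx$gene_sets, "tight_pathway",
                              sizes, n_perm = 30, seed = 5)
  nl2 <- permuted_pathway_null(fx$matrix, sw, fx$gene_sets, "tight_pathway",
                               sizes, n_perm = 30, seed = 5)
  expect_equal(tibble::as_tibble(nl), tibble::as_tibble(nl2))
  expect_true(all(nl$null_min <= nl$null_mean & nl$null_mean <= nl$null_max))
  # the planted ratiometric module is recovered far above any random model
  expect_true(all(nl$observed > nl$null_max))
})

test_that("ontology aggregation merges undersized terms into the nearest large ancestor", {
  # chain: child(50 detected) -> parent(180 cumulative) -> grandparent(210)
  dag <- tibble::tibble(child = c("c", "p"), parent = c("p", "g"))
  ann <- tibble::tibble(
    gene_id = c(sprintf("x%03d", 1:210)),
    term_id = c(rep("c", 50), rep("p", 130), rep("g", 30)))
  agg <- aggregate_ontology(dag, ann, detected_genes = ann$gene_id,
                            min_size = 200)
  expect_equal(agg$categories$category_id, "g")
  expect_equal(agg$categories$n_detected, 210)
  expect_setequal(agg$members$term_id[agg$members$category_id == "g"],
                  c("c", "p", "g"))

  # all terms already large enough: identity
  ann2 <- tibble::tibble(gene_id = sprintf("y%03d", 1:600),
                         term_id = rep(c("c", "p", "g"), each = 200))
  agg2 <- aggregate_ontology(dag, ann2, ann2$gene_id, min_size = 200)
  expect_setequal(agg2$categories$category_id, c("c", "p", "g"))
  # merged counts never fall below the minimum
  expect_true(all(agg2$categories$n_detected >= 200))

  # determinism
  agg3 <- aggregate_ontology(dag, ann, ann$gene_id, min_size = 200)
  expect_equal(agg3$members, agg$members)

  cyc <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"))
  expect_error(aggregate_ontology(cyc, ann, ann$gene_id), "cycle")
})

test_that("terms without a qualifying ancestor are merged into the root and flagged", {
  dag <- tibble::tibble(child = c("t1", "t2"), parent = c("root", "root"))
  ann <- tibble::tibble(gene_id = sprintf("z%02d", 1:30),
                        term_id = rep(c("t1", "t2", "root"), each = 10))
  agg <- aggregate_ontology(dag, ann, ann$gene_id, min_size = 200)
  expect_equal(agg$categories$category_id, "root")
  expect_true(agg$categories$at_root)
  expect_equal(agg$categories$n_detected, 30)
})

test_that("hypergeometric enrichment matches the closed form and the tail oracle", {
  bg <- sprintf("b%02d", 1:20)
  cat10 <- tibble::tibble(set_id = "half", gene_id = bg[1:10])
  res <- category_enrichment(bg[1:10], cat10, bg)
  # drawing all 10 of the 10-gene category in a 10-gene selection from 20
  expect_equal(res$p_value, 1 / choose(20, 10))
  expect_equal(res$p_value, 5.41e-6, tolerance = 1e-3)
  expect_equal(res$overlap, 10)

  # brute-force tail on random small instances
  set.seed(43)
  for (rep in 1:5) {
    N <- 30; K <- sample(5:15, 1); n <- sample(5:15, 1)
    bgx <- sprintf("g%02d", 1:N)
    cats <- tibble::tibble(set_id = "S", gene_id = bgx[1:K])
    sel <- sample(bgx, n)
    k <- length(intersect(sel, bgx[1:K]))
    got <- category_enrichment(sel, cats, bgx)
    expect_equal(got$p_value, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }

  # empty overlap on a large category is not enriched
  big <- tibble::tibble(set_id = "big", gene_id = bg[11:20])
  res2 <- category_enrichment(bg[1:5], big, bg)
  expect_gt(res2$p_value, 0.9)
  expect_false(res2$enriched)
  # Bonferroni correction multiplies by the number of tested categories
  both <- dplyr::bind_rows(cat10, big)
  res3 <- category_enrichment(bg[1:10], both, bg)
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_value * 2))
  expect_error(category_enrichment(c("nope"), cat10, bg), "subset")
})

test_that("pathway CV profiles average gene-level CVs and detect group differences", {
  set.seed(44)
  n_genes <- 30
  # two pathways whose genes have clearly different expression CVs
  low <- t(sapply(1:n_genes, function(i) 100 * exp(rnorm(40, 0, 0.05))))
  high <- t(sapply(1:n_genes, function(i) 100 * exp(rnorm(40, 0, 0.5))))
  m <- rbind(low, high)
  x <- tibble::tibble(gene_id = sprintf("g%02d", 1:(2 * n_genes))) |>
    dplyr::bind_cols(tibble::as_tibble(`colnames<-`(m, sprintf("s%02d", 1:40))))
  sets <- tibble::tibble(set_id = rep(c("LOW", "HIGH"), each = n_genes),
                         gene_id = x$gene_id)
  res <- pathway_cv_profiles(x, sets, groups = c(LOW = "1", HIGH = "4"))
  v <- as.matrix(x[-1])
  expect_equal(res$profiles$cv[1], sd(v[1, ]) / mean(v[1, ]))
  # group means equal brute-force averages
  cv_all <- apply(v, 1, function(r) sd(r) / mean(r))
  expect_equal(res$group_means$mean_cv[res$group_means$group == "1"],
               mean(cv_all[1:n_genes]))
  expect_equal(res$group_means$mean_cv[res$group_means$group == "4"],
               mean(cv_all[(n_genes + 1):(2 * n_genes)]))
  # Welch test flags the planted difference
  expect_lt(res$comparisons$p_value, 0.001)

  # constant genes have CV zero
  cx <- tibble::tibble(gene_id = "c1", s1 = 5, s2 = 5, s3 = 5)
  csets <- tibble::tibble(set_id = "C", gene_id = "c1")
  expect_equal(pathway_cv_profiles(cx, csets)$profiles$cv, 0)
})

test_that("pair lists and ontology files parse from text formats", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "c\tc", "a\tc"), tf)
  pr <- read_gene_pairs(tf)
  expect_equal(nrow(pr), 2)   # duplicate unordered pair collapsed, self-pair dropped
  expect_true(all(pr$gene_a < pr$gene_b))

  writeLines(c("c\tp", "p\tg"), tf)
  dag <- read_ontology(tf)
  expect_equal(dag$child, c("c", "p"))

  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:1", "name: x",
               "is_a: GO:2 ! parent", "", "[Term]", "id: GO:2", "name: y",
               "", "[Term]", "id: GO:3", "is_obsolete: true",
               "is_a: GO:2"), obo)
  d2 <- read_ontology(obo)
  expect_equal(d2$child, "GO:1")
  expect_equal(d2$parent, "GO:2")
})
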