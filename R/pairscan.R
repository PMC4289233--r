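#' Association statistics for all gene pairs
#'
#' Computes the full [pair_measures()] record for every unordered gene pair
#' of an expression matrix. Pairs are processed in row blocks with matrix
#' algebra (masked reciprocal products for the ratio moments, indicator
#' cross-products for the joint mutual-information histograms), so memory
#' stays bounded by the block size rather than the pair count. Output order
#' is deterministic: gene identifiers are sorted, pairs listed
#' lexicographically with `gene_a < gene_b`.
#'
#' @param x Expression tibble (filtered; at least 2 genes).
#' @param config A [measure_config()].
#' @param block_size Number of genes per processing block (default 256).
#' @return A tibble of class `ra_pairs` with one row per unordered pair and
#'   the columns of [pair_measures()] plus `gene_a`, `gene_b`. The config is
#'   attached as attribute `"config"` and the sample count as `"n_samples"`.
#' @export
all_pairs <- function(x, config = measure_config(), block_size = 256L) {
  X <- expr_values(x)
  X <- X[order(rownames(X)), , drop = FALSE]
  n_genes <- nrow(X)
  n <- ncol(X)
  if (n_genes < 2L) stop("need at least two genes", call. = FALSE)
  if (n < 3L) stop("need at least three samples", call. = FALSE)
  ids <- rownames(X)

  P <- X > 0
  W <- ifelse(P, 1 / X, 0)          # masked reciprocals
  X2 <- X^2
  W2 <- W^2

  # centred rows for Pearson, rank rows for Spearman
  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  Rk <- t(apply(X, 1L, rank, ties.method = "average"))
  Rc <- Rk - rowMeans(Rk)
  ssr <- rowSums(Rc^2)

  bins <- config$mi_bins
  B <- t(apply(X, 1L, mi_bin, bins = bins))
  Ind <- lapply(seq_len(bins), function(k) (B == k) * 1)
  marg <- vapply(Ind, rowSums, numeric(n_genes))  # n_genes x bins

  ddof <- config$cv_ddof
  min_used <- config$min_used_fraction

  blocks <- split(seq_len(n_genes), ceiling(seq_len(n_genes) / block_size))
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    nu <- P[rows, , drop = FALSE] %*% t(P)               # samples usable
    S1ab <- X[rows, , drop = FALSE] %*% t(W)
    S2ab <- X2[rows, , drop = FALSE] %*% t(W2)
    S1ba <- W[rows, , drop = FALSE] %*% t(X)
    S2ba <- W2[rows, , drop = FALSE] %*% t(X2)

    mean_ab <- S1ab / nu
    mean_ba <- S1ba / nu
    var_ab <- pmax(S2ab - nu * mean_ab^2, 0) / (nu - ddof)
    var_ba <- pmax(S2ba - nu * mean_ba^2, 0) / (nu - ddof)
    cv_ab <- sqrt(var_ab) / mean_ab
    cv_ba <- sqrt(var_ba) / mean_ba

    r <- (Xc[rows, , drop = FALSE] %*% t(Xc)) / sqrt(outer(ss[rows], ss))
    rs <- (Rc[rows, , drop = FALSE] %*% t(Rc)) / sqrt(outer(ssr[rows], ssr))

    mi <- matrix(0, nrow = length(rows), ncol = n_genes)
    for (k in seq_len(bins)) {
      for (l in seq_len(bins)) {
        N <- Ind[[k]][rows, , drop = FALSE] %*% t(Ind[[l]])
        denom <- outer(marg[rows, k], marg[, l])
        term <- N / n * log2((N * n) / denom)
        term[N == 0] <- 0
        mi <- mi + term
      }
    }

    evaluable <- nu >= 3L & (nu / n) >= min_used
    # upper triangle in global index space: pair (i, j) with i < j
    idx <- which(outer(rows, seq_len(n_genes), `<`), arr.ind = TRUE)
    gi <- rows[idx[, 1L]]
    gj <- idx[, 2L]
    flat <- idx
    ev <- evaluable[flat]
    v_cv_ab <- cv_ab[flat]; v_cv_ba <- cv_ba[flat]
    out[[bi]] <- tibble::tibble(
      gene_a = ids[gi], gene_b = ids[gj],
      cv_ab = ifelse(ev, v_cv_ab, NA_real_),
      cv_ba = ifelse(ev, v_cv_ba, NA_real_),
      delta_cv = ifelse(ev, abs(v_cv_ab - v_cv_ba), NA_real_),
      mean_ab = ifelse(ev, mean_ab[flat], NA_real_),
      mean_ba = ifelse(ev, mean_ba[flat], NA_real_),
      pearson_r = r[flat], pearson_r2 = r[flat]^2,
      spearman_r2 = rs[flat]^2, mi = mi[flat],
      n_used = as.integer(nu[flat]),
      ra_evaluable = ev
    )
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  attr(res, "config") <- config
  attr(res, "n_samples") <- n
  attr(res, "gene_ids") <- ids
  class(res) <- c("ra_pairs", class(res))
  res
}

pair_config <- function(table, config = NULL) {
  if (!is.null(config)) return(config)
  cfg <- attr(table, "config")
  if (is.null(cfg)) measure_config() else cfg
}

pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

#' Rank all pairs under one association method
#'
#' PE and SP rank all pairs by descending squared correlation and MI by
#' descending mutual information. RA first applies the delta-CV gate and then
#' ranks the surviving pairs by ascending stability (smaller = stronger).
#' Ties are broken by a secondary statistic (RA: delta-CV; PE/SP: |r|;
#' MI: R-squared) and finally by the gene-id pair, so rankings are
#' deterministic.
#'
#' @param table An [all_pairs()] table.
#' @param method One of `"RA"`, `"PE"`, `"MI"`, `"SP"`.
#' @param config Optional [measure_config()] overriding the one attached to
#'   `table`.
#' @return The ranked tibble (RA additionally gains a `stability` column).
#' @export
rank_pairs <- function(table, method = c("RA", "PE", "MI", "SP"), config = NULL) {
  method <- match.arg(method)
  cfg <- pair_config(table, config)
  tb <- tibble::as_tibble(table)
  switch(method,
    RA = tb |>
      dplyr::filter(.data$ra_evaluable,
                    .data$delta_cv < cfg$delta_cv_threshold) |>
      dplyr::mutate(stability = ra_stability(.data$cv_ab, .data$cv_ba,
                                             cfg$stability_rule)) |>
      dplyr::arrange(.data$stability, .data$delta_cv, .data$gene_a, .data$gene_b),
    PE = tb |>
      dplyr::arrange(dplyr::desc(.data$pearson_r2), dplyr::desc(abs(.data$pearson_r)),
                     .data$gene_a, .data$gene_b),
    SP = tb |>
      dplyr::arrange(dplyr::desc(.data$spearman_r2), dplyr::desc(abs(.data$pearson_r)),
                     .data$gene_a, .data$gene_b),
    MI = tb |>
      dplyr::arrange(dplyr::desc(.data$mi), dplyr::desc(.data$pearson_r2),
                     .data$gene_a, .data$gene_b)
  )
}

#' Stringency sweep: nested gene graphs over 100 thresholds
#'
#' Divides a method's statistic range into `n_steps` equal-width thresholds,
#' from most to least stringent, and records for each step the gene graph of
#' accepted pairs: edges are pairs meeting the step's threshold, vertices are
#' the genes with degree >= 1 (degree-0 genes are excluded by construction).
#' Ranges: PE/SP sweep R-squared from 1 to 0, MI sweeps the statistic from
#' its ceiling `log2(bins)` to 0, and RA in `"delta_cv"` mode sweeps delta-CV
#' from 0 to 1 over the evaluable pairs. In `"gated_cv"` mode the delta-CV
#' gate is applied first and the stability of the surviving pairs is swept
#' from 0 to its observed maximum.
#'
#' @param table An [all_pairs()] table.
#' @param method One of `"RA"`, `"PE"`, `"MI"`, `"SP"`.
#' @param n_steps Number of thresholds (default 100).
#' @param ra_sweep_mode `"delta_cv"` (default; the graph-growth reading) or
#'   `"gated_cv"` (the ranked-analysis reading). Ignored for other methods.
#' @param config Optional [measure_config()] override.
#' @return An object of class `ra_sweep`: a list with `method`, `mode`,
#'   `n_steps`, `steps` (tibble: step, threshold, n_vertices, n_edges) and
#'   `pairs` (tibble: gene_a, gene_b, stat, step_first -- the first, most
#'   stringent, step at which the pair is accepted).
#' @export
stringency_sweep <- function(table, method = c("RA", "PE", "MI", "SP"),
                             n_steps = 100L,
                             ra_sweep_mode = c("delta_cv", "gated_cv"),
                             config = NULL) {
  method <- match.arg(method)
  ra_sweep_mode <- match.arg(ra_sweep_mode)
  cfg <- pair_config(table, config)
  tb <- tibble::as_tibble(table)

  if (method == "RA") {
    tb <- dplyr::filter(tb, .data$ra_evaluable)
    if (ra_sweep_mode == "delta_cv") {
      stat <- tb$delta_cv
      hi <- 1; ascending <- TRUE
    } else {
      tb <- dplyr::filter(tb, .data$delta_cv < cfg$delta_cv_threshold)
      stat <- ra_stability(tb$cv_ab, tb$cv_ba, cfg$stability_rule)
      hi <- max(stat, 0); ascending <- TRUE
    }
  } else {
    stat <- switch(method, PE = tb$pearson_r2, SP = tb$spearman_r2, MI = tb$mi)
    hi <- switch(method, PE = 1, SP = 1, MI = log2(cfg$mi_bins))
    ascending <- FALSE
  }

  if (ascending) {
    thresholds <- hi * seq_len(n_steps) / n_steps
    step_first <- if (hi > 0) pmax(1L, ceiling(n_steps * stat / hi)) else rep(1L, length(stat))
    step_first[stat > hi] <- NA_integer_   # beyond the swept range: never accepted
  } else {
    thresholds <- hi * (1 - seq_len(n_steps) / n_steps)
    step_first <- pmax(1L, ceiling(n_steps * (hi - stat) / hi))
    step_first[stat < 0] <- n_steps  # negative statistic still >= final threshold 0
  }

  pairs <- tibble::tibble(gene_a = tb$gene_a, gene_b = tb$gene_b,
                          stat = stat, step_first = as.integer(step_first)) |>
    dplyr::filter(!is.na(.data$step_first))

  n_edges <- cumsum(tabulate(pairs$step_first, nbins = n_steps))
  gene_first <- c(tapply(pairs$step_first, pairs$gene_a, min),
                  tapply(pairs$step_first, pairs$gene_b, min))
  gene_first <- tapply(gene_first, names(gene_first), min)
  n_vertices <- cumsum(tabulate(as.integer(gene_first), nbins = n_steps))

  structure(
    list(method = method, mode = if (method == "RA") ra_sweep_mode else NA_character_,
         n_steps = as.integer(n_steps),
         steps = tibble::tibble(step = seq_len(n_steps), threshold = thresholds,
                                n_vertices = n_vertices, n_edges = n_edges),
         pairs = pairs,
         config = cfg),
    class = "ra_sweep"
  )
}

#' Extract the gene graph at one sweep step
#'
#' @param sweep An [stringency_sweep()] object.
#' @param step Step index in `1..n_steps` (1 = most stringent).
#' @return A tibble of class `ra_graph` with columns `gene_a`, `gene_b` (the
#'   accepted edges) and attributes `step`, `threshold`, `method`. Vertices
#'   are the genes appearing in at least one edge.
#' @export
graph_at <- function(sweep, step) {
  stopifnot(inherits(sweep, "ra_sweep"), step >= 1L, step <= sweep$n_steps)
  g <- sweep$pairs |>
    dplyr::filter(.data$step_first <= step) |>
    dplyr::select("gene_a", "gene_b")
  attr(g, "step") <- as.integer(step)
  attr(g, "threshold") <- sweep$steps$threshold[step]
  attr(g, "method") <- sweep$method
  class(g) <- c("ra_graph", class(g))
  g
}

#' Vertices of a gene graph
#' @param graph An edge tibble (`gene_a`, `gene_b`).
#' @return Character vector of genes with degree >= 1.
#' @export
graph_vertices <- function(graph) {
  unique(c(graph$gene_a, graph$gene_b))
}

#' Pick the most stringent step reaching a target graph size
#'
#' @param sweep An [stringency_sweep()] object.
#' @param target Target size (vertex or edge count).
#' @param match_on `"vertices"` or `"edges"`.
#' @return The step index (smallest step whose size first reaches `target`);
#'   errors if the sweep never reaches it.
#' @export
step_at_size <- function(sweep, target, match_on = c("vertices", "edges")) {
  match_on <- match.arg(match_on)
  sizes <- if (match_on == "vertices") sweep$steps$n_vertices else sweep$steps$n_edges
  hit <- which(sizes >= target)
  if (length(hit) == 0L) {
    stop(sprintf("sweep never reaches %d %s (max %d)", target, match_on, max(sizes)),
         call. = FALSE)
  }
  hit[1L]
}

#' Gene- and edge-inclusion profile of a sweep
#'
#' Per step, the percentage of all genes included in the graph and the number
#' of accepted edges; also records the first step at which a target coverage
#' is reached.
#'
#' @param sweep An [stringency_sweep()] object.
#' @param total_genes Size of the gene universe the percentage refers to.
#' @param target_percent Coverage of interest (default 95); the first step at
#'   or above it is stored in attribute `"coverage_step"` (`NA` if never
#'   reached).
#' @return Tibble (step, threshold, n_vertices, n_edges, percent_genes) with
#'   attribute `coverage_step`.
#' @export
inclusion_profile <- function(sweep, total_genes, target_percent = 95) {
  stopifnot(inherits(sweep, "ra_sweep"), total_genes >= 1)
  out <- sweep$steps |>
    dplyr::mutate(percent_genes = 100 * .data$n_vertices / total_genes)
  hit <- which(out$percent_genes >= target_percent)
  attr(out, "coverage_step") <- if (length(hit)) hit[1L] else NA_integer_
  attr(out, "target_percent") <- target_percent
  out
}

#' Overlap partition of three method graphs
#'
#' Given one size-matched graph per method, partitions the union of
#' discoveries (genes or gene pairs) into the seven exclusive regions of the
#' three-set Venn diagram and reports counts and union fractions.
#'
#' @param graphs Named list of exactly three edge tibbles (names are the
#'   method labels).
#' @param match_on `"pairs"` (default) compares edge sets, `"genes"` compares
#'   vertex sets.
#' @return Tibble (region, count, fraction) over the 7 regions; fractions sum
#'   to 1 over a non-empty union.
#' @export
method_overlap <- function(graphs, match_on = c("pairs", "genes")) {
  match_on <- match.arg(match_on)
  stopifnot(length(graphs) == 3L, !is.null(names(graphs)))
  sets <- lapply(graphs, function(g) {
    if (match_on == "genes") graph_vertices(g) else pair_key(g$gene_a, g$gene_b)
  })
  nm <- names(graphs)
  u <- unique(unlist(sets))
  inA <- u %in% sets[[1L]]; inB <- u %in% sets[[2L]]; inC <- u %in% sets[[3L]]
  counts <- c(
    sum(inA & !inB & !inC), sum(!inA & inB & !inC), sum(!inA & !inB & inC),
    sum(inA & inB & !inC), sum(inA & !inB & inC), sum(!inA & inB & inC),
    sum(inA & inB & inC)
  )
  region <- c(nm[1L], nm[2L], nm[3L],
              paste(nm[1L], nm[2L], sep = "&"), paste(nm[1L], nm[3L], sep = "&"),
              paste(nm[2L], nm[3L], sep = "&"), paste(nm, collapse = "&"))
  tibble::tibble(region = region, count = counts,
                 fraction = if (length(u)) counts / length(u) else rep(0, 7L))
}

#' Correlation matrix between the per-pair statistics
#'
#' Pearson correlations between the six per-pair statistics (MI, R-squared,
#' r, delta-CV, CV(A/B), CV(B/A)) across all pairs, using pairwise-complete
#' observations so pairs not evaluable for the ratio statistics contribute to
#' the correlation-only entries.
#'
#' @param table An [all_pairs()] table.
#' @return Symmetric 6x6 numeric matrix with unit diagonal, dimnames
#'   `I, R2, r, delta_CV, CV_AB, CV_BA`.
#' @export
measure_correlation_matrix <- function(table) {
  m <- cbind(I = table$mi, R2 = table$pearson_r2, r = table$pearson_r,
             delta_CV = table$delta_cv, CV_AB = table$cv_ab, CV_BA = table$cv_ba)
  stats::cor(m, use = "pairwise.complete.obs")
}

#' Gene-level expression variation versus best ratio stability
#'
#' For each gene, its own expression CV across samples and the best (minimum)
#' stability over all its gated ratiometric pairs. The squared Pearson
#' correlation between the two quantities, over the `top_k` genes ranked by
#' best stability, measures how much invariant expression alone explains
#' stable ratios.
#'
#' @param x Expression tibble the table was computed from.
#' @param table An [all_pairs()] table.
#' @param top_k Number of top-ranked genes entering the regression.
#' @param config Optional [measure_config()] override.
#' @return Tibble (gene_id, gene_cv, best_stability, rank) for the `top_k`
#'   genes, with the regression `r.squared` as attribute `"r_squared"`.
#' @export
invariance_diagnostic <- function(x, table, top_k, config = NULL) {
  cfg <- pair_config(table, config)
  m <- expr_values(x)
  gene_cv <- apply(m, 1L, cv_of, ddof = cfg$cv_ddof)
  gated <- rank_pairs(table, "RA", cfg)
  if (nrow(gated) == 0L) stop("no gated ratiometric pairs", call. = FALSE)
  best <- dplyr::bind_rows(
    tibble::tibble(gene_id = gated$gene_a, stability = gated$stability),
    tibble::tibble(gene_id = gated$gene_b, stability = gated$stability)
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(best_stability = min(.data$stability), .groups = "drop") |>
    dplyr::arrange(.data$best_stability, .data$gene_id)
  if (top_k > nrow(best)) {
    stop(sprintf("top_k (%d) exceeds the %d RA-ranked genes", top_k, nrow(best)),
         call. = FALSE)
  }
  out <- best |>
    utils::head(top_k) |>
    dplyr::mutate(gene_cv = unname(gene_cv[.data$gene_id]),
                  rank = dplyr::row_number()) |>
    dplyr::select("gene_id", "gene_cv", "best_stability", "rank")
  r2 <- if (stats::sd(out$gene_cv) == 0 || stats::sd(out$best_stability) == 0) 0
        else stats::cor(out$gene_cv, out$best_stability)^2
  attr(out, "r_squared") <- r2
  out
}

#' Flag pairs whose association is driven by a highly expressed subgroup
#'
#' Heuristic for the 2-regime pattern: a pair is flagged when removing the
#' top `high_fraction` of samples (ranked by the sum of the two expression
#' values) drops the squared Pearson correlation by more than `r2_drop` --
#' i.e. a small jointly-high subgroup, not the bulk of the samples, carries
#' the apparent association.
#'
#' @param a,b Equal-length expression vectors.
#' @param high_fraction Fraction of samples treated as the high subgroup
#'   (default 0.1).
#' @param r2_drop Required R-squared drop (default 0.5).
#' @return One-row tibble (flagged, r2_full, r2_reduced, n_removed).
#' @export
two_regime_flag <- function(a, b, high_fraction = 0.1, r2_drop = 0.5) {
  check_assoc_vectors(a, b)
  n <- length(a)
  n_remove <- max(1L, ceiling(high_fraction * n))
  keep <- order(a + b, decreasing = TRUE)[-seq_len(n_remove)]
  r2_full <- stats::cor(a, b)^2
  r2_red <- if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) 0
            else stats::cor(a[keep], b[keep])^2
  tibble::tibble(flagged = (r2_full - r2_red) > r2_drop,
                 r2_full = r2_full, r2_reduced = r2_red,
                 n_removed = n_remove)
}

#' Top-k overlap between two pair rankings
#'
#' Measures ranking reproducibility between batches: at each depth `k`, the
#' fraction of the top-`k` pairs of one ranking that also appear in the
#' top-`k` of the other.
#'
#' @param ranking_1,ranking_2 Ranked pair tibbles (`gene_a`, `gene_b` in rank
#'   order, e.g. from [rank_pairs()]).
#' @param depths Integer vector of depths `k`.
#' @return Tibble (depth, overlap, fraction).
#' @export
ranking_consistency <- function(ranking_1, ranking_2, depths) {
  k1 <- pair_key(ranking_1$gene_a, ranking_1$gene_b)
  k2 <- pair_key(ranking_2$gene_a, ranking_2$gene_b)
  purrr::map_dfr(depths, function(k) {
    top1 <- utils::head(k1, k)
    top2 <- utils::head(k2, k)
    ov <- length(intersect(top1, top2))
    tibble::tibble(depth = k, overlap = ov, fraction = ov / k)
  })
}
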