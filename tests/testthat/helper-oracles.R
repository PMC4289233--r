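# Independent brute-force references used to cross-check the vectorised
# implementation. These deliberately use explicit loops and naive formulas.

oracle_cv_ratio <- function(a, b, ddof = 1) {
  keep <- a > 0 & b > 0
  a <- a[keep]; b <- b[keep]
  ratios_ab <- numeric(length(a))
  ratios_ba <- numeric(length(a))
  for (i in seq_along(a)) {
    ratios_ab[i] <- a[i] / b[i]
    ratios_ba[i] <- b[i] / a[i]
  }
  cv1 <- function(r) {
    m <- sum(r) / length(r)
    s2 <- 0
    for (x in r) s2 <- s2 + (x - m)^2
    sqrt(s2 / (length(r) - ddof)) / m
  }
  list(cv_ab = cv1(ratios_ab), cv_ba = cv1(ratios_ba),
       mean_ab = mean(ratios_ab), mean_ba = mean(ratios_ba),
       n_used = length(a))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# plug-in MI by an explicit double loop over the joint count table
oracle_mi <- function(a, b, bins = 4) {
  bin_of <- function(x) {
    r <- rank(x, ties.method = "average")
    pmin(pmax(ceiling(bins * r / length(x)), 1), bins)
  }
  ba <- bin_of(a); bb <- bin_of(b)
  n <- length(a)
  counts <- matrix(0, bins, bins)
  for (i in seq_len(n)) counts[ba[i], bb[i]] <- counts[ba[i], bb[i]] + 1
  mi <- 0
  for (k in seq_len(bins)) {
    for (l in seq_len(bins)) {
      if (counts[k, l] > 0) {
        pkl <- counts[k, l] / n
        pk <- sum(counts[k, ]) / n
        pl <- sum(counts[, l]) / n
        mi <- mi + pkl * log2(pkl / (pk * pl))
      }
    }
  }
  mi
}

# hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_tail <- function(k, K, N, n) {
  p <- 0
  for (x in k:min(K, n)) {
    p <- p + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  p
}

# naive all-pairs table via pair_measures on every unordered pair
oracle_all_pairs <- function(mat_tbl, config = measure_config()) {
  v <- as.matrix(mat_tbl[-1])
  rownames(v) <- mat_tbl$gene_id
  v <- v[order(rownames(v)), , drop = FALSE]
  ids <- rownames(v)
  rows <- list()
  for (i in seq_len(nrow(v) - 1)) {
    for (j in (i + 1):nrow(v)) {
      pm <- pair_measures(v[i, ], v[j, ], config)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(gene_a = ids[i], gene_b = ids[j]), pm)
    }
  }
  dplyr::bind_rows(rows)
}

# small positive random expression tibble
random_expr <- function(n_genes, n_samples, seed, zeros = 0) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, log(50), 0.8), nrow = n_genes)
  if (zeros > 0) m[sample(length(m), zeros)] <- 0
  tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes))) |>
    dplyr::bind_cols(tibble::as_tibble(
      `colnames<-`(m, sprintf("s%02d", seq_len(n_samples)))))
}
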