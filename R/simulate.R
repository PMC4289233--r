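#' Range-restriction simulation: flat ratio CV, shrinking correlation
#'
#' Generates gene pairs `a_i = slope * b_i + u_i` with `u_i ~ N(0, noise_sd)`
#' and `b_i ~ N(mu_b, s)` for a sweep of standard deviations `s`, i.e. CV(B)
#' running from 0 up to `max(sd_values)/mu_b`. For each `s`, several
#' replicate datasets are drawn and all association statistics computed; the
#' per-`s` mean and standard error are returned. The point of the experiment:
#' the pair relationship is identical at every `s`, yet the
#' correlation-based statistics collapse as the expression range of B
#' narrows, while the ratio CV stays flat. Draws with a non-positive value in
#' either gene are rejected and redrawn jointly so ratios stay defined.
#'
#' @param slope Proportionality constant (default 2).
#' @param noise_sd SD of the additive noise on A (default 50).
#' @param mu_b Mean expression of B (default 500).
#' @param sd_values SD sweep for B (default `seq(0, 125, by = 5)`, i.e. CV(B)
#'   0--25% of `mu_b`).
#' @param n Samples per dataset (default 100).
#' @param replicates Datasets per SD (default 10).
#' @param seed RNG seed.
#' @param config A [measure_config()].
#' @return Tibble of class `ra_sim_range`, long over (sd_b, statistic) with
#'   columns `sd_b`, `cv_b_pct`, `statistic`, `mean`, `se`. Statistics with
#'   an undefined value (e.g. Pearson at `sd_b = 0`, where B is constant)
#'   are `NA`. Attribute `"n_rejected"` counts redrawn samples.
#' @export
simulate_range_restriction <- function(slope = 2, noise_sd = 50, mu_b = 500,
                                       sd_values = seq(0, 125, by = 5),
                                       n = 100L, replicates = 10L, seed = 1L,
                                       config = measure_config()) {
  stopifnot(noise_sd >= 0, all(sd_values >= 0), mu_b > 0)
  set.seed(seed)
  rejected <- 0L
  draw_pair <- function(s) {
    b <- stats::rnorm(n, mu_b, s)
    a <- slope * b + stats::rnorm(n, 0, noise_sd)
    bad <- which(a <= 0 | b <= 0)
    while (length(bad) > 0L) {
      rejected <<- rejected + length(bad)
      b[bad] <- stats::rnorm(length(bad), mu_b, s)
      a[bad] <- slope * b[bad] + stats::rnorm(length(bad), 0, noise_sd)
      bad <- which(a <= 0 | b <= 0)
    }
    list(a = a, b = b)
  }
  rows <- purrr::map_dfr(sd_values, function(s) {
    stats_rep <- purrr::map_dfr(seq_len(replicates), function(r) {
      d <- draw_pair(s)
      pair_measures(d$a, d$b, config)
    })
    long <- stats_rep |>
      dplyr::select("pearson_r2", "spearman_r2", "mi", "cv_ab", "cv_ba", "delta_cv") |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "statistic",
                          values_to = "value")
    long |>
      dplyr::group_by(.data$statistic) |>
      dplyr::summarise(
        mean = if (all(is.na(.data$value))) NA_real_ else mean(.data$value, na.rm = TRUE),
        se = if (all(is.na(.data$value))) NA_real_ else
          stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
        .groups = "drop") |>
      dplyr::mutate(sd_b = s, cv_b_pct = 100 * s / mu_b, .before = 1L)
  })
  attr(rows, "n_rejected") <- rejected
  attr(rows, "spec") <- list(slope = slope, noise_sd = noise_sd, mu_b = mu_b,
                             n = n, replicates = replicates, seed = seed)
  class(rows) <- c("ra_sim_range", class(rows))
  rows
}

# bivariate normal draws as n x runs matrices
rbvn <- function(n, runs, mean_a, mean_b, sd, rho) {
  z1 <- stats::rnorm(n * runs)
  z2 <- stats::rnorm(n * runs)
  list(A = matrix(mean_a + sd * (rho * z1 + sqrt(1 - rho^2) * z2), nrow = n),
       B = matrix(mean_b + sd * z1, nrow = n))
}

col_cv <- function(M, ddof = 1L) {
  n <- nrow(M)
  m <- colMeans(M)
  v <- (colSums(M^2) - n * m^2) / (n - ddof)
  sqrt(pmax(v, 0)) / m
}

#' Bivariate-normal sweep: constant correlation, decaying ratiometric fraction
#'
#' Draws correlated bivariate-normal gene pairs at a fixed generative
#' correlation while the (equal) standard deviations of both genes sweep
#' upward. By the constancy property of the multivariate normal the sample
#' correlation stays at the generative value at every SD, but the ratio CVs
#' grow with SD/mean, so the fraction of runs meeting the ratiometric
#' definition (delta-CV gate plus stability bound) decays -- steeply once the
#' SD passes roughly 15% of the mean.
#'
#' @param mean_a,mean_b Gene means (default 200 each).
#' @param correlation Generative Pearson correlation (default 0.47).
#' @param sd_values Equal-SD sweep (default `seq(10, 80, by = 10)`).
#' @param runs Datasets per SD (default 1000).
#' @param n Observations per dataset (default 1000).
#' @param stability_bound Stability cut combined with the gate
#'   (default 0.135).
#' @param stability_only If `TRUE`, the ratiometric call uses the stability
#'   bound alone, without the delta-CV gate.
#' @param seed RNG seed.
#' @param config A [measure_config()]; supplies the gate and stability rule.
#' @return Tibble of class `ra_sim_bivariate`: one row per SD with `sd`,
#'   `mean_r`, `se_r`, `ratiometric_fraction`.
#' @export
simulate_bivariate_normal <- function(mean_a = 200, mean_b = 200,
                                      correlation = 0.47,
                                      sd_values = seq(10, 80, by = 10),
                                      runs = 1000L, n = 1000L,
                                      stability_bound = 0.135,
                                      stability_only = FALSE,
                                      seed = 1L,
                                      config = measure_config()) {
  stopifnot(correlation > -1, correlation < 1, all(sd_values > 0))
  set.seed(seed)
  out <- purrr::map_dfr(sd_values, function(s) {
    d <- rbvn(n, runs, mean_a, mean_b, s, correlation)
    A <- d$A; B <- d$B
    mA <- colMeans(A); mB <- colMeans(B)
    covAB <- colMeans(A * B) - mA * mB
    r <- covAB / sqrt((colMeans(A^2) - mA^2) * (colMeans(B^2) - mB^2))
    # a run with a non-positive draw has undefined ratios: never ratiometric
    positive <- colSums(A <= 0 | B <= 0) == 0L
    cv1 <- suppressWarnings(col_cv(A / B, config$cv_ddof))
    cv2 <- suppressWarnings(col_cv(B / A, config$cv_ddof))
    dlt <- abs(cv1 - cv2)
    stab <- ra_stability(cv1, cv2, config$stability_rule)
    ok <- if (stability_only) stab <= stability_bound
          else dlt < config$delta_cv_threshold & stab <= stability_bound
    ok <- positive & !is.na(ok) & ok
    tibble::tibble(sd = s, mean_r = mean(r), se_r = stats::sd(r) / sqrt(runs),
                   ratiometric_fraction = mean(ok))
  })
  attr(out, "spec") <- list(mean_a = mean_a, mean_b = mean_b,
                            correlation = correlation, runs = runs, n = n,
                            stability_bound = stability_bound,
                            stability_only = stability_only, seed = seed)
  class(out) <- c("ra_sim_bivariate", class(out))
  out
}

#' False-positive rate of the ratiometric gate on independent genes
#'
#' Draws pairs of independently expressed genes from a log-normal abundance
#' law and measures the fraction that pass the delta-CV gate (and, if set, a
#' stability bound) -- the chance that mere independence produces a spurious
#' ratiometric call.
#'
#' @param n_samples Samples per simulated pair (default 100).
#' @param n_runs Number of independent pairs (default 10000).
#' @param meanlog,sdlog Log-normal abundance parameters for both genes
#'   (defaults `log(100)` and 0.5).
#' @param stability_bound Optional stability cut conjoined with the gate.
#' @param seed RNG seed.
#' @param config A [measure_config()].
#' @return One-row tibble (rate, se, n_runs) -- the false-positive gate rate
#'   with its Monte-Carlo standard error.
#' @export
simulate_independent_null <- function(n_samples = 100L, n_runs = 10000L,
                                      meanlog = log(100), sdlog = 0.5,
                                      stability_bound = NULL, seed = 1L,
                                      config = measure_config()) {
  set.seed(seed)
  A <- matrix(stats::rlnorm(n_samples * n_runs, meanlog, sdlog), nrow = n_samples)
  B <- matrix(stats::rlnorm(n_samples * n_runs, meanlog, sdlog), nrow = n_samples)
  cv1 <- col_cv(A / B, config$cv_ddof)
  cv2 <- col_cv(B / A, config$cv_ddof)
  ok <- abs(cv1 - cv2) < config$delta_cv_threshold
  if (!is.null(stability_bound)) {
    ok <- ok & ra_stability(cv1, cv2, config$stability_rule) <= stability_bound
  }
  rate <- mean(ok)
  tibble::tibble(rate = rate, se = sqrt(rate * (1 - rate) / n_runs),
                 n_runs = n_runs)
}

#' Synthetic expression fixture with planted pair classes
#'
#' Builds a seeded gene-by-sample matrix emulating a homogeneous RNA-seq
#' panel, with labelled ground truth: ratiometric pairs
#' (`a_i = c * b_i * (1 + eps_i)` with multiplicative noise), wide-range
#' correlated pairs (strong linear relation with an offset across a wide
#' abundance range), 2-regime pairs (an uncorrelated low-expression bulk
#' plus a small jointly-high sample subgroup), and independent background
#' genes. Optionally plants two gene modules for enrichment experiments: a
#' "tight" pathway (all genes proportional to one narrow-range base profile;
#' low expression CV, strongly ratiometric) and a "wide" pathway (all genes
#' linearly tied to one wide-range profile; strongly correlated).
#'
#' @param n_samples Samples (default 200).
#' @param n_ratiometric,n_wide,n_two_regime Planted pair counts (defaults
#'   50 each; every pair uses two dedicated genes).
#' @param n_independent Independent background genes (default 500).
#' @param noise_sd Multiplicative noise scale of the ratiometric pairs
#'   (default 0.05).
#' @param n_pathway_tight,n_pathway_wide Genes in the planted modules
#'   (defaults 0: no modules).
#' @param abundance_range Range gene mean abundances are drawn from,
#'   log-uniformly (default `c(1, 1000)`).
#' @param high_fraction Fraction of jointly-high samples in 2-regime pairs
#'   (default 0.1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List of class `ra_fixture`: `matrix` (expression tibble), `truth`
#'   (gene_a, gene_b, class, constant -- the planted ratio constant for
#'   ratiometric pairs), `gene_classes` (gene_id, class) and `gene_sets`
#'   (set_id, gene_id long tibble for the planted modules; empty if none).
#' @export
generate_fixture <- function(n_samples = 200L, n_ratiometric = 50L,
                             n_wide = 50L, n_two_regime = 50L,
                             n_independent = 500L, noise_sd = 0.05,
                             n_pathway_tight = 0L, n_pathway_wide = 0L,
                             abundance_range = c(1, 1000),
                             high_fraction = 0.1, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(n_samples >= 10L, noise_sd >= 0)
  set.seed(seed)
  lo <- log(abundance_range[1L]); hi <- log(abundance_range[2L])
  rmean <- function(k) exp(stats::runif(k, lo, hi))
  mult_noise <- function(k, s) pmax(1 + stats::rnorm(k, 0, s), 0.05)

  rows <- list(); ids <- character(0); classes <- character(0)
  truth <- list(); sets <- list()
  add_gene <- function(id, v, cls) {
    rows[[length(rows) + 1L]] <<- v
    ids <<- c(ids, id)
    classes <<- c(classes, cls)
  }

  # ratiometric pairs: shared lognormal base, proportional with 5% noise
  for (k in seq_len(n_ratiometric)) {
    base <- rmean(1L) * exp(stats::rnorm(n_samples, 0, 0.3))
    const <- exp(stats::runif(1L, log(0.2), log(5)))
    ga <- sprintf("RAT%03d_A", k); gb <- sprintf("RAT%03d_B", k)
    add_gene(gb, base, "ratiometric")
    add_gene(ga, const * base * mult_noise(n_samples, noise_sd), "ratiometric")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      gene_a = min(ga, gb), gene_b = max(ga, gb),
      class = "ratiometric",
      constant = if (min(ga, gb) == ga) const else 1 / const)
  }

  # wide-range correlated pairs: linear with offset over a wide range
  for (k in seq_len(n_wide)) {
    b <- exp(stats::runif(n_samples, log(5), log(2000)))
    slope <- stats::runif(1L, 0.5, 3)
    offset <- stats::runif(1L, 20, 100)
    a <- offset + slope * b + stats::rnorm(n_samples, 0, 0.02 * (offset + slope * b))
    a <- pmax(a, 0.01)
    ga <- sprintf("WID%03d_A", k); gb <- sprintf("WID%03d_B", k)
    add_gene(gb, b, "wide"); add_gene(ga, a, "wide")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      gene_a = min(ga, gb), gene_b = max(ga, gb), class = "wide",
      constant = NA_real_)
  }

  # 2-regime pairs: independent low bulk + jointly high subgroup
  n_high <- max(1L, round(high_fraction * n_samples))
  for (k in seq_len(n_two_regime)) {
    a <- stats::rlnorm(n_samples, log(10), 0.4)
    b <- stats::rlnorm(n_samples, log(10), 0.4)
    hi_idx <- seq_len(n_high)   # sample order is exchangeable
    lvl <- stats::runif(1L, 300, 800)
    a[hi_idx] <- lvl * exp(stats::rnorm(n_high, 0, 0.05))
    b[hi_idx] <- lvl * exp(stats::rnorm(n_high, 0, 0.05))
    ga <- sprintf("TWO%03d_A", k); gb <- sprintf("TWO%03d_B", k)
    add_gene(gb, b, "two_regime"); add_gene(ga, a, "two_regime")
    truth[[length(truth) + 1L]] <- tibble::tibble(
      gene_a = min(ga, gb), gene_b = max(ga, gb), class = "two_regime",
      constant = NA_real_)
  }

  # independent background genes
  for (k in seq_len(n_independent)) {
    sdlog <- stats::runif(1L, 0.2, 0.6)
    add_gene(sprintf("IND%04d", k),
             rmean(1L) * exp(stats::rnorm(n_samples, 0, sdlog)), "independent")
  }

  # planted modules
  if (n_pathway_tight > 0L) {
    base <- 200 * exp(stats::rnorm(n_samples, 0, 0.08))   # narrow range
    g <- sprintf("TPW%03d", seq_len(n_pathway_tight))
    for (i in seq_along(g)) {
      ci <- exp(stats::runif(1L, log(0.3), log(3)))
      add_gene(g[i], ci * base * mult_noise(n_samples, noise_sd), "pathway_tight")
    }
    sets[[length(sets) + 1L]] <- tibble::tibble(set_id = "tight_pathway",
                                                gene_id = g)
  }
  if (n_pathway_wide > 0L) {
    base <- exp(stats::runif(n_samples, log(5), log(2000)))  # wide range
    g <- sprintf("WPW%03d", seq_len(n_pathway_wide))
    for (i in seq_along(g)) {
      slope <- stats::runif(1L, 0.5, 2)
      offset <- stats::runif(1L, 20, 100)
      v <- offset + slope * base + stats::rnorm(n_samples, 0, 0.02 * (offset + slope * base))
      add_gene(g[i], pmax(v, 0.01), "pathway_wide")
    }
    sets[[length(sets) + 1L]] <- tibble::tibble(set_id = "wide_pathway",
                                                gene_id = g)
  }

  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  mat <- dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(m))
  structure(
    list(matrix = validate_expression(mat),
         truth = if (length(truth)) dplyr::bind_rows(truth) else
           tibble::tibble(gene_a = character(0), gene_b = character(0),
                          class = character(0), constant = numeric(0)),
         gene_classes = tibble::tibble(gene_id = ids, class = classes),
         gene_sets = if (length(sets)) dplyr::bind_rows(sets) else
           tibble::tibble(set_id = character(0), gene_id = character(0)),
         seed = seed),
    class = "ra_fixture"
  )
}
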