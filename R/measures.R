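#' Configuration for pair association measures
#'
#' Bundles the tunable parameters shared by the ratiometric statistics and the
#' mutual-information baseline.
#'
#' @param delta_cv_threshold Gate on the CV discrepancy below which a pair is
#'   called ratiometric. Default 0.01, the bulk RNA-seq setting; 0.025 is the
#'   usual choice for noisier single-cell libraries.
#' @param stability_rule How `cv_ab` and `cv_ba` collapse into the single
#'   stability value that ranks gated pairs: `"max"` (default, conservative)
#'   or `"mean"`.
#' @param mi_bins Number of equal-frequency bins for the mutual-information
#'   estimator (default 4, giving the \[0, 2\]-bit range). Log base is fixed
#'   at 2.
#' @param cv_ddof Degrees-of-freedom correction for the ratio standard
#'   deviation: 1 (default, sample SD) or 0.
#' @param min_used_fraction Minimum fraction of samples with strictly positive
#'   values in both genes for the ratio statistics to be evaluable
#'   (default 0.95).
#' @return A list of class `ra_config`.
#' @export
measure_config <- function(delta_cv_threshold = 0.01,
                           stability_rule = c("max", "mean"),
                           mi_bins = 4L,
                           cv_ddof = 1L,
                           min_used_fraction = 0.95) {
  stability_rule <- match.arg(stability_rule)
  stopifnot(delta_cv_threshold >= 0, mi_bins >= 2L, cv_ddof %in% c(0L, 1L),
            min_used_fraction >= 0, min_used_fraction <= 1)
  structure(
    list(delta_cv_threshold = delta_cv_threshold,
         stability_rule = stability_rule,
         mi_bins = as.integer(mi_bins),
         mi_log_base = 2,
         cv_ddof = as.integer(cv_ddof),
         min_used_fraction = min_used_fraction),
    class = "ra_config"
  )
}

ra_stability <- function(cv_ab, cv_ba, rule = "max") {
  if (rule == "max") pmax(cv_ab, cv_ba) else (cv_ab + cv_ba) / 2
}

#' Coefficient of variation of both expression ratios
#'
#' For paired expression vectors `a` and `b`, computes the CV (standard
#' deviation over mean) of the per-sample ratios `a/b` and `b/a`. Samples
#' where either gene is zero are excluded, since the ratio is undefined
#' there; the number of samples actually used is returned.
#'
#' @param a,b Equal-length non-negative expression vectors (length >= 3).
#' @param config A [measure_config()]; `cv_ddof` and `min_used_fraction`
#'   are consulted.
#' @return One-row tibble with `cv_ab`, `cv_ba`, `mean_ab`, `mean_ba`,
#'   `n_used`.
#' @examples
#' cv_ratio(c(1, 2, 3), c(2, 2, 2))
#' @export
cv_ratio <- function(a, b, config = measure_config()) {
  check_pair_vectors(a, b)
  used <- a > 0 & b > 0
  n_used <- sum(used)
  if (n_used < 3L || n_used / length(a) < config$min_used_fraction) {
    stop(sprintf("insufficient usable samples for ratio statistics (%d of %d positive in both genes)",
                 n_used, length(a)), call. = FALSE)
  }
  r_ab <- a[used] / b[used]
  r_ba <- b[used] / a[used]
  tibble::tibble(
    cv_ab = cv_of(r_ab, config$cv_ddof),
    cv_ba = cv_of(r_ba, config$cv_ddof),
    mean_ab = mean(r_ab),
    mean_ba = mean(r_ba),
    n_used = n_used
  )
}

cv_of <- function(x, ddof = 1L) {
  m <- mean(x)
  n <- length(x)
  v <- sum((x - m)^2) / (n - ddof)
  sqrt(v) / m
}

check_pair_vectors <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("expression values must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Stringency of fit to a ratiometric relationship
#'
#' The discrepancy between the two ratio CVs, `|CV(A/B) - CV(B/A)|`. It is
#' zero for an exactly proportional pair, invariant to gene order, and small
#' whenever the two CVs agree -- the situation in which a single CV summarises
#' the pair's ratio stability.
#'
#' @param cv_ab,cv_ba Non-negative ratio CVs (vectorised).
#' @return `|cv_ab - cv_ba|`.
#' @export
delta_cv <- function(cv_ab, cv_ba) {
  stopifnot(all(cv_ab >= 0), all(cv_ba >= 0))
  abs(cv_ab - cv_ba)
}

#' Apply the ratiometric gate and compute stability
#'
#' A pair follows a ratiometric profile when its delta-CV falls strictly below
#' the configured gate. Gated pairs are then ranked by their stability -- the
#' combined magnitude of the two ratio CVs; the smaller the stability, the
#' stronger the ratiometric association.
#'
#' @param pm Data frame with columns `cv_ab`, `cv_ba` and `delta_cv` (for
#'   instance rows of an [all_pairs()] table or the output of
#'   [pair_measures()]).
#' @param config A [measure_config()].
#' @return `pm` with logical `ratiometric` and numeric `stability` columns
#'   appended.
#' @export
is_ratiometric <- function(pm, config = measure_config()) {
  stopifnot(all(c("cv_ab", "cv_ba", "delta_cv") %in% names(pm)))
  pm |>
    dplyr::mutate(
      ratiometric = .data$delta_cv < config$delta_cv_threshold,
      stability = ra_stability(.data$cv_ab, .data$cv_ba, config$stability_rule)
    )
}

#' Pearson association of a gene pair
#'
#' @param a,b Equal-length numeric vectors (length >= 3), neither constant.
#' @return One-row tibble with the sample correlation `r` and `r2 = r^2`.
#' @export
pearson_association <- function(a, b) {
  check_assoc_vectors(a, b)
  r <- stats::cor(a, b)
  tibble::tibble(r = r, r2 = r^2)
}

#' Squared Spearman rank association of a gene pair
#'
#' Ties receive average ranks, so the statistic equals the squared Pearson
#' correlation of the rank-transformed vectors.
#'
#' @param a,b Equal-length numeric vectors (length >= 3), neither constant.
#' @return Squared Spearman correlation, a scalar in `[0, 1]`.
#' @export
spearman_association <- function(a, b) {
  check_assoc_vectors(a, b)
  stats::cor(a, b, method = "spearman")^2
}

check_assoc_vectors <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  invisible(TRUE)
}

# equal-frequency bin labels in 1..bins; average-rank ties, tie groups on a
# boundary fall into the lower bin
mi_bin <- function(x, bins) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  pmin(pmax(ceiling(bins * r / n), 1L), bins)
}

#' Binned mutual information of a gene pair
#'
#' Each vector is discretised into `bins` equal-frequency bins (average-rank
#' tie handling; tie groups spanning a boundary fall deterministically into
#' the lower bin) and the plug-in mutual information of the joint bin
#' histogram is returned in bits. With the default 4 bins the statistic lies
#' in `[0, 2]`.
#'
#' @param a,b Equal-length numeric vectors, neither constant, with at least
#'   `bins^2` samples.
#' @param bins Number of bins per margin (default 4).
#' @return Mutual information in bits.
#' @examples
#' b <- 1:8
#' mutual_information(2 * b, b)  # 2 bits: diagonal joint histogram
#' @export
mutual_information <- function(a, b, bins = 4L) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < bins) {
    stop("need at least as many samples as bins", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  if (min(a) == max(a) || min(b) == max(b)) {
    stop("degenerate binning: constant vector", call. = FALSE)
  }
  ba <- mi_bin(a, bins)
  bb <- mi_bin(b, bins)
  joint <- table(factor(ba, levels = seq_len(bins)),
                 factor(bb, levels = seq_len(bins)))
  mi_from_counts(joint)
}

mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pa <- rowSums(p)
  pb <- colSums(p)
  terms <- p * log2(p / outer(pa, pb))
  sum(terms[p > 0])
}

#' All association statistics for one gene pair
#'
#' Computes the full record used throughout the package: both ratio CVs,
#' delta-CV, the ratio means (estimates of the ratiometric constants `c` and
#' `d = 1/c`), Pearson r and R-squared, squared Spearman correlation, and
#' binned mutual information. Ratio statistics use only samples where both
#' genes are positive; the correlation and MI statistics use all samples.
#' A pair with too few usable samples is reported as not evaluable for the
#' ratiometric statistics (`ra_evaluable = FALSE`, CV fields `NA`) rather
#' than silently scored.
#'
#' @param a,b Equal-length non-negative expression vectors.
#' @param config A [measure_config()].
#' @return One-row tibble with columns `cv_ab`, `cv_ba`, `delta_cv`,
#'   `mean_ab`, `mean_ba`, `pearson_r`, `pearson_r2`, `spearman_r2`, `mi`,
#'   `n_used`, `ra_evaluable`.
#' @export
pair_measures <- function(a, b, config = measure_config()) {
  check_pair_vectors(a, b)
  ratio <- tryCatch(cv_ratio(a, b, config), error = function(e) NULL)
  pe <- tryCatch(pearson_association(a, b), error = function(e) tibble::tibble(r = NA_real_, r2 = NA_real_))
  sp <- tryCatch(spearman_association(a, b), error = function(e) NA_real_)
  mi <- tryCatch(mutual_information(a, b, config$mi_bins), error = function(e) NA_real_)
  if (is.null(ratio)) {
    ratio <- tibble::tibble(cv_ab = NA_real_, cv_ba = NA_real_,
                            mean_ab = NA_real_, mean_ba = NA_real_,
                            n_used = sum(a > 0 & b > 0))
    evaluable <- FALSE
  } else {
    evaluable <- TRUE
  }
  tibble::tibble(
    cv_ab = ratio$cv_ab, cv_ba = ratio$cv_ba,
    delta_cv = abs(ratio$cv_ab - ratio$cv_ba),
    mean_ab = ratio$mean_ab, mean_ba = ratio$mean_ba,
    pearson_r = pe$r, pearson_r2 = pe$r2,
    spearman_r2 = sp, mi = mi,
    n_used = ratio$n_used, ra_evaluable = evaluable
  )
}
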