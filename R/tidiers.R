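#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the step table of a stringency sweep
#'
#' @param x An [stringency_sweep()] object.
#' @param ... Unused.
#' @return Tibble (step, threshold, n_vertices, n_edges).
#' @method tidy ra_sweep
#' @export
tidy.ra_sweep <- function(x, ...) {
  x$steps
}

#' One-row summary of a stringency sweep
#'
#' @param x An [stringency_sweep()] object.
#' @param ... Unused.
#' @return Tibble with method, mode, step count and final graph sizes.
#' @method glance ra_sweep
#' @export
glance.ra_sweep <- function(x, ...) {
  tibble::tibble(method = x$method, mode = x$mode, n_steps = x$n_steps,
                 final_vertices = x$steps$n_vertices[x$n_steps],
                 final_edges = x$steps$n_edges[x$n_steps])
}

#' Tidy an all-pairs table
#'
#' @param x An [all_pairs()] table.
#' @param ... Unused.
#' @return The pair table as a plain tibble.
#' @method tidy ra_pairs
#' @export
tidy.ra_pairs <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ra_pairs")
  attr(out, "config") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of an all-pairs table
#'
#' @param x An [all_pairs()] table.
#' @param ... Unused.
#' @return Tibble with pair counts, evaluable counts and the gated-pair count
#'   under the attached configuration.
#' @method glance ra_pairs
#' @export
glance.ra_pairs <- function(x, ...) {
  cfg <- pair_config(x)
  tibble::tibble(
    n_pairs = nrow(x),
    n_evaluable = sum(x$ra_evaluable),
    n_gated = sum(x$ra_evaluable & x$delta_cv < cfg$delta_cv_threshold, na.rm = TRUE),
    delta_cv_threshold = cfg$delta_cv_threshold,
    n_samples = attr(x, "n_samples") %||% NA_integer_
  )
}

#' Tidy a bivariate-normal sweep result
#'
#' @param x A [simulate_bivariate_normal()] result.
#' @param ... Unused.
#' @return The per-SD tibble.
#' @method tidy ra_sim_bivariate
#' @export
tidy.ra_sim_bivariate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ra_sim_bivariate")
  tibble::as_tibble(out)
}

#' One-row summary of a bivariate-normal sweep
#'
#' @param x A [simulate_bivariate_normal()] result.
#' @param ... Unused.
#' @return Tibble with the grand-mean sample correlation (pooled over every
#'   run at every SD), its Monte-Carlo standard error, the generative
#'   correlation, and the range of the ratiometric fraction.
#' @method glance ra_sim_bivariate
#' @export
glance.ra_sim_bivariate <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble::tibble(
    grand_mean_r = mean(x$mean_r),
    se_grand_mean_r = sqrt(sum(x$se_r^2)) / nrow(x),
    generative_correlation = spec$correlation,
    max_fraction = max(x$ratiometric_fraction),
    min_fraction = min(x$ratiometric_fraction)
  )
}

#' Tidy a range-restriction simulation result
#'
#' @param x A [simulate_range_restriction()] result.
#' @param ... Unused.
#' @return The long per-SD, per-statistic tibble.
#' @method tidy ra_sim_range
#' @export
tidy.ra_sim_range <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ra_sim_range")
  tibble::as_tibble(out)
}

#' Tidy the ground truth of a synthetic fixture
#'
#' @param x A [generate_fixture()] result.
#' @param ... Unused.
#' @return The truth tibble (gene_a, gene_b, class, constant).
#' @method tidy ra_fixture
#' @export
tidy.ra_fixture <- function(x, ...) {
  x$truth
}

#' One-row summary of a synthetic fixture
#'
#' @param x A [generate_fixture()] result.
#' @param ... Unused.
#' @return Tibble with gene, sample and planted-class counts.
#' @method glance ra_fixture
#' @export
glance.ra_fixture <- function(x, ...) {
  cls <- table(x$gene_classes$class)
  tibble::tibble(
    n_genes = nrow(x$matrix),
    n_samples = length(expr_sample_ids(x$matrix)),
    n_ratiometric_pairs = sum(x$truth$class == "ratiometric"),
    n_wide_pairs = sum(x$truth$class == "wide"),
    n_two_regime_pairs = sum(x$truth$class == "two_regime"),
    n_independent_genes = as.integer(cls["independent"] %||% 0L),
    seed = x$seed
  )
}
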