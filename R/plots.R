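#' Plot the gene/edge inclusion profile of a sweep
#'
#' Solid line: percentage of genes included; dashed line: accepted edges
#' (scaled to the secondary axis), both against the stringency step.
#'
#' @param object An [stringency_sweep()] object.
#' @param total_genes Gene-universe size for the percentage; defaults to the
#'   vertex count at the final step.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ra_sweep
#' @export
autoplot.ra_sweep <- function(object, total_genes = NULL, ...) {
  if (is.null(total_genes)) total_genes <- max(object$steps$n_vertices, 1L)
  prof <- inclusion_profile(object, total_genes)
  emax <- max(prof$n_edges, 1)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$percent_genes)) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$n_edges / emax),
                       linetype = "dashed") +
    ggplot2::scale_y_continuous(
      name = "% genes included",
      sec.axis = ggplot2::sec_axis(~ . * emax / 100, name = "edges accepted")) +
    ggplot2::labs(x = "stringency step (1 = most stringent)",
                  title = sprintf("%s inclusion profile", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a range-restriction simulation
#'
#' Mean +/- SE of each statistic against the SD of gene B, one panel per
#' statistic: the correlation-based statistics fall as the range narrows
#' while the ratio CVs stay flat.
#'
#' @param object A [simulate_range_restriction()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ra_sim_range
#' @export
autoplot.ra_sim_range <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sd_b, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$statistic, scales = "free_y") +
    ggplot2::labs(x = "SD of gene B", y = "mean over replicates") +
    ggplot2::theme_minimal()
}

#' Plot a bivariate-normal sweep
#'
#' The ratiometric fraction (solid) and the mean sample correlation (dashed)
#' against the shared standard deviation.
#'
#' @param object A [simulate_bivariate_normal()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ra_sim_bivariate
#' @export
autoplot.ra_sim_bivariate <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$sd)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ratiometric_fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_r), linetype = "dashed") +
    ggplot2::labs(x = "standard deviation of A and B",
                  y = "ratiometric fraction (solid) / mean r (dashed)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a permutation-null recovery envelope
#'
#' Observed within-pathway edge counts against graph size, over the
#' permutation null mean and min--max envelope (dashed).
#'
#' @param object A [permuted_pathway_null()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ra_perm_null
#' @export
autoplot.ra_perm_null <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$target_vertices)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_min,
                                      ymax = .data$null_max), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "graph size |V(G)|", y = "within-pathway edges",
                  title = attr(object, "pathway_id")) +
    ggplot2::theme_minimal()
}

#' Plot per-depth ranking consistency
#'
#' @param consistency A [ranking_consistency()] tibble, or several bound
#'   together with a `method` column.
#' @return A ggplot object.
#' @export
plot_ranking_consistency <- function(consistency) {
  p <- ggplot2::ggplot(consistency,
                       ggplot2::aes(x = .data$depth, y = .data$fraction))
  if ("method" %in% names(consistency)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$method))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "ranking depth k", y = "top-k overlap fraction") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}
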