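#' Plot a conservation profile
#'
#' Bar height is the per-column conservation (consensus-residue frequency);
#' bars are labeled with the consensus residue, mirroring the shaded
#' consensus rows of theme figures.
#'
#' @param object A [consensus_profile()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$score), width = 0.9,
                      show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$consensus_residue),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_fill_gradient(low = "grey85", high = "grey25",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1.08),
                                expand = ggplot2::expansion(0)) +
    ggplot2::labs(x = "theme column", y = "conservation",
                  title = "Consensus and per-column conservation") +
    ggplot2::theme_minimal()
}

#' Plot a fitted score null with its Gumbel density
#'
#' @param object A `gumbel_fit`.
#' @param scores Optional raw score sample to show as a histogram.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gumbel_fit <- function(object, scores = NULL, ...) {
  lo <- qgumbel(0.0005, object$mu, object$beta)
  hi <- qgumbel(0.9995, object$mu, object$beta)
  grid <- seq(lo, hi, length.out = 300)
  dens <- tibble::tibble(
    score = grid,
    density = exp(-(grid - object$mu) / object$beta -
                    exp(-(grid - object$mu) / object$beta)) / object$beta
  )
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$score, y = .data$density))
  if (!is.null(scores)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(score = scores),
      mapping = ggplot2::aes(x = .data$score, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 40, fill = "grey80", color = "grey60"
    )
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "alignment score", y = "density",
                  title = sprintf("Gumbel null (mu = %.2f, beta = %.2f)",
                                  object$mu, object$beta)) +
    ggplot2::theme_minimal()
}

#' Plot the hit funnel of a pipeline run
#'
#' Shows every scanned domain's E-value and theme coverage with the
#' retention thresholds, colored by lineage.
#'
#' @param hits A hits tibble from [scan_database()].
#' @param evalue_max,coverage_min Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_hit_filters <- function(hits, evalue_max = 1e-3, coverage_min = 0.85) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$coverage, y = .data$evalue,
                                     color = .data$lineage,
                                     shape = .data$retained)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = evalue_max, linetype = 2) +
    ggplot2::geom_vline(xintercept = coverage_min, linetype = 2) +
    ggplot2::labs(x = "theme coverage", y = "E-value",
                  title = "Scan hits against the retention thresholds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
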