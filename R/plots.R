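#' Per-age-group error curves
#'
#' Line plot of MAE per one-year age bin for each method, the standard
#' way to compare estimators across the developmental range.
#'
#' @param bin_mae a tibble as in `study$bin_mae` (columns `method`,
#'   `age_bin`, `mae`, and optionally `split`).
#' @return a ggplot object.
#' @export
plot_bin_mae <- function(bin_mae) {
  p <- ggplot2::ggplot(
    bin_mae,
    ggplot2::aes(x = .data$age_bin, y = .data$mae,
                 colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Age group (years)", y = "MAE (years)",
                  colour = "Method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if ("split" %in% names(bin_mae) && length(unique(bin_mae$split)) > 1) {
    p <- p + ggplot2::facet_wrap(~split)
  }
  p
}

#' Chronological vs dental age agreement plot
#'
#' Scatter of DA against CA with the identity line, faceted by method;
#' the visual check of calibration and spread.
#'
#' @param pairs a paired-ages tibble (possibly several methods).
#' @return a ggplot object.
#' @export
plot_agreement <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$age, y = .data$dental_age,
                                      colour = .data$sex)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Dental age (years)", colour = "Sex") +
    ggplot2::theme_minimal()
}

#' @describeIn run_study plot a study: `type = "bin_mae"` (default)
#'   per-age-group error curves, `type = "agreement"` CA-vs-DA scatter
#'   of the score-model estimates.
#' @param object a `dae_study`.
#' @param type which panel to draw.
#' @param ... unused.
#' @method autoplot dae_study
#' @export
autoplot.dae_study <- function(object, type = c("bin_mae", "agreement"), ...) {
  type <- match.arg(type)
  if (type == "bin_mae") {
    plot_bin_mae(object$bin_mae)
  } else {
    if (nrow(object$estimates) == 0) abort("study has no score-model estimates")
    plot_agreement(object$estimates)
  }
}
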