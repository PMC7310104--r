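#' Plot per-amplicon coverage
#'
#' Boxplot of coverage per amplicon across samples with the dropout
#' threshold as a dashed line, the standard QC view of a multiplex panel.
#'
#' @param report a [coverage_report()].
#' @return a ggplot object.
#' @export
plot_coverage <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  ggplot2::ggplot(report$per_sample,
                  ggplot2::aes(x = .data$amplicon, y = .data$coverage)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = report$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "coverage (reads)",
                  title = "Per-amplicon sequencing coverage") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) plot_coverage(object)

#' Plot a fitted bias curve against its control gradient
#'
#' Observed-vs-expected methylation of the control ladder with the fitted
#' hyperbolic curve and the unbiased identity line.
#'
#' @param fit a [fit_bias()] result.
#' @param gradient the gradient tibble the fit was computed from.
#' @return a ggplot object.
#' @export
plot_bias <- function(fit, gradient) {
  g <- as_tibble(gradient)
  if (!"amplicon" %in% names(g)) g$amplicon <- "amplicon"
  grid <- tidyr::expand_grid(amplicon = fit$amplicon,
                             expected = seq(0, 1, by = 0.01)) |>
    left_join(select(as_tibble(unclass_tbl(fit)), "amplicon", "b"),
              by = "amplicon") |>
    mutate(observed = bias_forward(.data$expected, .data$b[1]))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~amplicon) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expected methylation", y = "observed methylation",
                  title = "PCR bias calibration") +
    ggplot2::theme_bw()
}

#' @method autoplot bias_fit
#' @export
autoplot.bias_fit <- function(object, gradient, ...) {
  plot_bias(object, gradient)
}

#' Plot sensitivity stars across the coverage grid
#'
#' @param result a [sensitivity_test()] tibble.
#' @return a ggplot object.
#' @export
plot_sensitivity <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(
    x = factor(.data$coverage),
    y = factor(.data$level * 100),
    fill = -log10(pmax(.data$p, 1e-16))
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars)) +
    ggplot2::facet_wrap(~amplicon) +
    ggplot2::labs(x = "coverage (reads)", y = "methylation level (%)",
                  fill = "-log10 p",
                  title = "Detection sensitivity by coverage") +
    ggplot2::theme_bw()
}

#' Plot an epiallele pattern matrix
#'
#' Barplot of pattern frequencies per (sample, amplicon), most frequent
#' patterns first; N-containing patterns are omitted.
#'
#' @param pm a [pattern_matrix()].
#' @param top show at most this many patterns per panel.
#' @return a ggplot object.
#' @export
plot_patterns <- function(pm, top = 12) {
  d <- pm |>
    filter(!.data$has_n) |>
    group_by(.data$sample, .data$amplicon) |>
    dplyr::slice_max(.data$frequency, n = top, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$pattern, -.data$frequency),
    y = .data$frequency * 100
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(sample ~ amplicon, scales = "free_x") +
    ggplot2::labs(x = "methylation pattern (C = methylated)",
                  y = "frequency (%)",
                  title = "Epiallele pattern frequencies") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot pattern_matrix
#' @export
autoplot.pattern_matrix <- function(object, ...) plot_patterns(object, ...)
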