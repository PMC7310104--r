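#' Coverage quality-control report
#'
#' Flags every (sample, amplicon) pair whose coverage falls strictly below
#' the threshold (default 100 reads, the conventional dropout cut-off for
#' multiplex bisulphite panels: exactly 100 passes). An amplicon is a
#' panel-level `DROPOUT` when its median coverage across samples is below
#' the threshold — the median is robust to single failed samples, and the
#' per-sample flags are retained alongside.
#'
#' @param tables one or more methylation tables from [call_methylation()]
#'   bound together (or any tibble with `sample`, `amplicon`, `coverage`).
#' @param threshold minimum acceptable coverage (default 100).
#' @return object of class `coverage_report`: list with `per_sample`
#'   (tibble `sample`, `amplicon`, `coverage`, `low`), `per_amplicon`
#'   (tibble `amplicon`, `median_coverage`, `status`) and `threshold`.
#' @export
coverage_report <- function(tables, threshold = 100) {
  if (nrow(tables) == 0 || dplyr::n_distinct(tables$sample) < 1) {
    abort("need at least one sample")
  }
  per_sample <- tables |>
    distinct(.data$sample, .data$amplicon, .data$coverage) |>
    mutate(low = .data$coverage < threshold)
  per_amplicon <- per_sample |>
    group_by(.data$amplicon) |>
    summarise(median_coverage = median(.data$coverage), .groups = "drop") |>
    mutate(status = if_else(.data$median_coverage < threshold,
                            "DROPOUT", "PASS"))
  structure(
    list(per_sample = per_sample, per_amplicon = per_amplicon,
         threshold = threshold),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  n_drop <- sum(x$per_amplicon$status == "DROPOUT")
  cat(sprintf(
    "<coverage_report> %d amplicons, %d samples, threshold %gX: %d dropout(s)\n",
    nrow(x$per_amplicon), dplyr::n_distinct(x$per_sample$sample),
    x$threshold, n_drop
  ))
  print(x$per_amplicon, ...)
  invisible(x)
}

#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  left_join(x$per_sample, x$per_amplicon, by = "amplicon")
}

#' Post-sequencing primer rebalancing plan
#'
#' Operationalises the rescue of a poorly balanced multiplex panel:
#' relative to the panel's median amplicon coverage, under-represented
#' amplicons (below `low_frac` x median) have their primer concentration
#' doubled, over-represented ones (above `high_frac` x median) halved,
#' and dropout amplicons are moved to a separate sub-panel with a 3-fold
#' primer concentration increase.
#'
#' @param report a [coverage_report()].
#' @param low_frac,high_frac multiples of the median coverage delimiting
#'   under/over-representation (defaults 0.5 and 2).
#' @param subpanel_multiplier concentration multiplier for sub-panel
#'   amplicons (default 3).
#' @return tibble `amplicon`, `median_coverage`, `action` (`KEEP`,
#'   `DOUBLE`, `HALVE`, `SUBPANEL`), `multiplier`.
#' @export
rebalance <- function(report, low_frac = 0.5, high_frac = 2,
                      subpanel_multiplier = 3) {
  stopifnot(inherits(report, "coverage_report"))
  amp <- report$per_amplicon
  if (nrow(amp) < 2) abort("rebalancing needs at least two amplicons")
  if (all(amp$status == "DROPOUT")) {
    warn("all amplicons are dropouts; plan is all-SUBPANEL")
  }
  med <- median(amp$median_coverage)
  amp |>
    mutate(
      action = dplyr::case_when(
        .data$status == "DROPOUT" ~ "SUBPANEL",
        .data$median_coverage < med * low_frac ~ "DOUBLE",
        .data$median_coverage > med * high_frac ~ "HALVE",
        TRUE ~ "KEEP"
      ),
      multiplier = dplyr::case_when(
        .data$action == "SUBPANEL" ~ subpanel_multiplier,
        .data$action == "DOUBLE" ~ 2,
        .data$action == "HALVE" ~ 0.5,
        TRUE ~ 1
      )
    ) |>
    select("amplicon", "median_coverage", "action", "multiplier")
}

#' Remove low-coverage amplicon-sample pairs from a methylation table
#'
#' Drops the rows of every (sample, amplicon) pair flagged below threshold
#' in the coverage report. Idempotent.
#'
#' @param table a methylation table.
#' @param report a [coverage_report()] over matching keys.
#' @return filtered methylation table.
#' @export
filter_table <- function(table, report) {
  stopifnot(inherits(report, "coverage_report"))
  flagged <- filter(report$per_sample, .data$low) |>
    select("sample", "amplicon")
  out <- anti_join(table, flagged, by = c("sample", "amplicon"))
  n_removed <- nrow(table) - nrow(out)
  if (n_removed > 0) {
    inform(sprintf(
      "filter_table: removed %d row(s) across %d low-coverage pair(s)",
      n_removed, nrow(flagged)
    ))
  }
  if (nrow(out) == 0) warn("all rows removed by coverage filtering")
  out
}
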