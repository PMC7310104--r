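#' Forward PCR-bias model
#'
#' Preferential amplification of the methylated (C-rich) or unmethylated
#' (T-rich) post-conversion template distorts observed methylation away
#' from the true molecule fraction. With a single per-amplicon bias
#' coefficient `b` (b = 1 unbiased, b > 1 favouring the methylated
#' template), the observed fraction after amplification of an expected
#' fraction `E` is
#' \deqn{O = \frac{bE}{1 + (b - 1)E},}
#' monotone increasing in `E` and fixing 0 and 1.
#'
#' @param E expected methylation fraction(s) in `[0,1]`.
#' @param b bias coefficient, `b > 0`.
#' @return observed fraction(s).
#' @export
#' @examples
#' bias_forward(0.5, 2)  # 0.6667
bias_forward <- function(E, b) {
  if (any(b <= 0)) abort("bias coefficient b must be > 0")
  stopifnot(all(E >= 0 & E <= 1))
  # mathematically in [0,1]; clamp away one-ULP overshoot at E = 1
  clamp01(b * E / (1 + (b - 1) * E))
}

#' Fit per-amplicon PCR bias from a methylated-control gradient
#'
#' Regression of observed against expected methylation over a control
#' ladder (default design 0/10/25/50/75/90/100%). The default
#' `"hyperbolic"` mode estimates the single coefficient `b` of
#' [bias_forward()] by bounded least squares over `b` in `[0.01, 100]`;
#' it is invertible in closed form, so correction is exact. The
#' `"cubic"` mode additionally fits a cubic polynomial of expected on
#' observed as the correction curve. In both modes the
#' `needs_correction` flag derives from the hyperbolic coefficient:
#' `|b - 1| > tolerance`.
#'
#' @param gradient tibble with columns `expected` and `observed` in
#'   `[0,1]`, optionally `amplicon` (fits are per amplicon).
#' @param mode `"hyperbolic"` (default) or `"cubic"`.
#' @param tolerance flag threshold on `|b - 1|` (default 0.1).
#' @return tibble of class `bias_fit`, one row per amplicon: `amplicon`,
#'   `mode`, `b`, `rms` (residual RMS of the mode's fit),
#'   `needs_correction`, `c0`..`c3` (cubic coefficients, `NA` under
#'   hyperbolic mode).
#' @export
fit_bias <- function(gradient, mode = c("hyperbolic", "cubic"),
                     tolerance = 0.1) {
  mode <- match.arg(mode)
  g <- as_tibble(gradient)
  if (!"amplicon" %in% names(g)) g$amplicon <- "amplicon"
  stopifnot(all(c("expected", "observed") %in% names(g)))
  if (any(g$expected < 0 | g$expected > 1 |
          g$observed < 0 | g$observed > 1, na.rm = TRUE)) {
    abort("expected and observed fractions must lie in [0, 1]")
  }
  out <- purrr::map(split(g, g$amplicon), function(d) {
    d <- filter(d, !is.na(.data$observed))
    if (dplyr::n_distinct(d$expected) < 3) {
      abort("bias fitting needs >= 3 distinct expected levels")
    }
    if (dplyr::n_distinct(d$observed) < 2) {
      abort(sprintf("degenerate gradient for amplicon %s: all observed values equal",
                    d$amplicon[1]))
    }
    ss <- function(b) sum((d$observed - bias_forward(d$expected, b))^2)
    opt <- optimize(ss, interval = c(0.01, 100), tol = 1e-9)
    b <- opt$minimum
    row <- tibble(
      amplicon = d$amplicon[1], mode = mode, b = b,
      rms = sqrt(opt$objective / nrow(d)),
      needs_correction = abs(b - 1) > tolerance,
      c0 = NA_real_, c1 = NA_real_, c2 = NA_real_, c3 = NA_real_
    )
    if (mode == "cubic") {
      fit <- lm(expected ~ observed + I(observed^2) + I(observed^3),
                data = d)
      cf <- unname(coef(fit))
      row$c0 <- cf[1]; row$c1 <- cf[2]; row$c2 <- cf[3]; row$c3 <- cf[4]
      row$rms <- sqrt(mean(stats::residuals(fit)^2))
    }
    row
  })
  res <- bind_rows(out)
  res <- res[match(unique(g$amplicon), res$amplicon), ]
  structure(res, class = c("bias_fit", class(tibble())))
}

#' @method tidy bias_fit
#' @export
tidy.bias_fit <- function(x, ...) as_tibble(unclass_tbl(x))

#' @method glance bias_fit
#' @export
glance.bias_fit <- function(x, ...) {
  tibble(
    n_amplicons = nrow(x),
    n_corrected = sum(x$needs_correction),
    mean_b = mean(x$b),
    mean_rms = mean(x$rms)
  )
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), "bias_fit")
  x
}

#' Correct observed methylation for PCR bias
#'
#' Inverts the fitted bias model. Under the hyperbolic mode the exact
#' inverse of [bias_forward()] is used,
#' \deqn{\hat E = \frac{O}{b - (b - 1)O},}
#' under the cubic mode the fitted polynomial is evaluated; both are
#' clamped to `[0,1]` (clamping events are reported). Amplicons whose
#' `needs_correction` flag is `FALSE` pass through unchanged.
#'
#' @param x either a numeric vector of observed fractions (with a
#'   single-row `fit`), or a methylation table from [call_methylation()]
#'   whose per-CpG betas are corrected using each amplicon's coefficient.
#' @param fit a [fit_bias()] result.
#' @param force apply the correction even where `needs_correction` is
#'   `FALSE` (default `FALSE`).
#' @return corrected vector, or the methylation table with `beta`
#'   replaced by the corrected value and a logical `corrected` column.
#' @export
#' @examples
#' f <- fit_bias(tibble::tibble(expected = c(0, .1, .25, .5, .75, .9, 1),
#'                              observed = bias_forward(c(0, .1, .25, .5, .75, .9, 1), 2)))
#' bias_correct(2 / 3, f)  # 0.5
bias_correct <- function(x, fit, force = FALSE) {
  stopifnot(inherits(fit, "bias_fit"))
  if (is.numeric(x)) {
    if (nrow(fit) != 1) {
      abort("vector correction needs a single-amplicon bias fit")
    }
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      abort("observed fractions must lie in [0, 1]")
    }
    return(correct_values(x, fit[1, ], force))
  }
  out <- x
  out$corrected <- FALSE
  for (i in seq_len(nrow(fit))) {
    row <- fit[i, ]
    idx <- which(out$amplicon == row$amplicon)
    if (length(idx) == 0) next
    if (row$needs_correction || force) {
      out$beta[idx] <- correct_values(out$beta[idx], row, force)
      out$corrected[idx] <- TRUE
    }
  }
  out
}

correct_values <- function(o, row, force) {
  if (!row$needs_correction && !force) return(o)
  est <- if (row$mode == "hyperbolic") {
    o / (row$b - (row$b - 1) * o)
  } else {
    row$c0 + row$c1 * o + row$c2 * o^2 + row$c3 * o^3
  }
  clamped <- sum(est < 0 | est > 1, na.rm = TRUE)
  if (clamped > 0) {
    inform(sprintf("bias_correct: clamped %d value(s) to [0, 1]", clamped))
  }
  clamp01(est)
}

#' Build a control gradient table from amplicon summaries
#'
#' Joins expected control fractions onto observed per-amplicon mean
#' methylation, yielding the input of [fit_bias()].
#'
#' @param summaries output of [summarise_amplicons()] over control
#'   samples.
#' @param expected named numeric vector mapping sample label to expected
#'   methylation fraction.
#' @return tibble `amplicon`, `sample`, `expected`, `observed`.
#' @export
control_gradient <- function(summaries, expected) {
  exp_tbl <- tibble(sample = names(expected),
                    expected = unname(expected))
  summaries |>
    inner_join(exp_tbl, by = "sample") |>
    select("amplicon", "sample", "expected", observed = "amplicon_beta")
}
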