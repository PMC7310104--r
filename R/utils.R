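#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join bind_rows n across pull rename
#'   first count if_else
#' @importFrom stats optimize lm rbinom rnbinom rhyper runif t.test prop.test
#'   cor.test median coef setNames p.adjust
#' @importFrom utils head modifyList packageVersion
NULL

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Significance stars for the assay's p-value scheme
#'
#' Maps p-values onto the star categories used throughout the package's
#' sensitivity reports: `ns` (p >= 0.05), `*` (0.01 <= p < 0.05),
#' `**` (0.001 <= p < 0.01), `***` (0.0001 <= p < 0.001) and `****`
#' (p < 0.0001). `NA` p-values map to `NA`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
#' @examples
#' p_stars(c(0.2, 0.03, 0.002, 2e-5))
p_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- as.character(cut(
    p[ok],
    breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
    labels = c("****", "***", "**", "*", "ns"),
    right = FALSE
  ))
  out
}

# Run code under a fixed seed when one is given, otherwise use the
# current RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Reverse complement preserving IUPAC Y/R ambiguity (Y <-> R under
# complement) and N.
revcomp <- function(x) {
  chartr("ACGTYRN", "TGCARYN", vapply(
    strsplit(x, NULL),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  ))
}

s2c <- function(x) strsplit(x, NULL)[[1]]

phred_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)
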