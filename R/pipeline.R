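#' Read a pipeline run configuration from YAML
#'
#' The configuration names the panel (either `panel_tsv` or `bed` +
#' `fasta` + optional `primer_len`), a sample sheet mapping sample labels
#' to FASTQ paths and roles (`sample`, or `control:<expected fraction>`
#' for calibration controls), processing thresholds and an output
#' directory. Every threshold falls back to the assay's conventional
#' default: `min_q` 30, `min_len` 20, `clip` 1, `max_mismatch` 1,
#' `min_coverage` 100, `bias_tolerance` 0.1.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(min_q = 30, min_len = 20, clip = 1, max_mismatch = 1,
                   min_coverage = 100, bias_tolerance = 0.1, seed = NULL,
                   out_dir = ".")
  cfg <- modifyList(defaults, cfg)
  if (!is.null(cfg$samples)) {
    roles <- purrr::map_chr(cfg$samples, ~ .x$role %||% "sample")
    bad <- !grepl("^(sample|control:)", roles)
    if (any(bad)) abort("sample roles must be 'sample' or 'control:<fraction>'")
    fr <- suppressWarnings(as.numeric(sub("^control:", "", roles[grepl("^control:", roles)])))
    if (any(is.na(fr) | fr < 0 | fr > 1)) {
      abort("control expected fractions must lie in [0, 1]")
    }
  }
  structure(cfg, class = "run_config")
}

load_config_panel <- function(cfg) {
  if (!is.null(cfg$panel_tsv)) {
    if (!file.exists(cfg$panel_tsv)) {
      abort(sprintf("panel file not found: %s", cfg$panel_tsv))
    }
    load_panel_tsv(cfg$panel_tsv)
  } else {
    for (p in c(cfg$bed, cfg$fasta)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("panel file not found: %s", p %||% "<missing>"))
      }
    }
    load_panel(cfg$bed, cfg$fasta, primer_spec = cfg$primer_len %||% 0L)
  }
}

provenance_header <- function(cfg) {
  c(sprintf("# bisamp %s", as.character(packageVersion("bisamp"))),
    sprintf("# config_hash: %s",
            rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])),
    sprintf("# seed: %s", cfg$seed %||% "none"))
}

write_output <- function(tbl, cfg, name) {
  path <- file.path(cfg$out_dir, name)
  readr::write_lines(provenance_header(cfg), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full processing pipeline on a configured sample set
#'
#' Trim, assign, call methylation and QC every sample in the
#' configuration; when calibration controls are present, fit the
#' per-amplicon PCR bias from the control gradient and emit a corrected
#' methylation table alongside the raw one. Read counts at each stage and
#' the per-sample conversion-rate estimate are logged, and all outputs
#' carry a provenance header (version, configuration hash, seed).
#'
#' @param cfg a `run_config` from [read_run_config()].
#' @return (invisibly) list with `table`, `filtered`, `summaries`,
#'   `report`, `patterns`, `conversion`, and, when controls are present,
#'   `bias_fit` and `corrected`; TSV files are written under
#'   `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  panel <- load_config_panel(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  per_sample <- purrr::imap(cfg$samples, function(s, label) {
    reads <- read_fastq(s$fastq)
    trimmed <- trim_reads(reads, min_q = cfg$min_q, min_len = cfg$min_len,
                          clip = cfg$clip)
    asg <- assign_reads(trimmed, panel, max_mismatch = cfg$max_mismatch)
    n_assigned <- sum(!asg$amplicon %in% c("UNASSIGNED", "AMBIGUOUS"))
    inform(sprintf(
      "%s: %d reads in, %d after trimming, %d assigned",
      label, nrow(reads), nrow(trimmed), n_assigned
    ))
    if (n_assigned == 0) warn(sprintf("no reads assigned for sample %s", label))
    conv <- conversion_rate(asg)
    inform(sprintf("%s: conversion rate %.4f", label, conv))
    tab <- call_methylation(asg, panel, sample = label)
    list(asg = mutate(asg, sample = label), table = tab,
         conversion = tibble(sample = label, conversion_rate = conv))
  })
  table <- bind_rows(purrr::map(per_sample, "table"))
  conv <- bind_rows(purrr::map(per_sample, "conversion"))
  assignments <- bind_rows(purrr::map(per_sample, "asg"))
  report <- coverage_report(table, threshold = cfg$min_coverage)
  filtered <- filter_table(table, report)
  summaries <- summarise_amplicons(filtered)
  patterns <- pattern_matrix(assignments)
  inform(sprintf(
    "thresholds: min_q=%g min_len=%g clip=%g max_mismatch=%g min_coverage=%g",
    cfg$min_q, cfg$min_len, cfg$clip, cfg$max_mismatch, cfg$min_coverage
  ))
  out <- list(table = table, filtered = filtered, summaries = summaries,
              report = report, patterns = patterns, conversion = conv)
  roles <- purrr::map_chr(cfg$samples, ~ .x$role %||% "sample")
  ctrl <- grepl("^control:", roles)
  if (any(ctrl)) {
    expected <- setNames(as.numeric(sub("^control:", "", roles[ctrl])),
                         names(cfg$samples)[ctrl])
    grad <- control_gradient(summarise_amplicons(table), expected)
    fit <- fit_bias(grad, tolerance = cfg$bias_tolerance)
    out$bias_fit <- fit
    out$corrected <- bias_correct(filtered, fit)
    write_output(tidy(fit), cfg, "bias_model.tsv")
    write_output(out$corrected, cfg, "methylation_corrected.tsv")
  }
  write_output(table, cfg, "methylation.tsv")
  write_output(filtered, cfg, "methylation_filtered.tsv")
  write_output(summaries, cfg, "amplicon_summary.tsv")
  write_output(tidy(report), cfg, "coverage_report.tsv")
  write_output(rebalance(report), cfg, "rebalance_plan.tsv")
  write_output(as_tibble(patterns), cfg, "pattern_matrix.tsv")
  write_output(conv, cfg, "conversion_rate.tsv")
  invisible(out)
}

#' Simulate configured control samples to FASTQ
#'
#' Thin wrapper over [simulate_gradient()]: writes one FASTQ and one
#' truth TSV per (level, replicate) under the configured output
#' directory.
#'
#' @param cfg `run_config` with a `simulate` section (`levels`,
#'   `replicates`, and optional [sim_config()] fields).
#' @return tibble of written sample labels and paths, invisibly.
#' @export
simulate_cmd <- function(cfg) {
  panel <- load_config_panel(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfg$simulate %||% list()
  levels <- sim_args$levels %||% c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1)
  replicates <- sim_args$replicates %||% 1
  sim_args$levels <- NULL
  sim_args$replicates <- NULL
  if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  grad <- simulate_gradient(panel, levels = levels,
                            replicates = replicates, cfg = scfg)
  grad$fastq <- file.path(cfg$out_dir, paste0(grad$sample, ".fastq"))
  grad$truth <- file.path(cfg$out_dir, paste0(grad$sample, ".truth.tsv"))
  purrr::pwalk(list(grad$sim, grad$fastq, grad$truth), write_sim)
  invisible(select(grad, "sample", "level", "replicate", "fastq", "truth"))
}

#' Down-sampling sensitivity analysis from a configuration
#'
#' Simulates replicate control pools per configured level and runs
#' [sensitivity_test()] over the coverage grid, writing the star table.
#'
#' @param cfg `run_config` with a `sensitivity` section (`levels`,
#'   `replicates`, `depth`, `coverages`, `conversion_rate`).
#' @return the sensitivity result tibble, invisibly.
#' @export
sensitivity_cmd <- function(cfg) {
  panel <- load_config_panel(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- cfg$sensitivity %||% list()
  replicates <- s$replicates %||% 3
  if (replicates < 2) abort("sensitivity analysis needs >= 2 replicates")
  pools <- sensitivity_pools(
    panel = panel,
    levels = s$levels %||% c(0, 0.01, 0.05),
    replicates = replicates,
    depth = s$depth %||% 10000,
    conversion_rate = s$conversion_rate %||% 0.995,
    seed = cfg$seed
  )
  res <- sensitivity_test(
    pools, baseline = s$baseline %||% 0,
    coverages = s$coverages %||% c(100, 1000, 10000, 100000),
    seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1L
  )
  write_output(res, cfg, "sensitivity.tsv")
  invisible(res)
}

#' Export per-CpG betas as bedGraph
#'
#' @param table methylation table (one sample).
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(table, path) {
  cpg <- filter(table, !is.na(.data$beta))
  if (!"chrom" %in% names(cpg)) cpg$chrom <- "."
  gr <- GenomicRanges::GRanges(
    seqnames = cpg$chrom,
    ranges = IRanges::IRanges(start = cpg$genomic_pos + 1L, width = 1L),
    score = cpg$beta
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
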