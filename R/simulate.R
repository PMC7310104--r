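#' Simulation configuration for synthetic bisulphite amplicon reads
#'
#' Collects every knob of the read simulator with defaults reflecting a
#' well-behaved multiplex bisulphite PCR run: near-complete bisulphite
#' conversion (0.995), no inappropriate conversion of methylated
#' cytosines, a conventional per-base substitution error rate of 0.001,
#' negative-binomial per-amplicon coverage (dispersion 0.2, emulating the
#' uneven coverage of real multiplex panels) and no PCR bias.
#'
#' @param level methylation level in `[0,1]` (fraction of methylated
#'   molecules under `mode = "all_or_none"`, per-CpG Bernoulli probability
#'   under `mode = "per_cpg"`).
#' @param mode molecule methylation model: `"all_or_none"` (each molecule
#'   is fully methylated with probability `level`), `"per_cpg"`
#'   (independent Bernoulli per CpG, mosaic patterns), or `"pattern"`
#'   (explicit distribution given via `pattern_probs`).
#' @param pattern_probs named numeric vector, names are C/T pattern
#'   strings, values are probabilities summing to 1 (mode `"pattern"`).
#' @param conversion_rate probability an unmethylated cytosine converts
#'   and reads as T.
#' @param inappropriate probability a methylated cytosine reads as T.
#' @param seq_error per-base substitution probability.
#' @param mean_coverage mean reads per amplicon.
#' @param dispersion negative-binomial dispersion of coverage (variance =
#'   mu + mu^2 * dispersion); `0` gives exact `mean_coverage` reads.
#' @param bias PCR bias coefficient `b > 0`, scalar or named per-amplicon
#'   vector; molecules are sampled for sequencing with weight `b^f` where
#'   `f` is the molecule's methylated-CpG fraction, so for all-or-none
#'   methylation at level `E` the expected observed methylated-read
#'   fraction is `bE / (1 + (b - 1)E)`.
#' @param strand_mix fraction of reads emitted from the original-top (OT)
#'   strand.
#' @param quality quality-string model: `list(model = "constant", q = 40)`
#'   or `list(model = "degraded", q = 40, degrade_prob, tail, tail_q)`
#'   where a read's last `tail` bases drop to `tail_q` with probability
#'   `degrade_prob` (exercises quality trimming).
#' @param seed optional RNG seed; a fixed seed makes simulated FASTQ and
#'   truth files byte-identical across runs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(level = 0, mode = c("all_or_none", "per_cpg", "pattern"),
                       pattern_probs = NULL, conversion_rate = 0.995,
                       inappropriate = 0, seq_error = 0.001,
                       mean_coverage = 1000, dispersion = 0.2, bias = 1,
                       strand_mix = 1, quality = list(model = "constant", q = 40),
                       seed = NULL) {
  mode <- match.arg(mode)
  probs <- c(level = level, conversion_rate = conversion_rate,
             inappropriate = inappropriate, seq_error = seq_error,
             strand_mix = strand_mix)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (any(bias <= 0)) abort("bias coefficient b must be > 0")
  if (mode == "pattern") {
    if (is.null(pattern_probs) ||
        abs(sum(pattern_probs) - 1) > 1e-9) {
      abort("pattern_probs must be a named vector summing to 1")
    }
  }
  structure(
    list(level = level, mode = mode, pattern_probs = pattern_probs,
         conversion_rate = conversion_rate, inappropriate = inappropriate,
         seq_error = seq_error, mean_coverage = mean_coverage,
         dispersion = dispersion, bias = bias, strand_mix = strand_mix,
         quality = quality, seed = seed),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [sim_config()].
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# Draw molecule methylation states: integer matrix n x K, 1 = methylated.
draw_molecules <- function(n, n_cpg, cfg) {
  if (n_cpg == 0) return(matrix(0L, n, 0))
  switch(cfg$mode,
    all_or_none = {
      m <- rbinom(n, 1L, cfg$level)
      matrix(rep(m, n_cpg), n, n_cpg)
    },
    per_cpg = matrix(rbinom(n * n_cpg, 1L, cfg$level), n, n_cpg),
    pattern = {
      pats <- names(cfg$pattern_probs)
      if (any(nchar(pats) != n_cpg)) {
        abort("pattern strings must have one symbol per CpG")
      }
      pick <- sample(length(pats), n, replace = TRUE,
                     prob = cfg$pattern_probs)
      do.call(rbind, lapply(strsplit(pats, NULL), function(p) {
        as.integer(p == "C")
      }))[pick, , drop = FALSE]
    }
  )
}

# Composition-dependent PCR sampling: weight b^f, f = methylated fraction.
pcr_sample <- function(mol, b) {
  n <- nrow(mol)
  if (n == 0 || b == 1) return(seq_len(n))
  f <- if (ncol(mol) == 0) rep(0, n) else rowMeans(mol)
  sample.int(n, n, replace = TRUE, prob = b^f)
}

# Apparent per-CpG calls after bisulphite conversion: methylated reads C
# with prob 1 - inappropriate, unmethylated reads C with prob
# 1 - conversion_rate. Returns list(calls, n_conv) where n_conv counts
# CpG C->T conversion events per read.
convert_cpgs <- function(mol, cfg) {
  n <- nrow(mol); k <- ncol(mol)
  if (k == 0) return(list(calls = mol, n_conv = integer(n)))
  p_c <- ifelse(mol == 1L, 1 - cfg$inappropriate, 1 - cfg$conversion_rate)
  calls <- matrix(rbinom(n * k, 1L, as.vector(p_c)), n, k)
  list(calls = calls, n_conv = as.integer(rowSums(calls == 0L)))
}

#' Simulate per-read CpG methylation calls for one amplicon
#'
#' The call-level core of the simulator: molecule methylation states,
#' composition-dependent PCR sampling (weight `b^f`) and bisulphite
#' conversion, without rendering read sequences. With no sequencing error
#' the full FASTQ pipeline recovers exactly these calls, so this is the
#' workhorse for deep-coverage power and calibration experiments.
#'
#' @param n number of reads.
#' @param n_cpg number of CpG sites.
#' @param level,mode,pattern_probs,conversion_rate,inappropriate,bias as in
#'   [sim_config()].
#' @param seed optional RNG seed.
#' @return integer matrix `n x n_cpg` of apparent calls (1 = read C,
#'   methylated; 0 = read T) with attribute `"molecule"` holding the
#'   pre-conversion methylation states of the sampled molecules.
#' @export
simulate_calls <- function(n, n_cpg, level, mode = "all_or_none",
                           pattern_probs = NULL, conversion_rate = 0.995,
                           inappropriate = 0, bias = 1, seed = NULL) {
  cfg <- sim_config(level = level, mode = mode, pattern_probs = pattern_probs,
                    conversion_rate = conversion_rate,
                    inappropriate = inappropriate, bias = bias,
                    mean_coverage = n)
  with_seed_if(seed, {
    mol <- draw_molecules(n, n_cpg, cfg)
    mol <- mol[pcr_sample(mol, bias), , drop = FALSE]
    cc <- convert_cpgs(mol, cfg)
    structure(cc$calls, molecule = mol)
  })
}

calls_to_pattern <- function(calls) {
  if (ncol(calls) == 0) return(rep("", nrow(calls)))
  apply(calls, 1, function(r) paste(ifelse(r == 1L, "C", "T"), collapse = ""))
}

#' Simulate a FASTQ read set with known methylation truth
#'
#' For each amplicon, draws a negative-binomial number of molecules,
#' assigns each a methylation pattern, applies composition-dependent PCR
#' bias, bisulphite-converts, renders full-insert reads on the OT and/or
#' OB strand with sequencing errors and quality strings, and records a
#' per-read ground-truth table. Deterministic under `cfg$seed`.
#'
#' Degenerate `Y`/`R` reference bases (primer-synthesised CpG positions)
#' are emitted as their converted representative (`Y` as T, `R` as G).
#'
#' @param panel a [bs_panel].
#' @param cfg a [sim_config()].
#' @param sample sample label used in read ids.
#' @return list of class `bs_sim` with elements `reads` (tibble `id`,
#'   `seq`, `qual`) and `truth` (tibble `read_id`, `amplicon_id`, `strand`,
#'   `pattern` (pre-conversion molecule pattern over all CpGs),
#'   `apparent` (post-conversion calls), `n_conversion_events`,
#'   `n_error_events`).
#' @export
simulate_reads <- function(panel, cfg = sim_config(), sample = "sample1") {
  stopifnot(inherits(panel, "bs_panel"))
  if (nrow(panel$amplicons) == 0) abort("panel has no amplicons")
  if (cfg$mean_coverage <= 0) abort("mean coverage must be > 0")
  with_seed_if(cfg$seed, {
    per_amp <- purrr::pmap(
      list(panel$amplicons$id, panel$amplicons$ref_seq,
           panel$amplicons$cpg_offsets),
      function(id, ref, off) simulate_amplicon(id, ref, off, cfg, sample)
    )
    reads <- bind_rows(purrr::map(per_amp, "reads"))
    truth <- bind_rows(purrr::map(per_amp, "truth"))
    structure(list(reads = reads, truth = truth, sample = sample),
              class = "bs_sim")
  })
}

simulate_amplicon <- function(id, ref, off, cfg, sample) {
  n_cpg <- length(off)
  n <- if (cfg$dispersion > 0) {
    rnbinom(1, mu = cfg$mean_coverage, size = 1 / cfg$dispersion)
  } else {
    as.integer(round(cfg$mean_coverage))
  }
  empty <- list(
    reads = tibble(id = character(), seq = character(), qual = character()),
    truth = tibble(read_id = character(), amplicon_id = character(),
                   strand = character(), pattern = character(),
                   apparent = character(), n_conversion_events = integer(),
                   n_error_events = integer())
  )
  if (n == 0) return(empty)
  b <- if (length(cfg$bias) > 1) cfg$bias[[id]] else cfg$bias
  mol <- draw_molecules(n, n_cpg, cfg)
  mol <- mol[pcr_sample(mol, b), , drop = FALSE]
  cc <- convert_cpgs(mol, cfg)
  strand <- ifelse(runif(n) < cfg$strand_mix, "OT", "OB")
  out_seq <- character(n)
  n_conv_noncpg <- integer(n)
  n_err <- integer(n)
  for (st in c("OT", "OB")) {
    sel <- which(strand == st)
    if (length(sel) == 0) next
    r <- render_reads(ref, off, cc$calls[sel, , drop = FALSE], st, cfg)
    out_seq[sel] <- r$seqs
    n_conv_noncpg[sel] <- r$n_conv
    n_err[sel] <- r$n_err
  }
  ids <- sprintf("%s|%s|%s|%06d", sample, id, strand, seq_len(n))
  qual <- render_quality(nchar(out_seq), cfg)
  list(
    reads = tibble(id = ids, seq = out_seq, qual = qual),
    truth = tibble(
      read_id = ids, amplicon_id = id, strand = strand,
      pattern = calls_to_pattern(mol),
      apparent = calls_to_pattern(cc$calls),
      n_conversion_events = cc$n_conv + n_conv_noncpg,
      n_error_events = n_err
    )
  )
}

# Render n reads of one amplicon/strand as character sequences.
render_reads <- function(ref, off, calls, strand, cfg) {
  n <- nrow(calls)
  tpl <- s2c(ref)
  len <- length(tpl)
  if (strand == "OT") {
    cpg_pos <- off + 1L
  } else {
    tpl <- rev(chartr("ACGTYRN", "TGCARYN", tpl))
    cpg_pos <- len - off - 1L  # ob-space 1-based C of each CpG
  }
  # degenerate primer bases: emit the converted representative
  tpl[tpl == "Y"] <- "T"
  tpl[tpl == "R"] <- "G"
  conv_pos <- setdiff(which(tpl == "C"), cpg_pos)
  mat <- matrix(tpl, nrow = len, ncol = n)
  if (length(cpg_pos) > 0 && n > 0) {
    mat[cpg_pos, ] <- ifelse(t(calls) == 1L, "C", "T")
  }
  n_conv <- integer(n)
  if (length(conv_pos) > 0) {
    conv <- matrix(rbinom(length(conv_pos) * n, 1L, cfg$conversion_rate),
                   nrow = length(conv_pos))
    mat[conv_pos, ][conv == 1L] <- "T"
    n_conv <- as.integer(colSums(conv))
  }
  n_err <- integer(n)
  if (cfg$seq_error > 0) {
    hit <- which(runif(len * n) < cfg$seq_error)
    if (length(hit) > 0) {
      bases <- c("A", "C", "G", "T")
      cur <- mat[hit]
      alt <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                    character(1))
      mat[hit] <- alt
      n_err <- as.integer(tabulate(((hit - 1L) %/% len) + 1L, nbins = n))
    }
  }
  list(seqs = apply(mat, 2, paste, collapse = ""), n_conv = n_conv,
       n_err = n_err)
}

render_quality <- function(lens, cfg) {
  q <- cfg$quality
  good <- intToUtf8(q$q + 33L)
  base <- strrep(good, lens)
  if (identical(q$model, "degraded") && q$degrade_prob > 0) {
    bad <- intToUtf8(q$tail_q + 33L)
    hit <- which(runif(length(lens)) < q$degrade_prob)
    tail_len <- pmin(q$tail, lens[hit])
    base[hit] <- paste0(strrep(good, lens[hit] - tail_len),
                        strrep(bad, tail_len))
  }
  base
}

#' Write a simulation to FASTQ plus a truth TSV
#'
#' @param sim a `bs_sim` from [simulate_reads()].
#' @param fastq_path,truth_path output paths.
#' @return `sim`, invisibly.
#' @export
write_sim <- function(sim, fastq_path, truth_path) {
  stopifnot(inherits(sim, "bs_sim"))
  write_fastq(sim$reads, fastq_path)
  readr::write_tsv(
    select(sim$truth, read_id = "read_id", amplicon_id = "amplicon_id",
           strand = "strand", pattern = "pattern",
           n_conversion_events = "n_conversion_events",
           n_error_events = "n_error_events"),
    truth_path
  )
  invisible(sim)
}

#' Simulate a methylated-control gradient
#'
#' One simulated sample per (level, replicate), sharing the panel and every
#' configuration knob except the methylation level — the in-silico analogue
#' of running mixtures of fully methylated and unmethylated control DNA
#' (e.g. the 0/10/25/50/75/90/100% bias-calibration ladder, or the 0/1/5%
#' sensitivity gradient) across replicate sequencing runs.
#'
#' @param panel a [bs_panel].
#' @param levels expected methylation fractions in `[0,1]`.
#' @param replicates replicates per level.
#' @param cfg base [sim_config()]; its `level` is overridden, and when a
#'   seed is set each sample receives a distinct seed derived from it.
#' @return tibble with columns `sample`, `level`, `replicate`, `sim`
#'   (list-column of `bs_sim`).
#' @export
simulate_gradient <- function(panel, levels, replicates = 1,
                              cfg = sim_config()) {
  if (length(levels) == 0) abort("empty level list")
  if (any(levels < 0 | levels > 1)) abort("levels must lie in [0, 1]")
  grid <- tidyr::expand_grid(level = levels,
                             replicate = seq_len(replicates))
  grid$sample <- sprintf("ctrl%gpct_rep%d", grid$level * 100,
                         grid$replicate)
  grid$sim <- purrr::pmap(
    list(grid$level, grid$replicate, grid$sample, seq_len(nrow(grid))),
    function(lv, rep, lab, i) {
      c2 <- cfg
      c2$level <- lv
      if (!is.null(cfg$seed)) c2$seed <- cfg$seed + i
      simulate_reads(panel, c2, sample = lab)
    }
  )
  select(grid, "sample", "level", "replicate", "sim")
}
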