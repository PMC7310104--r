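#' Quality-trim reads
#'
#' Reproduces the standard amplicon preprocessing rule: clip a fixed
#' number of bases from both ends, then trim from the 3' end while the
#' terminal base quality is below `min_q`, and discard reads shorter than
#' `min_len`. Discarding is an outcome, not an error: discarded reads are
#' simply absent from the result (their count is attached as attribute
#' `n_discarded` and reported via a message).
#'
#' Note the end-clip is a one-shot operation on raw reads; the quality
#' trim and length filter alone are idempotent.
#'
#' @param reads tibble with `id`, `seq`, `qual` (see [read_fastq()]).
#' @param min_q minimum terminal base quality (default 30).
#' @param min_len minimum retained read length (default 20; reads of
#'   exactly `min_len` are kept).
#' @param clip bases clipped from each end before quality trimming
#'   (default 1).
#' @return trimmed read tibble (kept reads only).
#' @export
trim_reads <- function(reads, min_q = 30, min_len = 20, clip = 1) {
  if (nrow(reads) == 0) return(reads)
  trimmed <- purrr::map2(reads$seq, reads$qual, function(seq, qual) {
    q <- phred_to_int(qual)
    len <- length(q)
    lo <- clip + 1L
    hi <- len - clip
    if (hi < lo) return(NULL)
    q <- q[lo:hi]
    keep <- which(q >= min_q)
    last <- if (length(keep) == 0) 0L else max(keep)
    if (last < min_len) return(NULL)
    c(substr(seq, lo, lo + last - 1L), substr(qual, lo, lo + last - 1L))
  })
  kept <- !purrr::map_lgl(trimmed, is.null)
  n_disc <- sum(!kept)
  if (n_disc > 0) {
    inform(sprintf("trim_reads: discarded %d of %d reads", n_disc,
                   nrow(reads)))
  }
  out <- tibble(
    id = reads$id[kept],
    seq = purrr::map_chr(trimmed[kept], 1),
    qual = purrr::map_chr(trimmed[kept], 2)
  )
  attr(out, "n_discarded") <- n_disc
  out
}

# Compare read characters against a matching-space reference window.
# Ambiguity classes: Y matches C/T (bisulphite C context), R matches G/A,
# N in the reference matches anything. Everything else must be identical.
n_mismatch_at <- function(win, rd) {
  sum(!(win == rd |
          (win == "Y" & (rd == "C" | rd == "T")) |
          (win == "R" & (rd == "G" | rd == "A")) |
          win == "N"))
}

#' Assign reads to panel amplicons with bisulphite-aware matching
#'
#' Each read is aligned ungapped at every feasible offset against both
#' bisulphite strands of every amplicon. A read T over a reference
#' cytosine class (or A over a guanine class on the OB strand) is a
#' bisulphite conversion event, never a mismatch; a retained read C over a
#' reference cytosine is likewise a match (it is informative for the
#' conversion-rate estimate). The placement with the fewest remaining
#' non-bisulphite mismatches wins; reads are `UNASSIGNED` when the best
#' placement exceeds `max_mismatch` and `AMBIGUOUS` when distinct
#' amplicons tie (ties within one amplicon resolve deterministically to
#' the lowest offset, OT before OB).
#'
#' The methylation pattern is extracted at the amplicon's callable CpG
#' sites: read C = methylated (`C`), read T = unmethylated (`T`), anything
#' else (including CpGs outside the read) = `N`. OB-strand reads are
#' reverse-complemented into forward orientation first, so their G/A
#' states map onto the same convention.
#'
#' @param reads trimmed read tibble (`id`, `seq`, `qual`).
#' @param panel a [bs_panel].
#' @param max_mismatch maximum non-bisulphite mismatches (default 1).
#' @return tibble with one row per read: `read_id`, `amplicon` (id or
#'   `"UNASSIGNED"`/`"AMBIGUOUS"`), `strand`, `offset` (0-based placement
#'   on the reference), `n_mismatch`, `pattern`, and the per-read
#'   conversion-rate evidence `n_conv` / `n_ret` (converted / retained
#'   non-CpG cytosine positions).
#' @export
assign_reads <- function(reads, panel, max_mismatch = 1) {
  stopifnot(inherits(panel, "bs_panel"))
  if (nrow(panel$amplicons) == 0) abort("panel has no amplicons")
  ms <- match_space(panel)
  rows <- purrr::pmap(list(reads$id, reads$seq), function(id, seq) {
    assign_one(id, seq, ms, max_mismatch)
  })
  bind_rows(rows)
}

assign_one <- function(id, seq, ms, max_mismatch) {
  rd_fwd <- s2c(seq)
  rd_rev <- rev(chartr("ACGT", "TGCA", rd_fwd))
  m <- length(rd_fwd)
  best <- NULL   # list(amp, strand, offset, mm)
  best_amps <- character(0)
  for (a in ms) {
    if (m > a$len) next
    offsets <- 0:(a$len - m)
    for (st in c("OT", "OB")) {
      ref <- if (st == "OT") a$ot else a$ob
      rd <- if (st == "OT") rd_fwd else rd_rev
      for (o in offsets) {
        mm <- n_mismatch_at(ref[(o + 1L):(o + m)], rd)
        if (is.null(best) || mm < best$mm) {
          best <- list(amp = a$id, strand = st, offset = o, mm = mm)
          best_amps <- a$id
        } else if (mm == best$mm) {
          best_amps <- union(best_amps, a$id)
        }
      }
    }
  }
  na_row <- function(status) {
    tibble(read_id = id, amplicon = status, strand = NA_character_,
           offset = NA_integer_, n_mismatch = NA_integer_,
           pattern = NA_character_, n_conv = NA_integer_,
           n_ret = NA_integer_)
  }
  if (is.null(best) || best$mm > max_mismatch) return(na_row("UNASSIGNED"))
  if (length(best_amps) > 1) return(na_row("AMBIGUOUS"))
  a <- ms[[which(purrr::map_chr(ms, "id") == best$amp)]]
  rd <- if (best$strand == "OT") rd_fwd else rd_rev
  span <- (best$offset + 1L):(best$offset + m)
  # methylation readout at callable CpG sites
  cpg <- if (best$strand == "OT") a$cpg_c else a$cpg_g
  meth_sym <- if (best$strand == "OT") "C" else "G"
  unmeth_sym <- if (best$strand == "OT") "T" else "A"
  call1 <- function(pos) {
    j <- pos - best$offset
    if (j < 1L || j > m) return("N")
    b <- rd[j]
    if (b == meth_sym) "C" else if (b == unmeth_sym) "T" else "N"
  }
  pattern <- paste(vapply(cpg[a$callable], call1, character(1)),
                   collapse = "")
  # non-CpG cytosine evidence for the conversion rate
  conv_pos <- if (best$strand == "OT") a$conv_ot else a$conv_ob
  conv_pos <- conv_pos[conv_pos %in% span]
  j <- conv_pos - best$offset
  n_conv <- sum(rd[j] == unmeth_sym)
  n_ret <- sum(rd[j] == meth_sym)
  tibble(read_id = id, amplicon = best$amp, strand = best$strand,
         offset = best$offset, n_mismatch = best$mm, pattern = pattern,
         n_conv = as.integer(n_conv), n_ret = as.integer(n_ret))
}

#' Per-CpG methylation table from read assignments
#'
#' Counts, per callable CpG site, the reads calling it methylated (`C`)
#' and unmethylated (`T`); `N` calls contribute to neither. Coverage is
#' the number of assigned reads per amplicon. Amplicons with no assigned
#' reads appear with coverage 0 and undefined betas.
#'
#' @param assignments tibble from [assign_reads()] (one sample).
#' @param panel a [bs_panel].
#' @param sample sample label.
#' @return tibble with one row per (sample, amplicon, callable CpG):
#'   `sample`, `amplicon`, `cpg_offset`, `genomic_pos` (0-based),
#'   `coverage`, `meth`, `unmeth`, `beta`.
#' @export
call_methylation <- function(assignments, panel, sample = "sample1") {
  stopifnot(inherits(panel, "bs_panel"))
  cpgs <- panel_cpgs(panel) |> filter(.data$callable)
  asg <- filter(assignments,
                !.data$amplicon %in% c("UNASSIGNED", "AMBIGUOUS"))
  cov <- asg |> count(.data$amplicon, name = "coverage")
  counts <- purrr::map(split(asg, asg$amplicon), function(d) {
    k <- nchar(d$pattern[1])
    if (k == 0) return(NULL)
    mat <- matrix(unlist(strsplit(d$pattern, NULL)), ncol = k, byrow = TRUE)
    tibble(
      amplicon = d$amplicon[1],
      cpg_index = seq_len(k),
      meth = as.integer(colSums(mat == "C")),
      unmeth = as.integer(colSums(mat == "T"))
    )
  }) |> bind_rows()
  if (nrow(counts) == 0) {
    counts <- tibble(amplicon = character(), cpg_index = integer(),
                     meth = integer(), unmeth = integer())
  }
  cpgs <- cpgs |>
    group_by(.data$amplicon) |>
    mutate(cpg_index = dplyr::row_number()) |>
    ungroup()
  out <- cpgs |>
    left_join(counts, by = c("amplicon", "cpg_index")) |>
    left_join(cov, by = "amplicon") |>
    mutate(
      sample = sample,
      coverage = dplyr::coalesce(.data$coverage, 0L),
      meth = dplyr::coalesce(.data$meth, 0L),
      unmeth = dplyr::coalesce(.data$unmeth, 0L),
      beta = if_else(.data$meth + .data$unmeth > 0,
                     .data$meth / (.data$meth + .data$unmeth),
                     NA_real_)
    ) |>
    select("sample", "amplicon", "chrom", "cpg_offset", "genomic_pos",
           "coverage", "meth", "unmeth", "beta")
  out
}

#' Summarise a methylation table per amplicon
#'
#' A single methylation value per (sample, amplicon): the unweighted mean
#' of per-CpG betas across the amplicon's callable CpG sites.
#'
#' @param table a methylation table from [call_methylation()] (or several
#'   samples' tables bound together).
#' @return tibble `sample`, `amplicon`, `coverage`, `n_cpg`,
#'   `amplicon_beta`.
#' @export
summarise_amplicons <- function(table) {
  table |>
    group_by(.data$sample, .data$amplicon) |>
    summarise(
      coverage = first(.data$coverage),
      n_cpg = n(),
      amplicon_beta = mean(.data$beta, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(amplicon_beta = if_else(is.nan(.data$amplicon_beta), NA_real_,
                                   .data$amplicon_beta))
}

#' Estimate the bisulphite conversion rate
#'
#' Non-conversion of non-CpG cytosines estimates the conversion rate:
#' over all assigned reads, the fraction of non-CpG reference-cytosine
#' positions read as T among those read as C or T (OB-strand reads use
#' guanine positions symmetrically). The per-read evidence is gathered at
#' assignment time.
#'
#' @param assignments tibble from [assign_reads()].
#' @return conversion-rate estimate in `[0,1]`, or `NA` (with a warning)
#'   when no informative positions exist.
#' @export
conversion_rate <- function(assignments) {
  asg <- filter(assignments,
                !.data$amplicon %in% c("UNASSIGNED", "AMBIGUOUS"))
  tot <- sum(asg$n_conv, na.rm = TRUE) + sum(asg$n_ret, na.rm = TRUE)
  if (tot == 0) {
    warn("no informative non-CpG cytosine positions; conversion rate NA")
    return(NA_real_)
  }
  sum(asg$n_conv, na.rm = TRUE) / tot
}
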