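#' Construct an amplicon panel
#'
#' A panel is the definition of a targeted multiplex bisulphite PCR assay:
#' one row per amplicon with its genomic interval, reference (insert)
#' sequence, primer geometry and the offsets of every CpG dinucleotide.
#' CpGs whose cytosine falls inside a primer are retained but flagged
#' non-callable: primer bases are synthetic (CpG cytosines in primers are
#' ordered as Y/R degenerate bases) and do not report genomic methylation.
#'
#' @param amplicons a data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `ref_seq` (uppercase DNA over `A,C,G,T,N,Y,R`),
#'   `fwd_primer_len`, `rev_primer_len`.
#' @param name panel label.
#' @param genome_build genome build label (metadata only; default `"hg19"`,
#'   no genome is ever downloaded).
#' @return an object of class `bs_panel`: a list with `name`,
#'   `genome_build` and an `amplicons` tibble carrying list-columns
#'   `cpg_offsets` (0-based offset of each CpG cytosine in `ref_seq`) and
#'   `callable` (logical per CpG, FALSE for primer-overlapped sites).
#' @export
#' @examples
#' bs_panel(tibble::tibble(
#'   id = "amp1", chrom = "chr1", start = 100, end = 112,
#'   ref_seq = "ATCGGTACGTTA", fwd_primer_len = 0, rev_primer_len = 0
#' ))
bs_panel <- function(amplicons, name = "panel", genome_build = "hg19") {
  amp <- as_tibble(amplicons)
  needed <- c("id", "chrom", "start", "end", "ref_seq")
  missing_cols <- setdiff(needed, names(amp))
  if (length(missing_cols) > 0) {
    abort(paste0("panel definition lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"fwd_primer_len" %in% names(amp)) amp$fwd_primer_len <- 0L
  if (!"rev_primer_len" %in% names(amp)) amp$rev_primer_len <- 0L
  amp <- amp |>
    mutate(
      id = as.character(.data$id),
      chrom = as.character(.data$chrom),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      ref_seq = toupper(as.character(.data$ref_seq)),
      fwd_primer_len = as.integer(.data$fwd_primer_len),
      rev_primer_len = as.integer(.data$rev_primer_len)
    )
  if (anyDuplicated(amp$id)) {
    abort(paste0("duplicated amplicon id(s): ",
                 paste(unique(amp$id[duplicated(amp$id)]), collapse = ", ")))
  }
  bad_alpha <- stringr::str_detect(amp$ref_seq, "[^ACGTNYR]")
  if (any(bad_alpha)) {
    abort(paste0("non-DNA characters in reference of amplicon(s): ",
                 paste(amp$id[bad_alpha], collapse = ", ")))
  }
  bad_len <- (amp$end - amp$start) != nchar(amp$ref_seq)
  if (any(bad_len)) {
    abort(paste0("interval length != reference length for amplicon(s): ",
                 paste(amp$id[bad_len], collapse = ", ")))
  }
  amp <- select(amp, "id", "chrom", "start", "end", "ref_seq",
                "fwd_primer_len", "rev_primer_len")
  amp$cpg_offsets <- purrr::map(amp$ref_seq, find_cpgs)
  amp$callable <- purrr::pmap(
    list(amp$cpg_offsets, amp$fwd_primer_len, amp$rev_primer_len,
         nchar(amp$ref_seq)),
    function(off, fwd, rev, len) off >= fwd & off < (len - rev)
  )
  structure(
    list(name = name, genome_build = genome_build, amplicons = amp),
    class = "bs_panel"
  )
}

# 0-based offsets of the C of every literal "CG"; degenerate Y/R bases
# never define a CpG.
find_cpgs <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' @export
print.bs_panel <- function(x, ...) {
  n_cpg <- sum(lengths(x$amplicons$cpg_offsets))
  n_call <- sum(unlist(x$amplicons$callable))
  cat(sprintf(
    "<bs_panel '%s'> %d amplicons, %d CpG sites (%d callable), build %s\n",
    x$name, nrow(x$amplicons), n_cpg, n_call, x$genome_build
  ))
  print(select(x$amplicons, -"ref_seq"), ...)
  invisible(x)
}

#' Load a panel from BED intervals plus an amplicon reference FASTA
#'
#' BED names must match FASTA record ids one-to-one, and each FASTA
#' sequence is the amplicon reference (primer-to-primer insert). Amplicon
#' order follows the BED file.
#'
#' @param bed_path BED4 file (chrom, start, end, name).
#' @param fasta_path FASTA of amplicon reference sequences keyed by the BED
#'   name column.
#' @param primer_spec either a single integer applied to both primers of
#'   every amplicon, a length-2 vector `c(fwd, rev)`, or a data frame with
#'   columns `id`, `fwd_primer_len`, `rev_primer_len`.
#' @inheritParams bs_panel
#' @return a [bs_panel] object.
#' @export
load_panel <- function(bed_path, fasta_path, primer_spec = 0L,
                       name = "panel", genome_build = "hg19") {
  gr <- rtracklayer::import(bed_path, format = "bed")
  ids <- as.character(gr$name)
  # BStringSet keeps the raw characters so alphabet validation (and its
  # error message) happens in one place, in bs_panel()
  fa <- Biostrings::readBStringSet(fasta_path)
  miss <- setdiff(ids, names(fa))
  extra <- setdiff(names(fa), ids)
  if (length(miss) > 0 || length(extra) > 0) {
    abort(paste0(
      "BED/FASTA id mismatch: ",
      if (length(miss)) paste0("missing from FASTA: ",
                               paste(miss, collapse = ", ")) else "",
      if (length(miss) && length(extra)) "; " else "",
      if (length(extra)) paste0("absent from BED: ",
                                paste(extra, collapse = ", ")) else ""
    ))
  }
  amp <- tibble(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    ref_seq = as.character(fa[ids])
  )
  amp <- add_primer_spec(amp, primer_spec)
  bs_panel(amp, name = name, genome_build = genome_build)
}

add_primer_spec <- function(amp, primer_spec) {
  if (is.data.frame(primer_spec)) {
    spec <- as_tibble(primer_spec)
    amp <- left_join(amp, spec, by = "id")
    amp$fwd_primer_len[is.na(amp$fwd_primer_len)] <- 0L
    amp$rev_primer_len[is.na(amp$rev_primer_len)] <- 0L
  } else if (length(primer_spec) == 1) {
    amp$fwd_primer_len <- as.integer(primer_spec)
    amp$rev_primer_len <- as.integer(primer_spec)
  } else {
    amp$fwd_primer_len <- as.integer(primer_spec[1])
    amp$rev_primer_len <- as.integer(primer_spec[2])
  }
  amp
}

#' Load a self-contained panel TSV
#'
#' One row per amplicon with columns `id`, `chrom`, `start`, `end`,
#' `fwd_primer_len`, `rev_primer_len`, `ref_seq`. Lines beginning with `#`
#' are ignored.
#'
#' @param path TSV path.
#' @inheritParams bs_panel
#' @return a [bs_panel] object.
#' @export
load_panel_tsv <- function(path, name = "panel", genome_build = "hg19") {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  bs_panel(tbl, name = name, genome_build = genome_build)
}

#' Write a panel to BED + FASTA (or a combined TSV)
#'
#' @param panel a [bs_panel].
#' @param bed_path,fasta_path output paths for the interval/reference pair.
#' @param tsv_path optional combined-TSV output; when given, `bed_path` and
#'   `fasta_path` may be `NULL`.
#' @return the panel, invisibly.
#' @export
write_panel <- function(panel, bed_path = NULL, fasta_path = NULL,
                        tsv_path = NULL) {
  stopifnot(inherits(panel, "bs_panel"))
  amp <- panel$amplicons
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = amp$chrom,
      ranges = IRanges::IRanges(start = amp$start + 1L, end = amp$end),
      name = amp$id
    )
    rtracklayer::export(gr, bed_path, format = "bed")
  }
  if (!is.null(fasta_path)) {
    fa <- Biostrings::DNAStringSet(setNames(amp$ref_seq, amp$id))
    Biostrings::writeXStringSet(fa, fasta_path)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(
      select(amp, "id", "chrom", "start", "end",
             "fwd_primer_len", "rev_primer_len", "ref_seq"),
      tsv_path
    )
  }
  invisible(panel)
}

#' Per-CpG site table of a panel
#'
#' @param panel a [bs_panel].
#' @param one_based emit 1-based genomic coordinates (default 0-based,
#'   matching BED).
#' @return tibble with one row per CpG: `amplicon`, `cpg_offset`,
#'   `genomic_pos`, `callable`.
#' @export
panel_cpgs <- function(panel, one_based = FALSE) {
  stopifnot(inherits(panel, "bs_panel"))
  amp <- panel$amplicons
  out <- tidyr::unnest(
    tibble(
      amplicon = amp$id, chrom = amp$chrom, start = amp$start,
      cpg_offset = amp$cpg_offsets, callable = amp$callable
    ),
    c("cpg_offset", "callable")
  )
  out$genomic_pos <- out$start + out$cpg_offset + if (one_based) 1L else 0L
  select(out, "amplicon", "chrom", "cpg_offset", "genomic_pos", "callable")
}

#' Bisulphite-converted reference of an amplicon
#'
#' On the original-top (OT) strand every cytosine outside a CpG is fully
#' converted and reads as T, while CpG cytosines are ambiguous
#' (methylation-dependent, `Y` = C/T). The original-bottom (OB) strand is
#' reported in forward-reference orientation: non-CpG guanines read as A,
#' CpG guanines are ambiguous (`R` = G/A). Degenerate `Y`/`R` bases in the
#' reference stay ambiguous.
#'
#' @param panel a [bs_panel].
#' @param strand `"OT"` or `"OB"`.
#' @param amplicon optional amplicon id(s); default all.
#' @return named character vector of converted references (IUPAC codes).
#' @export
#' @examples
#' p <- bs_panel(tibble::tibble(id = "a", chrom = "c", start = 0, end = 6,
#'                              ref_seq = "ACCGAT"))
#' bis_reference(p, "OT")  # "ATYGAT"
bis_reference <- function(panel, strand = c("OT", "OB"), amplicon = NULL) {
  stopifnot(inherits(panel, "bs_panel"))
  strand <- match.arg(strand)
  amp <- panel$amplicons
  if (!is.null(amplicon)) amp <- filter(amp, .data$id %in% amplicon)
  out <- purrr::map2_chr(amp$ref_seq, amp$cpg_offsets, function(seq, off) {
    ch <- s2c(seq)
    if (strand == "OT") {
      is_cpg_c <- seq_along(ch) %in% (off + 1L)
      ch[ch == "C" & !is_cpg_c] <- "T"
      ch[ch == "C" & is_cpg_c] <- "Y"
    } else {
      is_cpg_g <- seq_along(ch) %in% (off + 2L)
      ch[ch == "G" & !is_cpg_g] <- "A"
      ch[ch == "G" & is_cpg_g] <- "R"
    }
    paste(ch, collapse = "")
  })
  setNames(out, amp$id)
}

# Internal matching-space references for read assignment. Unlike
# bis_reference(), every original C (OT) / G (OB) becomes ambiguous so a
# retained (unconverted) non-CpG cytosine is a bisulphite event, never a
# mismatch. OB is kept in forward orientation; reads are reverse
# complemented before comparison.
match_space <- function(panel) {
  amp <- panel$amplicons
  purrr::pmap(
    list(amp$id, amp$ref_seq, amp$cpg_offsets, amp$callable),
    function(id, seq, off, callable) {
      ch <- s2c(seq)
      len <- length(ch)
      ot <- ch
      ot[ot == "C"] <- "Y"
      ob <- ch
      ob[ob == "G"] <- "R"
      list(
        id = id, len = len,
        ot = ot, ob = ob,
        cpg_c = off + 1L,               # 1-based C position (OT readout)
        cpg_g = off + 2L,               # 1-based G position (OB readout)
        callable = callable,
        # informative positions for conversion-rate estimation
        conv_ot = setdiff(which(ch == "C"), off + 1L),
        conv_ob = setdiff(which(ch == "G"), off + 2L)
      )
    }
  )
}

#' Generate a synthetic amplicon panel
#'
#' Builds random amplicon references with a controlled number of CpG sites
#' per amplicon, mimicking the geometry of a real multiplex bisulphite
#' panel (inserts of 105-150 bp by default, fixed-length primers at both
#' ends). Accidental CpGs are scrubbed before the requested sites are
#' planted, so each amplicon carries exactly `n_cpg[i]` CpGs.
#'
#' @param n_amplicons number of amplicons.
#' @param n_cpg integer vector (recycled) of CpG sites per amplicon.
#' @param insert_range length-2 range of insert sizes in bp.
#' @param fwd_primer_len,rev_primer_len primer lengths in bp.
#' @param seed optional RNG seed for reproducibility.
#' @inheritParams bs_panel
#' @return a [bs_panel].
#' @export
synthetic_panel <- function(n_amplicons = 2, n_cpg = 4,
                            insert_range = c(105, 150),
                            fwd_primer_len = 20, rev_primer_len = 20,
                            seed = NULL, name = "synthetic_panel",
                            genome_build = "hg19") {
  n_cpg <- rep_len(as.integer(n_cpg), n_amplicons)
  with_seed_if(seed, {
    amp <- purrr::map(seq_len(n_amplicons), function(i) {
      len <- sample(insert_range[1]:insert_range[2], 1)
      ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3))
      # remove accidental CpGs
      repeat {
        cg <- which(ch[-len] == "C" & ch[-1] == "G")
        if (length(cg) == 0) break
        ch[cg + 1L] <- "A"
      }
      # plant CpGs at callable, non-adjacent offsets
      lo <- fwd_primer_len
      hi <- len - rev_primer_len - 2L
      pos <- sort(sample(seq(lo, hi, by = 3L), n_cpg[i]))
      ch[pos + 1L] <- "C"
      ch[pos + 2L] <- "G"
      # planting may create no new CpGs elsewhere because flanks stay as-is;
      # scrub once more in case a planted C abuts an existing G
      repeat {
        cg <- setdiff(which(ch[-len] == "C" & ch[-1] == "G"), pos + 1L)
        if (length(cg) == 0) break
        ch[cg] <- "T"
      }
      tibble(
        id = sprintf("amp%02d", i), chrom = "chrS",
        start = (i - 1L) * 1000L, end = (i - 1L) * 1000L + len,
        ref_seq = paste(ch, collapse = ""),
        fwd_primer_len = as.integer(fwd_primer_len),
        rev_primer_len = as.integer(rev_primer_len)
      )
    })
    bs_panel(bind_rows(amp), name = name, genome_build = genome_build)
  })
}
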