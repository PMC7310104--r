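# Small fixed panels and an exhaustive brute-force read scorer used as the
# independent oracle for the bisulphite-aware matcher.

tiny_panel <- function() {
  bs_panel(tibble::tibble(
    id = c("ampA", "ampB"),
    chrom = "chr1",
    start = c(100L, 500L),
    end = c(100L + 40L, 500L + 40L),
    ref_seq = c(
      #          1    6           18     (CpGs at 4, 12, 25)
      "ATTACGTTAGGTCGATTAGGATTAACCGATTAGGATTAGG",
      "TTAGGACGGATTAACGTTAGGATCGATTAGGATTAACCTT"
    ),
    fwd_primer_len = 0L,
    rev_primer_len = 0L
  ), name = "tiny")
}

random_small_panel <- function(n_amp = NULL) {
  n_amp <- n_amp %||% sample(2:5, 1)
  synthetic_panel(
    n_amplicons = n_amp, n_cpg = sample(1:4, n_amp, replace = TRUE),
    insert_range = c(40, 60), fwd_primer_len = 5, rev_primer_len = 5,
    name = "rand"
  )
}

rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTYRN", "TGCARYN", s), NULL)[[1]]),
        collapse = "")
}

# Exhaustive naive scorer: enumerates every (amplicon, strand, offset),
# counts mismatches position by position with explicit conditionals, and
# applies the same first-best / distinct-amplicon-tie rules as the
# matcher. Written independently of the package internals.
oracle_assign <- function(seq, panel, max_mismatch = 1) {
  amp <- panel$amplicons
  rd_fwd <- strsplit(seq, NULL)[[1]]
  rd_rev <- strsplit(rc_chr(seq), NULL)[[1]]
  m <- length(rd_fwd)
  base_ok <- function(ref_b, read_b, strand) {
    if (ref_b == "N") return(TRUE)
    if (strand == "OT" && (ref_b == "C" || ref_b == "Y")) {
      return(read_b == "C" || read_b == "T")
    }
    if (strand == "OB" && (ref_b == "G" || ref_b == "R")) {
      return(read_b == "G" || read_b == "A")
    }
    if (ref_b == "Y") return(read_b == "C" || read_b == "T")
    if (ref_b == "R") return(read_b == "G" || read_b == "A")
    ref_b == read_b
  }
  best_mm <- Inf
  best <- NULL
  best_amps <- character(0)
  for (i in seq_len(nrow(amp))) {
    ref <- strsplit(amp$ref_seq[i], NULL)[[1]]
    if (m > length(ref)) next
    for (strand in c("OT", "OB")) {
      rd <- if (strand == "OT") rd_fwd else rd_rev
      for (off in 0:(length(ref) - m)) {
        mm <- 0L
        for (j in seq_len(m)) {
          if (!base_ok(ref[off + j], rd[j], strand)) mm <- mm + 1L
        }
        if (mm < best_mm) {
          best_mm <- mm
          best <- list(amplicon = amp$id[i], strand = strand,
                       offset = off, n_mismatch = mm)
          best_amps <- amp$id[i]
        } else if (mm == best_mm) {
          best_amps <- union(best_amps, amp$id[i])
        }
      }
    }
  }
  if (is.null(best) || best_mm > max_mismatch) {
    return(list(amplicon = "UNASSIGNED"))
  }
  if (length(best_amps) > 1) return(list(amplicon = "AMBIGUOUS"))
  best
}

# Extract the callable-CpG sub-pattern of a truth 'apparent' pattern.
callable_pattern <- function(apparent, amplicon, panel) {
  mapply(function(p, a) {
    idx <- which(panel$amplicons$callable[[match(a, panel$amplicons$id)]])
    paste(strsplit(p, NULL)[[1]][idx], collapse = "")
  }, apparent, amplicon, USE.NAMES = FALSE)
}

read_tbl <- function(seq, qual = NULL, id = "r1") {
  qual <- qual %||% strrep("I", nchar(seq))
  tibble::tibble(id = id, seq = seq, qual = qual)
}
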