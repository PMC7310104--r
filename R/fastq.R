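#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (Sanger / Phred+33 qualities).
#' @return tibble with columns `id`, `seq`, `qual` (quality string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}
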