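## FASTQ ingestion/emission. Records travel through the package as tibbles
## with columns id, seq, qual so transformations stay pipe-friendly;
## parsing and writing are delegated to Biostrings.

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file, plain or gzip-compressed.
#' @return Tibble with columns `id` (full header after `@`), `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_data("FASTQ file not found: %s", path)
  if (file.size(path) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop_data("cannot parse FASTQ '%s': %s", path, conditionMessage(e))
  )
  tibble(
    id = as.character(names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads tibble with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual))) {
    stop_data("sequence/quality length mismatch at record %d",
      which(nchar(reads$seq) != nchar(reads$qual))[1])
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

## Fatal pairing check: equal record counts and pairwise-consistent ids
## (after stripping /1,/2 suffixes and comments). Reports the first offender.
check_paired <- function(r1, r2, label1 = "R1", label2 = "R2") {
  if (nrow(r1) != nrow(r2)) {
    stop_data(
      "%s has %d records but %s has %d; first unmatched record index: %d",
      label1, nrow(r1), label2, nrow(r2), min(nrow(r1), nrow(r2)) + 1L
    )
  }
  if (nrow(r1) == 0) {
    return(invisible(TRUE))
  }
  id1 <- normalize_read_id(r1$id)
  id2 <- normalize_read_id(r2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop_data(
      "%s/%s ids diverge at record %d ('%s' vs '%s')",
      label1, label2, bad[1], id1[bad[1]], id2[bad[1]]
    )
  }
  invisible(TRUE)
}

## Phred+33 decoding of one quality string vector -> list of integer vectors
## is avoided; per-read summary statistics are computed directly.
phred_stat <- function(qual, stat) {
  vapply(qual, function(s) {
    q <- utf8ToInt(s) - 33L
    if (length(q) == 0) {
      return(NA_real_)
    }
    if (any(q < 0 | q > 93)) stop_data("invalid Phred+33 quality string '%s'", s)
    stat(q)
  }, numeric(1), USE.NAMES = FALSE)
}
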