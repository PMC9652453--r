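## Low-level sequence utilities shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

## Fixed pad applied to barcodes shorter than 16 bp: reads and whitelists are
## padded with the same prefix of this sequence, so exact matching survives
## canonicalization.
PAD_SEQUENCE_16 <- "ACGTACGTACGTACGT"

## Placeholder linker used where a chemistry needs constant spacer bases whose
## true sequence is platform-proprietary; overridable via custom config files.
LINKER_PLACEHOLDER <- "CAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGT"

CANONICAL_BARCODE_LENGTH <- 16L
PAD_QUALITY_CHAR <- "I" # Phred 40 under Phred+33

#' All DNA k-mers in lexicographic order
#'
#' Enumerates the `4^k` sequences over A,C,G,T of length `k`, smallest first
#' ("AAA...", then "AAC...", ...). Used for permutation whitelists and for
#' rank-based surrogate barcode assignment.
#'
#' @param k k-mer length, between 1 and 16.
#' @return Character vector of length `4^k`.
#' @keywords internal
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 16)
  out <- ""
  for (i in seq_len(k)) {
    out <- paste0(rep(out, each = 4L), DNA_BASES)
  }
  out
}

#' Encode nonnegative integers as fixed-length DNA (base-4, A=0 ... T=3)
#'
#' The i-th k-mer in lexicographic order is `int_to_kmer(i - 1, k)`.
#' Vectorized over `n`; uses double arithmetic so ranks up to 4^16 are exact.
#'
#' @param n nonnegative integer ranks (0-based).
#' @param k output length in bases.
#' @keywords internal
int_to_kmer <- function(n, k) {
  n <- as.numeric(n)
  stopifnot(all(n >= 0), all(n < 4^k))
  cols <- vector("list", k)
  r <- n
  for (j in seq(k, 1L)) {
    d <- r %% 4
    cols[[j]] <- DNA_BASES[d + 1L]
    r <- (r - d) / 4
  }
  do.call(paste0, cols)
}

#' @rdname int_to_kmer
#' @param kmer character vector of equal-length DNA strings.
#' @keywords internal
kmer_to_int <- function(kmer) {
  k <- unique(nchar(kmer))
  stopifnot(length(k) == 1)
  m <- matrix(match(unlist(strsplit(kmer, "", fixed = TRUE)), DNA_BASES) - 1,
    ncol = k, byrow = TRUE
  )
  as.numeric(m %*% 4^((k - 1):0))
}

#' Random DNA sequences
#'
#' @param n number of sequences.
#' @param width length of each sequence in bases.
#' @keywords internal
random_dna <- function(n, width) {
  if (n == 0) {
    return(character())
  }
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(width), function(j) m[, j]))
}

## Distinct random DNA sequences; retries until n unique draws are collected.
random_dna_distinct <- function(n, width) {
  stopifnot(n <= 4^width)
  out <- unique(random_dna(n, width))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), width)))
  }
  out
}

#' Strip pair suffixes and comments from a read identifier
#'
#' `"r1/1"` and `"r1 2:N:0:ACGT"` both normalize to `"r1"`, so mates can be
#' compared for lockstep pairing.
#' @keywords internal
normalize_read_id <- function(id) {
  sub("/[123]$", "", sub("\\s.*$", "", id))
}

pad_to <- function(x, width, pad_char) {
  short <- nchar(x) < width
  x[short] <- paste0(x[short], strrep(pad_char, width - nchar(x[short])))
  x
}

## error with class so the CLI can map data errors to exit code 1
stop_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scunify_data_error")
}

stop_usage <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scunify_usage_error")
}
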