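## Barcode whitelists: loading, permutation generation, recoding to the
## canonical 16 bp space, and emission.

#' Construct a validated whitelist
#'
#' @param barcodes character vector of barcodes over A/C/G/T, all the same
#'   length, no duplicates.
#' @param source provenance: `"file"` or `"permutations"`.
#' @return An `sc_whitelist` object (list with `barcodes`, `native_length`,
#'   `source`).
#' @export
new_whitelist <- function(barcodes, source = "file") {
  if (length(barcodes) == 0) stop_data("empty whitelist is unusable")
  lens <- unique(nchar(barcodes))
  if (length(lens) != 1) {
    stop_data(
      "whitelist barcodes have mixed lengths: %s",
      paste(sort(lens), collapse = ", ")
    )
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    bad <- barcodes[grepl("[^ACGT]", barcodes)][1]
    stop_data("whitelist barcode '%s' contains characters outside A/C/G/T", bad)
  }
  if (anyDuplicated(barcodes)) {
    stop_data(
      "duplicate whitelist barcode: %s",
      barcodes[duplicated(barcodes)][1]
    )
  }
  structure(
    list(
      barcodes = barcodes, native_length = lens,
      source = match.arg(source, c("file", "permutations"))
    ),
    class = "sc_whitelist"
  )
}

#' @export
print.sc_whitelist <- function(x, ...) {
  cat(sprintf(
    "<sc_whitelist> %d barcodes of %d bp (source: %s)\n",
    length(x$barcodes), x$native_length, x$source
  ))
  invisible(x)
}

#' Load a barcode whitelist from a one-barcode-per-line file
#'
#' Lines are upper-cased; blank lines are ignored. Mixed lengths, duplicate
#' barcodes, or characters outside A/C/G/T (including N, which is disallowed
#' in whitelists) are fatal.
#'
#' @param path text file, one barcode per line (optionally gzipped).
#' @param config optional `tech_config`; if given, the barcode length must
#'   equal the config's `barcode_total_length`.
#' @return An `sc_whitelist`.
#' @export
load_whitelist <- function(path, config = NULL) {
  if (!file.exists(path)) stop_data("whitelist file not found: %s", path)
  lines <- toupper(trimws(readr::read_lines(path)))
  lines <- lines[nzchar(lines)]
  wl <- new_whitelist(lines, source = "file")
  if (!is.null(config) && wl$native_length != config$barcode_total_length) {
    stop_data(
      "whitelist barcodes are %d bp but config '%s' expects %d bp",
      wl$native_length, config$name, config$barcode_total_length
    )
  }
  wl
}

#' Generate the whitelist of all barcode permutations of a given length
#'
#' For platforms without known barcode sets, the whitelist is the full set of
#' `4^length` sequences. By default the list is only materialized for
#' lengths up to 10 (about one million barcodes); longer lists should be
#' consumed with [stream_permutation_whitelist()].
#'
#' @param length barcode length, 1..16.
#' @param materialize force (or forbid) building the full vector in memory.
#' @return An `sc_whitelist` in lexicographic order.
#' @export
generate_permutation_whitelist <- function(length, materialize = length <= 10) {
  length <- as.integer(length)
  if (is.na(length) || length < 1 || length > 16) {
    stop_data("permutation whitelist length must be in 1..16 (got %s)", length)
  }
  if (!materialize) {
    stop_data(
      "a %d bp permutation whitelist has %.0f entries; stream it with stream_permutation_whitelist() or pass materialize = TRUE",
      length, 4^length
    )
  }
  new_whitelist(all_kmers(length), source = "permutations")
}

#' Stream the permutation whitelist in lexicographic chunks
#'
#' Enumerates all `4^length` barcodes without ever holding more than one
#' chunk in memory, invoking `callback(chunk)` for each chunk in order.
#'
#' @param length barcode length, 1..16.
#' @param callback optional function applied to each character-vector chunk.
#' @param chunk_prefix_length chunk granularity: chunks share a fixed prefix
#'   of this length (so each chunk holds `4^(length - chunk_prefix_length)`
#'   barcodes).
#' @return The total number of barcodes streamed, invisibly.
#' @examples
#' stream_permutation_whitelist(6) # 4096
#' @export
stream_permutation_whitelist <- function(length, callback = NULL,
                                         chunk_prefix_length = max(0L, length - 8L)) {
  L <- as.integer(length)
  if (is.na(L) || L < 1 || L > 16) {
    stop_data("permutation whitelist length must be in 1..16 (got %s)", L)
  }
  p <- as.integer(chunk_prefix_length)
  stopifnot(p >= 0, p < L)
  suffixes <- all_kmers(L - p)
  total <- 0
  prefixes <- if (p == 0) "" else all_kmers(p)
  for (pre in prefixes) {
    chunk <- if (nzchar(pre)) paste0(pre, suffixes) else suffixes
    total <- total + base::length(chunk)
    if (!is.null(callback)) callback(chunk)
  }
  invisible(total)
}

#' Restrict a whitelist to selected wells
#'
#' Well-based platforms allow running on a subset of wells; the selection can
#' be the barcodes themselves or 1-based indices into the lexicographically
#' sorted whitelist.
#'
#' @param whitelist an `sc_whitelist`.
#' @param selected character barcodes (all must be present) or integer well
#'   indices.
#' @return The restricted `sc_whitelist`.
#' @export
subset_wells <- function(whitelist, selected) {
  stopifnot(inherits(whitelist, "sc_whitelist"))
  if (length(selected) == 0) stop_data("empty well selection")
  if (is.numeric(selected)) {
    idx <- as.integer(selected)
    ordered <- sort(whitelist$barcodes, method = "radix")
    if (any(idx < 1 | idx > length(ordered))) {
      stop_data("well index out of range 1..%d", length(ordered))
    }
    selected <- ordered[idx]
  }
  selected <- toupper(unique(selected))
  missing <- setdiff(selected, whitelist$barcodes)
  if (length(missing)) {
    stop_data(
      "selected barcodes not in whitelist: %s",
      paste(head(missing, 5), collapse = ", ")
    )
  }
  new_whitelist(whitelist$barcodes[whitelist$barcodes %in% selected],
    source = whitelist$source
  )
}

#' Determine the whitelist for a run
#'
#' Resolution order: an explicit user file wins; otherwise a bundled preset
#' file for the technology, if one is shipped; otherwise the permutation
#' whitelist (possible only for barcodes up to 16 bp). The choice is logged.
#'
#' @param config a `tech_config`.
#' @param path optional user-supplied whitelist file.
#' @return An `sc_whitelist`.
#' @export
determine_whitelist <- function(config, path = NULL) {
  if (!is.null(path)) {
    inform(sprintf("whitelist: user file %s", path))
    return(load_whitelist(path, config))
  }
  bundled <- system.file("extdata", "whitelists",
    paste0(config$name, "_synthetic_example.txt"),
    package = "scunify"
  )
  if (nzchar(bundled)) {
    inform(sprintf("whitelist: bundled example for %s", config$name))
    return(load_whitelist(bundled, config))
  }
  if (config$barcode_total_length <= 16) {
    inform(sprintf(
      "whitelist: all permutations of %d bp",
      config$barcode_total_length
    ))
    return(generate_permutation_whitelist(config$barcode_total_length,
      materialize = TRUE
    ))
  }
  stop_data(
    "no whitelist available for '%s': barcodes of %d bp cannot use permutations; supply a whitelist file",
    config$name, config$barcode_total_length
  )
}

#' Build the recoder that maps native barcodes into the 16 bp space
#'
#' Barcodes of exactly 16 bp pass through unchanged; shorter barcodes are
#' right-padded with a fixed pad sequence (identically for reads and
#' whitelist, so matching is preserved); longer barcodes are recoded through
#' a bijective surrogate table: the whitelist is sorted lexicographically and
#' the i-th barcode receives the i-th 16 bp sequence in lexicographic order,
#' so the table is reproducible without a seed.
#'
#' @param whitelist an `sc_whitelist` (mandatory for surrogate mode, where it
#'   defines the table's domain).
#' @param config optional `tech_config` for a length cross-check.
#' @return A `barcode_recoder` with `mode` one of `identity`, `pad`,
#'   `surrogate`.
#' @seealso [recode_barcodes()], [invert_barcodes()]
#' @export
build_recoder <- function(whitelist, config = NULL) {
  stopifnot(inherits(whitelist, "sc_whitelist"))
  if (!is.null(config) && whitelist$native_length != config$barcode_total_length) {
    stop_data(
      "whitelist length %d does not match config '%s' barcode length %d",
      whitelist$native_length, config$name, config$barcode_total_length
    )
  }
  recoder_for_length(whitelist$native_length, whitelist$barcodes)
}

## Internal constructor; pad/identity recoders need no whitelist.
recoder_for_length <- function(native_length, barcodes = NULL) {
  n <- as.integer(native_length)
  if (n == CANONICAL_BARCODE_LENGTH) {
    mode <- "identity"
    pad <- ""
    fwd <- NULL
  } else if (n < CANONICAL_BARCODE_LENGTH) {
    mode <- "pad"
    pad <- substr(PAD_SEQUENCE_16, 1, CANONICAL_BARCODE_LENGTH - n)
    fwd <- NULL
  } else {
    mode <- "surrogate"
    pad <- ""
    if (is.null(barcodes)) {
      stop_data("barcodes longer than 16 bp require a whitelist to build the surrogate table")
    }
    if (length(barcodes) > 4^16) stop_data("cannot embed more than 4^16 barcodes in 16 bp")
    sorted <- sort(barcodes, method = "radix")
    fwd <- setNames(int_to_kmer(seq_along(sorted) - 1, CANONICAL_BARCODE_LENGTH), sorted)
  }
  structure(
    list(
      native_length = n, mode = mode, pad_sequence = pad,
      surrogate_table = fwd,
      inverse_table = if (!is.null(fwd)) setNames(names(fwd), unname(fwd))
    ),
    class = "barcode_recoder"
  )
}

#' @export
print.barcode_recoder <- function(x, ...) {
  cat(sprintf(
    "<barcode_recoder> %d bp -> 16 bp, mode %s%s\n", x$native_length, x$mode,
    if (x$mode == "pad") paste0(" (pad '", x$pad_sequence, "')") else
      if (x$mode == "surrogate") sprintf(" (%d entries)", length(x$surrogate_table)) else ""
  ))
  invisible(x)
}

#' Apply / invert a barcode recoder
#'
#' `recode_barcodes()` maps native barcodes to their canonical 16 bp form.
#' In surrogate mode a barcode absent from the table maps to the 16-N
#' sentinel `NNNNNNNNNNNNNNNN` (N never occurs in a whitelist, so such reads
#' can never be mistaken for valid cells). `invert_barcodes()` recovers the
#' native barcode; the sentinel inverts to `NA`.
#'
#' @param recoder a `barcode_recoder`.
#' @param barcodes character vector (native for `recode_barcodes`, 16 bp
#'   canonical for `invert_barcodes`).
#' @return Character vector of the same length.
#' @export
recode_barcodes <- function(recoder, barcodes) {
  stopifnot(inherits(recoder, "barcode_recoder"))
  bad <- nchar(barcodes) != recoder$native_length
  if (any(bad)) {
    stop_data(
      "barcode '%s' has length %d, recoder expects %d",
      barcodes[bad][1], nchar(barcodes[bad][1]), recoder$native_length
    )
  }
  switch(recoder$mode,
    identity = barcodes,
    pad = paste0(barcodes, recoder$pad_sequence),
    surrogate = {
      out <- unname(recoder$surrogate_table[barcodes])
      out[is.na(out)] <- strrep("N", CANONICAL_BARCODE_LENGTH)
      out
    }
  )
}

#' @rdname recode_barcodes
#' @export
invert_barcodes <- function(recoder, barcodes) {
  stopifnot(inherits(recoder, "barcode_recoder"))
  switch(recoder$mode,
    identity = barcodes,
    pad = substr(barcodes, 1, recoder$native_length),
    surrogate = unname(recoder$inverse_table[barcodes])
  )
}

#' Recode a whole whitelist to 16 bp
#'
#' @param whitelist an `sc_whitelist`.
#' @param recoder a `barcode_recoder` built from it (defaults to
#'   `build_recoder(whitelist)`).
#' @return An `sc_whitelist` of 16 bp barcodes with the same cardinality.
#' @export
recode_whitelist <- function(whitelist, recoder = build_recoder(whitelist)) {
  out <- new_whitelist(recode_barcodes(recoder, whitelist$barcodes),
    source = whitelist$source
  )
  stopifnot(length(out$barcodes) == length(whitelist$barcodes))
  out
}

#' Write a (recoded) whitelist to disk
#'
#' One barcode per line, lexicographic order, newline-terminated — the
#' `barcodes.txt` convention. When `recoder` is in surrogate mode a sidecar
#' translation table `<path>.translation.tsv` (columns `native`, `surrogate`)
#' is written alongside, one row per barcode.
#'
#' @param whitelist an `sc_whitelist` (or character vector) of 16 bp barcodes.
#' @param path output file.
#' @param recoder optional `barcode_recoder` used to produce the entries.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(whitelist, path, recoder = NULL) {
  barcodes <- if (inherits(whitelist, "sc_whitelist")) whitelist$barcodes else whitelist
  if (any(nchar(barcodes) != CANONICAL_BARCODE_LENGTH)) {
    stop_data("write_whitelist expects 16 bp (recoded) barcodes")
  }
  readr::write_lines(sort(barcodes, method = "radix"), path)
  if (!is.null(recoder) && recoder$mode == "surrogate") {
    tab <- tibble(
      native = names(recoder$surrogate_table),
      surrogate = unname(recoder$surrogate_table)
    )
    readr::write_tsv(tab, paste0(path, ".translation.tsv"))
  }
  invisible(path)
}
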