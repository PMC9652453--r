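## Read-structure transformation: pull barcode/UMI/cDNA elements out of raw
## read pairs according to a chemistry's segment layout, then rewrite them in
## the canonical layout (16 bp barcode + fixed-length UMI in R1, cDNA in R2).

#' Canonical UMI length for a chemistry
#'
#' Every output R1 carries a UMI of this fixed length: 12 bp (the longest
#' UMI among the droplet chemistries the canonical layout targets), or the
#' native UMI length when a chemistry's UMI is longer (icell8's 14 bp), so
#' that no UMI bases are ever discarded. Chemistries without a UMI receive a
#' 12 bp deterministic pseudo-UMI (see [canonicalize()]).
#'
#' @param config a `tech_config`.
#' @return Integer length in bp.
#' @export
canonical_umi_length <- function(config) {
  if (is.na(config$umi_length)) 12L else max(12L, config$umi_length)
}

#' Extract barcode, UMI and cDNA elements from read pairs
#'
#' Applies a chemistry's segment layout to a set of read pairs: barcode
#' segments are concatenated in segment order with the config's linker fill
#' inserted after the first segment; linker-role segments are dropped; for
#' UMI-before-barcode chemistries the UMI simply occupies the earlier
#' positions; for chemistries whose elements sit in R2 the cDNA is taken
#' from R1. Reads too short for the required span are flagged (`status =
#' "short"`), not fatal.
#'
#' @param r1,r2 tibbles of reads (`id`, `seq`, `qual`) as from [read_fastq()].
#' @param config a `tech_config`.
#' @param i1,i2 optional index-read tibbles; mandatory when the config has
#'   `dual_index` or declares I1/I2 segments.
#' @return Tibble with one row per input pair: `read_id`, `barcode_raw`,
#'   `barcode_qual`, `umi_raw`, `umi_qual`, `cdna`, `cdna_qual`, `status`
#'   (`"ok"`, `"short"` or `"malformed"`).
#' @export
extract_elements <- function(r1, r2, config, i1 = NULL, i2 = NULL) {
  stopifnot(inherits(config, "tech_config"))
  check_paired(r1, r2)
  reads <- list(R1 = r1, R2 = r2, I1 = i1, I2 = i2)
  seg <- config$segments
  need_index <- union(
    intersect(unique(seg$source), c("I1", "I2")),
    if (config$dual_index) c("I1", "I2") else character()
  )
  for (src in need_index) {
    if (is.null(reads[[src]])) {
      stop_data("config '%s' requires index read %s, but none was supplied", config$name, src)
    }
    check_paired(r1, reads[[src]], "R1", src)
  }
  n <- nrow(r1)
  read_id <- normalize_read_id(r1$id)
  if (n == 0) {
    return(tibble(
      read_id = character(), barcode_raw = character(),
      barcode_qual = character(), umi_raw = character(),
      umi_qual = character(), cdna = character(), cdna_qual = character(),
      status = character()
    ))
  }

  ## a pair is too short if any source read is shorter than its required span
  status <- rep("ok", n)
  for (src in unique(seg$source)) {
    span <- max(seg$start[seg$source == src] + seg$length[seg$source == src])
    status[nchar(reads[[src]]$seq) < span] <- "short"
  }
  malformed <- is.na(r1$seq) | is.na(r2$seq) |
    nchar(r1$seq) != nchar(r1$qual) | nchar(r2$seq) != nchar(r2$qual)
  status[malformed] <- "malformed"

  slice_seg <- function(s) {
    src <- reads[[s$source]]
    list(
      seq = substr(src$seq, s$start + 1L, s$start + s$length),
      qual = substr(src$qual, s$start + 1L, s$start + s$length)
    )
  }
  bc_rows <- which(seg$role == "barcode")
  pieces <- lapply(bc_rows, function(i) slice_seg(seg[i, ]))
  if (nzchar(config$linker_fill)) {
    ## fill inserted after the first barcode segment (multi-segment barcodes
    ## whose parts do not reach the declared total)
    fill <- list(
      seq = rep(config$linker_fill, n),
      qual = rep(strrep(PAD_QUALITY_CHAR, nchar(config$linker_fill)), n)
    )
    pieces <- append(pieces, list(fill), after = 1L)
  }
  barcode_raw <- do.call(paste0, lapply(pieces, `[[`, "seq"))
  barcode_qual <- do.call(paste0, lapply(pieces, `[[`, "qual"))

  umi_rows <- which(seg$role == "umi")
  if (length(umi_rows)) {
    upieces <- lapply(umi_rows, function(i) slice_seg(seg[i, ]))
    umi_raw <- do.call(paste0, lapply(upieces, `[[`, "seq"))
    umi_qual <- do.call(paste0, lapply(upieces, `[[`, "qual"))
  } else {
    umi_raw <- rep(NA_character_, n)
    umi_qual <- rep(NA_character_, n)
  }

  cdna_read <- reads[[cdna_source(config)]]
  tibble(
    read_id = read_id,
    barcode_raw = barcode_raw, barcode_qual = barcode_qual,
    umi_raw = umi_raw, umi_qual = umi_qual,
    cdna = cdna_read$seq, cdna_qual = cdna_read$qual,
    status = status
  )
}

#' Rewrite extracted elements in the canonical layout
#'
#' Barcodes become exactly 16 bp through the recoder (identity at 16 bp,
#' fixed right-pad below, bijective surrogate above); pad bases get quality
#' `I`. UMIs are right-padded with `A` (quality `I`) to the canonical UMI
#' length. Chemistries without a UMI receive a deterministic pseudo-UMI
#' encoding the read's within-run ordinal in base-4, so no two reads of a
#' barcode collapse during deduplication — counts for such chemistries are
#' read counts, not molecule counts. The cDNA passes through byte-for-byte.
#'
#' @param elements tibble from [extract_elements()]; rows with `status !=
#'   "ok"` are rejected.
#' @param config a `tech_config`.
#' @param recoder a `barcode_recoder`; defaults to the whitelist-free
#'   pad/identity recoder, which exists only for barcodes up to 16 bp.
#' @param ordinal_start 0-based ordinal of the first read, for pseudo-UMIs
#'   spanning multiple lanes.
#' @return Tibble with `read_id`, `barcode16`, `barcode16_qual`, `umi`,
#'   `umi_qual`, `cdna`, `cdna_qual`.
#' @export
canonicalize <- function(elements, config, recoder = NULL, ordinal_start = 0) {
  stopifnot(inherits(config, "tech_config"))
  if (any(elements$status != "ok")) {
    stop_data("canonicalize() requires elements with status 'ok' only; filter first")
  }
  if (is.null(recoder)) {
    if (config$barcode_total_length > CANONICAL_BARCODE_LENGTH) {
      stop_data(
        "barcodes of %d bp need a whitelist-derived surrogate recoder",
        config$barcode_total_length
      )
    }
    recoder <- recoder_for_length(config$barcode_total_length)
  }
  n <- nrow(elements)
  bad <- nchar(elements$barcode_raw) != config$barcode_total_length
  if (any(bad)) {
    stop_data(
      "internal error: extracted barcode length %d != config total %d",
      nchar(elements$barcode_raw[bad][1]), config$barcode_total_length
    )
  }
  barcode16 <- recode_barcodes(recoder, elements$barcode_raw)
  barcode16_qual <- switch(recoder$mode,
    identity = elements$barcode_qual,
    pad = paste0(
      elements$barcode_qual,
      strrep(PAD_QUALITY_CHAR, CANONICAL_BARCODE_LENGTH - recoder$native_length)
    ),
    surrogate = rep(strrep(PAD_QUALITY_CHAR, CANONICAL_BARCODE_LENGTH), n)
  )
  umi_len <- canonical_umi_length(config)
  if (is.na(config$umi_length)) {
    umi <- if (n) int_to_kmer(ordinal_start + seq_len(n) - 1, umi_len) else character()
    umi_qual <- rep(strrep(PAD_QUALITY_CHAR, umi_len), n)
  } else {
    umi <- pad_to(elements$umi_raw, umi_len, "A")
    umi_qual <- pad_to(elements$umi_qual, umi_len, PAD_QUALITY_CHAR)
  }
  tibble(
    read_id = elements$read_id,
    barcode16 = barcode16, barcode16_qual = barcode16_qual,
    umi = umi, umi_qual = umi_qual,
    cdna = elements$cdna, cdna_qual = elements$cdna_qual
  )
}

#' Transform FASTQ files of any chemistry into the canonical layout
#'
#' Reads paired FASTQ input (one or more lanes), extracts and canonicalizes
#' barcode/UMI/cDNA per the chemistry, and writes output R1 (16 bp barcode +
#' canonical UMI) and R2 (untouched cDNA) FASTQ files under the
#' `<sample>_S1_L00<lane>_R1_001.fastq.gz` naming convention. Record order
#' and R1/R2 lockstep are preserved; pairs whose source reads are shorter
#' than the chemistry's span are dropped and counted. When a whitelist is
#' supplied, the recoded 16 bp whitelist (plus, for >16 bp chemistries, the
#' surrogate translation table) is written next to the reads, and the
#' report's `whitelist_match_rate` is filled in.
#'
#' @param r1_path,r2_path input FASTQ paths (vectors of equal length = lanes).
#' @param config a `tech_config` from [get_config()] or
#'   [make_custom_config()].
#' @param out_dir output directory, created if needed.
#' @param index_paths optional `list(i1 =, i2 =)` of index FASTQ paths
#'   (vectors parallel to `r1_path`), required for dual-index chemistries.
#' @param whitelist optional `sc_whitelist` (native barcodes); mandatory for
#'   chemistries with barcodes longer than 16 bp.
#' @param sample sample name used in output file names.
#' @param compress write gzip-compressed outputs (default `TRUE`).
#' @return A `transform_report` tibble with one row per lane plus a `total`
#'   row: `reads_in`, `reads_out`, `reads_discarded_short`,
#'   `reads_discarded_malformed`, `whitelist_match_rate`. The output file
#'   paths are in `attr(, "files")`; the report is also written as TSV.
#' @export
transform_fastq <- function(r1_path, r2_path, config, out_dir,
                            index_paths = NULL, whitelist = NULL,
                            sample = "sample", compress = TRUE) {
  stopifnot(inherits(config, "tech_config"))
  if (length(r1_path) != length(r2_path)) {
    stop_data("r1_path and r2_path must list the same number of lanes")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  recoder <- if (!is.null(whitelist)) {
    build_recoder(whitelist, config)
  } else if (config$barcode_total_length <= CANONICAL_BARCODE_LENGTH) {
    recoder_for_length(config$barcode_total_length)
  } else {
    stop_data(
      "chemistry '%s' has %d bp barcodes; a whitelist is required for surrogate recoding",
      config$name, config$barcode_total_length
    )
  }

  wl16 <- NULL
  if (!is.null(whitelist)) {
    wl16 <- recode_barcodes(recoder, whitelist$barcodes)
    write_whitelist(wl16, file.path(out_dir, paste0(sample, "_whitelist_16bp.txt")),
      recoder = recoder
    )
  }

  ext <- if (compress) ".fastq.gz" else ".fastq"
  files <- character()
  rows <- list()
  ordinal <- 0
  for (lane in seq_along(r1_path)) {
    r1 <- read_fastq(r1_path[lane])
    r2 <- read_fastq(r2_path[lane])
    i1 <- if (!is.null(index_paths$i1)) read_fastq(index_paths$i1[lane])
    i2 <- if (!is.null(index_paths$i2)) read_fastq(index_paths$i2[lane])
    el <- extract_elements(r1, r2, config, i1 = i1, i2 = i2)
    ok <- el[el$status == "ok", , drop = FALSE]
    can <- canonicalize(ok, config, recoder = recoder, ordinal_start = ordinal)
    ordinal <- ordinal + nrow(can)

    keep <- el$status == "ok"
    out_r1 <- tibble(
      id = r1$id[keep],
      seq = paste0(can$barcode16, can$umi),
      qual = paste0(can$barcode16_qual, can$umi_qual)
    )
    out_r2 <- tibble(id = r2$id[keep], seq = can$cdna, qual = can$cdna_qual)
    f1 <- file.path(out_dir, sprintf("%s_S1_L%03d_R1_001%s", sample, lane, ext))
    f2 <- file.path(out_dir, sprintf("%s_S1_L%03d_R2_001%s", sample, lane, ext))
    write_fastq(out_r1, f1)
    write_fastq(out_r2, f2)
    files <- c(files, f1, f2)

    match_rate <- if (!is.null(wl16) && nrow(can) > 0) {
      mean(can$barcode16 %in% wl16)
    } else {
      NA_real_
    }
    rows[[lane]] <- tibble(
      lane = as.character(lane),
      reads_in = nrow(el),
      reads_out = nrow(can),
      reads_discarded_short = sum(el$status == "short"),
      reads_discarded_malformed = sum(el$status == "malformed"),
      whitelist_match_rate = match_rate
    )
  }
  report <- bind_rows(rows)
  total <- summarise(report,
    lane = "total",
    across(c(reads_in, reads_out, reads_discarded_short, reads_discarded_malformed), sum),
    whitelist_match_rate = if (all(is.na(whitelist_match_rate))) NA_real_ else {
      sum(whitelist_match_rate * reads_out, na.rm = TRUE) / sum(reads_out[!is.na(whitelist_match_rate)])
    }
  )
  report <- bind_rows(report, total)
  report_path <- file.path(out_dir, paste0(sample, "_transform_report.tsv"))
  readr::write_tsv(report, report_path)
  inform(sprintf(
    "transform: %d pairs in, %d out (%d short, %d malformed)",
    total$reads_in, total$reads_out,
    total$reads_discarded_short, total$reads_discarded_malformed
  ))
  structure(report,
    files = files, report_path = report_path,
    class = c("transform_report", class(report))
  )
}
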