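## Pair-preserving quality filtering: drop read pairs based on Read-2 quality
## alone, keeping R1 and R2 strictly synchronized. Sequences are never edited.

#' Filter read pairs by Read-2 quality
#'
#' A pair is kept if and only if Read 2 passes the chosen quality metric at
#' the threshold; both mates are then written in original order, so the two
#' outputs stay in lockstep and cell barcodes are never mismatched. Read 1
#' quality is never consulted.
#'
#' Metrics (on Phred+33 scores of R2):
#' * `mean` (default): mean base quality >= `threshold`;
#' * `min`: minimum base quality >= `threshold`;
#' * `fraction_below`: fraction of bases below `threshold` must be at most
#'   `max_fraction`.
#'
#' @param r1_path,r2_path input FASTQ files (plain or gzipped).
#' @param out_prefix output prefix; writes `<prefix>_R1.fastq(.gz)`,
#'   `<prefix>_R2.fastq(.gz)` and `<prefix>_filter_report.tsv`.
#' @param threshold Phred threshold (default 20, a conventional choice — not
#'   a calibrated value).
#' @param metric quality statistic, see above.
#' @param max_fraction tolerance for `fraction_below` (default 0.5).
#' @param compress gzip the outputs (default: inherited from the input's
#'   extension).
#' @return A `filter_report` tibble: `pairs_in`, `pairs_kept`,
#'   `pairs_dropped`, `threshold`, `metric`.
#' @export
filter_pairs <- function(r1_path, r2_path, out_prefix, threshold = 20,
                         metric = c("mean", "min", "fraction_below"),
                         max_fraction = 0.5,
                         compress = grepl("\\.gz$", r1_path)) {
  metric <- match.arg(metric)
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  check_paired(r1, r2)

  keep <- if (nrow(r2) == 0) {
    logical()
  } else {
    switch(metric,
      mean = phred_stat(r2$qual, mean) >= threshold,
      min = phred_stat(r2$qual, min) >= threshold,
      fraction_below = phred_stat(r2$qual, function(q) mean(q < threshold)) <= max_fraction
    )
  }

  ext <- if (compress) ".fastq.gz" else ".fastq"
  f1 <- paste0(out_prefix, "_R1", ext)
  f2 <- paste0(out_prefix, "_R2", ext)
  write_fastq(r1[keep, , drop = FALSE], f1)
  write_fastq(r2[keep, , drop = FALSE], f2)

  report <- tibble(
    pairs_in = nrow(r1), pairs_kept = sum(keep),
    pairs_dropped = nrow(r1) - sum(keep),
    threshold = threshold, metric = metric
  )
  readr::write_tsv(report, paste0(out_prefix, "_filter_report.tsv"))
  inform(sprintf(
    "filter-quality: kept %d of %d pairs (R2 %s >= %s)",
    report$pairs_kept, report$pairs_in, metric, threshold
  ))
  structure(report,
    files = c(f1, f2),
    class = c("filter_report", class(report))
  )
}
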