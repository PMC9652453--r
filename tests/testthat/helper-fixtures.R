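## Shared fixtures built in code: toy reads, FASTQ writers, small GBMs.

fastq_tbl <- function(ids, seqs, quals = strrep("I", nchar(seqs))) {
  tibble::tibble(id = ids, seq = seqs, qual = quals)
}

write_tmp_fastq <- function(reads, ext = ".fastq") {
  path <- tempfile(fileext = ext)
  write_fastq(reads, path)
  path
}

## n distinct random DNA strings, independent of package internals
random_dna_distinct_for_test <- function(n, width) {
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), ncol = width)
    out <- unique(c(out, apply(m, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}

## dense matrix -> gbm with default labels
toy_gbm <- function(m, genes = paste0("g", seq_len(nrow(m))),
                    barcodes = paste0("bc", seq_len(ncol(m)))) {
  new_gbm(Matrix::Matrix(m, sparse = TRUE), genes = genes, barcodes = barcodes)
}

## independent brute-force UMI tally: distinct (barcode, gene, umi) triples
## among records passing the counting rule, via base R only
brute_force_counts <- function(x, whitelist) {
  keep <- x$mapped & !x$is_secondary & x$alignment_count == 1 &
    !is.na(x$gene) & x$barcode %in% whitelist
  x <- x[keep, , drop = FALSE]
  key <- unique(paste(x$barcode, x$gene, x$umi, sep = "\r"))
  if (length(key) == 0) {
    return(data.frame(barcode = character(), gene = character(), n = integer()))
  }
  parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
  agg <- aggregate(list(n = rep(1L, nrow(parts))),
    by = list(barcode = parts[, 1], gene = parts[, 2]), FUN = sum
  )
  agg[order(agg$gene, agg$barcode), , drop = FALSE]
}

## gbm -> long data frame for comparison with the brute-force tally
gbm_long <- function(g) {
  s <- Matrix::summary(g$counts)
  out <- data.frame(
    barcode = g$barcodes[s$j], gene = g$genes[s$i], n = as.integer(s$x)
  )
  out[order(out$gene, out$barcode), , drop = FALSE]
}

expect_same_counts <- function(gbm, brute) {
  got <- gbm_long(gbm)
  rownames(got) <- rownames(brute) <- NULL
  expect_equal(got, brute[, c("barcode", "gene", "n")])
}
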