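## UMI counting over tagged alignments, and GBM I/O.

aln_row <- function(read_id, barcode, umi, gene, mapped = TRUE,
                    alignment_count = 1L, is_secondary = FALSE) {
  tibble::tibble(
    read_id = read_id, barcode = barcode, umi = umi, gene = gene,
    mapped = mapped, alignment_count = as.integer(alignment_count),
    is_secondary = is_secondary
  )
}

test_that("multi-mapping, secondary, unmapped and unassigned reads are inert", {
  bc <- strrep("A", 16)
  base <- aln_row("r1", bc, "ACGT", "g1")
  extras <- dplyr::bind_rows(
    aln_row("r2", bc, "TTTT", "g1", alignment_count = 2L), # multimapper
    aln_row("r3", bc, "GGGG", "g1", mapped = FALSE), # unmapped
    aln_row("r4", bc, "CCCC", NA_character_), # no gene
    aln_row("r5", bc, "AAAA", "g1", is_secondary = TRUE) # secondary
  )
  g <- count_matrix(dplyr::bind_rows(base, extras), whitelist = bc)
  expect_identical(sum(g$counts), 1)
  g_clean <- count_matrix(base, whitelist = bc)
  expect_identical(as.matrix(g), as.matrix(g_clean))
})

test_that("identical (barcode, gene, UMI) triples collapse to one count", {
  bc <- strrep("C", 16)
  x <- dplyr::bind_rows(
    aln_row("r1", bc, "ACGT", "g1"),
    aln_row("r2", bc, "ACGT", "g1"), # duplicate molecule
    aln_row("r3", bc, "TGCA", "g1") # second molecule
  )
  g <- count_matrix(x, whitelist = bc)
  expect_identical(as.vector(as.matrix(g)), 2)
})

test_that("barcodes off the whitelist contribute nothing", {
  bc1 <- strrep("A", 16)
  bc2 <- strrep("G", 16)
  x <- dplyr::bind_rows(
    aln_row("r1", bc1, "ACGT", "g1"),
    aln_row("r2", bc2, "ACGT", "g1")
  )
  g <- count_matrix(x, whitelist = bc1)
  expect_identical(g$barcodes, bc1)
})

test_that("count_matrix equals the brute-force distinct-triple tally", {
  for (s in 1:25) {
    sim <- simulate_tagged_alignments(
      n_reads = 200, n_genes = 6, n_barcodes = 5,
      mapped_rate = 0.8, multimap_rate = 0.2, seed = s
    )
    g <- count_matrix(sim$alignments, whitelist = sim$barcodes)
    brute <- brute_force_counts(sim$alignments, sim$barcodes)
    expect_same_counts(g, brute)
    ## and the generator's planted tally agrees
    expect_identical(sum(g$counts), as.numeric(sum(sim$truth$umi_counts$n_umis)))
  }
})

test_that("adding multi-mapping records never changes the matrix", {
  for (s in 1:5) {
    sim <- simulate_tagged_alignments(150, 5, 4, seed = s, multimap_rate = 0)
    g0 <- count_matrix(sim$alignments, whitelist = sim$barcodes)
    extra <- sim$alignments[sample(nrow(sim$alignments), 30), ]
    extra$alignment_count <- 3L
    extra$umi <- strrep("T", 10) # even a fresh UMI must not count
    g1 <- count_matrix(dplyr::bind_rows(sim$alignments, extra),
      whitelist = sim$barcodes
    )
    expect_identical(as.matrix(g0), as.matrix(g1))
  }
})

test_that("per-barcode summaries tally reads, mappings, assignments, UMIs", {
  bc <- strrep("T", 16)
  ## 10 reads: 8 mapped, of which 6 uniquely assigned with 5 distinct UMIs
  x <- dplyr::bind_rows(
    aln_row(paste0("r", 1:5), bc, c("A1", "A2", "A3", "A4", "A5"), "g1"),
    aln_row("r6", bc, "A5", "g1"), # duplicate UMI
    aln_row("r7", bc, "B1", "g1", alignment_count = 2L),
    aln_row("r8", bc, "B2", NA_character_),
    aln_row(paste0("r", 9:10), bc, c("C1", "C2"), "g1", mapped = FALSE)
  )
  s <- summarize_barcodes(x)
  per <- s$per_barcode
  expect_identical(per$reads_total, 10L)
  expect_identical(per$reads_mapped, 8L)
  expect_identical(per$reads_assigned, 6L)
  expect_identical(per$umi_count, 5L)
  expect_true(per$umi_count <= per$reads_assigned)
  expect_true(per$reads_assigned <= per$reads_mapped)
  expect_identical(s$global$mapping_rate, 0.8)
})

test_that("column sums of the GBM equal per-barcode UMI counts", {
  sim <- simulate_tagged_alignments(400, 8, 6, seed = 17)
  g <- count_matrix(sim$alignments, whitelist = sim$barcodes)
  s <- summarize_barcodes(sim$alignments)
  col_sums <- Matrix::colSums(g$counts)
  per <- s$per_barcode[match(g$barcodes, s$per_barcode$barcode), ]
  expect_identical(unname(col_sums), as.numeric(per$umi_count))
})

test_that("empty stream yields empty summaries without a mapping rate", {
  empty <- aln_row(character(), character(), character(), character())
  s <- summarize_barcodes(empty)
  expect_identical(nrow(s$per_barcode), 0L)
  expect_true(is.na(s$global$mapping_rate))
})

test_that("planted mapping rates are reproduced exactly from the manifest", {
  sim <- simulate_tagged_alignments(1000, 10, 8,
    mapped_rate = 0.8,
    multimap_rate = 0.1, seed = 23
  )
  s <- summarize_barcodes(sim$alignments)
  expect_identical(
    s$global$mapping_rate,
    sim$truth$n_mapped / nrow(sim$alignments)
  )
  ## realized count is binomially near the planted rate
  expect_gt(sim$truth$n_mapped, 740)
  expect_lt(sim$truth$n_mapped, 860)
})

test_that("GBM MatrixMarket round trip is value-equal, plain and gzipped", {
  g <- toy_gbm(matrix(c(0, 3, 1, 0, 2, 5), nrow = 3))
  for (compress in c(FALSE, TRUE)) {
    d <- tempfile()
    write_gbm(g, d, compress = compress)
    mtx <- file.path(d, if (compress) "matrix.mtx.gz" else "matrix.mtx")
    expect_true(file.exists(mtx))
    back <- read_gbm(d)
    expect_identical(back$genes, g$genes)
    expect_identical(back$barcodes, g$barcodes)
    expect_true(all(back$counts == g$counts))
  }
  ## entry count in the file equals the number of nonzeros
  d <- tempfile()
  write_gbm(g, d)
  lines <- readLines(file.path(d, "matrix.mtx"))
  body <- lines[!startsWith(lines, "%")]
  dims <- as.integer(strsplit(body[1], "\\s+")[[1]])
  expect_identical(dims[3], as.integer(Matrix::nnzero(g$counts)))
  expect_identical(length(body) - 1L, as.integer(Matrix::nnzero(g$counts)))
})

test_that("label/dimension mismatches on read are fatal", {
  g <- toy_gbm(matrix(1:6, nrow = 3))
  d <- tempfile()
  write_gbm(g, d)
  writeLines(c("g1", "g2"), file.path(d, "features.tsv"))
  expect_error(read_gbm(d), "mismatch")
})

test_that("tagged alignments load from TSV and SAM with standard tags", {
  sim <- simulate_tagged_alignments(50, 4, 3, seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(sim$alignments, tsv)
  x <- read_tagged_alignments(tsv)
  expect_identical(
    count_matrix(x, sim$barcodes)$counts,
    count_matrix(sim$alignments, sim$barcodes)$counts
  )

  skip_if_not_installed("Rsamtools")
  a <- sim$alignments[1:20, ]
  sam <- tempfile(fileext = ".sam")
  flag <- ifelse(a$mapped, 0L, 4L) + ifelse(a$is_secondary, 256L, 0L)
  gene_tag <- ifelse(is.na(a$gene), "", sprintf("\tGX:Z:%s", a$gene))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    sprintf(
      "%s\t%d\tchr1\t%d\t30\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tCB:Z:%s\tUB:Z:%s\tNH:i:%d%s",
      a$read_id, flag, seq_len(nrow(a)) * 10, a$barcode, a$umi,
      a$alignment_count, gene_tag
    )
  ), sam)
  y <- read_tagged_alignments(sam)
  expect_identical(nrow(y), 20L)
  y <- y[match(a$read_id, y$read_id), ]
  expect_identical(y$barcode, a$barcode)
  expect_identical(y$mapped, a$mapped)
  expect_identical(y$alignment_count, a$alignment_count)
  expect_identical(is.na(y$gene), is.na(a$gene))
})
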