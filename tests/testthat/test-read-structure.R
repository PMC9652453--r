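## Extraction and canonicalization of read elements.

test_that("single-segment extraction slices barcode, UMI and cDNA correctly", {
  cfg <- get_config("dropseq") # 12 bp barcode + 8 bp UMI on R1
  bc <- "AACCGGTTAACC"
  umi <- "GGGGTTTT"
  r1 <- fastq_tbl("r1", paste0(bc, umi, "ACGTAC")) # with tail
  r2 <- fastq_tbl("r1", "TTTTACGTACGTACGTAAAA")
  el <- extract_elements(r1, r2, cfg)
  expect_identical(el$barcode_raw, bc)
  expect_identical(el$umi_raw, umi)
  expect_identical(el$cdna, r2$seq)
  expect_identical(el$status, "ok")
})

test_that("UMI-before-barcode chemistries read the UMI from the front", {
  cfg <- get_config("celseq2") # 6 bp UMI then 6 bp barcode
  r1 <- fastq_tbl("r1", paste0("TTTTTT", "ACACAC", "GGG"))
  r2 <- fastq_tbl("r1", strrep("A", 30))
  el <- extract_elements(r1, r2, cfg)
  expect_identical(el$umi_raw, "TTTTTT")
  expect_identical(el$barcode_raw, "ACACAC")
})

test_that("elements-in-R2 chemistries take barcode/UMI from R2, cDNA from R1", {
  cfg <- get_config("indrops-v2")
  sim <- simulate_reads(cfg, n_cells = 2, reads_per_cell = 3, seed = 11)
  r1 <- read_fastq(sim$r1)
  r2 <- read_fastq(sim$r2)
  el <- extract_elements(r1, r2, cfg)
  expect_identical(unname(el$barcode_raw), sim$manifest$true_barcode)
  expect_identical(unname(el$umi_raw), sim$manifest$true_umi)
  expect_identical(el$cdna, r1$seq) # cDNA from R1 for this chemistry
})

test_that("linker segments are removed and linker fill is inserted", {
  cfg <- get_config("indrops-v1") # R2: 8bc + 4 linker + 8bc + 6 umi, fill CAG
  b1 <- "AAAATTTT"
  b2 <- "CCCCGGGG"
  r2 <- fastq_tbl("r", paste0(b1, "XXXX", b2, "ACACAC")) # linker bases arbitrary
  r2$seq <- sub("XXXX", "GGTT", r2$seq)
  r1 <- fastq_tbl("r", strrep("T", 40))
  el <- extract_elements(r1, r2, cfg)
  expect_identical(el$barcode_raw, paste0(b1, "CAG", b2))
  expect_identical(nchar(el$barcode_raw), 19L)
})

test_that("too-short source reads are flagged, not fatal", {
  cfg <- get_config("dropseq") # needs 20 bp of R1
  r1 <- fastq_tbl(c("a", "b"), c("ACGTA", strrep("A", 20)))
  r2 <- fastq_tbl(c("a", "b"), c(strrep("C", 30), strrep("C", 30)))
  el <- extract_elements(r1, r2, cfg)
  expect_identical(el$status, c("short", "ok"))
})

test_that("dual-index chemistries demand their index reads", {
  cfg <- get_config("indrops-v3")
  r1 <- fastq_tbl("a", strrep("A", 30))
  r2 <- fastq_tbl("a", strrep("C", 30))
  expect_error(extract_elements(r1, r2, cfg), "index read")
  i <- fastq_tbl("a", strrep("G", 8))
  el <- extract_elements(r1, r2, cfg, i1 = i, i2 = i)
  expect_identical(el$status, "ok")
})

test_that("canonicalization pads short barcodes with the fixed pad", {
  cfg <- get_config("dropseq")
  el <- tibble::tibble(
    read_id = "r", barcode_raw = "ACGTACGTACGT", barcode_qual = strrep("F", 12),
    umi_raw = "ACGTACGT", umi_qual = strrep("F", 8),
    cdna = "AAAA", cdna_qual = "IIII", status = "ok"
  )
  can <- canonicalize(el, cfg)
  expect_identical(nchar(can$barcode16), 16L)
  expect_identical(substr(can$barcode16, 1, 12), "ACGTACGTACGT")
  expect_identical(substr(can$barcode16, 13, 16), "ACGT") # pad prefix
  expect_identical(can$barcode16_qual, paste0(strrep("F", 12), "IIII"))
  ## UMI padded from 8 to 12 with A, quality I
  expect_identical(can$umi, "ACGTACGTAAAA")
  expect_identical(can$umi_qual, paste0(strrep("F", 8), "IIII"))
  expect_identical(can$cdna, el$cdna)
})

test_that("16 bp barcodes pass through canonicalization unchanged", {
  cfg <- get_config("10x-v3")
  bc <- strrep("GT", 8)
  el <- tibble::tibble(
    read_id = "r", barcode_raw = bc, barcode_qual = strrep("J", 16),
    umi_raw = strrep("A", 12), umi_qual = strrep("J", 12),
    cdna = "AAAA", cdna_qual = "IIII", status = "ok"
  )
  can <- canonicalize(el, cfg)
  expect_identical(can$barcode16, bc)
  expect_identical(can$barcode16_qual, el$barcode_qual)
  expect_identical(can$umi, el$umi_raw)
})

test_that("oversized barcodes go through the bijective surrogate and back", {
  cfg <- get_config("splitseq") # 18 bp
  wl <- new_whitelist(sort(random_dna_distinct_for_test(50, 18)))
  rec <- build_recoder(wl, cfg)
  surr <- recode_barcodes(rec, wl$barcodes)
  expect_true(all(nchar(surr) == 16))
  expect_identical(anyDuplicated(surr), 0L)
  expect_identical(invert_barcodes(rec, surr), wl$barcodes)
})

test_that("chemistries without a UMI get distinct deterministic pseudo-UMIs", {
  cfg <- get_config("quartz-seq") # 6 bp barcode, no UMI
  n <- 5
  el <- tibble::tibble(
    read_id = paste0("r", 1:n), barcode_raw = strrep("A", 6),
    barcode_qual = strrep("I", 6), umi_raw = NA_character_,
    umi_qual = NA_character_, cdna = "AAAA", cdna_qual = "IIII", status = "ok"
  )
  can1 <- canonicalize(el, cfg)
  can2 <- canonicalize(el, cfg)
  expect_identical(can1$umi, can2$umi) # deterministic
  expect_identical(anyDuplicated(can1$umi), 0L) # no two reads collapse
  expect_true(all(nchar(can1$umi) == 12))
  ## ordinal offset continues across lanes
  can3 <- canonicalize(el, cfg, ordinal_start = n)
  expect_identical(anyDuplicated(c(can1$umi, can3$umi)), 0L)
})

test_that("transform_fastq writes canonical pairs in lockstep", {
  cfg <- get_config("dropseq")
  sim <- simulate_reads(cfg, n_cells = 5, reads_per_cell = 10, seed = 1)
  out <- withr::local_tempdir()
  rep <- transform_fastq(sim$r1, sim$r2, cfg, out,
    whitelist = sim$whitelist, sample = "t", compress = FALSE
  )
  expect_identical(rep$reads_out[rep$lane == "total"], 50L)
  expect_identical(rep$reads_in[rep$lane == "total"], 50L)
  r1o <- read_fastq(file.path(out, "t_S1_L001_R1_001.fastq"))
  r2o <- read_fastq(file.path(out, "t_S1_L001_R2_001.fastq"))
  expect_identical(nrow(r1o), nrow(r2o))
  expect_identical(normalize_read_id(r1o$id), normalize_read_id(r2o$id))
  expect_true(all(nchar(r1o$seq) == 16 + canonical_umi_length(cfg)))
  ## cDNA immutability: output R2 bytes equal input R2 bytes
  expect_identical(r2o$seq, read_fastq(sim$r2)$seq)
  ## report invariant
  tot <- rep[rep$lane == "total", ]
  expect_identical(
    tot$reads_in,
    tot$reads_out + tot$reads_discarded_short + tot$reads_discarded_malformed
  )
})

test_that("transform handles discards while preserving lockstep and totals", {
  cfg <- get_config("dropseq")
  sim <- simulate_reads(cfg, n_cells = 3, reads_per_cell = 4, seed = 2)
  r1 <- read_fastq(sim$r1)
  r1$seq[c(2, 7)] <- substr(r1$seq[c(2, 7)], 1, 5) # too short now
  r1$qual[c(2, 7)] <- substr(r1$qual[c(2, 7)], 1, 5)
  f1 <- write_tmp_fastq(r1)
  out <- withr::local_tempdir()
  rep <- transform_fastq(f1, sim$r2, cfg, out, sample = "d", compress = FALSE)
  tot <- rep[rep$lane == "total", ]
  expect_identical(tot$reads_discarded_short, 2L)
  expect_identical(tot$reads_out, 10L)
  r1o <- read_fastq(file.path(out, "d_S1_L001_R1_001.fastq"))
  r2o <- read_fastq(file.path(out, "d_S1_L001_R2_001.fastq"))
  expect_identical(normalize_read_id(r1o$id), normalize_read_id(r2o$id))
})

test_that("empty inputs produce valid empty outputs", {
  cfg <- get_config("dropseq")
  empty <- fastq_tbl(character(), character(), character())
  f1 <- write_tmp_fastq(empty)
  f2 <- write_tmp_fastq(empty)
  out <- withr::local_tempdir()
  rep <- transform_fastq(f1, f2, cfg, out, sample = "e", compress = FALSE)
  expect_identical(rep$reads_in[rep$lane == "total"], 0L)
  expect_identical(nrow(read_fastq(file.path(out, "e_S1_L001_R1_001.fastq"))), 0L)
})

test_that("unequal record counts or divergent ids are fatal with an index", {
  cfg <- get_config("dropseq")
  r1 <- fastq_tbl(paste0("r", 1:10), strrep("A", 25))
  r2 <- fastq_tbl(paste0("r", 1:9), strrep("C", 25))
  err <- expect_error(
    transform_fastq(write_tmp_fastq(r1), write_tmp_fastq(r2), cfg,
      withr::local_tempdir(),
      compress = FALSE
    ),
    class = "scunify_data_error"
  )
  expect_match(conditionMessage(err), "10")
  r2b <- fastq_tbl(c(paste0("r", 1:5), "zzz", paste0("r", 7:10)), strrep("C", 25))
  expect_error(
    transform_fastq(write_tmp_fastq(r1), write_tmp_fastq(r2b), cfg,
      withr::local_tempdir(),
      compress = FALSE
    ),
    "record 6"
  )
})

test_that("multi-lane inputs give per-lane outputs with continuing ordinals", {
  cfg <- get_config("quartz-seq") # no UMI -> ordinal pseudo-UMIs
  sim1 <- simulate_reads(cfg, n_cells = 2, reads_per_cell = 3, seed = 5)
  sim2 <- simulate_reads(cfg, n_cells = 2, reads_per_cell = 3, seed = 6)
  out <- withr::local_tempdir()
  rep <- transform_fastq(c(sim1$r1, sim2$r1), c(sim1$r2, sim2$r2), cfg, out,
    sample = "ml", compress = FALSE
  )
  expect_identical(nrow(rep), 3L) # two lanes + total
  l1 <- read_fastq(file.path(out, "ml_S1_L001_R1_001.fastq"))
  l2 <- read_fastq(file.path(out, "ml_S1_L002_R1_001.fastq"))
  umis <- substr(c(l1$seq, l2$seq), 17, 28)
  expect_identical(anyDuplicated(umis), 0L)
})

test_that("two runs on identical input are byte-identical", {
  cfg <- get_config("celseq")
  sim <- simulate_reads(cfg, n_cells = 3, reads_per_cell = 5, seed = 9)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  transform_fastq(sim$r1, sim$r2, cfg, out1, sample = "x", compress = FALSE)
  transform_fastq(sim$r1, sim$r2, cfg, out2, sample = "x", compress = FALSE)
  for (f in c("x_S1_L001_R1_001.fastq", "x_S1_L001_R2_001.fastq")) {
    expect_identical(
      readLines(file.path(out1, f)), readLines(file.path(out2, f))
    )
  }
})
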