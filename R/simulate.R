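## Ground-truthed synthetic data: reads assembled exactly per a chemistry's
## segment layout (linkers inserted, roles/positions inverted where the
## chemistry demands, index files emitted for dual-index platforms), plus
## tagged alignment streams with planted rates. Everything is deterministic
## given the seed, and realized (not just expected) quantities are recorded
## so tests can assert exact equality.

#' Simulate reads for a chemistry, with a truth manifest
#'
#' Draws `n_cells` cell barcodes (from `whitelist` if given, otherwise
#' random distinct barcodes of the chemistry's native length), assigns each
#' read a random UMI and a source transcript from a toy transcriptome, and
#' assembles the FASTQ records by writing each segment's bases at its
#' configured position: barcode parts, UMI, constant linker bases, and the
#' cDNA on the partner read. Substitution errors are injected into the cDNA
#' at `error_rate` (barcodes and UMIs stay clean unless
#' `barcode_error_rate > 0`, for negative tests).
#'
#' @param config a `tech_config`.
#' @param n_cells number of cells.
#' @param reads_per_cell reads per cell.
#' @param seed RNG seed; identical calls are byte-identical.
#' @param out_dir output directory for FASTQ, manifest and whitelist files.
#' @param error_rate per-base substitution rate in the cDNA, in `[0, 1)`.
#' @param barcode_error_rate per-base substitution rate in barcode segments.
#' @param whitelist optional `sc_whitelist` to draw cells from
#'   (`n_cells <= |whitelist|`).
#' @param n_genes,cdna_length toy transcriptome size and transcript length.
#' @param tail_length extra random bases appended to the barcode-bearing
#'   read beyond its last segment (real reads often run past the structured
#'   region).
#' @return List with FASTQ paths (`$r1`, `$r2`, and `$i1`/`$i2` when index
#'   reads are emitted), the truth `$manifest` tibble (read_id,
#'   true_barcode at native length, true_umi, gene), the `$whitelist` of all
#'   cell barcodes, and `$params`.
#' @export
simulate_reads <- function(config, n_cells, reads_per_cell, seed,
                           out_dir = tempfile("sim"), error_rate = 0,
                           barcode_error_rate = 0, whitelist = NULL,
                           n_genes = 10, cdna_length = 60, tail_length = 0) {
  stopifnot(inherits(config, "tech_config"))
  if (n_cells < 1 || reads_per_cell < 1) stop_data("n_cells and reads_per_cell must be positive")
  if (error_rate < 0 || error_rate >= 1) stop_data("error_rate must be in [0, 1)")
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seg <- config$segments
  bc_seg <- seg[seg$role == "barcode", , drop = FALSE]
  part_lengths <- bc_seg$length
  fill <- config$linker_fill

  ## cell barcodes: native form = part1 + linker_fill + remaining parts
  if (!is.null(whitelist)) {
    if (n_cells > length(whitelist$barcodes)) {
      stop_data("n_cells exceeds whitelist size %d", length(whitelist$barcodes))
    }
    if (whitelist$native_length != config$barcode_total_length) {
      stop_data("whitelist length does not match config barcode length")
    }
    native <- sample(whitelist$barcodes, n_cells)
    all_barcodes <- whitelist$barcodes
  } else {
    joined <- random_dna_distinct(n_cells, sum(part_lengths))
    parts <- split_parts(joined, part_lengths)
    native <- join_native(parts, fill)
    all_barcodes <- native
  }
  cell_parts <- decompose_native(native, part_lengths, fill)

  n <- n_cells * reads_per_cell
  read_id <- sprintf("read%06d", seq_len(n))
  cell_idx <- rep(seq_len(n_cells), each = reads_per_cell)

  has_umi <- !is.na(config$umi_length)
  umi <- if (has_umi) random_dna(n, config$umi_length) else rep(NA_character_, n)

  genes <- sprintf("gene%03d", seq_len(n_genes))
  transcriptome <- setNames(random_dna(n_genes, cdna_length), genes)
  gene_of_read <- sample(genes, n, replace = TRUE)
  cdna <- inject_errors(unname(transcriptome[gene_of_read]), error_rate)

  bc_parts_of_read <- lapply(cell_parts, function(p) {
    inject_errors(p[cell_idx], barcode_error_rate)
  })

  ## assemble each source read present in the layout; barcode segments take
  ## their parts in global assembly order
  bc_rank <- cumsum(seg$role == "barcode")
  sources <- unique(seg$source)
  element_reads <- list()
  for (src in sources) {
    rows <- which(seg$source == src)
    width <- max(seg$start[rows] + seg$length[rows])
    body <- random_dna(n, width)
    for (k in rows) {
      piece <- switch(seg$role[k],
        barcode = bc_parts_of_read[[bc_rank[k]]],
        umi = umi,
        linker = rep(linker_bases(seg$length[k], fill), n)
      )
      substr(body, seg$start[k] + 1, seg$start[k] + seg$length[k]) <- piece
    }
    if (tail_length > 0) body <- paste0(body, random_dna(n, tail_length))
    element_reads[[src]] <- tibble(
      id = read_id, seq = body,
      qual = strrep(PAD_QUALITY_CHAR, nchar(body))
    )
  }
  cdna_src <- cdna_source(config)
  element_reads[[cdna_src]] <- tibble(
    id = read_id, seq = cdna, qual = strrep(PAD_QUALITY_CHAR, nchar(cdna))
  )
  if (config$dual_index) {
    for (src in c("I1", "I2")) {
      if (is.null(element_reads[[src]])) {
        element_reads[[src]] <- tibble(
          id = read_id, seq = random_dna(n, 8), qual = strrep(PAD_QUALITY_CHAR, 8)
        )
      }
    }
  }

  paths <- list()
  for (src in names(element_reads)) {
    p <- file.path(out_dir, paste0(tolower(src), ".fastq"))
    write_fastq(element_reads[[src]], p)
    paths[[tolower(src)]] <- p
  }

  manifest <- tibble(
    read_id = read_id,
    true_barcode = native[cell_idx],
    true_umi = umi,
    gene = gene_of_read
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  readr::write_lines(
    sort(all_barcodes, method = "radix"),
    file.path(out_dir, "whitelist.txt")
  )

  list(
    r1 = paths$r1, r2 = paths$r2, i1 = paths$i1, i2 = paths$i2,
    manifest = manifest,
    whitelist = new_whitelist(all_barcodes, source = "file"),
    config = config,
    params = list(
      seed = seed, n_cells = n_cells, reads_per_cell = reads_per_cell,
      error_rate = error_rate, barcode_error_rate = barcode_error_rate,
      n_genes = n_genes, cdna_length = cdna_length
    )
  )
}

## split joined part-strings into the per-segment pieces
split_parts <- function(joined, part_lengths) {
  off <- cumsum(c(0, part_lengths))
  lapply(seq_along(part_lengths), function(i) {
    substr(joined, off[i] + 1, off[i + 1])
  })
}

## native barcode = part1 + fill + part2 + ...
join_native <- function(parts, fill) {
  if (length(parts) == 1) {
    return(paste0(parts[[1]], fill))
  }
  do.call(paste0, c(parts[1], list(fill), parts[-1]))
}

## inverse of join_native
decompose_native <- function(native, part_lengths, fill) {
  nf <- nchar(fill)
  out <- vector("list", length(part_lengths))
  pos <- 0
  for (i in seq_along(part_lengths)) {
    out[[i]] <- substr(native, pos + 1, pos + part_lengths[i])
    pos <- pos + part_lengths[i]
    if (i == 1) pos <- pos + nf
  }
  out
}

linker_bases <- function(len, fill) {
  src <- paste0(if (nzchar(fill)) fill else "", LINKER_PLACEHOLDER, LINKER_PLACEHOLDER)
  substr(src, 1, len)
}

## independent per-base substitutions; a mutated base always changes
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) {
    return(seqs)
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    orig <- flat[hit]
    repl <- vapply(orig, function(b) sample(setdiff(DNA_BASES, b), 1), "", USE.NAMES = FALSE)
    flat[hit] <- repl
  }
  grp <- rep(seq_along(seqs), lens)
  vapply(split(flat, grp), paste0, "", collapse = "", USE.NAMES = FALSE)
}

#' Simulate a tagged alignment stream with planted rates
#'
#' Generates records with known per-read mapping, multi-mapping and gene
#' assignment, drawing UMIs from a small pool so deduplication has real work
#' to do. The realized (drawn) quantities — not just the expected rates —
#' are returned so tests can assert exact equality.
#'
#' @param n_reads,n_genes,n_barcodes stream dimensions.
#' @param mapped_rate probability a read is mapped.
#' @param multimap_rate probability a mapped read is reported with more than
#'   one alignment (and is therefore discarded by [count_matrix()]).
#' @param unassigned_rate probability a mapped read lacks a gene tag.
#' @param umi_pool_size distinct UMIs available per read draw.
#' @param seed RNG seed.
#' @return List with `$alignments` (tibble) and `$truth`: realized
#'   `n_mapped`, `n_multimapped`, `n_contributing`, and `umi_counts`, the
#'   distinct-UMI tally per (gene, barcode) among contributing reads.
#' @export
simulate_tagged_alignments <- function(n_reads, n_genes, n_barcodes,
                                       mapped_rate = 0.9, multimap_rate = 0.1,
                                       unassigned_rate = 0.1,
                                       umi_pool_size = 8, seed = 1) {
  stopifnot(
    n_reads > 0, n_genes > 0, n_barcodes > 0,
    mapped_rate >= 0, mapped_rate <= 1, multimap_rate >= 0, multimap_rate <= 1
  )
  set.seed(seed)
  barcodes <- random_dna_distinct(n_barcodes, CANONICAL_BARCODE_LENGTH)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  umi_pool <- random_dna_distinct(umi_pool_size, 10)

  x <- tibble(
    read_id = sprintf("aln%06d", seq_len(n_reads)),
    barcode = sample(barcodes, n_reads, replace = TRUE),
    umi = sample(umi_pool, n_reads, replace = TRUE),
    mapped = stats::runif(n_reads) < mapped_rate
  )
  multi <- x$mapped & stats::runif(n_reads) < multimap_rate
  x$alignment_count <- ifelse(multi, sample(2:4, n_reads, replace = TRUE), 1L)
  assigned <- x$mapped & stats::runif(n_reads) >= unassigned_rate
  x$gene <- ifelse(assigned, sample(genes, n_reads, replace = TRUE), NA_character_)
  x$is_secondary <- FALSE

  contributing <- x$mapped & !multi & !is.na(x$gene)
  keep <- x[contributing, c("barcode", "gene", "umi")]
  keep <- keep[!duplicated(keep), , drop = FALSE]
  umi_counts <- keep |>
    count(.data$gene, .data$barcode, name = "n_umis") |>
    arrange(.data$gene, .data$barcode)

  list(
    alignments = x,
    barcodes = barcodes,
    truth = list(
      n_mapped = sum(x$mapped),
      n_multimapped = sum(multi),
      n_contributing = sum(contributing),
      umi_counts = umi_counts
    )
  )
}
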