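## UMI counting over tagged alignment records, and the sparse gene-barcode
## matrix (GBM) container with MatrixMarket I/O.

#' Construct a gene-barcode matrix
#'
#' A GBM is a sparse nonnegative integer matrix of deduplicated UMI counts,
#' genes in rows and 16 bp cell barcodes in columns.
#'
#' @param counts a matrix or `Matrix::sparseMatrix` (genes x barcodes).
#' @param genes,barcodes ordered labels; default to the dimnames.
#' @return A `gbm` object.
#' @export
new_gbm <- function(counts, genes = rownames(counts), barcodes = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(genes) || is.null(barcodes)) {
    stop_data("a GBM needs gene and barcode labels")
  }
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop_data(
      "label/dimension mismatch: %d genes x %d barcodes vs %d x %d counts",
      length(genes), length(barcodes), nrow(counts), ncol(counts)
    )
  }
  if (any(counts@x < 0)) stop_data("GBM counts must be nonnegative")
  dimnames(counts) <- list(genes, barcodes)
  structure(
    list(genes = as.character(genes), barcodes = as.character(barcodes), counts = counts),
    class = "gbm"
  )
}

#' @export
print.gbm <- function(x, ...) {
  cat(sprintf(
    "<gbm> %d genes x %d barcodes, %d nonzero entries, %d total UMIs\n",
    length(x$genes), length(x$barcodes), Matrix::nnzero(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.gbm <- function(x) dim(x$counts)

#' @export
as.matrix.gbm <- function(x, ...) as.matrix(x$counts)

#' Read tagged alignment records
#'
#' Accepts either a TSV with columns `read_id`, `barcode`, `umi`, `gene`,
#' `mapped`, `alignment_count` (and optionally `is_secondary`), or a SAM/BAM
#' file whose records carry the conventional tags (CB = cell barcode,
#' UB = UMI, GX = gene, NH = number of hits). SAM/BAM ingestion requires the
#' Rsamtools package.
#'
#' @param path `.tsv`(`.gz`), `.sam` or `.bam` file.
#' @param tags named list overriding the barcode/umi/gene tag names.
#' @return Tibble of tagged alignments.
#' @export
read_tagged_alignments <- function(path,
                                   tags = list(barcode = "CB", umi = "UB", gene = "GX")) {
  if (!file.exists(path)) stop_data("alignment file not found: %s", path)
  if (grepl("\\.(tsv|txt)(\\.gz)?$", path)) {
    x <- readr::read_tsv(path,
      col_types = readr::cols(
        read_id = readr::col_character(), barcode = readr::col_character(),
        umi = readr::col_character(), gene = readr::col_character(),
        mapped = readr::col_logical(), alignment_count = readr::col_integer(),
        .default = readr::col_guess()
      )
    )
    return(validate_tagged_alignments(x))
  }
  if (!grepl("\\.(sam|bam)$", path)) {
    stop_data("unsupported alignment format: %s (use .tsv, .sam or .bam)", path)
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_data("SAM/BAM ingestion requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    )
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    tag = c(tags$barcode, tags$umi, tags$gene, "NH")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  nh <- rec$tag[["NH"]]
  x <- tibble(
    read_id = rec$qname,
    barcode = rec$tag[[tags$barcode]] %||% rep(NA_character_, length(rec$qname)),
    umi = rec$tag[[tags$umi]] %||% rep(NA_character_, length(rec$qname)),
    gene = rec$tag[[tags$gene]] %||% rep(NA_character_, length(rec$qname)),
    mapped = bitwAnd(rec$flag, 4L) == 0L,
    alignment_count = as.integer(nh %||% rep(1L, length(rec$qname))),
    is_secondary = bitwAnd(rec$flag, 256L) > 0L
  )
  validate_tagged_alignments(x)
}

validate_tagged_alignments <- function(x) {
  x <- as_tibble(x)
  required <- c("read_id", "barcode", "umi", "gene", "mapped", "alignment_count")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_data("tagged alignments lack column(s): %s", paste(missing, collapse = ", "))
  }
  if (!"is_secondary" %in% names(x)) x$is_secondary <- FALSE
  x$alignment_count[is.na(x$alignment_count)] <- 1L
  x$gene[!is.na(x$gene) & x$gene == ""] <- NA_character_
  if (any(x$mapped & x$alignment_count < 1, na.rm = TRUE)) {
    stop_data("mapped records must have alignment_count >= 1")
  }
  x
}

#' Count distinct UMIs per gene and barcode
#'
#' Implements the counting rule: a record contributes if and only if it is
#' mapped, primary, reported with exactly one alignment (all multi-mapping
#' reads are discarded), carries a gene assignment, and its barcode is on
#' the (recoded, 16 bp) whitelist. The count for a (gene, barcode) pair is
#' the number of distinct UMIs among its contributing records — exact-UMI
#' deduplication, no error collapsing. Malformed records (missing barcode or
#' UMI) are skipped and logged.
#'
#' @param alignments tibble of tagged alignments
#'   (see [read_tagged_alignments()]).
#' @param whitelist an `sc_whitelist` of 16 bp barcodes, or a character
#'   vector; `NULL` admits every barcode.
#' @return A `gbm`; barcodes never observed in the data are omitted from the
#'   columns.
#' @export
count_matrix <- function(alignments, whitelist = NULL) {
  x <- validate_tagged_alignments(alignments)
  malformed <- is.na(x$barcode) | x$barcode == "" | is.na(x$umi) | x$umi == ""
  if (any(malformed)) {
    inform(sprintf("count: skipping %d malformed record(s)", sum(malformed)))
    x <- x[!malformed, , drop = FALSE]
  }
  wl <- if (inherits(whitelist, "sc_whitelist")) whitelist$barcodes else whitelist
  kept <- x |>
    filter(
      .data$mapped, !.data$is_secondary, .data$alignment_count == 1L,
      !is.na(.data$gene)
    )
  if (!is.null(wl)) kept <- filter(kept, .data$barcode %in% wl)
  triples <- distinct(kept, .data$barcode, .data$gene, .data$umi)
  genes <- sort(unique(triples$gene), method = "radix")
  barcodes <- sort(unique(triples$barcode), method = "radix")
  counts <- Matrix::sparseMatrix(
    i = match(triples$gene, genes),
    j = match(triples$barcode, barcodes),
    x = 1L,
    dims = c(length(genes), length(barcodes)),
    dimnames = list(genes, barcodes)
  )
  new_gbm(counts)
}

#' Per-barcode and run-level summary statistics
#'
#' Tallies, for each barcode: total primary records, mapped records,
#' assigned records (mapped, unique-alignment, gene-tagged) and distinct-UMI
#' counts. The run-level summary reports the overall mapping rate and — over
#' the supplied cell barcodes, when given — mean reads and mean UMIs per
#' cell. Cell calling is out of scope: "filtered cells" are whatever the
#' caller passes.
#'
#' @inheritParams count_matrix
#' @param cell_barcodes optional character vector of called cells.
#' @return A `barcode_summary` list with `$per_barcode` and `$global`
#'   tibbles.
#' @export
summarize_barcodes <- function(alignments, cell_barcodes = NULL) {
  x <- validate_tagged_alignments(alignments)
  x <- x[!(is.na(x$barcode) | x$barcode == ""), , drop = FALSE]
  prim <- filter(x, !.data$is_secondary)
  per <- prim |>
    group_by(.data$barcode) |>
    summarise(
      reads_total = n(),
      reads_mapped = sum(.data$mapped),
      reads_assigned = sum(.data$mapped & .data$alignment_count == 1L & !is.na(.data$gene)),
      umi_count = n_distinct(.data$gene[.data$mapped & .data$alignment_count == 1L &
        !is.na(.data$gene)], .data$umi[.data$mapped & .data$alignment_count == 1L &
        !is.na(.data$gene)]),
      .groups = "drop"
    ) |>
    arrange(.data$barcode)
  global <- tibble(
    reads_total = sum(per$reads_total),
    mapping_rate = if (nrow(prim) == 0) NA_real_ else sum(prim$mapped) / nrow(prim),
    n_barcodes = nrow(per),
    mean_reads_per_cell = if (is.null(cell_barcodes)) NA_real_ else {
      mean(per$reads_total[per$barcode %in% cell_barcodes])
    },
    mean_umis_per_cell = if (is.null(cell_barcodes)) NA_real_ else {
      mean(per$umi_count[per$barcode %in% cell_barcodes])
    }
  )
  structure(list(per_barcode = per, global = global), class = "barcode_summary")
}

#' @export
print.barcode_summary <- function(x, ...) {
  cat(sprintf(
    "<barcode_summary> %d barcodes, %d reads, mapping rate %.3f\n",
    x$global$n_barcodes, x$global$reads_total, x$global$mapping_rate
  ))
  invisible(x)
}

#' Write / read a GBM as MatrixMarket triplets with label files
#'
#' The exchange layout is a directory holding `matrix.mtx`, `features.tsv`
#' (gene ids) and `barcodes.tsv`, optionally gzip-compressed — the layout
#' downstream single-cell tools expect.
#'
#' @param gbm a `gbm`.
#' @param out_dir directory to create/fill.
#' @param compress write `.gz` variants.
#' @return `write_gbm()` returns `out_dir` invisibly; `read_gbm()` returns a
#'   `gbm`.
#' @export
write_gbm <- function(gbm, out_dir, compress = FALSE) {
  stopifnot(inherits(gbm, "gbm"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(out_dir, "matrix.mtx")
  Matrix::writeMM(gbm$counts, mtx)
  if (compress) {
    for (f in c(mtx)) {
      con <- gzfile(paste0(f, ".gz"), "wb")
      writeLines(readLines(f), con)
      close(con)
      unlink(f)
    }
    readr::write_lines(gbm$genes, file.path(out_dir, "features.tsv.gz"))
    readr::write_lines(gbm$barcodes, file.path(out_dir, "barcodes.tsv.gz"))
  } else {
    readr::write_lines(gbm$genes, file.path(out_dir, "features.tsv"))
    readr::write_lines(gbm$barcodes, file.path(out_dir, "barcodes.tsv"))
  }
  invisible(out_dir)
}

#' @rdname write_gbm
#' @param dir directory holding `matrix.mtx[.gz]`, `features.tsv[.gz]`,
#'   `barcodes.tsv[.gz]`.
#' @export
read_gbm <- function(dir) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) {
        return(f)
      }
    }
    stop_data("missing %s[.gz] in %s", base, dir)
  }
  mtx <- pick("matrix.mtx")
  if (grepl("\\.gz$", mtx)) {
    tmp <- tempfile(fileext = ".mtx")
    writeLines(readLines(mtx), tmp)
    mtx <- tmp
  }
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readr::read_lines(pick("features.tsv"))
  barcodes <- readr::read_lines(pick("barcodes.tsv"))
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    stop_data(
      "label/matrix dimension mismatch in %s: %d genes, %d barcodes, %d x %d matrix",
      dir, length(genes), length(barcodes), nrow(counts), ncol(counts)
    )
  }
  new_gbm(counts, genes = genes, barcodes = barcodes)
}
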