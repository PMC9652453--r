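## Comparison of two gene-barcode matrices: harmonization to matching label
## sets, the non-both-zero scatter point set, Pearson correlation, and the
## Adjusted Rand Index between two clusterings of the shared barcodes.

#' Harmonize two GBMs to matching barcode and gene sets
#'
#' Only barcodes found in both matrices are kept (sorted); genes found in
#' only one matrix are added to the other with zero counts, so both end up
#' on the sorted union of genes. Counts are otherwise unchanged. Harmonizing
#' an already harmonized pair is a no-op.
#'
#' @param gbm_a,gbm_b `gbm` objects.
#' @return A `harmonized_gbm_pair` (list with `$a`, `$b`).
#' @export
harmonize <- function(gbm_a, gbm_b) {
  stopifnot(inherits(gbm_a, "gbm"), inherits(gbm_b, "gbm"))
  barcodes <- sort(intersect(gbm_a$barcodes, gbm_b$barcodes), method = "radix")
  if (length(barcodes) == 0) {
    stop_data(
      "no barcodes in common (%d vs %d barcodes); GBMs cannot be compared",
      length(gbm_a$barcodes), length(gbm_b$barcodes)
    )
  }
  genes <- sort(union(gbm_a$genes, gbm_b$genes), method = "radix")
  reindex <- function(g) {
    s <- Matrix::summary(g$counts)
    j_new <- match(g$barcodes[s$j], barcodes)
    keep <- !is.na(j_new)
    counts <- Matrix::sparseMatrix(
      i = match(g$genes[s$i], genes)[keep],
      j = j_new[keep], x = s$x[keep],
      dims = c(length(genes), length(barcodes)),
      dimnames = list(genes, barcodes)
    )
    new_gbm(counts)
  }
  structure(list(a = reindex(gbm_a), b = reindex(gbm_b)),
    class = "harmonized_gbm_pair"
  )
}

#' @export
print.harmonized_gbm_pair <- function(x, ...) {
  cat(sprintf(
    "<harmonized_gbm_pair> %d genes x %d barcodes\n",
    length(x$a$genes), length(x$a$barcodes)
  ))
  invisible(x)
}

#' Build the scatter point set of a harmonized pair
#'
#' One point per (gene, barcode) combination whose UMI counts are not both
#' zero: with 10 cells and 100 genes, up to 1000 points enter the
#' correlation.
#'
#' @param pair a `harmonized_gbm_pair`.
#' @return Tibble with `gene`, `barcode`, `count_a`, `count_b`.
#' @export
scatter_points <- function(pair) {
  stopifnot(inherits(pair, "harmonized_gbm_pair"))
  sa <- as_tibble(as.data.frame(Matrix::summary(pair$a$counts)))
  sb <- as_tibble(as.data.frame(Matrix::summary(pair$b$counts)))
  pts <- full_join(sa, sb, by = c("i", "j"), suffix = c("_a", "_b")) |>
    mutate(
      count_a = replace_na(.data$x_a, 0),
      count_b = replace_na(.data$x_b, 0)
    ) |>
    filter(.data$count_a > 0 | .data$count_b > 0) |>
    arrange(.data$j, .data$i) |>
    transmute(
      gene = pair$a$genes[.data$i],
      barcode = pair$a$barcodes[.data$j],
      count_a = .data$count_a, count_b = .data$count_b
    )
  pts
}

#' Pearson correlation of a scatter point set
#'
#' Standard product-moment correlation of `(count_a, count_b)` pairs. With
#' fewer than two points, or zero variance on either axis, the correlation
#' is undefined and `NA` is returned with a warning — never silently 0.
#'
#' @param points tibble from [scatter_points()].
#' @return A correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_correlation <- function(points) {
  stopifnot(all(c("count_a", "count_b") %in% names(points)))
  if (nrow(points) < 2) {
    warn("Pearson correlation undefined: fewer than 2 points")
    return(NA_real_)
  }
  if (stats::sd(points$count_a) == 0 || stats::sd(points$count_b) == 0) {
    warn("Pearson correlation undefined: zero variance on one axis")
    return(NA_real_)
  }
  cor(points$count_a, points$count_b, method = "pearson")
}

#' Adjusted Rand Index between two clusterings of the same items
#'
#' Chance-corrected pair-counting agreement in the Hubert-Arabie form,
#' computed from the contingency table of the two label vectors. Invariant
#' under permutation of cluster ids; 1 for identical partitions; at most 1
#' always. Both clusterings must label exactly the same items.
#'
#' @param clustering_a,clustering_b named vectors (names = barcodes, values
#'   = cluster ids), or two-column data frames (`barcode`, `cluster`).
#' @return The ARI (a number \eqn{\le 1}).
#' @export
adjusted_rand_index <- function(clustering_a, clustering_b) {
  a <- as_cluster_vector(clustering_a)
  b <- as_cluster_vector(clustering_b)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    stop_data(
      "clusterings label different item sets (%d vs %d items, %d shared)",
      length(a), length(b), length(intersect(names(a), names(b)))
    )
  }
  b <- b[names(a)]
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    ## degenerate: both partitions all-singletons or both one cluster
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

as_cluster_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("barcode", "cluster") %in% names(x)))
    x <- setNames(as.character(x$cluster), x$barcode)
  }
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop_data("a clustering must assign exactly one cluster per barcode")
  }
  setNames(as.character(x), names(x))
}

#' Read a clustering from a two-column TSV
#'
#' @param path TSV with columns `barcode` and `cluster` (header optional —
#'   detected from the first line).
#' @return Tibble with `barcode`, `cluster`.
#' @export
read_clustering <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  x <- readr::read_tsv(path,
    col_names = if (has_header) TRUE else c("barcode", "cluster"),
    skip = 0, col_types = readr::cols(.default = readr::col_character())
  )
  names(x)[1:2] <- c("barcode", "cluster")
  x
}

#' Compare two gene-barcode matrices end to end
#'
#' Harmonizes the pair, builds the scatter point set, computes the Pearson
#' correlation on raw counts, and — when clusterings are supplied — the
#' Adjusted Rand Index over the shared barcodes.
#'
#' @inheritParams harmonize
#' @param clusters_a,clusters_b optional clusterings (named vector or
#'   `barcode`/`cluster` data frame); they are restricted to the harmonized
#'   barcodes before the ARI.
#' @return A `gbm_comparison` object with [tidy()] (the scatter points),
#'   [glance()] (one-row metric summary) and [autoplot()] methods.
#' @examples
#' m <- Matrix::rsparsematrix(20, 5, 0.5, rand.x = function(n) rpois(n, 3))
#' m <- abs(m)
#' dimnames(m) <- list(paste0("g", 1:20), paste0("bc", 1:5))
#' g <- new_gbm(m)
#' compare_gbms(g, g)
#' @export
compare_gbms <- function(gbm_a, gbm_b, clusters_a = NULL, clusters_b = NULL) {
  pair <- harmonize(gbm_a, gbm_b)
  points <- scatter_points(pair)
  r <- pearson_correlation(points)
  ari <- NA_real_
  if (!is.null(clusters_a) && !is.null(clusters_b)) {
    ca <- as_cluster_vector(clusters_a)
    cb <- as_cluster_vector(clusters_b)
    shared <- pair$a$barcodes
    missing_a <- setdiff(shared, names(ca))
    missing_b <- setdiff(shared, names(cb))
    if (length(missing_a) || length(missing_b)) {
      stop_data(
        "clusterings do not cover all %d harmonized barcodes (missing: %d in a, %d in b)",
        length(shared), length(missing_a), length(missing_b)
      )
    }
    ari <- adjusted_rand_index(ca[shared], cb[shared])
  }
  structure(
    list(
      pair = pair, points = points, pearson = r, ari = ari,
      n_genes = length(pair$a$genes), n_barcodes = length(pair$a$barcodes)
    ),
    class = "gbm_comparison"
  )
}

#' @export
print.gbm_comparison <- function(x, ...) {
  cat(sprintf(
    "<gbm_comparison> %d genes x %d shared barcodes, %d scatter points\n  Pearson r = %s%s\n",
    x$n_genes, x$n_barcodes, nrow(x$points),
    format(x$pearson, digits = 4),
    if (is.na(x$ari)) "" else sprintf("   ARI = %s", format(x$ari, digits = 4))
  ))
  invisible(x)
}

#' @rdname compare_gbms
#' @param x a `gbm_comparison`.
#' @param ... unused.
#' @method tidy gbm_comparison
#' @export
tidy.gbm_comparison <- function(x, ...) {
  x$points
}

#' @rdname compare_gbms
#' @method glance gbm_comparison
#' @export
glance.gbm_comparison <- function(x, ...) {
  tibble(
    n_genes = x$n_genes, n_barcodes = x$n_barcodes,
    n_points = nrow(x$points), pearson = x$pearson, ari = x$ari
  )
}

#' @rdname compare_gbms
#' @param object a `gbm_comparison`.
#' @method autoplot gbm_comparison
#' @export
autoplot.gbm_comparison <- function(object, ...) {
  pts <- object$points |>
    count(.data$count_a, .data$count_b, name = "overlap")
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$count_a, y = .data$count_b,
    colour = .data$overlap
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(trans = "log10") +
    ggplot2::labs(
      x = "UMI count (matrix A)", y = "UMI count (matrix B)",
      colour = "overlapping\npoints",
      title = sprintf("Pearson r = %.3f", object$pearson)
    ) +
    ggplot2::theme_minimal()
}
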