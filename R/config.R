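## Chemistry configuration: the declarative description of where barcode, UMI,
## linker and cDNA bases live across the reads of one technology.

SEGMENT_SOURCES <- c("R1", "R2", "I1", "I2")
SEGMENT_ROLES <- c("barcode", "umi", "linker")
WHITELIST_SOURCES <- c("file", "permutations", "none")

#' Construct a chemistry configuration
#'
#' A `tech_config` fully describes one single-cell chemistry: the segment
#' layout of cell-barcode, UMI and linker bases across R1/R2 (and I1/I2 index
#' reads), the total barcode and UMI lengths, the role-inversion flags, and
#' how its barcode whitelist is obtained. Most users get one from
#' [get_config()] or [make_custom_config()] rather than calling this directly.
#'
#' @param name technology token, e.g. `"dropseq"`.
#' @param display_name human-readable name.
#' @param barcode_total_length total cell-barcode length in bp (after any
#'   linker fill), excluding index-file barcodes.
#' @param umi_length UMI length in bp, or `NA` for chemistries without a UMI.
#' @param umi_before_barcode flag: the UMI precedes the barcode on its read.
#' @param elements_in_r2 flag: barcode/UMI live in R2 and the cDNA in R1.
#' @param dual_index flag: I1/I2 index reads carry additional cell-barcode
#'   information and must be supplied.
#' @param linker_fill bases inserted after the first barcode segment to fill a
#'   multi-segment barcode to `barcode_total_length` (empty string for none).
#' @param whitelist_source one of `"file"`, `"permutations"`, `"none"`.
#' @param segments tibble with columns `source` (R1/R2/I1/I2), `start`
#'   (0-based), `length` (bp), `role` (barcode/umi/linker), in assembly order.
#' @return A validated `tech_config` object.
#' @seealso [get_config()], [make_custom_config()], [read_technology_config()]
#' @export
tech_config <- function(name, display_name = name, barcode_total_length,
                        umi_length = NA, umi_before_barcode = FALSE,
                        elements_in_r2 = FALSE, dual_index = FALSE,
                        linker_fill = "", whitelist_source = "permutations",
                        segments) {
  segments <- tibble::as_tibble(segments)
  segments$source <- as.character(segments$source)
  segments$start <- as.integer(segments$start)
  segments$length <- as.integer(segments$length)
  segments$role <- as.character(segments$role)
  cfg <- structure(
    list(
      name = as.character(name),
      display_name = as.character(display_name),
      barcode_total_length = as.integer(barcode_total_length),
      umi_length = if (is.na(umi_length)) NA_integer_ else as.integer(umi_length),
      umi_before_barcode = isTRUE(umi_before_barcode),
      elements_in_r2 = isTRUE(elements_in_r2),
      dual_index = isTRUE(dual_index),
      linker_fill = toupper(as.character(linker_fill %||% "")),
      whitelist_source = match.arg(whitelist_source, WHITELIST_SOURCES),
      segments = segments
    ),
    class = "tech_config"
  )
  validate_tech_config(cfg)
}

validate_tech_config <- function(cfg) {
  seg <- cfg$segments
  if (!nzchar(cfg$name) || grepl("\\s", cfg$name)) {
    stop_data("config name must be a non-empty token (got '%s')", cfg$name)
  }
  if (is.na(cfg$barcode_total_length) || cfg$barcode_total_length < 1) {
    stop_data("barcode_total_length must be >= 1 (got %s)", cfg$barcode_total_length)
  }
  if (!is.na(cfg$umi_length) && cfg$umi_length < 1) {
    stop_data("umi_length must be >= 1 or NA (got %d)", cfg$umi_length)
  }
  if (nrow(seg) == 0) stop_data("config '%s' declares no segments", cfg$name)
  if (!all(seg$source %in% SEGMENT_SOURCES)) {
    stop_data("segment source must be one of %s", paste(SEGMENT_SOURCES, collapse = ", "))
  }
  if (!all(seg$role %in% SEGMENT_ROLES)) {
    stop_data("segment role must be one of %s", paste(SEGMENT_ROLES, collapse = ", "))
  }
  if (any(seg$length < 1) || any(seg$start < 0)) {
    stop_data("segments need length >= 1 and start >= 0")
  }
  if (nzchar(cfg$linker_fill) &&
    !all(strsplit(cfg$linker_fill, "")[[1]] %in% DNA_BASES)) {
    stop_data("linker_fill must contain only A/C/G/T")
  }
  ## no two segments on the same source read may overlap
  for (src in unique(seg$source)) {
    s <- seg[seg$source == src, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < (s$start + s$length)[-nrow(s)])) {
      stop_data("config '%s': overlapping segments on %s", cfg$name, src)
    }
  }
  bc_sum <- sum(seg$length[seg$role == "barcode"]) + nchar(cfg$linker_fill)
  if (bc_sum != cfg$barcode_total_length) {
    stop_data(
      "config '%s': barcode segments (+ linker fill) sum to %d, declared total is %d",
      cfg$name, bc_sum, cfg$barcode_total_length
    )
  }
  umi_sum <- sum(seg$length[seg$role == "umi"])
  if (is.na(cfg$umi_length) && umi_sum > 0) {
    stop_data("config '%s' declares UMI segments but umi_length is absent", cfg$name)
  }
  if (!is.na(cfg$umi_length) && umi_sum != cfg$umi_length) {
    stop_data(
      "config '%s': UMI segments sum to %d, declared umi_length is %d",
      cfg$name, umi_sum, cfg$umi_length
    )
  }
  cfg
}

#' @export
print.tech_config <- function(x, ...) {
  umi <- if (is.na(x$umi_length)) "none" else paste0(x$umi_length, " bp")
  cat(sprintf(
    "<tech_config> %s (%s)\n  barcode: %d bp   UMI: %s\n", x$name,
    x$display_name, x$barcode_total_length, umi
  ))
  flags <- c(
    if (x$umi_before_barcode) "UMI-before-barcode",
    if (x$elements_in_r2) "elements-in-R2",
    if (x$dual_index) "dual-index",
    if (nzchar(x$linker_fill)) paste0("linker-fill:", x$linker_fill)
  )
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  cat(sprintf("  whitelist: %s\n", x$whitelist_source))
  seg <- x$segments
  cat(sprintf(
    "  segments: %s\n",
    paste(sprintf("%s[%d+%d]:%s", seg$source, seg$start, seg$length, seg$role),
      collapse = " "
    )
  ))
  invisible(x)
}

#' Which read carries the cDNA for a chemistry
#' @keywords internal
cdna_source <- function(config) {
  if (config$elements_in_r2) "R1" else "R2"
}

#' Build a custom chemistry from barcode and UMI lengths
#'
#' Synthesizes a configuration for a technology that is not among the bundled
#' presets. When `segments` is omitted, a single contiguous barcode block
#' followed by a UMI block is assumed on R1 (or on R2 with
#' `elements_in_r2 = TRUE`; UMI first with `umi_before_barcode = TRUE`).
#'
#' @inheritParams tech_config
#' @param segments optional explicit segment table; if given it must satisfy
#'   the same invariants as a preset (no overlaps, lengths summing to the
#'   declared totals).
#' @return A validated `tech_config`.
#' @examples
#' make_custom_config(20, 9)
#' @export
make_custom_config <- function(barcode_total_length, umi_length = NA,
                               umi_before_barcode = FALSE,
                               elements_in_r2 = FALSE, dual_index = FALSE,
                               linker_fill = "", segments = NULL,
                               name = "custom", display_name = "Custom chemistry",
                               whitelist_source = "permutations") {
  if (is.null(segments)) {
    src <- if (elements_in_r2) "R2" else "R1"
    bc_len <- as.integer(barcode_total_length) - nchar(linker_fill)
    if (is.na(bc_len) || bc_len < 1) {
      stop_data("barcode_total_length must be >= 1 (got %s)", barcode_total_length)
    }
    if (!is.na(umi_length) && umi_length < 1) {
      stop_data("umi_length must be >= 1 or NA (got %s)", umi_length)
    }
    if (umi_before_barcode && !is.na(umi_length)) {
      segments <- tibble(
        source = src, start = c(0L, umi_length),
        length = c(umi_length, bc_len), role = c("umi", "barcode")
      )
    } else if (is.na(umi_length)) {
      segments <- tibble(source = src, start = 0L, length = bc_len, role = "barcode")
    } else {
      segments <- tibble(
        source = src, start = c(0L, bc_len),
        length = c(bc_len, umi_length), role = c("barcode", "umi")
      )
    }
  }
  tech_config(
    name = name, display_name = display_name,
    barcode_total_length = barcode_total_length, umi_length = umi_length,
    umi_before_barcode = umi_before_barcode, elements_in_r2 = elements_in_r2,
    dual_index = dual_index, linker_fill = linker_fill,
    whitelist_source = whitelist_source, segments = segments
  )
}

#' Read / write a chemistry configuration file
#'
#' The on-disk format is plain key-value text: one `key = value` per line,
#' `#` comments, and one `segment = source,start,length,role` line per segment
#' in assembly order. The bundled presets under
#' `system.file("extdata", "chemistries", package = "scunify")` use the same
#' format, so any preset file is a valid template for a custom chemistry.
#'
#' @param path file to read or write.
#' @return `read_technology_config()` returns a `tech_config`;
#'   `write_technology_config()` returns `path` invisibly.
#' @export
read_technology_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: %s", path)
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop_data("malformed config line: '%s'", lines[bad][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))

  get1 <- function(key, default = NULL) {
    v <- vals[keys == key]
    if (length(v) == 0) {
      return(default)
    }
    if (length(v) > 1) stop_data("duplicate key '%s' in %s", key, path)
    v
  }
  seg_lines <- vals[keys == "segment"]
  if (length(seg_lines) == 0) stop_data("no segment lines in %s", path)
  parts <- strsplit(seg_lines, ",", fixed = TRUE)
  if (any(lengths(parts) != 4)) {
    stop_data("segment lines must be 'source,start,length,role' in %s", path)
  }
  segments <- tibble(
    source = trimws(vapply(parts, `[[`, "", 1)),
    start = as.integer(vapply(parts, `[[`, "", 2)),
    length = as.integer(vapply(parts, `[[`, "", 3)),
    role = trimws(vapply(parts, `[[`, "", 4))
  )
  umi_raw <- get1("umi_length", "none")
  tech_config(
    name = get1("name") %||% stop_data("missing 'name' in %s", path),
    display_name = get1("display_name", get1("name")),
    barcode_total_length = as.integer(get1("barcode_total_length") %||%
      stop_data("missing 'barcode_total_length' in %s", path)),
    umi_length = if (umi_raw %in% c("none", "NA", "")) NA else as.integer(umi_raw),
    umi_before_barcode = tolower(get1("umi_before_barcode", "false")) == "true",
    elements_in_r2 = tolower(get1("elements_in_r2", "false")) == "true",
    dual_index = tolower(get1("dual_index", "false")) == "true",
    linker_fill = get1("linker_fill", ""),
    whitelist_source = get1("whitelist_source", "permutations"),
    segments = segments
  )
}

#' @rdname read_technology_config
#' @param config a `tech_config` to serialize.
#' @export
write_technology_config <- function(config, path) {
  stopifnot(inherits(config, "tech_config"))
  seg <- config$segments
  lines <- c(
    sprintf("# %s", config$display_name),
    sprintf("name = %s", config$name),
    sprintf("display_name = %s", config$display_name),
    sprintf("barcode_total_length = %d", config$barcode_total_length),
    sprintf("umi_length = %s", if (is.na(config$umi_length)) "none" else config$umi_length),
    sprintf("umi_before_barcode = %s", tolower(config$umi_before_barcode)),
    sprintf("elements_in_r2 = %s", tolower(config$elements_in_r2)),
    sprintf("dual_index = %s", tolower(config$dual_index)),
    sprintf("linker_fill = %s", config$linker_fill),
    sprintf("whitelist_source = %s", config$whitelist_source),
    sprintf("segment = %s,%d,%d,%s", seg$source, seg$start, seg$length, seg$role)
  )
  readr::write_lines(lines, path)
  invisible(path)
}
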