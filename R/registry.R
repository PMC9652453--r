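## Registry of bundled chemistry presets. Presets are shipped as plain-text
## config files under inst/extdata/chemistries and parsed once per session.

the_registry <- new.env(parent = emptyenv())

registry_dir <- function() {
  system.file("extdata", "chemistries", package = "scunify", mustWork = TRUE)
}

load_registry <- function() {
  if (!is.null(the_registry$configs)) {
    return(the_registry$configs)
  }
  files <- list.files(registry_dir(), pattern = "\\.cfg$", full.names = TRUE)
  configs <- lapply(files, read_technology_config)
  names(configs) <- vapply(configs, `[[`, "", "name")
  if (anyDuplicated(names(configs))) {
    stop_data(
      "duplicate technology names in registry: %s",
      paste(unique(names(configs)[duplicated(names(configs))]), collapse = ", ")
    )
  }
  the_registry$configs <- configs[order(names(configs), method = "radix")]
  the_registry$configs
}

#' List the registered technology tokens
#'
#' @return Character vector of all bundled chemistry tokens in lexicographic
#'   order (one per preset).
#' @examples
#' length(list_technologies())
#' @export
list_technologies <- function() {
  names(load_registry())
}

#' Retrieve a bundled chemistry preset
#'
#' Looks a technology up by its token (case-insensitive). The alias `"10x"`
#' is accepted for the Chromium chemistries: it resolves to `10x-v3` when
#' `r1_length` indicates a 16+12 bp R1 (28 bp or longer), and to `10x-v2`
#' (16+10) otherwise; explicit version tokens always win.
#'
#' @param name technology token, e.g. `"dropseq"`, `"celseq2"`, `"10x"`.
#' @param r1_length optional observed R1 length in bp, used only to resolve
#'   the `"10x"` alias.
#' @return An immutable `tech_config`.
#' @examples
#' get_config("dropseq")
#' @export
get_config <- function(name, r1_length = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  token <- tolower(trimws(name))
  reg <- load_registry()
  if (token == "10x") {
    token <- if (!is.null(r1_length) && r1_length >= 28) "10x-v3" else "10x-v2"
  }
  if (!token %in% names(reg)) {
    d <- adist(token, names(reg), partial = FALSE)
    nearest <- names(reg)[order(d)][1:3]
    stop_data(
      "unknown technology '%s'; nearest registered names: %s",
      name, paste(nearest, collapse = ", ")
    )
  }
  reg[[token]]
}

#' Resolve a technology from either a token or a custom config file
#'
#' Exactly one of `technology` and `config_file` must be given; a run never
#' mixes chemistries.
#' @keywords internal
resolve_config <- function(technology = NULL, config_file = NULL,
                           r1_length = NULL) {
  if (is.null(technology) == is.null(config_file)) {
    stop_usage("exactly one of a technology token or a custom config file is required")
  }
  if (!is.null(technology)) {
    get_config(technology, r1_length = r1_length)
  } else {
    read_technology_config(config_file)
  }
}
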