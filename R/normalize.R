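#' Normalize microbe names
#'
#' Canonicalizes free-text microbe labels so that names coming from
#' different sources can be matched by exact string equality: underscores
#' become spaces, runs of whitespace collapse to a single space, leading
#' and trailing whitespace is stripped, and the result is lowercased.
#' The mapping is deterministic and idempotent; no taxonomy-aware synonym
#' resolution is attempted.
#'
#' @param raw Character vector of microbe labels.
#'
#' @return Character vector of normalized names, same length as `raw`.
#'
#' @examples
#' normalize_name(c(" Prevotella  copri ", "Bacteroides_fragilis"))
#'
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) {
    stop("microbe names must be given as a character vector", call. = FALSE)
  }
  x <- chartr("_", " ", raw)
  x <- gsub("[[:space:]]+", " ", x)
  x <- tolower(trimws(x))
  bad <- is.na(x) | !nzchar(x)
  if (any(bad)) {
    stop(sprintf("invalid microbe name at position %s: empty or missing",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read a plain-text list of microbe names
#'
#' Reads a query or background list: one name per line, blank lines and
#' `#` comment lines ignored. Names are normalized and de-duplicated,
#' preserving first-occurrence order.
#'
#' @param path Path to the list file.
#' @return Character vector of distinct normalized microbe names.
#' @seealso [normalize_name()], [animal_diet_query()]
#' @export
read_microbe_list <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (!length(lines)) {
    stop("no microbe names found in ", path, call. = FALSE)
  }
  unique(normalize_name(lines))
}
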