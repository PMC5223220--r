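#' Construct a microbe-disease association table
#'
#' Stores curated association records, one per (disease, microbe,
#' direction) observation. Duplicate records are deliberately preserved:
#' the number of records for a pair is its association count, the evidence
#' weight used by the similarity method. Direction is +1 for a microbe
#' increased in the disease and -1 for a microbe decreased.
#'
#' @param records Data frame with character columns `disease`, `microbe`
#'   and an integer column `direction` taking values in `{+1, -1}`.
#'   Microbe names are normalized on construction; disease labels are
#'   whitespace-trimmed but otherwise kept as given.
#'
#' @return An object of class `association_table`: a list with `records`
#'   (the validated data frame), `diseases` (sorted distinct labels) and
#'   `microbes` (sorted distinct normalized names).
#' @seealso [read_associations()], [sets_from_associations()],
#'   [run_similarity()]
#' @export
association_table <- function(records) {
  required <- c("disease", "microbe", "direction")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    stop("`records` must be a data frame with columns disease, microbe, direction",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("association table is empty", call. = FALSE)
  }
  disease <- trimws(as.character(records$disease))
  if (any(is.na(disease) | !nzchar(disease))) {
    stop("missing disease label in association records", call. = FALSE)
  }
  microbe <- normalize_name(as.character(records$microbe))
  direction <- as.integer(records$direction)
  if (any(is.na(direction)) || !all(direction %in% c(-1L, 1L))) {
    stop("direction must be +1 or -1 for every record", call. = FALSE)
  }
  rec <- data.frame(disease = disease, microbe = microbe,
                    direction = direction, stringsAsFactors = FALSE)
  structure(
    list(records = rec,
         diseases = sort(unique(disease)),
         microbes = sort(unique(microbe))),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> %d records, %d diseases, %d microbes\n",
              nrow(x$records), length(x$diseases), length(x$microbes)))
  invisible(x)
}

direction_from_token <- function(token) {
  key <- tolower(trimws(token))
  out <- ifelse(key %in% c("increase", "increased", "+1", "1"), 1L,
         ifelse(key %in% c("decrease", "decreased", "-1"), -1L, NA_integer_))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("row %d: unknown direction token '%s' (expected increase/decrease or +1/-1)",
                 bad, token[bad]), call. = FALSE)
  }
  out
}

#' Read microbe-disease association records from a TSV file
#'
#' Expects a header line with columns `disease`, `microbe` and
#' `direction`; direction tokens are `increase`/`decrease`
#' (case-insensitive) or `+1`/`-1`. Duplicate rows are kept — they encode
#' the association count for the pair. `#` comment lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return An [association_table()].
#' @seealso [write_associations()]
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE, fileEncoding = "UTF-8")
  names(df) <- tolower(trimws(names(df)))
  required <- c("disease", "microbe", "direction")
  if (!all(required %in% names(df))) {
    stop("association file must have header columns disease, microbe, direction",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("association table is empty: ", path, call. = FALSE)
  }
  df$direction <- direction_from_token(df$direction)
  association_table(df[required])
}

#' Write microbe-disease association records to a TSV file
#'
#' Inverse of [read_associations()]; directions are written as
#' `increase`/`decrease`. Record order and multiplicity are preserved.
#'
#' @param table An [association_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_associations <- function(table, path) {
  stopifnot(inherits(table, "association_table"))
  rec <- table$records
  lines <- c("disease\tmicrobe\tdirection",
             sprintf("%s\t%s\t%s", rec$disease, rec$microbe,
                     ifelse(rec$direction > 0, "increase", "decrease")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
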