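#' Construct a microbe set
#'
#' A microbe set is a named group of microbes sharing one annotation:
#' either association with the same disease or colonization of the same
#' body position. Members are normalized and de-duplicated.
#'
#' @param name Non-empty set identifier.
#' @param category `"disease"` or `"position"`.
#' @param members Character vector of microbe names (any case/format;
#'   normalized on construction).
#'
#' @return An object of class `microbe_set`: a list with elements `name`,
#'   `category` and sorted distinct `members`.
#' @seealso [set_database()]
#' @export
microbe_set <- function(name, category = c("disease", "position"), members) {
  category <- match.arg(category)
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop("set name must be a single non-empty string", call. = FALSE)
  }
  members <- sort(unique(normalize_name(members)))
  structure(
    list(name = trimws(name), category = category, members = members),
    class = "microbe_set"
  )
}

#' @export
print.microbe_set <- function(x, ...) {
  cat(sprintf("<microbe_set> %s [%s], %d members\n",
              x$name, x$category, length(x$members)))
  invisible(x)
}

#' Construct a microbe set database
#'
#' Bundles a collection of [microbe_set()] objects together with their
#' universe: the exact union of all member names, which serves as the
#' default background for enrichment analysis. Sets may overlap; set
#' names must be unique.
#'
#' @param sets List of `microbe_set` objects (may be empty).
#'
#' @return An object of class `set_database`: a list with `sets` (a named
#'   list of `microbe_set`s) and `universe` (sorted distinct member names).
#' @export
set_database <- function(sets = list()) {
  if (!is.list(sets) || !all(vapply(sets, inherits, TRUE, "microbe_set"))) {
    stop("`sets` must be a list of microbe_set objects", call. = FALSE)
  }
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  universe <- sort(unique(unlist(lapply(sets, `[[`, "members"),
                                 use.names = FALSE)))
  if (is.null(universe)) universe <- character(0)
  structure(list(sets = sets, universe = universe), class = "set_database")
}

#' @export
print.set_database <- function(x, ...) {
  cats <- table(vapply(x$sets, `[[`, character(1), "category"))
  cat(sprintf("<set_database> %d sets (%s), universe of %d microbes\n",
              length(x$sets),
              paste(sprintf("%s: %d", names(cats), cats), collapse = ", "),
              length(x$universe)))
  invisible(x)
}

#' @export
length.set_database <- function(x) length(x$sets)

#' Read a microbe set database from a GMT-style file
#'
#' One set per line: `name<TAB>category<TAB>member1<TAB>member2...`, where
#' category is `disease` or `position` (the description slot of a standard
#' GMT file). Lines starting with `#` and blank lines are ignored. Member
#' names are normalized and de-duplicated per set.
#'
#' @param path Path to the tab-separated set file.
#' @return A [set_database()].
#' @seealso [write_set_database()]
#' @export
read_set_database <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^[[:space:]]*(#|$)", lines))
  sets <- vector("list", length(keep))
  seen <- character(0)
  for (k in seq_along(keep)) {
    i <- keep[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3L) {
      stop(sprintf("line %d: expected at least 3 tab-separated fields (name, category, members...)", i),
           call. = FALSE)
    }
    category <- tolower(fields[2L])
    if (!category %in% c("disease", "position")) {
      stop(sprintf("line %d: unknown category '%s' (expected 'disease' or 'position')",
                   i, fields[2L]), call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("line %d: set '%s' has no members", i, fields[1L]),
           call. = FALSE)
    }
    if (fields[1L] %in% seen) {
      stop(sprintf("line %d: duplicate set name '%s'", i, fields[1L]),
           call. = FALSE)
    }
    seen <- c(seen, fields[1L])
    sets[[k]] <- microbe_set(fields[1L], category, members)
  }
  set_database(sets)
}

#' Write a microbe set database to a GMT-style file
#'
#' Inverse of [read_set_database()]. Members are emitted in sorted order
#' (they are stored sorted), so output is deterministic regardless of how
#' the database was assembled.
#'
#' @param db A [set_database()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_set_database <- function(db, path) {
  stopifnot(inherits(db, "set_database"))
  lines <- vapply(db$sets, function(s) {
    paste(c(s$name, s$category, s$members), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unname(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Build disease sets from an association table
#'
#' For each distinct disease, forms the union of its associated microbes
#' across all records (study multiplicity and change direction are both
#' ignored here: a set is the union of associated microbes). Sets with
#' fewer than `min_size` distinct members are dropped; by default only
#' sets with at least two microbes are kept.
#'
#' @param table An [association_table()].
#' @param min_size Minimum number of distinct members for a set to be
#'   retained (default 2).
#' @return A [set_database()] of disease-category sets, ordered by
#'   disease name.
#' @export
sets_from_associations <- function(table, min_size = 2) {
  stopifnot(inherits(table, "association_table"))
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1) {
    stop("`min_size` must be a single integer >= 1", call. = FALSE)
  }
  members_by_disease <- split(table$records$microbe, table$records$disease)
  members_by_disease <- lapply(members_by_disease, function(m) sort(unique(m)))
  keep <- vapply(members_by_disease, length, 0L) >= min_size
  members_by_disease <- members_by_disease[keep]
  diseases <- sort(names(members_by_disease))
  sets <- lapply(diseases, function(d) {
    microbe_set(d, "disease", members_by_disease[[d]])
  })
  set_database(sets)
}
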