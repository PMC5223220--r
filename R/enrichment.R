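#' Exact hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= m)` that a random draw of `M` microbes
#' from a background universe of `N` microbes, of which `n` belong to the
#' tested set, would contain at least the observed `m` set members. The
#' tail is inclusive of the observed overlap and is computed exactly via
#' the hypergeometric distribution function (no normal approximation).
#'
#' @param N Background universe size.
#' @param n Number of set members present in the background.
#' @param M Query size (after intersection with the background).
#' @param m Observed overlap between query and set.
#'
#' @return The tail probability, in `(0, 1]`. Vectorized over its
#'   arguments with the usual recycling.
#'
#' @examples
#' hypergeom_pvalue(N = 10, n = 4, M = 5, m = 3)  # 66/252
#'
#' @export
hypergeom_pvalue <- function(N, n, M, m) {
  counts <- cbind(N = N, n = n, M = M, m = m)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("N, n, M, m must be non-negative integers", call. = FALSE)
  }
  bad <- counts[, "n"] > counts[, "N"] | counts[, "M"] > counts[, "N"] |
    counts[, "m"] > pmin(counts[, "n"], counts[, "M"])
  if (any(bad)) {
    stop("inconsistent counts: require m <= min(n, M) and n, M <= N",
         call. = FALSE)
  }
  p <- stats::phyper(counts[, "m"] - 1, counts[, "n"],
                     counts[, "N"] - counts[, "n"], counts[, "M"],
                     lower.tail = FALSE)
  unname(pmin(p, 1))
}

#' Fold enrichment (observed over expected overlap)
#'
#' Ratio of the observed overlap fraction `m/M` to the fraction `n/N`
#' expected if the query were drawn at random from the background:
#' `(m/M) / (n/N)`. A fold of 1 means no enrichment; 0 means no overlap.
#'
#' @inheritParams hypergeom_pvalue
#' @return Non-negative fold-enrichment ratio, vectorized.
#' @export
fold_enrichment <- function(N, n, M, m) {
  counts <- cbind(N = N, n = n, M = M, m = m)
  if (any(counts[, c("n", "M", "N")] == 0)) {
    stop("fold enrichment requires N, n and M all >= 1", call. = FALSE)
  }
  unname((counts[, "m"] / counts[, "M"]) / (counts[, "n"] / counts[, "N"]))
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric and lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Bonferroni family-wise correction
#'
#' Multiplies each p-value by the number of tests performed (the length of
#' the vector) and caps at 1; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bonferroni <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up procedure: with the p-values sorted ascending,
#' `q_(i) = p_(i) * k / i`, made monotone by a cumulative minimum from the
#' largest rank down and capped at 1; results are returned in the original
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Microbe set over-representation analysis
#'
#' Tests a query list of microbes for over-representation in every set of
#' a database. The background universe defaults to the union of all set
#' members; a user-supplied background is first intersected with that
#' union. Query names absent from the background are dropped with a
#' warning (and recorded in the result's `dropped` attribute) and do not
#' count towards the query size `M`. Each set is restricted to the
#' background before testing and skipped when fewer than `min_size`
#' members remain; Bonferroni and BH corrections are applied across
#' exactly the sets actually tested.
#'
#' @param query Character vector of microbe names (normalized and
#'   de-duplicated internally).
#' @param db A [set_database()].
#' @param background Optional character vector of microbe names defining
#'   the background universe; defaults to `db$universe`.
#' @param min_size Minimum background-restricted set size to test
#'   (default 2).
#' @param category Restrict testing to `"disease"` or `"position"` sets;
#'   `"all"` (default) tests both.
#'
#' @return A data frame of class `enrichment_result` with one row per
#'   tested set, sorted by p-value (ties broken by set name), and columns
#'   `set`, `category`, `n` (set size in background), `m` (overlap),
#'   `percent` (`m/M`), `fold`, `p_value`, `bonferroni`, `fdr`, `matched`
#'   and `unmatched` (semicolon-joined member names). Attributes
#'   `background_size`, `query_size` and `dropped` describe the effective
#'   analysis inputs.
#'
#' @examples
#' db <- set_database(list(
#'   microbe_set("cirrhosis", "disease", c("veillonella", "streptococcus")),
#'   microbe_set("gut", "position", c("roseburia", "prevotella", "veillonella"))
#' ))
#' run_enrichment(c("veillonella", "streptococcus"), db)
#'
#' @export
run_enrichment <- function(query, db, background = NULL, min_size = 2,
                           category = c("all", "disease", "position")) {
  category <- match.arg(category)
  if (!inherits(db, "set_database")) {
    stop("`db` must be a set_database", call. = FALSE)
  }
  if (!length(db$sets)) {
    stop("set database is empty", call. = FALSE)
  }
  if (!is.numeric(min_size) || length(min_size) != 1L || min_size < 1) {
    stop("`min_size` must be a single integer >= 1", call. = FALSE)
  }
  query <- unique(normalize_name(query))
  if (is.null(background)) {
    bg <- db$universe
  } else {
    bg <- intersect(unique(normalize_name(background)), db$universe)
    if (!length(bg)) {
      stop("background shares no names with the database universe",
           call. = FALSE)
    }
  }
  dropped <- setdiff(query, bg)
  query <- intersect(query, bg)
  if (!length(query)) {
    stop("query is empty after intersection with the background",
         call. = FALSE)
  }
  if (length(dropped)) {
    warning(sprintf("%d query name(s) not in the background were dropped: %s",
                    length(dropped), paste(dropped, collapse = "; ")),
            call. = FALSE)
  }

  N <- length(bg)
  M <- length(query)
  sets <- db$sets
  if (category != "all") {
    sets <- Filter(function(s) s$category == category, sets)
  }

  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, bg)
    n <- length(members)
    if (n < min_size) return(NULL)
    matched <- sort(intersect(members, query))
    m <- length(matched)
    data.frame(
      set = s$name,
      category = s$category,
      n = n,
      m = m,
      percent = m / M,
      fold = fold_enrichment(N, n, M, m),
      p_value = hypergeom_pvalue(N, n, M, m),
      matched = paste(matched, collapse = ";"),
      unmatched = paste(sort(setdiff(members, matched)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no set passes the minimum size filter; empty result",
            call. = FALSE)
    res <- data.frame(set = character(0), category = character(0),
                      n = integer(0), m = integer(0), percent = numeric(0),
                      fold = numeric(0), p_value = numeric(0),
                      bonferroni = numeric(0), fdr = numeric(0),
                      matched = character(0), unmatched = character(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    res$bonferroni <- bonferroni(res$p_value)
    res$fdr <- bh_fdr(res$p_value)
    res <- res[order(res$p_value, res$set),
               c("set", "category", "n", "m", "percent", "fold",
                 "p_value", "bonferroni", "fdr", "matched", "unmatched")]
    rownames(res) <- NULL
  }
  attr(res, "background_size") <- N
  attr(res, "query_size") <- M
  attr(res, "dropped") <- dropped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write an enrichment result table to TSV
#'
#' Columns follow the result data frame; p-values, Bonferroni and FDR are
#' formatted in scientific notation with 6 significant digits, percent and
#' fold with 4 decimals.
#'
#' @param res An `enrichment_result` from [run_enrichment()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(res, path) {
  stopifnot(inherits(res, "enrichment_result"))
  out <- data.frame(
    set = res$set,
    category = res$category,
    n = res$n,
    m = res$m,
    percent = sprintf("%.4f", res$percent),
    fold = sprintf("%.4f", res$fold),
    p_value = formatC(res$p_value, format = "e", digits = 5),
    bonferroni = formatC(res$bonferroni, format = "e", digits = 5),
    fdr = formatC(res$fdr, format = "e", digits = 5),
    matched = res$matched,
    unmatched = res$unmatched,
    stringsAsFactors = FALSE
  )
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(sprintf, c(list(paste(rep("%s", ncol(out)),
                                           collapse = "\t")), out)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
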