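#' Signed association count for a disease-microbe pair
#'
#' Sums the change directions (+1 increase, -1 decrease) over every record
#' for the pair, so concordant reports accumulate and contradictory ones
#' net out. When all records agree this equals the association count times
#' the common direction; a pair with no records scores 0.
#'
#' @param table An [association_table()].
#' @param disease Disease label (as stored in the table).
#' @param microbe Microbe name (normalized internally).
#' @return Integer net direction-weighted count.
#' @export
signed_count <- function(table, disease, microbe) {
  stopifnot(inherits(table, "association_table"))
  microbe <- normalize_name(microbe)
  rec <- table$records
  sum(rec$direction[rec$disease == disease & rec$microbe == microbe])
}

#' Signed, inverse-disease-frequency-weighted disease vectors
#'
#' Builds one weight vector per disease over the table's full microbe
#' universe. The weight for disease i and microbe j is the signed
#' association count multiplied by `log(N / n_j)`, where `N` is the number
#' of distinct diseases in the table and `n_j` the number of diseases with
#' at least one record (of either direction) for microbe j. Microbes
#' associated with every disease are thus uninformative (weight 0), in the
#' spirit of inverse document frequency; absent pairs have weight 0.
#'
#' @param table An [association_table()].
#' @param base Logarithm base (default natural log). The choice only
#'   rescales all weights by a common positive constant, so downstream
#'   cosine similarities are invariant to it.
#'
#' @return Numeric matrix with one row per disease and one column per
#'   microbe, dimnames set to the table's sorted disease and microbe
#'   labels.
#' @export
weight_matrix <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "association_table"))
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    stop("`base` must be a single number > 1", call. = FALSE)
  }
  rec <- table$records
  d <- factor(rec$disease, levels = table$diseases)
  j <- factor(rec$microbe, levels = table$microbes)
  signed <- tapply(rec$direction, list(d, j), sum, default = 0L)
  n_records <- table(d, j)
  n_j <- colSums(n_records > 0)
  N <- length(table$diseases)
  w <- sweep(signed, 2L, log(N / n_j, base = base), `*`)
  dimnames(w) <- list(table$diseases, table$microbes)
  w
}

#' Cosine similarity between two disease vectors
#'
#' Dot product divided by the product of the Euclidean norms. If either
#' vector has zero norm the similarity is defined as 0 (with a warning)
#' rather than NaN. Signed weights make negative similarities meaningful
#' (two diseases whose shared microbes change in opposite directions).
#'
#' @param a,b Numeric vectors over the same microbe universe, in the same
#'   order (names, when present on both, must agree).
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop("`a` and `b` must be numeric vectors of equal length", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("`a` and `b` are indexed by different microbe universes", call. = FALSE)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm disease vector; similarity defined as 0", call. = FALSE)
    return(0)
  }
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Pairwise microbe-based disease similarity
#'
#' Computes the cosine similarity between every pair of disease weight
#' vectors from [weight_matrix()]. Diseases whose weight vector is all
#' zero (every associated microbe touches all diseases, or all signed
#' counts cancel) get similarity 0 against everything, including
#' themselves, with a warning.
#'
#' @inheritParams weight_matrix
#' @return A symmetric numeric matrix of class `similarity_matrix` with
#'   disease labels as dimnames; entries in `[-1, 1]`, diagonal 1 for
#'   every disease with a nonzero vector.
#'
#' @examples
#' tab <- association_table(data.frame(
#'   disease = c("d1", "d1", "d2", "d2", "d3"),
#'   microbe = c("m1", "m2", "m1", "m2", "m3"),
#'   direction = c(1, -1, 1, -1, 1)
#' ))
#' run_similarity(tab)
#'
#' @export
run_similarity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "association_table"))
  if (length(table$diseases) < 2L) {
    stop("similarity requires at least two distinct diseases", call. = FALSE)
  }
  w <- weight_matrix(table, base = base)
  nrm <- sqrt(rowSums(w^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("zero-weight vector for disease(s): ",
            paste(names(nrm)[zero], collapse = "; "),
            "; their similarities are reported as 0", call. = FALSE)
  }
  sim <- w %*% t(w)
  denom <- outer(nrm, nrm)
  sim <- ifelse(denom > 0, sim / denom, 0)
  sim <- pmin(pmax(sim, -1), 1)
  diag(sim)[!zero] <- 1
  dimnames(sim) <- list(table$diseases, table$diseases)
  class(sim) <- c("similarity_matrix", class(sim))
  sim
}

#' Long-format disease similarity pairs
#'
#' Lists each unordered disease pair once, sorted lexicographically by the
#' first then the second disease.
#'
#' @param sim A `similarity_matrix` from [run_similarity()].
#' @return Data frame with columns `disease_a`, `disease_b`, `similarity`.
#' @export
similarity_long <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  labels <- rownames(sim)
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  out <- data.frame(
    disease_a = labels[idx[, 1L]],
    disease_b = labels[idx[, 2L]],
    similarity = sim[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$disease_a, out$disease_b), ]
  rownames(out) <- NULL
  out
}

#' Write disease similarities to TSV
#'
#' Writes the long pair list (`disease_a`, `disease_b`, `similarity`) and
#' optionally the full square matrix with disease labels as header row and
#' first column.
#'
#' @param sim A `similarity_matrix` from [run_similarity()].
#' @param path Output path for the long-format pair list.
#' @param matrix_path Optional output path for the square matrix.
#' @return Invisibly, `path`.
#' @export
write_similarity <- function(sim, path, matrix_path = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  long <- similarity_long(sim)
  lines <- c("disease_a\tdisease_b\tsimilarity",
             sprintf("%s\t%s\t%.6f", long$disease_a, long$disease_b,
                     long$similarity))
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  if (!is.null(matrix_path)) {
    header <- paste(c("disease", colnames(sim)), collapse = "\t")
    rows <- vapply(seq_len(nrow(sim)), function(i) {
      paste(c(rownames(sim)[i], sprintf("%.6f", sim[i, ])), collapse = "\t")
    }, character(1))
    con <- file(matrix_path, open = "wb")
    writeLines(c(header, rows), con, useBytes = TRUE)
    close(con)
  }
  invisible(path)
}
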