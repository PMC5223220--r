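# Seeded synthetic fixtures: a miniature stand-in for a curated microbe
# set database and association table, used for benchmarking and tests.
# Names are invented binomial-style tokens; no real taxonomy is implied.

# Run code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic microbe name pool
#'
#' A fixed, deterministic pool of plausible binomial-style names
#' (genus-like token plus species-like epithet), already normalized.
#' The pool is synthetic: the names are invented and imply no real
#' taxonomy.
#'
#' @param n Number of names wanted (at most 300).
#' @return Character vector of `n` distinct normalized names.
#' @export
microbe_name_pool <- function(n) {
  genera <- c("brevibacter", "luminococcus", "terrabacter", "aquicella",
              "sylvanella", "petrimonas", "arvimicrobium", "caldispora",
              "nivalibacter", "umbrosella", "litorivibrio", "pratensium",
              "fontimonas", "collivirga", "dumosicoccus")
  epithets <- c("agrestis", "borealis", "calidus", "dulcis", "exiguus",
                "fluvialis", "gracilis", "humilis", "insulae", "lenis",
                "montanus", "nitidus", "obscurus", "palustris", "rarus",
                "tenuis", "vernalis", "arenosus", "silvae", "rivuli")
  pool <- as.vector(t(outer(genera, epithets, paste)))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > length(pool)) {
    stop(sprintf("`n` must be between 1 and %d", length(pool)), call. = FALSE)
  }
  pool[seq_len(n)]
}

default_size_bins <- function() {
  data.frame(
    min = c(1L, 6L, 11L, 16L, 21L),
    max = c(5L, 10L, 15L, 20L, 30L),
    weight = c(0.77, 0.11, 0.02, 0.04, 0.06)
  )
}

#' Specification for the synthetic fixture generators
#'
#' Collects every knob of the seeded generators in one validated object.
#' The defaults miniaturize a realistic curated database — many small
#' sets, with sizes heavily skewed towards 1-5 members — so that a full
#' benchmark run takes seconds.
#'
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   fixture files.
#' @param n_sets Number of microbe sets to generate.
#' @param n_diseases Number of diseases in the association table.
#' @param n_microbes Size of the synthetic microbe name pool.
#' @param size_bins Data frame with columns `min`, `max`, `weight` giving
#'   the set-size distribution (a bin is chosen by weight, then a size
#'   uniformly within it).
#' @param assoc_per_disease Distinct microbes associated with each
#'   disease.
#' @param repeat_rate Probability that an association record gains one
#'   duplicate (emulating the same pair curated from a second study).
#' @param p_increase Probability that a record reports an increase
#'   (direction +1) rather than a decrease.
#' @param planted_set Optional `list(name=, overlap=, n_noise=)`: build
#'   queries containing `overlap` of the named set's members plus
#'   `n_noise` random non-members (see [generate_planted_query()]).
#' @param planted_pair Optional `list(diseases=, shared=, concordant=)`:
#'   make two diseases share `shared` of their microbe profile with
#'   matching (or, if `concordant = FALSE`, opposite) change directions
#'   (see [generate_association_table()]).
#'
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_sets = 40L, n_diseases = 10L,
                         n_microbes = 60L, size_bins = default_size_bins(),
                         assoc_per_disease = 12L, repeat_rate = 0.15,
                         p_increase = 0.6, planted_set = NULL,
                         planted_pair = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(n_sets) || n_sets < 1) stop("`n_sets` must be >= 1", call. = FALSE)
  if (!is.numeric(n_diseases) || n_diseases < 1) stop("`n_diseases` must be >= 1", call. = FALSE)
  if (!is.numeric(n_microbes) || n_microbes < 1) stop("`n_microbes` must be >= 1", call. = FALSE)
  stopifnot(is.data.frame(size_bins),
            all(c("min", "max", "weight") %in% names(size_bins)),
            all(size_bins$min >= 1), all(size_bins$max >= size_bins$min),
            all(size_bins$weight >= 0), sum(size_bins$weight) > 0)
  stopifnot(assoc_per_disease >= 1, repeat_rate >= 0, repeat_rate <= 1,
            p_increase >= 0, p_increase <= 1)
  if (!is.null(planted_set)) {
    stopifnot(is.list(planted_set), !is.null(planted_set$name))
    planted_set$overlap <- planted_set$overlap %||% 0.8
    planted_set$n_noise <- planted_set$n_noise %||% 5L
    stopifnot(planted_set$overlap >= 0, planted_set$overlap <= 1,
              planted_set$n_noise >= 0)
  }
  if (!is.null(planted_pair)) {
    stopifnot(is.list(planted_pair))
    planted_pair$shared <- planted_pair$shared %||% 0.8
    planted_pair$concordant <- planted_pair$concordant %||% TRUE
    stopifnot(planted_pair$shared >= 0, planted_pair$shared <= 1,
              is.logical(planted_pair$concordant))
    if (n_diseases < 2) {
      stop("a planted disease pair requires n_diseases >= 2", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_sets = as.integer(n_sets),
         n_diseases = as.integer(n_diseases),
         n_microbes = as.integer(n_microbes), size_bins = size_bins,
         assoc_per_disease = as.integer(assoc_per_disease),
         repeat_rate = repeat_rate, p_increase = p_increase,
         planted_set = planted_set, planted_pair = planted_pair),
    class = "fixture_spec"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate a synthetic microbe set database
#'
#' Draws `n_sets` sets whose sizes follow the spec's bin distribution
#' (default heavily skewed towards sizes 1-5) with members sampled from
#' the synthetic name pool; roughly 80% of sets are disease-category and
#' 20% position-category. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return A [set_database()].
#' @export
generate_set_database <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- microbe_name_pool(spec$n_microbes)
  bins <- spec$size_bins
  if (any(bins$weight > 0 & bins$min > spec$n_microbes)) {
    stop("infeasible spec: a size bin requires sets larger than the microbe pool",
         call. = FALSE)
  }
  with_seed(spec$seed + 101L, {
    bin <- sample.int(nrow(bins), spec$n_sets, replace = TRUE,
                      prob = bins$weight)
    sizes <- vapply(bin, function(b) {
      hi <- min(bins$max[b], spec$n_microbes)
      if (hi < bins$min[b]) {
        stop("infeasible spec: set size exceeds the microbe pool",
             call. = FALSE)
      }
      sample(seq(bins$min[b], hi), 1L)
    }, integer(1))
    categories <- sample(c("disease", "position"), spec$n_sets,
                         replace = TRUE, prob = c(0.8, 0.2))
    sets <- lapply(seq_len(spec$n_sets), function(i) {
      label <- if (categories[i] == "disease") "disorder" else "habitat"
      microbe_set(sprintf("%s %02d", label, i), categories[i],
                  sample(pool, sizes[i]))
    })
    set_database(sets)
  })
}

#' Generate a query with a planted enriched set
#'
#' Builds a query list containing a fraction `overlap` of the planted
#' set's members plus `n_noise` random names from the rest of the
#' universe, shuffled. Deterministic under the spec's seed.
#'
#' @param db A [set_database()], typically from [generate_set_database()].
#' @param spec A [fixture_spec()] with `planted_set` filled in; its
#'   `name` must identify a set of `db` with at least two members.
#' @return Character vector of distinct normalized microbe names.
#' @export
generate_planted_query <- function(db, spec) {
  stopifnot(inherits(db, "set_database"), inherits(spec, "fixture_spec"))
  planted <- spec$planted_set
  if (is.null(planted)) {
    stop("spec has no `planted_set`", call. = FALSE)
  }
  target <- db$sets[[planted$name]]
  if (is.null(target)) {
    stop("unknown planted set: ", planted$name, call. = FALSE)
  }
  if (length(target$members) < 2L) {
    stop("planted set must have at least two members", call. = FALSE)
  }
  with_seed(spec$seed + 202L, {
    k <- round(planted$overlap * length(target$members))
    if (planted$overlap > 0) k <- max(1L, k)
    core <- if (k > 0) sample(target$members, k) else character(0)
    outside <- setdiff(db$universe, target$members)
    noise <- sample(outside, min(planted$n_noise, length(outside)))
    sample(c(core, noise))
  })
}

#' Generate a synthetic microbe-disease association table
#'
#' Each disease receives `assoc_per_disease` distinct associated microbes
#' with random change directions; a fraction of records (the
#' `repeat_rate`) is duplicated to emulate pairs curated from more than
#' one study. If `planted_pair` is set, the second planted disease copies
#' `shared` of the first's profile with matching (concordant) or flipped
#' (discordant) directions; with `shared = 1` the copy is exact (same
#' multiplicities, no extra noise), so a discordant pair is a perfect
#' sign flip. Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return An [association_table()]. Disease labels are
#'   `"condition 01"`, `"condition 02"`, ... unless `planted_pair$diseases`
#'   supplies two labels for the planted pair.
#' @export
generate_association_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- microbe_name_pool(spec$n_microbes)
  k <- min(spec$assoc_per_disease, spec$n_microbes)
  labels <- sprintf("condition %02d", seq_len(spec$n_diseases))
  planted <- spec$planted_pair
  if (!is.null(planted) && !is.null(planted$diseases)) {
    stopifnot(length(planted$diseases) == 2L)
    labels[1:2] <- planted$diseases
  }
  with_seed(spec$seed + 303L, {
    profile_for <- function(disease) {
      microbes <- sample(pool, k)
      data.frame(
        disease = disease,
        microbe = microbes,
        direction = ifelse(stats::rbinom(k, 1L, spec$p_increase) == 1L, 1L, -1L),
        stringsAsFactors = FALSE
      )
    }
    duplicate_some <- function(rec) {
      extra <- stats::rbinom(nrow(rec), 1L, spec$repeat_rate) == 1L
      rbind(rec, rec[extra, , drop = FALSE])
    }
    profiles <- lapply(labels, profile_for)
    names(profiles) <- labels
    if (!is.null(planted)) {
      a <- profiles[[labels[1L]]]
      n_shared <- round(planted$shared * nrow(a))
      shared <- a[seq_len(n_shared), , drop = FALSE]
      shared$disease <- labels[2L]
      if (!planted$concordant) shared$direction <- -shared$direction
      if (planted$shared >= 1) {
        profiles[[labels[2L]]] <- shared
      } else {
        own <- profiles[[labels[2L]]]
        own <- own[!own$microbe %in% shared$microbe, , drop = FALSE]
        own <- own[seq_len(min(nrow(own), k - n_shared)), , drop = FALSE]
        profiles[[labels[2L]]] <- rbind(shared, own)
      }
    }
    records <- do.call(rbind, lapply(profiles, duplicate_some))
    if (!is.null(planted) && planted$shared >= 1) {
      # keep the planted copy an exact (or exactly flipped) duplicate of
      # its partner, multiplicities included
      records <- records[!(records$disease == labels[2L]), , drop = FALSE]
      twin <- records[records$disease == labels[1L], , drop = FALSE]
      twin$disease <- labels[2L]
      if (!planted$concordant) twin$direction <- -twin$direction
      records <- rbind(records, twin)
    }
    association_table(records)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Materializes one spec as the three files the command-line tool
#' consumes: `db.gmt` (set database), `query.txt` (planted query, only
#' when the spec has a `planted_set`) and `assoc.tsv` (association
#' records). Identical spec + seed give byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named character vector of the files written.
#' @export
generate_fixture_files <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  db <- generate_set_database(spec)
  files <- c(db = file.path(outdir, "db.gmt"),
             assoc = file.path(outdir, "assoc.tsv"))
  write_set_database(db, files[["db"]])
  write_associations(generate_association_table(spec), files[["assoc"]])
  if (!is.null(spec$planted_set)) {
    query <- generate_planted_query(db, spec)
    files <- c(files, query = file.path(outdir, "query.txt"))
    con <- file(files[["query"]], open = "wb")
    writeLines(query, con, useBytes = TRUE)
    close(con)
  }
  invisible(files)
}

#' Packaged query: gut microbes changed under an animal-based diet
#'
#' The query list shipped with the package: the 51 species- and
#' genus-rank gut microbes reported as significantly changed when human
#' volunteers switched to an animal-based diet, normalized and
#' de-duplicated. A convenient realistic input for [run_enrichment()].
#'
#' @return Character vector of 51 distinct normalized microbe names.
#' @examples
#' length(animal_diet_query())
#' @export
animal_diet_query <- function() {
  path <- system.file("extdata", "animal_diet_microbes.txt",
                      package = "microsea", mustWork = TRUE)
  read_microbe_list(path)
}
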