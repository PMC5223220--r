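test_that("hypergeometric tail matches exact enumeration and handles edge cases", {
  expect_equal(hypergeom_pvalue(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # m = 0 is certain; a set equal to the background forces m = M
  expect_identical(hypergeom_pvalue(20, 5, 7, 0), 1)
  expect_identical(hypergeom_pvalue(8, 8, 3, 3), 1)
  # monotone non-increasing in m at fixed (N, n, M)
  p <- hypergeom_pvalue(30, 10, rep(12, 11), 0:10)
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeom_pvalue(10, 11, 5, 3), "inconsistent")
  expect_error(hypergeom_pvalue(10, 4, 5, 5), "inconsistent")
  expect_error(hypergeom_pvalue(10, 4, 5.5, 2), "integers")
})

test_that("fold enrichment is the observed/expected overlap ratio", {
  expect_equal(fold_enrichment(100, 10, 20, 6), 3.0)
  expect_identical(fold_enrichment(100, 10, 20, 0), 0)
  # query = background leaves no room for enrichment
  expect_equal(fold_enrichment(50, 8, 50, 8), 1.0)
  expect_error(fold_enrichment(10, 0, 5, 0), ">= 1")
})

test_that("Bonferroni and BH corrections reproduce hand-computed values", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni(c(0.2, 0.3, 0.4)), c(0.6, 0.9, 1.0))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.001, 0.5, 1.0)), c(0.003, 0.75, 1.0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(c(-0.1, 0.2)), "\\[0, 1\\]")
})

test_that("BH output is permutation-equivariant and ordered below Bonferroni", {
  set.seed(42)
  for (rep in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_true(all(bonferroni(p) >= bh_fdr(p)))
    expect_true(all(bh_fdr(p) >= p))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
    expect_equal(bh_fdr(p), bh_step_up_oracle(p))
  }
})

enrich_db <- function() {
  set_database(list(
    microbe_set("planted", "disease", sprintf("target %02d", 1:6)),
    microbe_set("decoy a", "disease", sprintf("other %02d", 1:6)),
    microbe_set("decoy b", "position", sprintf("other %02d", 4:9)),
    microbe_set("tiny", "disease", "target 01")
  ))
}

test_that("a query drawn from one set ranks that set first with maximal overlap", {
  db <- enrich_db()
  res <- run_enrichment(sprintf("target %02d", 1:6), db)
  expect_identical(res$set[1], "planted")
  expect_identical(res$m[1], res$n[1])
  expect_identical(attr(res, "background_size"), length(db$universe))
  expect_identical(attr(res, "query_size"), 6L)
  # "tiny" is below the default min-size filter
  expect_false("tiny" %in% res$set)
  expect_true(all(res$bonferroni >= res$fdr & res$fdr >= res$p_value))
  # matched/unmatched partition each set's background members
  for (i in seq_len(nrow(res))) {
    matched <- strsplit(res$matched[i], ";", fixed = TRUE)[[1]]
    unmatched <- strsplit(res$unmatched[i], ";", fixed = TRUE)[[1]]
    members <- db$sets[[res$set[i]]]$members
    expect_identical(sort(c(matched, unmatched)), members)
    expect_length(intersect(matched, unmatched), 0L)
  }
})

test_that("zero-overlap queries give p = 1 and fold = 0 everywhere", {
  db <- enrich_db()
  res <- run_enrichment(c("other 01", "other 02"), db,
                        category = "disease")
  expect_true(all(res$category == "disease"))
  planted_row <- res[res$set == "planted", ]
  expect_identical(planted_row$p_value, 1)
  expect_identical(planted_row$fold, 0)
  expect_identical(planted_row$m, 0L)
})

plain_table <- function(res) {
  out <- as.data.frame(res)
  attributes(out)[c("background_size", "query_size", "dropped")] <- NULL
  class(out) <- "data.frame"
  out
}

test_that("result table is invariant to query order and duplicates; unknown names drop with a warning", {
  db <- enrich_db()
  q <- c("target 01", "target 02", "other 05")
  base <- run_enrichment(q, db)
  shuffled <- run_enrichment(c(rev(q), "Target_02"), db)
  expect_identical(plain_table(base), plain_table(shuffled))

  expect_warning(
    res <- run_enrichment(c(q, "no such microbe"), db),
    "dropped"
  )
  expect_identical(attr(res, "dropped"), "no such microbe")
  expect_identical(attr(res, "query_size"), 3L)
  expect_identical(plain_table(res), plain_table(base))
})

test_that("explicit backgrounds restrict the universe and the tested sets", {
  db <- enrich_db()
  bg <- c(sprintf("target %02d", 1:6), "other 01", "not in universe")
  res <- run_enrichment(sprintf("target %02d", 1:3), db, background = bg,
                        min_size = 1)
  # background intersected with the universe: 7 microbes
  expect_identical(attr(res, "background_size"), 7L)
  # decoy b has no members left in this background -> not tested
  expect_identical(sort(res$set), c("decoy a", "planted", "tiny"))
  expect_identical(res[res$set == "decoy a", ]$n, 1L)

  expect_error(run_enrichment("target 01", db, background = "nowhere"),
               "background shares no names")
  expect_error(run_enrichment("absent", db), "query is empty")
  expect_error(run_enrichment("x", set_database(list())), "empty")
})

test_that("enrichment TSV export writes the documented columns and formats", {
  db <- enrich_db()
  res <- run_enrichment(sprintf("target %02d", 1:6), db)
  path <- tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  lines <- readLines(path)
  expect_identical(strsplit(lines[1], "\t")[[1]],
                   c("set", "category", "n", "m", "percent", "fold",
                     "p_value", "bonferroni", "fdr", "matched", "unmatched"))
  first <- strsplit(lines[2], "\t")[[1]]
  expect_identical(first[1], "planted")
  expect_match(first[7], "^[0-9]\\.[0-9]{5}e[+-][0-9]{2}$")
  expect_match(first[5], "^[0-9]+\\.[0-9]{4}$")
})
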