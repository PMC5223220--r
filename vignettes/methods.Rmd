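---
title: "Methods: microbe set enrichment and microbe-based disease similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbe set enrichment and microbe-based disease similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsea)
```

This vignette is the package's own account of its statistical methods:
the models, the assumptions behind them, the parameters that matter, and
the design choices made where more than one reasonable convention
exists.

## Data model

A **microbe set** is a named group of microbes sharing one annotation:
association with the same disease, or colonization of the same body
position. Sets are stored together in a **set database** whose
*universe* is the exact union of all member names; sets may overlap
freely. An **association table** is a multiset of curated records
(disease, microbe, direction), where direction is +1 for a microbe
reported increased in the disease and −1 for decreased. Duplicate
records are deliberately kept: the number of records for a pair counts
independent curated reports and is the evidence weight used by the
similarity method. Disease sets can be derived from an association
table as the union of each disease's associated microbes across
studies, ignoring direction — a deliberately permissive rule, because
differential-abundance results are too variable across studies for an
intersection or vote to be stable.

Name matching is purely lexical: `normalize_name()` lowercases, maps
underscores to spaces, and collapses whitespace, and matching is by
exact equality of the normalized strings. No taxonomy-aware synonym
resolution is attempted; a query name spelled differently from the
database simply fails to overlap. This keeps matching deterministic and
testable, at the cost of sensitivity to curation spelling. Taxonomic
rank is likewise a curation-time concern: a well-built database retains
species- and genus-rank names only, but queries are not filtered by
rank at run time.

## Over-representation analysis

For background universe size $N$, set size in the background $n$, query
size $M$ and observed overlap $m$, the p-value is the exact
hypergeometric upper tail

$$P(X \ge m) \;=\; \sum_{k=m}^{\min(n,M)}
  \frac{\binom{n}{k}\binom{N-n}{M-k}}{\binom{N}{M}},$$

computed through R's hypergeometric distribution function — exact, with
no normal approximation. The tail is *inclusive* of the observed
overlap ($\ge m$, not $> m$), the standard over-representation
convention; only over-representation is tested, not depletion.

Three conventions are not forced by the method and were fixed as
package design choices:

* **Fold of over-representation** is the observed/expected ratio
  $(m/M)/(n/N)$: 1 means the set behaves like a random draw, 0 means no
  overlap.
* **Percent** is $m/M$, the fraction of the query matching the set
  (the DAVID-style convention for annotation tables).
* **Correction family**: Bonferroni and Benjamini–Hochberg corrections
  use $k$ = the number of sets actually tested after filtering, not the
  number of sets in the database file. Both corrections are the
  standard procedures from `stats::p.adjust`.

The background defaults to the database universe. A user-supplied
background is first intersected with the universe (names outside the
database carry no information for the test and would silently deflate
every p-value), and query names outside the effective background are
dropped with a warning rather than an error — they are reported in the
result's `dropped` attribute, and do not count towards $M$. Each set is
restricted to the background before testing and skipped if fewer than
`min_size` members remain; the default `min_size = 2` excludes
singleton sets, for which the test carries almost no information.
Results are sorted by p-value with lexicographic set-name tie-breaking,
so output is byte-stable for identical inputs.

Assumptions worth keeping in mind: the hypergeometric model treats the
query as a uniform draw from the background, so the background must be
the set of microbes that *could have been detected* by the study; and
overlapping sets make the tests correlated, which BH tolerates but does
not model.

## Microbe-based disease similarity

Every disease $i$ is represented by a vector over the table's $M$
microbes,

$$w_{ij} = S_{ij}\,\log\!\frac{N}{n_j},$$

where $S_{ij}$ is the signed record count for the pair (sum of +1 per
increase and −1 per decrease report), $N$ is the number of distinct
diseases in the table, and $n_j$ is the number of diseases with at
least one record for microbe $j$, irrespective of direction. The
$\log(N/n_j)$ factor is an inverse-document-frequency weight: a microbe
associated with every disease carries weight 0 everywhere, a
disease-specific microbe is up-weighted. Disease similarity is the
cosine of two weight vectors. Because the vectors are signed, negative
similarities are meaningful — two diseases whose shared microbes shift
in opposite directions — and are reported as-is, without clamping to
$[0, 1]$.

Design choices in this module:

* **Mixed directions net out.** A pair reported both increased and
  decreased is not an error; the signs cancel in $S_{ij}$. When all
  records for a pair agree, $S_{ij}$ reduces to the record count times
  the common direction, which is the quantity the weighting is meant to
  capture.
* **Logarithm base.** Natural log by default. The choice is immaterial:
  switching base rescales every weight by the same positive constant,
  which cancels in the cosine. This invariance is asserted in the test
  suite (ln vs log2, agreement to $10^{-12}$).
* **Zero-norm vectors.** A disease whose every weight is zero (all its
  microbes touch all diseases, or all signs cancel) has no direction in
  the space; its similarity to everything, itself included, is defined
  as 0, with a warning, rather than NaN.
* Diagonal entries for nonzero vectors are set to exactly 1, and all
  entries are clamped to $[-1, 1]$, removing floating-point wobble at
  the boundaries.

## The synthetic fixture generator

No suitable curated microbe-set resource ships with the package, so the
generators in `fixture_spec()` build one in miniature, and every
benchmark in the test suite runs against it. The defaults emulate the
salient shape of a real curated database while staying small enough
that the full suite runs in seconds: 40 sets drawn from a 60-microbe
pool with set sizes heavily skewed to the small end (bins 1–5 / 6–10 /
11–15 / 16–20 / 21–30 with weights 0.77 / 0.11 / 0.02 / 0.04 / 0.06,
matching the size skew typical of curated disease sets), roughly 80%
disease- and 20% position-category sets, and an association table of 10
diseases with about 12 associated microbes each, a 60/40
increase/decrease split, and a 15% chance that a record is duplicated
(the same pair curated from a second study). Microbe names come from a
fixed pool of invented binomial-style tokens; no real taxonomy is
implied.

Two kinds of signal can be planted. A **planted set** yields a query
containing a fraction (default 0.8) of one set's members plus `n_noise`
random non-members; the default `n_noise = 5` keeps the query dominated
by the signal while still containing realistic off-target names. A
**planted disease pair** makes the second disease share a fraction
(default 0.8) of the first's microbe profile with concordant or flipped
directions; at `shared = 1` the copy is exact, multiplicities included,
so a discordant pair is a perfect sign flip with similarity −1.

All generators are pure functions of the spec (which includes the
seed): the same spec produces byte-identical fixture files, and the
caller's RNG state is left untouched.

What passing the planted benchmarks does and does not show: recovery of
a planted set (minimum FDR in ≥95% of 100 seeded replicates) and of a
planted pair (off-diagonal similarity maximum at the same rate)
demonstrates that the statistics rank a known signal above background
under the generator's idealized conditions — exchangeable microbes,
uniform membership sampling, independent noise. Real curated databases
have correlated sets, heavy-tailed microbe popularity, and
curation-spelling noise, none of which the generator reproduces, so
these benchmarks validate the machinery, not field performance.

## Numerical and degenerate-input conventions

* Counts are validated before any computation: `m ≤ min(n, M)`,
  `n, M ≤ N`, all non-negative integers; violations raise errors rather
  than returning NaN.
* `m = 0` gives $P = 1$ and fold 0; a set equal to the background
  forces $m = M$ and $P = 1$.
* An empty effective query, an empty database, and a background
  disjoint from the universe are errors; a database with no set passing
  the size filter returns an empty table with a warning.
* File writers emit members in sorted order and results in fully
  determined order, so identical inputs give byte-identical outputs;
  the command-line tool writes outputs atomically (a failed run never
  leaves a truncated file).
* In exported TSVs, p-values and corrections are printed in scientific
  notation with 6 significant digits, percent and fold with 4 decimals;
  full precision is available from the R objects.

## Problem sizes used in validation

The test suite exercises the hypergeometric implementation against an
independent binomial-coefficient enumeration over every valid
configuration with $N \le 12$ (several thousand cases), the BH
implementation against hand-computed step-up values and 1000 random
p-vectors, the similarity implementation against a loop-based oracle on
tables with up to 5 diseases and 6 microbes, and the planted-recovery
benchmarks over 100 seeded replicates of the default generator. These
sizes were chosen so each property is checked exhaustively or with
comfortable replication while the whole suite stays fast enough to run
on every change.

## Known limitations

* Lexical name matching: synonyms, strain-level labels and spelling
  variants are distinct names.
* The hypergeometric background assumption is the user's
  responsibility; an inappropriate background (e.g. all known microbes
  when only gut taxa were measurable) inflates significance.
* Similarities come with no significance measure; a high cosine between
  two sparsely annotated diseases can rest on one shared microbe.
* Under-representation (depletion) is not tested.
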