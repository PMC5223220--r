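# Independent oracles and small fixture builders shared across tests.

# Exact hypergeometric upper tail by direct enumeration of the pmf:
# P(X >= m) = sum_{k=m}^{min(n,M)} C(n,k) C(N-n,M-k) / C(N,M).
hyper_tail_oracle <- function(N, n, M, m) {
  ks <- seq.int(m, min(n, M))
  if (!length(ks)) return(0)
  sum(choose(n, ks) * choose(N - n, M - ks)) / choose(N, M)
}

# Independent Benjamini-Hochberg step-up, written from the definition.
bh_step_up_oracle <- function(p) {
  k <- length(p)
  ord <- order(p)
  q <- p[ord] * k / seq_len(k)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(k)
  out[ord] <- q
  out
}

# Brute-force disease similarity from an association record data frame,
# computed with explicit loops, independently of the package's
# matrix-based implementation.
similarity_oracle <- function(records, base = exp(1)) {
  diseases <- sort(unique(records$disease))
  microbes <- sort(unique(records$microbe))
  N <- length(diseases)
  w <- matrix(0, N, length(microbes), dimnames = list(diseases, microbes))
  for (j in microbes) {
    n_j <- length(unique(records$disease[records$microbe == j]))
    for (i in diseases) {
      sc <- sum(records$direction[records$disease == i & records$microbe == j])
      w[i, j] <- sc * log(N / n_j, base = base)
    }
  }
  sim <- matrix(0, N, N, dimnames = list(diseases, diseases))
  for (i in seq_len(N)) {
    for (k in seq_len(N)) {
      ni <- sqrt(sum(w[i, ]^2))
      nk <- sqrt(sum(w[k, ]^2))
      sim[i, k] <- if (ni == 0 || nk == 0) 0 else sum(w[i, ] * w[k, ]) / (ni * nk)
    }
  }
  sim
}

# A small random association record set for property tests; every one of
# the n_diseases labels is guaranteed at least one record.
random_records <- function(n_diseases, n_microbes, n_records,
                           p_increase = 0.5) {
  labels <- sprintf("d%02d", seq_len(n_diseases))
  total <- n_diseases + n_records
  data.frame(
    disease = c(labels, sample(labels, n_records, replace = TRUE)),
    microbe = sample(sprintf("microbe %02d", seq_len(n_microbes)), total,
                     replace = TRUE),
    direction = sample(c(1L, -1L), total, replace = TRUE,
                       prob = c(p_increase, 1 - p_increase)),
    stringsAsFactors = FALSE
  )
}

# Write a character vector as a one-name-per-line list file.
write_list <- function(names, path = tempfile(fileext = ".txt")) {
  writeLines(names, path)
  path
}
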