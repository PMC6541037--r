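# Independent oracles used by the tests. Each is a direct, brute-force or
# closed-form computation, kept free of the code paths it checks.

# hypergeometric upper tail P(X >= a) by explicit binomial-coefficient sums
oracle_hyper_upper <- function(a, K, N, n) {
  ks <- a:min(K, n)
  if (a > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# D+ of a set of ranks within a list of length n
oracle_dplus <- function(ranks, n) {
  s <- sort(ranks); m <- length(s)
  max(0, max(seq_len(m) / m - s / n))
}

# exhaustive permutation null of D+: all C(n, m) placements
oracle_ks_null <- function(n, m) {
  subsets <- utils::combn(n, m)
  apply(subsets, 2, oracle_dplus, n = n)
}

oracle_ks_pvalue <- function(ranks, n) {
  d <- oracle_dplus(ranks, n)
  null <- oracle_ks_null(n, length(ranks))
  mean(null >= d - 1e-12)
}

# Benjamini-Hochberg step-up applied by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# complete-linkage distance between two groups: max pairwise distance
oracle_complete_linkage <- function(points, g1, g2) {
  d <- as.matrix(stats::dist(points))
  max(d[g1, g2])
}

# memoized full default build shared by the acceptance blocks
default_build_cached <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- build_default_ontology()
    res
  }
})

# memoized small ontologies shared across test files
.toy_cache <- new.env(parent = emptyenv())
toy_ontology <- function(n_classes = 2L, n_fa = 3L, classes = NULL,
                         with_biophysics = TRUE) {
  key <- paste(n_classes, n_fa, paste(classes, collapse = ","),
               with_biophysics, sep = "|")
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- make_toy_ontology(
      n_classes, utils::head(default_fatty_acids(), n_fa),
      classes = classes, with_biophysics = with_biophysics)
  .toy_cache[[key]]
}
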