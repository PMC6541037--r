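# Ontology enrichment statistics: one-tailed Fisher exact tests over 2x2
# tables (target-list mode) and one-tailed Kolmogorov-Smirnov tests over a
# ranked lipid list (ranking mode), with BH correction, term-subset
# restriction and redundant-parent pruning. Every term is tested
# independently with its full closed annotation set ("classic" semantics).

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction: q_(i) = min_{j >= i} (m * p_(j) / j), capped at 1
#' and mapped back to input order. Output is invariant to input order and
#' monotone in p.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# --- one-sided KS over ranks, finite-population (permutation) null ---------

# D+ = max(0, max_i(i/m - r_i/n)) computed in exact integer arithmetic:
# returns K = max_i(i*n - s_i*m) so that D+ = max(0, K) / (m*n).
ks_dplus_K <- function(sorted_ranks, m, n) {
  i <- seq_len(m)
  max(i * n - sorted_ranks * m)
}

# P(D+ >= K/(m*n)) when m ranks are drawn without replacement from 1..n.
# Complement counting: subsets with all i*n - s_i*m < K, i.e.
# s_i >= lb_i = floor((i*n - K)/m) + 1, counted by a prefix-sum DP over
# increasing sequences. Exact for the finite-population null.
ks_exact_pvalue <- function(K, m, n) {
  if (K <= 0L) return(1)
  i <- seq_len(m)
  lb <- pmax((i * n - K) %/% m + 1L, i)
  if (any(lb > n - (m - i))) {
    # some position cannot be filled => no subset avoids D+ >= d => p = 1
    # (can only happen when every subset reaches the observed statistic)
    return(1)
  }
  # w[s] = number of valid prefixes of length i ending exactly at rank s
  w <- as.numeric(seq_len(n) >= lb[1])
  if (m > 1L) {
    for (ii in 2L:m) {
      cum <- cumsum(w)
      w <- numeric(n)
      s <- seq_len(n)
      valid <- s >= lb[ii] & s >= 2L
      w[valid] <- cum[s[valid] - 1L]
    }
  }
  count_below <- sum(w)
  total <- choose(n, m)
  p <- 1 - count_below / total
  min(max(p, 0), 1)
}

# Smirnov one-sided asymptotic with finite-population variance correction
ks_asymptotic_pvalue <- function(d, m, n) {
  if (d <= 0) return(1)
  if (m >= n) return(1)
  exp(-2 * d^2 * m * n / (n - m))
}

#' One-sided KS p-value for term positions in a ranked list
#'
#' Computes D+ = max(0, max_i(i/m - rank_i/n)) — over-representation of
#' annotated lipids at the top of the list — and its p-value under the
#' permutation null (the m annotated positions drawn uniformly without
#' replacement from 1..n). The p-value is exact (lower-bound counting DP)
#' for m <= `exact_limit`; beyond that a Smirnov-type asymptotic with
#' finite-population variance correction is used.
#'
#' @param ranks Integer positions (1 = top) of the annotated lipids.
#' @param n Length of the ranked list.
#' @param exact_limit Largest m for which the exact null is computed.
#' @return List with `statistic` (D+) and `p_value`.
#' @export
ks_rank_test <- function(ranks, n, exact_limit = 50L) {
  m <- length(ranks)
  stopifnot(m >= 1L, n >= m, all(ranks >= 1L), all(ranks <= n),
            !anyDuplicated(ranks))
  s <- sort(as.integer(ranks))
  K <- ks_dplus_K(s, m, as.integer(n))
  d <- max(0, K) / (m * n)
  p <- if (m <= exact_limit && is.finite(choose(n, m)))
    ks_exact_pvalue(as.integer(K), m, as.integer(n))
  else ks_asymptotic_pvalue(d, m, n)
  list(statistic = d, p_value = p)
}

# --- local statistics -------------------------------------------------------

welch_one_tailed <- function(x, y) {
  # alternative: mean(x) > mean(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  out <- tryCatch(
    stats::t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value,
    error = function(e) {
      mx <- mean(x); my <- mean(y)   # zero-variance degenerate rows
      if (mx > my) 0 else if (mx < my) 1 else 0.5
    })
  out
}

#' Per-lipid local statistics
#'
#' Computes the per-lipid value used to rank the list in ranking-mode
#' enrichment: one-tailed Welch t-test p-values (alternative: condition of
#' interest greater than reference), log2 fold changes (condition of interest
#' over reference, with a global half-minimum pseudocount when a mean is
#' zero), one-way ANOVA F-test p-values, or user-supplied custom values.
#'
#' @param matrix Numeric lipid-by-sample matrix with rownames (lipids) and
#'   colnames (samples). Missing values allowed.
#' @param group_labels Character vector of condition labels, one per column.
#' @param method One of `"welch_t_p"`, `"log2_fold_change"`, `"anova_f_p"`,
#'   `"custom"`.
#' @param condition_of_interest For the two-condition methods, the label of
#'   the condition tested as "greater"; defaults to the first label in
#'   `group_labels` order.
#' @param custom_values Named numeric vector for `method = "custom"`.
#' @return Named numeric vector, one value per lipid.
#' @export
local_statistic <- function(matrix, group_labels,
                            method = c("welch_t_p", "log2_fold_change",
                                       "anova_f_p", "custom"),
                            condition_of_interest = NULL,
                            custom_values = NULL) {
  method <- match.arg(method)
  if (method == "custom") {
    if (is.null(custom_values) || is.null(names(custom_values)))
      stop("custom method requires a named custom_values vector")
    return(custom_values)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            length(group_labels) == ncol(matrix))
  groups <- unique(group_labels)
  if (method %in% c("welch_t_p", "log2_fold_change")) {
    if (length(groups) != 2L)
      stop(method, " requires exactly 2 conditions")
    if (is.null(condition_of_interest)) condition_of_interest <- groups[1]
    if (!condition_of_interest %in% groups)
      stop("unknown condition_of_interest: ", condition_of_interest)
    ref <- setdiff(groups, condition_of_interest)
    xi <- matrix[, group_labels == condition_of_interest, drop = FALSE]
    xr <- matrix[, group_labels == ref, drop = FALSE]
    if (method == "welch_t_p") {
      if (ncol(xi) < 2L || ncol(xr) < 2L)
        stop("Welch t-test needs >= 2 samples per condition")
      vals <- vapply(seq_len(nrow(matrix)),
                     function(i) welch_one_tailed(xi[i, ], xr[i, ]), numeric(1))
    } else {
      mi <- rowMeans(xi, na.rm = TRUE); mr <- rowMeans(xr, na.rm = TRUE)
      pos <- matrix[!is.na(matrix) & matrix > 0]
      pc <- if (length(pos)) min(pos) / 2 else NA_real_
      vals <- numeric(nrow(matrix))
      for (i in seq_len(nrow(matrix))) {
        a <- mi[i]; b <- mr[i]
        if ((is.na(a) || a == 0) && (is.na(b) || b == 0)) {
          vals[i] <- 0   # all-zero row: flagged neutral
        } else {
          if (a == 0 || b == 0) { a <- a + pc; b <- b + pc }
          vals[i] <- log2(a / b)
        }
      }
    }
  } else {
    if (length(groups) < 2L) stop("ANOVA requires >= 2 conditions")
    if (any(table(group_labels) < 2L))
      stop("ANOVA needs >= 2 samples per condition")
    g <- factor(group_labels)
    vals <- vapply(seq_len(nrow(matrix)), function(i) {
      y <- matrix[i, ]
      ok <- !is.na(y)
      tryCatch(
        stats::oneway.test(y[ok] ~ g[ok], var.equal = TRUE)$p.value,
        error = function(e) 1)
    }, numeric(1))
    vals[is.na(vals)] <- 1  # zero between- and within-group variance
  }
  stats::setNames(vals, rownames(matrix))
}

#' Rank lipids by a local statistic
#'
#' Default direction: p-value statistics rank low-to-high (most significant
#' first); log2 fold changes and custom statistics rank high-to-low. Ties are
#' broken deterministically by canonical name, so the ranked list (and hence
#' every KS p-value) is invariant under permutations of the input.
#'
#' @param values Named numeric vector of local statistics (names = lipids).
#' @param statistic_name One of `"welch_t_p"`, `"log2_fold_change"`,
#'   `"anova_f_p"`, `"custom"`.
#' @param manual_direction Optional override: `"low_to_high"` or
#'   `"high_to_low"`.
#' @return A `ranked_list`: `species` (in rank order), `local_values`,
#'   `statistic_name`, `direction`.
#' @export
rank_lipids <- function(values,
                        statistic_name = c("welch_t_p", "log2_fold_change",
                                           "anova_f_p", "custom"),
                        manual_direction = NULL) {
  statistic_name <- match.arg(statistic_name)
  stopifnot(!is.null(names(values)), all(is.finite(values)))
  direction <- if (!is.null(manual_direction)) {
    match.arg(manual_direction, c("low_to_high", "high_to_low"))
  } else if (statistic_name %in% c("welch_t_p", "anova_f_p")) {
    "low_to_high"
  } else {
    "high_to_low"
  }
  key <- if (direction == "low_to_high") values else -values
  ord <- order(key, names(values))
  structure(list(species = names(values)[ord],
                 local_values = unname(values[ord]),
                 statistic_name = statistic_name, direction = direction),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d lipids by %s (%s)\n", length(x$species),
              x$statistic_name, x$direction))
  invisible(x)
}

# --- candidate terms and result assembly ------------------------------------

# closed (species, term) pairs restricted to a universe of species
universe_annotation <- function(ontology, universe) {
  dt <- ontology$closed[ontology$closed$species %in% universe, ]
  data.table::setkey(dt, term)
  dt
}

candidate_terms <- function(ontology, ann_dt, term_subset = NULL,
                            min_term_size = 1L, prune_redundant = FALSE,
                            universe = NULL) {
  counts <- ann_dt[, list(n = .N), by = "term"]
  cands <- counts$term[counts$n >= max(1L, min_term_size)]
  if (!is.null(term_subset)) {
    missing <- setdiff(term_subset, ontology$terms$id)
    if (length(missing))
      stop("unknown term(s) in term_subset: ",
           paste(missing, collapse = ", "))
    allowed <- unique(unlist(lapply(term_subset, descendants,
                                    ontology = ontology)))
    cands <- intersect(cands, allowed)
  }
  if (prune_redundant && length(cands) > 1L)
    cands <- prune_redundant_parents(ontology, cands, universe = universe)
  cands
}

finish_report <- function(df, ontology, alpha) {
  nm <- stats::setNames(ontology$terms$name, ontology$terms$id)
  br <- stats::setNames(ontology$terms$branch, ontology$terms$id)
  df$term_name <- unname(nm[df$term_id])
  df$branch <- unname(br[df$term_id])
  df$q_value <- bh_adjust(df$p_raw)
  df$significant <- df$q_value < alpha
  df <- df[order(df$q_value, df$p_raw, df$term_id), ]
  rownames(df) <- NULL
  df[, c("term_id", "term_name", "branch", "mode", "n_annotated",
         "statistic", "p_raw", "q_value", "significant")]
}

#' Target-list enrichment (one-tailed Fisher exact tests)
#'
#' For every candidate term a 2x2 contingency table (annotated/not x
#' target/background) is built from the closed annotations restricted to the
#' universe, and over-representation of the term in the target is tested
#' with the one-tailed Fisher exact test (hypergeometric upper tail
#' P(X >= a)). Raw p-values are BH-adjusted over the family of terms
#' actually tested.
#'
#' @param target Character vector of species names (subset of `universe`).
#' @param universe Character vector of species names, all present in the
#'   ontology (match inputs with [match_names()] first).
#' @param ontology A `lion_ontology`.
#' @param term_subset Optional term ids: only their descendant terms are
#'   tested (and form the BH family).
#' @param prune_redundant Drop most-generic terms whose universe-restricted
#'   annotation set is identical to a descendant's before testing.
#' @param min_term_size Minimum number of annotated universe species for a
#'   term to be tested (default 1; terms annotating none are always skipped).
#' @param alpha Significance label threshold for the report (rows are never
#'   filtered).
#' @return Report data.frame: term_id, term_name, branch, mode, n_annotated
#'   (in universe), statistic (odds ratio), p_raw, q_value, significant.
#' @export
fisher_enrichment <- function(target, universe, ontology,
                              term_subset = NULL, prune_redundant = FALSE,
                              min_term_size = 1L, alpha = 0.05) {
  target <- unique(target); universe <- unique(universe)
  if (length(target) < 1L) stop("target must contain at least one species")
  if (!all(target %in% universe))
    stop("target must be a subset of the universe")
  unknown <- setdiff(universe, ontology$species$name)
  if (length(unknown))
    stop("universe species not in ontology: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  ann <- universe_annotation(ontology, universe)
  cands <- candidate_terms(ontology, ann, term_subset, min_term_size,
                           prune_redundant, universe = universe)
  if (!length(cands))
    return(finish_report(data.frame(term_id = character(0),
                                    mode = character(0),
                                    n_annotated = integer(0),
                                    statistic = numeric(0),
                                    p_raw = numeric(0)), ontology, alpha))
  N <- length(universe); n_t <- length(target)
  ann_c <- ann[ann$term %in% cands, ]
  K <- ann_c[, list(K = .N), by = "term"]
  a <- ann_c[ann_c$species %in% target, list(a = .N), by = "term"]
  tab <- merge(K, a, by = "term", all.x = TRUE)
  tab$a[is.na(tab$a)] <- 0L
  # one-tailed over-representation: P(X >= a) hypergeometric upper tail
  p <- stats::phyper(tab$a - 1L, tab$K, N - tab$K, n_t, lower.tail = FALSE)
  b <- n_t - tab$a; cc <- tab$K - tab$a; d <- N - tab$K - b
  odds <- (tab$a * d) / (b * cc)
  finish_report(data.frame(term_id = tab$term, mode = "target_list",
                           n_annotated = tab$K, statistic = odds,
                           p_raw = p, stringsAsFactors = FALSE),
                ontology, alpha)
}

#' Ranking-mode enrichment (one-tailed Kolmogorov-Smirnov tests)
#'
#' For every candidate term the positions of its annotated lipids in the
#' ranked list are compared with a uniform placement: the one-sided statistic
#' D+ measures over-representation of highly ranked (top) lipids, and its
#' p-value comes from the permutation null ([ks_rank_test()]). Raw p-values
#' are BH-adjusted over the family of terms tested.
#'
#' @param ranked A `ranked_list` from [rank_lipids()], with species names
#'   already matched to the ontology.
#' @inheritParams fisher_enrichment
#' @param exact_limit Passed to [ks_rank_test()].
#' @return Report data.frame as in [fisher_enrichment()] with `statistic`
#'   = D+.
#' @export
ks_enrichment <- function(ranked, ontology, term_subset = NULL,
                          prune_redundant = FALSE, min_term_size = 1L,
                          alpha = 0.05, exact_limit = 50L) {
  stopifnot(inherits(ranked, "ranked_list"))
  n <- length(ranked$species)
  if (n < 2L) stop("ranked list must contain at least 2 species")
  if (anyDuplicated(ranked$species)) stop("duplicate species in ranked list")
  unknown <- setdiff(ranked$species, ontology$species$name)
  if (length(unknown))
    stop("ranked species not in ontology: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  ann <- universe_annotation(ontology, ranked$species)
  cands <- candidate_terms(ontology, ann, term_subset, min_term_size,
                           prune_redundant, universe = ranked$species)
  pos <- stats::setNames(seq_len(n), ranked$species)
  rows <- lapply(cands, function(t) {
    sp <- ann[list(t), on = "term", nomatch = NULL]$species
    res <- ks_rank_test(unname(pos[sp]), n, exact_limit = exact_limit)
    data.frame(term_id = t, mode = "ranking", n_annotated = length(sp),
               statistic = res$statistic, p_raw = res$p_value,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(term_id = character(0), mode = character(0),
                        n_annotated = integer(0), statistic = numeric(0),
                        p_raw = numeric(0))
  finish_report(df, ontology, alpha)
}

#' Run a full enrichment analysis
#'
#' Orchestrates name matching, candidate-term selection (optional
#' restriction to the descendants of a term subset, minimum term size,
#' optional redundant-parent pruning), the mode's statistics and BH
#' correction. The significance threshold only labels rows; nothing is
#' silently filtered.
#'
#' @param mode `"target_list"` or `"ranking"`.
#' @param ontology A `lion_ontology`.
#' @param target,universe Raw lipid names for target-list mode (universe is
#'   also used as the ranking-mode input when `values` is `NULL`).
#' @param values Named numeric vector of local statistics for ranking mode
#'   (names are raw lipid names), e.g. from [local_statistic()].
#' @param statistic_name Ranking statistic label (sets default direction).
#' @param manual_direction Optional ranking direction override.
#' @param term_subset,prune_redundant,min_term_size,alpha See
#'   [fisher_enrichment()].
#' @param synonyms Class-alias table for name matching.
#' @return The report data.frame, with the `match_report`(s) attached as
#'   attribute `"match"`.
#' @export
run_enrichment <- function(mode = c("target_list", "ranking"), ontology,
                           target = NULL, universe = NULL, values = NULL,
                           statistic_name = "custom",
                           manual_direction = NULL, term_subset = NULL,
                           prune_redundant = FALSE, min_term_size = 1L,
                           alpha = 0.05, synonyms = default_synonyms()) {
  mode <- match.arg(mode)
  if (mode == "target_list") {
    stopifnot(!is.null(target), !is.null(universe))
    mu <- match_names(universe, ontology, synonyms)
    mt <- match_names(target, ontology, synonyms)
    uni <- unique(mu$mapping$canonical_name[mu$mapping$matched])
    tgt <- unique(mt$mapping$canonical_name[mt$mapping$matched])
    tgt <- intersect(tgt, uni)
    report <- fisher_enrichment(tgt, uni, ontology, term_subset,
                                prune_redundant, min_term_size, alpha)
    attr(report, "match") <- list(universe = mu$report, target = mt$report)
  } else {
    stopifnot(!is.null(values), !is.null(names(values)))
    mv <- match_names(names(values), ontology, synonyms)
    ok <- mv$mapping$matched & !duplicated(mv$mapping$canonical_name)
    matched_values <- stats::setNames(unname(values[ok]),
                                      mv$mapping$canonical_name[ok])
    ranked <- rank_lipids(matched_values, statistic_name, manual_direction)
    report <- ks_enrichment(ranked, ontology, term_subset, prune_redundant,
                            min_term_size, alpha)
    attr(report, "match") <- list(input = mv$report)
  }
  report
}

#' Write an enrichment report as CSV
#' @param report Report data.frame from the enrichment functions.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
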