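test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # order invariance
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("Fisher p equals the hypergeometric-sum oracle on all small tables", {
  # exhaustive: all 2x2 tables with universe N <= 30
  worst <- 0
  for (N in c(5L, 12L, 21L, 30L)) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (a in max(0, n + K - N):min(K, n)) {
          p_impl <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
          p_oracle <- oracle_hyper_upper(a, K, N, n)
          worst <- max(worst, abs(p_impl - p_oracle))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("target-list enrichment builds the right tables and p-values", {
  ont <- toy_ontology(2L, 4L, classes = c("PC", "PE"),
                      with_biophysics = FALSE)
  universe <- ont$species$name
  pc <- universe[startsWith(universe, "PC")]
  pe <- universe[startsWith(universe, "PE")]

  # target = all PC species: the PC class term is the top hit
  rep1 <- fisher_enrichment(pc, universe, ont)
  top <- rep1$term_id[1]
  expect_true(top %in% c("LION:CLS:Diacylglycerophosphocholines",
                         "LION:CLS:Glycerophosphocholines"))
  row <- rep1[rep1$term_id == "LION:CLS:Diacylglycerophosphocholines", ]
  expect_equal(row$n_annotated, length(pc))
  expect_equal(row$p_raw,
               oracle_hyper_upper(length(pc), length(pc),
                                  length(universe), length(pc)),
               tolerance = 1e-12)

  # a term annotating the whole universe can never be enriched
  root_rows <- rep1[rep1$term_id == "CAT:0000001", ]
  expect_equal(root_rows$p_raw, 1)

  # target = universe: no term with p_raw < 1
  rep2 <- fisher_enrichment(universe, universe, ont)
  expect_true(all(rep2$p_raw == 1))

  # frozen worked example: universe 100 (10 annotated), target 10, a = 5
  expect_equal(oracle_hyper_upper(5, 10, 100, 10), 6.716277482650501e-04,
               tolerance = 1e-12)
  expect_equal(stats::phyper(4, 10, 90, 10, lower.tail = FALSE),
               6.716277482650501e-04, tolerance = 1e-15)

  expect_error(fisher_enrichment(c(pc, "XX(1:0)"), universe, ont),
               "subset of the universe")
  expect_error(fisher_enrichment(character(0), universe, ont),
               "at least one")
})

test_that("local statistics follow their documented conventions", {
  m <- rbind(a = c(1, 2, 3, 1, 2, 3),
             b = c(4, 5, 6, 1, 2, 3),
             c = c(2, 4, 6, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  g <- rep(c("T", "C"), each = 3)

  # identical groups: one-tailed Welch p = 0.5
  p <- local_statistic(m, g, "welch_t_p", condition_of_interest = "T")
  expect_equal(unname(p["a"]), 0.5, tolerance = 1e-12)
  expect_lt(p["b"], 0.5)  # T above C: evidence in the tested direction
  # and the oracle: one-tailed p from the t distribution directly
  tt <- t.test(m["b", 1:3], m["b", 4:6], alternative = "greater")
  expect_equal(unname(p["b"]), tt$p.value, tolerance = 1e-12)

  # log2 fold change: means 2x apart -> exactly 1
  fc <- local_statistic(m, g, "log2_fold_change",
                        condition_of_interest = "T")
  expect_equal(unname(fc["c"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(fc["a"]), 0.0, tolerance = 1e-12)
  # all-zero row is flagged neutral
  m0 <- rbind(m, z = rep(0, 6))
  fc0 <- local_statistic(m0, g, "log2_fold_change",
                         condition_of_interest = "T")
  expect_equal(unname(fc0["z"]), 0)

  # ANOVA: three identical groups -> F = 0 -> p = 1
  m3 <- rbind(x = c(1, 2, 1, 2, 1, 2), y = c(1, 2, 3, 4, 5, 6))
  colnames(m3) <- paste0("s", 1:6)
  g3 <- rep(c("A", "B", "C"), each = 2)
  p3 <- local_statistic(m3, g3, "anova_f_p")
  expect_equal(unname(p3["x"]), 1, tolerance = 1e-12)
  ow <- oneway.test(m3["y", ] ~ factor(g3), var.equal = TRUE)
  expect_equal(unname(p3["y"]), ow$p.value, tolerance = 1e-12)

  expect_error(local_statistic(m, rep(c("T", "C"), 3)[1:5], "welch_t_p"),
               "length")
  expect_error(local_statistic(m[, 1:3],
                               c("T", "C", "C"), "welch_t_p"),
               ">= 2 samples")
  expect_error(local_statistic(m, g, "custom"), "named")
  expect_equal(local_statistic(m, g, "custom",
                               custom_values = c(a = 1, b = 2)),
               c(a = 1, b = 2))
})

test_that("ranking directions default by statistic and respect overrides", {
  v <- c(l1 = 0.9, l2 = 0.01, l3 = 0.5)
  r <- rank_lipids(v, "welch_t_p")
  expect_equal(r$species, c("l2", "l3", "l1"))
  expect_equal(r$direction, "low_to_high")

  r2 <- rank_lipids(v, "welch_t_p", manual_direction = "high_to_low")
  expect_equal(r2$species, rev(r$species))

  fc <- c(l1 = -2, l2 = 3, l3 = 0)
  expect_equal(rank_lipids(fc, "log2_fold_change")$species,
               c("l2", "l3", "l1"))

  # ties break deterministically by name; input order is irrelevant
  tie <- c(b = 0.5, a = 0.5, c = 0.1)
  r3 <- rank_lipids(tie, "welch_t_p")
  expect_equal(r3$species, c("c", "a", "b"))
  expect_equal(rank_lipids(tie[c(2, 3, 1)], "welch_t_p")$species,
               r3$species)
})

test_that("one-sided KS p equals the exhaustive permutation null", {
  # spec worked example: n = 5, annotated ranks {1, 2}
  res <- ks_rank_test(c(1L, 2L), 5L)
  expect_equal(res$statistic, 0.6)
  expect_equal(res$p_value, oracle_ks_pvalue(c(1, 2), 5), tolerance = 1e-12)
  expect_equal(res$p_value, 0.1)

  # exhaustive agreement for all n <= 12, all m, all placements
  worst <- 0
  for (n in 2:12) {
    for (m in 1:n) {
      subsets <- utils::combn(n, m)
      null_d <- apply(subsets, 2, oracle_dplus, n = n)
      for (j in seq_len(ncol(subsets))) {
        p_impl <- ks_rank_test(subsets[, j], n)$p_value
        p_oracle <- mean(null_d >= null_d[j] - 1e-12)
        worst <- max(worst, abs(p_impl - p_oracle))
      }
    }
  }
  expect_lt(worst, 1e-9)

  # term annotating every species: D+ = 0, p = 1
  all_res <- ks_rank_test(1:8, 8L)
  expect_equal(all_res$statistic, 0)
  expect_equal(all_res$p_value, 1)

  # moving an annotated lipid up the list never increases p
  n <- 10L
  ranks <- c(5L, 8L)
  p_prev <- ks_rank_test(ranks, n)$p_value
  for (top in 4:1) {
    p_new <- ks_rank_test(c(top, 8L), n)$p_value
    expect_lte(p_new, p_prev + 1e-12)
    p_prev <- p_new
  }
})

test_that("ranking-mode enrichment finds a top-loaded term", {
  ont <- toy_ontology(2L, 4L, classes = c("PC", "PE"),
                      with_biophysics = FALSE)
  mols <- sort(ont$species$name[ont$species$level == "molecular_species"])
  pc_first <- c(sort(mols[startsWith(mols, "PC")]),
                sort(mols[startsWith(mols, "PE")]))
  values <- stats::setNames(seq_along(pc_first), pc_first)
  ranked <- rank_lipids(values, "custom", manual_direction = "low_to_high")
  rep <- ks_enrichment(ranked, ont)
  pc_term <- "LION:CLS:Diacylglycerophosphocholines"
  expect_true(pc_term %in% rep$term_id[1:2])
  expect_gt(rep$statistic[rep$term_id == pc_term], 0.4)
  expect_lt(rep$p_raw[rep$term_id == pc_term], 0.01)
})

test_that("term-subset restriction changes the BH family but no raw p", {
  ont <- toy_ontology(2L, 4L, classes = c("PC", "PE"),
                      with_biophysics = FALSE)
  universe <- ont$species$name
  target <- universe[startsWith(universe, "PC")][1:5]
  full <- fisher_enrichment(target, universe, ont)
  slim <- fisher_enrichment(target, universe, ont,
                            term_subset = "CAT:0000100")
  # only contains-fatty-acid descendants are tested
  expect_true(all(startsWith(slim$term_id, "LION:FA:")))
  # raw p-values are identical to the unrestricted run, q-values differ
  shared <- intersect(slim$term_id, full$term_id)
  expect_equal(slim$p_raw[match(shared, slim$term_id)],
               full$p_raw[match(shared, full$term_id)], tolerance = 1e-15)
  expect_error(fisher_enrichment(target, universe, ont,
                                 term_subset = "LION:NOPE"),
               "unknown term")
})

test_that("pruning removes redundant ancestors from reports", {
  ont <- toy_ontology(1L, 3L, classes = "PC", with_biophysics = FALSE)
  universe <- ont$species$name
  target <- universe[1:3]
  parent <- "LION:CLS:Glycerophosphocholines"
  child <- "LION:CLS:Diacylglycerophosphocholines"
  unpruned <- fisher_enrichment(target, universe, ont)
  expect_true(all(c(parent, child) %in% unpruned$term_id))
  pruned <- fisher_enrichment(target, universe, ont, prune_redundant = TRUE)
  expect_false(parent %in% pruned$term_id)
  expect_true(child %in% pruned$term_id)
})

test_that("run_enrichment orchestrates matching and both modes", {
  ont <- toy_ontology(2L, 4L, classes = c("PC", "PE"),
                      with_biophysics = FALSE)
  universe <- ont$species$name
  target <- c(universe[startsWith(universe, "PC")][1:4], "junk")
  rep <- run_enrichment("target_list", ont, target = target,
                        universe = c(universe, "alsojunk"))
  m <- attr(rep, "match")
  expect_equal(m$target$n_matched, 4L)
  expect_true(m$universe$matched_fraction < 1)
  expect_true(all(c("term_id", "term_name", "branch", "mode", "n_annotated",
                    "statistic", "p_raw", "q_value", "significant")
                  %in% names(rep)))
  # significance threshold labels rows, never filters them
  expect_true(any(!rep$significant))

  vals <- stats::setNames(runif(length(universe)), universe)
  rep2 <- run_enrichment("ranking", ont, values = vals,
                         statistic_name = "welch_t_p")
  expect_equal(unique(rep2$mode), "ranking")
  expect_equal(attr(rep2, "match")$input$matched_fraction, 1.0)
})
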