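test_that("enumeration counts equal multisets with repetition", {
  rules <- lion_class_rules()
  fa <- default_fatty_acids()

  # one acyl position: one molecular species per fatty acid
  lpc <- rules[rules$class_id == "LPC", ]
  expect_equal(nrow(enumerate_species(lpc, fa)), 37L)

  # two positions over the 37-chain alphabet: C(38, 2) = 703 molecular
  pc <- rules[rules$class_id == "PC", ]
  sp <- enumerate_species(pc, fa)
  expect_equal(sum(sp$level == "molecular_species"), choose(38, 2))

  # exhaustive cross-check against a brute-force multiset listing
  for (n in c(2L, 4L, 7L, 10L)) {
    fan <- utils::head(fa, n)
    for (cls in c("LPC", "PC", "TG")) {
      k <- rules$n_acyl_positions[rules$class_id == cls]
      spn <- enumerate_species(rules[rules$class_id == cls, ], fan)
      mol <- spn$name[spn$level == "molecular_species"]
      grid <- do.call(expand.grid, rep(list(seq_len(n)), k))
      brute <- unique(apply(grid, 1, function(r)
        paste(sort(as.integer(r)), collapse = ",")))
      expect_equal(length(mol), choose(n + k - 1, k))
      expect_equal(length(mol), length(brute))
    }
  }

  expect_error(enumerate_species(pc, fa[0, ]), "non-empty")
})

test_that("a hand-enumerable PC ontology has the expected nodes", {
  rules <- lion_class_rules()
  pc <- rules[rules$class_id == "PC", ]
  fa <- default_fatty_acids()
  fa2 <- fa[fa$label %in% c("16:0", "18:1"), ]
  ont <- build_ontology(pc, fa2)
  mol <- ont$species$name[ont$species$level == "molecular_species"]
  expect_setequal(mol, c("PC(16:0_16:0)", "PC(16:0_18:1)", "PC(18:1_18:1)"))
  sums <- ont$species$name[ont$species$level == "sum_composition"]
  expect_setequal(sums, c("PC(32:0)", "PC(34:1)", "PC(36:2)"))
  # every species reaches the classification root through the closure
  root <- "CAT:0000001"
  expect_setequal(species_of_term(ont, root), ont$species$name)
})

test_that("chemical terms are inferred from names", {
  t1 <- infer_chemical_terms(parse_lipid_name("PC(16:0/18:1)"))
  expect_setequal(t1, c("LION:FA:C16:0", "LION:FA:C18:1", "LION:LEN:C34",
                        "LION:UNS:1", "LION:BOND:diacyl"))
  # sum-composition species carry no contains-fatty-acid terms
  t2 <- infer_chemical_terms(parse_lipid_name("PS(34:2)"))
  expect_setequal(t2, c("LION:LEN:C34", "LION:UNS:2"))
  # ether prefix read-off
  t3 <- infer_chemical_terms(parse_lipid_name("PC(O-34:1)"))
  expect_true("LION:BOND:ether_alkyl" %in% t3)
  t4 <- infer_chemical_terms(parse_lipid_name("PC(P-16:0/18:1)"))
  expect_true("LION:BOND:ether_alkenyl" %in% t4)
  # duplicate chains yield one contains term
  t5 <- infer_chemical_terms(parse_lipid_name("PC(16:0/16:0)"))
  expect_equal(sum(startsWith(t5, "LION:FA:")), 1L)
  # sphingoid base is not a fatty acid
  t6 <- infer_chemical_terms(parse_lipid_name("SM(d18:1/16:0)"))
  expect_setequal(grep("^LION:FA:", t6, value = TRUE), "LION:FA:C16:0")

  # the build's vectorized annotation agrees with the per-species inference
  ont <- toy_ontology(2L, 3L, with_biophysics = FALSE)
  for (nm in ont$species$name[c(1, 5, 8)]) {
    direct <- annotations_of(ont, nm, closed = FALSE)
    inferred <- infer_chemical_terms(parse_lipid_name(nm))
    expect_true(all(inferred %in% direct), label = nm)
  }
})

test_that("annotation closure contains all ancestors", {
  ont <- toy_ontology(2L, 3L)
  sp_names <- ont$species$name[c(1, 3, 7, nrow(ont$species))]
  for (nm in sp_names) {
    direct <- annotations_of(ont, nm, closed = FALSE)
    closed <- annotations_of(ont, nm, closed = TRUE)
    for (t in direct)
      expect_true(all(ancestors(ont, t) %in% closed), label = t)
  }
  # edge accounting: is_a links + direct associations
  expect_equal(ont$edge_count,
               sum(lengths(ont$parents)) + nrow(ont$direct))
})

test_that("ancestors and species_of_term follow the DAG", {
  ont <- toy_ontology(2L, 3L)
  expect_equal(ancestors(ont, "CAT:0000001"), character(0))
  # chain: contains-C12:0 -> contains fatty acid -> chemical root
  expect_setequal(ancestors(ont, "LION:FA:C12:0"),
                  c("CAT:0000100", "CAT:0000002"))
  # closure monotonicity along the classification lineage
  parent <- "LION:CLS:Glycerophosphocholines"
  child <- "LION:CLS:Diacylglycerophosphocholines"
  expect_true(all(species_of_term(ont, child) %in%
                    species_of_term(ont, parent)))
  expect_error(ancestors(ont, "LION:NOPE"), "unknown term")
  expect_error(species_of_term(ont, "LION:NOPE"), "unknown term")
})

test_that("redundant generic parents are pruned, specific terms kept", {
  ont <- toy_ontology(1L, 3L, classes = "PC", with_biophysics = FALSE)
  parent <- "LION:CLS:Glycerophosphocholines"
  child <- "LION:CLS:Diacylglycerophosphocholines"
  # single-class ontology: parent and child annotate identical species sets
  expect_setequal(species_of_term(ont, parent), species_of_term(ont, child))
  kept <- prune_redundant_parents(ont, c(parent, child))
  expect_equal(kept, child)

  # chain of three with identical sets: only the deepest survives
  gp <- "LION:CLS:Glycerophospholipids"
  kept3 <- prune_redundant_parents(ont, c(gp, parent, child))
  expect_equal(kept3, child)

  # strictly larger parent set: both kept
  ont2 <- toy_ontology(2L, 3L, classes = c("PC", "LPC"),
                       with_biophysics = FALSE)
  expect_gt(length(species_of_term(ont2, parent)),
            length(species_of_term(ont2, child)))
  expect_setequal(prune_redundant_parents(ont2, c(parent, child)),
                  c(parent, child))
})

test_that("building rejects cycles and unknown terms", {
  expect_error(
    lipidont:::compute_ancestors(c("A", "B"), list(A = "B", B = "A")),
    "cycle")
  rules <- lion_class_rules()[1, ]
  fa2 <- utils::head(default_fatty_acids(), 2)
  bad <- data.frame(species = "PC(24:0)", term = "LION:NOT:here")
  expect_error(build_ontology(rules, fa2, property_assignments = bad),
               "unknown term")
})
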