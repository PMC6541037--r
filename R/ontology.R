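# Assembly of the four-branch lipid ontology DAG: term registry, species
# annotation, ancestor closure, and redundant-parent pruning.

BRANCH_ROOTS <- c(lipid_classification = "CAT:0000001",
                  chemical_physical_properties = "CAT:0000002",
                  "function" = "CAT:0000003",
                  cellular_component = "CAT:0000004")

CHEM_SUBROOTS <- c(contains_fatty_acid = "CAT:0000100",
                   fatty_acid_length = "CAT:0000110",
                   fatty_acid_unsaturation = "CAT:0000120",
                   type_by_bond = "CAT:0000130",
                   charge_headgroup = "CAT:0000140",
                   intrinsic_curvature = "CAT:0000150",
                   transition_temperature = "CAT:0001734",
                   bilayer_thickness = "CAT:0080940",
                   lateral_diffusion = "CAT:0080950")

BOND_NAMES <- c(monoacyl = "monoacyl", diacyl = "diacyl", triacyl = "triacyl",
                ether_alkyl = "ether bond (alkyl)",
                ether_alkenyl = "vinyl ether bond (plasmalogen)",
                amide_sphingoid = "amide-linked (sphingoid backbone)",
                polyacyl = "polyacyl")

#' Category names of the quintile bins
#' @return Character vector of the five category names, in bin order.
#' @export
category_names <- function() c("very low", "low", "average", "high", "very high")

category_slug <- function(x) gsub(" ", "_", x, fixed = TRUE)

BIOPHYS_PROPERTIES <- c(transition_temperature = "LION:TT:",
                        bilayer_thickness = "LION:BT:",
                        lateral_diffusion = "LION:LD:")

BIOPHYS_LABELS <- c(transition_temperature = "transition temperature",
                    bilayer_thickness = "bilayer thickness",
                    lateral_diffusion = "lateral diffusion")

#' Term id of a biophysical category term
#' @param property One of `"transition_temperature"`, `"bilayer_thickness"`,
#'   `"lateral_diffusion"`.
#' @param category One of [category_names()].
#' @return Character term id.
#' @export
biophysics_term_id <- function(property, category) {
  prefix <- BIOPHYS_PROPERTIES[[match.arg(property,
                                          names(BIOPHYS_PROPERTIES))]]
  stopifnot(all(category %in% category_names()))
  paste0(prefix, category_slug(category))
}

slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

class_leaf_term <- function(rule_row) {
  lineage <- rule_row$classification_parents[[1]]
  paste0("LION:CLS:", slug(lineage[length(lineage)]))
}

# term registry: id, name, branch + parents list
build_term_table <- function(rules, fatty_acids, lengths, unsats, bond_types) {
  ids <- character(0); nms <- character(0); br <- character(0)
  parents <- list()
  add <- function(id, name, branch, parent) {
    if (id %in% ids) {
      parents[[id]] <<- unique(c(parents[[id]], parent))
      return(invisible(NULL))
    }
    ids <<- c(ids, id); nms <<- c(nms, name); br <<- c(br, branch)
    parents[[id]] <<- parent
  }
  add(BRANCH_ROOTS[["lipid_classification"]], "lipid classification",
      "lipid_classification", character(0))
  add(BRANCH_ROOTS[["chemical_physical_properties"]],
      "chemical and physical properties",
      "chemical_physical_properties", character(0))
  add(BRANCH_ROOTS[["function"]], "function", "function", character(0))
  add(BRANCH_ROOTS[["cellular_component"]], "cellular component",
      "cellular_component", character(0))

  # classification lineages
  for (i in seq_len(nrow(rules))) {
    lineage <- rules$classification_parents[[i]]
    parent <- BRANCH_ROOTS[["lipid_classification"]]
    for (nm in lineage) {
      id <- paste0("LION:CLS:", slug(nm))
      add(id, nm, "lipid_classification", parent)
      parent <- id
    }
  }

  # chemical / physical subtree
  chem_root <- BRANCH_ROOTS[["chemical_physical_properties"]]
  chem_names <- c(contains_fatty_acid = "contains fatty acid",
                  fatty_acid_length = "fatty acid length",
                  fatty_acid_unsaturation = "fatty acid unsaturation",
                  type_by_bond = "type by bond",
                  charge_headgroup = "charge headgroup",
                  intrinsic_curvature = "intrinsic curvature",
                  transition_temperature = "chain-melting transition temperature",
                  bilayer_thickness = "bilayer thickness",
                  lateral_diffusion = "lateral diffusion")
  for (key in names(CHEM_SUBROOTS))
    add(CHEM_SUBROOTS[[key]], chem_names[[key]],
        "chemical_physical_properties", chem_root)
  for (i in seq_len(nrow(fatty_acids)))
    add(fa_term_id(fatty_acids$label[i]),
        paste0("contains C", fatty_acids$label[i]),
        "chemical_physical_properties", CHEM_SUBROOTS[["contains_fatty_acid"]])
  for (n in sort(lengths))
    add(len_term_id(n), sprintf("total fatty acid chain length C%d", n),
        "chemical_physical_properties", CHEM_SUBROOTS[["fatty_acid_length"]])
  for (n in sort(unsats))
    add(uns_term_id(n), sprintf("total fatty acid unsaturation %d", n),
        "chemical_physical_properties",
        CHEM_SUBROOTS[["fatty_acid_unsaturation"]])
  for (b in bond_types)
    add(bond_term_id(b), BOND_NAMES[[b]],
        "chemical_physical_properties", CHEM_SUBROOTS[["type_by_bond"]])
  charge_names <- c(negative = "headgroup with negative charge",
                    positive_zwitterion = "headgroup with positive charge or zwitter-ion",
                    neutral = "headgroup with neutral charge")
  for (g in names(charge_names))
    add(paste0("LION:CHG:", g), charge_names[[g]],
        "chemical_physical_properties", CHEM_SUBROOTS[["charge_headgroup"]])
  for (g in c("negative", "neutral", "positive"))
    add(paste0("LION:CUR:", g), paste(g, "intrinsic curvature"),
        "chemical_physical_properties", CHEM_SUBROOTS[["intrinsic_curvature"]])
  for (prop in names(BIOPHYS_PROPERTIES))
    for (cat in category_names())
      add(biophysics_term_id(prop, cat),
          paste(cat, BIOPHYS_LABELS[[prop]]),
          "chemical_physical_properties", CHEM_SUBROOTS[[prop]])

  # function / component leaves from the rules
  for (f in sort(unique(unlist(rules$function_terms))))
    add(paste0("LION:FUN:", slug(f)), f, "function",
        BRANCH_ROOTS[["function"]])
  for (cc in sort(unique(unlist(rules$component_terms))))
    add(paste0("LION:COM:", slug(cc)), cc, "cellular_component",
        BRANCH_ROOTS[["cellular_component"]])

  list(terms = data.frame(id = ids, name = nms, branch = br,
                          stringsAsFactors = FALSE),
       parents = parents)
}

# ancestors (excluding self) for every term; errors on cycles
compute_ancestors <- function(ids, parents) {
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  visit <- function(id) {
    st <- state[[id]]
    if (identical(st, 2L)) return(anc[[id]])
    if (identical(st, 1L)) stop("cycle detected in ontology at term ", id)
    state[[id]] <- 1L
    ps <- parents[[id]]
    ps <- ps[!is.na(ps) & nzchar(ps)]
    out <- character(0)
    for (p in ps) out <- c(out, p, visit(p))
    out <- unique(out)
    anc[[id]] <- out
    state[[id]] <- 2L
    out
  }
  res <- vector("list", length(ids)); names(res) <- ids
  for (id in ids) res[[id]] <- visit(id)
  res
}

#' Build the lipid ontology
#'
#' Enumerates species (unless a species table is supplied), constructs the
#' four CAT-rooted branches, annotates every species with its classification
#' lineage, name-inferred chemical terms, class-level charge / curvature /
#' function / sub-cellular component terms and any supplied biophysical
#' category assignments, and precomputes the annotation closure (a species
#' annotated to a term is annotated to all of its ancestors).
#'
#' @param rules A `lipid_class_rules` table.
#' @param fatty_acids Fatty-acid alphabet; default [default_fatty_acids()].
#' @param sphingoid_bases Sphingoid backbones; default
#'   [default_sphingoid_bases()].
#' @param property_assignments Optional data.frame (`species`, `term`) of
#'   biophysical category terms, e.g. from [assign_biophysics_terms()].
#' @param species Optional pre-enumerated species table (as returned by
#'   [enumerate_species()]); enumerated from the rules when `NULL`.
#' @return A `lion_ontology` object with fields `terms`, `parents`,
#'   `species`, `direct` (direct annotations), `closed` (annotation
#'   closure), and `edge_count` (is_a links plus direct annotations).
#' @examples
#' rules <- lion_class_rules()
#' ont <- build_ontology(rules[rules$class_id %in% c("PC", "PE"), ],
#'                       utils::head(default_fatty_acids(), 3))
#' @export
build_ontology <- function(rules, fatty_acids = default_fatty_acids(),
                           sphingoid_bases = default_sphingoid_bases(),
                           property_assignments = NULL, species = NULL) {
  if (is.null(rules) || nrow(rules) == 0L) stop("rules must be non-empty")
  fa <- order_fa(fatty_acids)
  if (is.null(species))
    species <- enumerate_species(rules, fa, sphingoid_bases)
  sp <- data.table::as.data.table(species)

  # --- direct annotations (vectorized) ------------------------------------
  ann <- vector("list", 8L)

  # classification leaf per class
  leaf_by_class <- vapply(seq_len(nrow(rules)),
                          function(i) class_leaf_term(rules[i, ]), character(1))
  names(leaf_by_class) <- rules$class_id
  ann[[1]] <- data.table::data.table(
    species = sp$name, term = leaf_by_class[sp$lipid_class])

  # contains-fatty-acid terms (molecular species; sphingoid bases excluded)
  mol <- sp[sp$level == "molecular_species" & nzchar(sp$chains), ]
  if (nrow(mol)) {
    ch_list <- strsplit(mol$chains, "|", fixed = TRUE)
    lens <- lengths(ch_list)
    long <- data.table::data.table(
      species = rep(mol$name, lens), chain = unlist(ch_list))
    long <- long[!startsWith(long$chain, "d"), ]
    long$chain <- sub("^[OP]-", "", long$chain)
    long <- unique(long)
    ann[[2]] <- data.table::data.table(
      species = long$species, term = fa_term_id(long$chain))
  }

  # total length / unsaturation terms
  ann[[3]] <- data.table::data.table(
    species = sp$name, term = len_term_id(sp$total_carbons))
  ann[[4]] <- data.table::data.table(
    species = sp$name, term = uns_term_id(sp$total_double_bonds))

  # type-by-bond: molecular from chain labels, sums from the class rule
  bond_of <- function(chains, n) {
    out <- character(length(chains))
    out[grepl("O-", chains, fixed = TRUE)] <- "ether_alkyl"
    out[grepl("P-", chains, fixed = TRUE)] <- "ether_alkenyl"
    left <- !nzchar(out) & grepl("d", chains, fixed = TRUE)
    out[left] <- "amide_sphingoid"
    miss <- !nzchar(out)
    out[miss] <- c("monoacyl", "diacyl", "triacyl", "polyacyl")[
      pmin(n[miss], 4L)]
    out
  }
  if (nrow(mol)) {
    ann[[5]] <- data.table::data.table(
      species = mol$name,
      term = bond_term_id(bond_of(mol$chains, mol$n_chains)))
  }
  sums <- sp[sp$level == "sum_composition", ]
  if (nrow(sums)) {
    rule_bond <- ifelse(rules$backbone == "sphingoid", "amide_sphingoid",
                 ifelse(rules$linkage == "ether_O", "ether_alkyl",
                 ifelse(rules$linkage == "ether_P", "ether_alkenyl", "")))
    names(rule_bond) <- rules$class_id
    sb <- rule_bond[sums$lipid_class]
    keep <- nzchar(sb)
    if (any(keep))
      ann[[6]] <- data.table::data.table(
        species = sums$name[keep], term = bond_term_id(sb[keep]))
  }

  # class-level charge / curvature / function / component
  chg <- stats::setNames(paste0("LION:CHG:", rules$charge), rules$class_id)
  cur <- stats::setNames(paste0("LION:CUR:", rules$curvature), rules$class_id)
  ann[[7]] <- rbind(
    data.table::data.table(species = sp$name, term = chg[sp$lipid_class]),
    data.table::data.table(species = sp$name, term = cur[sp$lipid_class]))
  fun_com <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    ids <- c(paste0("LION:FUN:", slug(rules$function_terms[[i]])),
             paste0("LION:COM:", slug(rules$component_terms[[i]])))
    if (!length(ids)) next
    members <- sp$name[sp$lipid_class == rules$class_id[i]]
    fun_com[[i]] <- data.table::data.table(
      species = rep(members, each = length(ids)),
      term = rep(ids, times = length(members)))
  }
  ann[[8]] <- data.table::rbindlist(fun_com)

  direct <- data.table::rbindlist(ann[!vapply(ann, is.null, logical(1))])
  if (!is.null(property_assignments) && nrow(property_assignments)) {
    pa <- data.table::as.data.table(
      property_assignments[, c("species", "term")])
    if (!all(pa$species %in% sp$name))
      stop("property assignment references unknown species")
    direct <- rbind(direct, pa)
  }
  direct <- unique(direct)

  # --- term table + closure ------------------------------------------------
  reg <- build_term_table(rules, fa,
                          lengths = unique(sp$total_carbons),
                          unsats = unique(sp$total_double_bonds),
                          bond_types = intersect(
                            names(BOND_NAMES),
                            unique(sub("^LION:BOND:", "",
                                       grep("^LION:BOND:", direct$term,
                                            value = TRUE)))))
  unknown <- setdiff(unique(direct$term), reg$terms$id)
  if (length(unknown))
    stop("species references unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))

  anc <- compute_ancestors(reg$terms$id, reg$parents)
  anc_lens <- lengths(anc)
  anc_dt <- data.table::data.table(
    term = rep(names(anc), anc_lens + 1L),
    anc = unlist(lapply(names(anc), function(id) c(id, anc[[id]])),
                 use.names = FALSE))
  closed <- merge(direct, anc_dt, by = "term", allow.cartesian = TRUE)
  closed <- unique(data.table::data.table(species = closed$species,
                                          term = closed$anc))
  data.table::setkey(closed, term)
  data.table::setkey(direct, species)

  n_parent_edges <- sum(lengths(reg$parents))
  structure(
    list(terms = reg$terms, parents = reg$parents, ancestors = anc,
         species = as.data.frame(sp), direct = direct, closed = closed,
         edge_count = n_parent_edges + nrow(direct),
         rules = rules),
    class = "lion_ontology")
}

#' @export
print.lion_ontology <- function(x, ...) {
  cat(sprintf(
    "<lion_ontology> %d terms, %d species (%d molecular, %d sum), %d edges\n",
    nrow(x$terms), nrow(x$species),
    sum(x$species$level == "molecular_species"),
    sum(x$species$level == "sum_composition"), x$edge_count))
  invisible(x)
}

check_term <- function(ontology, term_id) {
  if (!term_id %in% ontology$terms$id)
    stop("unknown term: ", term_id)
}

#' Ancestors of a term
#'
#' Transitive closure over is_a parent links, excluding the term itself.
#'
#' @param ontology A `lion_ontology`.
#' @param term_id Term identifier.
#' @return Character vector of ancestor term ids (empty for branch roots).
#' @export
ancestors <- function(ontology, term_id) {
  check_term(ontology, term_id)
  ontology$ancestors[[term_id]]
}

#' Descendants of a term
#'
#' All terms having `term_id` among their ancestors.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant term ids.
#' @export
descendants <- function(ontology, term_id) {
  check_term(ontology, term_id)
  ids <- names(ontology$ancestors)
  ids[vapply(ontology$ancestors, function(a) term_id %in% a, logical(1))]
}

#' Species annotated to a term (after closure)
#'
#' @inheritParams ancestors
#' @return Character vector of species canonical names whose closed
#'   annotation set contains the term.
#' @export
species_of_term <- function(ontology, term_id) {
  check_term(ontology, term_id)
  ontology$closed[list(term_id), on = "term", nomatch = NULL]$species
}

#' Closed annotation set of a species
#'
#' @param ontology A `lion_ontology`.
#' @param species_name Canonical species name.
#' @param closed Return the ancestor-closed set (default) or only direct
#'   annotations.
#' @return Character vector of term ids.
#' @export
annotations_of <- function(ontology, species_name, closed = TRUE) {
  if (!species_name %in% ontology$species$name)
    stop("unknown species: ", species_name)
  dt <- if (closed) ontology$closed else ontology$direct
  dt[dt$species == species_name, ]$term
}

#' Drop redundant generic terms
#'
#' When an ancestor and a descendant in the candidate set annotate identical
#' species sets, the ancestor (the most generic term) is removed, so that
#' only the most specific term of each equal-annotation group is kept.
#'
#' @param ontology A `lion_ontology`.
#' @param candidate_terms Character vector of term ids (subset of the
#'   ontology's terms).
#' @param universe Optional character vector of species names; annotation
#'   sets are restricted to this universe before comparison.
#' @return Character vector: the retained subset of `candidate_terms`.
#' @export
prune_redundant_parents <- function(ontology, candidate_terms,
                                    universe = NULL) {
  stopifnot(all(candidate_terms %in% ontology$terms$id))
  if (length(candidate_terms) <= 1L) return(candidate_terms)
  sets <- lapply(candidate_terms, function(t) {
    s <- species_of_term(ontology, t)
    if (!is.null(universe)) s <- intersect(s, universe)
    sort(s)
  })
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  drop <- logical(length(candidate_terms))
  for (g in split(seq_along(candidate_terms), keys)) {
    if (length(g) < 2L) next
    for (i in g) {
      others <- setdiff(g, i)
      # drop i if it is an ancestor of any other term with the same set
      if (any(vapply(others, function(j)
        candidate_terms[i] %in% ontology$ancestors[[candidate_terms[j]]],
        logical(1))))
        drop[i] <- TRUE
    }
  }
  candidate_terms[!drop]
}
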