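# Combinatorial enumeration of lipid species from class rules and the
# fatty-acid alphabet, plus inference of chemical terms from species names.

# all multisets of size k drawn from 1..n, columns nondecreasing
multiset_indices <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 0L, ncol = 1L))
  if (n == 1L) return(matrix(rep(1L, k), nrow = k))
  m <- utils::combn(n + k - 1L, k)
  m - (seq_len(k) - 1L)
}

order_fa <- function(fa) fa[order(fa$carbons, fa$double_bonds), , drop = FALSE]

# enumerate molecular species for one class rule; returns a data.frame
enumerate_class <- function(rule, fa, bases) {
  k <- rule$n_acyl_positions
  cls <- rule$class_id
  display <- sub(" [OP]-$", "", cls)
  ether <- switch(rule$linkage, ether_O = "O-", ether_P = "P-", "")

  join <- function(mat_c, mat_d, mat_l) {
    # columns of mat_* are chains of one species, already in canonical order
    tc <- colSums(mat_c); tdb <- colSums(mat_d)
    chains <- apply(mat_l, 2, paste, collapse = "|")
    body <- apply(mat_l, 2, paste, collapse = "_")
    data.frame(name = sprintf("%s(%s)", display, body),
               lipid_class = cls, level = "molecular_species",
               total_carbons = as.integer(tc),
               total_double_bonds = as.integer(tdb),
               chains = chains, n_chains = nrow(mat_l),
               stringsAsFactors = FALSE)
  }

  if (rule$backbone == "sphingoid") {
    if (k == 1L) {
      return(data.frame(name = sprintf("%s(%s)", display, bases$label),
                        lipid_class = cls, level = "molecular_species",
                        total_carbons = bases$carbons,
                        total_double_bonds = bases$double_bonds,
                        chains = bases$label, n_chains = 1L,
                        stringsAsFactors = FALSE))
    }
    idx <- multiset_indices(nrow(fa), k - 1L)
    out <- vector("list", nrow(bases))
    for (b in seq_len(nrow(bases))) {
      mat_c <- rbind(bases$carbons[b], matrix(fa$carbons[idx], nrow = k - 1L))
      mat_d <- rbind(bases$double_bonds[b],
                     matrix(fa$double_bonds[idx], nrow = k - 1L))
      mat_l <- rbind(bases$label[b], matrix(fa$label[idx], nrow = k - 1L))
      out[[b]] <- join(mat_c, mat_d, mat_l)
    }
    return(do.call(rbind, out))
  }

  if (ether != "") {
    # one ether chain (a distinct slot, printed first) + k-1 ester chains
    idx <- multiset_indices(nrow(fa), k - 1L)
    out <- vector("list", nrow(fa))
    elab <- paste0(ether, fa$label)
    for (e in seq_len(nrow(fa))) {
      mat_c <- rbind(fa$carbons[e], matrix(fa$carbons[idx], nrow = k - 1L))
      mat_d <- rbind(fa$double_bonds[e],
                     matrix(fa$double_bonds[idx], nrow = k - 1L))
      mat_l <- rbind(elab[e], matrix(fa$label[idx], nrow = k - 1L))
      out[[e]] <- join(mat_c, mat_d, mat_l)
    }
    return(do.call(rbind, out))
  }

  idx <- multiset_indices(nrow(fa), k)
  join(matrix(fa$carbons[idx], nrow = k),
       matrix(fa$double_bonds[idx], nrow = k),
       matrix(fa$label[idx], nrow = k))
}

#' Enumerate lipid species from class rules
#'
#' For each class, emits every unordered multiset of acyl chains of the
#' class's size drawn with repetition from the fatty-acid alphabet
#' (order-collapsed: sn-positions are not distinguished), plus a
#' sum-composition layer over the distinct (total carbons, total double
#' bonds) pairs of classes with two or more positions. Sphingoid classes take
#' one sphingoid backbone plus N-acyl chains; ether classes take one
#' alkyl/alkenyl chain (a distinct slot) plus ester chains.
#'
#' @param rules A `lipid_class_rules` table ([lion_class_rules()]).
#' @param fatty_acids Fatty-acid alphabet data.frame (`carbons`,
#'   `double_bonds`, `label`); default [default_fatty_acids()].
#' @param sphingoid_bases Backbone table; default [default_sphingoid_bases()].
#' @return A data.frame of species: `name`, `lipid_class`, `level`,
#'   `total_carbons`, `total_double_bonds`, `chains` (pipe-joined chain
#'   labels, empty for sum compositions), `n_chains`.
#' @examples
#' rules <- lion_class_rules()
#' sp <- enumerate_species(rules[rules$class_id == "PC", ],
#'                         utils::head(default_fatty_acids(), 3))
#' @export
enumerate_species <- function(rules, fatty_acids = default_fatty_acids(),
                              sphingoid_bases = default_sphingoid_bases()) {
  stopifnot(nrow(rules) >= 1L)
  if (is.null(fatty_acids) || nrow(fatty_acids) == 0L)
    stop("fatty-acid alphabet must be non-empty")
  fa <- order_fa(fatty_acids)
  bases <- order_fa(sphingoid_bases)
  out <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    mol <- enumerate_class(rule, fa, bases)
    if (rule$n_acyl_positions >= 2L) {
      display <- sub(" [OP]-$", "", rule$class_id)
      prefix <- if (rule$backbone == "sphingoid") "d"
                else switch(rule$linkage, ether_O = "O-", ether_P = "P-", "")
      sums <- unique(mol[, c("total_carbons", "total_double_bonds")])
      sums <- sums[order(sums$total_carbons, sums$total_double_bonds), ]
      sum_df <- data.frame(
        name = sprintf("%s(%s%d:%d)", display, prefix,
                       sums$total_carbons, sums$total_double_bonds),
        lipid_class = rule$class_id, level = "sum_composition",
        total_carbons = sums$total_carbons,
        total_double_bonds = sums$total_double_bonds,
        chains = "", n_chains = 0L, stringsAsFactors = FALSE)
      mol <- rbind(mol, sum_df)
    }
    out[[i]] <- mol
  }
  species <- do.call(rbind, out)
  rownames(species) <- NULL
  if (anyDuplicated(species$name))
    stop("species name collision across classes: ",
         species$name[duplicated(species$name)][1])
  species
}

# term ids for the chemical/physical leaf terms (deterministic, readable)
fa_term_id <- function(label) paste0("LION:FA:C", label)
len_term_id <- function(n) sprintf("LION:LEN:C%d", n)
uns_term_id <- function(n) sprintf("LION:UNS:%d", n)
bond_term_id <- function(type) paste0("LION:BOND:", type)

bond_type_from_chains <- function(chains, n_chains) {
  if (grepl("O-", chains, fixed = TRUE)) return("ether_alkyl")
  if (grepl("P-", chains, fixed = TRUE)) return("ether_alkenyl")
  if (grepl("d", chains, fixed = TRUE)) return("amide_sphingoid")
  switch(as.character(n_chains), "1" = "monoacyl", "2" = "diacyl",
         "3" = "triacyl", "polyacyl")
}

#' Infer chemical terms from a species name
#'
#' Chemical descriptions are read off the (parsed) species name: one
#' "contains fatty acid X" term per distinct acyl chain (molecular level
#' only; sphingoid backbones are not fatty acids and contribute none), a
#' total chain-length term, a total unsaturation term, and — when the
#' linkage chemistry is visible in the name — a type-by-bond term.
#' Sum-composition species carry length and unsaturation terms but no
#' contains-fatty-acid terms.
#'
#' @param species A [lipid_species()] object.
#' @return Character vector of term ids.
#' @examples
#' infer_chemical_terms(parse_lipid_name("PC(16:0/18:1)"))
#' infer_chemical_terms(parse_lipid_name("PS(34:2)"))
#' @export
infer_chemical_terms <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  terms <- c(len_term_id(species$total_carbons),
             uns_term_id(species$total_double_bonds))
  if (species$level == "molecular_species") {
    labs <- vapply(species$acyls, function(a) {
      if (a$linkage == "sphingoid_d") NA_character_
      else sprintf("%d:%d", a$carbons, a$double_bonds)
    }, character(1))
    labs <- unique(labs[!is.na(labs)])
    chains <- paste(vapply(species$acyls, format, character(1)),
                    collapse = "|")
    terms <- c(terms, fa_term_id(labs),
               bond_term_id(bond_type_from_chains(chains,
                                                  length(species$acyls))))
  } else {
    if (species$sphingoid_sum)
      terms <- c(terms, bond_term_id("amide_sphingoid"))
    else if (species$ether_sum == "O-")
      terms <- c(terms, bond_term_id("ether_alkyl"))
    else if (species$ether_sum == "P-")
      terms <- c(terms, bond_term_id("ether_alkenyl"))
  }
  unname(terms)
}
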