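# Lipid shorthand nomenclature: parsing, canonicalization, ontology matching.

#' Construct a fatty acyl chain
#'
#' A fatty acyl is described by its carbon count, number of double bonds and
#' linkage chemistry. Sphingoid bases (the `sphingoid_d` linkage, shorthand
#' prefix "d") are restricted to the supported backbones d18:0 (sphinganine)
#' and d18:1 (sphingosine).
#'
#' @param carbons Integer number of chain carbons (>= 2).
#' @param double_bonds Integer number of double bonds (>= 0, < carbons).
#' @param linkage One of `"ester"`, `"ether_O"` (alkyl ether), `"ether_P"`
#'   (vinyl ether / plasmalogen) or `"sphingoid_d"`.
#' @param hydroxyl_count Integer; 0 for plain acyls, 2 for "d"-prefixed
#'   sphingoid bases (the dihydroxy backbone encoded by the prefix).
#' @return An object of class `fatty_acyl`.
#' @examples
#' fatty_acyl(16, 0)
#' fatty_acyl(18, 1, linkage = "sphingoid_d")
#' @export
fatty_acyl <- function(carbons, double_bonds,
                       linkage = c("ester", "ether_O", "ether_P", "sphingoid_d"),
                       hydroxyl_count = NULL) {
  linkage <- match.arg(linkage)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2L)
    stop("fatty acyl must have at least 2 carbons")
  if (is.na(double_bonds) || double_bonds < 0L || double_bonds >= carbons)
    stop("double bond count must satisfy 0 <= db < carbons")
  if (linkage == "sphingoid_d" &&
      (carbons != 18L || !double_bonds %in% c(0L, 1L)))
    stop("supported sphingoid backbones are d18:0 and d18:1")
  if (is.null(hydroxyl_count))
    hydroxyl_count <- if (linkage == "sphingoid_d") 2L else 0L
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         linkage = linkage, hydroxyl_count = as.integer(hydroxyl_count)),
    class = "fatty_acyl"
  )
}

#' @export
format.fatty_acyl <- function(x, ...) {
  prefix <- switch(x$linkage,
    ester = "", ether_O = "O-", ether_P = "P-", sphingoid_d = "d")
  sprintf("%s%d:%d", prefix, x$carbons, x$double_bonds)
}

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<fatty_acyl>", format(x), "\n")
  invisible(x)
}

# Sort order for acyl chains inside a canonical name: the sphingoid base (for
# sphingolipids) or the ether chain (for ether classes) is pinned first; the
# remaining chains are ordered by carbons ascending, then double bonds
# ascending. sn-positions are deliberately not distinguished.
sort_acyls <- function(acyls) {
  if (length(acyls) <= 1L) return(acyls)
  pinned <- vapply(acyls, function(a)
    a$linkage %in% c("sphingoid_d", "ether_O", "ether_P"), logical(1))
  rest <- acyls[!pinned]
  if (length(rest) > 1L) {
    keys <- vapply(rest, function(a)
      a$carbons * 1000L + a$double_bonds, integer(1))
    rest <- rest[order(keys)]
  }
  c(acyls[pinned], rest)
}

#' Construct a lipid species
#'
#' A lipid species is either a *molecular species* (individual acyl chains
#' known, e.g. PC(16:0_18:1)) or a *sum composition* (only total carbons and
#' total double bonds known, e.g. PS(34:2)). Acyl chains are stored in
#' canonical order; sn-positions are not distinguished.
#'
#' @param lipid_class Class identifier (e.g. `"PC"`, `"SM"`, `"TG"`,
#'   `"PC O-"`).
#' @param acyls For molecular species, a list of [fatty_acyl()] objects.
#'   `NULL` for sum compositions.
#' @param total_carbons,total_double_bonds For sum compositions, the summed
#'   chain composition. Ignored (recomputed) when `acyls` is given.
#' @param sphingoid_sum Logical; `TRUE` when a sum composition includes a
#'   sphingoid backbone (rendered with the "d" prefix, e.g. SM(d34:1)).
#' @param ether_sum `""`, `"O-"` or `"P-"` for ether sum compositions.
#' @return An object of class `lipid_species` with fields `lipid_class`,
#'   `level`, `acyls`, `total_carbons`, `total_double_bonds` and
#'   `canonical_name`.
#' @examples
#' lipid_species("PC", acyls = list(fatty_acyl(18, 1), fatty_acyl(16, 0)))
#' lipid_species("PS", total_carbons = 34, total_double_bonds = 2)
#' @export
lipid_species <- function(lipid_class, acyls = NULL,
                          total_carbons = NULL, total_double_bonds = NULL,
                          sphingoid_sum = FALSE, ether_sum = "") {
  if (!is.null(acyls) && length(acyls)) {
    stopifnot(all(vapply(acyls, inherits, logical(1), "fatty_acyl")))
    acyls <- sort_acyls(acyls)
    level <- "molecular_species"
    total_carbons <- sum(vapply(acyls, `[[`, integer(1), "carbons"))
    total_double_bonds <- sum(vapply(acyls, `[[`, integer(1), "double_bonds"))
    sphingoid_sum <- any(vapply(acyls, function(a)
      a$linkage == "sphingoid_d", logical(1)))
    eth <- vapply(acyls, `[[`, character(1), "linkage")
    ether_sum <- if (any(eth == "ether_O")) "O-"
                 else if (any(eth == "ether_P")) "P-" else ""
  } else {
    acyls <- list()
    level <- "sum_composition"
    total_carbons <- as.integer(total_carbons)
    total_double_bonds <- as.integer(total_double_bonds)
    if (is.na(total_carbons) || total_carbons < 2L ||
        is.na(total_double_bonds) || total_double_bonds < 0L)
      stop("sum composition requires total_carbons >= 2, total_double_bonds >= 0")
  }
  sp <- structure(
    list(lipid_class = lipid_class, level = level, acyls = acyls,
         total_carbons = total_carbons,
         total_double_bonds = total_double_bonds,
         sphingoid_sum = isTRUE(sphingoid_sum), ether_sum = ether_sum,
         canonical_name = NA_character_),
    class = "lipid_species"
  )
  sp$canonical_name <- canonical_name(sp)
  sp
}

#' Canonical name of a lipid species
#'
#' Molecular-species names list the chains inside parentheses joined by "_",
#' with the sphingoid base (or ether chain) first and the remaining acyls
#' ordered by chain length then unsaturation, both ascending. Sum-composition
#' names render `CLASS(tc:tdb)`, with a "d" prefix for sphingoid classes and
#' an "O-"/"P-" prefix for ether classes. The function is idempotent: parsing
#' a canonical name and re-canonicalizing returns the same string.
#'
#' @param species A [lipid_species()] object.
#' @return A single character string.
#' @examples
#' canonical_name(parse_lipid_name("PC(18:1/16:0)"))  # "PC(16:0_18:1)"
#' @export
canonical_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  # ether classes carry an " O-"/" P-" suffix in the class id; the rendered
  # name places that marker on the chain (molecular) or composition (sum)
  display <- sub(" [OP]-$", "", species$lipid_class)
  if (species$level == "molecular_species") {
    chains <- vapply(species$acyls, format, character(1))
    sprintf("%s(%s)", display, paste(chains, collapse = "_"))
  } else {
    prefix <- if (species$sphingoid_sum) "d" else species$ether_sum
    sprintf("%s(%s%d:%d)", display, prefix,
            species$total_carbons, species$total_double_bonds)
  }
}

#' @export
format.lipid_species <- function(x, ...) x$canonical_name

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s [%s, class %s, C%d:%d]\n",
              x$canonical_name, x$level, x$lipid_class,
              x$total_carbons, x$total_double_bonds))
  invisible(x)
}

unmatched_flag <- function(raw, reason) {
  structure(list(raw = raw, reason = reason), class = "lipid_unmatched")
}

#' @export
print.lipid_unmatched <- function(x, ...) {
  cat(sprintf("<unmatched lipid name> %s (%s)\n", x$raw, x$reason))
  invisible(x)
}

#' Test whether a parse result is an unmatched flag
#' @param x Result of [parse_lipid_name()].
#' @return Logical scalar.
#' @export
is_unmatched <- function(x) inherits(x, "lipid_unmatched")

#' Default class-synonym table
#'
#' Maps common alternative class abbreviations onto the canonical identifiers
#' used by the shipped class rules. Matching is case-sensitive.
#'
#' @return Named character vector (names are aliases, values canonical ids).
#' @export
default_synonyms <- function() {
  c(TAG = "TG", DAG = "DG", MAG = "MG",
    LysoPC = "LPC", LysoPE = "LPE", LysoPS = "LPS", LysoPG = "LPG",
    LysoPI = "LPI", LysoPA = "LPA",
    LPtdCho = "LPC", PtdCho = "PC", PtdEtn = "PE", PtdSer = "PS",
    PtdGro = "PG", PtdIns = "PI",
    GlcCer = "HexCer", GalCer = "HexCer", LacCer = "Hex2Cer",
    ChE = "CE", CholE = "CE", "Cholesteryl ester" = "CE",
    Sph = "SPH", So = "SPH", Sa1P = "S1P",
    ST = "SHexCer")
}

# one chain token like "16:0", "d18:1", "O-16:0", "P-18:0"
parse_chain <- function(token) {
  m <- regmatches(token, regexec("^(d|O-|P-)?([0-9]+):([0-9]+)$", token))[[1]]
  if (!length(m)) return(NULL)
  linkage <- switch(m[2], "d" = "sphingoid_d", "O-" = "ether_O",
                    "P-" = "ether_P", "ester")
  carbons <- as.integer(m[3]); db <- as.integer(m[4])
  if (carbons < 2L || db >= carbons) return(NULL)
  if (linkage == "sphingoid_d" && (carbons != 18L || !db %in% c(0L, 1L)))
    return("bad_sphingoid")
  fatty_acyl(carbons, db, linkage)
}

#' Parse a lipid shorthand name
#'
#' Supported dialects (an explicit whitelist): class abbreviation plus sum
#' composition with or without parentheses (`PC(34:1)`, `PC 34:1`);
#' molecular species with `/`, `_` or space separators (`PC(16:0/18:1)`,
#' `PC 16:0_18:1`); sphingoid "d" prefixes (`SM(d18:1/16:0)`); ether "O-"
#' and "P-" prefixes (`PC(O-34:1)`, `PE(P-16:0/20:4)`). Class abbreviations
#' are case-sensitive; common aliases are resolved through a synonym table.
#' Anything outside the whitelist yields an explicit unmatched flag carrying
#' a reason — never a silent guess.
#'
#' @param raw A single non-empty character string.
#' @param synonyms Named character vector of class aliases
#'   (default [default_synonyms()]).
#' @return A [lipid_species()] on success, otherwise a `lipid_unmatched`
#'   flag (test with [is_unmatched()]).
#' @examples
#' parse_lipid_name("PS(34:2)")
#' parse_lipid_name("SM(d18:1/16:0)")
#' is_unmatched(parse_lipid_name("notalipid"))
#' @export
parse_lipid_name <- function(raw, synonyms = default_synonyms()) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) ||
      !nzchar(trimws(raw)))
    stop("lipid name must be a single non-empty string")
  txt <- trimws(raw)

  # CLASS(BODY) | CLASS BODY | CLASS-BODY where CLASS may contain an
  # embedded ether suffix ("PC O-")
  m <- regmatches(txt, regexec(
    "^([A-Za-z][A-Za-z0-9]*[A-Za-z0-9]?(?: [OP]-)?)[ (]\\s*([^()]+?)\\s*\\)?$",
    txt))[[1]]
  if (!length(m)) {
    # compact form like "PC34:1" is not whitelisted
    return(unmatched_flag(raw, "does not match any supported dialect"))
  }
  cls <- trimws(m[2]); body <- m[3]
  if (!is.null(synonyms) && cls %in% names(synonyms))
    cls <- unname(synonyms[[cls]])

  tokens <- strsplit(body, "[/_ ]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    return(unmatched_flag(raw, "empty composition"))

  if (length(tokens) == 1L) {
    tok <- tokens[1]
    mm <- regmatches(tok, regexec("^(d|O-|P-)?([0-9]+):([0-9]+)$", tok))[[1]]
    if (!length(mm))
      return(unmatched_flag(raw, sprintf("unparseable composition '%s'", tok)))
    prefix <- mm[2]
    tc <- as.integer(mm[3]); tdb <- as.integer(mm[4])
    if (tc < 2L || tdb < 0L || tdb >= tc)
      return(unmatched_flag(raw, "implausible carbon/double-bond counts"))
    # A single chain token is a sum composition at the class level; for
    # 1-chain classes the two coincide and the sum rendering is canonical.
    if (prefix %in% c("O-", "P-")) {
      cls2 <- sub(" [OP]-$", "", cls)
      return(lipid_species(paste(cls2, paste0(substr(prefix, 1, 1), "-")),
                           total_carbons = tc, total_double_bonds = tdb,
                           ether_sum = prefix))
    }
    if (grepl(" O-$| P-$", cls)) {
      eth <- sub("^.* ", "", cls)
      return(lipid_species(cls, total_carbons = tc, total_double_bonds = tdb,
                           ether_sum = eth))
    }
    return(lipid_species(cls, total_carbons = tc, total_double_bonds = tdb,
                         sphingoid_sum = identical(prefix, "d")))
  }

  # molecular species: parse each chain
  acyls <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    ch <- parse_chain(tokens[i])
    if (is.null(ch))
      return(unmatched_flag(raw,
        sprintf("unparseable composition '%s'", tokens[i])))
    if (identical(ch, "bad_sphingoid"))
      return(unmatched_flag(raw,
        "unsupported sphingoid base (supported: d18:0, d18:1)"))
    acyls[[i]] <- ch
  }
  n_sph <- sum(vapply(acyls, function(a) a$linkage == "sphingoid_d", logical(1)))
  n_eth <- sum(vapply(acyls, function(a)
    a$linkage %in% c("ether_O", "ether_P"), logical(1)))
  if (n_sph > 1L)
    return(unmatched_flag(raw, "more than one sphingoid base"))
  if (n_eth > 1L)
    return(unmatched_flag(raw, "more than one ether chain"))
  # an ether chain folds into the class id ("PC O-"), mirroring LIPID MAPS
  if (n_eth == 1L && !grepl(" [OP]-$", cls)) {
    eth <- vapply(acyls, `[[`, character(1), "linkage")
    suffix <- if (any(eth == "ether_O")) "O-" else "P-"
    cls <- paste(cls, suffix)
  }
  lipid_species(cls, acyls = acyls)
}

#' Match raw lipid names against an ontology
#'
#' Each name is parsed and canonicalized, then looked up among the
#' ontology's species. Molecular-species names absent from the ontology fall
#' back to their sum-composition species. Duplicate names (after
#' canonicalization) map to the same node. Unmatched names never abort the
#' analysis; they are excluded and reported.
#'
#' @param raw_names Non-empty character vector of lipid names.
#' @param ontology A `lion_ontology` (see [build_ontology()]).
#' @param synonyms Class-alias table passed to [parse_lipid_name()].
#' @return A list with `mapping` (data.frame: raw_name, canonical_name,
#'   matched, reason) and `report` (a `match_report`: `n_input`,
#'   `n_matched`, `matched_fraction`, `unmatched_names`).
#' @export
match_names <- function(raw_names, ontology, synonyms = default_synonyms()) {
  stopifnot(inherits(ontology, "lion_ontology"))
  if (!is.character(raw_names) || length(raw_names) == 0L)
    stop("raw_names must be a non-empty character vector")
  known <- ontology$species$name
  canon <- character(length(raw_names))
  matched <- logical(length(raw_names))
  reason <- rep(NA_character_, length(raw_names))
  for (i in seq_along(raw_names)) {
    sp <- tryCatch(parse_lipid_name(raw_names[i], synonyms = synonyms),
                   error = function(e) unmatched_flag(raw_names[i],
                                                      conditionMessage(e)))
    if (is_unmatched(sp)) {
      canon[i] <- NA_character_; reason[i] <- sp$reason
      next
    }
    cn <- sp$canonical_name
    if (cn %in% known) {
      canon[i] <- cn; matched[i] <- TRUE
    } else if (sp$level == "molecular_species") {
      # fall back to the sum-composition species of the same class
      sum_sp <- lipid_species(sp$lipid_class,
                              total_carbons = sp$total_carbons,
                              total_double_bonds = sp$total_double_bonds,
                              sphingoid_sum = sp$sphingoid_sum,
                              ether_sum = sp$ether_sum)
      if (sum_sp$canonical_name %in% known) {
        canon[i] <- sum_sp$canonical_name; matched[i] <- TRUE
        reason[i] <- "matched via sum-composition fallback"
      } else {
        canon[i] <- NA_character_
        reason[i] <- "species not in ontology"
      }
    } else {
      canon[i] <- NA_character_
      reason[i] <- "species not in ontology"
    }
  }
  mapping <- data.frame(raw_name = raw_names, canonical_name = canon,
                        matched = matched, reason = reason,
                        stringsAsFactors = FALSE)
  report <- structure(
    list(n_input = length(raw_names), n_matched = sum(matched),
         matched_fraction = if (length(raw_names)) sum(matched) / length(raw_names) else NA_real_,
         unmatched_names = raw_names[!matched]),
    class = "match_report")
  list(mapping = mapping, report = report)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d/%d names matched (%.1f%%)\n",
              x$n_matched, x$n_input, 100 * x$matched_fraction))
  if (length(x$unmatched_names))
    cat("  unmatched:", paste(utils::head(x$unmatched_names, 10),
                              collapse = ", "),
        if (length(x$unmatched_names) > 10) "..." else "", "\n")
  invisible(x)
}

#' Read a plain-text lipid name list
#'
#' One name per line; blank lines and lines starting with "#" are ignored.
#'
#' @param path Path to a UTF-8 text file.
#' @return Character vector of names.
#' @export
read_name_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a match report as CSV
#'
#' @param match Result of [match_names()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(match, path) {
  utils::write.csv(match$mapping, path, row.names = FALSE, na = "")
  invisible(path)
}
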