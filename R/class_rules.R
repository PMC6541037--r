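# Lipid class rules and the fatty-acid alphabet driving species enumeration.

#' The default fatty-acid alphabet
#'
#' The 37 acyl chains used to enumerate molecular species: saturated and
#' unsaturated chains from C12 to C26 as found across mammalian lipidomes
#' (C12:0, C14:0-C14:1, C16:0-C16:1, C18:0-C18:3, C20:0-C20:5, C22:0-C22:6,
#' C24:0-C24:6, C26:0-C26:7).
#'
#' @return A data.frame with columns `carbons`, `double_bonds`, `label`.
#' @export
default_fatty_acids <- function() {
  spec <- list(c(12L, 0L), c(14L, 1L), c(16L, 1L), c(18L, 3L),
               c(20L, 5L), c(22L, 6L), c(24L, 6L), c(26L, 7L))
  carbons <- integer(0); db <- integer(0)
  for (s in spec) {
    carbons <- c(carbons, rep(s[1], s[2] + 1L))
    db <- c(db, 0L:s[2])
  }
  data.frame(carbons = carbons, double_bonds = db,
             label = sprintf("%d:%d", carbons, db),
             stringsAsFactors = FALSE)
}

#' The default sphingoid backbones
#'
#' Sphingosine (d18:1) and sphinganine (d18:0).
#'
#' @return A data.frame with columns `carbons`, `double_bonds`, `label`.
#' @export
default_sphingoid_bases <- function() {
  data.frame(carbons = c(18L, 18L), double_bonds = c(0L, 1L),
             label = c("d18:0", "d18:1"), stringsAsFactors = FALSE)
}

#' Load lipid class rules
#'
#' Class rules define, per lipid class, how many acyl positions it has, its
#' backbone and linkage chemistry, its classification lineage and its
#' class-level headgroup charge, intrinsic curvature, function and
#' sub-cellular component assignments. The shipped table
#' (`inst/extdata/lipid_class_rules.csv`) is a versioned, editable CSV; users
#' may pass their own.
#'
#' @param path Path to a rules CSV. Defaults to the shipped table.
#' @return A data.frame of class `lipid_class_rules`; list-columns
#'   `classification_parents`, `function_terms` and `component_terms` hold
#'   the parsed multi-valued fields.
#' @export
lion_class_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lipid_class_rules.csv",
                        package = "lipidont", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("class_id", "class_name", "n_acyl_positions", "backbone",
                "linkage", "lineage", "charge", "curvature",
                "function_terms", "component_terms")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("rules CSV lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$class_id))
    stop("duplicate class_id in rules CSV")
  stopifnot(all(df$n_acyl_positions >= 0L),
            all(df$backbone %in% c("glycerol", "sphingoid", "sterol", "none")),
            all(df$linkage %in% c("ester", "ether_O", "ether_P")),
            all(df$charge %in% c("negative", "positive_zwitterion", "neutral")),
            all(df$curvature %in% c("negative", "neutral", "positive")))
  split_field <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                    function(v) trimws(v[nzchar(trimws(v))]))
  df$classification_parents <- strsplit(df$lineage, ">", fixed = TRUE)
  df$function_terms <- split_field(df$function_terms)
  df$component_terms <- split_field(df$component_terms)
  class(df) <- c("lipid_class_rules", class(df))
  df
}
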