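# Minimal OBO 1.2 reader/writer (format-version header, [Term] stanzas with
# id / name / namespace / is_a lines). The reader validates acyclicity.

#' Write an ontology to an OBO 1.2 file
#'
#' Emits a `format-version: 1.2` header followed by one `[Term]` stanza per
#' term (`id`, `name`, `namespace`, `is_a` lines). With
#' `include_species = TRUE`, species are written as additional terms whose
#' `is_a` lines are their direct annotations.
#'
#' @param ontology A `lion_ontology`, or any list with `terms`
#'   (id/name/branch data.frame) and `parents` (named list).
#' @param path Output file path.
#' @param include_species Write species stanzas as well (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path, include_species = FALSE) {
  terms <- ontology$terms
  parents <- ontology$parents
  name_of <- stats::setNames(terms$name, terms$id)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: lion", ""), con)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    lines <- c("[Term]", paste0("id: ", id),
               paste0("name: ", terms$name[i]),
               paste0("namespace: ", terms$branch[i]))
    for (p in parents[[id]])
      lines <- c(lines, sprintf("is_a: %s ! %s", p, name_of[[p]]))
    writeLines(c(lines, ""), con)
  }
  if (include_species && !is.null(ontology$species)) {
    direct <- ontology$direct
    by_sp <- split(direct$term, direct$species)
    for (sname in ontology$species$name) {
      lines <- c("[Term]", paste0("id: ", sname),
                 paste0("name: ", sname), "namespace: species")
      for (p in by_sp[[sname]])
        lines <- c(lines, sprintf("is_a: %s ! %s", p,
                                  if (p %in% names(name_of)) name_of[[p]] else p))
      writeLines(c(lines, ""), con)
    }
  }
  invisible(path)
}

#' Read an OBO file into an ontology skeleton
#'
#' Parses `[Term]` stanzas (id, name, namespace, is_a) and validates that the
#' is_a graph is acyclic. Trailing `! comment` parts of is_a lines are
#' stripped. Returns a skeleton (terms plus parent links, no species layer)
#' suitable for round-tripping with [write_obo()].
#'
#' @param path Path to an OBO file.
#' @return A list of class `obo_skeleton` with `terms` (data.frame: id,
#'   name, branch) and `parents` (named list), plus `ancestors`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- character(0); nms <- character(0); ns <- character(0)
  parents <- list()
  in_term <- FALSE
  cur_id <- NA_character_; cur_name <- NA_character_
  cur_ns <- NA_character_; cur_parents <- character(0)
  flush <- function(lineno) {
    if (!in_term) return(invisible(NULL))
    if (is.na(cur_id))
      stop("malformed [Term] stanza (missing id) before line ", lineno)
    ids <<- c(ids, cur_id)
    nms <<- c(nms, if (is.na(cur_name)) cur_id else cur_name)
    ns <<- c(ns, if (is.na(cur_ns)) "" else cur_ns)
    parents[[cur_id]] <<- cur_parents
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      flush(i)
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_; cur_name <- NA_character_
      cur_ns <- NA_character_; cur_parents <- character(0)
      next
    }
    if (!in_term) {
      if (!grepl("^[A-Za-z0-9_-]+:", line))
        stop("malformed header line ", i, ": ", line)
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (!length(m)) stop("malformed stanza line ", i, ": ", line)
    key <- m[2]; value <- m[3]
    if (key == "id") cur_id <- value
    else if (key == "name") cur_name <- value
    else if (key == "namespace") cur_ns <- value
    else if (key == "is_a")
      cur_parents <- c(cur_parents, trimws(sub("!.*$", "", value)))
  }
  flush(length(lines) + 1L)
  if (!length(ids)) stop("no [Term] stanzas found in ", path)
  if (anyDuplicated(ids)) stop("duplicate term id: ", ids[duplicated(ids)][1])
  miss <- setdiff(unique(unlist(parents)), ids)
  if (length(miss))
    stop("is_a references unknown term(s): ", paste(miss, collapse = ", "))
  anc <- compute_ancestors(ids, parents)  # errors on cycles
  structure(list(terms = data.frame(id = ids, name = nms, branch = ns,
                                    stringsAsFactors = FALSE),
                 parents = parents, ancestors = anc),
            class = "obo_skeleton")
}
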