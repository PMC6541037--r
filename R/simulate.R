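# Synthetic fixture generation: toy ontologies, property training tables,
# reference lipidomes and abundance matrices with planted enrichments. All
# generators are deterministic given (parameters, seed).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Build a small but structurally complete toy ontology
#'
#' Uses the first `n_classes` classes of the shipped rule table (preferring
#' a mix of glycerophospholipid and sphingolipid classes) and a reduced
#' fatty-acid alphabet, with biophysical category terms assigned from
#' noiseless synthetic training models. All four CAT-rooted branches and
#' both species layers are present.
#'
#' @param n_classes Number of lipid classes (>= 1).
#' @param fatty_acid_subset Fatty-acid alphabet rows to use; default the
#'   first 3 entries of [default_fatty_acids()].
#' @param classes Optional explicit class ids, overriding the preference
#'   order c("PC", "PE", "PS", "SM", "TG", "PG", ...).
#' @param with_biophysics Assign biophysical category terms (default TRUE).
#' @return A `lion_ontology`.
#' @export
make_toy_ontology <- function(n_classes = 2L,
                              fatty_acid_subset = utils::head(default_fatty_acids(), 3L),
                              classes = NULL, with_biophysics = TRUE) {
  stopifnot(n_classes >= 1L)
  rules <- lion_class_rules()
  if (is.null(classes)) {
    preference <- c("PC", "PE", "PS", "SM", "TG", "PG", "PI", "PA", "Cer",
                    "DG", "LPC", "CE")
    preference <- c(preference, setdiff(rules$class_id, preference))
    classes <- preference[seq_len(min(n_classes, nrow(rules)))]
  }
  rules <- rules[match(classes, rules$class_id), ]
  if (anyNA(rules$class_id)) stop("unknown class id requested")
  ont <- build_ontology(rules, fatty_acid_subset)
  if (with_biophysics) {
    trained <- intersect(c("PC", "PE", "PS", "PG", "PA", "SM"), classes)
    if (length(trained) >= 1L) {
      models <- list(
        transition_temperature = fit_property_model(
          make_property_training(trained, beta_length = 4,
                                 beta_unsaturation = -30, noise_sd = 0,
                                 n = 40, seed = 101, intercept = -90),
          "transition_temperature", units = "degC"),
        lateral_diffusion = fit_property_model(
          make_property_training(trained, beta_length = -0.6,
                                 beta_unsaturation = 1.2, noise_sd = 0,
                                 n = 40, seed = 102, intercept = 35),
          "lateral_diffusion", units = "um^2/s"))
      preds <- lapply(models, predict_property, species = ont$species)
      limits <- list()
      for (p in names(models)) {
        v <- preds[[p]][!is.na(preds[[p]])]
        if (length(unique(v)) >= 5L)
          limits[[p]] <- derive_limits(v, p)
      }
      models <- models[names(limits)]
      if (length(models)) {
        pa <- assign_biophysics_terms(ont, models, limits)
        ont <- build_ontology(rules, fatty_acid_subset,
                              property_assignments = pa,
                              species = ont$species)
      }
    }
  }
  ont
}

#' Generate a synthetic property training table
#'
#' Records are drawn from the stated linear model
#' `value = intercept + class_offset + beta_length * chain_length +
#' beta_unsaturation * unsaturation + N(0, noise_sd)`, with chain lengths
#' sampled from even totals 24-44 and unsaturations 0-6. The generating
#' truth is stored in the `"truth"` attribute for recovery tests.
#'
#' @param classes Character vector of class ids.
#' @param beta_length,beta_unsaturation True slopes.
#' @param noise_sd Gaussian noise standard deviation (0 for noiseless).
#' @param n Number of records (>= 10).
#' @param seed RNG seed (fixed seed implies a reproducible table).
#' @param intercept True intercept (reference class).
#' @param class_offsets Optional named offsets (reference = first class,
#'   offset 0); defaults to evenly spaced offsets 0, 5, 10, ...
#' @return Training data.frame (`lipid_class`, `chain_length`,
#'   `unsaturation`, `value`) with attribute `"truth"`.
#' @export
make_property_training <- function(classes, beta_length = 2,
                                   beta_unsaturation = -5, noise_sd = 1,
                                   n = 50L, seed = 1L, intercept = 0,
                                   class_offsets = NULL) {
  stopifnot(n >= 10L, length(classes) >= 1L)
  classes <- sort(unique(classes))
  if (is.null(class_offsets))
    class_offsets <- stats::setNames(5 * (seq_along(classes) - 1), classes)
  stopifnot(all(classes %in% names(class_offsets)))
  with_local_seed(seed, {
    cls <- sample(classes, n, replace = TRUE)
    len <- sample(seq(24L, 44L, by = 2L), n, replace = TRUE)
    uns <- sample(0L:6L, n, replace = TRUE)
    value <- intercept + unname(class_offsets[cls]) + beta_length * len +
      beta_unsaturation * uns + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(lipid_class = cls, chain_length = len,
                      unsaturation = uns, value = value,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(intercept = intercept,
                               class_offsets = class_offsets,
                               beta_length = beta_length,
                               beta_unsaturation = beta_unsaturation,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Describe a planted enrichment
#'
#' @param planted_term Term id whose annotated lipids receive the effect.
#' @param effect_size Multiplicative abundance shift (> 0; 1 = null).
#' @param affected_condition Condition label receiving the shift.
#' @param seed Integer seed; a fixed seed yields a byte-identical fixture.
#' @return A `planted_truth` list.
#' @export
planted_truth <- function(planted_term, effect_size = 4,
                          affected_condition = "treated", seed = 1L) {
  stopifnot(effect_size > 0)
  structure(list(planted_term = planted_term, effect_size = effect_size,
                 affected_condition = affected_condition,
                 seed = as.integer(seed)),
            class = "planted_truth")
}

#' Simulate an abundance matrix with a planted enrichment
#'
#' Molecular species of the ontology are given log-normal baseline
#' abundances (per-lipid mean levels with sigma_log = 1, replicate noise
#' sigma_log = 0.25); lipids annotated to the planted term are multiplied by
#' `effect_size` in the affected condition; cells are masked at
#' `missing_rate`. Everything is reproducible from (parameters, seed).
#'
#' @param ontology A `lion_ontology`.
#' @param n_samples_per_condition Samples per condition (default 3).
#' @param conditions Character vector of >= 2 condition labels.
#' @param planted A [planted_truth()]; its term must annotate >= 5 of the
#'   measured (molecular-level) species.
#' @param missing_rate Fraction of cells masked at random (default 0).
#' @return List: `matrix` (lipids x samples), `groups` (condition label per
#'   column), `truth` (the `planted_truth`).
#' @export
make_abundance_matrix <- function(ontology, n_samples_per_condition = 3L,
                                  conditions = c("control", "treated"),
                                  planted = planted_truth("LION:CHG:negative"),
                                  missing_rate = 0) {
  stopifnot(length(conditions) >= 2L, n_samples_per_condition >= 1L,
            missing_rate >= 0, missing_rate < 1)
  lipids <- ontology$species$name[
    ontology$species$level == "molecular_species"]
  annotated <- intersect(species_of_term(ontology, planted$planted_term),
                         lipids)
  if (length(annotated) < 5L)
    stop("planted term annotates fewer than 5 measured species")
  if (!planted$affected_condition %in% conditions)
    stop("affected_condition must be one of the conditions")
  n_l <- length(lipids)
  n_s <- length(conditions) * n_samples_per_condition
  groups <- rep(conditions, each = n_samples_per_condition)
  with_local_seed(planted$seed, {
    meanlog <- stats::rnorm(n_l, mean = log(1e4), sd = 1)
    eps <- matrix(stats::rnorm(n_l * n_s, 0, 0.25), nrow = n_l)
    m <- exp(meanlog + eps)
    hit <- lipids %in% annotated
    m[hit, groups == planted$affected_condition] <-
      m[hit, groups == planted$affected_condition] * planted$effect_size
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(n_l * n_s) < missing_rate, nrow = n_l)
      m[mask] <- NA_real_
    }
    dimnames(m) <- list(lipids,
                        paste0(groups, "_", sequence(rep(
                          n_samples_per_condition, length(conditions)))))
    list(matrix = m, groups = groups, truth = planted)
  })
}

#' Sample a synthetic mammalian-like reference lipidome
#'
#' Draws species from the ontology with class weights mimicking a typical
#' mammalian membrane lipidome (PC- and PE-dominated, with TG, SM and minor
#' classes). Used to calibrate the quintile limits of the biophysical
#' properties. Synthetic: it stands in for published reference lipidomes,
#' which are not bundled.
#'
#' @param species Species data.frame (e.g. `ontology$species`).
#' @param n Number of species to draw.
#' @param seed RNG seed.
#' @return Character vector of species names.
#' @export
synthetic_reference_lipidome <- function(species, n = 1000L, seed = 1734L) {
  weights <- c(PC = 35, PE = 25, PS = 6, PI = 6, PG = 2, PA = 2, SM = 8,
               Cer = 2, TG = 8, DG = 2, LPC = 2, CE = 2)
  mol <- species[species$level == "molecular_species", ]
  w <- weights[mol$lipid_class]
  w[is.na(w)] <- 0.5  # remaining classes at trace weight
  with_local_seed(seed, {
    idx <- sample.int(nrow(mol), size = min(n, nrow(mol)),
                      prob = w / sum(w))
    mol$name[idx]
  })
}
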