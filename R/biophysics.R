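# Biophysical property models: OLS regression on (class, chain length,
# unsaturation), LOOCV validation, quintile calibration and categorization.

validate_training <- function(records) {
  req <- c("lipid_class", "chain_length", "unsaturation", "value")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("training records lack columns: ", paste(missing, collapse = ", "))
  stopifnot(all(records$chain_length > 0), all(records$unsaturation >= 0))
  records
}

#' Fit a biophysical property model
#'
#' Ordinary least squares of `value ~ class + chain_length + unsaturation`:
#' additive class offsets (reference class = lexicographically first) plus
#' common slopes for summed chain length and summed unsaturation. This is the
#' model used to extrapolate measured transition temperatures, bilayer
#' thicknesses and lateral diffusion coefficients to all enumerated species
#' of the trained classes.
#'
#' @param records Data.frame with columns `lipid_class`, `chain_length`
#'   (summed carbons), `unsaturation` (summed double bonds), `value`.
#' @param property_name One of `"transition_temperature"`,
#'   `"bilayer_thickness"`, `"lateral_diffusion"` (or any label; carried as
#'   metadata together with `units`).
#' @param units Free-text unit metadata (e.g. `"degC"`).
#' @return A `property_model`: `property_name`, `units`, `intercept`,
#'   `class_offsets` (named, reference class 0), `beta_length`,
#'   `beta_unsaturation`, `classes`, `sigma`, `n`.
#' @examples
#' rec <- make_property_training(c("PC", "PE"), beta_length = 2,
#'                               beta_unsaturation = -5, noise_sd = 0,
#'                               n = 30, seed = 1)
#' fit_property_model(rec)
#' @export
fit_property_model <- function(records, property_name = "property",
                               units = "") {
  records <- validate_training(records)
  classes <- sort(unique(records$lipid_class))
  multi <- length(classes) > 1L
  n_par <- length(classes) - multi + 1L + 2L  # intercept + offsets + 2 slopes
  if (nrow(records) < n_par)
    stop("fewer records (", nrow(records), ") than free parameters (",
         n_par, ")")
  df <- data.frame(value = records$value,
                   lipid_class = factor(records$lipid_class, levels = classes),
                   chain_length = records$chain_length,
                   unsaturation = records$unsaturation)
  form <- if (multi) value ~ lipid_class + chain_length + unsaturation
          else value ~ chain_length + unsaturation
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  offsets <- stats::setNames(rep(0, length(classes)), classes)
  if (multi) {
    oc <- cf[grepl("^lipid_class", names(cf))]
    offsets[sub("^lipid_class", "", names(oc))] <- unname(oc)
  }
  structure(
    list(property_name = property_name, units = units,
         intercept = unname(cf[["(Intercept)"]]),
         class_offsets = offsets,
         beta_length = unname(cf[["chain_length"]]),
         beta_unsaturation = unname(cf[["unsaturation"]]),
         classes = classes,
         sigma = stats::sigma(fit), n = nrow(records)),
    class = "property_model")
}

#' @export
print.property_model <- function(x, ...) {
  cat(sprintf(
    "<property_model> %s [%s]: value = %.4g %+.4g*length %+.4g*unsat + class offset (%d classes, n = %d)\n",
    x$property_name, x$units, x$intercept, x$beta_length,
    x$beta_unsaturation, length(x$classes), x$n))
  invisible(x)
}

predict_property_vec <- function(model, lipid_class, total_carbons,
                                 total_double_bonds, class_proxy = NULL) {
  cls <- as.character(lipid_class)
  if (!is.null(class_proxy)) {
    mapped <- !cls %in% model$classes & cls %in% names(class_proxy)
    cls[mapped] <- unname(class_proxy[cls[mapped]])
  }
  out <- rep(NA_real_, length(cls))
  ok <- cls %in% model$classes
  out[ok] <- model$intercept + model$class_offsets[cls[ok]] +
    model$beta_length * total_carbons[ok] +
    model$beta_unsaturation * total_double_bonds[ok]
  unname(out)
}

#' Predict a biophysical property for a lipid species
#'
#' Deterministic linear prediction from (class, total carbons, total double
#' bonds); two species with equal class, length and unsaturation get equal
#' predictions (sn-positions play no role). Species of untrained classes with
#' no proxy mapping are not predictable and return `NA`.
#'
#' @param model A `property_model`.
#' @param species A [lipid_species()] object, or a data.frame with columns
#'   `lipid_class`, `total_carbons`, `total_double_bonds` for vectorized use.
#' @param class_proxy Optional named character vector mapping untrained
#'   classes onto trained ones (e.g. `c("PC O-" = "PC")`).
#' @return Numeric prediction(s); `NA` where not predictable.
#' @export
predict_property <- function(model, species, class_proxy = NULL) {
  stopifnot(inherits(model, "property_model"))
  if (inherits(species, "lipid_species"))
    return(predict_property_vec(model, species$lipid_class,
                                species$total_carbons,
                                species$total_double_bonds, class_proxy))
  predict_property_vec(model, species$lipid_class, species$total_carbons,
                       species$total_double_bonds, class_proxy)
}

#' Leave-one-out cross-validation of a property model
#'
#' Each record in turn is held out, the model refit on the remaining
#' records, and the held-out value predicted. Records whose refit is
#' rank-deficient are flagged and excluded from the aggregate statistics.
#'
#' @inheritParams fit_property_model
#' @return A `loocv_report`: data.frame `predictions` (observed, predicted,
#'   flagged), `rmse`, `r_squared`.
#' @export
loocv <- function(records, property_name = "property") {
  records <- validate_training(records)
  n <- nrow(records)
  classes <- sort(unique(records$lipid_class))
  n_par <- length(classes) - (length(classes) > 1L) + 3L
  if (n < n_par + 1L) stop("need at least parameters + 1 records for LOOCV")
  pred <- rep(NA_real_, n); flagged <- logical(n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    m <- tryCatch(fit_property_model(train, property_name),
                  error = function(e) NULL)
    if (is.null(m)) { flagged[i] <- TRUE; next }
    p <- predict_property_vec(m, records$lipid_class[i],
                              records$chain_length[i],
                              records$unsaturation[i])
    if (is.na(p)) flagged[i] <- TRUE else pred[i] <- p
  }
  ok <- !flagged
  err <- records$value[ok] - pred[ok]
  sst <- sum((records$value[ok] - mean(records$value[ok]))^2)
  structure(
    list(predictions = data.frame(observed = records$value,
                                  predicted = pred, flagged = flagged),
         rmse = sqrt(mean(err^2)),
         r_squared = 1 - sum(err^2) / sst,
         property_name = property_name),
    class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %s: n = %d, RMSE = %.4g, R^2 = %.4f\n",
              x$property_name, nrow(x$predictions), x$rmse, x$r_squared))
  invisible(x)
}

#' Derive quintile category limits from a reference distribution
#'
#' The four limits are the empirical 20th/40th/60th/80th percentiles
#' (inclusive linear interpolation, `stats::quantile` type 7) of the
#' predicted property values over a reference lipidome; they bound the five
#' categories "very low", "low", "average", "high", "very high".
#'
#' @param reference_values Numeric vector with at least 5 distinct values.
#' @param property_name Label carried as metadata.
#' @return A `category_limits` object: `limits` (length-4, nondecreasing),
#'   `category_names`, `property_name`.
#' @export
derive_limits <- function(reference_values, property_name = "property") {
  v <- reference_values[!is.na(reference_values)]
  if (length(unique(v)) < 5L)
    stop("need at least 5 distinct reference values to define quintiles")
  q <- stats::quantile(v, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                       names = FALSE)
  structure(list(limits = q, category_names = category_names(),
                 property_name = property_name),
            class = "category_limits")
}

#' @export
print.category_limits <- function(x, ...) {
  cat(sprintf("<category_limits> %s: %s\n", x$property_name,
              paste(sprintf("%.4g", x$limits), collapse = " | ")))
  invisible(x)
}

#' Categorize a value into a quintile bin
#'
#' Half-open bins: (-Inf, q20) is "very low", \[q20, q40) "low",
#' \[q40, q60) "average", \[q60, q80) "high", \[q80, Inf) "very high".
#' Every finite value maps to exactly one category.
#'
#' @param value Numeric vector (no NaN/NA).
#' @param limits A `category_limits` object.
#' @return Character vector of category names.
#' @export
categorize <- function(value, limits) {
  stopifnot(inherits(limits, "category_limits"))
  if (any(is.na(value)))
    stop("cannot categorize NA/NaN values")
  limits$category_names[findInterval(value, limits$limits) + 1L]
}

#' Assign biophysical category terms to ontology species
#'
#' Predicts every property for every species (sum-composition and molecular
#' layers are treated identically: class plus total carbons and double
#' bonds), categorizes the predictions with the per-property limits, and
#' returns the species-to-category-term assignments. Species of untrained
#' classes (no proxy) receive no terms for that property.
#'
#' @param ontology A `lion_ontology`, or a species data.frame.
#' @param models Named list of `property_model`s (names are property names).
#' @param limits_per_property Named list of `category_limits` matching
#'   `models`.
#' @param class_proxy Optional proxy table passed to [predict_property()].
#' @return Data.frame (`species`, `term`, `property`, `value`, `category`).
#' @export
assign_biophysics_terms <- function(ontology, models, limits_per_property,
                                    class_proxy = NULL) {
  sp <- if (inherits(ontology, "lion_ontology")) ontology$species else ontology
  stopifnot(length(models) >= 1L,
            all(names(models) %in% names(BIOPHYS_PROPERTIES)),
            all(names(models) %in% names(limits_per_property)))
  out <- vector("list", length(models))
  for (k in seq_along(models)) {
    prop <- names(models)[k]
    v <- predict_property_vec(models[[k]], sp$lipid_class, sp$total_carbons,
                              sp$total_double_bonds, class_proxy)
    ok <- !is.na(v)
    cat_k <- categorize(v[ok], limits_per_property[[prop]])
    out[[k]] <- data.frame(species = sp$name[ok],
                           term = biophysics_term_id(prop, cat_k),
                           property = prop, value = v[ok],
                           category = cat_k, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export model coefficients as a tidy table
#'
#' @param models Named list of `property_model`s.
#' @return Data.frame with columns `property`, `coefficient`, `value`,
#'   `units` (one row per coefficient), suitable for CSV export.
#' @export
export_coefficients <- function(models) {
  rows <- lapply(names(models), function(p) {
    m <- models[[p]]
    data.frame(
      property = p,
      coefficient = c("(Intercept)", "chain_length", "unsaturation",
                      paste0("class:", names(m$class_offsets))),
      value = c(m$intercept, m$beta_length, m$beta_unsaturation,
                unname(m$class_offsets)),
      units = m$units, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
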