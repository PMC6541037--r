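# The default full-scale ontology build: every shipped class rule, the
# 37-chain fatty-acid alphabet, d18:0/d18:1 backbones, and biophysical
# category terms from synthetic training models calibrated against a
# synthetic reference lipidome.

#' Default class-proxy table for biophysical prediction
#'
#' Ether and lyso subclasses are predicted with their parent diacyl class's
#' coefficients; BMP behaves like PG. Classes absent from the table and from
#' the training set (storage lipids, glycosphingolipids, sterol esters,
#' free fatty acids) are not predictable and carry no biophysics terms.
#'
#' @return Named character vector (untrained class -> trained class).
#' @export
default_class_proxy <- function() {
  c("PC O-" = "PC", "PC P-" = "PC", "LPC" = "PC",
    "PE O-" = "PE", "PE P-" = "PE", "LPE" = "PE",
    "LPS" = "PS", "LPG" = "PG", "LPA" = "PA", "LPI" = "PC",
    "PI" = "PC", "BMP" = "PG", "Cer" = "SM",
    "HexCer" = "SM", "Hex2Cer" = "SM", "SHexCer" = "SM", "GM3" = "SM")
}

#' Fit the default synthetic biophysics models
#'
#' Three property models fit on synthetic training tables whose coefficient
#' magnitudes follow the literature: chain-melting transition temperature
#' (degC) rises with chain length (~4 degC per carbon) and drops steeply
#' with unsaturation (~-35 degC per double bond; trained classes PC, PE, PG,
#' PA, PS, SM); bilayer thickness (nm) rises with length and drops with
#' unsaturation; lateral diffusion (um^2/s) does the opposite (trained
#' classes PC, PS, PG, PA, PE; the coarse-grained source lacks
#' sphingolipids, so SM is untrained there).
#'
#' @return Named list of three `property_model`s.
#' @export
default_biophysics_models <- function() {
  tt <- make_property_training(
    c("PC", "PE", "PG", "PA", "PS", "SM"),
    beta_length = 4.25, beta_unsaturation = -35, noise_sd = 3,
    n = 90L, seed = 11L, intercept = -95,
    class_offsets = c(PA = 5, PC = 0, PE = 20, PG = -3, PS = 10, SM = 6))
  bt <- make_property_training(
    c("PC", "PS", "PG", "PA", "PE"),
    beta_length = 0.09, beta_unsaturation = -0.07, noise_sd = 0.08,
    n = 75L, seed = 12L, intercept = 1.0,
    class_offsets = c(PA = 0.05, PC = 0, PE = -0.1, PG = 0.02, PS = 0.08))
  ld <- make_property_training(
    c("PC", "PS", "PG", "PA", "PE"),
    beta_length = -0.6, beta_unsaturation = 1.2, noise_sd = 0.5,
    n = 75L, seed = 13L, intercept = 35,
    class_offsets = c(PA = -1, PC = 0, PE = 1.5, PG = 0.5, PS = -0.5))
  list(transition_temperature = fit_property_model(tt,
         "transition_temperature", units = "degC"),
       bilayer_thickness = fit_property_model(bt,
         "bilayer_thickness", units = "nm"),
       lateral_diffusion = fit_property_model(ld,
         "lateral_diffusion", units = "um^2/s"))
}

#' Build the full default lipid ontology
#'
#' Enumerates species from the complete shipped class-rule table with the
#' 37-chain fatty-acid alphabet and the d18:0/d18:1 sphingoid backbones,
#' then (by default) fits the synthetic biophysics models, calibrates
#' quintile limits on predictions over a synthetic mammalian-like reference
#' lipidome, and annotates every predictable species with one category term
#' per property. The result holds over 50,000 species and over 250,000
#' edges.
#'
#' @param with_biophysics Assign biophysical category terms (default TRUE).
#' @param reference_n Size of the sampled reference lipidome.
#' @param reference_seed Seed of the reference-lipidome draw.
#' @return A list: `ontology` (`lion_ontology`), `models`, `limits`,
#'   `reference` (the reference species names). With
#'   `with_biophysics = FALSE`, `models`/`limits`/`reference` are `NULL`.
#' @export
build_default_ontology <- function(with_biophysics = TRUE,
                                   reference_n = 1000L,
                                   reference_seed = 1734L) {
  rules <- lion_class_rules()
  fa <- default_fatty_acids()
  species <- enumerate_species(rules, fa)
  models <- limits <- reference <- NULL
  assignments <- NULL
  if (with_biophysics) {
    models <- default_biophysics_models()
    proxy <- default_class_proxy()
    reference <- synthetic_reference_lipidome(species, n = reference_n,
                                              seed = reference_seed)
    ref_sp <- species[match(reference, species$name), ]
    limits <- list()
    for (p in names(models)) {
      v <- predict_property(models[[p]], ref_sp, class_proxy = proxy)
      limits[[p]] <- derive_limits(v[!is.na(v)], p)
    }
    assignments <- assign_biophysics_terms(species, models, limits,
                                           class_proxy = proxy)
  }
  ontology <- build_ontology(rules, fa,
                             property_assignments = assignments,
                             species = species)
  list(ontology = ontology, models = models, limits = limits,
       reference = reference)
}
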