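test_that("OLS recovers generating coefficients", {
  # noiseless data: recovery to machine precision
  rec <- make_property_training(c("PC", "PE"), beta_length = 2.0,
                                beta_unsaturation = -5.0, noise_sd = 0,
                                n = 40, seed = 3, intercept = 10,
                                class_offsets = c(PC = 0, PE = 7))
  m <- fit_property_model(rec, "transition_temperature", units = "degC")
  expect_equal(m$beta_length, 2.0, tolerance = 1e-10)
  expect_equal(m$beta_unsaturation, -5.0, tolerance = 1e-10)
  expect_equal(m$intercept, 10, tolerance = 1e-8)
  expect_equal(unname(m$class_offsets["PE"]), 7, tolerance = 1e-8)
  expect_equal(unname(m$class_offsets["PC"]), 0)

  # noisy data: |beta_hat - beta| < 3 SE, with SE from the OLS covariance
  # formula computed independently of the fitting code
  rec2 <- make_property_training(c("PC", "PE"), beta_length = 2.0,
                                 beta_unsaturation = -5.0, noise_sd = 1,
                                 n = 200, seed = 4, intercept = 10,
                                 class_offsets = c(PC = 0, PE = 7))
  m2 <- fit_property_model(rec2)
  X <- cbind(1, rec2$lipid_class == "PE", rec2$chain_length,
             rec2$unsaturation)
  XtXi <- solve(t(X) %*% X)
  resid <- rec2$value - X %*% c(m2$intercept, m2$class_offsets["PE"],
                                m2$beta_length, m2$beta_unsaturation)
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(XtXi) * s2)
  expect_lt(abs(m2$beta_length - 2.0), 3 * se[3])
  expect_lt(abs(m2$beta_unsaturation - (-5.0)), 3 * se[4])
  expect_lt(abs(m2$intercept - 10), 3 * se[1])

  # single-class fit degenerates to intercept + slopes
  rec1 <- make_property_training("PC", beta_length = 1, beta_unsaturation = 0,
                                 noise_sd = 0, n = 20, seed = 5)
  m1 <- fit_property_model(rec1)
  expect_equal(m1$beta_length, 1, tolerance = 1e-10)
  expect_equal(unname(m1$class_offsets), 0)
})

test_that("degenerate designs are rejected with the offending column", {
  rec <- make_property_training(c("PC", "PE"), noise_sd = 0, n = 12, seed = 1)
  expect_error(fit_property_model(rec[1:3, ]), "fewer records")
  rec$chain_length <- 30L  # constant predictor: rank-deficient
  expect_error(fit_property_model(rec), "chain_length")
})

test_that("prediction is linear, sn-blind and flags untrained classes", {
  rec <- make_property_training("PC", beta_length = 1, beta_unsaturation = 0,
                                noise_sd = 0, n = 20, seed = 5, intercept = 0)
  m <- fit_property_model(rec)
  expect_equal(predict_property(m, parse_lipid_name("PC(34:1)")), 34.0)
  # equal class/length/unsaturation => equal predictions
  expect_equal(predict_property(m, parse_lipid_name("PC(16:0/18:1)")),
               predict_property(m, parse_lipid_name("PC(14:0/20:1)")))
  # untrained class without proxy: not predictable
  expect_true(is.na(predict_property(m, parse_lipid_name("SM(d18:1/16:0)"))))
  # proxy mapping makes it predictable
  expect_equal(predict_property(m, parse_lipid_name("SM(d18:1/16:0)"),
                                class_proxy = c(SM = "PC")), 34.0)
})

test_that("LOOCV matches the closed-form leverage shortcut", {
  rec <- make_property_training(c("PC", "PE"), beta_length = 2,
                                beta_unsaturation = -5, noise_sd = 2,
                                n = 30, seed = 8)
  rep <- loocv(rec)
  expect_equal(nrow(rep$predictions), 30L)
  expect_false(any(rep$predictions$flagged))

  # hat-matrix oracle: held-out residual e_i / (1 - h_ii)
  X <- cbind(1, rec$lipid_class == "PE", rec$chain_length, rec$unsaturation)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  beta <- solve(t(X) %*% X, t(X) %*% rec$value)
  e <- rec$value - X %*% beta
  loo_resid <- e / (1 - diag(H))
  expect_equal(rec$value - rep$predictions$predicted, as.numeric(loo_resid),
               tolerance = 1e-8)

  # exact linear data: perfect held-out prediction
  rec0 <- make_property_training(c("PC", "PE"), noise_sd = 0, n = 25,
                                 seed = 9)
  rep0 <- loocv(rec0)
  expect_equal(rep0$rmse, 0, tolerance = 1e-8)
  expect_equal(rep0$r_squared, 1, tolerance = 1e-8)
})

test_that("quintile limits put exactly 20% of distinct values below q20", {
  lim <- derive_limits(as.numeric(1:1000))
  expect_equal(mean(1:1000 < lim$limits[1]), 0.20)
  expect_equal(length(lim$limits), 4L)
  expect_true(all(diff(lim$limits) >= 0))

  # 5 values: one per category under the documented quantile convention
  lim5 <- derive_limits(as.numeric(1:5))
  expect_equal(categorize(1:5, lim5),
               c("very low", "low", "average", "high", "very high"))

  expect_error(derive_limits(rep(3, 10)), "distinct")
  expect_error(derive_limits(c(1, 2, 3, 4)), "distinct")
})

test_that("categorization is total, ordered and follows half-open bins", {
  lim <- derive_limits(as.numeric(1:100))
  expect_equal(categorize(-1e6, lim), "very low")
  expect_equal(categorize(1e6, lim), "very high")
  # boundary values fall in the upper (closed-from-below) bin
  expect_equal(categorize(lim$limits[1], lim), "low")
  expect_equal(categorize(lim$limits[2], lim), "average")
  expect_equal(categorize(lim$limits[4], lim), "very high")
  # order preservation
  v <- sort(runif(50, -50, 150))
  cats <- categorize(v, lim)
  ranks <- match(cats, category_names())
  expect_true(all(diff(ranks) >= 0))
  expect_error(categorize(NaN, lim), "NA/NaN")
})

test_that("biophysics terms partition predictable species", {
  ont <- toy_ontology(2L, 4L, with_biophysics = FALSE)
  rec <- make_property_training(c("PC", "PE"), beta_length = 1,
                                beta_unsaturation = -3, noise_sd = 0,
                                n = 30, seed = 10)
  m <- fit_property_model(rec, "transition_temperature")
  v <- predict_property(m, ont$species)
  lim <- derive_limits(v[!is.na(v)], "transition_temperature")
  pa <- assign_biophysics_terms(ont, list(transition_temperature = m),
                                list(transition_temperature = lim))
  # per property, each species has exactly 0 or 1 category term
  expect_false(any(duplicated(pa$species)))
  expect_equal(sort(unique(pa$species)), sort(ont$species$name))

  # a constant (zero-slope) model puts every species in a single category
  rec0 <- make_property_training(c("PC", "PE"), beta_length = 0,
                                 beta_unsaturation = 0, noise_sd = 0,
                                 n = 30, seed = 11, intercept = 7,
                                 class_offsets = c(PC = 0, PE = 0))
  m0 <- fit_property_model(rec0, "lateral_diffusion")
  lim0 <- derive_limits(c(1, 3, 5, 7, 9), "lateral_diffusion")
  pa0 <- assign_biophysics_terms(ont, list(lateral_diffusion = m0),
                                 list(lateral_diffusion = lim0))
  expect_equal(unique(pa0$category), "high")  # 7 lies in [q60, q80) = [5.8, 7.4)
  # monotone model: category nonincreasing in unsaturation at fixed
  # class/length when beta_unsaturation < 0
  sp <- ont$species[ont$species$lipid_class == "PC" &
                      ont$species$total_carbons == 28, ]
  sp <- sp[order(sp$total_double_bonds), ]
  cats <- pa$category[match(sp$name, pa$species)]
  ranks <- match(cats, category_names())
  expect_true(all(diff(ranks) <= 0))
})

test_that("opposing unsaturation effects yield anticorrelated predictions", {
  # transition temperature falls with unsaturation, lateral diffusion rises:
  # over species predictable by both, rank correlation is negative
  models <- default_biophysics_models()
  rules <- lion_class_rules()
  sp <- enumerate_species(rules[rules$class_id %in% c("PC", "PE", "PS"), ],
                          utils::head(default_fatty_acids(), 8))
  tt <- predict_property(models$transition_temperature, sp)
  ld <- predict_property(models$lateral_diffusion, sp)
  ok <- !is.na(tt) & !is.na(ld)
  expect_lt(cor(tt[ok], ld[ok], method = "spearman"), 0)
})

test_that("coefficient export is tidy", {
  models <- default_biophysics_models()
  tab <- export_coefficients(models)
  expect_true(all(c("property", "coefficient", "value", "units") %in%
                    names(tab)))
  expect_equal(length(unique(tab$property)), 3L)
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_equal(nrow(read.csv(path)), nrow(tab))
})
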