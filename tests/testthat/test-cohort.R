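test_that("simulated IgG matches the per-strain calibration and is reproducible", {
  n <- 10000
  cd2 <- simulate_covariates(n, strain = 1, tumour = 0, seed = 11)
  b6 <- simulate_covariates(n, strain = 0, tumour = 0, seed = 12)
  # arithmetic mean within 2 standard errors of the calibration target
  expect_lt(abs(mean(cd2$IGG) - 37.328), 2 * 15.914 / sqrt(n))
  expect_lt(abs(mean(b6$IGG) - 6.610), 2 * 2.451 / sqrt(n))
  expect_identical(simulate_covariates(50, 1, 1, seed = 3),
                   simulate_covariates(50, 1, 1, seed = 3))
  expect_error(simulate_covariates(0, 1, 0), "positive")
})

test_that("tumour-bearing covariates shift in the cachectic direction", {
  n <- 4000
  tf <- simulate_covariates(n, strain = 1, tumour = 0, seed = 21)
  tb <- simulate_covariates(n, strain = 1, tumour = 1, seed = 22)
  expect_lt(mean(tb$MWT), mean(tf$MWT))
  expect_lt(mean(tb$FWT), mean(tf$FWT))
  expect_lt(mean(tb$ALB), mean(tf$ALB))
  expect_lt(mean(tb$FCRN), mean(tf$FCRN))
  expect_lt(mean(tb$PBWT), 0)
  expect_gt(mean(tf$PBWT), 0)
  expect_true(all(tb$MWT > 0 & tb$FWT > 0 & tb$IGG > 0 & tb$ALB > 0 &
                    tb$FCRN > 0))
})

test_that("individual parameters apply the covariate and eta sub-models", {
  meds <- c(IGG = 15, MWT = 0.12, FCRN = 1)
  sp <- pembro_mouse_spec("covariate", covariate_medians = meds)
  at_median <- list(TUM = 0, STR = 0, IGG = 15, MWT = 0.12, FCRN = 1)
  # identity case: eta = 0, covariates at medians, tumour-free
  p0 <- individual_parameters(sp, at_median, eta = c(CL = 0, V1 = 0, V2 = 0))
  expect_equal(as.numeric(p0), as.numeric(sp$theta), tolerance = 1e-12)
  # dichotomous tumour shift on CL: 8.35 * (1 + 0.65)
  ptum <- individual_parameters(sp, modifyList(at_median, list(TUM = 1)))
  expect_equal(ptum[["CL"]], 8.35 * 1.65, tolerance = 1e-12)
  expect_equal(ptum[["V1"]], sp$theta[["V1"]], tolerance = 1e-12)
  # doubling IgG multiplies CL by 2^0.286 (power model arithmetic)
  pigg <- individual_parameters(sp, modifyList(at_median, list(IGG = 30)))
  expect_equal(pigg[["CL"]] / p0[["CL"]], 2^0.286, tolerance = 1e-12)
  expect_equal(pigg[["Q"]] / p0[["Q"]], 2^0.415, tolerance = 1e-12)
  # exponential eta
  pe <- individual_parameters(sp, at_median, eta = c(CL = 0.3, V1 = -0.1, V2 = 0.2))
  expect_equal(pe[["CL"]] / p0[["CL"]], exp(0.3), tolerance = 1e-12)
  expect_equal(pe[["Q"]], p0[["Q"]])  # Q carries no eta
  expect_error(individual_parameters(sp, modifyList(at_median, list(IGG = -1))),
               "positive")
})

test_that("simulated profiles follow the log-additive residual model", {
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  sched <- c(1, 48, 96, 168)
  noise_free <- simulate_profile(p, 2000, sched, sigma_log = 0)
  expect_equal(noise_free$conc, concentration(p, 2000, hours_to_days(sched)))
  expect_identical(simulate_profile(p, 2000, sched, 0.11, seed = 5),
                   simulate_profile(p, 2000, sched, 0.11, seed = 5))
  # Monte-Carlo check of the noise model over 10^4 draws
  dense <- seq(1, 200, length.out = 10000)
  noisy <- simulate_profile(p, 2000, dense, sigma_log = 0.11, seed = 9)
  resid <- log(noisy$conc) - log(concentration(p, 2000, hours_to_days(dense)))
  expect_lt(abs(sd(resid) - 0.11), 2 * 0.11 / sqrt(2 * length(dense)))
  ks <- stats::ks.test(resid / 0.11, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_error(simulate_profile(p, 2000, c(0, 24)), "> 0")
  expect_error(simulate_profile(p, 2000, c(48, 24)), "increasing")
})

test_that("tumour volume uses the ellipsoid calliper formula", {
  expect_equal(tumour_volume(10, 8), 10 * 64 * pi / 6)
  expect_equal(tumour_volume(6, 6), 6^3 * pi / 6)
  w <- 3.7
  expect_equal(tumour_volume(w, w), pi / 6 * w^3)
  expect_error(tumour_volume(5, 8), "length >= width")
  expect_error(tumour_volume(5, 0), "length >= width")
})

test_that("absorption artifacts produce rising early profiles that QC catches", {
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  sched <- c(1, 48, 96, 168)
  rec <- simulate_profile(p, 2000, sched, sigma_log = 0)
  # near-complete IV fraction leaves the profile essentially unchanged
  almost_iv <- inject_absorption_artifact(rec, 1 - 1e-12, ka = 0.5,
                                          params = p, dose = 2000, sigma_log = 0)
  expect_equal(almost_iv$conc, rec$conc, tolerance = 1e-6)
  # pure slow depot: concentration still rising at 48 h
  depot <- inject_absorption_artifact(rec, 0, ka = 0.5,
                                      params = p, dose = 2000, sigma_log = 0)
  expect_gt(depot$conc[2], depot$conc[1])
  flag <- flag_absorption_phase(depot)
  expect_true(flag$excluded)
  expect_identical(flag$reason, "partial_dose_absorption")
  expect_error(inject_absorption_artifact(rec, 1, 0.5, params = p, dose = 2000),
               "dose_fraction_iv")
  expect_error(inject_absorption_artifact(rec, 0.5, -1, params = p, dose = 2000),
               "ka")
})

test_that("generated cohorts have the study shape and are reproducible", {
  des <- study_design(spec = pembro_mouse_spec("structural"))
  data <- generate_cohort(des, seed = 7)
  ids <- unique(data$ID)
  expect_length(ids, 135)
  # vehicle animals: a zero-amount dose row, covariates, no concentrations
  veh <- unique(data$ID[data$EVID == 1 & data$AMT == 0])
  expect_length(veh, 28)
  expect_equal(sum(data$EVID == 0 & data$ID %in% veh), 0)
  dosed <- setdiff(ids, veh)
  expect_length(dosed, 107)
  expect_true(all(table(data$ID[data$EVID == 0]) == 4))
  # terminal samples at 144 or 168 h only
  last <- tapply(data$TIME[data$EVID == 0], data$ID[data$EVID == 0], max)
  expect_true(all(last %in% c(144, 168)))
  expect_identical(generate_cohort(des, seed = 7), data)
  expect_false(identical(generate_cohort(des, seed = 8), data))
})

test_that("an artifact-free low-noise cohort passes QC untouched", {
  spec <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                         omega2 = c(CL = 0.1, V1 = 0.05, V2 = 0.1),
                         sigma_log = 1e-6)
  des <- small_design(spec, n_per_arm = 3)
  data <- generate_cohort(des, seed = 3)
  flags <- qc_dataset(data)
  expect_equal(sum(flags$excluded), 0)
})
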