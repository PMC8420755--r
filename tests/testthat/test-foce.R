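# Helper: pipeline dataset from explicit per-subject records.
dataset_from_records <- function(recs, doses) {
  rows <- lapply(seq_along(recs), function(i) {
    rbind(data.frame(ID = i, TIME = 0, DV = NA_real_, AMT = doses[i], EVID = 1L),
          data.frame(ID = i, TIME = recs[[i]]$time_h, DV = recs[[i]]$conc,
                     AMT = NA_real_, EVID = 0L))
  })
  do.call(rbind, rows)
}

test_that("predicted log-concentrations match the simulator round-trip", {
  sp <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                       omega2 = c(CL = 0.1, V1 = 0.1, V2 = 0.1),
                       sigma_log = 0.11)
  sub <- make_subject(sp$theta, 2000, c(1, 48, 96, 168))
  expect_equal(predict_log_concentrations(sp, sub), log(sub$records$conc),
               tolerance = 1e-12)
  # raising eta_CL lowers late concentrations monotonically
  base <- predict_log_concentrations(sp, sub, c(CL = 0, V1 = 0, V2 = 0))
  up <- predict_log_concentrations(sp, sub, c(CL = 0.2, V1 = 0, V2 = 0))
  expect_true(all(up < base))
  expect_true(all(diff(up - base) < 0))
})

test_that("the conditional mode recovers a known eta and shrinks with the prior", {
  sp <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                       omega2 = c(CL = 0.3, V1 = 0.3, V2 = 0.3),
                       sigma_log = 1e-3)
  eta_true <- c(CL = 0.25, V1 = -0.15, V2 = 0.1)
  pars <- individual_parameters(sp, list(), eta_true)
  sub <- make_subject(pars, 2000, c(1, 24, 48, 96, 120, 168))
  # near-noiseless data with a diffuse prior: the mode sits at eta_true
  expect_equal(map_eta(sp, sub), eta_true, tolerance = 1e-4)
  # vanishing prior variance pins the mode at zero
  sp0 <- sp
  sp0$omega2 <- c(CL = 1e-10, V1 = 1e-10, V2 = 1e-10)
  sp0$sigma_log <- 0.2
  expect_lt(max(abs(map_eta(sp0, sub))), 1e-5)
})

test_that("the conditional mode matches a brute-force grid search", {
  sp <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                       omega2 = c(CL = 0.09, V1 = 0.09, V2 = 0),
                       sigma_log = 0.11)
  sub <- make_subject(sp$theta, 2000, c(1, 48, 96, 168),
                      sigma_log = 0.3, seed = 42)
  qfun <- function(e1, e2) {
    pars <- individual_parameters(sp, list(), c(CL = e1, V1 = e2, V2 = 0))
    f <- log(concentration(pars, 2000, hours_to_days(sub$records$time_h)))
    sum((log(sub$records$conc) - f)^2) / sp$sigma_log^2 +
      e1^2 / 0.09 + e2^2 / 0.09
  }
  grid <- seq(-0.6, 0.6, by = 0.01)
  q <- outer(grid, grid, Vectorize(qfun))
  idx <- which(q == min(q), arr.ind = TRUE)
  eta_hat <- map_eta(sp, sub)
  expect_lt(abs(eta_hat[["CL"]] - grid[idx[1]]), 0.011)
  expect_lt(abs(eta_hat[["V1"]] - grid[idx[2]]), 0.011)
  expect_equal(eta_hat[["V2"]], 0)
})

test_that("OFV matches the conjugate-Gaussian closed form on a linear toy", {
  # one observation at t = 0 with IIV on V1 only: log C = log(dose/V1) - eta,
  # exactly linear in eta, so the linearized marginal is exact
  sp <- pop_model_spec(theta = pk_params(10, 50, 10, 50),
                       omega2 = c(CL = 0, V1 = 0.2, V2 = 0),
                       sigma_log = 0.15)
  y <- 45  # observed concentration, ug/mL
  data <- data.frame(ID = 1, TIME = c(0, 0), DV = c(NA, y), AMT = c(2000, NA),
                     EVID = c(1L, 0L))
  v <- 0.2 + 0.15^2
  a <- log(2000 / 50)
  oracle <- log(v) + (log(y) - a)^2 / v
  expect_equal(foce_ofv(sp, data), oracle, tolerance = 1e-8)
})

test_that("FOCE-I OFV agrees with adaptive Gauss-Hermite quadrature on small toys", {
  skip_if_not_installed("pracma")
  sp <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                       omega2 = c(CL = 0.09, V1 = 0, V2 = 0),
                       sigma_log = 0.15)
  sched <- c(24, 96)
  recs <- list(
    simulate_profile(individual_parameters(sp, list(), c(CL = 0.3, V1 = 0, V2 = 0)),
                     2000, sched, 0.15, seed = 1),
    simulate_profile(individual_parameters(sp, list(), c(CL = -0.2, V1 = 0, V2 = 0)),
                     2000, sched, 0.15, seed = 2),
    simulate_profile(sp$theta, 10000, sched, 0.15, seed = 3))
  data <- dataset_from_records(recs, c(2000, 2000, 10000))
  gh <- pracma::gaussHermite(64)
  neg2ll <- 0
  for (i in seq_along(recs)) {
    dose <- c(2000, 2000, 10000)[i]
    loglik_eta <- function(eta) {
      pars <- individual_parameters(sp, list(), c(CL = eta, V1 = 0, V2 = 0))
      f <- log(concentration(pars, dose, hours_to_days(sched)))
      r <- log(recs[[i]]$conc) - f
      -sum(r^2) / (2 * 0.15^2) - length(r) * log(0.15) -
        eta^2 / (2 * 0.09) - 0.5 * log(0.09)
    }
    # adaptive centering at the conditional mode
    opt <- optimize(function(e) -loglik_eta(e), c(-2, 2))
    mode <- opt$minimum
    h <- 1e-4
    curv <- -(loglik_eta(mode + h) - 2 * loglik_eta(mode) +
                loglik_eta(mode - h)) / h^2
    s <- 1 / sqrt(curv)
    vals <- vapply(gh$x, function(z) {
      eta <- mode + sqrt(2) * s * z
      exp(loglik_eta(eta) + z^2)  # undo the e^{-z^2} GH weight
    }, numeric(1))
    lik0 <- sqrt(2) * s * sum(gh$w * vals)
    ## loglik_eta drops (n_i + 1)/2 factors of log(2pi); the engine's OFV
    ## convention drops n_i of them, so one log(2pi) remains per subject
    neg2ll <- neg2ll - 2 * log(lik0) + log(2 * pi)
  }
  expect_lt(abs(foce_ofv(sp, data) - neg2ll), 0.5)
})

test_that("zero IIV reduces the OFV to the weighted least-squares deviance", {
  sp <- pop_model_spec(theta = pk_params(11.9, 61.8, 62.3, 62.3),
                       omega2 = c(CL = 0, V1 = 0, V2 = 0),
                       sigma_log = 0.2)
  sched <- c(1, 48, 96, 168)
  recs <- list(simulate_profile(sp$theta, 2000, sched, 0.2, seed = 4),
               simulate_profile(sp$theta, 10000, sched, 0.2, seed = 5))
  data <- dataset_from_records(recs, c(2000, 10000))
  rss <- 0
  for (i in 1:2) {
    f <- log(concentration(sp$theta, c(2000, 10000)[i], hours_to_days(sched)))
    rss <- rss + sum((log(recs[[i]]$conc) - f)^2)
  }
  expect_equal(foce_ofv(sp, data), 8 * log(0.2^2) + rss / 0.2^2,
               tolerance = 1e-10)
})

test_that("OFV is invariant to subject relabelling", {
  spec <- ref_structural()
  des <- small_design(spec, n_per_arm = 2)
  data <- generate_cohort(des, seed = 31)
  perm <- data
  perm$ID <- max(data$ID) + 1 - perm$ID   # reverse the labels
  perm <- perm[order(perm$ID, perm$EVID == 0, perm$TIME), ]
  expect_equal(foce_ofv(spec, data), foce_ofv(spec, perm), tolerance = 1e-8)
})

test_that("noise-free zero-IIV data return the generative fixed effects", {
  truth <- pk_params(11.9, 61.8, 62.3, 62.3)
  sched <- c(1, 12, 24, 48, 96, 120, 144, 168)
  recs <- c(lapply(1:6, function(i) simulate_profile(truth, 2000, sched, 0)),
            lapply(1:6, function(i) simulate_profile(truth, 10000, sched, 0)))
  data <- dataset_from_records(recs, rep(c(2000, 10000), each = 6))
  init <- pop_model_spec(theta = pk_params(8, 80, 40, 40),
                         omega2 = c(CL = 0, V1 = 0, V2 = 0),
                         sigma_log = 0.05)
  fit <- foce_fit(data, init)
  expect_equal(as.numeric(fit$theta_hat), as.numeric(truth), tolerance = 1e-3)
})

test_that("eta shrinkage rises as individual data become sparse", {
  spec <- ref_structural()
  rich_des <- small_design(spec, n_per_arm = 3)
  rich_des$schedule_h <- c(1, 6, 12, 24, 48, 72, 96, 120, 144)
  rich <- generate_cohort(rich_des, seed = 61)
  sparse_des <- small_design(spec, n_per_arm = 3)
  sparse_des$schedule_h <- c(48)
  sparse <- generate_cohort(sparse_des, seed = 61)
  fit_rich <- foce_fit(rich, spec)
  fit_sparse <- foce_fit(sparse, spec)
  expect_lt(fit_rich$shrinkage_pct[["CL"]], 40)
  expect_gt(fit_sparse$shrinkage_pct[["CL"]],
            fit_rich$shrinkage_pct[["CL"]])
  expect_identical(eta_shrinkage(fit_rich), fit_rich$shrinkage_pct)
})

test_that("standard errors are positive and shrink with the sample size", {
  spec <- ref_structural()
  small <- generate_cohort(small_design(spec, n_per_arm = 3), seed = 71)
  big <- generate_cohort(small_design(spec, n_per_arm = 12), seed = 71)
  fit_s <- foce_fit(small, init_spec_from_data(small))
  fit_b <- foce_fit(big, init_spec_from_data(big))
  se_s <- standard_errors(fit_s, small)
  se_b <- standard_errors(fit_b, big)
  expect_true(all(is.finite(se_s[1:4])) && all(se_s[1:4] > 0))
  expect_true(all(is.finite(se_b[1:4])) && all(se_b[1:4] > 0))
  # 4x the subjects: SE should drop roughly like 1/sqrt(n)
  expect_lt(se_b[["lCL"]], se_s[["lCL"]])
  ratio <- se_s[["lCL"]] / se_b[["lCL"]]
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})
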