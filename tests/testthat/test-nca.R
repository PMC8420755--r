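test_that("lambda-z regression is exact on log-linear data", {
  rec <- mono_exp_records(100, 0.1, times_h = c(1, 2, 3, 4) * 24)
  fit <- fit_lambda_z(rec, 1:4)
  expect_equal(fit[["lambda_z"]], 0.1, tolerance = 1e-12)
  expect_equal(fit[["r2_adj"]], 1, tolerance = 1e-12)
  # duplicate-time points are allowed; compare with the closed-form OLS
  rec2 <- data.frame(time_h = c(24, 24, 48, 96),
                     conc = c(95, 105, 60, 20), bql = 0L)
  fit2 <- fit_lambda_z(rec2, 1:4)
  ols <- stats::lm(log(conc) ~ I(time_h / 24), data = rec2)
  expect_equal(fit2[["lambda_z"]], -unname(coef(ols)[2]), tolerance = 1e-10)
  # rising terminal data: non-positive slope must be flagged upstream
  rising <- data.frame(time_h = c(24, 48, 96), conc = c(1, 2, 4), bql = 0L)
  expect_lt(fit_lambda_z(rising, 1:3)[["lambda_z"]], 0)
  expect_true(is.na(nca_parameters(rising, dose = 100)$lambda_z))
  expect_error(fit_lambda_z(rec, 1:2), "at least 3")
})

test_that("automatic tail selection matches a brute-force oracle", {
  oracle <- function(rec) {
    n <- nrow(rec)
    imax <- which.max(rec$conc)
    cand <- list()
    for (s in 1:(n - 2)) {
      idx <- s:n
      if (imax %in% idx) next
      cand[[length(cand) + 1]] <- idx
    }
    if (!length(cand)) for (s in 1:(n - 2)) cand[[length(cand) + 1]] <- s:n
    best <- NULL; best_r2 <- -Inf
    for (idx in cand) {
      m <- stats::lm(log(conc) ~ time_h, data = rec[idx, ])
      r2 <- summary(m)$adj.r.squared
      lz <- -coef(m)[2]
      if (lz <= 0) next
      if (r2 > best_r2 + 1e-12) { best_r2 <- r2; best <- idx }
    }
    best
  }
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  set.seed(99)
  for (i in 1:30) {
    times <- sort(sample(c(1, 6, 24, 48, 72, 96, 120, 168), 6))
    rec <- simulate_profile(p, 2000, times, sigma_log = 0.15,
                            seed = 1000 + i)
    expect_identical(select_terminal_points(rec), oracle(rec))
  }
  # a bare 3-point declining profile: the full set is the only choice
  rec3 <- mono_exp_records(50, 0.2, c(24, 96, 168))
  expect_identical(select_terminal_points(rec3), 1:3)
})

test_that("trapezoidal AUC matches the analytic integral", {
  # rectangle case: constant 10 ug/mL over one hour
  flat <- data.frame(time_h = c(1, 2), conc = c(10, 10), bql = 0L)
  expect_equal(auc_linear_trapezoid(flat), 10 / 24)
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  dense <- seq(1, 240, length.out = 1000)
  rec <- simulate_profile(p, 2000, dense, sigma_log = 0)
  exact <- stats::integrate(function(t) concentration(p, 2000, t),
                            hours_to_days(1), hours_to_days(240),
                            rel.tol = 1e-12)$value
  expect_equal(auc_linear_trapezoid(rec), exact, tolerance = 1e-4)
  expect_error(auc_linear_trapezoid(flat[1, ]), "at least 2")
})

test_that("NCA recovers one-compartment parameters on noise-free data", {
  # quasi one-compartment kinetics: negligible peripheral exchange
  p <- pk_params(CL = 10, V1 = 60, Q = 1e-7, V2 = 60)
  # sampling from very nearly t = 0 so the unobserved initial segment of
  # the observation-based AUC is negligible
  sched <- seq(1e-5, 1440, length.out = 100000)
  rec <- simulate_profile(p, 2000, sched, sigma_log = 0)
  out <- nca_parameters(rec, dose = 2000,
                        indices = (nrow(rec) - 9):nrow(rec))
  expect_equal(out$cl, 10, tolerance = 1e-6)
  expect_equal(out$vz, 60, tolerance = 1e-6)
  expect_equal(out$t_half, log(2) * 6, tolerance = 1e-7)
  expect_equal(out$lambda_z * out$t_half, log(2), tolerance = 1e-12)
  expect_equal(out$vz * out$lambda_z, out$cl, tolerance = 1e-12)
  expect_equal(out$c0, 2000 / 60, tolerance = 1e-6)
  expect_error(nca_parameters(rec, dose = 0), "dose")
})

test_that("NCA clearance matches the generative value for the reference kinetics", {
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  sched <- exp(seq(log(1), log(2400), length.out = 2000))
  rec <- simulate_profile(p, 2000, sched, sigma_log = 0)
  out <- nca_parameters(rec, dose = 2000,
                        indices = (nrow(rec) - 199):nrow(rec))
  expect_equal(out$cl, 11.9, tolerance = 0.01)
  expect_equal(out$auc_inf, 2000 / 11.9, tolerance = 0.01)
})

test_that("group summaries use geometric statistics with (n-1) variance", {
  const <- data.frame(cl = rep(4, 5), vz = rep(2, 5), c0 = rep(1, 5),
                      auc_last = rep(3, 5), auc_inf = rep(5, 5),
                      t_half = rep(2, 5))
  s <- summarize_group(const)
  expect_equal(s$cl_gm, 4)
  expect_equal(s$cl_gcv, 0)
  two <- data.frame(cl = c(1, exp(2)), vz = c(1, 1), c0 = c(1, 1),
                    auc_last = c(1, 1), auc_inf = c(1, 1), t_half = c(1, 3))
  s2 <- summarize_group(two)
  expect_equal(s2$cl_gm, exp(1), tolerance = 1e-12)
  expect_equal(s2$cl_gcv, 100 * sqrt(exp(2) - 1), tolerance = 1e-12)
  expect_equal(s2$t_half_median, 2)
  expect_equal(c(s2$t_half_min, s2$t_half_max), c(1, 3))
  # Monte-Carlo consistency of the geometric CV on a log-normal sample
  set.seed(8)
  x <- rlnorm(1e5, 0, 0.4)
  expect_equal(geo_cv_pct(x), 100 * sqrt(exp(0.4^2) - 1), tolerance = 0.02)
  expect_error(geo_mean(c(1, -1)), "positive")
})
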