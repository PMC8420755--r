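test_that("absorption-phase flagging follows the early-rise and tolerance rules", {
  clean <- data.frame(time_h = c(1, 48, 96, 168), conc = c(30, 20, 12, 6))
  expect_false(flag_absorption_phase(clean)$excluded)
  rising2 <- data.frame(time_h = c(1, 48, 96), conc = c(10, 12, 8))
  fl <- flag_absorption_phase(rising2)
  expect_true(fl$excluded)
  expect_identical(fl$reason, "partial_dose_absorption")
  # a 5% late rise sits inside the 10% noise guard
  late5 <- data.frame(time_h = c(1, 48, 96, 168), conc = c(30, 20, 12, 12.6))
  expect_false(flag_absorption_phase(late5)$excluded)
  late15 <- data.frame(time_h = c(1, 48, 96, 168), conc = c(30, 20, 12, 13.8))
  expect_true(flag_absorption_phase(late15)$excluded)
  # the guard is configurable
  expect_true(flag_absorption_phase(late5, rel_tol = 0.01)$excluded)
  expect_error(flag_absorption_phase(data.frame()), "empty")
})

test_that("QC catches injected partial-dose profiles and spares clean ones", {
  p <- pk_params(11.9, 61.8, 62.3, 62.3)
  sched <- c(1, 48, 96, 168)
  # artifacts over the generator's default severity range (IV fraction up
  # to 0.2; milder partial doses yield monotone profiles that carry no
  # detectable absorption signature)
  set.seed(44)
  n_flagged <- 0
  for (s in 1:30) {
    rec <- simulate_profile(p, 2000, sched, sigma_log = 0.110, seed = s)
    f_iv <- runif(1, 0, 0.2)
    bad <- inject_absorption_artifact(rec, f_iv, ka = runif(1, 0.2, 1),
                                      seed = s + 500, params = p,
                                      dose = 2000, sigma_log = 0.110)
    n_flagged <- n_flagged + flag_absorption_phase(bad)$excluded
  }
  expect_equal(n_flagged, 30)   # every artifact profile is excluded
  set.seed(12)
  clean_flags <- vapply(1:200, function(s) {
    rec <- simulate_profile(p, 2000, sched, sigma_log = 0.110, seed = 10000 + s)
    flag_absorption_phase(rec)$excluded
  }, logical(1))
  # the 10% late-rise guard trips on ~5% of clean profiles at this noise
  # level and sampling schedule (the terminal declines are shallow)
  expect_lt(mean(clean_flags), 0.08)
})

test_that("exact Mann-Whitney p-values equal full enumeration for n <= 6", {
  enum_oracle <- function(x, y) {
    N <- length(x) + length(y)
    pooled <- c(x, y)
    U_obs <- sum(rank(pooled)[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    picks <- utils::combn(N, length(x))
    us <- apply(picks, 2, function(ix) {
      sum(rank(pooled)[ix]) - length(x) * (length(x) + 1) / 2
    })
    p_le <- mean(us <= U_obs)
    p_ge <- mean(us >= U_obs)
    list(U = U_obs, p = min(1, 2 * min(p_le, p_ge)))
  }
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  set.seed(5)
  for (nx in 2:6) for (ny in 2:6) {
    x <- round(runif(nx, 0, 100), 6)
    y <- round(runif(ny, 30, 130), 6)
    got <- mann_whitney_u(x, y, mode = "exact")
    ora <- enum_oracle(x, y)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
    # cross-check against the standard implementation
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("ties and identical samples fall back to the corrected normal test", {
  same <- c(3, 1, 4, 1, 5)
  res <- mann_whitney_u(same, same)
  expect_identical(res$method, "normal")
  expect_equal(res$p, 1)
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), mode = "exact"), "tie")
  # the approximation tracks the exact tail for moderate samples
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8, 0.5)
    pe <- mann_whitney_u(x, y, mode = "exact")$p
    pn <- mann_whitney_u(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn), 0.005 + 0.05 * pe)
  }
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("tumour-adjusted weight is a guarded subtraction", {
  expect_equal(tumour_adjusted_weight(25, 0), 25)
  expect_equal(tumour_adjusted_weight(25, 2.5), 22.5)
  expect_error(tumour_adjusted_weight(20, 20), "tumour_weight")
  expect_error(tumour_adjusted_weight(20, -1), "tumour_weight")
})
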