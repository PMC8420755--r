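# Shared builders for the test suite. Everything is generated in code at
# run time; no stored fixtures.

# A small balanced dosed-only design (no vehicle, no artifacts) for quick
# population fits: `n_per_arm` animals in each of the 8 strain x tumour x
# dose arms.
small_design <- function(spec, n_per_arm = 3L, artifact_rate = 0) {
  des <- study_design(spec = spec, artifact_rate = artifact_rate)
  a <- des$arms
  a$n <- ifelse(a$dose_group == "vehicle", 0L, as.integer(n_per_arm))
  des$arms <- a
  des$terminal_h <- 168
  des
}

# Noise-free records of a mono-exponential decline C(t) = c0 * exp(-lz * t)
# (lz in 1/day, times in hours).
mono_exp_records <- function(c0, lz, times_h) {
  data.frame(time_h = times_h, conc = c0 * exp(-lz * hours_to_days(times_h)),
             bql = 0L)
}

# Reference structural parameters used throughout the recovery tests.
ref_structural <- function() pembro_mouse_spec("structural")
ref_covariate <- function() pembro_mouse_spec("covariate")

# Dosed-only balanced design (no vehicle, no artifacts): 8 arms of
# `n_per_arm`, fixed 168 h terminal sample.
small_dosed_design_test <- function(spec, n_per_arm) {
  small_design(spec, n_per_arm = n_per_arm)
}

# Subject list for map_eta / predict_log_concentrations.
make_subject <- function(params, dose, times_h, sigma_log = 0, seed = 1L,
                         cov = NULL) {
  rec <- simulate_profile(params, dose, times_h, sigma_log, seed)
  list(dose = dose, cov = cov, records = rec)
}
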