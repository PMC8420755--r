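## Replicate simulation-estimation experiments: the package's own evidence
## that the estimation machinery recovers known generative values at the
## study's design and sample size.

#' Structural-model parameter recovery experiment
#'
#' Simulates replicate 79-animal studies ([pk_population_design()]) from
#' the reference structural model, refits each with data-driven initial
#' values, and summarises the typical CL and V1 and the CL between-subject
#' CV% as medians across replicates.
#'
#' @param seeds integer vector of replicate seeds.
#' @param settings [foce_settings()].
#' @return list with `median_cl`, `median_v1`, `median_iiv_cl_cv`,
#'   `n_subjects`, and the per-replicate `fits` data frame.
#' @export
structural_recovery <- function(seeds = 1:5, settings = foce_settings()) {
  truth <- pembro_mouse_spec("structural")
  des <- pk_population_design(truth)
  rows <- lapply(seeds, function(s) {
    data <- generate_cohort(des, seed = s)
    fit <- foce_fit(data, init_spec_from_data(data), settings)
    data.frame(seed = s, cl = fit$theta_hat[["CL"]], v1 = fit$theta_hat[["V1"]],
               q = fit$theta_hat[["Q"]], v2 = fit$theta_hat[["V2"]],
               iiv_cl_cv = fit$iiv_cv_pct[["CL"]], sigma = fit$sigma_hat,
               ofv = fit$ofv, converged = fit$converged)
  })
  fits <- do.call(rbind, rows)
  list(median_cl = stats::median(fits$cl), median_v1 = stats::median(fits$v1),
       median_iiv_cl_cv = stats::median(fits$iiv_cl_cv),
       n_subjects = sum(des$arms$n), fits = fits)
}

#' Covariate-model parameter recovery experiment
#'
#' Simulates replicate 79-animal studies from the reference final
#' covariate model (tumour, muscle weight, IgG and Fcgrt-expression
#' effects), refits the same covariate model (coefficients started at 0)
#' by FOCE-I, and summarises the typical CL (median covariates,
#' tumour-free) and the residual SD as medians across replicates.
#'
#' @inheritParams structural_recovery
#' @return list with `median_cl`, `median_sigma`, `n_subjects`, `fits`.
#' @export
covariate_recovery <- function(seeds = 1:5, settings = foce_settings()) {
  truth <- pembro_mouse_spec("covariate")
  des <- pk_population_design(truth)
  rows <- lapply(seeds, function(s) {
    data <- generate_cohort(des, seed = s)
    init <- init_spec_from_data(data, covariate_effects = truth$covariate_effects)
    fit <- foce_fit(data, init, settings)
    data.frame(seed = s, cl = fit$theta_hat[["CL"]], v1 = fit$theta_hat[["V1"]],
               sigma = fit$sigma_hat, ofv = fit$ofv, converged = fit$converged,
               tum_cl = fit$coefficients[["TUM~CL"]],
               igg_cl = fit$coefficients[["IGG~CL"]])
  })
  fits <- do.call(rbind, rows)
  list(median_cl = stats::median(fits$cl),
       median_sigma = stats::median(fits$sigma),
       n_subjects = sum(des$arms$n), fits = fits)
}

#' First-selected covariate across replicate stepwise runs
#'
#' Simulates replicate cohorts from the final covariate model and records,
#' for each, which candidate effect the forward search would add first
#' (the univariate round of the stepwise procedure) at level `alpha`.
#'
#' @param seeds replicate seeds.
#' @param n_per_arm animals per strain x tumour x dose arm (8 arms; the
#'   default keeps the experiment light while preserving the design).
#' @param alpha inclusion threshold.
#' @param settings [foce_settings()].
#' @return list with `first` (character vector, `"COV~PAR"` or `"none"`)
#'   and `prop_tum_cl`, the fraction of replicates whose first addition is
#'   the tumour effect on clearance.
#' @export
scm_first_selection <- function(seeds = 1:20, n_per_arm = 5L, alpha = 0.05,
                                settings = foce_settings()) {
  truth <- pembro_mouse_spec("covariate")
  des <- small_dosed_design(truth, n_per_arm)
  cand <- rbind(
    covariate_effect("CL", "TUM", 0, "proportional"),
    covariate_effect("CL", "STR", 0, "proportional"),
    covariate_effect("CL", "MWT", 0, "power"),
    covariate_effect("CL", "FWT", 0, "power"),
    covariate_effect("CL", "IGG", 0, "power"),
    covariate_effect("CL", "FCRN", 0, "power"))
  base <- pop_model_spec(theta = pk_params(10, 60, 40, 60),
                         omega2 = c(CL = 0.1, V1 = 0.1, V2 = 0.1),
                         sigma_log = 0.15)
  first <- vapply(seeds, function(s) {
    data <- generate_cohort(des, seed = s)
    scr <- univariate_screen(data, base, cand, settings)
    rec <- scr$records
    ok <- which(is.finite(rec$p_value) & rec$p_value < alpha)
    if (!length(ok)) return("none")
    paste0(rec$covariate[ok[1]], "~", rec$parameter[ok[1]])
  }, character(1))
  list(first = first, prop_tum_cl = mean(first == "TUM~CL"))
}

#' Type-I error of the univariate covariate screen under the null
#'
#' Adds pure-noise covariates (log-normal, independent of everything) to
#' small cohorts simulated from the structural model and screens each as a
#' power effect on CL. Under the null the drop in OFV is chi-square(1), so
#' the selection rate at level `alpha` should match `alpha`.
#'
#' @param n_null total number of null screens.
#' @param n_datasets number of base cohorts the nulls are spread over.
#' @param n_per_arm animals per dosed arm of each base cohort.
#' @param alpha nominal level.
#' @param seed experiment seed.
#' @param settings [foce_settings()].
#' @return list with `rate`, `n_selected`, `n_null` and the vector of
#'   null `delta_ofv` values.
#' @export
null_screen_rate <- function(n_null = 200L, n_datasets = 5L, n_per_arm = 2L,
                             alpha = 0.05, seed = 1L,
                             settings = foce_settings()) {
  truth <- pembro_mouse_spec("structural")
  des <- small_dosed_design(truth, n_per_arm)
  base <- pop_model_spec(theta = pk_params(10, 60, 40, 60),
                         omega2 = c(CL = 0.1, V1 = 0.1, V2 = 0.1),
                         sigma_log = 0.15)
  per <- ceiling(n_null / n_datasets)
  deltas <- numeric(0)
  for (ds in seq_len(n_datasets)) {
    data <- generate_cohort(des, seed = derive_seed(seed, 7000L + ds))
    nsub <- length(unique(data$ID))
    noise <- with_seed(derive_seed(seed, 8000L + ds), {
      matrix(stats::rlnorm(nsub * per, 0, 0.3), nsub, per)
    })
    idx <- match(data$ID, sort(unique(data$ID)))
    k_here <- min(per, n_null - length(deltas))
    cand <- NULL
    for (k in seq_len(k_here)) {
      nm <- paste0("NZ", k)
      data[[nm]] <- noise[idx, k]
      cand <- rbind(cand, covariate_effect("CL", nm, 0, "power"))
    }
    scr <- univariate_screen(data, base, cand, settings)
    deltas <- c(deltas, scr$records$delta_ofv)
    if (length(deltas) >= n_null) break
  }
  deltas <- deltas[seq_len(n_null)]
  p <- lrt_p(deltas, 1L)
  list(rate = mean(p < alpha, na.rm = TRUE),
       n_selected = sum(p < alpha, na.rm = TRUE),
       n_null = n_null, delta_ofv = deltas)
}

## dosed-only balanced design used by the scaled-down experiments
small_dosed_design <- function(spec, n_per_arm) {
  des <- study_design(spec = spec, artifact_rate = 0)
  a <- des$arms
  a$n <- ifelse(a$dose_group == "vehicle", 0L, as.integer(n_per_arm))
  des$arms <- a
  des$terminal_h <- 168
  des
}
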