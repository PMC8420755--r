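## Population model specification: typical values, covariate effects,
## between-subject variances and the residual error SD.

#' Define a covariate effect
#'
#' @param parameter one of `"CL"`, `"V1"`, `"Q"`, `"V2"`.
#' @param covariate name of a covariate column (e.g. `"TUM"`, `"IGG"`).
#' @param coefficient dimensionless effect size.
#' @param form `"power"` for continuous covariates normalised by the
#'   population median (`(cov/median)^coefficient`), `"proportional"` for
#'   dichotomous indicators (`1 + coefficient * I`), or `"exponential"`
#'   for the alternative dichotomous form `exp(coefficient * I)`.
#' @return one-row data frame.
#' @export
covariate_effect <- function(parameter, covariate, coefficient,
                             form = c("power", "proportional", "exponential")) {
  form <- match.arg(form)
  stopifnot(parameter %in% c("CL", "V1", "Q", "V2"), is.numeric(coefficient))
  data.frame(parameter = parameter, covariate = covariate,
             coefficient = coefficient, form = form,
             stringsAsFactors = FALSE)
}

#' Construct a population pharmacokinetic model specification
#'
#' Holds the typical two-compartment parameters, the covariate sub-model,
#' the diagonal between-subject (eta) variances and the residual SD of the
#' additive error on log-concentration. Individual parameters are
#'
#' `P_i = theta_P * prod (cov/median)^coef * prod (1 + coef * I) * exp(eta_P)`
#'
#' with eta supported on CL, V1 and V2 (Q carries no between-subject term).
#'
#' @param theta a [pk_params()] vector of typical values.
#' @param covariate_effects data frame of rows from [covariate_effect()],
#'   or `NULL` for the structural (covariate-free) model. An optional
#'   logical column `forced` marks effects exempt from backward elimination.
#' @param omega2 named non-negative variances for `CL`, `V1`, `V2` on the
#'   log scale; a zero fixes that random effect at 0.
#' @param sigma_log positive residual SD on the log-concentration scale.
#' @param covariate_medians named numeric normalisation constants for every
#'   continuous covariate used in a power-form effect; `NULL` to fill them
#'   from the data at fit/simulation time.
#' @return object of class `pop_model_spec`.
#' @export
pop_model_spec <- function(theta, covariate_effects = NULL,
                           omega2 = c(CL = 0, V1 = 0, V2 = 0),
                           sigma_log = 0.1, covariate_medians = NULL) {
  theta <- as_pk_params(theta)
  om <- c(CL = 0, V1 = 0, V2 = 0)
  if (!is.null(omega2)) {
    if (is.null(names(omega2))) names(omega2) <- c("CL", "V1", "V2")[seq_along(omega2)]
    stopifnot(all(names(omega2) %in% names(om)))
    om[names(omega2)] <- omega2
  }
  if (any(om < 0)) stop("omega2 entries must be >= 0")
  if (!is.finite(sigma_log) || sigma_log <= 0) stop("sigma_log must be > 0")
  if (!is.null(covariate_effects)) {
    stopifnot(is.data.frame(covariate_effects),
              all(c("parameter", "covariate", "coefficient", "form") %in%
                    names(covariate_effects)))
    if (is.null(covariate_effects$forced)) covariate_effects$forced <- FALSE
    bad <- !covariate_effects$parameter %in% c("CL", "V1", "Q", "V2")
    if (any(bad)) stop("covariate effect on unknown parameter: ",
                       paste(covariate_effects$parameter[bad], collapse = ", "))
  }
  structure(list(theta = theta, covariate_effects = covariate_effects,
                 omega2 = om, sigma_log = sigma_log,
                 covariate_medians = covariate_medians),
            class = "pop_model_spec")
}

#' @export
print.pop_model_spec <- function(x, ...) {
  cat("Population two-compartment IV-bolus model\n")
  cat(sprintf("  theta: CL %.4g mL/day/kg, V1 %.4g mL/kg, Q %.4g mL/day/kg, V2 %.4g mL/kg\n",
              x$theta[["CL"]], x$theta[["V1"]], x$theta[["Q"]], x$theta[["V2"]]))
  cat(sprintf("  IIV CV%%: CL %.1f, V1 %.1f, V2 %.1f\n",
              omega2_to_cv_pct(x$omega2[["CL"]]),
              omega2_to_cv_pct(x$omega2[["V1"]]),
              omega2_to_cv_pct(x$omega2[["V2"]])))
  cat(sprintf("  residual SD (log scale): %.4g\n", x$sigma_log))
  if (!is.null(x$covariate_effects) && nrow(x$covariate_effects)) {
    cat("  covariate effects:\n")
    for (i in seq_len(nrow(x$covariate_effects))) {
      e <- x$covariate_effects[i, ]
      cat(sprintf("    %s on %s: %.4g (%s)%s\n", e$covariate, e$parameter,
                  e$coefficient, e$form, if (isTRUE(e$forced)) " [forced]" else ""))
    }
  }
  invisible(x)
}

#' Reference population estimates for pembrolizumab in tumour-bearing mice
#'
#' Published population estimates from a single-dose murine pembrolizumab
#' cachexia study: the covariate-free structural model, or the final
#' covariate model in which tumour presence, terminal gastrocnemius weight,
#' total murine IgG and relative hepatic Fcgrt expression act on CL, and
#' total IgG additionally acts on V1 and Q. Used as simulation truth and as
#' a benchmark for recovery experiments.
#'
#' @param model `"structural"` or `"covariate"`.
#' @param covariate_medians optional named medians for IGG, MWT and FCRN;
#'   left `NULL` they are filled from data when the spec is used.
#' @return a [pop_model_spec()].
#' @export
pembro_mouse_spec <- function(model = c("structural", "covariate"),
                              covariate_medians = NULL) {
  model <- match.arg(model)
  if (model == "structural") {
    pop_model_spec(
      theta = pk_params(CL = 11.9, V1 = 61.8, Q = 62.3, V2 = 62.3),
      omega2 = c(CL = cv_pct_to_omega2(55.0), V1 = cv_pct_to_omega2(30.2),
                 V2 = cv_pct_to_omega2(50.7)),
      sigma_log = 0.110)
  } else {
    eff <- rbind(
      covariate_effect("CL", "TUM", 0.65, "proportional"),
      covariate_effect("CL", "MWT", -1.04, "power"),
      covariate_effect("CL", "IGG", 0.286, "power"),
      covariate_effect("V1", "IGG", 0.116, "power"),
      covariate_effect("Q", "IGG", 0.415, "power"),
      covariate_effect("CL", "FCRN", -0.227, "power"))
    eff$forced <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
    pop_model_spec(
      theta = pk_params(CL = 8.35, V1 = 61.6, Q = 61.1, V2 = 66.1),
      covariate_effects = eff,
      omega2 = c(CL = cv_pct_to_omega2(29.6), V1 = cv_pct_to_omega2(27.6),
                 V2 = cv_pct_to_omega2(51.9)),
      sigma_log = 0.110,
      covariate_medians = covariate_medians)
  }
}

## Multiplicative covariate factor on one parameter for a set of subjects.
## `cov_df` is a data frame with one row per subject. Returns a vector of
## factors (1 when no effect applies). Complex-safe not required here:
## coefficients enter linearly through log/log1p at fit time instead.
covariate_factors <- function(spec, cov_df, parameter) {
  eff <- spec$covariate_effects
  n <- max(1L, NROW(cov_df))   # empty covariates: a single unadjusted subject
  fac <- rep(1, n)
  if (is.null(eff)) return(fac)
  eff <- eff[eff$parameter == parameter, , drop = FALSE]
  for (i in seq_len(nrow(eff))) {
    e <- eff[i, ]
    if (!e$covariate %in% names(cov_df)) {
      stop("covariate '", e$covariate, "' not present in data")
    }
    x <- cov_df[[e$covariate]]
    if (e$form == "power") {
      med <- spec$covariate_medians[[e$covariate]]
      if (is.null(med)) stop("no median supplied for covariate '", e$covariate, "'")
      if (any(x <= 0)) stop("power-form covariate '", e$covariate,
                            "' must be strictly positive")
      fac <- fac * (x / med)^e$coefficient
    } else if (e$form == "proportional") {
      shift <- 1 + e$coefficient * x
      if (any(shift <= 0)) stop("proportional effect of '", e$covariate,
                                "' yields non-positive factor")
      fac <- fac * shift
    } else {
      fac <- fac * exp(e$coefficient * x)
    }
  }
  fac
}

#' Individual pharmacokinetic parameters
#'
#' Applies the covariate sub-model and the exponential between-subject
#' terms to the typical values:
#' `P_i = theta_P * prod (cov/median)^coef * prod (1 + coef*I) * exp(eta_P)`.
#'
#' @param spec a [pop_model_spec()] whose `covariate_medians` cover every
#'   power-form covariate.
#' @param cov named list / one-row data frame of covariate values.
#' @param eta named numeric with entries `CL`, `V1`, `V2` (missing entries
#'   are taken as 0; Q never carries an eta).
#' @return a [pk_params()] vector.
#' @export
#' @examples
#' sp <- pembro_mouse_spec("covariate",
#'   covariate_medians = c(IGG = 15, MWT = 0.12, FCRN = 1))
#' individual_parameters(sp,
#'   cov = list(TUM = 1, IGG = 15, MWT = 0.12, FCRN = 1),
#'   eta = c(CL = 0, V1 = 0, V2 = 0))
individual_parameters <- function(spec, cov, eta = c(CL = 0, V1 = 0, V2 = 0)) {
  stopifnot(inherits(spec, "pop_model_spec"))
  cov_df <- as.data.frame(cov, stringsAsFactors = FALSE)
  e <- c(CL = 0, V1 = 0, V2 = 0)
  if (length(eta)) {
    if (is.null(names(eta))) names(eta) <- c("CL", "V1", "V2")[seq_along(eta)]
    e[names(eta)] <- eta
  }
  p <- vapply(c("CL", "V1", "Q", "V2"), function(pn) {
    spec$theta[[pn]] * covariate_factors(spec, cov_df, pn)[1] *
      exp(if (pn == "Q") 0 else e[[pn]])
  }, numeric(1))
  pk_params(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]])
}
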