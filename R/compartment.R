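## Closed-form linear two-compartment IV-bolus kinetics.
##
## The model is parameterized in terms of clearance (CL, mL/day/kg), central
## volume (V1, mL/kg), intercompartmental clearance (Q, mL/day/kg) and
## peripheral volume (V2, mL/kg); doses are per kg body weight (ug/kg) so
## concentrations come out in ug/mL. Micro and hybrid rate constants are
## internal reparameterizations.

#' Construct a two-compartment parameter vector
#'
#' @param CL clearance, mL/day/kg.
#' @param V1 central volume of distribution, mL/kg.
#' @param Q intercompartmental clearance, mL/day/kg.
#' @param V2 peripheral volume of distribution, mL/kg.
#' @return named numeric vector of class `pk_params`.
#' @export
#' @examples
#' pk_params(CL = 11.9, V1 = 61.8, Q = 62.3, V2 = 62.3)
pk_params <- function(CL, V1, Q, V2) {
  p <- c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all of CL, V1, Q, V2 must be finite and strictly positive")
  }
  structure(p, class = "pk_params")
}

#' Micro rate constants of the two-compartment model
#'
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` (all 1/day).
#'
#' @param params a [pk_params()] vector.
#' @return named vector `c(k10, k12, k21)`.
#' @export
micro_constants <- function(params) {
  params <- as_pk_params(params)
  c(k10 = unname(params["CL"] / params["V1"]),
    k12 = unname(params["Q"] / params["V1"]),
    k21 = unname(params["Q"] / params["V2"]))
}

as_pk_params <- function(params) {
  if (inherits(params, "pk_params")) return(params)
  if (!is.numeric(params) || length(params) != 4) {
    stop("params must be a pk_params vector or numeric of length 4 (CL, V1, Q, V2)")
  }
  if (is.null(names(params))) names(params) <- c("CL", "V1", "Q", "V2")
  pk_params(params[["CL"]], params[["V1"]], params[["Q"]], params[["V2"]])
}

#' Hybrid (biexponential) constants
#'
#' Roots `alpha > beta` of `s^2 - (k10+k12+k21) s + k10 k21` and the
#' coefficients of `C(t) = dose (coefA e^{-alpha t} + coefB e^{-beta t})`,
#' with `coefA + coefB = 1/V1`.
#'
#' @param k micro constants from [micro_constants()].
#' @param V1 central volume, mL/kg.
#' @return named vector `c(alpha, beta, coefA, coefB)`.
#' @export
hybrid_constants <- function(k, V1) {
  stopifnot(all(k > 0), V1 > 0)
  s <- k[["k10"]] + k[["k12"]] + k[["k21"]]
  disc <- s^2 - 4 * k[["k10"]] * k[["k21"]]
  if (disc <= 0 || sqrt(disc) / s < 1e-10) {
    stop("degenerate kinetics: alpha and beta are not separated; unsupported input")
  }
  root <- sqrt(disc)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  coefA <- (alpha - k[["k21"]]) / (V1 * (alpha - beta))
  coefB <- (k[["k21"]] - beta) / (V1 * (alpha - beta))
  c(alpha = alpha, beta = beta, coefA = coefA, coefB = coefB)
}

#' Plasma concentration after an IV bolus
#'
#' Closed-form biexponential solution
#' `C(t) = dose * (coefA e^{-alpha t} + coefB e^{-beta t})`; `C(0) = dose/V1`.
#'
#' @param params a [pk_params()] vector.
#' @param dose dose in ug per kg body weight.
#' @param t time(s) in days, `>= 0`.
#' @return concentrations in ug/mL, one per element of `t`.
#' @export
#' @examples
#' p <- pk_params(11.9, 61.8, 62.3, 62.3)
#' concentration(p, dose = 2000, t = c(0, 1, 2, 7))
concentration <- function(params, dose, t) {
  params <- as_pk_params(params)
  stopifnot(dose >= 0, all(t >= 0))
  h <- hybrid_constants(micro_constants(params), params[["V1"]])
  dose * (h[["coefA"]] * exp(-h[["alpha"]] * t) + h[["coefB"]] * exp(-h[["beta"]] * t))
}

#' Analytic area under the curve to infinity
#'
#' For linear kinetics `AUC(0, Inf) = dose / CL`, independent of the
#' distributional parameters.
#'
#' @inheritParams concentration
#' @return AUC in day*ug/mL.
#' @export
#' @examples
#' analytic_auc_inf(pk_params(9.81, 60, 60, 60), dose = 2000) # 2000 / 9.81
analytic_auc_inf <- function(params, dose) {
  params <- as_pk_params(params)
  stopifnot(dose >= 0)
  dose / params[["CL"]]
}

## Vectorised biexponential evaluation used by the simulator and the FOCE
## engine: CL, V1, Q, V2, dose, t are equal-length vectors (or scalars that
## recycle). Branch-free so it also supports complex-step differentiation.
conc_2cmt_vec <- function(CL, V1, Q, V2, dose, t) {
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  root <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  coefA <- (alpha - k21) / (V1 * (alpha - beta))
  coefB <- (k21 - beta) / (V1 * (alpha - beta))
  dose * (coefA * exp(-alpha * t) + coefB * exp(-beta * t))
}

## Concentration under partial IV bolus (fraction f of the dose) plus a
## first-order depot absorbing the remaining 1 - f at rate ka (1/day).
## Standard three-exponential solution of the depot + two-compartment system.
conc_2cmt_depot_vec <- function(CL, V1, Q, V2, dose, t, f_iv, ka) {
  civ <- conc_2cmt_vec(CL, V1, Q, V2, dose * f_iv, t)
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  root <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  da <- dose * (1 - f_iv)
  cdep <- (ka * da / V1) * (
    (k21 - alpha) / ((ka - alpha) * (beta - alpha)) * exp(-alpha * t) +
    (k21 - beta) / ((ka - beta) * (alpha - beta)) * exp(-beta * t) +
    (k21 - ka) / ((alpha - ka) * (beta - ka)) * exp(-ka * t))
  civ + cdep
}
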