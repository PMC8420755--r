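#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

HOURS_PER_DAY <- 24

#' Convert hours to days
#'
#' Sampling schedules are recorded in hours (the bench convention) while all
#' rate constants and clearances are per day, so time is converted once at
#' the boundary.
#'
#' @param h numeric vector of times in hours.
#' @return times in days.
#' @export
hours_to_days <- function(h) h / HOURS_PER_DAY

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return `exp(mean(log(x)))`.
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Geometric coefficient of variation (percent)
#'
#' Computed as `100 * sqrt(exp(var(log(x))) - 1)` with the sample (n - 1)
#' variance, the convention used for log-normal pharmacokinetic summaries.
#'
#' @inheritParams geo_mean
#' @return geometric CV in percent.
#' @export
geo_cv_pct <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric CV requires strictly positive values")
  100 * sqrt(exp(stats::var(log(x))) - 1)
}

#' Convert a log-scale variance to a CV percent
#'
#' For an exponential (log-normal) between-subject model with variance
#' `omega2` on the log scale, the coefficient of variation of the individual
#' parameter is `100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 non-negative variance on the log scale.
#' @return CV in percent.
#' @export
omega2_to_cv_pct <- function(omega2) {
  stopifnot(all(omega2 >= 0))
  100 * sqrt(exp(omega2) - 1)
}

#' Convert a CV percent to a log-scale variance
#'
#' Inverse of [omega2_to_cv_pct()].
#'
#' @param cv_pct CV in percent.
#' @return variance on the log scale.
#' @export
cv_pct_to_omega2 <- function(cv_pct) {
  stopifnot(all(cv_pct >= 0))
  log1p((cv_pct / 100)^2)
}

## Log-normal meanlog/sdlog matching a target arithmetic mean and SD.
lnorm_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log1p((sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

## Deterministic per-subject sub-seed derived from a cohort seed; kept well
## below .Machine$integer.max.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}

## Run expr with a local RNG state seeded at `seed`, restoring the caller's
## stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
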