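## Per-subject non-compartmental analysis: automatic terminal-phase
## selection (adjusted-R^2 maximisation over contiguous tails), log-linear
## lambda-z regression, linear trapezoidal AUC, and group summaries
## reported as geometric mean (geometric CV%) with T1/2 as median (min,
## max). Time is handled in days throughout; records carry hours.

#' Automatic terminal-phase point selection
#'
#' Evaluates every contiguous tail of at least three positive-concentration
#' points that excludes the maximum-concentration point, and returns the
#' tail maximising the adjusted R^2 of the log-linear regression, ties
#' broken toward more points (the "best fit" convention of standard NCA
#' software).
#'
#' @param records data frame with `time_h` and `conc` (and optionally
#'   `bql`; BQL rows are ignored).
#' @return integer indices into `records` of the selected tail, or `NULL`
#'   when no admissible tail yields a positive lambda-z.
#' @export
select_terminal_points <- function(records) {
  usable <- which(records$conc > 0 & (records$bql %||% 0) == 0)
  if (length(usable) < 3) return(NULL)
  imax <- usable[which.max(records$conc[usable])]
  n <- length(usable)
  pick_best <- function(require_no_cmax) {
    best <- NULL
    best_r2 <- -Inf
    # longest tails are visited first, so strict > keeps them on ties
    for (s in seq_len(n - 2)) {
      idx <- usable[s:n]
      if (require_no_cmax && imax %in% idx) next
      fit <- loglin_fit(records$time_h[idx], records$conc[idx])
      if (fit[["lambda_z"]] <= 0) next
      if (fit[["r2_adj"]] > best_r2 + 1e-12) {
        best_r2 <- fit[["r2_adj"]]
        best <- idx
      }
    }
    best
  }
  # the peak is excluded from the terminal fit; when too few points remain
  # for that (e.g. a bare 3-point profile) the unrestricted tails are used
  pick_best(TRUE) %||% pick_best(FALSE)
}

## OLS of log(conc) on time (hours in, rate per day out).
loglin_fit <- function(time_h, conc) {
  t_d <- hours_to_days(time_h)
  y <- log(conc)
  n <- length(y)
  mx <- mean(t_d)
  my <- mean(y)
  sxx <- sum((t_d - mx)^2)
  sxy <- sum((t_d - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * t_d)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  r2_adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  c(lambda_z = -slope, intercept = intercept, r2 = r2, r2_adj = r2_adj)
}

#' Terminal elimination rate constant by log-linear least squares
#'
#' @param records data frame with `time_h`, `conc`.
#' @param indices indices of the terminal points (>= 3, concentrations > 0).
#' @return named vector `c(lambda_z, intercept, r2_adj)`; `lambda_z` in
#'   1/day, intercept on the log scale.
#' @export
fit_lambda_z <- function(records, indices) {
  if (length(indices) < 3) stop("need at least 3 terminal points")
  conc <- records$conc[indices]
  if (any(conc <= 0)) stop("terminal points must have positive concentrations")
  fit <- loglin_fit(records$time_h[indices], conc)
  fit[c("lambda_z", "intercept", "r2_adj")]
}

#' Linear trapezoidal AUC between the first and last measurable samples
#'
#' `sum (t_{i+1} - t_i) (C_i + C_{i+1}) / 2` over the observed records; no
#' back-extrapolation to time zero (the observation-based AUC_last
#' convention; the initial concentration is reported separately).
#'
#' @param records data frame with `time_h`, `conc`, times increasing.
#' @return AUC in day*ug/mL.
#' @export
auc_linear_trapezoid <- function(records) {
  keep <- (records$bql %||% 0) == 0
  t_d <- hours_to_days(records$time_h[keep])
  c_ <- records$conc[keep]
  if (length(t_d) < 2) stop("need at least 2 records for a trapezoidal AUC")
  if (is.unsorted(t_d, strictly = TRUE)) stop("record times must be strictly increasing")
  sum(diff(t_d) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
}

#' Per-subject non-compartmental parameters
#'
#' Computes lambda-z (automatic tail selection unless `indices` is given),
#' AUC_last (linear trapezoid from the first observation), AUC_inf =
#' AUC_last + C_last/lambda-z, CL = dose/AUC_inf, Vz = CL/lambda-z, T1/2 =
#' ln2/lambda-z, and C0 by log-linear back-extrapolation through the first
#' two points (IV-bolus convention; falls back to the first observed
#' concentration when the profile starts flat or rising).
#'
#' @param records data frame with `time_h`, `conc` and optional `bql`.
#' @param dose dose in ug/kg, > 0.
#' @param indices optional terminal-point indices overriding the automatic
#'   selection.
#' @return one-row data frame (class amended with `nca_result`) with
#'   columns `lambda_z`, `n_lambda_points`, `r2_adj`, `auc_last`,
#'   `auc_inf`, `cl`, `vz`, `t_half`, `c0`, `pct_extrapolated`,
#'   `n_bql`; all-NA PK columns when lambda-z is not estimable.
#' @export
nca_parameters <- function(records, dose, indices = NULL) {
  if (!is.numeric(dose) || dose <= 0) stop("dose must be > 0")
  n_bql <- sum((records$bql %||% 0) != 0)
  if (is.null(indices)) indices <- select_terminal_points(records)
  na_row <- data.frame(lambda_z = NA_real_, n_lambda_points = 0L,
                       r2_adj = NA_real_, auc_last = NA_real_,
                       auc_inf = NA_real_, cl = NA_real_, vz = NA_real_,
                       t_half = NA_real_, c0 = NA_real_,
                       pct_extrapolated = NA_real_, n_bql = n_bql)
  if (is.null(indices) || length(indices) < 3) return(na_row)
  fit <- fit_lambda_z(records, indices)
  lz <- fit[["lambda_z"]]
  if (lz <= 0) return(na_row)
  keep <- which((records$bql %||% 0) == 0 & records$conc > 0)
  auc_last <- auc_linear_trapezoid(records[keep, ])
  c_last <- records$conc[keep[length(keep)]]
  auc_inf <- auc_last + c_last / lz
  cl <- dose / auc_inf
  vz <- cl / lz
  i12 <- keep[1:2]
  c0 <- if (records$conc[i12[2]] < records$conc[i12[1]]) {
    f2 <- loglin_fit(records$time_h[i12], records$conc[i12])
    exp(f2[["intercept"]])
  } else records$conc[i12[1]]
  data.frame(lambda_z = lz, n_lambda_points = length(indices),
             r2_adj = fit[["r2_adj"]], auc_last = auc_last, auc_inf = auc_inf,
             cl = cl, vz = vz, t_half = log(2) / lz, c0 = c0,
             pct_extrapolated = 100 * (auc_inf - auc_last) / auc_inf,
             n_bql = n_bql)
}

#' Non-compartmental analysis of a pipeline dataset
#'
#' Runs [nca_parameters()] on every dosed subject.
#'
#' @param data pipeline dataset (see [read_pk_dataset()]).
#' @return data frame, one row per dosed subject, with `ID`, dose, the
#'   dataset covariates and the NCA parameter columns.
#' @export
run_nca <- function(data) {
  doses <- data[data$EVID == 1 & data$AMT > 0, c("ID", "AMT")]
  res <- lapply(seq_len(nrow(doses)), function(i) {
    id <- doses$ID[i]
    obs <- data[data$EVID == 0 & data$ID == id, ]
    rec <- data.frame(time_h = obs$TIME, conc = obs$DV,
                      bql = if ("BQL" %in% names(obs)) obs$BQL else 0L)
    out <- nca_parameters(rec, doses$AMT[i])
    covs <- obs[1, intersect(c("TUM", "STR", "DOSEGRP", "MWT", "FWT", "PBWT",
                               "IGG", "ALB", "FCRN"), names(obs)), drop = FALSE]
    cbind(data.frame(ID = id, dose = doses$AMT[i]), covs, out)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group summary of NCA results
#'
#' Geometric mean with geometric CV% for `c0`, `vz`, `cl`, `auc_last` and
#' `auc_inf`; the terminal half-life is summarised as median (min, max).
#'
#' @param results rows from [run_nca()] / [nca_parameters()] (one group).
#' @return one-row data frame with `n` and, per parameter, the point
#'   summary and spread columns.
#' @export
summarize_group <- function(results) {
  if (!nrow(results)) stop("empty result set")
  ok <- !is.na(results$cl)
  r <- results[ok, ]
  gm <- function(x) geo_mean(x)
  gcv <- function(x) geo_cv_pct(x)
  data.frame(
    n = nrow(r),
    t_half_median = stats::median(r$t_half),
    t_half_min = min(r$t_half), t_half_max = max(r$t_half),
    c0_gm = gm(r$c0), c0_gcv = gcv(r$c0),
    vz_gm = gm(r$vz), vz_gcv = gcv(r$vz),
    cl_gm = gm(r$cl), cl_gcv = gcv(r$cl),
    auc_last_gm = gm(r$auc_last), auc_last_gcv = gcv(r$auc_last),
    auc_inf_gm = gm(r$auc_inf), auc_inf_gcv = gcv(r$auc_inf))
}

#' Table-shaped NCA summary by tumour status and dose
#'
#' @param nca_table output of [run_nca()].
#' @return data frame with one row per tumour-status x dose group.
#' @export
nca_group_table <- function(nca_table) {
  nca_table <- nca_table[!is.na(nca_table$cl), ]
  groups <- split(nca_table, list(nca_table$TUM, nca_table$dose), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(data.frame(tumour = g$TUM[1], dose_ug_kg = g$dose[1]),
          summarize_group(g))
  }))
  rownames(out) <- NULL
  out[order(out$tumour, out$dose_ug_kg), ]
}
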