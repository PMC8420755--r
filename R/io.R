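## Dataset I/O in a NONMEM-like rectangular CSV dialect: one row per dose
## event or observation, comma-separated, "." as the missing marker,
## header required. TIME is stored in hours in files and converted to days
## internally by the analysis engines.

DATASET_COLS <- c("ID", "TIME", "DV", "AMT", "EVID",
                  "TUM", "STR", "DOSEGRP", "MWT", "FWT", "PBWT", "IGG",
                  "ALB", "FCRN")

#' Write a pipeline dataset
#'
#' @param data dataset data frame (see [read_pk_dataset()] for the layout).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  cols <- intersect(DATASET_COLS, names(data))
  out <- data[, cols, drop = FALSE]
  for (cn in cols) {
    x <- out[[cn]]
    out[[cn]] <- ifelse(is.na(x), ".",
                        if (is.numeric(x)) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE) else as.character(x))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a pipeline dataset
#'
#' Required columns: `ID`, `TIME` (hours), `DV` (ug/mL, "." on dose rows),
#' `AMT` (ug/kg, "." on observation rows), `EVID` (0 observation, 1 dose).
#' Covariate columns (`TUM`, `STR`, `DOSEGRP`, `MWT`, `FWT`, `PBWT`,
#' `IGG`, `ALB`, `FCRN`) are carried through when present. Violations are
#' reported with row numbers.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_pk_dataset <- function(path) {
  raw <- utils::read.csv(path, na.strings = ".", stringsAsFactors = FALSE)
  required <- c("ID", "TIME", "DV", "AMT", "EVID")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- intersect(setdiff(DATASET_COLS, "DOSEGRP"), names(raw))
  for (cn in num_cols) {
    if (!is.numeric(raw[[cn]])) {
      bad <- which(!is.na(raw[[cn]]) & is.na(suppressWarnings(as.numeric(raw[[cn]]))))
      if (length(bad)) {
        stop("non-numeric values in column ", cn, " at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      raw[[cn]] <- as.numeric(raw[[cn]])
    }
  }
  if (any(bad <- raw$TIME < 0)) {
    stop("negative TIME at row(s): ", paste(which(bad), collapse = ", "))
  }
  if (!all(raw$EVID %in% c(0L, 1L))) stop("EVID must be 0 or 1")
  key <- paste(raw$ID, raw$TIME, raw$EVID)
  if (anyDuplicated(key)) {
    stop("duplicate (ID, TIME, EVID) keys at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  obs <- raw$EVID == 0
  if (any(bad <- obs & is.na(raw$DV))) {
    stop("missing DV on observation row(s): ", paste(which(bad), collapse = ", "))
  }
  if (any(bad <- !obs & !is.na(raw$DV))) {
    stop("DV present on dose row(s): ", paste(which(bad), collapse = ", "))
  }
  ndose <- table(factor(raw$ID[raw$EVID == 1], levels = unique(raw$ID)))
  if (any(ndose > 1)) {
    stop("subjects with more than one dose row: ",
         paste(names(ndose)[ndose > 1], collapse = ", "))
  }
  raw
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate, QC, non-compartmental analysis, FOCE-I fit and (optionally)
#' stepwise covariate modelling, writing one CSV per stage plus a run log
#' carrying the seed and settings hash so identical seed and configuration
#' reproduce identical outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param design [study_design()] config.
#' @param seed cohort seed.
#' @param fit_spec initial spec for the population fit; `NULL` for
#'   data-driven initials via [init_spec_from_data()].
#' @param steps subset of `c("simulate", "qc", "nca", "fit", "scm")`.
#' @param candidates,alpha SCM candidate set and threshold.
#' @param settings [foce_settings()].
#' @return list with the per-stage results, invisibly.
#' @export
run_pipeline <- function(out_dir, design = study_design(), seed = 1L,
                         fit_spec = NULL,
                         steps = c("simulate", "qc", "nca", "fit"),
                         candidates = default_candidates(), alpha = 0.05,
                         settings = foce_settings()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  logline("cachexpk pipeline, package %s",
          as.character(utils::packageVersion("cachexpk")))
  logline("seed: %d", as.integer(seed))
  logline("steps: %s", paste(steps, collapse = ", "))

  out <- list()
  data <- generate_cohort(design, seed = seed)
  if ("simulate" %in% steps) {
    write_pk_dataset(data, file.path(out_dir, "dataset.csv"))
    logline("simulate: %d subjects, %d rows", length(unique(data$ID)), nrow(data))
  }
  out$data <- data

  flags <- qc_dataset(data)
  if ("qc" %in% steps) {
    utils::write.csv(flags, file.path(out_dir, "qc_flags.csv"), row.names = FALSE)
    logline("qc: %d of %d dosed subjects excluded", sum(flags$excluded),
            nrow(flags))
  }
  clean <- apply_qc(data, flags)
  out$qc <- flags

  if ("nca" %in% steps) {
    nca <- run_nca(clean)
    utils::write.csv(nca, file.path(out_dir, "nca_subjects.csv"), row.names = FALSE)
    grp <- nca_group_table(nca)
    utils::write.csv(grp, file.path(out_dir, "nca_summary.csv"), row.names = FALSE)
    logline("nca: %d subjects, %d groups", nrow(nca), nrow(grp))
    out$nca <- nca
    out$nca_summary <- grp
  }

  if ("fit" %in% steps) {
    if (is.null(fit_spec)) fit_spec <- init_spec_from_data(clean)
    fit <- foce_fit(clean, fit_spec, settings)
    est <- fit_estimates_table(fit)
    utils::write.csv(est, file.path(out_dir, "fit_estimates.csv"), row.names = FALSE)
    utils::write.csv(fit$ebes, file.path(out_dir, "fit_ebes.csv"), row.names = FALSE)
    logline("fit: OFV %.3f, converged %s", fit$ofv, fit$converged)
    out$fit <- fit
  }

  if ("scm" %in% steps) {
    base_spec <- if (!is.null(out$fit)) out$fit$spec_init else
      init_spec_from_data(clean)
    scm <- run_scm(clean, base_spec, candidates, alpha, settings)
    utils::write.csv(scm$screen, file.path(out_dir, "scm_univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(scm$forward, file.path(out_dir, "scm_forward.csv"),
                     row.names = FALSE)
    utils::write.csv(scm$backward, file.path(out_dir, "scm_backward.csv"),
                     row.names = FALSE)
    logline("scm: %d effects in final model",
            NROW(scm$final_spec$covariate_effects))
    out$scm <- scm
  }
  invisible(out)
}

#' Estimates table of a FOCE-I fit
#'
#' One row per estimated quantity with the units used throughout
#' (mL/day/kg, mL/kg), IIV as CV% and the residual as a standard
#' deviation on the log scale.
#'
#' @param fit a [foce_fit()] result.
#' @return data frame.
#' @export
fit_estimates_table <- function(fit) {
  rows <- data.frame(
    parameter = c("CL (mL/day/kg)", "V1 (mL/kg)", "Q (mL/day/kg)", "V2 (mL/kg)"),
    estimate = as.numeric(fit$theta_hat),
    iiv_cv_pct = c(fit$iiv_cv_pct[["CL"]], fit$iiv_cv_pct[["V1"]], NA,
                   fit$iiv_cv_pct[["V2"]]))
  if (length(fit$coefficients)) {
    rows <- rbind(rows, data.frame(parameter = names(fit$coefficients),
                                   estimate = as.numeric(fit$coefficients),
                                   iiv_cv_pct = NA))
  }
  rows <- rbind(rows, data.frame(parameter = "residual SD (log scale)",
                                 estimate = fit$sigma_hat, iiv_cv_pct = NA))
  if (!is.null(fit$se_pct)) {
    se <- rep(NA_real_, nrow(rows))
    se[1:4] <- fit$se_pct[1:4]
    ne <- length(fit$coefficients)
    if (ne) se[4 + seq_len(ne)] <- fit$se_pct[4 + seq_len(ne)]
    se[nrow(rows)] <- fit$se_pct[length(fit$se_pct)]
    rows$se_pct <- se
  }
  rows
}
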