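## Stepwise covariate modelling: likelihood-ratio univariate screen,
## forward addition against the growing model, and backward elimination,
## each step refitted by FOCE-I and judged by the chi-square distribution
## of the change in objective function value between nested models.

#' Likelihood-ratio p-value from a change in OFV
#'
#' Under the null, the drop in OFV when adding `df` coefficients is
#' chi-square distributed with `df` degrees of freedom. `delta_ofv` follows
#' the `extended - reference` convention (<= 0 for an improving extension);
#' non-negative values return p = 1.
#'
#' @param delta_ofv OFV(extended) - OFV(reference).
#' @param df number of added coefficients (>= 1).
#' @return upper-tail chi-square probability.
#' @export
#' @examples
#' lrt_p(-3.841, 1) # 0.05
lrt_p <- function(delta_ofv, df = 1L) {
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  ifelse(delta_ofv >= 0, 1, stats::pchisq(-delta_ofv, df, lower.tail = FALSE))
}

#' Candidate covariate-effect set for the murine mAb analysis
#'
#' The covariate-parameter pairs screened in the study design this package
#' emulates: every covariate on CL and V1 (continuous as median-normalised
#' power terms; tumour, strain and dose group as dichotomous shifts) plus
#' IgG on Q.
#'
#' @return data frame of candidates for [univariate_screen()] /
#'   [forward_addition()].
#' @export
default_candidates <- function() {
  rbind(
    covariate_effect("CL", "TUM", 0, "proportional"),
    covariate_effect("CL", "STR", 0, "proportional"),
    covariate_effect("CL", "MWT", 0, "power"),
    covariate_effect("CL", "FWT", 0, "power"),
    covariate_effect("CL", "IGG", 0, "power"),
    covariate_effect("CL", "FCRN", 0, "power"),
    covariate_effect("V1", "TUM", 0, "proportional"),
    covariate_effect("V1", "STR", 0, "proportional"),
    covariate_effect("V1", "IGG", 0, "power"),
    covariate_effect("V1", "FCRN", 0, "power"),
    covariate_effect("Q", "IGG", 0, "power"))
}

add_effect_to_spec <- function(spec, effect, init_coef = 0) {
  effect$coefficient <- init_coef
  effect$forced <- effect$forced %||% FALSE
  spec$covariate_effects <- if (is.null(spec$covariate_effects)) effect else
    rbind(spec$covariate_effects, effect)
  spec
}

effect_key <- function(eff) paste(eff$covariate, eff$parameter, eff$form, sep = "~")

scm_record <- function(label, eff, ofv, ref_ofv, action) {
  delta <- ofv - ref_ofv
  data.frame(model_label = label, parameter = eff$parameter,
             covariate = eff$covariate, ofv = ofv, delta_ofv = delta,
             p_value = lrt_p(delta, 1L), action = action,
             stringsAsFactors = FALSE)
}

refit_with <- function(data, spec, settings, warm_fit = NULL) {
  tryCatch(foce_fit(data, spec, settings), error = function(e) NULL)
}

#' Univariate covariate screen
#'
#' Fits the base model plus one candidate effect at a time and ranks the
#' candidates by the drop in OFV (most significant first).
#'
#' @param data pipeline dataset.
#' @param base_spec base-model [pop_model_spec()] (used as initial values).
#' @param candidates data frame of [covariate_effect()] rows.
#' @param settings [foce_settings()].
#' @param base_fit optional pre-computed base [foce_fit()] to avoid
#'   refitting.
#' @return list with `records` (one row per candidate, sorted by
#'   `delta_ofv`) and `base_fit`.
#' @export
univariate_screen <- function(data, base_spec, candidates = default_candidates(),
                              settings = foce_settings(), base_fit = NULL) {
  if (is.null(base_fit)) base_fit <- foce_fit(data, base_spec, settings)
  recs <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    eff <- candidates[i, , drop = FALSE]
    sp <- add_effect_to_spec(base_fit$spec_hat, eff)
    fit <- refit_with(data, sp, settings)
    recs[[i]] <- if (is.null(fit)) {
      data.frame(model_label = paste0("base + ", eff$covariate, " on ", eff$parameter),
                 parameter = eff$parameter, covariate = eff$covariate,
                 ofv = NA_real_, delta_ofv = NA_real_, p_value = NA_real_,
                 action = "screened", stringsAsFactors = FALSE)
    } else {
      scm_record(paste0("base + ", eff$covariate, " on ", eff$parameter),
                 eff, fit$ofv, base_fit$ofv, "screened")
    }
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$delta_ofv), ]
  rownames(records) <- NULL
  list(records = records, base_fit = base_fit)
}

#' Forward addition of covariate effects
#'
#' Iteratively refits every remaining candidate against the growing model
#' and adds the one with the smallest likelihood-ratio p-value while it is
#' below `alpha`; stops when no candidate passes.
#'
#' @inheritParams univariate_screen
#' @param alpha inclusion threshold on the likelihood-ratio p-value.
#' @return list with `final_spec`, `final_fit`, and `trace` (one added
#'   effect per round, plus the per-round screening records in
#'   `screen_trace`).
#' @export
forward_addition <- function(data, base_spec, candidates = default_candidates(),
                             alpha = 0.05, settings = foce_settings(),
                             base_fit = NULL) {
  if (!nrow(candidates)) stop("candidates must be non-empty")
  if (is.null(base_fit)) base_fit <- foce_fit(data, base_spec, settings)
  current <- base_fit
  remaining <- candidates
  trace <- list()
  screen_trace <- list()
  round <- 0L
  label_prefix <- "1. base"
  while (nrow(remaining)) {
    round <- round + 1L
    fits <- vector("list", nrow(remaining))
    recs <- vector("list", nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      eff <- remaining[i, , drop = FALSE]
      sp <- add_effect_to_spec(current$spec_hat, eff)
      fit <- refit_with(data, sp, settings)
      fits[[i]] <- fit
      recs[[i]] <- if (is.null(fit)) {
        scm_record("failed", eff, NA_real_, current$ofv, "screened")
      } else {
        scm_record(sprintf("%d + %s on %s", round, eff$covariate, eff$parameter),
                   eff, fit$ofv, current$ofv, "screened")
      }
    }
    rd <- do.call(rbind, recs)
    rd$round <- round
    screen_trace[[round]] <- rd
    ok <- which(is.finite(rd$p_value))
    if (!length(ok)) break
    best <- ok[order(rd$p_value[ok], rd$delta_ofv[ok])][1]
    if (rd$p_value[best] >= alpha) break
    add <- rd[best, ]
    add$action <- "added"
    trace[[length(trace) + 1L]] <- add
    current <- fits[[best]]
    remaining <- remaining[-best, , drop = FALSE]
  }
  list(final_spec = current$spec_hat, final_fit = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(model_label = character(), parameter = character(),
                    covariate = character(), ofv = numeric(),
                    delta_ofv = numeric(), p_value = numeric(),
                    action = character(), round = integer()),
       screen_trace = do.call(rbind, screen_trace),
       base_fit = base_fit)
}

#' Backward elimination of covariate effects
#'
#' Iteratively removes the effect whose removal costs the least OFV
#' (largest removal p-value) as long as that p-value exceeds `alpha`
#' strictly; effects flagged `forced` in the spec are never removed.
#'
#' @param data pipeline dataset.
#' @param full_spec fitted full-model spec (initial values).
#' @param alpha retention threshold: an effect is removed only when the
#'   p-value of its removal test is `> alpha` (a removal exactly at the
#'   chi-square threshold is retained).
#' @param settings [foce_settings()].
#' @param full_fit optional pre-computed full-model [foce_fit()].
#' @return list with `final_spec`, `final_fit` and `trace` of removals /
#'   retentions.
#' @export
backward_elimination <- function(data, full_spec, alpha = 0.05,
                                 settings = foce_settings(), full_fit = NULL) {
  if (is.null(full_fit)) full_fit <- foce_fit(data, full_spec, settings)
  current <- full_fit
  trace <- list()
  repeat {
    eff <- current$spec_hat$covariate_effects
    if (is.null(eff) || !nrow(eff)) break
    removable <- which(!(eff$forced %||% FALSE))
    if (!length(removable)) break
    recs <- vector("list", length(removable))
    fits <- vector("list", length(removable))
    for (j in seq_along(removable)) {
      i <- removable[j]
      sp <- current$spec_hat
      sp$covariate_effects <- sp$covariate_effects[-i, , drop = FALSE]
      if (!nrow(sp$covariate_effects)) sp$covariate_effects <- NULL
      fit <- refit_with(data, sp, settings)
      fits[[j]] <- fit
      d_removal <- if (is.null(fit)) NA_real_ else fit$ofv - current$ofv
      recs[[j]] <- data.frame(
        model_label = sprintf("full - %s on %s", eff$covariate[i], eff$parameter[i]),
        parameter = eff$parameter[i], covariate = eff$covariate[i],
        ofv = if (is.null(fit)) NA_real_ else fit$ofv,
        delta_ofv = d_removal,
        p_value = if (is.na(d_removal)) NA_real_ else lrt_p(-d_removal, 1L),
        action = "screened", stringsAsFactors = FALSE)
    }
    rd <- do.call(rbind, recs)
    ok <- which(is.finite(rd$p_value))
    if (!length(ok)) break
    worst <- ok[which.max(rd$p_value[ok])]
    if (rd$p_value[worst] > alpha) {
      rem <- rd[worst, ]
      rem$action <- "removed"
      trace[[length(trace) + 1L]] <- rem
      current <- fits[[worst]]
    } else {
      rd$action <- "retained"
      trace[[length(trace) + 1L]] <- rd
      break
    }
  }
  list(final_spec = current$spec_hat, final_fit = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(model_label = character(), parameter = character(),
                    covariate = character(), ofv = numeric(),
                    delta_ofv = numeric(), p_value = numeric(),
                    action = character()))
}

#' Full stepwise covariate modelling run
#'
#' Univariate screen, forward addition, then backward elimination with the
#' same threshold, returning the three traces.
#'
#' @inheritParams forward_addition
#' @return list with `screen`, `forward`, `backward` and `final_spec` /
#'   `final_fit`.
#' @export
run_scm <- function(data, base_spec, candidates = default_candidates(),
                    alpha = 0.05, settings = foce_settings()) {
  base_fit <- foce_fit(data, base_spec, settings)
  screen <- univariate_screen(data, base_spec, candidates, settings, base_fit)
  fwd <- forward_addition(data, base_spec, candidates, alpha, settings, base_fit)
  bwd <- backward_elimination(data, fwd$final_spec, alpha, settings, fwd$final_fit)
  list(screen = screen$records, forward = fwd$trace, backward = bwd$trace,
       final_spec = bwd$final_spec, final_fit = bwd$final_fit)
}
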