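## Nonlinear mixed-effects estimation of the two-compartment model by
## first-order conditional estimation with interaction (FOCE-I).
##
## Between-subject variability is exponential (diagonal Omega on CL, V1,
## V2; Q carries none) and the residual error is additive on the
## log-concentration scale with SD sigma. Because sigma does not depend on
## eta for this error model, the interaction term of FOCE-I is exact.
##
## Per objective-function evaluation the conditional modes eta-hat of all
## subjects are located by a parallel damped Newton iteration whose model
## Jacobian comes from complex-step differentiation of the closed-form
## biexponential (machine precision, no subtractive cancellation). The
## marginal contribution of subject i is then the standard linearised form
##
##   OFV_i = log det(C_i) + res_i' C_i^{-1} res_i,
##   C_i = F_i Omega F_i' + sigma^2 I,  res_i = y_i - f(eta-hat) + F_i eta-hat,
##
## evaluated with Woodbury / determinant-lemma identities on the d x d
## (d <= 3) inner matrices so the whole evaluation is vectorised across
## subjects. Additive 2*pi constants are dropped (the usual pharmacometric
## convention), so only differences in OFV are meaningful.

ETA_NAMES <- c("CL", "V1", "V2")

## ---- small vectorised symmetric linear algebra (d in 1..3) -------------

## H: n x d(d+1)/2 matrix of packed upper-triangle entries
## (d=3 order: 11,12,13,22,23,33); g: n x d. Solves H x = g rowwise.
sym_solve_vec <- function(H, g) {
  d <- ncol(g)
  if (d == 1) return(g / H)
  if (d == 2) {
    det <- H[, 1] * H[, 3] - H[, 2]^2
    cbind((H[, 3] * g[, 1] - H[, 2] * g[, 2]) / det,
          (H[, 1] * g[, 2] - H[, 2] * g[, 1]) / det)
  } else {
    a <- H[, 1]; b <- H[, 2]; cc <- H[, 3]
    dd <- H[, 4]; e <- H[, 5]; f <- H[, 6]
    A11 <- dd * f - e * e; A12 <- cc * e - b * f; A13 <- b * e - cc * dd
    A22 <- a * f - cc * cc; A23 <- b * cc - a * e; A33 <- a * dd - b * b
    det <- a * A11 + b * A12 + cc * A13
    cbind((A11 * g[, 1] + A12 * g[, 2] + A13 * g[, 3]) / det,
          (A12 * g[, 1] + A22 * g[, 2] + A23 * g[, 3]) / det,
          (A13 * g[, 1] + A23 * g[, 2] + A33 * g[, 3]) / det)
  }
}

sym_det_vec <- function(H, d) {
  if (d == 1) return(H[, 1])
  if (d == 2) return(H[, 1] * H[, 3] - H[, 2]^2)
  a <- H[, 1]; b <- H[, 2]; cc <- H[, 3]
  dd <- H[, 4]; e <- H[, 5]; f <- H[, 6]
  a * (dd * f - e * e) + b * (cc * e - b * f) + cc * (b * e - cc * dd)
}

## ---- data preparation ---------------------------------------------------

COV_COLS <- c("TUM", "STR", "DOSEGRP", "MWT", "FWT", "PBWT", "IGG", "ALB", "FCRN")

## Flatten a pipeline dataset into the row/subject structures the engine
## needs. Subjects without observations (vehicle) are dropped.
build_foce_data <- function(data) {
  obs <- data[data$EVID == 0 & !is.na(data$DV), , drop = FALSE]
  if ("BQL" %in% names(obs)) obs <- obs[obs$BQL == 0, , drop = FALSE]
  if (!nrow(obs)) stop("dataset contains no usable observations")
  if (any(obs$DV <= 0)) stop("observed concentrations must be positive")
  doses <- data[data$EVID == 1 & data$AMT > 0, c("ID", "AMT"), drop = FALSE]
  ids <- sort(intersect(doses$ID, unique(obs$ID)))
  if (!length(ids)) stop("no dosed subjects with observations")
  obs <- obs[obs$ID %in% ids, , drop = FALSE]
  obs <- obs[order(obs$ID, obs$TIME), , drop = FALSE]
  isub <- match(obs$ID, ids)
  dose <- doses$AMT[match(ids, doses$ID)]
  ## every non-core column rides along as a candidate covariate
  cov_cols <- setdiff(names(obs), c("ID", "TIME", "DV", "AMT", "EVID", "BQL"))
  first <- obs[match(ids, obs$ID), cov_cols, drop = FALSE]
  rownames(first) <- NULL
  list(ids = ids, nsub = length(ids), nobs = nrow(obs), isub = isub,
       t_obs = hours_to_days(obs$TIME), logy = log(obs$DV),
       dose_obs = dose[isub], dose = dose, cov = first,
       n_i = tabulate(isub, length(ids)))
}

## Fill power-form covariate medians from the fitted subjects when absent.
fill_medians <- function(spec, fd) {
  eff <- spec$covariate_effects
  if (is.null(eff)) return(spec)
  pow <- unique(eff$covariate[eff$form == "power"])
  need <- setdiff(pow, names(spec$covariate_medians %||% numeric()))
  if (length(need)) {
    med <- vapply(need, function(cn) {
      if (!cn %in% names(fd$cov)) stop("covariate '", cn, "' not in dataset")
      stats::median(fd$cov[[cn]])
    }, numeric(1))
    spec$covariate_medians <- c(spec$covariate_medians, med)
  }
  spec
}

## Per-effect precomputation: target parameter index, functional type and
## the per-subject covariate transform feeding the log-scale linear (power,
## exponential) or log1p (proportional) contribution.
effect_terms <- function(spec, fd) {
  eff <- spec$covariate_effects
  if (is.null(eff) || !nrow(eff)) return(list())
  lapply(seq_len(nrow(eff)), function(i) {
    e <- eff[i, ]
    if (!e$covariate %in% names(fd$cov)) {
      stop("covariate '", e$covariate, "' not in dataset")
    }
    x <- fd$cov[[e$covariate]]
    v <- if (e$form == "power") {
      med <- spec$covariate_medians[[e$covariate]]
      if (any(x <= 0)) stop("power-form covariate '", e$covariate, "' must be > 0")
      log(x / med)
    } else x
    list(p = match(e$parameter, c("CL", "V1", "Q", "V2")), form = e$form,
         v = v, label = paste0(e$covariate, "~", e$parameter))
  })
}

## ---- parameter packing --------------------------------------------------

pack_start <- function(spec, terms, active) {
  par <- log(as.numeric(spec$theta))
  names(par) <- paste0("l", c("CL", "V1", "Q", "V2"))
  if (length(terms)) {
    cf <- spec$covariate_effects$coefficient
    names(cf) <- vapply(terms, `[[`, "", "label")
    par <- c(par, cf)
  }
  if (any(active)) {
    lo <- log(spec$omega2[ETA_NAMES[active]])
    names(lo) <- paste0("lo_", ETA_NAMES[active])
    par <- c(par, lo)
  }
  c(par, lsig = log(spec$sigma_log))
}

pack_bounds <- function(spec, terms, active) {
  ne <- length(terms)
  lower <- c(rep(-7, 4),
             vapply(terms, function(tm) if (tm$form == "proportional") -0.99 else -50,
                    numeric(1)),
             rep(-15, sum(active)), -12)
  upper <- c(rep(14, 4), rep(50, ne), rep(5, sum(active)), 2)
  list(lower = lower, upper = upper)
}

unpack_par <- function(par, ne, active) {
  lth <- par[1:4]
  coefs <- if (ne) par[4 + seq_len(ne)] else numeric()
  om <- c(CL = 0, V1 = 0, V2 = 0)
  if (any(active)) om[ETA_NAMES[active]] <- exp(par[4 + ne + seq_len(sum(active))])
  list(ltheta = lth, coefs = coefs, omega2 = om, sigma = exp(par[[length(par)]]))
}

## ---- inner problem: conditional eta modes -------------------------------

## Parallel damped Gauss-Newton for the penalised conditional objective
##   q_i(eta) = sum_j (y_ij - f_ij(eta))^2 / sigma^2 + eta' Omega^{-1} eta.
## For large-residual subjects the undamped GN map can oscillate around
## the mode instead of contracting, so a per-subject Levenberg-Marquardt
## damping term is raised whenever a subject's gradient stops decaying.
## The few subjects the parallel iteration still cannot finish are handed
## to a per-subject quasi-Newton fallback (run from both eta = 0 and the
## current iterate, keeping the lower-objective mode, so a dominant mode
## wins when the conditional density is multimodal), after which a second
## parallel sweep polishes every mode back toward `tol`; subjects are
## finally accepted at `accept_tol` gradient precision, which perturbs the
## OFV far below what the outer optimiser resolves.
## Returns eta, the Jacobian at the mode, residuals and a convergence flag.
inner_newton <- function(fp, fd, omega2, sigma, eta, tol = 5e-7, maxit = 300L,
                         accept_tol = 1e-4) {
  act <- which(omega2 > 0)
  d <- length(act)
  nsub <- fd$nsub
  isub <- fd$isub
  sigma2 <- sigma^2
  h <- 1e-20
  inv_om <- 1 / omega2[act]
  IOM <- matrix(inv_om, nsub, d, byrow = TRUE)
  prior <- function(e) {
    if (d == 0) return(numeric(nsub))
    as.numeric(e[, act, drop = FALSE]^2 %*% inv_om)
  }
  rs1 <- function(x) rowsum(x, isub, reorder = FALSE)

  if (d == 0) {
    f0 <- fp(eta)
    r <- fd$logy - f0
    return(list(eta = eta, Fm = NULL, r = r, act = act,
                converged = all(is.finite(r)), iters = 0L))
  }

  f0 <- fp(eta)
  r <- fd$logy - f0
  obj0 <- as.numeric(rs1(r * r)) / sigma2 + prior(eta)
  if (any(!is.finite(obj0))) {
    eta[] <- 0
    f0 <- fp(eta)
    r <- fd$logy - f0
    obj0 <- as.numeric(rs1(r * r)) / sigma2 + prior(eta)
    if (any(!is.finite(obj0))) {
      return(list(eta = eta, Fm = NULL, r = r, act = act,
                  converged = FALSE, iters = 0L))
    }
  }

  npair <- d * (d + 1L) / 2L
  pair_i <- pair_j <- integer(npair)
  k <- 0L
  for (a in seq_len(d)) for (b in a:d) {
    k <- k + 1L
    pair_i[k] <- a
    pair_j[k] <- b
  }
  diag_pos <- which(pair_i == pair_j)

  Fm <- matrix(0, fd$nobs, d)
  converged <- FALSE
  it <- 0L
  for (round in 1:2) {
  mu <- numeric(nsub)
  mg_prev <- rep(Inf, nsub)
  rit <- 0L
  while (rit < maxit) {
    rit <- rit + 1L
    it <- it + 1L
    for (j in seq_len(d)) {
      ep <- eta
      ep[, act[j]] <- complex(real = ep[, act[j]], imaginary = h)
      Fm[, j] <- Im(fp(ep)) / h
    }
    cross <- cbind(Fm * r,
                   Fm[, pair_i, drop = FALSE] * Fm[, pair_j, drop = FALSE])
    CS <- rs1(cross)
    u <- CS[, seq_len(d), drop = FALSE]
    G <- -u / sigma2 + Re(eta[, act, drop = FALSE]) * IOM
    mg <- abs(G[, 1])
    if (d > 1) mg <- pmax(mg, abs(G[, 2]))
    if (d > 2) mg <- pmax(mg, abs(G[, 3]))
    conv <- mg < tol
    if (all(conv)) {
      converged <- TRUE
      break
    }
    ## raise the LM damping for subjects whose gradient has stopped
    ## contracting (the oscillation signature), relax it otherwise
    nodecay <- mg > 0.7 * mg_prev
    mu <- ifelse(nodecay & !conv, pmax(4 * mu, 1), mu / 4)
    mg_prev <- mg
    Hm <- CS[, d + seq_len(npair), drop = FALSE] / sigma2
    Hm[, diag_pos] <- Hm[, diag_pos, drop = FALSE] + IOM + mu
    step <- sym_solve_vec(Hm, G)
    step[conv | !is.finite(rowSums(step)), ] <- 0
    lam <- as.numeric(!conv)
    for (ls in seq_len(30L)) {
      trial <- eta
      trial[, act] <- eta[, act, drop = FALSE] - step * lam
      f1 <- fp(trial)
      r1 <- fd$logy - f1
      obj1 <- as.numeric(rs1(r1 * r1)) / sigma2 + prior(trial)
      ok <- conv | (is.finite(obj1) & obj1 <= obj0 + 1e-10)
      if (all(ok)) {
        eta <- trial
        r <- r1
        obj0 <- obj1
        break
      }
      lam[!ok] <- lam[!ok] / 2
      if (ls == 30L) {
        lam[!ok] <- 0
        trial[, act] <- eta[, act, drop = FALSE] - step * lam
        f1 <- fp(trial)
        r <- fd$logy - f1
        obj0 <- as.numeric(rs1(r * r)) / sigma2 + prior(trial)
        eta <- trial
      }
    }
  }
  if (converged || round == 2L) break

  ## per-subject quasi-Newton fallback for the stragglers; the second
  ## parallel sweep then polishes every mode back toward `tol`
  eta <- Re(eta)
  for (s in which(mg_prev >= tol)) {
    rows <- isub == s
    qfun <- function(es) {
      e <- eta
      e[s, act] <- es
      f <- Re(fp(e))
      rr <- fd$logy[rows] - f[rows]
      v <- sum(rr * rr) / sigma2 + sum(es * es * inv_om)
      if (!is.finite(v)) 1e12 else v
    }
    best_q <- qfun(eta[s, act])
    for (start in list(numeric(d), eta[s, act])) {
      fb <- tryCatch(stats::nlminb(start, qfun,
                                   control = list(rel.tol = 1e-14,
                                                  eval.max = 500)),
                     error = function(e) NULL)
      if (!is.null(fb) && is.finite(fb$objective) && fb$objective < best_q - 1e-12) {
        best_q <- fb$objective
        eta[s, act] <- fb$par
      }
    }
  }
  f0 <- fp(eta)
  r <- fd$logy - f0
  obj0 <- as.numeric(rs1(r * r)) / sigma2 + prior(eta)
  }
  if (!converged) converged <- all(mg_prev < accept_tol)
  list(eta = eta, Fm = Fm, r = r, act = act, converged = converged, iters = it)
}

## FOCE-I objective given the structures of an inner solution.
ofv_from_inner <- function(sol, fd, omega2, sigma) {
  sigma2 <- sigma^2
  act <- sol$act
  d <- length(act)
  rs1 <- function(x) rowsum(x, fd$isub, reorder = FALSE)
  if (d == 0) {
    S <- as.numeric(rs1(sol$r^2))
    return(sum(fd$n_i * log(sigma2) + S / sigma2))
  }
  Fm <- sol$Fm
  eta_obs <- sol$eta[fd$isub, act, drop = FALSE]
  rf <- sol$r + rowSums(Fm * eta_obs)
  npair <- d * (d + 1L) / 2L
  pair_i <- pair_j <- integer(npair)
  k <- 0L
  for (a in seq_len(d)) for (b in a:d) {
    k <- k + 1L
    pair_i[k] <- a
    pair_j[k] <- b
  }
  diag_pos <- which(pair_i == pair_j)
  CS <- rs1(cbind(rf * rf, Fm * rf,
                  Fm[, pair_i, drop = FALSE] * Fm[, pair_j, drop = FALSE]))
  S <- CS[, 1]
  u <- CS[, 1 + seq_len(d), drop = FALSE]
  M <- CS[, 1 + d + seq_len(npair), drop = FALSE]
  M[, diag_pos] <- sweep(M[, diag_pos, drop = FALSE], 2,
                         sigma2 / omega2[act], `+`)
  x <- sym_solve_vec(M, u)
  quad <- (S - rowSums(u * x)) / sigma2
  logdet <- (fd$n_i - d) * log(sigma2) + log(sym_det_vec(M, d)) +
    sum(log(omega2[act]))
  val <- sum(logdet + quad)
  if (!is.finite(val)) val <- NA_real_
  val
}

## Model prediction closure on log-concentration for a given base-parameter
## set; complex-safe in eta.
make_fp <- function(baseP, fd) {
  bCL <- baseP[, 1][fd$isub]
  bV1 <- baseP[, 2][fd$isub]
  bQ <- baseP[, 3][fd$isub]
  bV2 <- baseP[, 4][fd$isub]
  function(eta) {
    e1 <- exp(eta[, 1])[fd$isub]
    e2 <- exp(eta[, 2])[fd$isub]
    e3 <- exp(eta[, 3])[fd$isub]
    log(conc_2cmt_vec(bCL * e1, bV1 * e2, bQ, bV2 * e3, fd$dose_obs, fd$t_obs))
  }
}

## Per-subject base (eta = 0) parameters under a packed parameter vector.
base_params <- function(up, terms, nsub) {
  lbase <- matrix(rep(up$ltheta, each = nsub), nsub, 4)
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    co <- up$coefs[[i]]
    contrib <- switch(tm$form,
                      power = co * tm$v,
                      exponential = co * tm$v,
                      proportional = log1p(co * tm$v))
    lbase[, tm$p] <- lbase[, tm$p] + contrib
  }
  exp(lbase)
}

PENALTY_OFV <- 1e10

## Full objective evaluation; warm-started etas live in `env`.
ofv_eval <- function(par, fd, terms, active, env, settings) {
  up <- unpack_par(par, length(terms), active)
  baseP <- base_params(up, terms, fd$nsub)
  if (any(!is.finite(baseP)) || any(baseP <= 0)) return(PENALTY_OFV)
  fp <- make_fp(baseP, fd)
  sol <- inner_newton(fp, fd, up$omega2, up$sigma, env$eta,
                      tol = settings$inner_tol, maxit = settings$inner_maxit)
  if (!sol$converged) {
    cold <- matrix(0, fd$nsub, 3)
    sol <- inner_newton(fp, fd, up$omega2, up$sigma, cold,
                        tol = settings$inner_tol, maxit = settings$inner_maxit)
    if (!sol$converged) return(PENALTY_OFV)
  }
  env$eta <- Re(sol$eta)
  env$last_sol <- sol
  val <- ofv_from_inner(sol, fd, up$omega2, up$sigma)
  if (!is.finite(val)) return(PENALTY_OFV)
  val
}

## ---- public API ---------------------------------------------------------

#' Settings for the FOCE-I estimator
#'
#' @param n_starts number of optimisation starts (start 1 is the supplied
#'   initial spec; further starts jitter the typical values multiplicatively).
#' @param jitter_sd SD of the log-scale jitter for extra starts.
#' @param jitter_seed RNG seed for the jitter.
#' @param rel_tol relative OFV convergence tolerance of the outer
#'   quasi-Newton optimiser.
#' @param grad_tol maximum absolute outer-gradient component accepted for
#'   the `converged` flag. The default of 1 is calibrated to the
#'   finite-difference noise floor of the profiled objective: on an OFV of
#'   magnitude several hundred it corresponds to a suboptimality well
#'   below 0.01 OFV units, while gross non-convergence shows up as
#'   gradients orders of magnitude larger.
#' @param iter_max,eval_max outer iteration / evaluation budget.
#' @param inner_tol gradient tolerance of the conditional-mode Newton
#'   solver (half-gradient scale, so the full gradient norm is below
#'   `2 * inner_tol`).
#' @param inner_maxit inner Newton iteration cap.
#' @param compute_se also compute standard errors ([standard_errors()]).
#' @return settings list.
#' @export
foce_settings <- function(n_starts = 1L, jitter_sd = 0.15, jitter_seed = 77L,
                          rel_tol = 1e-8, grad_tol = 1, iter_max = 500L,
                          eval_max = 4000L, inner_tol = 5e-7,
                          inner_maxit = 300L, compute_se = FALSE) {
  list(n_starts = n_starts, jitter_sd = jitter_sd, jitter_seed = jitter_seed,
       rel_tol = rel_tol, grad_tol = grad_tol, iter_max = iter_max,
       eval_max = eval_max, inner_tol = inner_tol, inner_maxit = inner_maxit,
       compute_se = compute_se)
}

#' FOCE-I objective function value at a given specification
#'
#' Locates the conditional eta modes and evaluates the linearised marginal
#' -2 log-likelihood (2*pi constants dropped) without any estimation.
#'
#' @param spec a [pop_model_spec()].
#' @param data pipeline dataset.
#' @param settings [foce_settings()].
#' @return the OFV (numeric scalar).
#' @export
foce_ofv <- function(spec, data, settings = foce_settings()) {
  fd <- build_foce_data(data)
  spec <- fill_medians(spec, fd)
  terms <- effect_terms(spec, fd)
  active <- spec$omega2[ETA_NAMES] > 0
  par <- pack_start(spec, terms, active)
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, fd$nsub, 3)
  ofv_eval(par, fd, terms, active, env, settings)
}

#' Conditional mode of the random effects for one subject
#'
#' Minimises `sum (log y - log f(eta))^2 / sigma^2 + eta' Omega^{-1} eta`
#' for a single subject; components with zero variance are fixed at 0.
#'
#' @param spec a [pop_model_spec()] with medians covering its power-form
#'   covariates.
#' @param subject list with elements `dose` (ug/kg), `cov` (named covariate
#'   values) and `records` (data frame `time_h`, `conc`).
#' @param settings [foce_settings()].
#' @return named eta vector (`CL`, `V1`, `V2`).
#' @export
map_eta <- function(spec, subject, settings = foce_settings()) {
  rec <- subject$records
  stopifnot(nrow(rec) >= 1)
  fd <- list(ids = 1L, nsub = 1L, nobs = nrow(rec), isub = rep(1L, nrow(rec)),
             t_obs = hours_to_days(rec$time_h), logy = log(rec$conc),
             dose_obs = rep(subject$dose, nrow(rec)), dose = subject$dose,
             cov = as.data.frame(subject$cov %||% list()),
             n_i = nrow(rec))
  spec <- fill_medians(spec, fd)
  terms <- effect_terms(spec, fd)
  up <- list(ltheta = log(as.numeric(spec$theta)),
             coefs = if (length(terms)) spec$covariate_effects$coefficient else numeric(),
             omega2 = spec$omega2[ETA_NAMES], sigma = spec$sigma_log)
  baseP <- base_params(up, terms, 1L)
  fp <- make_fp(baseP, fd)
  sol <- inner_newton(fp, fd, up$omega2, up$sigma, matrix(0, 1, 3),
                      tol = min(settings$inner_tol, 5e-7),
                      maxit = max(settings$inner_maxit, 500L))
  if (!sol$converged) stop("conditional-mode search did not converge")
  eta <- as.numeric(Re(sol$eta))
  names(eta) <- ETA_NAMES
  eta
}

#' Predicted log-concentrations for one subject
#'
#' @inheritParams map_eta
#' @param eta named random-effect vector (`CL`, `V1`, `V2`).
#' @return vector of log(ug/mL) at the subject's record times.
#' @export
predict_log_concentrations <- function(spec, subject, eta = c(CL = 0, V1 = 0, V2 = 0)) {
  pars <- individual_parameters(spec, subject$cov %||% list(), eta)
  log(concentration(pars, subject$dose, hours_to_days(subject$records$time_h)))
}

#' Fit the population model by FOCE-I
#'
#' Outer quasi-Newton (PORT) minimisation of the FOCE-I objective over
#' log typical values, covariate coefficients, log eta-variances and log
#' residual SD, with the conditional modes re-solved (warm-started) at
#' every objective evaluation.
#'
#' @param data pipeline dataset (see [read_pk_dataset()]).
#' @param spec initial [pop_model_spec()]; its `omega2 > 0` pattern fixes
#'   which random effects are estimated, and `NULL` medians are filled from
#'   the fitted subjects. See [init_spec_from_data()] for data-driven
#'   starting values.
#' @param settings [foce_settings()].
#' @return object of class `foce_fit` with elements `theta_hat`,
#'   `coefficients`, `omega2_hat`, `iiv_cv_pct`, `sigma_hat`, `ofv`,
#'   `converged`, `grad_norm`, `ebes`, `shrinkage_pct`, `se_pct` (when
#'   requested), `spec_hat` (spec updated to the estimates), `n_subjects`,
#'   `n_obs`, `n_evals`.
#' @export
foce_fit <- function(data, spec, settings = foce_settings()) {
  fd <- build_foce_data(data)
  if (fd$nsub < 2 || sum(fd$n_i >= 2) < 2) {
    stop("need at least 2 subjects with at least 2 observations each")
  }
  spec <- fill_medians(spec, fd)
  terms <- effect_terms(spec, fd)
  active <- spec$omega2[ETA_NAMES] > 0
  par0 <- pack_start(spec, terms, active)
  bounds <- pack_bounds(spec, terms, active)

  starts <- list(par0)
  if (settings$n_starts > 1) {
    jit <- with_seed(settings$jitter_seed, {
      lapply(seq_len(settings$n_starts - 1L), function(s) {
        p <- par0
        p[1:4] <- p[1:4] + stats::rnorm(4, 0, settings$jitter_sd)
        p
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  n_evals <- 0L
  for (s in seq_along(starts)) {
    env <- new.env(parent = emptyenv())
    env$eta <- matrix(0, fd$nsub, 3)
    evals <- 0L
    obj <- function(p) {
      evals <<- evals + 1L
      ofv_eval(p, fd, terms, active, env, settings)
    }
    ## quasi-Newton minimisation, restarted (with a refreshed PORT Hessian
    ## model) until the outer gradient is flat or the OFV stops improving
    res <- tryCatch({
      ctrl <- list(rel.tol = settings$rel_tol, iter.max = settings$iter_max,
                   eval.max = settings$eval_max)
      r <- stats::nlminb(starts[[s]], obj, lower = bounds$lower,
                         upper = bounds$upper, control = ctrl)
      gn <- Inf
      for (rep in 1:3) {
        gn <- max(abs(outer_gradient(obj, r$par, bounds)))
        if (!is.finite(r$objective) || gn < settings$grad_tol) break
        r2 <- stats::nlminb(r$par, obj, lower = bounds$lower,
                            upper = bounds$upper, control = ctrl)
        improved <- is.finite(r2$objective) && r2$objective < r$objective - 1e-7
        if (is.finite(r2$objective) && r2$objective <= r$objective) r <- r2
        if (!improved) break
      }
      r$grad_norm <- gn
      r
    }, error = function(e) NULL)
    n_evals <- n_evals + evals
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$res$objective) {
      best <- list(res = res, env = env)
    }
  }
  if (is.null(best)) stop("FOCE-I estimation failed from every start")
  res <- best$res
  env <- best$env

  ## final inner solve at the optimum for EBEs and the reported OFV
  final_ofv <- ofv_eval(res$par, fd, terms, active, env, settings)
  if (final_ofv >= PENALTY_OFV && is.finite(res$objective) &&
      res$objective < PENALTY_OFV) {
    final_ofv <- res$objective
  }
  sol <- env$last_sol

  grad_norm <- max(abs(outer_gradient(
    function(p) ofv_eval(p, fd, terms, active, env, settings),
    res$par, bounds)))
  converged <- is.finite(final_ofv) && final_ofv < PENALTY_OFV &&
    grad_norm < settings$grad_tol

  up <- unpack_par(res$par, length(terms), active)
  theta_hat <- pk_params(exp(up$ltheta[[1]]), exp(up$ltheta[[2]]),
                         exp(up$ltheta[[3]]), exp(up$ltheta[[4]]))
  spec_hat <- spec
  spec_hat$theta <- theta_hat
  if (length(terms)) spec_hat$covariate_effects$coefficient <- as.numeric(up$coefs)
  spec_hat$omega2 <- up$omega2
  spec_hat$sigma_log <- up$sigma

  ebes <- Re(sol$eta)
  colnames(ebes) <- ETA_NAMES
  shrink <- rep(NA_real_, 3)
  names(shrink) <- ETA_NAMES
  for (k in which(active)) {
    shrink[k] <- 100 * (1 - stats::sd(ebes[, k]) / sqrt(up$omega2[[k]]))
  }

  fit <- structure(list(
    theta_hat = theta_hat,
    coefficients = if (length(terms)) stats::setNames(as.numeric(up$coefs),
      vapply(terms, `[[`, "", "label")) else numeric(),
    omega2_hat = up$omega2,
    iiv_cv_pct = omega2_to_cv_pct(up$omega2),
    sigma_hat = up$sigma,
    ofv = final_ofv,
    converged = converged,
    grad_norm = grad_norm,
    par_hat = res$par,
    active = active,
    ebes = data.frame(ID = fd$ids, ebes),
    shrinkage_pct = shrink,
    spec_hat = spec_hat,
    spec_init = spec,
    n_subjects = fd$nsub,
    n_obs = fd$nobs,
    n_evals = n_evals,
    settings = settings), class = "foce_fit")
  if (isTRUE(settings$compute_se)) fit$se_pct <- standard_errors(fit, data)
  fit
}

## Central-difference gradient respecting box bounds. The step is kept
## well above the inner-solve noise floor of the objective.
outer_gradient <- function(f, par, bounds, h_rel = 1e-4) {
  vapply(seq_along(par), function(i) {
    h <- h_rel * max(1, abs(par[i]))
    up <- pmin(par[i] + h, bounds$upper[i])
    lo <- pmax(par[i] - h, bounds$lower[i])
    p1 <- par; p1[i] <- up
    p2 <- par; p2[i] <- lo
    (f(p1) - f(p2)) / (up - lo)
  }, numeric(1))
}

#' @export
print.foce_fit <- function(x, ...) {
  cat("FOCE-I fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat(sprintf("  OFV %.3f  (converged: %s, max |grad| %.3g)\n",
              x$ofv, x$converged, x$grad_norm))
  cat(sprintf("  CL %.4g mL/day/kg, V1 %.4g mL/kg, Q %.4g mL/day/kg, V2 %.4g mL/kg\n",
              x$theta_hat[["CL"]], x$theta_hat[["V1"]],
              x$theta_hat[["Q"]], x$theta_hat[["V2"]]))
  cat(sprintf("  IIV CV%%: CL %.1f, V1 %.1f, V2 %.1f; residual SD %.4g\n",
              x$iiv_cv_pct[["CL"]], x$iiv_cv_pct[["V1"]], x$iiv_cv_pct[["V2"]],
              x$sigma_hat))
  if (length(x$coefficients)) {
    cat("  covariate coefficients:\n")
    for (nm in names(x$coefficients)) {
      cat(sprintf("    %s = %.4g\n", nm, x$coefficients[[nm]]))
    }
  }
  invisible(x)
}

#' Standard errors of a FOCE-I fit
#'
#' Central-difference Hessian of the OFV at the optimum; the covariance of
#' the estimates is `2 H^{-1}` (OFV is -2 log-likelihood), mapped to the
#' natural scale by the delta method and reported as percent of each
#' estimate.
#'
#' @param fit a [foce_fit()] result.
#' @param data the dataset the fit was produced from.
#' @return named vector of SE%, `NA` with a warning when the Hessian is
#'   not positive definite.
#' @export
standard_errors <- function(fit, data) {
  fd <- build_foce_data(data)
  spec <- fit$spec_init
  terms <- effect_terms(spec, fd)
  active <- fit$active
  bounds <- pack_bounds(spec, terms, active)
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, fd$nsub, 3)
  settings <- fit$settings
  f <- function(p) ofv_eval(p, fd, terms, active, env, settings)
  par <- fit$par_hat
  p <- length(par)
  H <- matrix(0, p, p)
  hs <- vapply(par, function(x) 1e-4 * max(1, abs(x)), numeric(1))
  f0 <- f(par)
  for (i in seq_len(p)) {
    pi1 <- par; pi1[i] <- par[i] + hs[i]
    pi2 <- par; pi2[i] <- par[i] - hs[i]
    H[i, i] <- (f(pi1) - 2 * f0 + f(pi2)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      pp <- par; pp[i] <- par[i] + hs[i]; pp[j] <- par[j] + hs[j]
      pm <- par; pm[i] <- par[i] + hs[i]; pm[j] <- par[j] - hs[j]
      mp <- par; mp[i] <- par[i] - hs[i]; mp[j] <- par[j] + hs[j]
      mm <- par; mm[i] <- par[i] - hs[i]; mm[j] <- par[j] - hs[j]
      H[i, j] <- H[j, i] <- (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * hs[i] * hs[j])
    }
  }
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    warning("OFV Hessian is not positive definite; standard errors unavailable")
  } else {
    se_trans <- sqrt(diag(cov))
    ## log-scale entries: SE% of the natural estimate = 100 * SE(log estimate)
    ne <- length(terms)
    idx_log <- c(1:4, if (any(active)) 4 + ne + seq_len(sum(active)), p)
    se[idx_log] <- 100 * se_trans[idx_log]
    if (ne) {
      idx_cf <- 4 + seq_len(ne)
      se[idx_cf] <- 100 * se_trans[idx_cf] / abs(par[idx_cf])
    }
  }
  names(se) <- names(par)
  se
}

#' Eta shrinkage of a fit
#'
#' `100 * (1 - SD(eta-hat) / sqrt(omega2-hat))` per estimated random
#' effect; near 0 for rich data, near 100% when individual data carry no
#' information and the empirical Bayes estimates collapse to zero.
#'
#' @param fit a [foce_fit()] result.
#' @return named percent vector (`NA` for effects not estimated).
#' @export
eta_shrinkage <- function(fit) {
  fit$shrinkage_pct
}

#' Crude data-driven initial values
#'
#' Builds a starting [pop_model_spec()] from a quick non-compartmental
#' pass: CL from dose/AUC, V1 from dose/C0, Q and V2 started at CL and V1,
#' moderate variances and residual SD, and zero covariate coefficients.
#'
#' @param data pipeline dataset.
#' @param covariate_effects optional covariate model (coefficients are
#'   reset to 0).
#' @return a [pop_model_spec()] suitable as `spec` for [foce_fit()].
#' @export
init_spec_from_data <- function(data, covariate_effects = NULL) {
  nca <- run_nca(data)
  ok <- !is.na(nca$cl)
  cl0 <- geo_mean(nca$cl[ok])
  v10 <- geo_mean(nca$dose[ok] / nca$c0[ok])
  if (!is.null(covariate_effects)) covariate_effects$coefficient <- 0
  pop_model_spec(theta = pk_params(cl0, v10, cl0, v10),
                 covariate_effects = covariate_effects,
                 omega2 = c(CL = 0.1, V1 = 0.1, V2 = 0.1),
                 sigma_log = 0.2)
}
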