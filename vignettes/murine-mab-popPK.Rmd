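---
title: "Population pharmacokinetics of an IgG antibody in murine cancer-cachexia models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of an IgG antibody in murine cancer-cachexia models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachexpk)
```

## The scientific problem

Therapeutic IgG monoclonal antibodies — including the PD-1 checkpoint
inhibitor pembrolizumab — are cleared catabolically: they are taken up by
pinocytosis, degraded in lysosomes, and partially salvaged by the neonatal
Fc receptor (FcRn, gene *Fcgrt*). In cancer patients, high baseline
antibody clearance associates with cachexia and with poor survival,
independent of drug exposure. The C26 (CD2F1 mouse) and LLC (C57BL/6
mouse) tumour models reproduce the cachectic phenotype — loss of muscle,
fat, body weight, and serum albumin — and can be used to ask whether
catabolic antibody clearance rises with cachexia and which animal-level
covariates carry that signal.

`cachexpk` implements the full analysis chain for such a single-dose IV
study: a synthetic cohort generator shaped like the two-strain
tumour-bearing/tumour-free design, study-level quality control,
per-animal non-compartmental analysis (NCA), population (nonlinear
mixed-effects) estimation by FOCE-I, and stepwise covariate modelling.
Because the underlying animal data are not publicly deposited, the
generator is a first-class, tested component: every downstream stage is
validated against data simulated with known ground truth.

## Study design emulated by the generator

The default [study_design()] mirrors the published study shape: 135 mice
in two strains (63 CD2F1, 72 C57BL/6), tumour-bearing and tumour-free
arms, a single IV bolus of vehicle, 2, or 10 mg/kg at time zero, samples
at 1, 48 and 96 h and a terminal sample at 144 or 168 h (randomised 50/50
per animal). A fraction 28/107 of dosed animals receives a partial IV
dose (see *Quality control* below), so the expected number of exclusions
matches the published attrition from 107 dosed animals to 79 analysed.
Doses are carried per kg body weight (2 mg/kg = 2000 ug/kg), so volumes
are in mL/kg and clearances in mL/day/kg, and body weight cancels
throughout.

Covariates are drawn per animal:

* **Total murine IgG** (ug/mL) is log-normal per strain, moment-matched
  to the published strain means: 37.328 +/- 15.914 for CD2F1 and
  6.610 +/- 2.451 for C57BL/6, with no tumour shift (none was observed).
* **Gastrocnemius weight (MWT, g), epididymal fat (FWT, g), albumin
  (ALB, g/dL) and relative hepatic Fcgrt expression (FCRN)** are
  log-normal with defaults plausible for 6-8 week old male mice
  (0.14 g, 0.35 g, 3.0 g/dL, 1.0) and multiplicative tumour effects
  (x0.72, x0.45, x0.82, x0.80) calibrated **in direction only** — the
  study reports these phenotypes graphically, not numerically, so the
  magnitudes are package defaults, not measured ground truth, and all of
  them are configurable through [covariate_config()].
* **Percent body-weight change (PBWT)** is normal: +2 +/- 3 % tumour-free,
  -10 +/- 5 % tumour-bearing.

What the generator deliberately does **not** emulate: tumour growth over
time, mechanistic FcRn biology, assay (ELISA) error structure, between-
experiment batch effects, or correlation between covariates beyond what
the shared tumour status induces. Consequently, passing recovery tests
demonstrate that the estimation machinery is correct and well calibrated
at the study's design and sample size — not that the biological model is
complete.

## The kinetic model

Concentrations follow a linear two-compartment IV-bolus model
parameterized by clearance `CL` (mL/day/kg), central volume `V1` (mL/kg),
intercompartmental clearance `Q` (mL/day/kg) and peripheral volume `V2`
(mL/kg). Internally the closed-form biexponential solution is used,

$$C(t) = \mathrm{dose}\,(A e^{-\alpha t} + B e^{-\beta t}),$$

with micro constants $k_{10} = CL/V1$, $k_{12} = Q/V1$, $k_{21} = Q/V2$
and the usual hybrid roots. Time is handled in days internally (rates are
per day); sampling schedules are written in hours and converted once at
the boundary. Repeated-root kinetics ($\alpha \approx \beta$ within
1e-10 relative) are rejected rather than special-cased: they cannot occur
in the parameter ranges of this problem.

Target-mediated elimination is out of scope on purpose: the drug does not
bind the murine target, which is precisely why the study isolates
catabolic clearance.

## Individual parameters and the covariate sub-model

Individual parameters are

$$P_i = \theta_P \times \prod_{\text{continuous}} (x_{ik}/\tilde x_k)^{\beta_k}
      \times \prod_{\text{dichotomous}} (1 + \beta_k I_{ik})
      \times e^{\eta_{P,i}},$$

with continuous covariates normalised by their population medians
(computed from the analysed animals unless supplied) and random effects
$\eta \sim N(0, \omega^2)$ on CL, V1 and V2 (none on Q — its
between-subject variability is not estimable from four samples per
animal). The proportional form for dichotomous covariates and the power
form for continuous ones are the field's standard choices and match the
reported coefficient signs; an exponential dichotomous form
(`exp(coef * I)`) can be swapped in per effect. Residual error is
additive on the log-concentration scale with SD `sigma` — equivalent to
first order to a proportional error model, and exact for log-transformed
estimation.

[pembro_mouse_spec()] stores the published reference estimates of both
the structural model (CL 11.9, V1 61.8, Q 62.3, V2 62.3; IIV CV% 55.0,
30.2, 50.7; sigma 0.110) and the final covariate model (CL 8.35 with
tumour +65%, muscle-weight power -1.04, IgG power 0.286 and
Fcgrt-expression power -0.227 on CL; IgG 0.116 on V1 and 0.415 on Q).
These are used as simulation truth in the recovery experiments.

## Non-compartmental analysis

Per animal, the terminal phase is selected automatically: every
contiguous tail of at least three positive concentrations that excludes
the concentration maximum is fit log-linearly, and the tail with the
highest adjusted R^2 wins, ties going to the longer tail (the "best fit"
convention of standard NCA software). When excluding the peak leaves
fewer than three points (a bare three-point profile), the unrestricted
tails are used. `lambda_z` is minus the OLS slope; animals with a
non-positive slope are reported as non-estimable rather than dropped
silently.

`AUC_last` is the linear trapezoid from the **first observation** to the
last measurable concentration — no back-extrapolation to time zero; `C0`
(log-linear back-extrapolation through the first two points) is reported
separately, matching the observation-based convention. With the study's
1 h first sample this convention biases CL upward by under 1%, far below
the between-animal spread. Then `AUC_inf = AUC_last + C_last/lambda_z`,
`CL = dose/AUC_inf`, `Vz = CL/lambda_z`, `T1/2 = ln 2/lambda_z`. Group
summaries are geometric mean with geometric CV%
($100\sqrt{e^{s^2_{\ln}}-1}$, sample variance with $n-1$), except the
half-life, reported as median (min, max). Records below the
quantification limit are excluded from both the terminal fit and the AUC
and counted per animal.

## FOCE-I estimation

The marginal likelihood of each animal is approximated by first-order
conditional estimation with interaction. For this error model (additive
on the log scale with constant `sigma`) the interaction term is exact,
because the residual variance does not depend on the random effects. Per
objective evaluation:

1. The conditional mode $\hat\eta_i$ of every animal is located by a
   **parallel damped Gauss-Newton** iteration, vectorised across
   animals. The model Jacobian with respect to $\eta$ is computed by
   **complex-step differentiation** of the closed-form biexponential —
   machine-precision derivatives with no subtraction cancellation, which
   keeps the profiled objective smooth enough for the outer optimiser.
2. For animals with large residuals the undamped Gauss-Newton map can
   oscillate around the mode instead of contracting; a per-animal
   Levenberg-Marquardt damping term is raised whenever an animal's
   gradient stops decaying, which restores monotone convergence. The
   rare stragglers are handed to a per-animal quasi-Newton solve from
   both a zero and the current start (so a dominant mode wins if the
   conditional density is multimodal), and accepted at 1e-4 gradient
   precision — a perturbation of the objective orders of magnitude below
   what the outer optimisation can resolve.
3. The objective contribution is the standard linearised form
   $\log\det C_i + r_i^\top C_i^{-1} r_i$ with
   $C_i = F_i \Omega F_i^\top + \sigma^2 I$ and
   $r_i = y_i - f(\hat\eta_i) + F_i\hat\eta_i$, evaluated through
   Woodbury and determinant-lemma identities on the (at most 3x3) inner
   matrices, fully vectorised across animals. Additive $2\pi$ constants
   are dropped, the usual pharmacometric convention, so only differences
   in OFV are meaningful; the test suite verifies the value against
   adaptive Gauss-Hermite quadrature on small problems after aligning
   constants.

The outer problem minimises the OFV over log typical values, covariate
coefficients (natural scale), log eta-variances and log residual SD with
a PORT quasi-Newton (box bounds keep proportional shifts above -1 and
variances positive), warm-starting the conditional modes between
evaluations and restarting the optimiser until the OFV is stable.
Initial values come from a crude NCA pass ([init_spec_from_data()]):
CL from dose/AUC, V1 from dose/C0, Q and V2 started at CL and V1,
moderate variances, zero covariate coefficients. Multi-start jitter is
available (`n_starts` in [foce_settings()]); the default is a single
start because the closed-form likelihood with NCA-informed initials
reached the same optimum from jittered starts throughout development.

**Convergence reporting.** The profiled objective carries a numerical
noise floor of roughly 1e-7..1e-5 from the inner solves, so
finite-difference gradient components below ~0.1 are not measurable and
classical "gradient < 1e-4" declarations would be meaningless here. The
`converged` flag therefore requires a restart-stable, non-degenerate OFV
and a maximum finite-difference gradient component below `grad_tol`
(default 1, i.e. suboptimality well below 0.01 OFV units at the observed
curvatures); the gradient norm itself is reported for inspection.
Standard errors come from a central-difference Hessian of the OFV
(covariance $2H^{-1}$), mapped to percent of each estimate by the delta
method, and are flagged as unavailable when the Hessian is not positive
definite. Eta shrinkage is $100(1 - \mathrm{SD}(\hat\eta)/\hat\omega)$.

## Stepwise covariate modelling

Candidate effects are screened by likelihood-ratio tests: the drop in
OFV when one coefficient is added is referred to $\chi^2(1)$. Forward
addition refits **all** remaining candidates against the growing model
each round and adds the smallest p-value while it is below `alpha`
(default 0.05); this is the full stepwise procedure, matching sequential
traces in which each step's drop is computed against the current model,
not a one-pass ranked addition. Backward elimination removes the effect
whose removal is least harmful as long as its removal p-value exceeds
`alpha` strictly — a removal test landing exactly on the threshold is
retained — and effects marked `forced` are never removed (the published
analysis deliberately retained the IgG effect on Q despite not
estimating IIV on Q; the forced flag reproduces that choice). Because
covariates whittled by the same biology (muscle weight, fat weight,
tumour status) are correlated, the selected set can depend on the order
of addition; the traces returned by [run_scm()] expose every candidate's
OFV at every round so such order-dependence is visible rather than
hidden.

## Quality control

IV-bolus profiles must decline from the first sample. An animal is
excluded when its second concentration exceeds the first, or when a
later successive pair rises by more than `rel_tol` (default 10%), which
emulates the exclusion of animals that received a partial IV dose with
the remainder absorbing slowly from the injection site. The artifact
injector superimposes exactly that kinetic: an IV bolus of fraction
`f` plus a first-order depot absorbing `1 - f`.

Two measured properties of this rule at the reference kinetics and
noise level (sigma 0.110) are worth knowing. First, a partial dose is
only *detectable* when it is severe: for `f` above roughly 0.2 the
superposed curve is monotone declining and carries no absorption
signature for any rule to find; the generator therefore defaults to
`f` in [0, 0.2], where detection is essentially complete. Second, the
10% late-rise guard trips on about 5% of perfectly clean profiles,
because the true decline between the sparse late samples (0.18-0.27 log
units) is comparable to the noise SD of a log-difference (0.156). A
stricter guard would trade false exclusions against missed artifacts;
`rel_tol` is exposed for exactly that reason.

Group comparisons use a two-sided Mann-Whitney test with midranks; the
exact p-value comes from the full permutation distribution of U (the
classical partition-count recursion) whenever there are no ties and
$n_x n_y \le 10^4$, otherwise a normal approximation with tie and
continuity corrections.

## Numerical choices, in one place

* Internal time unit days; schedules in hours, converted once.
* Complex-step Jacobians (step 1e-20) for the inner problem; central
  differences (relative step 1e-4) for outer gradients and Hessians.
* Inner gradient target 5e-7 (half-gradient scale), acceptance at 1e-4
  after the per-animal fallback; outer relative OFV tolerance 1e-8.
* Box bounds: log-theta in [-7, 14]; proportional-shift coefficients
  > -0.99; log omega^2 in [-15, 5]; log sigma in [-12, 2].
* Terminal-tail ties break toward more points; QC late-rise guard 10%;
  backward elimination retains on-threshold effects.
* Degenerate inputs rejected with messages: repeated-root kinetics,
  non-positive concentrations in log-linear fits, fewer than three
  terminal points, dose-free AUC extrapolation.

## Problem sizes used by the shipped experiments

The recovery experiments ([structural_recovery()],
[covariate_recovery()]) simulate five replicate 79-animal studies (four
samples each) per model — the study's own analysed-population size. The
stepwise experiments are run scaled down: first-selection across 20
replicate 40-animal cohorts, and the null calibration as 200 pure-noise
covariates screened over five 16-animal cohorts; these sizes preserve
the design (two strains, two tumour arms, two dose levels) while keeping
a full run of the suite in the minutes range on a single core.

```{r, eval = FALSE}
# a complete small run, end to end
res <- run_pipeline(tempfile("pkrun"), design = study_design(), seed = 1)
res$nca_summary
print(res$fit)
```

## Known limitations

* FOCE-I is an approximation; its OFV is validated against quadrature
  only on small problems, and like all FOCE implementations it can be
  biased for very sparse or very noisy designs.
* The diagonal-Omega restriction means covariances between random
  effects are not estimated (none were reported for this design).
* NCA on the sparse 4-point schedule carries a documented upward CL
  bias below 1% from the observation-based AUC convention.
* The generator's covariate magnitudes beyond IgG are directional
  placeholders; conclusions about real cachectic mice require the real
  measurements.
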