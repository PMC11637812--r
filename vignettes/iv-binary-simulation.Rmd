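---
title: "Comparing instrumental-variable estimators for a binary outcome: models, design choices, and what the simulations can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing instrumental-variable estimators for a binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a continuous exposure (think BMI) may affect a binary outcome (think
incident diabetes) but unmeasured confounders distort the observational
association, instrumental variables (IVs) — in Mendelian randomization,
SNPs — offer a route to the causal effect.  With a binary outcome, however,
the analyst faces a menu of estimators that target subtly different
quantities and fail in different ways, especially when most instruments are
weak.  `ivbin` implements a controlled Monte-Carlo environment in which six
estimator families can be compared head to head under known truth, together
with G-formula standardization that converts each fitted model into causal
risk ratios (CRR) and risk differences (CRD) on an exposure grid.

## The data-generating mechanism

One simulated cohort of `n` subjects contains:

* `K = 500` instruments, $Z_k \sim \mathrm{Bin}(2, q_k)$ with
  $q_k \sim U(0.1, 0.9)$ — genotype dosages in Hardy–Weinberg proportions
  with no linkage structure;
* folded-normal instrument effects: 25 strong,
  $\alpha_k \sim |N(0.02, 0.07^2)|$, and 475 weak,
  $\alpha_k \sim |N(0.001, 0.01^2)|$;
* a measured covariate (age) $X \sim N(55, 7^2)$;
* a confounder pair $(V, U)$ drawn from one of five copula families
  (below), $V$ loading on the exposure and $U$ on the latent outcome index;
* the structural equations
  $$T = 20 + \textstyle\sum_k Z_k \alpha_k + 0.2\,X + V, \qquad
    Y = 1\{-7.5 + 0.1\,T + 0.05\,X + U \ge 0\}.$$

The latent-scale coefficient $\beta_T = 0.1$ is the estimand every
estimator targets.  With standard-normal margins the closed-form expected
exposure is $20 + 25\,E|N(0.02,0.07^2)| + 475\,E|N(0.001,0.01^2)| + 11
\approx 36.3$ and the event rate averaged over the two Gaussian correlation
signs is about 15% — a rare-ish outcome, which matters because predictor
substitution is known to be approximately unbiased only for rare outcomes.

Estimation deliberately never sees the full instrument set: the `mixed`
analysis set uses the 25 strong instruments plus the first 25 weak ones,
the `weak_only` set the first 50 weak ones, so the fitted exposure model is
always misspecified relative to the generative one.  The omitted 450 weak
instruments contribute (independent, near-normal) variance to the effective
exposure error, which slightly inflates the estimated residual scale but
introduces no confounding.

A note on the indicator: `Y = 1` exactly when the latent index is
non-negative.  Ties occur with probability zero under continuous `U`; the
convention is fixed for bit-reproducibility.

### Confounder dependence families

`copula_spec()` supports five bivariate families, chosen to vary symmetry
and tail weight while holding the association level fixed:

| family | margins | dependence | tails |
|---|---|---|---|
| `gaussian` | normal | Gaussian | light, symmetric |
| `t_copula` | normal | t (df = 3) | joint-heavy, symmetric |
| `clayton` | normal | Clayton | lower-tail asymmetric |
| `gumbel` | normal | Gumbel | upper-tail asymmetric |
| `gaussian_copula_t_margins` | Student t (df = 3), rescaled to unit variance | Gaussian | marginal-heavy, symmetric |

The association level `rho` is stated on the Gaussian-correlation scale.
For the non-Gaussian families the copula parameter is calibrated so
Kendall's $\tau$ matches a Gaussian copula at `rho` ($\tau = (2/\pi)
\arcsin \rho$; at $\rho = 0.5$, $\tau = 1/3$, Clayton $\theta = 1$, Gumbel
$\theta = 1.5$).  Rank-based calibration is margin-free; a `pearson`
calibration option root-finds the parameter on the simulated product-moment
correlation instead.  Clayton and Gumbel model positive dependence only and
therefore accept only `rho > 0`.  Samplers are exact: Cholesky for the
Gaussian, a chi-square scale mixture for the t copula, gamma frailty for
Clayton and positive-stable (Chambers–Mallows–Stuck) frailty for Gumbel.

Two quantities are not pinned down by the study description and are exposed
as parameters with documented defaults:

* **t degrees of freedom** (`df = 3`): the smallest value with finite
  variance, giving visibly heavy tails;
* **t-margin standardization** (`standardize_t = TRUE`): the heavy-tailed
  margins are rescaled by $\sqrt{df/(df-2)}$ to unit variance so the
  outcome threshold retains a comparable event rate.  Even so, the
  standardized t places more mass deep in the threshold's tail, and the
  heavy-margin settings run at a 9–13% event rate rather than 15%.

### The scale of V, and why the reference tables are only approximately reproducible

The study description fixes `U` to a standard normal (it is the probit
error) but never states the scale of `V`.  `ivbin` defaults to
`margin_scale_v = 1`, the literal reading.  Under that reading the analytic
exposure moments are mean 36.3, SD 1.74, whereas the original study
reports 37.63 and 2.70.  The SD is matched exactly by
`margin_scale_v = 2.3`; the mean offset can only be explained by a single
(apparently frozen) genetics draw sitting well above its expectation, which
also raises the event rate and with it every probit- and
linear-probability-scale coefficient by roughly 10%.  We verified both
readings empirically: the larger V scale improves agreement for a few
estimators (notably split-sample IVW with the log link) but substantially
worsens the weak-instrument sign-reversal benchmark, while the literal
reading keeps that benchmark's sign and the headline LIML/2SLS/prevalence
quantities inside their bands.  The package therefore keeps the literal
default, exposes `margin_scale_v`, and treats residual ~10% discrepancies
in a handful of reference cells as irreducible without the original code.
The generator redraws $q$ and $\alpha$ every iteration (their distributions
are part of the generative recipe), which makes first-stage strength itself
random; in the weak-instrument scenarios this inflates the across-iteration
dispersion well beyond the reference tables' (ours ~0.14 vs their 0.050 for
the weak-only predictor-substitution cell), further evidence that the
original study used one frozen draw.  `freeze_genetics = TRUE` reproduces
the frozen-architecture variant for variance-decomposition studies.

## The estimators

All first stages are ordinary least squares of `T` on the 50 analysis
instruments (plus age, in the with-age scenarios).  Covariate handling is
symmetric: when a scenario includes age it enters both stages, when it does
not it enters neither.  A control function with age in one stage only is
incoherent, and we verified the asymmetric reading moves only one estimator
(2SRI with probit link) without resolving the table discrepancies.

* **2SLS** — OLS of `Y` on the fitted exposure (linear-probability scale).
* **2SPS** (predictor substitution) — binomial GLM of `Y` on the fitted
  exposure, probit (`_PR`) or log (`_LL`) link.
* **2SRI** (residual inclusion) — binomial GLM of `Y` on the *observed*
  exposure plus the first-stage residual (the control function), probit or
  log link.
* **LIML** — one-step maximum likelihood on the joint model: normal linear
  exposure equation plus probit outcome equation with bivariate-normal
  errors (correlation $\rho$, exposure error SD $\sigma_v$).  The
  log-likelihood for subject $i$ is
  $\log\phi(e_i/\sigma_v) - \log\sigma_v + Y_i\log\Phi(m_i) +
  (1-Y_i)\log(1-\Phi(m_i))$ with $e_i = T_i - \mu_i$ and
  $m_i = (\beta_0 + \beta_T T_i + \beta_x X_i + \rho e_i/\sigma_v)/
  \sqrt{1-\rho^2}$.
* **IVW** (split-sample, inverse-variance weighted) — the cohort is split
  into random halves; per-instrument exposure slopes come from one half and
  outcome slopes from the other (linear for `IVW_LI`, log-link binomial for
  `IVW_LL`); Wald ratios are pooled with fixed-effect weights
  $1/se(\hat\Gamma_k)^2$; the halves then swap roles and the two pooled
  estimates are averaged (cross-fitting).

### Numerical choices that matter

**LIML optimization.** The joint likelihood has ~55 parameters, most of
them instrument nuisance slopes.  `fit_liml()` optimizes the negative
*mean* log-likelihood by BFGS with analytic gradients on an unconstrained
reparameterization ($\log\sigma_v$, $\operatorname{atanh}\rho$), after
internally standardizing the exposure, covariate and instrument columns
(exact back-transformation afterwards).  Scaling matters far more than the
algorithm here: on raw scales the BFGS line search thrashes (hundreds of
function evaluations); standardized and 1/n-scaled it converges in ~20
iterations.  The start combines first-stage OLS (exposure block) with a
2SRI probit fit shrunk by $\sqrt{1-\tilde\rho^2}$, $\tilde\rho$ recovered
from the control-function coefficient — consistent under correct
specification and far from the $|\rho| = 1$ boundary.  Convergence is at
relative tolerance $10^{-8}$ with one deterministic restart on failure;
best-found parameters are always returned (flagged), never discarded, and
summaries never truncate extreme estimates — under badly misspecified
confounder distributions LIML is known to wander, and that behaviour is
part of what the study measures.

**Log-binomial instability.** With a continuous covariate the log-link
binomial likelihood typically has its maximum on the boundary of the
parameter space (fitted risks reaching 1 at high age), where IRLS cycles
forever — the classic log-binomial pathology; with age adjustment this
affects essentially every fit in the study.  The package detects a binding
risk cap (or a Poisson warm start already predicting risks above 1) and
falls back to the field-standard modified-Poisson log-risk fit, which
targets the same coefficients and always converges; such fits are flagged
`converged = FALSE` with `fallback = "poisson"`, and per-instrument
fallbacks are counted in the IVW output.  Dropping non-convergent
instruments instead (the strictest reading of the contract) would leave
`IVW_LL` undefined in every with-age scenario, which the reference tables
show cannot have been the original behaviour.

**Per-instrument regressions at scale.** 100 separate `glm()` calls per
IVW fit would dominate the study's runtime.  The per-SNP regressions are
therefore computed by an IRLS that is vectorized *across* instruments: one
compiled pass accumulates the weighted sufficient sums for all 50
single-SNP models, and the 2×2/3×3 normal equations are solved in closed
form (Cramer) for all SNPs at once.  Variables are centred first — the
slopes are unchanged and the normal equations become well-conditioned.
Tests pin these fits to `stats::glm` (binomial and Poisson) and `stats::lm`
to $10^{-6}$ or better per instrument.

**IVW intercept for standardization.** The IVW procedure yields a slope
only, but the risk maps need an intercept.  It is anchored at the observed
prevalence and mean exposure: $\hat\alpha_0 = g(\bar Y) - \bar T
\hat\beta$ with $g = \log$ or the identity.  This is a package decision —
the source description is silent — and it is why the IVW risk-ratio columns
should be read as anchored summaries, not independent estimates.

**G-formula standardization.** With a covariate in the model,
$\hat p(t') = n^{-1}\sum_i g(\hat\alpha_0 + t'\hat\alpha_t +
x_i\hat\alpha_x)$ with $g = \Phi$, $\exp$ or identity by family, averaging
over the same cohort's covariate vector; without one, the map is evaluated
once.  Risks and ratios are never clipped: a linear-probability model
extrapolated to BMI 37 can go negative, and the resulting negative CRRs are
informative about that misspecification.  A zero baseline risk yields a
signed-infinite CRR with a flag; the CRD is unaffected.  LIML standardizes
its latent-scale coefficients through the probit map.

## The scenario runner

`build_grid()` enumerates the 32 = 2 (instrument sets) × 2 (age in/out) ×
8 (dependence settings) scenarios in a fixed order.  Iteration `r` of
scenario `s` derives a child seed from `(master_seed, s, r)` (a fixed
integer hash below $2^{31}$), so any scenario subset can be re-run
independently and bit-identically; all estimators within an iteration see
the same cohort, making method contrasts paired.  Per-fit failures are
recorded as non-converged rows, never fatal.  Summaries report the mean and
the empirical standard error (sample SD across iterations, denominator
$R-1$) per scenario × method, over *all* iterations — extreme LIML values
included.  `render_table()` formats method × dependence-setting tables as
`mean (ESE)` with magnitudes above 999 printed as `>999`, the convention
used for unbounded estimates.

## Problem sizes

The package's own test and reproduction runs use: the flagship scenario at
$R = 50$, $n = 100{,}000$ (Monte-Carlo SE of a mean = ESE$/\sqrt{50}$,
i.e. about 0.0006 for 2SLS and 0.025 for LIML); the full 32-scenario grid
at $R = 10$, $n = 20{,}000$ for structural and ordering checks; oracle and
recovery checks at $n = 10^5$ with 20 replicates.  Monte-Carlo standard
errors scale as ESE$/\sqrt{R}$, so a full-size $R = 200$ grid (available
via `analysis/03_full_grid.R --reps 200 --n 100000`) halves them at about
25× the cost.

## What the synthetic cohorts do and do not emulate

They emulate: many independent bi-allelic instruments of realistic mixed
strength, a measured confounder in both equations, flexible unmeasured
confounding including tail-asymmetric and heavy-tailed dependence, a
rare-ish probit outcome.  They do not emulate: linkage disequilibrium or
allele-frequency spectra, pleiotropy or any IV-assumption violation,
effect heterogeneity (the homogeneity assumption holds by construction,
with no exposure–confounder interaction in the outcome index),
time-varying exposures, or selection/missingness.  A pass here therefore
speaks to estimator behaviour under valid instruments and homogeneous
effects only; it says nothing about robustness to invalid instruments,
which the estimators are known to lack in different ways.

## Known limitations

* The reference tables embed an unreproducible frozen genetics draw and an
  unstated V scale (above); a handful of their cells differ from this
  implementation by ~10% systematically.
* Isolated reference cells (2SLS under Clayton) are internally inconsistent
  with every neighbouring value and are treated as probable typos.
* The dispersions printed alongside the reference CRR tables are on an
  unclear scale and are not used for comparison; the IVW CRR constants
  printed there cannot be derived from the stated procedure.
* LIML standard errors for $\hat\rho$ are not provided; inference about the
  confounding correlation is out of scope.
* The per-fit coefficient standard errors are model-based and
  informational; the study's dispersion metric is the across-iteration ESE.
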