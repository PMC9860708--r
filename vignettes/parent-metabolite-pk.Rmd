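---
title: "Parent-metabolite pharmacokinetics of formononetin: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-metabolite pharmacokinetics of formononetin: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmnpk)
```

`fmnpk` analyses plasma concentration–time data of formononetin (FMN, the
parent isoflavone) and daidzein (DZN, its principal metabolite) after a
single oral dose in rats. This vignette is the package's own account of the
science: the structural model and its assumptions, the likelihood machinery,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Units and the bioanalytical layer

All pharmacokinetic computation is molar: amounts in nmol, volumes in L,
clearances in L/h, concentrations in nmol/L. The metabolic conversion
FMN → DZN is then a clean 1:1 transfer and the metabolite mass balance holds
without molecular-weight bookkeeping inside the model. The bioanalytical
world is mass-based (calibration 2–200 ng/mL, LLOQ 2 ng/mL), so
`ngml_to_nmoll()` / `nmoll_to_ngml()` convert at fixed molecular weights
(FMN 268.26 g/mol, DZN 254.24 g/mol — standard chemical constants) and
`dose_in_nmol()` converts a mg/kg dose at a given body weight. A 20 mg/kg
dose at the 0.2217 kg cohort-mean weight is 16,529 nmol; dividing by a
typical parent AUC reproduces the reported apparent clearances, which is the
consistency check that pins the unit system down.

The assay module covers the arithmetic a validated method reports: weighted
(1/x²) calibration regression — the weighting that equalises *relative*
error across two orders of magnitude of concentration — with r² computed on
the weighted fit (weighted residual and total sums of squares; the weighted
convention is stated because reports rarely define it); accuracy as
100·measured/nominal; precision as the percent CV; and ultrafiltration
protein binding as 100·(C_total − C_UF)/C_total. An ultrafiltrate
concentration above total is reported as negative binding with a warning
rather than clipped: it flags a real assay problem (nonspecific binding,
filter artefacts) that silent truncation would hide.

## The structural model

A two-compartment disposition model with first-order absorption for the
parent, coupled to a one-compartment metabolite:

$$\begin{aligned}
\dot A_{depot} &= -k_a A_{depot}\\
\dot A_1 &= k_a A_{depot} - \frac{CL_1}{V_1}A_1 - \frac{CL_2}{V_1}A_1 + \frac{CL_2}{V_2}A_2\\
\dot A_2 &= \frac{CL_2}{V_1}A_1 - \frac{CL_2}{V_2}A_2\\
\dot A_m &= F_m\frac{CL_1}{V_1}A_1 - \frac{CL_m}{V_m}A_m
\end{aligned}$$

with $A_{depot}(t_{lag}^+) = F \cdot D$ and all other compartments empty.
Only the fraction $F_m$ of parent elimination produces observable
metabolite; the remainder (conjugates, unobserved metabolites, biliary loss)
leaves the system. Key structural assumptions: linear (first-order)
absorption and elimination in the final model; no enterohepatic
recirculation and no gut-microflora compartment (pre-systemic microbial
conversion exists for isoflavones but there is no rat-specific
quantification to parameterise it, so absorbed-dose conversion is the
operating assumption); single dose, oral route only.

Parameters, units and the defaults used as the reference set (the published
final-model estimates for the solid-dispersion arm,
`fmn_reference_params()`):

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| F | fraction of dose absorbed | – | 0.31 |
| Fm | fraction of CL₁ forming DZN | – | 0.89 |
| ka | absorption rate constant | 1/h | 7.12 |
| V1, V2 | parent central / peripheral volume | L | 25.04, 48.31 |
| Vm | metabolite volume | L | 10.46 |
| CL1, CL2 | parent total / distributional clearance | L/h | 19.85, 38.68 |
| CLm | metabolite clearance | L/h | 41.54 |
| tlag | absorption lag | h | 0 |

### Numerical solution

The system is linear with a constant matrix, so the production path is the
closed form $x(t) = V e^{\Lambda t} V^{-1} x_0$ from an eigen-decomposition.
The eigensystem is accepted only if the eigenvalues are real, separated by
more than $10^{-8}$ relative to their magnitude, and the eigenvector matrix
has reciprocal condition above $10^{-10}$; otherwise the solver switches to
a scaling-and-squaring Padé matrix exponential, so eigenvalue degeneracy
(e.g. $k_a$ colliding with $CL_m/V_m$) is handled, not failed.
`method = "ode"` runs the same right-hand side through `deSolve::lsoda`
(rtol $10^{-10}$, atol $10^{-12}$) and is used throughout the tests as an
independent oracle; the two paths agree to $10^{-8}$ relative over random
parameter draws. Mass balance ($F D = A_{depot}+A_1+A_2+\int$ elimination)
is verified to $10^{-8}$ relative by augmenting the ODE with cumulative-flux
states, and the closed-form exposure identities $AUC_p = FD/CL_1$,
$AUC_m = F_m F D/CL_m$ are confirmed by adaptive quadrature of the
simulated curves.

A Michaelis–Menten parent-elimination variant
(`elimination = "michaelis_menten"`, flux $V_{max}A_1/(K_m V_1 + A_1)$) is
available for simulation through the ODE path; it reproduces the *structure*
of the rejected nonlinear candidates in the model-development table, but no
published $V_{max}/K_m$ values exist to verify estimates against, so it is
not part of the fitting surface.

## Non-compartmental analysis

`run_nca()` computes, per subject and analyte: Cmax/Tmax from the observed
points (ties to the earliest time); AUC to the last quantifiable point by
the linear trapezoidal rule; the terminal slope λz; t½ = ln 2/λz;
AUC∞ = AUC_last + C_last/λz; CL/F = D/AUC∞ and Vd/F = D/(λz·AUC∞) for the
parent (no metabolite dose exists, so apparent metabolite clearance is not
reported). BLQ records are excluded.

The λz point-selection rule is not something a study report ever prints, so
the package adopts the convention of standard NCA software: candidate sets
are the last 3, 4, … up to all positive post-Tmax points; the set with the
best adjusted R² wins; ties within $10^{-4}$ go to the larger set; fewer
than three usable points, or a non-negative slope, leave λz — and everything
downstream of it — undefined (`NA`). This reproduces the dashes that real
NCA tables show when a terminal phase cannot be characterised. t½ uses the
full-precision ln 2, displayed at the conventional 0.693 precision only in
text.

## Likelihood machinery

Residual error is per-analyte with four kinds: additive ($g = \sigma^2$),
proportional ($g = \sigma^2 f^2$), log-additive (Gaussian on log
concentrations) and combined. The pooled objective is exact maximum
likelihood treating all observations as one subject:
$-2LL = \sum[\ln(2\pi g) + (y-f)^2/g]$. The log-additive objective includes
the $2\ln y$ change-of-variables term so that it is directly comparable
with the proportional objective — to first order in the CV the two
coincide, which is exactly the near-identity the study's error-model
comparison table shows; omitting the term would shift the value by
$\sum 2\ln f$ and make the kinds incomparable.

Mixed-effects estimation (`fit_pk_nlme()`) uses exponential IIV,
$P_i = P_{tv}e^{\eta_i}$ with diagonal $\omega^2$ (per-parameter variances,
no covariances — matching how such studies report IIV), and approximates
each subject's marginal likelihood by the Laplace method at the mode of the
joint density: $-2LL_i = j(\hat\eta) - q\ln 2\pi + \ln\det(H/2)$. Variances
below $10^{-10}$ are treated as structurally zero, so the objective
collapses smoothly (and exactly, as tested) onto the pooled one. The
implementation is verified per subject against a one-dimensional quadrature
oracle. FOCE-ELS, the other engine named in such reports, follows a
proprietary objective convention; absolute $-2LL$ values are therefore
comparable only within one implementation, and the package compares
candidate models by *differences* on its own objective.

### Optimization and uncertainty

Positive parameters are optimized on the log scale, the fractions F and Fm
on the logit scale; sigmas are bounded below at $10^{-6}$ (transformed
scale) to keep noise-free fixtures away from degenerate zero-variance
optima. The optimizer is `nlminb` (quasi-Newton, numeric gradients,
relative tolerance $10^{-8}$), with optional jittered multi-start. The
inner η-optimizations of the Laplace objective always start from
deterministic points: a warm-start tied to optimizer history makes the
outer objective non-reproducible at the $10^{-7}$ level, which is enough to
corrupt finite-difference gradients. CV% (100·SE/estimate) comes from the
inverse observed information at the optimum via the delta method; a
singular Hessian yields `NA` CVs rather than a failure.

Identifiability: with oral-only data on parent and metabolite, F is
confounded with the scale of (V₁, V₂, CL₁, CL₂) and Fm with (Vₘ, CLₘ) —
only F·D/V-type ratios enter the likelihood. The package's convention,
used in all recovery experiments, is to fix F and Fm; the remaining seven
structural parameters are then identifiable from two-analyte data.

## Model selection and the bootstrap

`aic()`/`bic()` implement $-2LL + 2p$ and $-2LL + p\ln n$ with $n$ the
included-observation count. `nested_decision()` applies the χ²(df = 1)
rule: adding a parameter must buy a $-2LL$ decrease above the 95% quantile
(3.84); removing one is acceptable if the increase stays below the 99%
quantile (6.63). `pk_bootstrap()` resamples *subjects* with replacement —
the only exchangeable unit in a five-animal study — keeping the subject
count, refits from the original estimates, and reports per-parameter
percentile (2.5/50/97.5) summaries over converged replicates;
non-converging replicates are dropped and counted, not retried. The whole
procedure is a pure function of the seed. The refit engine is the pooled
fit; a mixed-effects bootstrap at the conventional 1000 replicates is far
beyond interactive scale and is out of scope.

## The synthetic study generator

`simulate_pk_study()` emulates the solid-dispersion study arm: 5 rats,
20 mg/kg oral FMN, sampling at 0.08, 0.16, 0.33, 0.5, 1, 2, 4, 8, 12, 24 h,
the reference parameters as truth, exponential IIV (off by default),
residual noise per the error model, and LLOQ censoring at 2 ng/mL converted
per analyte (BLQ rows keep the flag and carry the LLOQ, not a fake value).
Body weight defaults to the cohort mean 0.2217 kg, with optional Normal
variation (the cohort SD was 4.9 g). Negative perturbed concentrations are
truncated at zero and counted.

Two generator choices deserve explanation:

* The published residual-error magnitudes (0.75 for FMN, 0.42 for DZN,
  labelled "proportional error") have an unstated scale — SD, variance or
  CV%. The generator's default uses them as proportional SDs and flags the
  ambiguity in its metadata; every recovery experiment instead states an
  explicit σ = 0.20 on both analytes so that no conclusion depends on the
  reading. 0.75 as a proportional SD is heavy-tailed enough to produce
  occasional negative draws (truncated, warned) — consistent with the very
  large between-animal spread the study reports.
* Recovery experiments use 20 subjects per replicate rather than 5: the
  target is the *estimator*, and 5-animal replicates confound estimator
  bias with design noise. The published 5-animal design is the generator's
  default for everything else.

What the generator does **not** emulate: the gut-microflora conversion
pathway, absorption-model misspecification (truth and fitted model share
the structural form), correlated random effects, per-timepoint missingness,
and assay error structure beyond the chosen residual model. Passing
recovery tests therefore demonstrate that the estimation machinery inverts
the generative model correctly at study-like noise — not that the
structural model is right for real rats.

## Problem sizes and runtimes

The test suite and the acceptance script are sized for a single CPU: the
recovery experiment runs 20 replicates of 20 subjects (~3 s per pooled
fit); property suites use up to 100 random parameter draws for solver
agreement and 1000-point grids for NCA convergence; bootstrap unit tests
use 4–12 replicates on reduced parameter sets; the mixed-effects recovery
check runs one 24-subject study with σ fixed at truth. The study-scale
bootstrap (B = 1000) and a full nine-parameter NLME fit run in hours, not
minutes, and are intentionally not part of any default run.

## Known limitations

* Absolute $-2LL$ values are objective-convention-dependent; only
  differences on a common implementation are meaningful, so the published
  model-development table is checked through its internal AIC/BIC
  identities, not by refitting (the raw animal data are not deposited).
* The Laplace approximation can bias variance components low in very small
  samples; empirical-Bayes η shrinkage is inherent.
* BLQ handling is exclusion ("discard"); likelihood-based censoring (M3)
  is not implemented.
* Single oral dose only: no IV, infusion, or multiple dosing.
* The bootstrap refits the pooled model (see above).
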