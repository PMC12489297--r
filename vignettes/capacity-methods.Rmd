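---
title: "Methods: estimating C4 photosynthetic capacity from A/Ci curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating C4 photosynthetic capacity from A/Ci curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4aci)
```

# The model

A C4 A/Ci curve records net CO2 assimilation `A` across intercellular CO2
`Ci`. At low `Ci` the curve is limited by PEP carboxylation and follows a
Michaelis-Menten response,

$$A = \frac{C_i \, V_{pmaxA}}{C_i + K_p} - R_m,$$

where `VpmaxA` is the apparent maximal PEP carboxylase activity, `Kp` the
Michaelis constant of PEPc for CO2, and `Rm` the mesophyll half of daytime
respiration. `Kp` follows an Arrhenius temperature response around its 25
degC reference of 80 ubar (activation energy 36.3 kJ/mol) and is divided by
atmospheric pressure to express it as a mole fraction commensurate with
`Ci`. Respiration follows a Q10 = 2 response around 1.2 umol m-2 s-1 at 25
degC, and `Rm` is half of `Rday`. These defaults live in
`kinetic_constants()` and can be overridden there or via a plain-text config
file (`read_constants_config()`).

At high `Ci` assimilation saturates. The full curve is summarised by a
non-rectangular hyperbola in which the gross rate `X = A + Rday` is the
smaller root of

$$\theta X^2 - (\alpha C_i + A_{max}) X + \alpha C_i A_{max} = 0,$$

with curvature fixed at `theta = 0.7` and `Amax` defined as the asymptote of
the gross rate. The root is evaluated in the form
`2 * alpha * Ci * Amax / (b + sqrt(b^2 - 4 theta alpha Ci Amax))`, which is
numerically stable as `theta` approaches zero (the rectangular-hyperbola
limit), unlike the textbook `b - sqrt(...)` form.

# Fitting

`fit_vpmax()` uses only points with `Ci < 100` umol mol-1. Because the model
is linear in `VpmaxA` given `Kp` and `Rm`, the estimate is a closed-form
regression through the origin on `x = Ci/(Ci + Kp)`, `y = A + Rm`; its
sampling variance is the squared standard error of that slope. This is the
exact global least-squares minimiser, so no optimiser or starting value is
involved.

`fit_amax()` fits `(alpha, Amax)` of the hyperbola to all points of a group
by bounded Gauss-Newton (`nls`, algorithm "port") with a deterministic
three-start ladder derived from the data (initial slope from the two
lowest-Ci points, asymptote from the maximum observed `A` plus `Rday`).
Sampling variances come from the fit covariance. Both fits pool the
replicate curves of a group, which shrinks sampling variance roughly as
1/(number of curves).

Estimates at a box bound are flagged as non-converged rather than dropped;
quality control, not the fitting stage, decides what survives.

# Grouping and quality control

Replicate curves measured on the same species and genotype in one study
within a 5-day window are consolidated by `consolidate_groups()`. The window
is anchored greedily at the first date of each group, which makes the
grouping deterministic and invariant to input row order; undated curves
become singleton groups.

Three filters mirror common failure modes of compiled gas-exchange data:

* fewer than 2 points below `Ci = 100`: the initial slope (hence `VpmaxA`)
  is unreliable and dropped;
* fewer than 2 points above `Ci = 500`: the saturated region (hence `Amax`)
  is unreliable and dropped;
* limitation consistency: at low `Ci` the PEPc-limited prediction must not
  exceed the fitted CO2-saturated ceiling `Amax - Rday` at more than half of
  a fixed `Ci` grid (5 to 100 in steps of 5).

The consistency comparison deliberately uses the fitted asymptote rather
than the full hyperbola. Comparing two fitted curves pointwise at low `Ci`
amounts to asking which of two nearly identical local fits sits marginally
higher, which for clean curves is close to a coin flip and would discard
healthy groups at random; the asymptote comparison separates cleanly,
keeping clean curves and discarding curves whose initial slope outruns their
saturated rate. The pointwise variant remains available via
`limitation_consistency_check(..., compare = "hyperbola")` for sensitivity
analysis. The check is evaluated, and counted, only among groups that passed
both point-count filters, so the staged accounting in `run_qc()` attributes
every discarded group to exactly one stage.

# Meta-regression

Group-level estimates carry known sampling variances, so the second stage is
a multilevel meta-regression (`c4_meta()`): random intercepts for study,
species and observation (residual heterogeneity), plus a residual with the
known per-observation variance. Variance components are estimated by REML on
the marginal covariance, profiling out the fixed effects; the optimiser runs
over log variance components, so non-negativity is structural and the fit is
deterministic. Continuous covariates are mean-centred before interactions
are formed, making main effects interpretable at average conditions;
predictions re-apply the stored centring so results are invariant to it.

Inference is large-sample Wald (z) per coefficient. Variance explained is
reported as a marginal R2 (fixed effects over fixed plus random) and a
conditional R2 (fixed plus random over the total including mean sampling
variance). `marginal_means()` gives model-predicted means per factor level
with confidence intervals from the fixed-effect covariance and prediction
intervals that add the summed random-effect variance; `predict_surface()`
evaluates the temperature interaction on a `tleaf` by `mean_tmax` grid and
flags extrapolation beyond the observed ranges.

The implementation is self-contained (base R linear algebra via Cholesky
factorisations). The test suite cross-checks coefficients, standard errors
and variance components against `metafor::rma.mv` on multiple datasets, and
against closed forms in balanced designs.

# Estimate relationships

`sma_fit()` fits standardized major axis lines of `Amax` against `VpmaxA`
within leaf-temperature bins -- appropriate when both variables carry error
-- and tests slope homogeneity with a likelihood-ratio statistic based on
the residual-versus-fitted-axis correlation, asymptotically chi-squared with
bins minus one degrees of freedom. `log_linear_fit()` summarises the
saturating coupling `Amax = a + b ln(VpmaxA)`.

# Synthetic data

`simulate_curves()` generates a multi-study curve compilation with known
ground truth: studies with 4-12 groups, 1-9 replicate curves per group,
species nested in studies, study-level growth location and mean maximum
growth temperature (truncated normal, mean 26, sd 3.5, on [15, 38]). Two
design choices matter for realism and identifiability:

* Leaf temperature is the growth temperature plus a bounded offset
  (uniform on [-3, 8], clamped to [15, 42]) because gas exchange is measured
  near growth conditions; this induces the realistic correlation between
  `tleaf` and `mean_tmax` that the centred interaction model has to
  disentangle.
* The group's true gross saturated rate is coupled to its true `VpmaxA`
  through `amax = -72 + 26 ln(vpmax)` plus noise, floored at half of
  `vpmax`. The floor guarantees the PEPc-limited branch is the operative
  limitation at every `Ci` below 100, i.e. the generated curves satisfy the
  assumption the consistency check tests.

Default fixed-effect sizes (for example, a `tleaf` slope of 3.58 and an
outdoor offset of -15.19 for `VpmaxA`) act as planted truths for recovery
checks; coefficients for subtype, growth form, species group and all
interactions default to zero and double as nulls for type-I-error checks.
Measurement noise is Gaussian with sd 0.5 on `A`; each curve runs a fixed
`Ci` ladder plus a repeated point at 400 as a stability check.
`plant_qc_violations()` injects the three QC defect types into whole groups
and returns the ground-truth labels so the QC accounting can be verified
exactly. `simulate_meta_observations()` bypasses the curve stage to test the
meta-regression in isolation, drawing known sampling variances from a
log-normal (median 4).

One caveat is intentional: the generator's forward curve subtracts the full
`Rday` while the initial-slope fit subtracts `Rm = Rday/2`, exactly the
mismatch a real analysis faces. This contributes a small negative bias to
recovered `VpmaxA` (median absolute relative bias around 3-4% at the default
noise level), which the recovery checks bound below 5% rather than pretend
away.

# Problem sizes and limitations

The defaults target the scale of a compiled literature dataset: roughly 400
groups from 49 studies, curves of 14 points. REML fits at that size take
well under a second each; full parameter-recovery runs (200 groups,
curve-level fitting) take on the order of a minute.

Limitations: theta is fixed, not estimated; the meta-regression assumes
independent random intercepts (no phylogenetic covariance); Wald inference
is asymptotic, so standard errors of study-level covariates can be slightly
optimistic with few dozen studies; and SMA slopes inflate with residual
noise by construction, which is a property of the method rather than the
implementation.
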