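---
title: "One-compartment kinetics of TBI blood biomarkers: model, uncertainty, and the inverse problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-compartment kinetics of TBI blood biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbikin)
```

## The model and its assumptions

A concussion releases an amount $D_0$ (pg) of a brain protein into the
brain compartment at the moment of impact. The model treats what follows
exactly like oral drug absorption: first-order transfer into a single
well-mixed blood compartment at rate $k_a$ (hr$^{-1}$), with a fraction
$F$ (bioavailability) ever arriving, and first-order elimination from
blood at rate $k_e$ (hr$^{-1}$). Writing $V_d$ (ml) for the volume of
distribution — approximated by total blood volume — the plasma
concentration is the bi-exponential

$$C_p(t) = \frac{F D_0 k_a}{V_d (k_a - k_e)}
  \left( e^{-k_e t} - e^{-k_a t} \right),$$

with elimination half-life $t_{1/2} = 0.693/k_e$ and peak time
$T_{max} = \ln(k_a/k_e)/(k_a - k_e)$ separating the absorption phase
(levels rising) from the elimination phase (levels falling).

The assumptions worth keeping in mind when interpreting anything
downstream:

* **Instantaneous release.** All of $D_0$ enters the brain compartment at
  $t_0$; no staged or continuing release, and no ongoing synthesis.
* **One compartment.** Biomarker in blood stays there until renal
  elimination — no redistribution to fat or other tissues. S100B is known
  to strain this assumption (it has extra-cerebral sources and probable
  redistribution); its preset is provided and used as printed, but fits
  for S100B deserve extra skepticism.
* **No baseline.** The model describes the injury-attributable rise only;
  healthy-control baseline levels are not subtracted. The synthetic
  generator can *add* a baseline (off by default) precisely so that the
  estimator's behaviour in the presence of unmodeled baseline can be
  studied.
* **Constant rates.** $k_a$ aggregates several drainage routes
  (glymphatic, perivascular, direct blood–brain-barrier breach) into one
  time-constant rate.

## Parameters, units, defaults

Units are fixed package-wide: hours, pg, ml, pg/ml. There is no unit
conversion layer.

| Parameter | Meaning | Default / source |
|---|---|---|
| $k_a$, $k_e$ | absorption / elimination rates, hr$^{-1}$ | per-biomarker presets |
| $F$ | bioavailability fraction | 0.8 for every preset |
| $D_0$ | release at impact, pg | nominal 400,000 |
| $V_d$ | volume of distribution, ml | nominal 5,000 |

The six presets (`list_presets()`) store the published, *rounded* rate
constants verbatim, so that predicted curves reproduce the published
ones digit-for-digit. Two internal inconsistencies in that table are
deliberate and preserved: the UCH-L1 and tau $k_a$ values (0.09 and
0.07) do not satisfy the $T_{max}$ relation given their own printed
$T_{max}$ of 8 h (the relation would give roughly 0.17 and 0.20).
`get_preset(name, recompute = TRUE)` derives $k_e = 0.693/t_{1/2}$ and
$k_a$ from the $T_{max}$ relation at full precision for users who want
internally consistent kinetics instead. The constant 0.693 (not
$\ln 2$) is the default half-life constant for the same
reproduce-the-printed-numbers reason; every conversion accepts
`const = log(2)`.

`ka_from_tmax()` must confront "flip-flop" kinetics: the peak-time
relation is symmetric in $k_a \leftrightarrow k_e$, so a given
($T_{max}$, $k_e$) admits one root above $k_e$ and one below. The
default branch is absorption-faster ($k_a > k_e$), which every preset
satisfies; the other branch is available by flag. The root is found by
Brent's method on a bracket $[k_e(1+10^{-9}), \max(10, 100k_e)]$
(expanded if needed) to ~$10^{-12}$ relative tolerance; the function is
monotone on each branch so convergence is guaranteed. At
$T_{max} k_e = 1$ the branches meet at $k_a = k_e$ and the result is
flagged degenerate.

### Numerical choices

* The bi-exponential has a removable singularity at $k_a = k_e$. Below a
  relative difference of $10^{-8}$ the analytic limit
  $F D_0 k_a t e^{-k_a t}/V_d$ is used; tests verify continuity across
  the switch to $10^{-6}$ relative.
* Negative concentrations cannot arise analytically but tiny negative
  values can arise in floating point at $t = 0$; outputs are clamped at
  zero.
* CSV output is written at 6 significant digits for byte-stable files
  across platforms.

## Input uncertainty and sampling

Model inputs are positive, so uncertain inputs get a **mean-preserving
lognormal**: $p_i \sim \text{lognormal}(\log p_{nom,i} - \sigma_i^2/2,
\sigma_i^2)$, whose expectation is exactly the nominal value. The
defaults mirror the published analysis: $\sigma = 0.3$ for $D_0$ (the
least-known input), $\sigma = 0.1$ for $V_d$, $k_a$, $k_e$ in the joint
analyses, and $\sigma = 0.2$ when a single rate constant is varied for
an uncertainty band.

Reproducibility contract: every sampler takes one root seed, and each
named input column draws from its own deterministic sub-stream (a hash
of the root seed and the column name), so adding or removing a column
never perturbs the draws of the others. Plain Monte Carlo is used
throughout — no Latin hypercube — matching the published simulation
design of 1,000-row sample matrices.

## Sensitivity analysis

`pcc_over_time()` draws one joint sample matrix of $(D_0, V_d, k_a,
k_e)$, pushes it through the model at each time point, and computes the
**partial correlation coefficient** $\gamma$ of each input with $C_p$,
adjusting for the other three by linear residualization. Raw values,
not ranks, are the default (a rank option exists) because the published
analysis used partial, not partial-rank, correlations. One shared
matrix across time points — rather than fresh draws per time — was a
design choice the source leaves open; it produces smooth
$\gamma(t)$ curves and changes nothing statistically at a fixed time.

Significance uses
$T = \gamma\sqrt{N-2-p}/\sqrt{1-\gamma^2} \sim t_{N-2-p}$ with $p$ the
number of varied inputs minus one; inverting analytically gives the
band half-width $t_q/\sqrt{N-2-p+t_q^2}$. The level $\alpha$ defaults
to 0.05 (the source states none). $N$ per time point defaults to 1,000.

The reproducible pattern: $\gamma_{D_0} > 0$ and $\gamma_{V_d} < 0$ at
all times; $|\gamma_{k_a}|$ dominates early and $|\gamma_{k_e}|$ late,
with the hand-over near $T_{max}$ — hence later for NF-L than for GFAP.

## Uncertainty scenarios

Four Monte Carlo scenarios, all bit-reproducible given (seed, config):

1. **Joint** (`joint_uncertainty()`): all four inputs varied at the
   default sigmas; reported as Pearson correlations of each input with
   the output at each requested time (default 5 h and 50 h), the
   quantitative stand-in for scatter plots.
2. **Single rate constant** (`single_param_band()`): one of $k_a$/$k_e$
   lognormal at $\sigma = 0.2$, everything else nominal; band =
   mean ± 2δ with δ the per-time output sd. The $k_a$ band is widest
   during absorption, the $k_e$ band during elimination, for every
   preset.
3. **Sampling time** (`time_uncertainty()`): the draw time is uniform on
   nominal ± half-width (scenarios 6 ± 3 h and 36 ± 12 h). Uniform is
   the weakest assumption consistent with a "±" statement; no
   distribution family was stated. A caption in the source gives
   conflicting ranges for these windows; the body text ("6 ± 3",
   "36 ± 12") governs here. Note that at 6 ± 3 h NF-L shows by far the
   smallest *absolute* spread (its curve is barely off the floor there)
   while its *relative* spread is the largest of the four — claims about
   NF-L's insensitivity to timing are absolute-scale claims.
4. **Blood volume** (`blood_volume_uncertainty()`): $V_d$ normal with
   sex-specific nominal means 4,750 ml (women) / 5,320 ml (men). The
   source does not state the standard deviations; the default is 10% of
   the sex mean, configurable, chosen as order-of-magnitude consistent
   with published blood-volume variability. Nonpositive draws are
   redrawn (truncated normal) rather than clipped, to avoid a point
   mass at zero.

## The inverse problem

Because the model is linear in $D_0$, writing $s(t) = C_p(t)/D_0$ turns
least squares over measurements $(t_i, y_i)$ into the closed form
$\hat D_0 = \sum_i s(t_i) y_i / \sum_i s(t_i)^2$ — no iterative
optimization, and the estimate is exact on noise-free data from any
schedule. Ordinary (unweighted) least squares is the default, matching
the published description; negative estimates are clamped to zero
(negative release being unphysical) with the raw value always reported
alongside, since whether the original analysis constrained the sign is
unknown.

Real cohort samples are date-stamped, not time-stamped, in four windows:
under 6 h, 24–48 h, when asymptomatic, and 7 days after return to play.
`fit_cohort()` maps the labels to single assumed hours — defaults 6, 36
(window midpoint), 168 (one week) and 336 (two weeks) — all
configurable, and any conclusion that leans on them is qualitative
only. Rows with unmappable labels are skipped with a warning; subjects
left with no usable rows are excluded, mirroring the exclusion of
subjects with missing date stamps. Per-subject $V_d$ is 5,000 ml unless
the table carries a `Vd_ml` column.

`predicted_vs_measured()` quantifies systematic misfit at one window as
the mean signed error (estimated − measured). This is how the NF-L
revision is motivated and tested here on synthetic data: generate a
cohort with fast-absorbing NF-L kinetics ($k_a = 0.2$), fit with the
slow literature preset ($k_a = 0.009$), and the 6-h mean signed error
is strongly negative; swapping to the revised preset shrinks it.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the restricted validation
cohort so that every estimator is testable against known ground truth:

* **Schedule**: the four windows above, sampled at the scheduled hour
  plus uniform jitter, shared across biomarkers within a subject/visit
  (one venipuncture). Jitter defaults: ±3 h (6-h draw) and ±12 h
  (24–48 h draw) mirror the timing-uncertainty scenarios; the
  asymptomatic and return-to-play windows have no stated spread, and
  ±48 h was chosen once as a realistic clinical spread.
* **Heterogeneity**: $D_0$ mean-preserving lognormal (nominal 400,000
  pg, $\sigma = 0.3$), optionally a two-component lognormal mixture to
  emulate the bimodal spread of kinetic profiles reported for the real
  cohort (whose mixture parameters are unpublished; the option is a
  structural placeholder, not a calibration). $V_d$ sex-specific
  truncated normal (4,750/5,320 ml ± 10%).
* **Noise**: multiplicative mean-preserving lognormal on levels,
  default $\sigma = 0.2$ — immunoassay coefficients of variation are
  proportional, and the source specifies no noise model.
* **Baseline**: off by default (the model ignores baseline); on, adds a
  uniform draw from the biomarker's healthy range.
* **Missingness**: with the configured rate a row loses its date stamp,
  which downstream fitting then excludes.

What passing tests on this generator do **not** show about real data:
assay floors/ceilings (no limit of detection is simulated), repeat
concussions, continuing biomarker synthesis, baseline drift, or any
misspecification of the one-compartment form itself. The generator and
the fitter share the model family by construction, so recovery tests
validate the estimator, not the biology.

## Problem sizes and test design

The test suite and examples run Monte Carlo at the published run count
(1,000) or below, cohorts of 5–500 subjects, and dense grids only where
an analytic identity is being checked (e.g. the trapezoid integral of
the GFAP curve over 0–2000 h at 0.1 h steps reproduces
$F D_0/(k_e V_d)$ to 0.1%). Estimator regression bounds were frozen
from a fixed-seed simulation: with 20% assay noise, no timing jitter
and known $V_d$, the median relative error of $\hat D_0$ at $n = 200$
is about 10% and is asserted below 15%.

One published qualitative claim fails under the published parameters
and is left failing in the acceptance tests rather than papered over:
the assertion that GFAP levels are still rising at 36 h. GFAP's own
printed rates put its peak at 23.4 h, so the model's slope at 36 h is
negative; NF-L (peak ≈ 245 h) is rising there, and tau/UCH-L1 are
falling, as claimed.

## Known limitations

* Presets inherit the source's approximate rate constants; NF-L's
  literature kinetics are sparse enough that its preset exists in two
  versions.
* The label-to-hours mapping injects up to tens of hours of
  unquantified timing error into real-cohort fits.
* No weighting for heteroscedastic assay error is applied by default
  (`estimate_D0(..., weights = )` provides weighted LS).
* The bimodality machinery generates mixtures but the package contains
  no formal bimodality test.
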