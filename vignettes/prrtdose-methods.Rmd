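---
title: "Methods: per-cycle 177Lu-DOTA-TATE dosimetry in prrtdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cycle 177Lu-DOTA-TATE dosimetry in prrtdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrtdose)
```

## The clinical problem

PRRT with [¹⁷⁷Lu]-DOTA-TATE treats metastatic neuroendocrine tumors
over up to four cycles of roughly 7.4 GBq each. The kidneys (via
tubular reabsorption of the peptide) and the red bone marrow are the
dose-limiting tissues; institutional practice tracks their absorbed
dose cycle by cycle and withholds further treatment when the expected
cumulative dose after the *next* cycle would exceed the safety limits
(23 Gy kidneys, 2 Gy marrow) by more than a 10% decision margin, i.e.
25.3 Gy and 2.2 Gy. `prrtdose` implements that analysis from
desk-scale inputs: activity-concentration samples, VOI masses,
administered activities, and a dose-factor table.

## Kinetic model

Every source region is modeled mono-exponentially,
$C(t) = C_0 e^{-\lambda_{\mathrm{eff}} t}$, where
$\lambda_{\mathrm{eff}} = \lambda_{\mathrm{phys}} + \lambda_{\mathrm{bio}}$
combines ¹⁷⁷Lu physical decay
($T_{1/2} = 6.647\,\mathrm{d} = 159.5\,\mathrm{h}$, so
$\lambda_{\mathrm{eff}} \ge \lambda_{\mathrm{phys}} = \ln 2/159.5\,\mathrm{h}^{-1}$)
with biological clearance. Organs are sampled at 18 h, 25 h and 7 days
after the first cycle; blood only at 18 h and 25 h. Choices that
follow from this design:

* **Two points → exact algebra.** The blood curve has two samples, so
  `fit_monoexp()` solves for $(C_0, \lambda)$ through both points
  exactly rather than iterating. Fitting is refused for fewer than two
  points, duplicated times, non-positive concentrations, or a
  non-decaying curve.
* **≥ 3 points → least squares in linear space.** Log-space-only
  fitting is biased under multiplicative noise, so the log-linear OLS
  solution serves as the initializer for Levenberg–Marquardt
  (`minpack.lm::nlsLM`) on the untransformed model. If the optimizer
  fails, the log-linear estimate is used with a warning.
* **Sub-physical decay warns, never errors.** Noise can push a fitted
  $\lambda_{\mathrm{eff}}$ below $\lambda_{\mathrm{phys}}$; the fit is
  physically impossible but statistically legitimate, so it is flagged
  (`prrtdose_subphysical_lambda`) and kept. Two close blood time
  points make this warning fairly common at realistic noise; a noisy
  *rising* blood curve, by contrast, is a hard error
  (`prrtdose_nonphysical_fit`).
* **Later cycles reuse the cycle-1 half-life.** Cycles ≥ 2 are imaged
  once (~20 h); assuming an unchanged effective half-life, the curve
  is re-anchored as $C_0 = C(t)\,e^{\lambda t}$
  (`rescale_to_cycle()`). No uncertainty is propagated onto fitted
  parameters.
* **Units.** Time stays in hours everywhere; the single ×3600
  conversion to seconds lives inside `residence_time()`, which returns
  $t_r = C_0 \cdot 3600/(\lambda_{\mathrm{eff}} A_{\mathrm{adm}})$ in
  (MBq·s)/(MBq·kg). Doses are carried in mGy; limits and reports use Gy.

## Dose model and the mass-scaling convention

Absorbed doses follow the MIRD self- plus cross-dose sum over source
regions $s$:

$$D(r_t) = A_{\mathrm{adm}}\left[t_{r_t}\,\mathrm{DF}(r_t \leftarrow r_t)
          + \sum_{s \ne t} t_{r_s}\,\mathrm{DF}(r_t \leftarrow r_s)\right].$$

Residence times here are *concentration* residence times, so the unit
bookkeeping is closed by the factor `kind` in the table:

* `organ_level` factors (mGy/(MBq·s)) pair with a source mass:
  cross terms use $t_r \cdot m_{\mathrm{VOI}}$ (delineated VOI mass,
  density 1.0 g/cm³). For the *self* term, the standard inverse-mass
  scaling of the self-absorbed fraction rescales the S value by
  $m_{\mathrm{phantom}}/m_{\mathrm{VOI}}$, which cancels the VOI mass
  and leaves
  $A_{\mathrm{adm}} \cdot t_r \cdot \mathrm{DF}_{\mathrm{self}} \cdot m_{\mathrm{phantom}}$.
  The cancellation is deliberate and tested: at fixed measured
  concentration, re-drawing an organ VOI smaller or larger does not
  change its self-dose. This convention was a genuinely open design
  point (exact mass-scaling formulas are rarely printed); it was
  chosen for consistency with the concentration-factor tumor method
  below.
* `concentration` factors (mGy·kg/(MBq·s)) multiply $t_r$ directly:
  the marrow self-dose (marrow concentration assumed equal to blood
  concentration, hence computed from the blood curve) and the
  remainder-of-body terms.

Special cases: tumors receive self-dose only, via a dose concentration
factor (default 0.0236 mGy·g/(MBq·s); the 10⁻³ inside `tumor_dose()`
converts g→kg). As cross-dose *sources* tumors radiate with the
liver's factors (lesions are predominantly hepatic) paired with the
tumor VOI mass. The remainder→marrow factor is replaced by
30.3 / 35.8 nGy·kg/(MBq·s) (male / female), because phantom tables
overestimate that term when there is no bone uptake. The shipped
tables under `inst/extdata/` are **synthetic** fixtures with plausible
¹⁷⁷Lu magnitudes — they are not OLINDA/EXM values, which is why the
table is a user-supplied input with strict schema validation.

## Management rule

`expected_after_next()` implements the expected cumulative dose after
cycle $p+1$ as the cumulative dose plus the mean per-cycle dose,
$\sum d \cdot (p+1)/p$. `decide_continuation()` withholds iff any
managed organ *strictly* exceeds its threshold ("will exceed" —
boundary equality continues); only the kidneys and marrow are managed
by default, and per-cycle dosimetry must be complete for every managed
organ. An `override` flag records — but never applies — the rare
clinical decision to continue beyond the limits. `ct_count()` models
the imaging burden: $3 + (n-1)$ CTs classically versus a single CT,
a reduction of $1 - 1/(n+2)$ (5/6 for four cycles).

## Agreement statistics

`bland_altman()` uses per-pair relative differences
$(a-b)/\tfrac{a+b}{2}\cdot 100\%$ with the sample SD ($n-1$, the small-n
convention of agreement studies) and hard-coded 1.96 for the 95%
limits of agreement. Signed differences are the default — unsigned
summaries cannot produce the negative mean differences such analyses
report — with `signed = FALSE` available. Pearson $r$ uses the
standard $t$-based two-sided p-value. `binomial_power()` builds the
exact one-sided rejection region $\{X \ge k^*\}$,
$k^* = \min\{k: P(X \ge k \mid p_0) \le \alpha\}$; under the
discordance null $p_0 = 0$ this reduces to $1-(1-p_1)^n$, e.g. 0.92
for $n = 24$, $p_1 = 0.10$, $\alpha = 0.05$. The general construction
is exposed because the degenerate-null reading, while the default, is
only one formalization of a "one-sided binomial test" power statement.

## What the synthetic cohort emulates — and what it does not

`cohort_config()` defaults define the study conditions: 24 patients,
administered activity $\mathcal{N}(7400, 250)$ MBq per cycle, 1–4
cycles drawn with weights (0.05, 0.12, 0.15, 0.68) giving a median of
4 and a mean near 3.5, and uniform per-organ kinetic ranges (e.g.
kidneys $C_0 \in [150, 450]$ MBq/kg, $T_{\mathrm{eff}} \in [35, 65]$ h)
sized so that per-cycle kidney doses span roughly 2–12 Gy and marrow
doses tens to ~150 mGy with the shipped tables — realistic magnitudes
for this therapy. Effective half-lives are clamped at the physical
half-life. These ranges are invented fixtures: no distributional data
on inter-patient kinetic variability backs them, and they are
documented here precisely because they are a package choice.

Measurement noise is multiplicative lognormal
($\times e^{\mathcal{N}(0, 0.05)}$ by default): concentrations are
positive with scale-proportional error. The single-CT protocol is
modeled as one extra per-cycle lognormal factor
($\sigma_{\log} = 0.06$) on *organ* samples of cycles ≥ 2 only — blood
counting is CT-independent, which is exactly why marrow dose is nearly
protocol-independent, and the first cycle carries the reference CT.
Classical and single-CT simulations share their noise sub-stream, so
protocol contrasts isolate the perturbation. Seeds split as
`(master + 104729·k) mod (2³¹−1)` per patient, making patient $k$
reproducible in isolation and invariant to cohort size.

The generator does **not** emulate: multi-exponential washout,
inter-cycle kinetic drift (true parameters are fixed per patient, so
true per-cycle doses are constant across cycles), VOI delineation
error on masses, camera calibration drift, or any image physics.
Passing recovery tests therefore demonstrate correctness of the
estimation chain under the stated noise model, not clinical accuracy
on real images.

## The misregistration phantom

`phantom_grid()` builds an ellipsoidal hot organ (default semi-axes
25×15×35 mm, activity 100 vs background 5) on a 2 mm grid, blurred by
an isotropic Gaussian of 10 mm FWHM approximating SPECT resolution;
attenuation-correction physics is deliberately reduced to this
VOI-displacement proxy. `misreg_recovery_error()` translates either
the anatomical VOI (`fixed_voi`, manual CT-based delineation) or the
activity map under a SPECT-threshold VOI (`threshold_voi`, default 42%
of maximum) axially by 2–20 mm. Errors are reported against the
zero-shift recovery of the same method — the "inherently aligned"
reference — so zero shift gives exactly zero error even with blur.
Within this proxy the threshold VOI follows the activity and is
essentially shift-invariant; on real data small residual errors remain
(attenuation mismatch), so the package asserts only the qualitative
ordering: fixed-VOI error grows with the shift and the threshold VOI
is at least as accurate from 6 mm on. Shifts must be integer voxel
multiples; sub-voxel interpolation is out of scope.

## Numerical choices and degenerate inputs

* Optimizer: Levenberg–Marquardt, 500 iterations, log-linear start;
  grid-search-verified to ~10⁻³ relative in tests.
* Exactness tolerances: two-point fits reproduce inputs to 10⁻¹⁰
  relative; noiseless recovery and closed-form-vs-quadrature residence
  times to 10⁻⁶; dose components sum to their total exactly.
* Missing cross-dose factors contribute zero with a classed warning;
  missing *self* factors or VOI masses are configuration errors.
* Decisions use strict `>` at thresholds; ties continue treatment.
* Zero tumor residence time yields zero dose; a zero pair mean is a
  domain error in Bland–Altman.

## Problem sizes

Stochastic checks in the test and acceptance suites use: 200 patients
for the 5% noise kidney-dose recovery study (mean signed relative
error asserted within ±2%, median absolute error below 10%), 15 seeded
24-patient cohorts per arm for the concordance-ordering property
(6% versus 50% perturbation), and the default 40×40×60 phantom for the
misregistration sweep. These sizes are the package's choice of a
desk-scale experiment: large enough for the asserted contrasts, small
enough to run routinely.

## Known limitations

Marrow dosimetry inherits the two-point blood fit: with close time
points (18 h, 25 h) the decay constant is noisy, occasionally
sub-physical (warned) or non-decaying (a hard error that callers of
`run_course()` should expect at realistic noise), and the integral to
infinity will underestimate cumulated activity when clearance slows at
late times. The dose engine assumes the mass-scaling convention above;
other conventions (e.g. scaling cross-terms by phantom mass ratios)
exist. No biologically effective dose, voxel-level dosimetry, or
uncertainty propagation is attempted.
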