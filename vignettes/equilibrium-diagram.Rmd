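---
title: "Equilibrium-diagram analysis of sympathetic baroreflex pressure control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium-diagram analysis of sympathetic baroreflex pressure control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroloop)
```

## The model

The sympathetic arterial baroreflex is a negative-feedback loop that
buffers arterial pressure (AP) against disturbances such as standing
up. `baroloop` analyzes its *static* behaviour by splitting the loop
into two halves that share the same two variables and can therefore be
superimposed on one plane:

* the **mechanoneural (MN) arc** — the controller. Baroreceptors sense
  AP and the vasomotor center adjusts sympathetic outflow, read out as
  plasma norepinephrine (PNE, a surrogate for sympathetic nerve
  activity). Near the operating point it is modelled as a rectified
  line,
  \[ PNE = \max\{\mathrm{floor},\; G_{MN}\,(AP_{MN,0} - AP)\}, \]
  with gain \(G_{MN}\) (pg·ml\(^{-1}\)·mmHg\(^{-1}\)) and AP-axis
  intercept \(AP_{MN,0}\) (mmHg), which approximates the set point:
  above it the sympathetic limb is silent.

* the **neuromechanical (NM) arc** — the plant. Sympathetic outflow
  drives vasoconstriction and cardiac performance, generating pressure
  \[ AP = G_{NM}(\varphi)\,PNE + AP_{NM,0}(\varphi), \]
  where both the gain \(G_{NM}\) (mmHg·ml·pg\(^{-1}\)) and the null-PNE
  offset \(AP_{NM,0}\) depend on the tilt angle \(\varphi\): head-up
  tilt drains preload and both flattens and lowers the plant line.

The closed-loop **operating point** is the intersection of the two
curves (`solve_operating_point()`); for linear arcs it has the closed
form
\[ AP^* = \frac{G_L\,AP_{MN,0} + AP_{NM,0}}{1+G_L}, \qquad
   PNE^* = G_{MN}(AP_{MN,0}-AP^*), \qquad G_L = G_{MN}G_{NM}, \]
a convex combination of the two intercepts with weight
\(G_L/(1+G_L)\) on the set point. \(G_L\) is the **open-loop gain**:
an external disturbance that would move AP by \(\Delta\) with the
reflex disabled only moves the closed loop by \(\Delta/(1+G_L)\)
(`attenuation_factor()`, inverted by `gain_from_attenuation()`).

`tilt_disturbance_report()` decomposes a postural disturbance
accordingly: the closed-loop AP fall between two operating points, the
open-loop fall obtained by freezing PNE at its pre-tilt value and
dropping vertically onto the post-tilt NM line, their ratio, and the
loop gain implied by that ratio. Because tilt flattens the NM line as
well as shifting it, the implied gain *underestimates* the supine
\(G_L\); `parallel_shift_counterfactual()` quantifies this by rebuilding
the post-tilt line with the supine slope through the open-loop point,
for which the implied gain equals \(G_{MN}G_{NM}(0)\) as an exact
algebraic identity.

```{r fig3}
mn <- mn_arc(g_mn = 8.92, ap_mn0 = 103)
nm0 <- nm_arc(g_nm = 0.61, ap_nm0 = 34.1, angle_deg = 0)
nm15 <- nm_arc(g_nm = 0.36, ap_nm0 = 33.4, angle_deg = 15)
tilt_disturbance_report(mn, nm0, nm15)
parallel_shift_counterfactual(mn, nm0, nm15)$closed_loop_delta_ap
```

## The estimation pipeline

The parameters above are identifiable in humans without opening the
loop surgically, from a tilt protocol under vagal blockade:

1. **MN arc** (`fit_mn_arc()`): the baseline operating points measured
   at several tilt angles all lie on the MN line (tilt moves only the
   plant), so an ordinary least-squares regression of PNE on AP across
   the angles recovers \(-G_{MN}\) as its slope and \(AP_{MN,0}\) as
   its AP-axis intercept. Plain unweighted OLS of PNE on AP is used —
   not orthogonal or inverse regression — because the gain is defined
   as the slope with respect to the AP axis; the Pearson correlation
   of the points is reported as the fit diagnostic.
2. **NM arc** (`fit_nm_arc()`): ganglionic blockade abolishes the
   sympathetic response, so the measured point drops onto the NM line
   at the non-neural PNE residual. The line through the baseline and
   blockade points at the same angle identifies \(G_{NM}\) and
   \(AP_{NM,0}\) at 0° and 15°.
3. **Loop gain**: per subject, \(G_L(0)=G_{MN}G_{NM}(0)\) and
   \(G_L(15)=G_{MN}G_{NM}(15)\) as exact products.

`summarize_group()` reports each parameter as mean ± SD with the
sample (n−1) denominator — recorded in the output metadata because at
n = 7 the choice is material — and compares supine versus tilted NM
gain and loop gain with `wilcoxon_signed_rank_exact()`. Two
conventions deserve emphasis:

* the **group loop gain is the mean of per-subject products**, not the
  product of group means; the two differ whenever the arc gains covary
  across subjects, and the product of means is reported alongside as a
  diagnostic (`g_l_product_of_means`).
* the signed-rank test enumerates all \(2^n\) sign assignments for
  n ≤ 20 (zeros dropped, mid-ranks for ties), so its two-sided p-value
  is exact at small n — with seven pairs the most extreme achievable p
  is \(2/128 = 0.015625\). Beyond n = 20 a tie-corrected normal
  approximation is used.

Subjects whose estimation fails (too few angles, a missing blockade
row, a non-negative MN slope) are reported with their reasons, and an
anomalous negative NM gain is flagged rather than clamped, so group
summaries can exclude flagged subjects explicitly
(`exclude_flagged = TRUE`).

## The synthetic study generator

`simulate_study()` generates cohorts with the structure of the tilt +
ganglionic-blockade protocol so the whole pipeline is testable
end-to-end: baseline rows at −7°, 0°, 15° and 60° are closed-loop
operating points; blockade rows at 0° and 15° sit on the NM line at a
constant non-neural PNE residual (blockade PNE does not respond to
angle; the residual's default mean of 45 pg·ml\(^{-1}\) matches the
supine/tilted blockade levels of roughly 47 and 40, whose small
decline is treated as noise, not structure).

Choices a user should know about:

* **Population model** (`draw_population()`): per-subject truths are
  independent truncated-normal draws (truncated at zero for gains and
  the residual) around configurable means and SDs; the defaults are
  representative group values for healthy young men under vagal
  blockade (\(G_{MN}\) 8.92 ± 3.07, \(AP_{MN,0}\) 103.0 ± 9.5,
  \(G_{NM}(0)\) 0.61 ± 0.08, \(AP_{NM,0}(0)\) 34.1 ± 4.9,
  \(G_{NM}(15)\) 0.36 ± 0.05, \(AP_{NM,0}(15)\) 33.4 ± 8.6). Draws are
  independent across parameters because no between-parameter
  covariance is available — which is exactly why the generator does
  not target the group mean-of-products loop gain, only the
  parameter means themselves.
* **Angle dependence** (`nm_params_at_angle()`): between and beyond
  the two measured anchors the NM gain interpolates log-linearly in
  \(\sin\varphi\) (guaranteeing positivity out to 60°) and the offset
  linearly in \(\sin\varphi\), the natural scale for a hydrostatic
  disturbance. This is a generator assumption, not an estimated
  relationship; the anchors at 0° and 15° are reproduced exactly, and
  angles outside [−7°, 60°] are refused.
* **Noise model**: additive Gaussian measurement noise on AP (default
  SD 2 mmHg) and multiplicative unit-mean lognormal noise on PNE
  (default CV 8%, since assay error is proportional); both zeroable.
  Heart rate is a plausible passthrough column, never used downstream.
* **Reproducibility**: one integer seed controls the whole study;
  per-subject substreams are derived deterministically from it, so a
  fixed configuration is byte-identical across runs.
* The configured angles must include 0 and 15 (beyond being distinct),
  because the blockade protocol and the NM fits anchor there.

What passing tests on these cohorts do *not* show about real data: the
generator's subjects obey the linear-arc model exactly, with
uncorrelated parameters, symmetric noise and no drift, repositioning
artifacts, or assay censoring. Recovery results on synthetic cohorts
are therefore a check of the pipeline's correctness and noise
propagation, not a validation of the physiological model itself.

## Numerical choices

* The closed-form operating point is exact; the bisection solver
  (`solve_operating_point_numeric()`) brackets the fixed-point
  residual to |r| ≤ 1e−9 mmHg and exists both as the independent
  cross-check of the closed form (they agree to ≤ 1e−6 mmHg over
  randomized parameter grids in the test suite) and as the route for
  user-supplied monotone nonlinear arcs, e.g. sigmoidal controllers.
  Monotonicity of supplied curves is the caller's responsibility.
* When the unconstrained intersection would command PNE below the
  sympathetic floor, the operating point is placed on the NM line at
  the floor and flagged `boundary = TRUE`: the loop cannot command
  negative norepinephrine. Whether "silence" above the set point means
  zero PNE or a non-neural residual is configurable via `pne_floor`
  (default 0).
* A disturbance whose open-loop AP change is below the 1e−9 mmHg
  solver tolerance has no defined attenuation ratio and is refused
  (`baroloop_undefined_ratio`), rather than returning a 0/0.
* Stored outputs (tables, JSON reports) keep full double precision;
  rounding happens only in print methods. Study tables are written
  with 17 significant digits so write-then-read round-trips are
  lossless.

A worked decomposition from the default parameters, for orientation:
the closed-loop supine → 15° fall computes to ≈ 5.83 mmHg against an
open-loop fall of ≈ 24.55 mmHg (attenuation ≈ 0.237, implied gain
≈ 3.21, i.e. 6, 24, 1/4 and 3 at whole-number precision — quantities
this package reports unrounded), and the parallel-shift counterfactual
fall is ≈ 3.81 mmHg with implied gain exactly 8.92 × 0.61 = 5.4412.

## Problem sizes and calibration in the test suite

The suite checks recovery at the study's own scale: seven-subject
cohorts, four baseline angles, one row per condition and angle.
Cohort-level recovery under the default measurement noise is measured
over 200 replicate studies (population SDs zero so the truth is the
configured means): the median relative error of the group-mean
\(G_{MN}\) and of the group \(G_L(0)\) must stay under 10% and 15%.
The bound is placed on the cohort-level estimate — the quantity the
pipeline actually reports for a study — because single-subject
estimates at these noise levels are intrinsically noisier: an 8% assay
CV on PNE levels near 95 and 45 pg·ml\(^{-1}\) alone puts roughly 17%
noise on the PNE difference entering a subject's two-point NM fit.
Noise-versus-error monotonicity is checked on single-subject cohorts
across a fourfold noise range.

## Limitations

* Static equilibria only: no beat-to-beat dynamics, no time courses of
  tilt or blockade onset.
* Linear arcs in the operating range; full sigmoidal arc estimation is
  not implemented (the numeric solver merely accepts such curves).
* PNE is treated as a direct surrogate for sympathetic activity;
  spillover and clearance kinetics are outside the model, so
  between-subject comparisons of single-arc gains should be made
  cautiously — the dimensionless loop gain is the robust quantity.
* The blockade measurement at 15° is assumed to lie on the same NM
  line as the baseline point at 15°, as the two-point fit requires.
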