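---
title: "Quantifying contrast-enhanced ultrasound perfusion with the %CDA integral statistic"
author: "ceuskinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contrast-enhanced ultrasound perfusion with the %CDA integral statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceuskinetics)
```

## The problem and the measurement

Adnexal masses (ovary, fallopian tube) that remain indeterminate on standard
ultrasound criteria pose a triage problem: malignant lesions recruit dense,
structurally abnormal microvasculature, and that vasculature changes how an
intravenous microbubble contrast bolus washes in and out of the lesion.
Contrast-enhanced ultrasonography (CEUS) observes this directly: after a
bolus, the colour-Doppler overlay lights up the perfused fraction of a fixed
tumour cross-section.

The quantity this package works with is the **fractional colour-Doppler
area**,

$$F_{\%CDA}(t) = 100 \cdot \frac{|\text{colour pixels} \cap \text{ROI}|}{|\text{ROI}|},$$

the percentage of region-of-interest (ROI) pixels carrying colour signal in
the frame at time $t$. Plotted against time it forms a three-phase
**time-intensity curve** (TIC): a pre-contrast baseline, a rapid wash-in to a
peak, and a slower wash-out back toward baseline.

Two design choices in the imaging stage deserve a word:

* **Colour segmentation.** A pixel is called "colour" when its channel
  spread, $\max(R,G,B) - \min(R,G,B)$, exceeds a chroma threshold (default
  10 on a 0–255 scale). Greyscale speckle has zero spread at any brightness,
  so the rule separates the overlay from the background deterministically
  and without access to a scanner's colour map. The threshold is exposed
  (`chroma_threshold`) because clinical overlays vary.
* **Fixed ROI, no motion compensation.** The denominator is the ROI pixel
  count, not the whole image, and the same mask is applied to every frame:
  the acquisition protocol holds one cross-section of the solid tumour
  component throughout the exam, using anatomical landmarks. Tracking would
  add machinery the protocol does not require.

## Curve parameters and the integral statistic S

From a TIC, `extract_features()` computes the descriptive parameter set:

| symbol | meaning | estimator |
|---|---|---|
| $Y_{start}$ | baseline %CDA | mean over the pre-contrast window $[0, T_{kts}]$ |
| $T_{kts}$ | contrast-administration time | supplied by the protocol (default 10 s: the bolus is injected over 10 s) |
| $T_{max}, Y_{max}$ | peak coordinates | maximum of the sampled values, first index on ties |
| $\delta$ | relative enhancement $Y_{max}/Y_{start}$ | undefined (NA) when $Y_{start}=0$; never infinity |
| $T_{end}, Y_{end}$ | last sample | — |
| $T_{sp}$ | wash-out duration $T_{end}-T_{max}$ | — |
| $D$ | falling speed $(Y_{end}-Y_{max})/T_{sp}$, %/s | NA when $T_{sp}=0$ with $Y_{end} \ne Y_{max}$ |
| $S$ | $\int_0^{T^*} F_{\%CDA}(t)\,dt$ | trapezoid rule, reported in units of $10^3$ %CDA·s |

The headline statistic is the integral $S$: it summarises the whole
enhancement history and is insensitive to any single noisy sample. Because
integrals are only comparable over a common window, the upper limit $T^*$
must be shared by every curve in an analysis; `choose_t_star()` takes the
largest limit that avoids extrapolating any exam — the minimum of the last
sample times.

Numerical choices, stated once:

* **Trapezoid integration**, exact for piecewise-linear curves sampled at
  their breakpoints; $T^*$ between samples is handled by linear
  interpolation, and $T^*$ beyond the support is an error, never an
  extrapolation.
* **Baseline as a window mean** rather than the single $t=0$ sample: robust
  to measurement noise, and identical to the plateau value on noise-free
  curves.
* **First-maximum tie-break** for $T_{max}$: determinism.
* **Optional pre-peak smoothing** (`smooth_window`, a centred moving
  average) exists because clinical software typically smooths TICs before
  peak-picking, but it defaults to off: the smoothing used by the original
  acquisition software is unknown, and the integral never uses smoothed
  values.

### The scale of S

$S$ is reported in units of $10^3$ %CDA·seconds throughout the package: the
group summaries the synthetic cohort reproduces (means of 80.5 and 25.0),
the decision thresholds 30 and 90 and a cohort median near 47 are all
commensurable only on that scale. The scale has a consequence worth being
explicit about: with $F_{\%CDA} \le 100\%$, an integral of $80.5 \times 10^3$
%CDA·s requires acquisition windows of thousands of seconds. The synthetic
world therefore realises exam durations on that order
(`kinetics_from_record()` solves the wash-out duration from the target
$S$). Real bolus transits are minutes, so these durations should be read as
a unit convention of the summary scale, not as physiology; nothing in the
feature extraction or statistics depends on the absolute time scale.

## The synthetic world

No patient data ship with the package. The generator (`cohort_spec()`,
`generate_cohort()`) states a world with exactly the structure the analysis
assumes, so every downstream stage is testable:

* **Group kinetics.** 33 malignant and 18 benign records by default. Each
  kinetic summary ($Y_{start}$, $Y_{max}$, $S$) is drawn from a
  distribution whose mean and SD equal the published group moments —
  malignant $Y_{start}$ 10.91 (8.39), $Y_{max}$ 31.30 (16.91), $S$ 80.5
  (50.6); benign 4.27 (5.30), 11.29 (8.78), 25.00 (22.67).
* **Sampling family.** A truncated normal on the admissible range
  ($[0,100]$ for percentages, $[0,\infty)$ for $S$) whose *truncated*
  moments match the targets, solved numerically from the closed-form
  truncated-normal moments. Matching the truncated rather than the parent
  moments matters: naive truncation of N(31.30, 16.91²) at zero shifts the
  mean to ≈ 32.6, which a 10,000-draw recovery check at 3 standard errors
  would correctly flag. One marginal is infeasible for this family: benign
  $Y_{start}$ has CV = 124%, while no truncated normal on a half-line can
  exceed CV = 100% (the limit as the location goes to $-\infty$). That
  marginal falls back to a moment-matched gamma
  ($\text{shape} = (m/s)^2$), which matches both moments exactly on
  $[0,\infty)$.
* **Markers.** CD34 and CD105 expression scores are log-normal with a
  higher location in the malignant group (angiogenic tumours carry more
  microvessels and more proliferating endothelium); bcl-2 staining
  intensity is categorical on 0–3 with probabilities (17, 11, 8, 5)/41,
  the marginal distribution of the published association table. All marker
  draws are **independent of the kinetic draws**: the stated world encodes
  the published null association between perfusion and
  immunohistochemistry, and the association stage must find nothing.
* **Marginals, not joints.** The published summary constrains each
  parameter's marginal moments only, so the generator draws $Y_{start}$,
  $Y_{max}$ and $S$ independently within a group. Individual records can
  therefore combine, say, a small $Y_{max}$ with a large $S$ — there is no
  record-level coherence between peak and integral beyond what the group
  separation induces. When a record is realised as a full curve, an
  ordering violation ($Y_{start} > Y_{max}$, ~14% of malignant draws) is
  resolved by using $\min(Y_{start}, Y_{max})$ as the curve baseline — and,
  where that leaves the baseline within 5% of the peak (no wash-in phase to
  speak of), the rendered baseline is set to 80% of the peak; the record
  keeps its drawn values either way. A record whose drawn $S$ is smaller
  than the minimal area of any valid three-phase curve at its baseline
  (about 0.1% of draws) cannot be realised and raises an error rather than
  silently distorting the drawn summaries.
* **Exam realisation.** `kinetics_from_record()` fixes $T_{kts} = 10$ s and
  a 20 s wash-in (shrunk only if the target $S$ is tiny), then solves the
  wash-out duration and final value so that the trapezoid integral on a
  1 frame/s grid hits $1000 \cdot s$ exactly, with the wash-out constrained
  to be slower than the wash-in. `render_frames()` turns a curve into
  frames whose ROI colour fraction matches each requested value to within
  one-pixel quantisation ($100/|\mathrm{ROI}|$ percentage points), with
  colour grown outward from a few seed points so it stays vessel-like.

What the generator does **not** emulate: speckle statistics, attenuation,
transducer geometry, microbubble pharmacokinetics, probe or patient motion,
real Doppler colour maps, operator variability in ROI placement, or any
correlation between markers and kinetics. A green pipeline test therefore
establishes that the *computations* are correct on data with the assumed
statistical structure — not that the thresholds would transfer to any
clinical population.

## The statistical layer

Group comparisons use the statistics appropriate to unequal variances and
small unbalanced groups:

* **Cochran–Cox approximate test** for the difference of means under
  unequal variances (the Behrens–Fisher situation):
  $C = (\bar x_1 - \bar x_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ compared against
  the variance-weighted critical value
  $C_{kr} = (w_1 t_1 + w_2 t_2)/(w_1 + w_2)$, $w_i = s_i^2/n_i$, with
  $t_i$ the per-group two-sided t critical values on $n_i - 1$ df. The
  procedure defines a critical value, not a p-value; the p-value reported
  here is the $\alpha$ at which $C_{kr}(\alpha) = |C|$, found by root
  inversion, so `p_value < alpha` and `|statistic| > critical_value` are
  the same decision by construction. The weighted critical value is known
  to be **conservative in small samples** (at $n_1 = n_2 = 10$ the
  empirical size under the null is ≈ 3.6% at nominal 5%, because the
  combined critical value is the 9-df t quantile where a pooled test would
  use ≈ 18 df); the test suite checks the nominal 5% ± 1% size at
  $n = 30$ per group and conservatism at $n = 10$. This is a property of
  the method, accepted deliberately — it reproduces the published critical
  value $C_{kr} = 2.06$ exactly from the published group sizes.
* **Mann–Whitney U, normal form.** U from midranks; the reported statistic
  is the tie-corrected normal deviate $z$ with **no continuity
  correction**, compared against the standard-normal two-sided quantile
  (1.96 at 5%). On samples of ≤ 8 per group the z decision agrees with the
  exact permutation test in ≥ 95% of random instances (tested), which is
  the regime the method is used in here.
* **Chi-square independence** with expected counts from the product of
  margins, **no Yates correction**, df $=(r-1)(c-1)$ — on the published
  4×2 bcl-2 table this yields $\chi^2 = 2.80$ against the df = 3 critical
  value 7.81.
* **Pearson correlation** by the direct product-moment formula, with the
  two-sided t test on $n-2$ df for significance (`marker_s_correlation()`).

All tests are two-sided at $\alpha = 0.05$ by default, configurable per
call. No multiple-testing correction is applied anywhere — the analysis
scheme being reproduced applies none.

## Median dichotomisation and the bcl-2 table

`median_split()` uses the standard midpoint sample median with the low side
closed: a value equal to the median is "at or below". One subtlety surfaced
while validating against the published reference table: with an odd number
of distinct values, a closed-low median rule necessarily puts at least
$\lceil n/2 \rceil$ observations on the low side, so a 41-patient table with
a (20, 21) column split cannot arise from this rule applied to raw values.
The reference table is therefore treated as printed data (`table2_fixture()`)
— the chi-square reproduction runs on it directly — while `build_bcl2_table()`
applies the stated rule to cohorts the package generates. Records with an
undefined S (e.g. failed curve acquisition, via the `excluded` flag or an
`NA`) are dropped and counted, never imputed; no exclusion rule is invented.

## The S-band classifier

`classify_s()` is a transparent three-band rule, not a fitted model:
$s \le 30$ → likely-benign, $s > 90$ → likely-malignant, otherwise
indeterminate. The boundary orientations are exactly as stated by the
source bands (closed at 30, open at 90); the published cohort median 46.9
falls in the indeterminate band, as it should. Under the default synthetic
world the ≤ 30 band is benign-dominated (the benign S distribution puts
≈ 60% of its mass there against ≈ 13% for malignant), which the tests
check against independently simulated tail masses. The cuts are parameters
(`s_band_rule()`), not constants, because they are scale-bound to the S
convention above.

## Degenerate inputs, stated behaviour

* Flat curve ($Y_{start}=Y_{max}=Y_{end}$): valid; $\delta = 1$, $D = 0$.
* Zero baseline: $\delta$ is NA, never `Inf`; downstream consumers must
  handle the flag.
* All observations identical in both samples: Mann–Whitney $z = 0$, p = 1.
* Zero margin in a contingency table, empty ROI, non-increasing times,
  $T^*$ beyond support, negative S: errors, not warnings.
* `kinetics_from_record()` refuses a target S smaller than the minimal
  area of a valid three-phase curve at the drawn baseline rather than
  silently distorting the shape.

## Limitations

The package quantifies and tests; it does not diagnose. The synthetic
cohort inherits every simplification listed above, most importantly the
marginal-only calibration and the idealised colour overlay; the S-band
thresholds are reproduced, not validated; and the imaging stage assumes the
overlay/background separation that the synthetic renderer guarantees —
clinical frame data would need a scanner-specific segmentation rule before
the rest of the pipeline applies unchanged.
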