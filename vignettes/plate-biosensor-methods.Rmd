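---
title: "Quantifying biosensor signals from arrayed colonies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biosensor signals from arrayed colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platesensor)
library(tibble)
library(dplyr)
```

## The measurement problem

Phenotypic screens of microbial strain libraries are routinely run as arrayed
colonies pinned onto rectangular single-well agar plates. Because the pinning
robot places colonies on the ANSI/SLAS 96- or 384-well footprint, each colony
sits exactly where a well of a conventional microplate would sit, and a
monochromator-equipped microplate reader can read each colony individually as
if it were a well — at freely chosen excitation and emission wavelengths.
That removes the fixed-filter constraint of camera-based colony imaging and
makes ratiometric fluorescent reporter proteins usable on agar: sensors such
as the pH probe mCherryEA (excitation maxima 454 and 580 nm, emission 630 nm)
and the redox probe Mrx1-roGFP2 (excitation 380 and 470 nm, emission 510 nm)
encode the physiological state in the *ratio* of two excitation channels, so
the readout cancels colony size and expression level.

`platesensor` implements the full analysis chain for such measurements:

1. a canonical long-format data model for plate-reader exports and plate
   layouts (`plate_grid()`, `read_plate_csv()`, `apply_layout()`);
2. ratiometric signal computation and excitation-scan peak detection
   (`biosensor_ratio()`, `plate_ratios()`, `find_excitation_peaks()`);
3. oxidation-degree and pH calibration (`oxidation_degree()`,
   `oxd_from_ratios()`, `fit_ph_calibration()`, `ratio_to_ph()`,
   `colony_map()`);
4. screening statistics (`fit_hill()`, `fold_change()`, `one_way_anova()`,
   `tukey_hsd()`, size/OD normalization);
5. kinetic treatment-response analysis (`classify_redox_response()`,
   `time_to_steady()`);
6. colony-image quantification (`segment_colony_grid()`,
   `region_perimeter()`, `relative_sizes()`, `centering_offset()`);
7. a synthetic generator for all of the above, so every stage is testable
   without access to raw instrument data.

## Oxidation degree of a two-state redox sensor

roGFP2-type sensors interconvert between a reduced (dithiol) and an oxidized
(disulfide) state with different excitation spectra. Writing
$I380_s, I470_s$ for the sample intensities and $I380_{red}, I470_{red}$,
$I380_{ox}, I470_{ox}$ for fully reduced (DTT-treated) and fully oxidized
(NaOCl-treated) controls, the oxidation degree is

$$
OxD \;=\;
\frac{I380_s\, I470_{red} - I380_{red}\, I470_s}
     {I380_s\, I470_{red} - I380_s\, I470_{ox}
      + I380_{ox}\, I470_s - I380_{red}\, I470_s}.
$$

`oxidation_degree()` implements this exactly (the denominator is evaluated in
the grouped form $I380_s(I470_{red}-I470_{ox}) + I470_s(I380_{ox}-I380_{red})$,
which avoids catastrophic cancellation between large products). The
algebraically equivalent ratio form, exposed as `oxd_from_ratios()`, is

$$
OxD = \frac{R - R_{red}}{(R - R_{red}) + \alpha\,(R_{ox} - R)},
\qquad \alpha = \frac{I470_{ox}}{I470_{red}},
$$

with $R = I380_s/I470_s$. Two properties follow and are enforced by tests:
$OxD$ is 0 at the reduced control and 1 at the oxidized control, and it is
invariant to a common rescaling of the sample's two intensities (brightness
independence — the reason a ratiometric sensor works on colonies of any
size). $\alpha$ is an instrument/sensor property that must be estimated from
control colonies; because it is a ratio of *pooled mean intensities* of two
different sets of colonies, its error scales with control replication, not
with per-read noise. The bundled experiments use 12 reduced and 12 oxidized
control colonies; with only 4 + 4 controls of realistic brightness spread
(±12%), the $\alpha$ error alone can bias $OxD$ by ~0.04.

`oxidation_degree()` returns the value **unclamped**, with an `in_range`
flag. Noise legitimately pushes samples slightly outside $[0, 1]$; clamping
silently would destroy exactly the QC signal (miscalibrated controls, bad
wells) that the flag carries. Clamping is an opt-in reporting mode
(`plate_oxd(clamp = TRUE)`).

## Ratio-to-pH calibration

Over the physiological range pH 7.0–8.5, the 454/580 excitation ratio of
mCherryEA responds linearly to internal pH, so calibration is ordinary least
squares of ratio on pH (`fit_ph_calibration()`), fitted to in-colony
standards: colonies permeabilized with CTAB under buffers of known pH
(`role = "ph_standard"` in the layout). Inverse prediction
(`ratio_to_ph()`) is $pH = (ratio - intercept)/slope$, with an explicit
extrapolation flag outside the calibrated domain. We deliberately do not fit
an errors-in-variables model or a full pKa titration curve: the response is
linear in the calibrated regime, the standards' pH is set by the buffer (low
error), and a two-parameter line keeps the inversion exact and testable.
Per-colony pH is computed colony-by-colony and then summarized; summaries use
min/max spans (`range = max - min`) because the per-plate *span* of
recovered pH is the natural precision comparison between two measurement
methods at equal mean.

Ratio orientation (numerator channel first: 454/580 for pH, 380/470 for
redox) is mandatory metadata on every ratio, never inferred from the data —
a silent orientation swap is the classic failure mode of ratiometric
analyses.

## Screening statistics

Single-fluorophore reporters must be normalized to a growth proxy:
`normalize_to_od()` (liquid, OD600) or `normalize_to_size()` (agar, colony
perimeter in pixels). Dose–response curves of inducible
transcription-factor-based sensors are fitted with the Hill function
$F(c) = F_0 + F_{max}\, c^n/(K^n + c^n)$ by bounded Levenberg–Marquardt
(`fit_hill()`; dose 0 contributes exactly $F_0$ — no pseudo-dose), with
data-driven initialization and bounds $F_0, F_{max} \ge 0$,
$K \in [\min(c_{>0})/10,\; 10\max(c)]$, $n \in (0, 6]$. Reporter-free
strains are fitted with a line (`fit_linear()`). Group separability uses
classical one-way ANOVA followed by Tukey's HSD (Tukey–Kramer for unbalanced
groups) at the 0.05 threshold; significance tiers are labeled `n.s.`
(p > 0.05), `*` (p ≤ 0.001), and an explicit intermediate tier for
0.001 < p ≤ 0.05. Fold changes are ratios of group means with first-order
error propagation,
$sd_{fold} = fold \cdot \sqrt{(sd_g/\bar g)^2 + (sd_r/\bar r)^2}$ — whether a
published "±" on a fold is a propagated sd or an sd of per-colony folds is
usually unstated; we implement propagation and document it.

Degenerate inputs are resolved explicitly rather than left to downstream
`NaN`s: zero within-group variance yields $F = 0, p = 1$ when the group means
are equal and an `infinite_f` flag otherwise.

## Kinetic treatment responses

Applying a drop of reductant (DTT), oxidant (NaOCl), or plain buffer to a
colony and monitoring the biosensor ratio in real time gives a kinetic trace
(`kinetic_trace()`). The generator models the state fraction as holding at
`oxd_pre` before treatment and relaxing exponentially to `oxd_post` with
time constant τ afterwards; buffer-only drops are emulated with a transient
pulse that decays back to baseline. Classification
(`classify_redox_response()`) compares the pre-treatment mean ratio with the
post-treatment steady mean: `reduced` / `oxidized` when the change exceeds
`delta_threshold` (default 0.1 ratio units — above buffer-drop transients,
below the smallest genuine redox response of this sensor, ≈ 0.14), otherwise
`unchanged`.

`time_to_steady()` reports the earliest post-treatment time from which the
trace stays within a band around its final value (the mean over the last 20%
of post-treatment samples) for at least `min_dwell_s`. The band is
**relative** by default: `band = 0.02` means 2% of the response amplitude
$|\text{final} - \text{pre}|$. A scale-free band treats a shallow and a deep
response identically — for a pure exponential the steady time is
$\tau\,\ln(1/0.02) \approx 3.9\,\tau$ regardless of amplitude, so with
realistic sampling both reducing and oxidizing treatments stabilize at 4–6 τ,
matching the few-minute stabilization seen on colonies. An absolute band in
ratio units is available (`band_mode = "absolute"`) and is more useful when
comparing traces against a fixed instrument noise floor. A trace that never
stabilizes (e.g. monotone drift) is *flagged*, not raised, and classification
then falls back to the final 20% of post-treatment points. Traces are never
smoothed implicitly; replicate averaging is a separate explicit step
(`average_traces()`).

## Colony images

The imaging component is intentionally a minimal, fully specified pipeline —
global Otsu threshold, 8-connected components, nearest-well-center assignment
on the format's pitch grid (at most one region per well, largest kept) — so
every step has an exact oracle. It makes no attempt to reproduce any
particular external segmentation toolchain pixel-for-pixel. Perimeter is the
4-connectivity boundary-edge count: exactly 4 for a single pixel, $4n$ for an
$n \times n$ square, and $\approx 8r = 2\pi r \cdot (4/\pi)$ on a digital
disk of radius $r$ — the ~27% digitization bias relative to the Euclidean
circumference is documented and consistent across colonies, so it cancels in
relative comparisons and in RFLU normalization. Images whose foreground is
more than 30% unassignable to wells raise a grid-misalignment error.
`centering_offset()` implements the in-well absorbance raster check (default
30 × 30): background (median) subtracted intensity-weighted centroid minus
scan center, with a configurable centered tolerance of 3 scan units.

## The synthetic generator and its noise model

The generator exists so that every downstream stage can be validated against
known truth. It emulates: two-state linear-mixture photophysics for the redox
sensor (so the OxD equation is the exact inverse of the simulation — default
pure-state intensities give $R_{red} = 0.53$, $R_{ox} = 1.4$, $\alpha =
0.7$); a ratio-linear-in-pH response anchored at (pH 7.0, ratio 0.85) and
(pH 8.5, ratio 1.35); Hill dose–responses at three expression strengths
(defaults $F_0 = 4.96 \times 10^3$, $F_{max} = 1.63 \times 10^4$ /
$1.93 \times 10^5$ RFLU, $K = 0.1$ mM, $n = 1.5$ — the endpoint group means
are anchored to published plate-reader values, but no fitted Hill parameters
are published, so $K$ and $n$ are generator defaults only); exponential
kinetic relaxation; geometric colony-size loss (default 10% per dilution
step) with channel intensities linear in area; Gaussian excitation bands
(σ = 18 nm) for scan synthesis; and disk colonies on the pitch grid for
images.

Noise has two multiplicative Gaussian components plus additive background
(`noise_model()`):

* `cv` (default 0.05) — **per-colony, common-mode**: one factor per colony
  (per timepoint in kinetic mode) applied to both channels. It models biomass
  and expression variability and *cancels in the ratio*, which is precisely
  the point of ratiometric sensing.
* `channel_cv` (default 0.005) — **per-reading, independent**: monochromator
  and photomultiplier noise of each individual read. This is what limits
  ratio precision: the ratio noise CV is $\sqrt{2} \cdot channel\_cv \approx
  0.7\%$ at defaults, consistent with published per-colony ratio spreads of
  ~1% while absolute intensities vary by tens of percent.

Identical seed and configuration give byte-identical CSV output; seeds are
explicit arguments with documented defaults.

What the generator does **not** emulate — and hence what passing tests do not
demonstrate about real data: photobleaching, inner-filter effects, spatial
agar gradients and uneven illumination, colony-to-colony optical cross-talk,
non-Gaussian outliers (bubbles, satellite colonies), pKa curvature of the pH
sensor outside the linear regime, and instrument-specific spectral
sensitivity differences (calibrations are instrument-specific; curves from
different instruments must not be mixed).

## Problem sizes and numerical choices

The bundled validation experiments use desk-scale sizes chosen to keep the
whole suite fast while leaving comfortable statistical margins: 120 sample
colonies (+ standards/controls) on a 384-footprint plate for pH and redox
recovery, 11 doses × 4 replicates for Hill recovery, 5-spot dilution series,
25-minute kinetic traces sampled every 20 s with treatment at 5 min, and
480 × 320 px plate images. Background subtraction is **off** by default
(endpoint analyses are reported without it); when enabled, subtracted
intensities must stay positive or the well is flagged. Peak detection uses a
3-point moving average and windowed argmax with ties broken toward the lower
wavelength — deterministic and oracle-checkable. Tukey p values come from R's
studentized-range distribution (`ptukey`).

## Known limitations

* The pH calibration is linear-only; outside pH 7.0–8.5 predictions are
  flagged extrapolations, not reliable values.
* $OxD$ accuracy is limited by control replication (via $\alpha$) before it
  is limited by per-read noise; plates with very few control colonies will
  show systematic, not random, OxD error.
* The perimeter estimator's $4/\pi$ digitization bias makes absolute
  perimeter values estimator-specific; use them for normalization and
  relative comparison, not as physical lengths.
* Single-plate scope: multi-plate batch correction and FDR control across
  many sensors are out of scope.
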