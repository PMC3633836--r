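---
title: "Methods behind spherokit: spheroid volumetry, radial stain quantification, and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind spherokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherokit)
```

`spherokit` quantifies the standard battery of in-vitro assays used to
evaluate drug formulations against multicellular tumor spheroids (MCTS).
This vignette explains each model, its assumptions and tunable parameters,
the numerical choices made where the design was genuinely open, and what
the synthetic-data generators do and do not emulate.

## Spheroid volumetry

A brightfield micrograph of a spheroid shows a dark, roughly circular body
on a bright background. `segment_spheroid()` follows the classic automated
measurement chain:

1. greyscale conversion (`to_grayscale()`; Rec. 601 luminance weights
   0.299/0.587/0.114 for RGB input),
2. automated global thresholding (`auto_threshold()`),
3. foreground = pixels strictly *below* the threshold (brightfield
   polarity; a `dark_object = FALSE` flag inverts this for other
   modalities),
4. largest 8-connected component kept, interior holes filled,
5. calibrated measurement (`measure_spheroid()`): area
   $A = n_{px} \cdot s^2$ for calibration $s$ (µm/px), equivalent diameter
   $d = 2\sqrt{A/\pi}$, and sphere volume $V = \tfrac{4}{3}\pi (d/2)^3$.

**Why Otsu.** "Automated threshold" is underdetermined; we pin it to Otsu's
method — the threshold maximizing between-class variance on the 256-bin
8-bit histogram — because it is the de-facto automated global threshold in
the era's image-analysis tooling and is exactly reproducible. Conventions
that matter and are fixed: intensities are rounded to integer bins 0–255;
the split is $\{x \le T\}$ vs $\{x > T\}$; ties between equally good
thresholds resolve to the smallest; pixels exactly at $T$ fall on the
background side of a dark-object segmentation. The test suite holds
`auto_threshold()` equal to an exhaustive brute-force search over all 256
candidates on every image it tries.

**Component rules.** 8-connected foreground components with 4-connected
background complement (the standard dual pairing); holes are background
components not touching the frame border. Components touching the border
are eligible by default — a spheroid may graze the frame — with an
`exclude_border` strict mode. A speck of debris is removed by the
largest-component rule. No pre-smoothing is applied by default (the
`blur_sigma` flag adds a Gaussian blur for noisy acquisitions).

**Equivalent diameter, not calipers.** The diameter comes from the mask
area, not from min/max calipers; the caliper-style "average of largest and
smallest diameter" manual method exists only as the comparison arm of
`validate_against_manual()`, which regresses automated volumes on manual
ones by OLS.

## Radial quantification of stained sections

Spheroid sections stained for a marker (e.g. the Ki67 proliferation
antigen, or a hypoxia marker) show radially structured signal.
`radial_signal_distribution()` quantifies it without any nucleus-level
segmentation:

1. positive pixels: inside the section mask and strictly above a
   threshold (fixed, or Otsu restricted to in-section intensities);
2. depth map: Euclidean distance of every in-section pixel to the nearest
   out-of-section pixel (`depth_map()`, backed by a Euclidean distance
   transform). Pixels beyond the image frame count as outside, so a
   section grazing the frame keeps a finite depth;
3. regions: with $R$ the maximum depth, periphery is $0 < D \le R/3$,
   intermediate $R/3 < D \le 2R/3$, core $D > 2R/3$. Ties exactly at a
   boundary belong to the shallower region. Defining $R$ from the depth
   map (rather than a centroid distance) keeps the partition meaningful
   for non-circular sections; the two definitions coincide for a disc;
4. per-region sums of positive-pixel *intensities*, expressed as percent
   of the total. A `binary = TRUE` mode counts pixels instead — both modes
   are provided because a summed-intensity readout and a thresholded-count
   readout are both defensible and differ only when positive intensities
   vary.

A uniformly positive disc splits as the annulus areas
$1-(2/3)^2 : (2/3)^2-(1/3)^2 : (1/3)^2 = 5/9 : 3/9 : 1/9$
(55.6% / 33.3% / 11.1%), which the tests verify within pixelation error. A
section with no positive signal yields flagged `NA` percentages rather
than an error. On real sections the expected qualitative pattern for a
proliferation marker is periphery > intermediate ≥ core; the package makes
no cell-line-specific claims.

## Gompertz growth kinetics

Spheroid growth is sigmoidal on the volume scale and saturates;
`fit_gompertz()` fits

$$V(t) = V(0)\,\exp\!\left(\frac{\alpha}{\beta}\left(1 - e^{-\beta t}\right)\right),$$

with $V(0)$ the initial volume and $\alpha, \beta$ (per day) the initial
specific growth rate and its decay. The plateau is $V(0)e^{\alpha/\beta}$;
$\beta \to 0$ is handled as its exponential-growth limit. Fitting is
nonlinear least squares on **log volumes** by default: volumes span orders
of magnitude and measurement error is multiplicative, so Gaussian errors
on $\log V$ are the matched model (raw-scale fitting is a flag).
Initialization uses the first observation for $V(0)$, the reciprocal time
range for $\beta$, and the overall log-fold change for $\alpha$;
parameters are bounded below at $10^{-12}$ and optimized by
Levenberg–Marquardt (parameter tolerance $10^{-10}$, up to $10^4$
evaluations). The plateau's standard error comes from the delta method on
$(\log V_0, \alpha, \beta)$. Replicates are pooled into one fit;
`summarize_growth()` reports the per-timepoint mean ± sample SD (n−1), and
single-replicate timepoints report a missing SD rather than 0.

Arm comparisons (`compare_arms()`) use a two-sided Welch t-test per
timepoint with no multiplicity correction by default — the typical readout
is a single starred comparison at a chosen day; correcting across the full
time grid is the caller's decision. Degenerate zero-variance inputs are
resolved by convention (identical constant arms: $t = 0$, $p = 1$) because
the standard test is undefined there. A null simulation in the test suite
checks the nominal 5% type-I error within Monte-Carlo tolerance.

## Dose-response and the absolute IC50

APH-assay absorbances are normalized as
$\%\,viability = 100\,(A_{treat} - A_{media})/(A_{ctrl} - A_{media})$.
Values outside [0, 100] are retained and flagged, never clipped — clipping
would bias the fit. `fit_hill()` fits

$$v(C) = b + \frac{100 - b}{1 + (C/x_{50})^{h}}$$

on $\log_{10} C$ with the top fixed at 100 (the data are normalized to
controls), lower plateau $b \in [0, 100)$ and slope $h > 0$ free, on
individual wells rather than per-concentration means. The reported IC50 is
the **absolute** one — the concentration where the fitted curve crosses
50% viability, $x_{50}(50/(50-b))^{1/h}$ — not the curve midpoint. This
matters for resistant cultures: when the fitted plateau stays at or above
50%, or the crossing lies beyond the tested range, `ic50_reached` is
`FALSE` and the result is reported as "> max tested concentration" instead
of a number. `aph_linearity()` guards the assay itself: absorbance must be
linear in cell number (OLS $R^2 \ge 0.95$ by default); a saturating
readout fails validation.

## Clonogenic survival and release

Plating efficiency and surviving fraction are exact count ratios
(PE = colonies/plated for untreated controls;
SF = colonies/(plated × PE)); a zero PE makes SF undefined and is an
error, and zero colonies in a control warns. Release profiles are
summarized by linear interpolation of the cumulative fraction at a
requested time, refusing extrapolation outside the sampled range.

## Synthetic-data generators

Every generator takes an integer seed, restores the caller's RNG state,
and attaches the exact ground-truth parameters to its output:

- `gen_brightfield_spheroid()`: dark logistic-edged disc (default edge
  scale 2 px, centre jitter ≤ 2 px) on a bright background with additive
  Gaussian noise, clipped to the 8-bit range. Defaults 30/220 for
  foreground/background give the strong contrast of a focused brightfield
  image.
- `gen_stained_section()`: circular section; each pixel positive with
  probability `depth_profile(depth/R)`; positive/negative intensities
  Gaussian. The truth records the per-region positive sums *of the emitted
  image*, so quantification can be checked exactly.
- `gen_growth_series()`: Gompertz curve times a median-1 lognormal
  multiplier with coefficient of variation `cv`
  ($\sigma_{\log} = \sqrt{\log(1+cv^2)}$) — multiplicative because volume
  errors scale with size and volumes must stay positive.
- `gen_dose_response()`: well absorbances
  $A_{media} + (A_{ctrl}-A_{media})\,v(C)/100$ plus additive Gaussian read
  noise, with control and media-blank wells included so normalization runs
  exactly as on a real plate.
- `gen_clonogenic()`: colonies ~ Binomial(plated, PE × SF).
- `gen_release()`: first-order release $f_\infty(1 - e^{-kt})$ plus noise,
  clipped to [0, 1], optional monotone enforcement.

**Default noise magnitudes.** No assay's noise level is documented, so the
defaults are fixture choices held fixed across the whole project: volume
cv = 5% (typical replicate scatter for spheroid volumetry), absorbance
sd = 0.02 (plate-reader read noise on a ~0.1–0.9 absorbance range),
brightfield noise on the order of a few grey levels. The recovery studies
in the tests and the acceptance script run at these defaults: 20 seeds of
a 6-replicate, 10-timepoint growth study recover the Gompertz plateau
within 10% in ≥ 18/20 runs, and 20 seeds of a triplicate 9-concentration
plate recover the IC50 within 15% in ≥ 17/20 runs, with a bottom-80%
generator never yielding a reached IC50.

**What the generators do not emulate.** No optical physics (diffraction,
depth of field, uneven illumination), no histology chromatics (H&E/DAB
color), no spatial noise correlation, no plate-edge effects, no
within-spheroid shape irregularity beyond the smooth edge model. Passing
recovery tests therefore demonstrates the correctness and calibration of
the *algorithms*, not robustness to every artifact of real microscopy;
on real data the automated threshold and the section mask deserve visual
QC (the `threshold` and `n_components_discarded` fields exist for that).

## Problem sizes and determinism

The studies run at the scale of the assays they model: 512–700 px frames
(≈ 500 µm spheroids at 1.25 µm/px), sections of radius 150 px, growth
studies with n = 6 replicates over 14 days, plates with 9 concentrations ×
3 wells, clonogenic counts of 10³–10⁴ cells, and 20-seed recovery sweeps;
brute-force oracle comparisons use blobs ≤ 64×64 where the all-pairs
distance computation is exact and cheap. `run_demo()` and the
`analysis/` drivers are bit-reproducible for a fixed seed: per-stage seeds
are derived from the master seed by fixed offsets, and no global RNG state
leaks between stages.

## Known limitations

- One spheroid per image; no time-lapse tracking or 3-D stack volumetry.
- The sphere-volume conversion assumes sphericity; elongated spheroids
  bias $V$ high relative to their true volume.
- No color deconvolution: color sections must be reduced to a single
  quantification channel upstream.
- The Hill fit assumes a monotone response with top = 100%; stimulated
  wells (viability > 100%) are tolerated but not modelled.
- Welch's test per timepoint ignores the longitudinal correlation of
  repeated measures; a mixed-effects growth model is out of scope.
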