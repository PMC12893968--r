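---
title: "Super-resolution ultrasound microvascular analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolution ultrasound microvascular analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmpipe)
```

## The problem

Contrast-enhanced ultrasound (CEUS) images intravenously injected
microbubbles — gas-filled point scatterers that stay intravascular and trace
blood flow. At conventional resolution, vessels below the diffraction limit
(hundreds of micrometres at clinical frequencies) blur together. Ultrasound
localization microscopy (ULM, also called super-resolution ultrasound, SRUS)
breaks that limit statistically: across thousands of high-frame-rate frames,
individual microbubbles are detected, localized to sub-pixel precision, and
tracked; accumulating the localizations paints the microvascular bed at a
resolution set by localization precision rather than by the wavelength.

`ulmpipe` implements the full computational chain — clutter filtering,
detection, localization, tracking, microvascular metrics, bolus
time-intensity descriptors — together with the diagnostic statistics layer
used to compare two lesion groups (here labelled HER2-positive versus
HER2-negative, the breast-tumour biomarker context the defaults are drawn
from) and to combine imaging modalities into diagnostic models. Because no
patient data ship with the package, a first-class synthetic phantom module
provides ground truth for every stage.

## The phantom: what it emulates, and what it does not

`make_vessel_tree()` draws circular-arc vessel segments (radius, flow speed,
curvature per segment) inside the field of view; `simulate_mb_flow()` advects
point microbubbles along the centrelines with a fixed perpendicular offset
inside the lumen, respawning bubbles at the segment start so the bubble
density is stationary. The stored per-bubble velocity is the discrete
forward difference of positions times the frame rate, so positions and
velocities are exactly self-consistent; respawn steps are flagged.

`render_frames()` builds each frame as

\[
I_t = C\,\big(1 + a \sin(2\pi f_d t)\big)
      + \sum_b A\, G_\sigma(x - x_b(t)) + \varepsilon_t,
\]

a static clutter image \(C\) with an optional slow sinusoidal gain drift
(amplitude \(a\), frequency \(f_d\)), isotropic Gaussian point-spread
functions at the bubble positions, and i.i.d. Gaussian noise. Two choices
are deliberate:

* **Gaussian PSF, default σ = 150 µm.** The scanner's beam profile is not
  published; an isotropic Gaussian at roughly the diffraction-limited beam
  width of a 3–10 MHz linear probe at mid-band is the standard ULM phantom
  choice. σ is configurable but must stay ≥ pixel/2 to avoid aliasing.
* **Low-rank clutter.** Static clutter plus one sinusoidal gain drift spans
  a rank-≤2 temporal subspace, so the SVD stage can be verified analytically
  (one removed component annihilates static clutter to machine precision).

The default acquisition geometry is a 128×128 grid at 50 µm/pixel
(6.4 mm field of view), 1000 frames at 80 Hz — the scale of the
high-frame-rate acquisitions the pipeline targets while staying desk-sized.

What the phantom does **not** model: acoustic wave propagation, nonlinear
microbubble oscillation, speckle, out-of-plane motion, and tissue motion
beyond the smooth gain drift. Passing the phantom suite therefore
demonstrates the correctness of the *computational* chain, not robustness to
every artifact of clinical data.

The bolus simulator `simulate_tic()` uses a piecewise-linear
(triangular) wash-in/wash-out shape so that every descriptor — relative peak
intensity PI = (peak − baseline)/baseline, time to peak, trapezoid area,
limb slopes — has a closed form stored with the curve.

The cohort simulator `simulate_cohort()` draws per-group normal continuous
features and multinomial categorical features. `default_cohort_spec()`
carries the published two-group summaries (n = 23 vs 49; e.g. lump diameter
3.78 ± 1.38 vs 3.07 ± 1.34 cm; the printed proportions for orientation,
microcalcification, area of enhancement, microvascular distribution and flow
direction). Spreads reported as median (IQR) were converted under normality
(sd ≈ IQR/1.35). Features are drawn independently within groups — real
lesion features correlate, so synthetic multivariable model coefficients are
not comparable to the published ones, only the machinery is.

## SVD clutter filtering

The stack is rearranged into a Casorati matrix (pixels × frames). Tissue
clutter is slow and spatially coherent, so it concentrates in the leading
singular components; microbubbles are fast and sparse, spreading over the
rest. `svd_clutter_filter(stack, low_cut, high_cut)` rebuilds the stack from
components (low_cut, high_cut]. Rather than a full SVD of the tall Casorati
matrix, the implementation eigendecomposes the frames × frames Gram matrix
and subtracts the rejected subspace, `X − X V_r V_rᵀ`, which is exact and an
order of magnitude cheaper at 1000 frames. `suggest_rank_cut()` places the
cut at the largest multiplicative gap of the singular spectrum, falling back
to a configured minimum when the spectrum is gapless.

One property deserves emphasis because it shapes testing: *any* filter that
removes the static subspace also removes the temporal mean of the bubble
signal. The ideal output is therefore the mean-subtracted bubble movie, not
the raw bubble movie; on a single-vessel phantom the removed "ghost ridge"
bounds the raw-frame correlation near
\(\sqrt{1 - 2\sqrt{\pi}\,\sigma/L}\) for a vessel of length \(L\). The test
suite checks near-perfect agreement against the mean-subtracted reference
and a looser bound against the raw reference.

## Detection, localization, accumulation

Detection thresholds the filtered frame (default: frame mean + 3 sd,
absolute override available) and takes 8-connected components. Artifact
gates follow the standard ULM triplet — area within [2, 60] pixels at 50 µm
pitch, eccentricity ≤ 0.9 — where eccentricity is
\(\sqrt{1-\lambda_{\min}/\lambda_{\max}}\) of the intensity-weighted second
central moment matrix, with the 1/12 intra-pixel variance added per axis so
a one-pixel-wide line is elongated but not degenerate. Components touching
the border are kept but flagged.

Localization is the intensity-weighted centroid of the component, in
micrometres, with the origin at the top-left pixel centre and the axial
coordinate increasing with depth. On the phantom at 20 dB SNR the RMSE is
about 10 µm, a fifth of the pixel.

`accumulate_density_map()` bins localizations on a grid upsampled by an
integer factor (default 10×, i.e. 5 µm bins), incrementing exactly one bin
per localization so counts are conserved.

## Tracking

For each localization in frame F, candidates in frame F+1 within a 700 µm
search radius are scored by zero-mean normalized cross-correlation between
9×9-pixel patches; candidates below NCC 0.9 are rejected, and matching is
greedy in descending NCC with ties broken by smaller displacement, then by
index. Because same-shaped microbubbles yield NCC values identical to
numerical precision, NCC is quantized to 10⁻³ in the ordering so the
displacement tie-break actually decides. Greedy matching agrees with the
exhaustive optimal assignment on ≈96% of phantom-like frames at ≤6
bubbles per frame.

Two published constants conflict: a 700 µm window at 80 Hz admits speeds up
to 56 mm/s, while the stated trackable maximum is 40 mm/s. The radius is
exposed as configuration (`search_radius_um`) and the structural cap —
radius × frame rate — is asserted as an invariant; the package does not
resolve which figure is authoritative. Likewise whether the "window" is a
radius or a square side is unstated; the implementation uses a circular
radius.

Chains of one-to-one pairs become tracks; tracks shorter than 5
localizations (configurable) are discarded. Step speed is displacement ×
frame rate. Velocity/direction maps average step speeds and signed axial
velocities over the SR bins each step traverses; unvisited bins are NA,
never zero.

## Microvascular metrics

* **Velocity.** Per-track mean of in-ROI step speeds; the ROI mean is the
  average over tracks, and "max flow velocity" is the maximum *per-track
  mean* (robust to single-step outliers), not the global maximum step.
* **Tortuosity.** Path length / chord length per track (the distance
  metric): 1 for a straight track, π/2 for a semicircle. The published
  per-lesion values (means ≈ 3, maxima ≈ 60–120) imply a different or
  scaled definition that is never given; no attempt is made to match those
  magnitudes, and closed loops (zero chord) are flagged and excluded.
* **Diameter.** The SR map is binarized (counts > 0 after one morphological
  opening; the opening is skipped when it would empty a sparse map),
  skeletonized by Zhang–Suen thinning, and the diameter at each skeleton bin
  is twice the Euclidean distance transform × grid spacing; the
  discretization bias is at most one SR bin.
* **Fractal dimension.** Box counting over dyadic scales, least-squares
  slope of log N versus log(1/s); ≈1 for lines, ≈2 for filled regions,
  log 3/log 2 for a Sierpinski raster. A flat count profile is flagged
  degenerate rather than fit.
* **Microvascular density.** Tracked-footprint area / ROI area × 100. The
  footprint stamps a physical radius (default half a frame pixel) around
  each track point on the SR grid; a physical radius makes MVD approximately
  invariant under grid refinement, which bare centroid counts are not.
* **Distribution pattern.** Each localization gets an *area-normalized*
  radial position r — the squared ratio of its centroid distance to the
  centroid-boundary distance along the same ray — so a uniformly
  vascularized ROI yields uniform r. Peripheral if ≥60% of r > 0.6, central
  if ≥60% < 0.5, else diffuse; all three thresholds are configuration. The
  squaring is this package's operationalization of a reader-assessed
  feature: with the raw ray ratio a uniform fill would read as peripheral
  (64% of a disc's area lies beyond r = 0.6), which contradicts the
  feature's intent.
* **Flow direction.** Length-weighted mean of signed axial step velocities
  over in-ROI steps: positive (deepening) is "away from the transducer",
  negative "toward"; an exact zero is reported indeterminate.

Velocities are mm/s everywhere internally; any cm/s presentation is an
explicit, labelled conversion at the output layer.

## Time-intensity curves

`extract_tic()` averages the stack over the ROI per frame. Contrast arrival
is the first sample exceeding baseline + 2 sd (baseline grown from an
initial pre-contrast window) sustained for ≥3 samples; curves that never
qualify carry an NA arrival rather than a guessed one.

`tic_parameters()` computes PI (both the dimensionless ratio and a labelled
10·log10 dB variant), TTP, trapezoid AUC over the record, a least-squares
wash-in slope on the ascending limb between 10% and 90% of the enhancement
(the limb ends at the first upcrossing of the 90% level so decay samples
cannot leak into the fit), and a wash-out slope from the peak to 50% decay
or the record end. Peak finding smooths with a moving average (default 5
samples; 1 disables smoothing and makes all descriptors exact on noiseless
piecewise-linear boluses) and then refines the peak as the *intersection of
the two fitted limbs* — the smoothed argmax alone drifts toward the
shallower limb of an asymmetric bolus, an ≈6% TTP bias at 20 dB that the
intersection estimator removes. At 20 dB contrast SNR the mean PI and TTP
errors are ≈2% and ≈5% over 100 simulated boluses.

## Diagnostic statistics

The layer mirrors a standard two-group diagnostic workup:

* `pearson_chi_square()` — uncorrected Pearson statistic. The choice of *no*
  continuity correction is verified, not assumed: the seven contingency
  statistics printed with their counts (6.770, 5.554, 2.510, 0.888, 42.933,
  6.509, 13.064) are reproduced exactly only without correction. Expected
  counts below 5 do not trigger a switch (mirroring the source analysis);
  `fisher_exact()` is available where exactness is wanted.
* `two_sample_t()` — pooled by default, Welch when a Brown–Forsythe/Levene
  test (deviations from medians) has p < 0.1; both variants are retained in
  the result object, SPSS-style.
* `mann_whitney_u()` — U with the tie-corrected normal approximation; the
  z approximation is within 0.01 of the exact permutation p for untied
  samples around n ≈ 30 per group.
* `cohens_kappa()` — with large-sample CI; degenerate (single shared
  category) inputs are flagged, not NaN'd.
* `logistic_fit()` — `glm` binomial fit reported as β, SE, Wald = (β/SE)²,
  OR = exp(β) with exp(β ± 1.96 SE) intervals; quasi-complete separation is
  detected (diverging coefficients or fitted probabilities at the
  boundaries) and reported.
* `roc_analysis()` — empirical ROC, AUC by the Mann–Whitney identity (ties
  counted half), DeLong variance for the CI, and the Youden-optimal cutoff
  with ties broken toward higher specificity. Cross-checked against an
  independent ROC implementation in the test suite.
* `combine_modalities()` — all non-empty unions of named feature sets (seven
  combinations for CUS/CEUS/SRUS), each fit in-sample by logistic score and
  evaluated by ROC. Results are in-sample and labelled as such: without the
  original 72-lesion data no validated performance claim is possible, and
  the synthetic cohort's independent features make in-sample separation
  easier than reality.

## Numerical choices and degenerate inputs

Tie-breaks and degenerate cases are deterministic throughout: greedy
pairing (quantized NCC → displacement → index), Youden cutoff (higher
specificity), flat singular spectra (configured minimum cut), empty vessel
masks and ROIs (flagged NA, never silent zeros), closed-loop tracks
(excluded), zero-intensity detections (error). All randomness flows through
explicit integer seeds, and every pipeline artifact embeds the
configuration hash and seed.

Problem sizes in the test-suite phantoms — 64×64 grids, 80–150 frames,
100-seed Monte-Carlo loops, 10⁴ null replicates for test calibration — were
chosen so each property is measured with comfortable statistical margin on a
single core; the full default-scale pipeline (128×128, 1000 frames) runs
end-to-end in the determinism check and the acceptance script.

## Known limitations

* TIFF + JSON sidecar is the supported stack container; DICOM export is out
  of scope here (no reader dependency), so device exports need a one-time
  conversion.
* The installed TIFF writer stores unsigned 16-bit samples; stacks
  round-trip via min-max scaling recorded in the sidecar, exactly on the
  16-bit grid and to 1/65535 of the range otherwise.
* No motion correction and no Kalman-style motion model in tracking, by
  design (nearest-candidate within the gated radius only).
* The phantom's independence assumptions (features independent within
  groups; clutter exactly low-rank; no speckle) mean green tests bound
  implementation correctness, not clinical performance.
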