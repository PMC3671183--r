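---
title: "Quantifying in situ hybridization signal along epithelial depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in situ hybridization signal along epithelial depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

## The problem

Colorimetric RNA in situ hybridization (RISH) on sections of layered sensory
epithelia — the motivating system is the mouse main olfactory epithelium,
with supporting (sustentacular) cells apically, mature then immature
olfactory sensory neurons (OSNs) below them, and basal cells against the
basal lamina — produces label whose *depth* carries the biology: a probe
restricted to mature OSNs occupies the upper portion of the neuron layer,
an immature-OSN marker such as GAP43 occupies a basal band. `episcan`
turns such images into quantitative, comparable depth profiles and
summary statistics, and provides a matching relative-quantification stage
for qPCR data.

The analysis chain is the classical line-intensity-scan protocol:

1. invert the micrograph so label is bright ([invert_image()]);
2. draw straight scans perpendicular to the local tangent of the traced
   basal lamina, from the apical surface down to the lamina
   ([scan_line()], [extract_scan()]);
3. normalize each scan to its own maxima in both axes
   ([normalize_profile()]), so depth runs 0 (apical) to 1 (lamina) and
   peak intensity is 1;
4. average hierarchically ([hierarchical_average()]): the scans of each
   animal are linearly interpolated onto a 500-point grid and averaged,
   each animal curve is renormalized to peak 1, and animal curves are
   averaged on a 100-point grid with per-point SEM over animals;
5. summarize with trapezoidal area integrals over a marker-defined depth
   window ([area_integral()]) and compare two probes' distributions within
   that window with a two-sample Kolmogorov-Smirnov statistic
   ([ks_compare()]).

## Scan geometry

The basal lamina is supplied as an ordered polyline of (row, col) pixel
coordinates; row 0 is the apical edge and pixel centers sit at integer
coordinates. Local tangents are central differences over neighboring
vertices (one-sided at the ends); the scan direction is the exact unit
normal, oriented apically, so the perpendicularity residual is zero to
floating-point precision. Intensities are sampled by bilinear
interpolation every pixel (configurable `step_um`); bilinear sampling is
exact on linear intensity fields, and on synthetic two-layer sections the
recovered boundary sits within one pixel of the truth. The scan length
defaults to the distance from the basal anchor to the apical image edge
along the scan direction, mirroring a line drawn "from the apical surface
to the basal lamina"; an explicit length in micrometers (the motivating
protocol used 56–58 µm) can be given instead. Scan width is one pixel;
there is no band averaging.

RGB images are converted to Rec.709 luminance (0.2126, 0.7152, 0.0722)
before inversion, since a scalar intensity is required; integer images
invert as `dtype_max - value`, real-valued images as `1 - value`, and the
container tracks that inversion happened exactly once.

## Averaging and normalization choices

* Grids are uniform on [0, 1] with both endpoints included and spacing
  `1/(n-1)`; defaults are 500 points within animal and 100 points across
  animals.
* Interpolation is linear everywhere. Normalized profiles span [0, 1]
  exactly, so no extrapolation policy is needed.
* Per-scan normalization divides by the scan's own maxima; a scan with no
  positive signal cannot be normalized and is rejected with an explicit
  error rather than silently dropped.
* SEM is computed across animals (`sd/sqrt(n_animals)`), not across scans:
  animals are the independent units.
* The group curve is *not* renormalized after averaging — only the
  within-animal step renormalizes — so group peaks sit near but not
  exactly at 1. This is deliberate and matters when comparing peak
  heights.

## Windows, integrals and the KS comparison

The marker window defaults to the explicit interval [0.63, 0.93] of
normalized depth, the band occupied by the basal (GAP43-like) marker.
Alternatively [derive_window()] computes the outermost half-maximum
crossings of a marker curve (linearly interpolated between grid points);
it refuses constant curves and curves with disjoint supra-half-max
regions, for which an explicit window must be given.

Area integrals use the composite trapezoid rule over the grid points
inside the window, with the curve's interpolated values inserted exactly
at the window edges; this removes the O(grid-step) bias of truncating to
the nearest grid point, makes integrals exactly additive over abutting
windows, and agrees with a 10^6-interval Riemann reference to well below
1e-4.

For the KS comparison two modes are provided, and every report names the
mode used:

* `pointwise_values` (default): the two curves' values at the grid points
  inside the window are treated as the two samples;
  `D = sup |ECDF1 - ECDF2|`, with the asymptotic Kolmogorov p-value.
* `density_cdf`: each curve inside the window is treated as an
  unnormalized density over depth and D is the sup-distance between the
  normalized cumulative integrals. This is the statistically cleaner
  contrast of *shapes*, but it has no sampling model, so no p-value is
  attached (`p_value = 1`, flagged).

**Effective sample size.** Values of an averaged curve are not independent
draws: within a window they are interpolated from a handful of underlying
scans and share each animal's renormalization factor. Using the grid-point
counts as n1/n2 therefore overstates the information content, and in null
simulations (two cohorts generated from the identical configuration) the
pointwise KS test with grid-point n rejects at several times the nominal
5% level. `ks_compare()` consequently accepts `n_for_p = "scans"`, which
keeps D as defined above but takes n1/n2 from the number of contributing
scans per side — the independent units — and this is the default in the
cohort and pipeline workflows; its null rejection rate in the package's
calibration simulations is close to nominal (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, which
recompute it). The output's `n_meaning` field states which convention
produced the reported n, and the literal grid-point convention remains
available as `n_for_p = "values"`.

## qPCR stage

Technical replicates are collapsed by the arithmetic mean of Ct before
any differencing. Per sample, `dCt = Ct(gene) - Ct(reference)`; in
`delta_ct` mode the per-sample folds `2^-dCt` are averaged across
biological samples (mean ± SEM, matching the shape of published
"value ± SEM relative to Gapdh" tables); in `delta_delta_ct` mode each
dCt is first referenced to the calibrator group's mean dCt for that gene,
so the calibrator centers at fold 1. Both modes are first-class because
published analyses often cite the ddCt method while reporting folds
relative to the reference gene only (i.e., dCt); reports name the mode.
Adding a constant to all Ct values of a sample (a loading effect) leaves
every fold unchanged.

Differences among genes are tested by one-way ANOVA (via `stats::aov`)
followed by Tukey's HSD, with
`q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))` and the
adjusted p from the studentized-range distribution (`stats::ptukey`).
Equal within-group variance is assumed, not enforced. A perfect fit (zero
within-group variance with unequal means) is reported as `F = Inf`,
`p = 0` with a `degenerate` flag rather than the unreliable huge F a
naive computation yields. Against a 10^5-permutation max-|q|
randomization reference the adjusted p agrees typically to well under
0.01 at n = 5 per group, but the two references differ systematically by
up to ~0.03 for mid-range (non-significant) p — a known property of
comparing normal-theory and randomization distributions at small n, not
an implementation defect (the implementation matches `stats::TukeyHSD`
to 1e-8).

## The synthetic-data generator

No public image or Ct data accompany the motivating protocol, so the
package generates its own ground truth.

**Images.** A section is modeled as a curved, layered epithelium on a
2048 × 2048 grid at 0.372 µm/pixel by default (the motivating acquisition
geometry): the basal lamina follows
`row = baseline + amplitude * sin(2*pi*col / wavelength)`, normalized
depth is measured from the apical edge (row 0) to the local lamina row,
and strictly increasing depth fractions split the epithelium into named
layers. Each probe assigns a mean signal intensity to every layer.
In *continuous mode* every layer pixel equals `background + intensity`,
so expected profiles — and therefore designed integral ratios — are exact
and analytic. In *blob mode* Gaussian cell-body kernels (sigma = radius/2)
of amplitude equal to the layer intensity are seeded at
Poisson-distributed centers and combined by pixelwise maximum, emulating
label confined to scattered somata; the expected within-layer mean of
this Boolean model is `background + A*beta/(1+beta)` with
`beta = 2*pi*density*sigma^2` ([blob_expected_mean()]), which the renderer
reproduces within a few percent. Gaussian pixel noise is added last and
images are clipped to [0, 1]. The generated signal field is flipped by
[as_brightfield()] to emulate dark label on a bright field, so the
pipeline's inversion step operates end to end. The generator does *not*
model optics (PSF), stain spectra, section artifacts, or the true noise
statistics of NBT/BCIP development — the noise family is a stand-in — so
passing tests demonstrate correctness of the measurement chain, not
robustness to every real-data pathology.

**Cohort preset.** [moe_cohort_model()] encodes the study design used
throughout the tests: layers sus/mOSN/iOSN/basal with boundaries 0.25,
0.63, 0.93; a `Gb1` probe spanning the full neuron layer (0.8), a `Gg13`
probe at 0.8 in mOSN and 0.35 in iOSN, and a `GAP43` marker at 0.8 in
iOSN only; background 0.1 and pixel noise sd 0.05 (a moderate noise level
for 8-bit brightfield material). With these values the GAP43 half-max
band is exactly [0.63, 0.93] and the designed normalized windowed-integral
ratio Gb1 : Gg13 is exactly 2 — mirroring the motivating observation that
the mature-OSN probe covers half the marker window's area — since
`((0.1+0.35)/0.9) / ((0.1+0.8)/0.9) = 0.5`. Cohorts are 3 animals × 2
images × 2 scans (4 scans per animal), generated from deterministic,
stage-named substreams of one integer seed.

**Problem sizes.** Simulated sections in the test and acceptance cohorts
are 256 × 512 px (null-calibration cohorts 224 × 128 px) at the same
0.372 µm/pixel, giving an epithelium about 58 µm deep — the same scan
geometry as full-frame material at a fraction of the cost; the geometry
recovery, designed-ratio, and calibration results do not depend on the
frame size. The KS null calibration uses 500 simulated cohort pairs in
the test suite (200 in the acceptance script), and the ANOVA type-I
calibration uses 2000 Gaussian simulations.

**Ct tables.** [ct_design()] fixes designed relative expressions against
a reference gene (reference fold 1 by construction);
[generate_ct_table()] emits
`Ct = ct_reference_mean - log2(rel) + N(0, ct_noise_sd)` independently
per well (per sample × gene × technical replicate), with optional
per-group fold multipliers for ddCt designs. At `ct_noise_sd = 0` the
tables invert exactly to the designed folds; at the default 0.2 cycles a
designed 9.3-fold gene is recovered within a few percent with n = 3.

## Pipeline and reproducibility

[run_pipeline()] executes simulate → scan → average → window-stats → qPCR
from one YAML/JSON configuration ([default_pipeline_config()] and
`inst/extdata/default_config.yaml` show the full schema), writing every
interchange artifact (TIFF sections, lamina-trace CSVs, a scan manifest,
`profiles.csv`, `averaged.csv`, `stats.json`, `ct.csv`,
`relative_expression.csv`, `anova.json`) plus a JSON run report with
parameters, output digests and summary statistics. All randomness derives
from stage-name-hashed substreams of the single global seed, so a rerun
with the same configuration reproduces the report summaries exactly;
[validate_config()] checks a configuration without running it and names
the offending key in each finding. A thin command-line wrapper lives at
`inst/scripts/episcan.R`; the R functions are the primary interface.

## Known limitations

* The pointwise KS p-value is approximate under either n convention;
  curve values are never i.i.d. samples. The scan-count convention is
  approximately calibrated in the package's own null simulations; for a
  distribution-free contrast of curve shapes use `density_cdf` and report
  D without a p-value.
* The half-max window rule is a convenience for well-separated unimodal
  markers; noisy or multimodal marker curves require an explicit window.
* Tukey adjusted p-values follow normal theory; at very small group sizes
  they can differ from a randomization reference by a few percent in the
  non-significant range.
* The generator's realism boundaries are stated above; in particular
  designed integral ratios are exact only in continuous mode.
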