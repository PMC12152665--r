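---
title: "Quantifying Src trafficking and localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Src trafficking and localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcquant)
```

srcquant quantifies where a signaling protein sits in a migrating cell
and how fast it moves there. This vignette explains each measurement's
model and assumptions, the parameters that matter, what the synthetic
generators emulate (and what they deliberately do not), and the design
choices made where the procedures were genuinely open.

## Geometry conventions

Rasters are R matrices with `values[row, col]`, row = y, col = x, and
pixel centers at integer coordinates starting at 1. The boundary
between pixel columns *k* and *k + 1* lies at x = *k* + 0.5, which is
where a scratch edge flush with a cell's first pixel column belongs.
All physical distances are micrometers, converted through the mandatory
`pixel_size_um`; pixels must be square (anisotropic calibrations are
rejected rather than silently averaged), and a pixel size is never
assumed when metadata is missing. When a z-stack is supplied, every MFI
is measured on the per-pixel sum projection.

## ROI construction

Three derived ROIs feed the ratio metrics, all defined by exact
Euclidean distance between pixel centers with inclusive (≤)
comparisons:

* **Front band**: a cell's pixels within `depth_um` (default 5 µm) of
  the scratch edge. The band is a *distance band* from the edge — not a
  morphological translate of it — so curved wound fronts are handled
  identically; the edge may be a vertical line or any polyline.
* **Perinuclear region**: the nucleus dilated by `enlarge_um` (default
  5 µm) intersected with the host cell's mask. Nuclei are matched to
  cells by majority pixel overlap (exact ties break to the lower cell
  label, with a warning). The nuclear pixels themselves are included by
  default (`exclude_nucleus = FALSE`), since the dilation is meant to
  *extend* the nuclear zone, not replace it.
* **Membrane band**: cell pixels within `shrink_um` of the cell
  boundary, optionally restricted to an angular sector around the cell
  centroid representing the leading edge. The band width is a required
  analysis parameter — there is no universally correct value — with a
  2 µm default; how the leading-edge arc was set in the original manual
  workflow is not algorithmically specified, so the sector is the
  package's own operationalization.

The distance transforms (EBImage's exact Euclidean `distmap`) are
tested against brute-force per-pixel distance loops on every fixture up
to 64×64; connected components use 8-connectivity, implemented as a
diagonal-merge pass over 4-connected labels and checked against a
flood-fill oracle.

## Ratio metrics

Each metric is MFI(region)/MFI(cell) per cell. Ratios equal 1 exactly
on fields constant within a cell, are invariant to a pure intensity
gain, and are *not* invariant to an additive offset — which is exactly
why the kinetics module subtracts baselines before forming its ratio.
Cells with an empty region are reported with an `NA` ratio and a flag
rather than dropped, and border-touching cells are flagged but kept
(exclusion is the caller's decision). Saturated-pixel fraction is
reported as a QC column; saturated pixels are never excluded from the
MFI.

## Focal-adhesion sizing

Preprocessing is background subtraction (grey opening with a disc of
`bg_radius_px`), CLAHE, and Gaussian blur, in that order, then a rescale
to [0, 1]; detection applies a fixed threshold, labels 8-connected
components *within each cell mask* (adhesions of neighboring cells can
never merge), and drops components below `min_size_px`. Defaults
(`bg_radius_px` 50, tile 64 px, clip 0.01, sigma 1, threshold 0.5,
min size 4) are stated in `fa_params()` and logged with the output —
none is canonical, and each step can be disabled by setting its
parameter to 0.

Numerical notes: the CLAHE clip limit follows the fraction-of-histogram
convention (mapped internally to EBImage's mean-bin-count multiples),
and images whose dimensions are not multiples of the tile grid are
padded by edge replication and cropped back. On clean scenes the
recovery benchmark disables CLAHE and blur: a Gaussian blur of σ = 1 px
shrinks the 0.5-level set of a ~5-px-diameter object by several pixels
(a curvature effect), so exact-area recovery is only a fair test of the
segmentation and measurement machinery when smoothing is off. The full
chain is exercised separately: support preservation of a bright
ellipse under background subtraction + CLAHE, and mean-area recovery
within 10% at SNR 10 with blur on.

## Photoconversion kinetics

The pulse-chase model is a single-compartment saturating exponential.
After conversion, the background-corrected membrane/cell ratio follows

$$y(t) = a\,(1 - e^{-b t}), \qquad t_{1/2} = \ln 2 / b,$$

with *t* = 0 at the conversion frame and the first fitted point one
frame interval later. The standard acquisition is 30 frames at 25 s
with conversion after frame 5; the five pre-conversion frames define
the membrane and cell backgrounds by averaging. The model has no offset
term — the curve is forced through 0 at *t* = 0, matching the
background-correction step; an additive-offset variant is available
(`offset = TRUE`) for sensitivity analysis only.

Fitting is bounded Levenberg–Marquardt (a, b > 0) from a single start
(`a0 = max(y)`, `b0 = 3/t_last`); the 2-parameter model is
well-conditioned on these grids and multi-start adds nothing. A rate
guard at 10³ s⁻¹ catches the degenerate constant-ratio regime
(b → ∞): such fits are flagged `converged = FALSE` and excluded from
condition medians, with the exclusion count reported. Noiseless series
are recovered to better than 1e−6 relative error, and t½ ≡ ln 2/b holds
exactly for every returned fit. Frames whose corrected cell MFI is not
positive are flagged and excluded with a warning; at least five usable
post-conversion frames are required.

## Motility and transwells

Track speed is the mean instantaneous step speed (path length over
time) in µm/h, not net displacement over time — the convention of
manual TrackMate-style tracking. The default window is 3–9 h after
attachment at 10-min sampling; a 3-h-duration variant appears in parts
of the original figure legends, so the window is a config parameter
rather than a constant. Speeds are invariant to rigid motions of the
coordinate system and scale linearly with space. Transwell counts are
normalized to the mean of the control fields (control ≡ 1).

## Expression stratification and qPCR

FPKM values are transformed as log₂(x + 0.01). High/low groups are the
*strict* quartile intersection: a sample is "high" only if it exceeds
the 75th percentile of every marker, "low" only if it is below the 25th
percentile of every one; percentiles use linear interpolation
(R type 7) and boundary samples fall into neither tail. The intersection
is rank-based, hence invariant to monotone transforms of individual
markers. Group comparison is a two-tailed Welch t-test
(`stats::t.test`). qPCR fold changes follow 2^−ΔΔCt with a single
reference gene; shifts common to all samples cancel exactly.

## The synthetic generators

Every generator is a pure function of (parameters, seed): it restores
the caller's RNG state and reproduces identically under the same seed.
Truths are the exact generative quantities, so re-measuring a noiseless
scene returns the stored truth to numerical precision — this
self-consistency is tested for every stage.

* **Scratch / perinuclear scenes**: rectangular cells (defaults: 20 µm
  deep at 0.2 µm/px) with uniform base intensity and a region elevated
  by (1 + enrichment); noise is per-pixel additive Gaussian. The
  perinuclear truth region is computed from the closed-form distance to
  a rectangle, independently of the pipeline's distance transform.
* **Focal adhesions**: non-overlapping "digital ellipses" — the N
  pixels closest to a center under a random anisotropic metric — so
  every stored pixel area is exact by construction. Contrast is
  amplitude/noise-SD (`snr`).
* **Photoconversion**: the converted pool C is constant after
  conversion, so the corrected ratio follows a(1 − e^(−bt)) exactly and
  the generative model is the exact inverse of the fitting model. The
  cell-wide red-signal dynamics are not otherwise modeled — this is a
  modeling choice, not an observation. Noise is additive Gaussian on
  the MFIs (not per-pixel shot noise).
* **Tracks**: isotropic random walks with configurable step-length
  distribution; true speed = mean(step)/Δt.
* **Expression**: a latent per-sample EMT score drives four correlated
  log-normal markers; the target gene is shifted by `effect_size` in
  samples above the median latent score.

What the generators do **not** emulate: point-spread functions,
photobleaching, stage drift, shot noise, segmentation errors, cell
shape variability, or cohort-level confounding. Passing tests therefore
demonstrate that the *measurement* pipeline is correct and unbiased
under its own assumptions — not that those assumptions hold in any
particular real dataset.

## Benchmark problem sizes

The recovery benchmarks (also run by `scripts/acceptance.R`) use
cohorts chosen so estimator sampling error is small against the
tolerance being demonstrated: 120 cells per kinetics condition
(log-normal rates, sdlog 0.25 — a spread comparable to the wide
interquartile ranges typical of per-cell half-time data — and noise at
5% of the plateau signal; the median's sampling error is then ~3%),
40 adhesions per condition at SNR 50 with exact paired-jitter integer
areas, and 30 fixed-step tracks per condition. Fixed-step tracks make
the speed median exact, and exact-area adhesion scenes make the mean
area exact up to detection, so those benchmarks are deterministic given
the seed.

## Known limitations

* Segmentation here is fixture-grade thresholding; real cell masks
  should come from a dedicated segmenter and be imported.
* 16-bit PNG can be read but not written; 16-bit output uses TIFF.
* No 3D ROIs; z-stacks are collapsed by sum projection before
  measurement.
* The membrane-band width and the leading-edge arc are analysis
  choices the user must own; results should be reported with them.
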