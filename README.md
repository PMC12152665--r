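# srcquant

Quantification of Src-family kinase trafficking and localization from
fluorescence microscopy, for cell biologists studying how RhoGEF
signaling redistributes Src between the perinuclear compartment, the
leading edge and focal adhesions in migrating cells.

The package turns label masks (from Cellpose or any external segmenter)
plus multichannel TIFFs into per-cell statistics:

- **Scratch-front ratio** — MFI of a signal within 5 µm of the wound
  edge over the whole-cell MFI, per cell.
- **Perinuclear enrichment** — MFI inside the nucleus dilated by 5 µm
  (∩ cell mask) over the whole-cell MFI.
- **Focal-adhesion sizing** — background subtraction → CLAHE → Gaussian
  blur → fixed threshold → per-adhesion areas and per-cell means (µm²).
- **Photoconversion kinetics** — for pulse-chase series (30 frames,
  25 s, conversion after frame 5): baseline correction from frames 1–5,
  the background-corrected membrane/cell MFI ratio, and a per-cell
  nonlinear least-squares fit of

  y(t) = a · (1 − e^(−b·t)),  t½ = ln 2 / b

  with condition medians over converged fits.
- **Motility** — per-cell mean step speed (µm/h) over a 3–9 h tracking
  window at 10-min sampling; transwell counts normalized to control.
- **Expression stratification** — log₂(FPKM + 0.01), high/low groups as
  the strict quartile intersection across an EMT-marker panel
  (SLUG, ZEB1, ZEB2, TWIST2), Welch's t-test, and 2^−ΔΔCt qPCR fold
  changes.

Every stage has a paired synthetic-data generator (`gen_*`) that
produces scenes, series, tracks and expression tables with exact ground
truth, so the whole pipeline is testable without raw microscopy data.

## Worked example

Photoconversion kinetics on a synthetic cohort:

```r
library(srcquant)

g <- gen_photoseries(30, a_dist = 0.5, b_dist = 0.01,
                     noise_sd = 25, seed = 1)
fits <- lapply(g$series,
               function(s) fit_saturating_exponential(corrected_ratio(s)))
fits[[1]]
#> KineticFit: a = 0.4937, b = 0.01043 /s, t1/2 = 66.47 s (converged, 25 points)
condition_median_halftime(fits)$median_t_half_s
#> [1] 70.05132
```

The true half-time is ln 2 / 0.01 = 69.31 s; each cell's plateau `a`
and rate `b` are recovered from its noisy ratio curve, and the
condition median is taken over converged fits only.

Front-band ratios from a synthetic scratch scene:

```r
sc <- gen_scratch_scene(4, enrichment_front = 1, noise_sd = 0, seed = 2)
band <- front_band(sc$cell_mask, sc$front)   # pixels within 5 um of the edge
head(front_ratio(sc$image, sc$cell_mask, band)[, c("cell_id", "ratio")], 2)
#>   cell_id ratio
#> 1       1   1.6
#> 2       2   1.6
```

The default cell is 20 µm deep, so the 5-µm front band is a quarter of
it; with the band twice as bright as the rest, front MFI / cell MFI =
2 / 1.25 = 1.6. Measured ratios equal the generator's stored truth to
1e−9 on noiseless scenes.

A command-line interface is installed at `inst/cli/srcquant.R`
(subcommands `front-ratio`, `perinuclear`, `fa-size`, `photokin`,
`motility`, `expr-strat`, `simulate`; each takes `--config`, `--out`,
`--seed`).

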