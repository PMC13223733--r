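# psmorph

Quantification toolkit for super-resolution studies of nuclear
**paraspeckles** (PS) and their crosstalk with **nuclear speckles**.

Paraspeckles are nuclear condensates scaffolded by the long noncoding
RNA NEAT1_2 and built with a core–shell architecture: the 5′ and 3′
ends of NEAT1_2 occupy a shell of roughly constant geometry (~360 nm
sphere diameter in untreated cells) while the transcript's middle
region fills the core. Studies of this architecture by
dSTORM/DNA-PAINT and STED microscopy need a common set of downstream
measurements — particle morphometry, single-particle ring-model radii,
channel colocalization against a randomized null, RNA decay half-lives
after transcription shutoff, polyA-evidence read counts and splicing
stratification — and `psmorph` packages that pipeline for R, exercised
end-to-end on synthetic data with known ground truth.

## What it computes

* **Rendering** — localization quality filters (ellipticity, PSF
  width), dark-frame linking to photon-weighted positions, and 10 nm/px
  count-histogram rendering with sum-conserving Gaussian blur.
* **Morphometry** — Gaussian blur + threshold segmentation
  (8-connectivity), per-particle area, second-moment major axis,
  roundness `Round = 4·Area/(π·major_axis²)`, equivalent radius
  `√(Area/π)`, strict filters (area > 0.025 µm², roundness > 0.8),
  small/large classification at a 140 nm equivalent radius, cluster
  quantification (> 0.2 µm²), and radial signal distributions with FWHM
  (for a Gaussian of sd σ, FWHM = 2√(2 ln 2)·σ).
* **Ring fitting** — circle-Hough detection (sensitivity 0.85
  convention), mutual-nearest-neighbor 5′/3′ channel matching, bounded
  Levenberg–Marquardt fits of the two-Gaussian ring function
  `C₁ + C₂·exp(−(((x−a)/u₁)² + ((y−b)/v₁)²)) + C₃·exp(−(…u₂…))`,
  radius = center-to-outer-FWHM of the fitted model, 280 nm small/large
  cutoff, and 5′/3′ radius ratios.
* **Colocalization** — nucleus cropping, Pearson correlation, the
  mirrored-channel randomization null, object-overlap counting with
  percentages, averaged radial profiles of one channel around the
  other's particles, and confocal-style line scans.
* **Decay kinetics** — one-phase (`N(t) = n₀e^(−kt)`) and
  plateau-then-one-phase least-squares fits, half-life = ln 2 / k,
  AICc model selection.
* **Splicing / nascent reads** — regulated / non-regulated / ambiguous
  LSV stratification (|ΔPSI| > 5 % & P > 0.5 vs |ΔPSI| < 2 % & P = 0),
  binarization to two opposing main junctions, event classification
  (intron retention, alt 3′ss, alt 5′ss, cassette + subtypes), and
  strand-aware counting of soft-clipped polyA-evidence reads.
* **Synthetic data** — two-channel core–shell scenes (rings, disks,
  rod/aggregate clusters, SRSF5 speckles), decay series, SAM-style
  reads with non-templated A-tails, and LSV tables, all with ground
  truth and fully seeded.

## Worked example

Simulate a small field of ~360 nm particles, render, segment and
measure them, then fit a decay series:

```r
library(psmorph)

p <- scene_params(n_particles = 6, field_size = c(6000, 6000),
                  shell_radius_mean = 180, shell_radius_sd = 10,
                  channels = c("five_prime", "sphere"), seed = 42)
sc  <- simulate_scene(p)
img <- render_histogram(sc$localizations$sphere, pixel_size = 10,
                        blur_sigma = 30, extent = c(6000, 6000))
seg <- segment_image(img, blur_sigma = 10)
rec <- filter_particles(measure_particles(seg))
rec$size_class <- classify_size(rec)
rec[, c("label", "area_um2", "equiv_radius_nm", "roundness", "size_class")]
#>   label area_um2 equiv_radius_nm roundness size_class
#> 1     1    0.107             185     0.989      large
#> 2     2    0.126             200     0.945      large
#> 3     3    0.117             193     0.935      large
#> 4     4    0.132             205     0.931      large
#> 5     5    0.108             185     0.968      large
#> 6     6    0.116             192     0.959      large
```

All six simulated particles are recovered; their equivalent radii
scatter around the true 180 ± 10 nm, roundness is near 1 (they are
disks), and every radius exceeds the 140 nm cutoff, so all are
classed `large`.

```r
s <- simulate_decay_series(1, half_life = 44, plateau = 0,
                           timepoints = c(0, 60, 120, 240, 480),
                           noise_cv = 0.1, n_replicates = 3, seed = 42)
fit_one_phase(s)
#> decay_fit [one_phase]: n0 1.09, k 0.01586 /min, t0 0.0 min,
#>   half-life 43.7 min (AICc -87.8)
```

The fitted half-life (43.7 min) recovers the simulated 44 min within
the noise of a 5-timepoint, 3-replicate course.

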