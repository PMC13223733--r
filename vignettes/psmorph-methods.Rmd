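---
title: "Methods: paraspeckle morphometry, ring fitting, colocalization and downstream kinetics"
author: "psmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paraspeckle morphometry, ring fitting, colocalization and downstream kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmorph)
```

# Scope

`psmorph` implements the quantitative downstream pipeline of a
super-resolution study of nuclear paraspeckles (PS) — NEAT1_2-scaffolded
condensates whose 5' and 3' transcript ends form a shell around a core —
and their crosstalk with SR-protein nuclear speckles (SRSF5). The
package takes rendered super-resolution images or localization tables as
input and covers: localization post-processing and rendering,
threshold-based particle morphometry, single-particle ring-model
fitting, two-channel colocalization with a mirrored null,
transcription-shutoff decay kinetics, polyA-evidence read counting, and
binary stratification of local splicing variations. A synthetic-data
module generates every input with machine-readable ground truth, which
is what all tests run on.

# The synthetic scene generator

No generative model for PS images is published; the generator's
distributional choices are explicit stand-ins, chosen to reproduce the
*geometric* structure the measurements rely on, not the photophysics of
acquisition.

* **Shell channels** (5', 3'): localizations at radius
  `Normal(R, thickness / 2.355)` around the particle center with uniform
  angle — `shell_thickness` is the FWHM of the radial label
  distribution. Default `R ~ Normal(180, 10)` nm emulates the canonical
  ~360 nm PS sphere of untreated cells; thickness defaults to 50 nm, a
  plausible effective width once probe size and localization precision
  are folded in.
* **Core / sphere channels**: uniform disks of radius `0.6 R` (middle
  region label) or `R` (a label covering the whole particle).
* **Localization noise**: isotropic Gaussian, default 5 nm — typical
  dSTORM/DNA-PAINT precision after filtering.
* **Clusters**: `rod` places k sphere centers on a line at spacing 2R
  (the cylinder-like chains seen for PS clusters); `aggregate` packs k
  centers by hard-sphere rejection at contact distance 2R.
* **SRSF5**: uniform nucleoplasmic background, Gaussian speckle blobs,
  and optionally a shell-enrichment ring at 100–180 nm from a decorated
  fraction of PS centers.
* **Acquisition metadata** (frame, photons, ellipticity, PSF width) are
  drawn from fixed plausible distributions; they exist so that filtering
  and linking have realistic columns to operate on, nothing more.

What the generator does **not** emulate: camera frames, blinking
photophysics, drift, chromatic offsets, out-of-focus light, or real
transcription kinetics. Passing tests therefore demonstrate correctness
of the *measurement operators* on data satisfying their geometric
assumptions — not performance on raw microscope output.

Every generator takes an explicit seed; two calls with equal parameters
and seed are identical, and no generator touches the global RNG state
(seeding is scoped via `withr`).

# Rendering conventions

Localization quality filters are closed ranges on ellipticity and PSF
width (defaults 0–0.15 and 0.8–1.15 px, the NEAT1-channel settings;
protein channels typically use 0–0.2 / 0.7–1.3 px). Linking merges
re-appearances within a radius across frame gaps of up to
`max_dark_frames` (default 2) into photon-weighted mean positions with
summed photons. The linking radius is a plain nm parameter: in
acquisition pipelines it is commonly derived from the localization
precision (e.g. 4x a nearest-neighbour precision estimate), but that
estimate needs raw repeated-localization data, which is out of scope
here, so the radius is supplied directly.

Histogram rendering uses half-open pixels — zero-based pixel `i` covers
`[i*px, (i+1)*px)` nm — with origin top-left, y downward, default 10
nm/px. The unblurred image sum equals the number of in-field
localizations; the optional Gaussian blur uses a normalized kernel with
circular boundary, so blurring conserves total intensity exactly.

# Morphometry

Segmentation blurs with a 10 nm Gaussian and thresholds. The original
workflow used a manually chosen fixed threshold; for reproducibility
without a human in the loop the default here is Otsu's method on the
blurred image, with a numeric override, and the value used is always
recorded in the result. Connected components use 8-connectivity.

Per object: area (pixel count x px^2, reported in um^2), centroid,
major axis of the second-moment fitted ellipse (the particle-analyzer
convention), roundness

$$\mathrm{Round} = \frac{4\,\mathrm{Area}}{\pi\,\mathrm{major\_axis}^2},$$

and the equivalent-disk radius $\sqrt{\mathrm{Area}/\pi}$. Individual
PS are filtered at area > 0.025 um^2 *and* roundness > 0.8 (both
strict); clusters at area > 0.2 um^2. The small/large split uses a
fixed 140 nm threshold on the equivalent radius — the equivalent radius
is used because "radius" is otherwise undefined for irregular objects —
with the boundary value classed as small.

The radial signal distribution averages intensity over concentric
annuli, peak-normalizes, and reports FWHM by linear interpolation of
the half-maximum crossings flanking the peak. When the peak sits at
zero distance (a filled object) the profile is the positive half of a
symmetric peak and FWHM is twice the outer crossing; a profile with no
crossing (uniform image) is flagged undefined rather than given a
number. On a radial Gaussian of sd $\sigma$ this reproduces
$2\sqrt{2\ln 2}\,\sigma$ within ~1% at 5–10 nm sampling.

# Ring-model fitting

Ring-shaped 5' signals are detected by a circle Hough transform:
intensity-weighted votes over a radius range, one accumulator per
radius normalized by circumference, smoothed, with the candidate
threshold mapped from the sensitivity parameter as
`(1 - sensitivity) x max(accumulator)` (higher sensitivity admits
weaker rings; default 0.85). Two robustness measures were needed to
make the transform usable on rendered localization images, both exposed
as parameters: voting pixels are selected by a fraction-of-maximum
floor (default 0.1) rather than Otsu, which can swallow dim rings in
scenes of unequal brightness, and every candidate is verified by
angular coverage (default: signal in >= 60% of 24 sectors at its
radius), which rejects the partial-arc accumulator artifacts that
otherwise dominate. Non-maximum suppression operates in (x, y, r):
concentric candidates at clearly distinct radii (beyond 60 nm) survive
at one center.

5' and 3' detections are paired by mutual nearest neighbors within 300
nm (the pairing rule is not specified in the original description
beyond "matched"; mutual-NN is the standard conservative choice).

The fitted model is the published two-Gaussian ring function

$$C_1 + C_2\,e^{-\left(((x-a)/u_1)^2 + ((y-b)/v_1)^2\right)} +
  C_3\,e^{-\left(((x-a)/u_2)^2 + ((y-b)/u_2)^2 +
  ((y-b)/(v_1 u_2/u_1))^2\right)}$$

implemented exactly as printed (default `variant = "printed"`). The
third exponential contains the y offset twice and reuses `u2` for x and
y — very likely a typographical variant of a symmetric form; since the
original analysis script is not available, a `"symmetric"` variant
(x scaled by `u2`, y by `v_1 u_2 / u_1`) is offered behind the flag,
but fidelity to the printed form is the default.

Optimization is bounded Levenberg–Marquardt (`minpack.lm`), max 500
iterations, convergence at relative cost change < 1e-8, with
`C2 >= 0` and positive widths. The published initialization ordering
(`u1 = v1 = r/2`, `u2 = r`) makes the *positive* Gaussian the narrow
one, which cannot produce a ring under the `C2 >= 0` constraint; the
optimizer therefore runs from both width orderings — the published one
and the swap — and keeps the lower-residual solution. Degenerate fits
(no positive structure above the offset, e.g. on a flat patch) are
flagged and excluded from downstream statistics.

The particle radius is the distance from the fitted center to the
**outer half-maximum** of the background-subtracted, angularly averaged
profile of the fitted model, found numerically (1–2000 nm grid with
linear interpolation of the last downward crossing). Particles are
classed small/large at a 280 nm cutoff on the 5' radius (boundary ->
large), and the 5'/3' ratio is the ratio of the two radii.

**Known limitation.** For data whose radial profile is a thin Gaussian
annulus, the best achievable centered two-Gaussian representation has a
noticeably fatter outer tail than the annulus itself: its outer-FWHM
radius saturates near ~240 nm for a 180 nm-peak ring, essentially
independently of shell width. The model-based radius therefore carries
a positive offset relative to the annulus peak radius. This is a
property of the estimator (the model's tails cannot decay faster than a
centered Gaussian), not of the optimizer: on data generated from the
model itself, all eight parameters are recovered to machine precision
noiselessly and the radius to within 5% at SNR 5. In practice the
radius remains a strictly monotone, reproducible proxy for ring size,
and the offset cancels in the 5'/3' *ratio*, which is the main
comparative statistic. Absolute radii should be compared only within
one model variant and acquisition convention.

# Colocalization

Images are first restricted to the nucleus (pixels outside the mask are
excluded from every statistic). The Pearson coefficient is the standard
product-moment correlation over the shared finite pixel set. The null
is **mirror randomization**: the reference channel flipped along the
vertical image axis, which preserves all single-channel statistics
while destroying registration; the operation is an involution and is
applied to the NEAT1 channel by convention.

Object-overlap counting segments both channels (defaulting to the
morphometry module's blur/Otsu settings, always logged), counts
reference objects with 8-connectivity, and calls an object overlapping
when it shares at least one pixel with the other channel's objects (a
minimum-shared-pixel variant is available; the one-pixel criterion is
the permissive reading of an unspecified rule, stated explicitly).
Percentages are `100 * n_overlap / n_total`, undefined (flagged) when
the reference mask is empty.

Averaged radial profiles around segmented PS centers use per-annulus
*mean* intensity (area normalization first, so a uniform field gives a
flat profile), then per-particle peak normalization, then averaging
across particles per distance bin. The published profiles use an
undefined "normalized integrated" intensity, so only profile *shapes*,
not absolute heights, are comparable. Line scans are bilinear
interpolations between two endpoints.

# Decay kinetics

Two models are fitted to transcription-shutoff series:
one-phase decay $N(t) = n_0 e^{-kt}$ and plateau-then-decay
($N(t) = n_0$ for $t \le t_0$, exponential after), with
`half_life = ln 2 / k` by construction in every returned fit. Fitting
is least squares on the natural scale (the convention of the graphing
software the published fits imply), with a log-scale option that is
robust to multiplicative noise. The plateau breakpoint makes the
objective non-smooth, so $t_0$ is profiled over a 60-point grid across
the observed range and refined by golden-section search, with $n_0$
and $k$ fitted conditionally at each candidate; a fit whose $t_0$
reaches the penultimate timepoint (plateau unidentifiable) or whose $k$
collapses to its bound (no decay) is flagged. Model choice is by
small-sample-corrected AICc (error variance counted as a parameter),
ties to the simpler model.

The model-selection simulation study uses 8 timepoints with dense early
sampling (0, 20, 40, 60, 90, 120, 240, 480 min): a <= 60 min plateau is
identifiable only if several samples fall inside the delay period, so
this is the design a kineticist would choose; sparse designs sampling
hourly cannot separate the models reliably at 5% noise.

# Splicing stratification and polyA evidence

A local splicing variation (LSV) is *regulated* when its
maximum-|deltaPSI| junction exceeds 5% and the change probability
exceeds 0.5, *non-regulated* below 2% with probability exactly 0, and
*ambiguous* otherwise — the 2–5% gap deliberately yields a third class
rather than silently dropping rows. Binarization ranks junctions by
|deltaPSI| and retains an LSV when the second junction explains at
least 50% of the strongest junction's change *with opposing sign*
(the absolute-ratio-plus-opposing-signs reading of an ambiguous verbal
rule; stated here explicitly). Event classification combines the main
junctions of a regulated source and target LSV: intron-retention flags
win; two junctions sharing a donor are an alternative 3' splice site,
sharing an acceptor an alternative 5' splice site; a shared skip
junction plus flanking inclusion junctions around a middle exon is a
cassette. Cassettes are sub-classified against a transcript model
(terminal variable exon -> alternative first/last exon; more than the
binary junction pattern -> complex; no model -> complex still callable,
first/last reported unknown).

PolyA-evidence reads carry a non-templated adenosine tail: a 3'
soft-clip of >= 6 nt with >= 80% A (T on the 5' clip of reverse-strand
alignments). The thresholds are not given in the original description;
6 nt / 80% matches common polyA-site-calling practice and both are
exposed as parameters. Template-encoded A-runs never count (they are
aligned, not clipped). A read is attributed to a region by its aligned
3' end. Fold changes against a reference sample use a +1 pseudocount.
Coordinates are 1-based closed at all table/SAM interfaces.

# Numerical choices and degenerate inputs

* Blur kernels are normalized and circular — intensity sums are exact
  invariants, used as test oracles.
* Otsu thresholds are computed at 256 levels on the blurred image scaled
  to its maximum; an all-zero image yields zero labels without error.
* Zero-variance channels, empty reference masks, profiles without a
  half-maximum crossing, non-converged or non-ring fits, and zero-decay
  series all return flagged `NA`s rather than numbers.
* Boundary conventions: equivalent radius exactly 140 nm -> small; ring
  radius exactly 280 nm -> large; filter thresholds strict; linking gap
  of `max_dark_frames + 1` frames still links.

# Problem sizes

The test-suite and acceptance computations run at deliberately desk
scale: 30-particle fields at 10–20 nm/px (~600–1300 px square), 100
ring-fit replicates, 500 decay simulations for bias and 2 x 200 for
model selection, 1000 random LSVs against the exhaustive oracle, and
contingency reconstructions up to 1393 objects. These sizes make every
statistical tolerance (3 standard errors, binomial CIs) meaningful
while keeping a full run in minutes on one core.
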