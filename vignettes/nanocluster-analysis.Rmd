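---
title: "Quantifying PSD95 nanocluster architecture with nanopsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PSD95 nanocluster architecture with nanopsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopsd)
```

## The measurement problem

Excitatory synapses concentrate the scaffold protein PSD95 in the
postsynaptic density (PSD). Super-resolution microscopy shows that within
each PSD, PSD95 is further condensed into one or more *nanoclusters*
(NCs) of roughly 100–200 nm — structures invisible to diffraction-limited
imaging. Two orthogonal modalities resolve them: gated STED (g-STED)
microscopy produces pixel images at ~85 nm lateral resolution alongside a
registered ~240 nm confocal channel, and PALM produces tables of
single-molecule localisations with ~40 nm precision. The scientific
quantities of interest are the sizes and shapes of PSDs and NCs, the
number of NCs per PSD (the synapse "subtype": 1NC, 2NC, 3+NC), the
spatial statistics of NC positions, the apposition of pre- and
postsynaptic puncta, and how all of these vary across brain sub-regions
and with distance along the dendritic tree.

`nanopsd` implements this analysis chain as an open, tested pipeline:

* a **scene simulator** that generates ground-truth synaptic fields and
  renders them as confocal/g-STED image pairs, PALM localisation tables,
  or two-channel juxtaposition fields;
* a **segmentation core** (detection, seeded-watershed splitting,
  morphometry) applied to both pixel modalities;
* a **PALM pipeline** (2D Gaussian peak fitting, DBSCAN cluster
  definition, nearest-neighbour-weighted rendering);
* **morphometry** operators (line-profile FWHM, ellipse axes, subtype
  classification);
* **spatial statistics** (pair-correlation function with Monte-Carlo
  envelopes, juxtaposition analysis with a rotation control);
* **cohort statistics** (per-mouse medians, ANOVA with Tukey contrasts,
  distance gradients).

Because suitable raw brain-tissue image sets are rarely public, the
simulator is not a test fixture but a first-class component: it defines
the study conditions under which every recovery claim about the pipeline
is scored.

## The synthetic scene model

A scene is a rectangular field (default 20 × 20 µm) populated with PSDs
whose count is Poisson with density 19.2 per 20 µm² — the density
reported for the CA1 stratum oriens neuropil. Each PSD draws a number of
NCs from a subtype mixture (default 63.7 / 24.3 / 9.0 / 3.0 % for 1–4
NCs; the open-ended "3+" class, reported at 11.9 %, is split 3:1 between
3- and 4-NC synapses as a simulator choice). NC centres within a PSD are
placed by rejection sampling so that **every pairwise separation lies in
100–300 nm**, the reported within-PSD NC spacing. Rejection sampling is
capped at 10⁴ proposals per NC; a geometrically unsatisfiable request
(e.g. four pairwise-near-equal separations in the plane) fails loudly,
naming the PSD.

Each NC is an ellipse with log-normal axes around medians of 86 × 189 nm
(the manually measured NC short/long axes), dispersion 0.25 on the log
scale so the medians are preserved exactly, and uniform orientation. The
short ≤ long invariant is enforced by sorting each drawn pair; with
dispersion 0.25 the induced distortion of the marginal medians is
negligible. The intensity profile is a uniform filled ellipse by default
— matching the area-based morphometry downstream — with an elliptical
Gaussian profile available via `nc_profile = "gaussian"`.

Two brightness conventions are provided. `"constant_count"` (default)
gives every NC the same expected molecule count, which makes recovery
tests sensitive to brightness-independent detection. `"constant_density"`
scales the count with NC area, i.e. conserved molecular packing — the
biologically motivated regime in which all NC interiors render at the
same intensity. The PSF-free diameter-recovery analyses use the latter,
because with sharp-edged uniform objects an unbiased footprint requires a
threshold at half the interior level (the same half-maximum logic as a
FWHM measurement), and a half-max threshold is only globally meaningful
when interiors share one level.

Rendering integrates the profile over each pixel footprint with 4 × 4
supersampling, renormalises each NC's rasterised mass to exactly its
molecule count (so integrated intensity is conserved to machine precision
and exactly linear in molecule count), convolves with an isotropic
Gaussian PSF specified by its FWHM (240 nm confocal, 85 nm g-STED;
FWHM = 2√(2 ln 2) σ), and applies noise: Poisson shot noise at
`poisson_gain` photons per intensity unit plus additive Gaussian read
noise. The default gain of 200 puts bright puncta at a few hundred
detected photons per peak pixel, a typical regime for confocal/g-STED
imaging of eGFP-tagged scaffold proteins; it is a realism choice, not a
fitted constant. NCs smaller than the supersampling grid (point sources)
deposit their whole mass at the nearest pixel.

PALM simulation draws a Poisson number of events per NC (default mean
100), positions them uniformly inside the ellipse, and perturbs each with
isotropic Gaussian error of σ = precision / 2.355 where the precision is
the conventionally quoted ~40 nm figure. Uniform false localisations are
added at `background_rate` (default 1 µm⁻²). Every signal event carries
its true parent NC/PSD id so recovery can be scored exactly.

Every stochastic operation takes an explicit integer seed and leaves the
global RNG untouched. Internally, each operation hashes a tag with the
seed (`scene`, `palm`, `render_noise`, …) so that calling two operations
with the *same* seed never replays overlapping random streams — without
this, a scene and an "independent" second channel simulated with one seed
would be spuriously correlated.

### What the simulator does and does not emulate

It reproduces the densities, sizes, spacings, mixtures, PSF widths, pixel
size, localisation precision and noise regimes of the imaged tissue. It
does **not** model: 3D structure (scenes are planar, like the analysed 2D
sections); dendritic or laminar spatial organisation of PSDs (placement
is uniform, so near-coincident synapses occur at Poisson rates);
fluorophore photophysics (no blinking kinetics or repeated-emitter
merging); spatially varying background; or chromatic/registration error
between channels. Consequently, passing recovery tests demonstrate that
the *pipeline* is calibrated under the stated geometric and noise
conditions — they cannot certify behaviour under tissue-specific
artefacts absent from the model.

## Segmentation

The detection chain mirrors the commercial Imaris Cell procedure the
field uses, re-implemented openly:

1. **Prefilter** — Gaussian smoothing at σ = 40 nm, applied to both
   channels of the g-STED data set (it is required for stable peak
   detection on shot-noise-limited images; applied to the confocal
   channel for the same reason).
2. **Background subtraction** — the vendor semantics of "background
   subtraction with a diameter" are not public. We subtract a Gaussian
   low-pass of the image with FWHM equal to the stated diameter (140 nm
   for both g-STED stages) and clip negatives. This removes structure
   broader than the diameter, is analytically testable, and reproduces
   the intended local-background removal scale.
3. **Threshold** — Imaris thresholds are set interactively and leave no
   portable value; the default is a configurable fraction (10 %) of the robust
   image maximum (99.9th percentile of the background-subtracted image).
   An absolute threshold is available. For PSF-free sharp-edged objects
   the appropriate boundary rule is half the interior level
   (`threshold_fraction = 0.5`), for the same reason FWHM is measured at
   half maximum; at 10 % a sharp rim contributes ≈ (0.5 − t) extra
   pixels per perimeter pixel and inflates areas.
4. **Components** — 8-connected labelling (4-connected labels merged
   across diagonal adjacencies), consistent with watershed on square
   grids.
5. **Seeded watershed** — seeds are 3 × 3 local maxima of the image
   smoothed at σ = seed diameter / 4; within each component, maxima
   closer than the seed-point diameter are merged into the brighter one
   (ties broken by pixel index), which is what makes the seed diameter
   the splitting granularity (400 nm for PSDs, 160 nm for g-STED NCs).
   Components with no surviving maximum are seeded at their brightest
   pixel, so every component yields at least one object. Fragments are
   grown with EBImage's seeded propagation on the smoothed intensity.
6. **Filters** — fragments under the minimum pixel count (30 px PSDs,
   10 px NCs) are removed, as are objects touching the field border.

Morphometry reports pixel count, area, circle-equivalent diameter
(2√(area/π)), intensity-weighted centroid, second-moment ellipse axes
(full axis = 4√eigenvalue, with a px²/12 footprint correction; collinear
masks report the pixel extent along the principal axis and a one-pixel
short axis), aspect ratio (short/long ∈ (0, 1]), and mean/integrated
intensity. Intensity statistics are always measured on the raw channel,
not the background-subtracted one, because regional intensity comparisons
are part of the science and high-pass filtering would distort them.

NC→PSD assignment is by centroid containment in the PSD mask, falling
back to greatest mask overlap (ties to the larger overlap, then the lower
PSD label). PSDs without any NC are excluded from the records — the
excluded fraction is reported (in practice this filter removes on the
order of 10 % of PSDs) — and unassignable NCs are discarded and counted.

## The PALM pipeline

`fit_peaks()` localises sparse emitters by Levenberg–Marquardt
least-squares fits of a free 2D Gaussian (x, y, σ, amplitude, offset) in
a window around candidates above median + 5 MAD; non-convergent,
out-of-window or implausible-width fits are rejected and counted, and the
per-event precision is the fitted positional standard error.

`cluster_localisations()` is DBSCAN in nm space, with the point itself
counted towards `min_points`. The implementation is grid-indexed for
near-linear scaling, but its semantics are fixed to be order-independent:
clusters are connected components of the core-point graph, border points
join their lowest-row-index core neighbour, and labels are canonicalised
by first appearance. `dbscan_reference()` is an intentionally naive
pairwise-matrix implementation of the same definition, kept as the
independent cross-check. Because there is no field-standard choice of
eps/min-points, the defaults (eps = 100 nm ≈ 2.5 × the localisation
precision, min_points = 10) are exposed in the parameter object and
echoed into output metadata.

The "nearest-neighbour coefficient" weighting used for rendering has no
canonical formula; here it is the inverse of
an event's mean distance to its k = 5 nearest within-cluster neighbours,
normalised by the median coefficient of its cluster (per-cluster
normalisation is the default; a global mode is provided as the other
defensible convention). Each clustered event is drawn as a 40 nm
disc — the displayed fitting precision — antialiased by area coverage;
overlapping discs sum; noise events are not rendered.

Segmentation of the rendered image follows the g-STED logic with the
PALM-specific scales: PSD channel blurred with the large 250 nm kernel
and background-subtracted at 140 nm with a 250 nm seed; NC channel
smoothed at 40 nm, background-subtracted at 70 nm with a 70 nm seed. The
PALM threshold fraction defaults to 0.2: it was calibrated once by
recovering known NC sizes from simulated localisation tables — the
in-silico counterpart of calibrating a detection setting against manual
quantifications — and is exposed in `palm_params()`. Per-object
localisation counts and densities are attached, and the event budget is
conserved and reported (clustered = assigned + unassigned).

## Spatial statistics

The pair-correlation function g(r) is estimated on a binned grid (10 nm
bins to 1 µm) with translation edge correction: each ordered pair at
displacement (dx, dy) contributes 1/((W−|dx|)(H−|dy|)), and bin sums are
divided by λ² times the annulus area, λ = n/|W|. The binned (rather than
kernel-smoothed) estimator was chosen because the envelope logic is
pointwise per radius and the estimator then has an exact brute-force
oracle (`pair_correlation_reference()`). Envelopes are the pointwise
extrema of g over 49 simulated binomial (fixed-n) CSR patterns in the
same window; radii where the observed g exceeds the upper envelope are
flagged significantly clustered, a 2 % pointwise test per radius. Both
the peak radius and the span of significant radii are reported, since a
"maximal clustering range" can reasonably denote either. Input points
are intensity-weighted NC centroids.

Juxtaposition declares an A-punctum paired when any B centre lies within
600 nm centre-to-centre. Chance apposition is estimated by rotating
channel B 90° clockwise about the field centre and re-measuring; for the
square fields used here the rotation is measure-preserving, and the
excess (measured − control) is the bias-corrected apposition. Note the
excess underestimates a true paired fraction by half the chance rate, so
quantitative recovery of a known fraction requires sparse fields.

## Cohort statistics

The statistical unit is the mouse: structure-level measures are reduced
to a per-mouse median, then summarised as mean ± SD across mice (n = 3
in the emulated design), and group comparisons are one-way ANOVA with
post-hoc Tukey contrasts on those per-mouse values. Subtype fractions
are computed per mouse and averaged the same way. Distance gradients
(20 µm bins over 20–140 µm from the soma layer) report Pearson's r over
image-level observations, matching the error structure of per-image
sampling; bin means are returned alongside. The subtype-weighted
consistency check —
`subtype_consistency_report(c(269, 412, 525), c(63.7, 24.3, 11.9))` —
ties the per-subtype PSD diameters to the whole-population median by a
fraction-weighted mean rounded to the nearest nm.

## Numerical choices and degenerate inputs

* Gaussian fits (profiles and peaks) use `minpack.lm` with up to 200
  iterations; profile fits are invalid when non-convergent, when
  r² < 0.5, or when the profile has no peak (constant input).
* FWHM ↔ σ conversions use the exact 2√(2 ln 2) factor throughout.
* Seed-merging and border-point ties break deterministically (brighter
  first, then lower pixel/row index).
* Empty foregrounds, empty localisation tables and blank images yield
  empty record sets, not errors; impossible geometry and invalid
  configurations fail before any computation.
* Images are matrices with rows = y, columns = x, origin at the field
  corner, half-open pixel extents; the centre of pixel (1,1) is at
  (pixel/2, pixel/2) nm. All lengths are nm internally.

## Problem sizes used in the validation suites

The packaged checks use six 20 × 20 µm g-STED fields (≈ 2300 PSDs) for
subtype-fraction recovery, two 15 × 15 µm PSF-free fields (≈ 500 NCs)
for g-STED diameter recovery, two 10 × 10 µm PALM fields (≈ 250 detected
NCs, ~100 events per NC) for the localisation path, 25 sparse fields per
condition for the juxtaposition control, 49-simulation envelopes for the
pair-correlation checks, and 100 random instances (≤ 500 points) for the
DBSCAN/oracle equivalence. These sizes give binomial/sampling errors
comfortably below the tolerances being checked while keeping the default
validation run to a few minutes.

## Known limitations

* PSD merging: at realistic densities some PSD pairs fall within the
  400 nm seed diameter and are merged by construction, slightly
  depressing the recovered 1NC fraction; the same limitation applies to
  the procedure being re-implemented.
* The Imaris "background subtraction diameter" and threshold semantics,
  the NN-coefficient formula, and the DBSCAN parameters are
  reconstructions of undocumented vendor behaviour; all are exposed as
  configuration rather than hidden constants.
* PALM diameters reflect the disc size, smoothing and background scales
  as much as the underlying cluster extent; cross-modality agreement is
  parameter-mediated rather than automatic.
* No drift correction, multi-emitter fitting, 3D fitting, or
  deconvolution.
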