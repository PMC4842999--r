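# nanopsd

Quantification of PSD95 nanocluster architecture from super-resolution
microscopy, for neuroscientists studying the nanoscale organisation of
excitatory synapses.

Excitatory synapses concentrate the scaffold protein PSD95 into a
postsynaptic density (PSD), and super-resolution imaging resolves each
PSD into one or more ~100–200 nm **nanoclusters (NCs)**. The number of
NCs per PSD classifies synapses into subtypes (1NC / 2NC / 3+NC) and is a
principal axis of synaptic diversity across hippocampal circuits.
`nanopsd` is an open, tested R implementation of the full quantification
chain for the two modalities used to measure this:

* **g-STED path** — registered confocal (~240 nm FWHM) / g-STED (~85 nm
  FWHM) image pairs: Gaussian prefilter, local background subtraction
  (140 nm), thresholding, 8-connected components, seeded-watershed
  splitting at seed-point diameters of 400 nm (PSDs) and 160 nm (NCs),
  pixel-count and border filters, morphometry, and NC→PSD assignment by
  mask containment.
* **PALM path** — single-molecule localisation tables (~40 nm
  precision): least-squares 2D Gaussian peak fitting, DBSCAN cluster
  definition, nearest-neighbour-weighted rendering of events as 40 nm
  discs, and the same segmentation core with PALM-specific scales.
* **Statistics** — line-profile FWHM (2√(2 ln 2)·σ) and ellipse
  morphometry; pair-correlation function g(r) to 1 µm with translation
  edge correction and 49-simulation Monte-Carlo CSR envelopes;
  object-based juxtaposition at a 600 nm centre-to-centre threshold with
  a 90° rotation control; per-mouse median aggregation with one-way
  ANOVA + Tukey contrasts and distance-from-soma Pearson gradients.
* **Scene simulator** — ground-truth synaptic fields (Poisson PSD counts
  at 19.2 per 20 µm², NC subtype mixtures, elliptical NCs with 86 × 189
  nm median axes, 100–300 nm within-PSD spacing) rendered through
  Gaussian PSFs or as localisation tables, used to calibrate and validate
  every stage against known truth.

See `vignettes/nanocluster-analysis.Rmd` for the methods account and
design decisions.

## Worked example

Simulate a 10 × 10 µm field at CA1 stratum oriens conditions, render the
confocal/g-STED pair, segment it, and analyse NC clustering:

```r
library(nanopsd)

cfg    <- sim_config(field_width = 10000, field_height = 10000)
scene  <- sample_scene(cfg, seed = 42)
field  <- render_field(scene, cfg, seed = 42)
records <- run_sted_workflow(field$confocal, field$sted)
print(records)

median(records$psds$equivalent_diameter)   # nm
median(records$ncs$equivalent_diameter)    # nm

pcf <- pcf_with_envelopes(records$ncs[, c("centroid_x", "centroid_y")],
                          c(10000, 10000), n_sims = 49, seed = 1)
```

This prints:

```
<psd_records> 62 PSDs (0.0% excluded NC-less), 90 NCs (0 discarded)

 1NC  2NC 3+NC
62.9 30.6  6.5
median PSD diameter: 299 nm
median NC diameter:  189 nm
g(r) peak 11.6 at r = 245 nm; significant clustering over 175-565 nm
```

Reading the output: 62 PSDs were detected on the confocal channel and all
retained (none lacked a detectable NC in this small field; ~10 % NC-less
exclusions are typical at scale). The subtype row gives the percentage of
PSDs with one, two, or three-plus NCs — dominated by single-NC synapses,
as generated. Equivalent diameters are circle-equivalent sizes of the
segmented masks; g-STED NC diameters exceed the underlying ~128 nm truth
because of the 85 nm PSF, exactly as in real imaging. The
pair-correlation peak at ~245 nm reflects the 100–300 nm within-PSD NC
spacing, and radii where g(r) exceeds the 49-simulation upper envelope
are significantly more clustered than random.

The PALM path runs analogously from a localisation table:

```r
tab <- simulate_palm(scene, cfg, seed = 42)
tab <- cluster_localisations(tab, eps = 100, min_points = 10)
rec <- run_palm_workflow(tab)
```

`run_pipeline(pipeline_config(...))` executes either modality end to end
with full parameter provenance, and `inst/scripts/nanopsd.R` exposes
`simulate`, `segment-sted`, `pcf` and `fwhm` subcommands for shell use.

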