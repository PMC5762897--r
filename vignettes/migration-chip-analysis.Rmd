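---
title: "Quantifying microfluidic migration assays and tumor-initiating cell frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microfluidic migration assays and tumor-initiating cell frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migratic)
```

## The assay and the quantities it produces

Tumor-initiating cells (TICs) are commonly enriched by surface or enzymatic
markers that correlate only loosely with the one property that defines them:
the ability to seed a new tumor. An alternative is functional selection by
migration — epithelial-to-mesenchymal transition couples enhanced motility to
tumor-initiating potential — using a microfluidic chip in which single cells
are loaded at the entrances of hundreds of narrow migration channels and
migrate toward a serum chemoattractant in a central channel. Cells that
traverse a channel ("migratory") and cells that stay near the loading side
("non-migratory") can then be retrieved separately and compared: by
implantation at limiting dilution (stem-cell frequency), by transcriptome
contrast across cell lines, and by survival data mining for genes whose
expression change is concordant with patient prognosis.

`migratic` implements this computational stack end to end:

* **chipmodel** — device geometry, the linear chemoattractant gradient, and
  a seeded, ground-truthed synthetic image generator;
* **migration_quant** — the five-step automated analysis (TIFF import,
  channel segmentation, cell identification, false-event exclusion,
  migration-distance calculation) plus population splitting and
  tumor-sphere counting;
* **assay_stats** — Mann-Whitney U comparisons, box summaries with
  5th/95th-percentile whiskers, significance stars;
* **stemness** — single-hit Poisson limiting-dilution analysis with Wald
  confidence intervals;
* **prioritize** — per-line significance/fold-change filtering, cross-line
  directional overlap, and median-split Kaplan-Meier survival concordance.

## Device model

The default `device_geometry()` is a 900-channel chip: 450 migration
channels per side, each 30 µm wide and 1 mm long, on a 40 µm pitch, joining
two outer loading channels to a central retrieval channel. Channel heights
(5 µm migration, 40 µm main) are carried as metadata only: the micrographs
the pipeline analyzes are 2-D top views, so rendering and analysis are 2-D.
Because cancer cells (10–15 µm diameter) exceed the 5 µm channel height,
cells start at channel entrances; migration distance is measured along the
channel axis from the entrance line, increasing toward the central channel.

At steady state the chemoattractant concentration is linear in position
(1-D diffusion between fixed boundary concentrations), which
`linear_gradient()` evaluates exactly; its second differences vanish to
machine precision on any uniform grid.

The pixel calibration defaults to 1 µm/px. The imaging objective's true
scale is configurable (`pixel_size_um`); the default makes pixel and
micrometer coordinates coincide, which keeps tests and worked examples
legible.

## The synthetic-image generator

`sample_scene()` places cells with known channel assignment, migration
distance, viability, radius (5–7.5 µm), and peak fluorescence intensity
(uniform integers 120–220, comfortably above the default detection
threshold of 50), then `render_scene()` draws each cell as a hard disk with
a one-pixel anti-aliased rim: live cells into the FITC (live) plane, dead
cells into the TRITC (dead) plane, and everything plus the channel layout
into the bright field. Gaussian read noise of configurable standard
deviation is added and intensities clipped to 8 bits. Everything is
deterministic under the scene seed, and the caller's RNG state is never
disturbed.

Three modelling choices matter for interpretation:

* **Cell centers snap to the pixel grid.** A disk centered on a whole pixel
  has a symmetric footprint, so its detected centroid equals its true
  center and the noise-free pipeline recovers distances *exactly*. This is
  what makes the zero-error oracle tests sharp instead of
  tolerance-smeared.
* **Debris is defined operationally.** Debris objects are small (2 µm
  radius, ≈ 13 supra-threshold pixels) and dim, strictly below the 20-pixel
  cell-calling minimum — size is the testable axis on which the real
  program excludes noise, debris, and device defects.
* **Distance distributions.** Four families are provided
  (`point_mass_at_entrance`, `uniform`, `exponential`, and `two_component`,
  in which a Bernoulli fraction of cells traverses the full channel and the
  rest follow a truncated exponential). The two-component family emulates
  the observed heterogeneity: a small migratory subpopulation reaching the
  central channel against a non-migratory bulk.

The generator does **not** emulate optics (no point-spread function, no
photobleaching, no bright-field texture), 3-D structure, cell morphology,
or time-lapse dynamics — a single end-point frame is produced, matching how
the 24-hour assay is scored. Passing tests therefore demonstrate
correctness of the *algorithmic* pipeline on images whose ground truth is
known, not robustness to every artifact of real microscopy.

## The automated counting pipeline

`quantify_device()` chains the five stages:

1. **Import** (`load_image`): 1- or 3-page 8-bit grayscale TIFF; pages are
   bright field, FITC, TRITC.
2. **Segmentation** (`segment_channels`): the chip layout is known by
   design, so segmentation is the geometry template, optionally registered
   by the integer translation maximizing overlap between the template
   channel mask and the bright field (exhaustive ±10 px search). This
   deliberately avoids an under-specified free-form detection problem.
3. **Cell identification** (`find_bright_pixels`, `detect_objects`): a
   pixel is "bright" when strictly above the plane threshold (default 50);
   a connected component ("block") of at least `min_bright_pixels`
   (default 20) bright pixels is one valid cell. Connectivity is
   8-connected by default (configurable to 4). Components are labelled
   per channel ROI with a two-pass union-find.
4. **False-event exclusion**: sub-minimum components are kept but classed
   `rejected` (debris, noise, defects); an accepted object whose footprint
   overlaps any supra-threshold TRITC pixel is classed `dead` and excluded
   from the frontier. Detection runs on the union of the FITC and TRITC
   masks so that dead cells are observed (and counted) before being
   excluded; classification against the TRITC mask is the most
   conservative overlap rule.
5. **Migration distance** (`channel_frontier`): the frontier is the live
   cell farthest from the entrance — the along-axis component of its
   centroid, clamped to [0, L]. Empty channels score 0 rather than
   missing, matching how non-migratory channels enter the box plots; a
   flag preserves the distinction. The centroid (not the leading edge) is
   used; on symmetric footprints the two differ by a constant radius and
   the centroid is the noise-robust choice.

Only the `central_window` channels per side nearest the array midline
(default the central 300 of 450, i.e. indices 76–375) are flagged
`used_in_analysis`, where loading and gradient conditions are most uniform.
`classify_populations()` then partitions analyzed channels into migratory
(frontier reached the central channel) and non-migratory sets.

Tumor-sphere counting (`count_spheres`) reuses the same machinery on
single-plane well images: components above threshold are measured by
equivalent-area diameter and counted when larger than 40 µm.

### Numerical behavior

On noise-free scenes the pipeline reproduces ground-truth live counts and
frontier distances with zero error (tested). With additive Gaussian noise
of sd 10 on every plane and default settings, the median relative frontier
error over hundreds of channels is far below the 3% agreement reported
between automated and manual measurement; `scripts/acceptance.R` recomputes
this on a 220-channel device (110 per side, 880 cells, two-component
distances, frontiers ≥ 50 µm entering the median). Detection counts are
monotone in both thresholds and the size minimum, and the frontier is
invariant to adding cells strictly behind it.

## Assay statistics

Migration distances are heavily non-normal (a point mass of non-migratory
channels plus a long tail), so group comparisons use the two-sided
Mann-Whitney U test. `mann_whitney()` computes U from joint midranks; for
tie-free samples with n₁+n₂ ≤ 12 the exact null distribution is enumerated
(at most 924 arrangements), otherwise the normal approximation with tie and
continuity corrections is used. The two paths agree to within 0.02 at
n₁ = n₂ = 6 (the continuity-corrected approximation is slightly
conservative near p = 0.5 at such tiny n; typical disagreement is ≈ 0.01),
and Monte-Carlo calibration at n = 20/20 puts the type-I error at
α = 0.05 within [0.04, 0.06]. Box summaries follow the reporting
convention: box at Q1/median/Q3, whiskers at the 5th and 95th percentiles,
mean and min/max alongside; the quantile convention is fixed to linear
interpolation between order statistics (`stats::quantile` type 7) and
stated here because plotting software defaults differ. Significance stars
are strict: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05. A pooled
two-sample t test (`two_sample_t`) is included for bar-graph comparisons
such as sphere-formation rates, which conventionally use the classical
Student form.

## Limiting-dilution analysis

Under the single-hit Poisson model an implant of dose *d* cells is positive
with probability 1 − exp(−*f d*), where *f* is the stem-cell frequency.
With a single dose group the MLE is closed-form, *f* = −ln(1 − k/n)/d;
with several groups `estimate_frequency()` maximizes the complementary
log-log binomial likelihood in θ = ln *f* by Newton iteration (tolerance
1e-10), which matches the closed form to 1e-8 and an independent
`glm(binomial("cloglog"))` fit. Degenerate tables are flagged rather than
estimated: all-negative outcomes report frequency 0 (as the implantation
table prints for the fully negative arm), and all-positive outcomes have no
finite MLE — an error by default, or a one-sided bound via the k → n − ½
continuity correction when requested.

`wald_ci()` forms the 95% interval on ln *f* from the observed information
(for one group this equals the delta-method form
SE(ln f) = SE(p̂)/((1 − p̂) d f)), reported on the reciprocal
cells-per-stem-cell scale as (upper, lower) — the convention of the
published table. For the 4-of-10 group at dose 100 this computes
(527.2, 72.7), matching the printed interval; a profile-likelihood oracle
gives (625, 82.9) for the same group, confirming the printed interval is
the Wald one. For the 9-of-10 groups the same method gives (97.4, 19.4)
against a printed (94.4–19.4): the lower bound reproduces, the upper bound
is not reproduced by either the Wald or the profile interval, and we report
the computed value. `compare_frequencies()` contrasts two arms by a
likelihood-ratio test under the joint model (χ², 1 df), with boundary
conventions for degenerate arms.

## Gene prioritization

`significant_genes()` applies the per-line screen — raw p < 0.01 and fold
change > 2, both strict (raw p is used; the upstream differential-expression
tool's multiple-testing treatment is not restated here) —
and `overlap_concordant()` intersects two lines' sets directionally, so a
gene must move the same way in both cell lines. The packaged top-ranked
gene table (`read_table2_fixture()`) carries both lines' log2 fold changes;
PISD, the headline down-regulated gene, flows through the overlap with its
fold changes read back exactly.

Survival concordance uses a median split of expression (ties to the low
group, the convention of common survival-plotting services) and
`km_logrank()`: Kaplan-Meier product-limit curves per group, the log-rank
test from summed observed-minus-expected counts over event times, and the
Mantel-Haenszel hazard ratio HR = (O_low/E_low)/(O_high/E_high) with a
log-scale interval. The O/E form is chosen over a Cox fit because it is
self-contained and shares its machinery with the log-rank statistic; on
moderately sized cohorts it is slightly conservative (an HR of 2 is
recovered as ≈ 1.8 at 500 subjects per arm, within the tested band).
`concordance_filter()` keeps a down-regulated gene only when *low*
expression associates with significantly worse survival (log-rank p below
a configurable α = 0.05), and an up-regulated gene only when *high*
expression does, then ranks candidates by |mean log2 fold change|.

## Problem sizes and defaults used in the shipped checks

The test suite exercises devices of 4–110 channels per side (the full
900-channel geometry is checked at a coarser 4 µm/px calibration), scenes
of up to 880 cells, 10,000-replicate Monte-Carlo calibration of the
Mann-Whitney test, 1,000-replicate limiting-dilution parameter recovery
(median reciprocal within 10% of 1/43.4), and survival cohorts of up to
1,000 subjects. These sizes were chosen as the smallest that make each
property sharp.

## Known limitations

* Template-based segmentation assumes the imaged device matches the
  declared geometry up to translation; rotation and scale drift are out of
  scope.
* The renderer's disk model has no intensity gradients within cells, no
  out-of-focus blur, and no autofluorescence background, so detection
  thresholds transfer to real images only after recalibration.
* The O/E hazard ratio attenuates slightly for strong effects; users
  needing an efficient HR estimate on real cohorts should fit a Cox model.
* Only two-sided Mann-Whitney comparisons are provided, matching the
  reporting convention of the assay.
* The limiting-dilution machinery assumes the single-hit model; with a
  single dose per arm, goodness of fit of that assumption is not testable
  and is not tested.
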