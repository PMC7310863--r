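---
title: "Methods: nanoscale analysis of RAD51/DMC1 repair foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale analysis of RAD51/DMC1 repair foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanofoci)
```

## The biological question and the two imaging scales

During meiotic prophase I, the recombinases RAD51 and DMC1 load onto the
resected ends of programmed double-strand breaks (DSBs) and appear as
discrete foci along the axes of the synaptonemal complex (SC). `nanofoci`
quantifies how the two proteins are arranged relative to each other within
and between these foci, at two scales:

* **Confocal scale** (pixels of ~100 nm): are DSB foci placed randomly
  along the SC axes? Foci are detected as intensity maxima, restricted to a
  binary SC mask, and their nearest-neighbour (NN) distance distribution is
  compared against mask-constrained complete spatial randomness (CSR).
* **Single-molecule scale** (dSTORM localisations, nm): within a 600
  nm-diameter region of interest (ROI) around one focus, localisation
  clouds are segmented into *nanofoci* — connected regions of localisation
  density above threshold — and the per-focus configuration is described by
  counts (`DxRy` = x DMC1 and y RAD51 nanofoci), distances, morphology and
  alignment features.

A generative 3D model of the most informative configuration (D2R1: two DMC1
nanofoci, one RAD51 nanofocus) is then fitted to summary features of the
aligned data by grid search and least squares.

## Confocal focus detection and the CSR null

`find_maxima()` implements prominence-based maxima selection: a local
maximum is accepted only if it stands out from its surroundings by more
than the noise tolerance (90 for DMC1, 100 for RAD51 by default),
i.e. flooding down from the candidate, one reaches a higher maximum only
after descending more than the tolerance. Equal-valued plateaus yield one
maximum at the pixel nearest the plateau centroid, remaining ties broken in
column-major scan order; this convention is deterministic but may differ
from other implementations on perfectly flat plateaus, which do not occur
in noisy images.

The CSR reference (`csr_reference_distances()`) places the observed number
of foci uniformly on the mask and — crucially — pushes each placement
through the *same* chain as real images: single-pixel impulses are blurred
with a Gaussian point-spread proxy (SD 0.11 µm), a constant offset of 5 is
added, per-pixel uniform noise in ±√intensity is applied, maxima are
re-detected and mask-filtered. The pooled NN distances from 50 placements
are compared to the observed distances with the two-sample
Kolmogorov–Smirnov test (asymptotic p-values; distances are
pixel-quantised, so ties are expected and tie warnings are suppressed).
Distance histograms use half-open 100 nm bins with distances ≥ 3.4 µm
pooled as a "rest" class.

One statistical caveat is worth stating: NN distances within one point
pattern are mutually dependent (neighbour relations are shared), which the
two-sample KS test ignores. Under a true null the test is therefore mildly
anticonservative — in our calibrations the fraction of p-values below 0.05
runs at roughly 0.09–0.13 rather than 0.05. Interpret borderline
rejections accordingly; strong rejections (p ≪ 0.001), as produced by
genuinely non-random focus placement, are unaffected.

The impulse amplitude of a simulated focus is a free parameter. The
post-blur peak of one focus is approximately
`A · px² / (2π σ²)`; with 99 nm pixels and a 110 nm blur, the default
`A = 1200` gives a peak of ≈155, comfortably clearing the 90/100
tolerances plus shot noise, so simulated placements are re-detected at
essentially unit efficiency.

## ROI management and quality control

ROIs are closed 300 nm-radius discs around supplied centres (an event at
exactly 300 nm is a member). Two exclusion rules run before segmentation:

* ROI pairs sharing more than 25 % of their localisations are **both**
  removed. The overlap fraction is computed relative to the smaller ROI's
  event count; removing both members is the conservative reading of an
  exclusion rule that does not name a survivor.
* ROIs with fewer than 50 localisations are removed; exactly 50 is kept.
  The floor applies to the ROI total over both channels by default, since
  the rule does not carry a channel qualifier; `per_channel = TRUE` gives
  the stricter variant.

## Kernel-density segmentation of nanofoci

Per channel, a 2D Gaussian KDE is evaluated on a 5 nm grid covering the
ROI plus a three-bandwidth margin, in absolute units (events/nm²). The
evaluation sums per-event kernels exactly in compiled code, truncated at
four bandwidths (tail mass below 10⁻⁴) — on these grid sizes this is both
faster and slightly more accurate than binned FFT estimators, and the test
suite cross-checks it against `KernSmooth::bkde2D` as an independent
reference. The bandwidth default of 20 nm matches a typical average
localisation precision. Nanofoci are the 8-connected
components of the super-threshold set with at least 50 pixels
(1250 nm²); smaller components are treated as background. Each nanofocus
carries its binary mask, area, density-weighted centre of mass, member
localisation count and mask moments (major-axis SD, eccentricity).

### Calibration of the density threshold

The absolute threshold deserves care. A cluster of *N* localisations
smoothed with bandwidth *h* has peak density at most `N/(2πh²)` — about
0.22 events/nm² for *N* = 564 and *h* = 20 nm, and only 0.02 for *N* = 51.
A threshold quoted as "5 localisations per pixel" therefore means very
different things depending on the pixel it refers to: per 5 nm *rendering*
pixel it equals 0.2 events/nm², a level that typical 50–600-event nanofoci
can never reach at a 20 nm bandwidth; per 100 nm *camera* pixel it equals
5×10⁻⁴ events/nm², a level at which a 51-event cluster is segmented as a
compact nanofocus of ~500 rendering pixels, a 564-event cluster as a large
one (~1600 pixels), and a single stray localisation (peak 4×10⁻⁴) is not
segmented at all, while two or three clustered background events
occasionally rise just above threshold and are mostly removed by the
50-pixel area floor. We therefore default to the camera-pixel reading,
`density_from_per_pixel(5, 100)` = 5×10⁻⁴ events/nm², which is the only
choice self-consistent with the per-nanofocus localisation counts the
segmentation is meant to recover. The threshold is an explicit argument of
every segmentation function, and `density_from_per_pixel(5, 5)` = 0.2
remains available for data rendered at other scales.

## Configuration analytics

* `classify_dxry()` labels each ROI by its per-channel nanofocus counts;
  summaries collapse everything outside D1R1/D2R1/D1R2/D2R2 into "rest".
* `inter_channel_distances()` reports the minimum over DMC1–RAD51
  centre-of-mass pairs and the maximum over *all* nanofocus pairs
  (including same-channel pairs); for D1R1 the two coincide.
* `assign_close_far()` names the duplicated-channel nanofocus realising
  the inter-channel minimum "close" and the other "far"; ties go to the
  larger area, then the lower index.
* `classify_morphology()` is a deterministic surrogate for manual
  morphology calls, built on the inter-channel mask-overlap graph
  (overlap = ≥1 shared 5 nm pixel): a nanofocus overlapping two of the
  other channel is a *bridge*; no overlaps is *separate*; two disjoint
  overlapping twin pairs are *paired*; a single overlapping pair of
  "major" nanofoci (area ≥ 50 % of the largest same-channel nanofocus) is
  *simple* when both masks are round (eccentricity ≤ 0.85) and *complex*
  otherwise. The area and roundness cutoffs are explicit, configurable
  proxies for what is a verbal criterion in manual classification.
* `axis_min_distance()` is the minimum point-to-segment distance from a
  nanofocus centre to hand-drawn SC axis polylines; nanofoci beyond 1 µm
  are flagged as not axis-associated.

## Rotation alignment and summary features

`rotate_align()` applies the rigid motion (determinant +1, no reflection)
that puts an anchor nanofocus centre at the origin and a goal centre on
the positive y axis. Aligned foci are pooled per stage and rendered as
consensus count images. Three summary features feed the model fit:

* `sigma_R` — the SD of a single Gaussian with offset, least-squares
  fitted (via `minpack.lm::nlsLM`) to the y-marginal histogram of the
  pooled RAD51 localisations in the RAD51-to-top rotation. Fitting the
  pooled event marginal rather than image rows is a deliberate choice:
  it is bin-size independent and uses every localisation. Reported
  lengths are FWHM = 2√(2 ln 2)·σ ≈ 2.355 σ.
* `pct_D_tophalf` — the percentage of DMC1 localisations with y > 0 in
  the RAD51-to-top rotation. ("Top half of the centre" is read as the
  upper half-plane through the anchored close-DMC1 centre.)
* `pct_R_topquad` — the percentage of RAD51 localisations in the top
  quadrant of the far-DMC1-to-top rotation. Quadrants are the four
  90° wedges bounded by the diagonals y = ±x, so top/bottom/left/right
  are symmetric about the axes; boundary events count as vertical, and
  this convention is applied identically to simulated and observed data,
  so the fit compares like with like.

## The generative D2R1 model

A simulated D2R1 focus consists of three Gaussian clusters in 3D plus
uniform background:

* close DMC1: 564 localisations, isotropic SD 30 nm, at the origin;
* far DMC1: 51 localisations, isotropic SD 15 nm, centred at 400 nm in a
  uniformly random 3D direction;
* RAD51: 267 localisations in an ellipsoid (major-axis SD σ, minor-axis
  SD equal to the far-DMC1 SD), its major axis tilted from the DMC1–DMC1
  axis by an angle drawn uniformly in [0, α] with uniform azimuth, and its
  centre offset one major-axis SD from the close DMC1 along that axis, so
  the filament emanates from the close cluster ("physically connected");
* background: 50 localisations uniform in a 1200 nm cube centred on the
  close DMC1, assigned to the two channels at random at analysis time.

The cluster SDs are not constrained by published point estimates, so the
defaults were chosen to put segmented areas in the observed large/small
nanofocus regime at the calibrated threshold. The background cube side
(1200 nm) covers the full spatial extent of the model (far DMC1 at 400 nm
plus spreads): a background confined to a smaller central volume would
concentrate noise density near the clusters and inflate spurious-nanofocus
classes far beyond the small fractions actually observed, which is how the
default was fixed.

Simulation discards z, reassigns background, and re-runs the exact 2D
segmentation and classification used for experimental ROIs. Projection
makes a minority of 3D D2R1 foci appear as D1R1 in 2D (the two DMC1
contours merge when the projected DMC1–DMC1 distance is small), and
background occasionally adds a spurious nanofocus (small D3R1/D2R2
fractions). With mid-range parameters (FWHM 112 nm, α = 120°) about
10–20 % of foci register as D1R1 — the package's acceptance suite checks
exactly this number at 200 simulated foci.

For every (σ, α) combination, `simulate_d2r1_grid()` generates 200
configurations, records the DxRy frequency table and measures the three
features over the foci that remain D2R1. `lms_fit()` then returns the cell
minimising the mean squared feature difference. Because one feature is a
length and two are percentages, each feature is standardised by its range
over the grid before squaring; a raw-unit option exists, and ties break
towards smaller σ, then smaller α. The default grid spans FWHM
{80, 96, 112, 128, 144, 160} nm and α {90, 105, 120, 132, 150, 180}°,
bracketing the plausible parameter region.

## The synthetic nucleus generator

`nucleus_layout()` / `gen_nucleus_localizations()` place isotropic
two-channel Gaussian localisation clusters at chosen arc-length positions
along axis polylines, returning the table together with ground-truth focus
centres. This emulates the *statistical* structure the pipeline assumes —
Gaussian nanofocus clouds on curvilinear axes — and deliberately not the
photophysics of real dSTORM data: no blinking, no multi-frame grouping, no
drift, no variable per-event precision, no antibody-size offsets.
Passing tests on synthetic nuclei therefore demonstrate correctness of the
geometry, segmentation and accounting, not robustness to acquisition
artefacts, which enter real data upstream of this package's inputs.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed; per-focus / per-cell
  substreams are derived deterministically, so results are bit-identical
  under a fixed seed and independent of evaluation order.
* KDE grids are anchored at the ROI (or bounding-box) origin with exactly
  5 nm spacing; both channels of an ROI share one grid so masks are
  directly comparable. `bkde2D` truncates kernels at the grid edge; the
  three-bandwidth margin keeps the lost mass under 1 %.
* Connected components are 8-connected by default (diagonal touching
  merges); 4-connectivity is available.
* An empty channel raises an explicit error at KDE time and is skipped by
  the two-channel wrapper; an ROI with no nanofoci is labelled D0R0 and
  morphology falls back to "unclassified"/"separate" deterministically.
* A degenerate (all-coincident) cloud fits σ = 0 with a warning; groups
  too small to compare are skipped with a note; a paired comparison with
  constant non-zero differences reports p = 0 (the t statistic diverges).
* Significance follows the p < 0.05 convention with no multiple-testing
  correction, mirroring common practice in this literature; treat
  borderline p-values accordingly.

## Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: 200 simulated foci per grid cell on
the 6×6 default grid, 20 seeded recovery runs, 200-replicate CSR
calibration at the distance level plus a 40-replicate full image-chain
calibration, and synthetic nuclei of six foci. These sizes were chosen so
that Monte-Carlo error is small relative to the tolerances being asserted.

## Known limitations

* Segmentation is strictly 2D; z is used only by the generative model.
* The morphology rules are proxies for manual calls; their thresholds
  (major fraction 0.5, eccentricity 0.85) are reasonable but not fitted.
* The CSR reference assumes foci are far smaller than the mask and that
  detection efficiency on simulated images is uniform across the mask.
* The D2R1 fit explores only the D2R1 generative family and only a grid;
  no uncertainty is attached to the selected (σ, α) beyond grid spacing.
* The density-threshold calibration ties the default to 100 nm camera
  pixels; data rendered in other units must set the threshold explicitly.
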