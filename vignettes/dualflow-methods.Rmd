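---
title: "Processing dual-channel GCxGC batches with dualflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing dual-channel GCxGC batches with dualflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualflow)
```

## The problem

Comprehensive two-dimensional gas chromatography (GCxGC) re-separates every
fraction of a first column's effluent on a short second column via a
modulator that cycles with a fixed period (here 2.5 s). When the effluent is
split between a quadrupole mass spectrometer (qMS) and a flame ionization
detector (FID) — roughly 4.5:1 toward the FID — each injection yields two
complementary data streams: slow-scanning MS spectra for identification and
a fast (120 Hz), linear, quantitative FID trace. Turning a batch of such
dual-channel runs into one aligned sample-by-compound table involves a chain
of small, individually simple steps whose parameters and conventions are
rarely written down precisely enough to reproduce. `dualflow` implements the
entire chain as an open, deterministic pipeline:

1. read both channels from ANDI/AIA netCDF interchange files;
2. compute the TIC from the MS scan stream;
3. baseline-correct each channel (dynamic baseline correction for MS,
   TopHat for FID);
4. fold each 1D signal into the 2D retention plane;
5. detect and delineate peaks on the MS plane;
6. build a stencil — named rectangular regions, each carrying an apex mass
   spectrum — and merge it incrementally across samples, adding only
   compounds not seen before;
7. estimate the small rigid shift between the MS and FID planes of each
   sample and transfer the stencil onto the FID data;
8. quantify every region on the corrected FID plane, zero-filling regions
   where no peak is found;
9. combine per-sample reports into one rectangular batch table, pretreat it
   (unit-vector normalization, then autoscaling) and run PCA.

## Coordinate conventions

A folded plane stores rows as the second-dimension sampling grid within one
modulation and columns as consecutive complete modulations. With 1-based
indices, `1tR = (col - 1) * pm / 60` minutes is assigned at the modulation
start (no apex correction) and `2tR = (row - 1) / rate` seconds runs from the
modulation start with no hold-up-time subtraction, matching the usual
contour-plot axes. Wraparound peaks (eluting past the modulation period) are
represented as-is and are not rejoined across the top/bottom edge.

When the product `pm * rate` is an integer (the 120 Hz FID: 300 points per
2.5 s), folding is an exact reshape and `unfold()` inverts it bit-for-bit.
When it is not (the qMS at 1/0.0241 s = 41.49 scans/s gives 103.73 points
per modulation), each modulation is linearly interpolated onto a fixed grid
of `ceiling(pm * rate)` rows at the native sample spacing, measured from the
modulation start. Interpolation (rather than truncation) keeps apex
positions accurate to a fraction of a sample and makes results
bit-reproducible; the trailing partial modulation is discarded in both
cases, which is also why the expected modulation count uses a floor
(49 min x 60 / 2.5 s = 1176 complete cycles for the published method).

## Baseline correction

Both corrections operate on the unfolded 1D signal so each channel's native
rate is respected, and both subtract a **morphological opening** — a
centered rolling minimum followed by a centered rolling maximum with a flat
window, computed after extending the signal with its edge values. The
opening is the identity on monotone baselines (linear drift, exponential
column bleed) including at the boundaries, and annihilates any feature
narrower than the window. Its key property here is that the subtraction is
*exactly* idempotent: within every window of the corrected signal there is a
cell where the original signal equaled its block minimum, and the residual
is zero there, so a second application changes nothing. It is also exactly
equivariant under constant offsets, and a constant trace corrects to zero.

The two operators differ in how their window is set:

* `dbc()` (MS stream) uses `dbc_window_factor` (default 10) times the
  expected second-dimension peak width. An early design smoothed the opened
  baseline with a short Savitzky–Golay filter; the smoothing spread the
  opening's flank wedge into small negative dips and broke idempotence by
  three orders of magnitude, so it was removed. The window's dependence on
  the peak width is the "dynamic" part: re-estimate the width per dataset
  and the correction adapts.
* `tophat()` (FID stream) uses `tophat_factor` (default 5) times the peak
  width, incremented to an odd count, and its output is non-negative
  everywhere because an opening never exceeds the signal.

The reference peak width defaults to **0.35 s**, a compromise across a
dynamic range that spans several orders of magnitude both within a sample
and across a batch. `estimate_peak_width()` re-derives it from a
representative sample: candidate peaks are stratified into `n_peaks`
(default 10) log-spaced height bins spanning the detected dynamic range, one
peak per bin (nearest the bin's geometric-mean height, ties toward earlier
first-dimension retention) is measured for full width at half maximum along
the second dimension — interpolated between grid cells — and the arithmetic
mean is returned. FWHM was chosen as the width measure because it is robust
to the integration boundary; selecting across height bins deliberately
includes both near-trace and near-overload peaks.

## Peak detection and integration

Detection runs on a baseline-corrected plane. Noise is estimated robustly as
`1.4826 * median(|x - median|)` over below-median cells, so the sparse,
positive peaks cannot inflate it. The plane is pre-smoothed with a separable
Gaussian (sigma of one modulation along dimension one; `smooth_sigma_2d`,
default a quarter of the reference peak width, along dimension two); local
maxima of the smoothed plane above `snr_min * noise` (default SNR 10) are
snapped to the tallest raw cell within one cell and grown into 4-connected
footprints by flood fill on the *unsmoothed* plane down to
`max(boundary_fraction * apex, snr_min * noise)` with
`boundary_fraction = 0.05`. Maxima whose footprints overlap merge into the
tallest (ties: smaller column, then smaller row — fully specified so results
are bit-reproducible), which is what removes shoulder maxima and duplicate
markers; footprints of surviving peaks are disjoint. Volumes are the
footprint sum times the dwell time `1/rate` with negative cells clipped to
zero. For an isolated 2D Gaussian of amplitude A the 5% contour captures 95%
of the analytic volume `2 * pi * A * sigma1 * sigma2`; on realistic grids
(sigma of roughly one modulation by six second-dimension cells)
discretization of the contour boundary moves the captured fraction by about
±1%, which is why volume checks in the tests use a 5% tolerance against the
closed form. Flood-fill delineation (not watershed) is deliberate: it is
simple, deterministic, and adequate for well-modulated peaks; splitting
co-eluting peaks is out of scope.

## Stencils

A stencil is an ordered list of axis-aligned rectangles in retention
coordinates, each with a stable id, a name (default `Unknown_<id>`), an
origin sample, and optionally the apex mass spectrum normalized to base peak
1. Rectangles keep the JSON schema trivial to edit by hand (the supported
route for manual refinement) and make the inclusion test trivial; the apex
scan is used rather than a footprint average because baseline correction has
already removed background and the apex maximizes analyte purity. Library
searching and retention-index calibration are out of scope, so names stay
user-editable placeholders.

`merge_stencil()` adds a sample's peaks to an existing stencil: a peak
matches a region if its apex lies inside it, or within
(`rt_tol_1t` = 1 modulation, `rt_tol_2t` = 0.1 s) of the region center with
spectral cosine at least `cos_min = 0.8` when both spectra exist (cosines
are computed on intensity vectors aligned over the union of integer m/z).
Matched peaks add nothing; unmatched peaks append fresh regions. Existing
regions are never removed or shrunk, so merging is idempotent and ids stay
unique through arbitrary merge sequences. By default every sample
contributes to stencil building; for large batches a subset (for example one
or two replicates per class) can be configured, and the chosen subset is
recorded in the run log so the sampling plan is always traceable.

## Channel registration

The MS-derived stencil rarely lands exactly on the FID plane: the qMS runs
under vacuum, the FID at atmospheric pressure, and the channels sample at
different rates. `estimate_shift()` resamples the MS plane onto the FID grid
(linear interpolation per modulation), rank-transforms both planes (robust
to the dynamic-range and split-ratio differences between detectors), and
exhaustively scores normalized cross-correlation over integer shifts within
`max_d1t = 5` modulations and `max_d2t = 0.25` s. Ties break toward the
smallest shift norm; an optimum on the search boundary raises a warning. On
a common grid the recovery of integer shifts is exact; across grids the
second-dimension shift is resolved to the coarser channel's cell (about
0.024 s here), which is well inside the region margins. The transform is a
rigid translation only — the workflow's premise is "shift the stencil into
place", not warping — with an optional per-region `local_snap()` that
re-centers a region on the tallest cell of its tolerance-expanded window.
Snapping is off by default in the pipeline: when the global shift is
accurate, a snap window that looks beyond the region can drag a legitimately
empty region onto a large neighbor's tail and defeat zero-filling.

## Quantification, pretreatment and PCA

`quantify_stencil()` evaluates each region on the corrected FID plane: the
region's tallest cell is the apex; below `snr_min * noise` the region's
volume is recorded as **0** (zero-filling, not missing-value imputation, so
batch tables are complete by construction), otherwise the apex grows into a
flood-fill footprint clipped to the region and integrates as above.
`align_reports()` stacks per-sample reports into a samples-by-regions
matrix, filling absent pairs with zero and never altering a reported volume.

Pretreatment order is a genuine ambiguity in practice, and the package fixes
it deliberately: **row unit-vector normalization first** (each sample's
profile scaled to Euclidean norm 1, removing overall loading differences),
**then column autoscaling** (mean centering and division by the n-1 standard
deviation). Column statistics computed before sample normalization would mix
loading variation into every variable, so this order is the only one in
which both steps mean what they claim. The flags on a batch table are
monotone — once set they are never unset — and `batch_pca()` refuses
unpretreated input unless forced. PCA itself is a singular value
decomposition: scores are left singular vectors scaled by singular values,
loadings the orthonormal right vectors, and the sign convention (largest
loading magnitude positive per component) makes results invariant to sample
order. Zero-variance columns are centered, left unscaled, and warned about.

## The synthetic generator

Because the original raw data live in an external repository and its peak
tables depend on a proprietary integrator, the package carries its own
ground-truth generator. `synth_sample()` emulates the dual-channel
structure: peaks are pure 2D Gaussians in folded coordinates (sigma1 in
modulations, sigma2 in seconds), so each planted peak has the exact analytic
volume `2 * pi * A * sigma1 * sigma2` counts*s. The MS channel distributes
each peak over 5–15 random fragment lines within the 40–300 m/z scan range
(line weights summing to 1, so the TIC apex equals the planted amplitude);
the FID channel carries the same peaks scaled by the 4.5 detector-split
gain, translated by a small inter-channel shift (default +1 modulation,
+0.05 s), over linear drift (400 counts across the run) plus an exponential
column-bleed ramp (300 counts, 60 s time constant) with Gaussian noise
(sigma 2). `synth_batch()` arranges compounds on retention slots at least 8
sigma apart on both axes with log-uniform amplitudes spanning 5e2–5e4 (two
orders of magnitude of dynamic range), assigns shared and class-specific
compounds, and jitters replicate amplitudes log-normally (sdlog 0.1).
Everything is deterministic per seed.

The generator's defaults use the published detector rates, scan range, and
modulation period with a shortened 4-minute oven program (96 modulations),
which keeps a six-sample batch comfortably under a minute of compute while
preserving the real grid geometry (300-row FID and ~104-row MS planes). The
tests and the acceptance script run 2 classes x 3 replicates with 15 shared
plus 5 class-specific compounds (25-compound union), 20-peak detection
fixtures, and 10 random shift-recovery cases.

What passing these tests does *not* show about real data: synthetic peaks
have no tailing (the FID-vs-MS peak-shape contrast is therefore only
qualitative here), retention positions are identical across samples (no
retention drift between runs, so the stencil-merge tolerance is exercised
only by grid quantization), spectra are random sticks rather than library
spectra, and the noise is Gaussian/Poisson-like rather than structured
chemical interference. Conclusions about the real kava dataset's peak counts
(hundreds per sample) or its PCA geometry are explicitly out of reach
without the commercial integrator.

## Degenerate inputs and numeric choices

Readers reject rather than repair: truncated netCDF, non-monotone scan
indices, abscissa jitter above 1%, duplicate region ids, and schema
violations (reported with their JSON path) are format errors. Windows below
3 samples, empty footprints, all-zero sample rows, constant planes in
registration, fewer width candidates than requested, and out-of-range PCA
ranks are configuration errors. Intensities are handled as doubles
regardless of stored type; file times are seconds internally, with minutes
appearing only in report columns; all tie-breaks (merged maxima, shift
ties, bin selection) are specified exactly so that a rerun is byte-identical
— the run log records parameters and package version but never timestamps.

## Known limitations

* Co-eluting peaks are merged, not deconvolved; wraparound peaks are not
  rejoined.
* Registration is a rigid translation; nonlinear retention warping between
  channels or samples is out of scope (the stencil merge handles
  cross-sample identity at region level).
* Cross-rate shift estimation resolves the second dimension only to the
  coarser grid's cell.
* Stencil regions are rectangles; freeform region shapes must be
  approximated by their bounding boxes.
* Vendor `*.raw` parsing and mzML are out of scope: conversion to ANDI
  netCDF is assumed upstream.
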