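---
title: "Models and methods behind shipquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shipquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shipquant)
```

# The assay and what this package quantifies

Quench-based internalization probes separate two pools of a fluorescent
ligand bound to a cell-surface receptor: probe still exposed on the
membrane, and probe already taken up into vesicles. A complementary
quencher oligo hybridizes to the surface-exposed probe within seconds and
abolishes its fluorescence, so the surviving signal reports the
internalized pool only. `shipquant` implements the quantification layer of
that assay — flow-cytometry internalization statistics, colocalization
with endosomal markers, vesicle detection, sizing and tracking, and
replicate-level statistics — together with a forward simulator that
generates flow tables and microscopy images with complete ground truth, so
every estimator in the package can be validated against known answers
without any microscopy data.

# Internalization statistics

Two per-timepoint statistics are implemented on group summaries (mean by
default, median by flag — MFI conventions differ between instruments and
export pipelines, so the statistic is explicit):

* quench readout: percent surface
  $= 100 - \frac{F_Q - F_{bg}}{F_{noQ} - F_{bg}} \times 100$, where $F_Q$
  and $F_{noQ}$ are the quenched and unquenched group statistics at the
  same timepoint;
* time-zero readout (for surface stains without a quencher): percent
  surface $= \frac{F_x - F_{bg}}{F_0 - F_{bg}} \times 100$, with the
  on-ice time-0 group defining 100 %.

The background $F_{bg}$ comes from an unstained-control group when the
table carries one, else from a user constant. What an experiment's
"background sample" is (unstained cells vs. secondary-only staining)
varies between labs, so it is configuration, not policy. Non-positive
denominators are an explicit error naming the offending sample; values
outside $[0, 100]$ — perfectly possible with noisy groups — are returned
raw with an `out_of_range` flag, and clipped only on request, so noise
behaviour remains visible.

# The forward simulator

## Kinetics

Internalized fraction follows a delayed single exponential
$f(t) = 1 - e^{-k\,\max(0,\,t - t_{lag})}$. This is the simplest
two-parameter curve satisfying the two population anchors the assay is
calibrated to: under 10 % of bound antigen internalized at 5 min and
about 60 % at 30 min. The defaults $t_{lag} = 2$ min, $k = 0.0327$
min$^{-1}$ reproduce exactly those anchors ($f(5) = 9.3\,\%$,
$f(30) = 60.0\,\%$).

Internalized-probe signal additionally decays as
$e^{-\delta t}$ with $\delta = 0.005$ min$^{-1}$ by default: a slight,
slow loss of internal signal (endosomal acidification, probe
instability). No published number pins $\delta$; the default is chosen
once as a visible-but-small effect (about 14 % signal loss over 30 min)
and documented as a free parameter.

## Quenching

Quenching multiplies the surface pool by $1 - q$, with $q = 0.98$ by
default: quenching is near-complete within seconds but no exact residual
is published, so $q$ is a documented assumption. In live imaging the
factor develops as $1 - q\,(1 - e^{-s/\tau_q})$ with $\tau_q = 5$ s,
putting the membrane signal below 5 % of its pre-quench value half a
minute after quencher addition.

One consequence worth knowing: with $q < 1$ the quench statistic carries
a small structural bias of $+(1-q)\times(\text{surface share})$
percentage points, because the residual unquenched surface signal is
counted as internalized. At the defaults this is about +1.8 points at
5 min and +0.9 at 30 min — the recovery tests budget for it, and it is a
property of the assay itself, not of the implementation.

## Flow tables

Each simulated cell carries `background + size_factor * (surface +
internal) + read noise`, with a log-normal size factor (sdlog 0.25, mean
fixed at 1) shared by both pools — cell size scales both pools together,
which is exactly why the ratio statistics are size-robust. Each timepoint
gets paired quenched/unquenched groups of `n_cells` cells plus an
unstained autofluorescence group per replicate. The defaults
(`signal_mean` 1000 a.u. over `background` 50 a.u., `read_sd` 10) give a
bright, well-separated stain typical of a good antibody conjugate.

## Images

Scenes are rendered on a physical grid (default 80 nm pixels, a spinning
disk camera scale). Every structure is an isotropic Gaussian and the
rendered spot width is the quadrature sum of the structure width and the
channel PSF: $\mathrm{FWHM}_{app} = \sqrt{\mathrm{FWHM}_{struct}^2 +
\mathrm{FWHM}_{psf}^2}$. This choice makes the sizing pipeline verifiable
in closed form. Kernels are normalized over their in-image support, so a
noise-free image integrates exactly to its configured photon budget —
the flux-conservation tests rely on this.

The cell is a disc (radius 5 µm) whose nucleus fills about 70 % of the
volume (radius $0.7^{1/3}$ of the cell's), leaving the thin cytoplasmic
annulus characteristic of lymphocytes; vesicles are placed only there.
The membrane is a ring with a Gaussian cross-section (100 nm thick before
PSF blur) carrying the surface pool; vesicle spots (150 nm FWHM by
default, the unilamellar-vesicle scale) share the internal pool with
log-normal brightness spread. The marker channel places spots at a
`coloc_fraction` subset of vesicle positions plus independent extra
spots (by default topping the marker count up to the vesicle count).
Noise is Poisson on expected photons, then additive Gaussian read noise
(sd 2) and a constant camera offset (100) — the standard sCMOS/EMCCD
approximation.

The z axis, when present, is rendered as independent planes; there is no
full 3-D PSF, no vectorial optics, no photobleaching beyond $\delta$.
Timelapse vesicles move by 2-D Brownian steps (per-axis variance
$2 D \Delta t$) plus optional drift, with exact multi-bounce radial
reflection at the annulus walls (a triangle-wave fold of the radius), and
the membrane ring follows the live-quench factor after the quench frame.

## What the simulator does not emulate

Real B-cell images have heterogeneous vesicle brightness far beyond
log-normal, clustered (not uniform) vesicle placement late in
internalization, spatially varying background, optical aberrations and
depth-dependent PSFs, and imperfect cell segmentation. Passing recovery
tests on synthetic data therefore demonstrates correctness of the
estimators under the stated forward model — not robustness to every
real-data pathology. That separation is deliberate: the package's claims
are about the quantification layer.

# Colocalization

Thresholded Mander's coefficients with Costes automatic thresholds:
a least-squares regression $ch_2 = a\,ch_1 + b$ over the cell mask,
then candidate thresholds $T_1$ descending through the sorted unique
intensities of channel 1 with $T_2 = a T_1 + b$, stopping at the highest
$T_1$ whose below-threshold pixels are uncorrelated or anticorrelated
($r \le 0$); if that never happens the thresholds fall to the channel
minima. Scanning observed intensity values (rather than fixed-width
steps) keeps the scan deterministic and resolution-independent, and makes
the exhaustive brute-force oracle in the test suite exact. Undefined
below-threshold correlations (fewer than two pixels, zero variance) are
skipped rather than treated as a stop.

`tM1` sums channel-1 intensity over pixels where both channels exceed
their thresholds, divided by the channel-1 sum over its own
above-threshold pixels; `tM2` symmetrically. Fiji-lineage tools disagree
on whether the denominator is thresholded; both conventions exist here
(`denominator = "thresholded"` is the default, `"all"` the alternative)
and the choice is reported, not silent. An empty above-threshold set
yields a flagged `NA`, never a silent 0.

The random-colocalization control rotates channel 2 by 90° about the ROI
center and re-runs the whole measurement. "90° left" is read as
counterclockwise; the direction is irrelevant to the null's purpose but
fixed for reproducibility. Square regions rotate losslessly;
non-square regions are median-padded to square first (or refused when
`pad = FALSE`). Rotation preserves each channel's intensity histogram
while destroying true spatial correspondence, which is exactly what a
chance-overlap floor needs.

# Vesicle detection, MFI and sizing

Detection is a scale-normalized Laplacian-of-Gaussian filter at
$\sigma = \mathrm{FWHM}_{app}/2.355$, strict 8-neighbour local maxima
above a robust threshold (median + $k \cdot$ MAD of the response,
$k = 8$), and per-axis quadratic sub-pixel refinement. A detection scale
below one pixel is clamped with a warning.

MFI uses a circular cell ROI (diameter 100 px by default) on the z
sum-projection, minus the mean of four seeded-random circular background
ROIs placed outside all cell ROIs; the seed is recorded in the result so
"random positions" are reproducible. Background ROIs default to 30 px
diameter so four of them can always be placed in a crowded field; the
cell-ROI diameter is configurable.

Sizing follows the line-profile convention: a horizontal profile through
the sub-pixel spot center (direction configurable), bilinear
interpolation at 0.5 px steps, and a least-squares Gaussian fit
$A e^{-(x-\mu)^2/2\sigma^2} + B$ with apparent diameter
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. Initialization comes from the
peak and its half-maximum crossings; the fit window is ±3 initial sigmas
so neighbouring vesicles do not bias the fit; the optimizer is
Levenberg–Marquardt (`minpack.lm::nls.lm`) with an analytic Jacobian —
the `nls`-family interfaces reject symmetric noise-free profiles with a
spurious singular-gradient error, the raw optimizer does not. Fits with
$r^2 < 0.5$ or optimizer failure are flagged, never silently numeric.
Condition summaries take 5–10 vesicles per condition by convention and
warn (but still report) below 5.

# Tracking

Linking is greedy mutual-nearest-neighbour per frame pair under a
displacement gate, with no gap closing, splitting or merging — a missed
detection ends a track. This is deliberately simpler than a full LAP
assignment: at the vesicle densities the simulator produces it links
> 95 % of steps correctly, and its failure mode (terminating a track) is
conservative for downstream statistics. Two properties are guaranteed
and tested: permutation invariance to spot order within frames, and
identity tracking in the single-spot/infinite-gate limit.

Motility statistics use the time-averaged MSD at the first 4 lags;
$\hat D$ is the linear-fit slope over lag time divided by 4 (2-D). Tracks
shorter than 3 frames are excluded and counted. A quadratic lag term that
dominates the linear one flags directed motion (MSD $= v^2\tau^2$), where
a linear $\hat D$ is not interpretable. Note that $\hat D$ from
*linked* tracks is biased low when links are imperfect — fragmentation
censors large displacements — so diffusion validation runs on full-length
tracks, and linker validation is a separate link-accuracy measurement.
The linker-validation scene uses a widened cytoplasmic annulus (16 µm
field) so that 50 simultaneous tracks are optically resolvable; at the
default thin B-cell annulus, 50 vesicles are crowded enough that *no*
unaided nearest-neighbour linker is reliable, which is a statement about
the scene, not the linker.

# Replicate statistics

Cells within an experiment are not independent, so significance testing
collapses each replicate × condition to its mean and runs a classical
two-sided paired Student's t-test across replicates (`stats::t.test`),
with the usual star mapping (*P < 0.05, **P < 0.01, ***P < 0.001).
Zero-variance differences (degenerate, infinite t) are flagged rather
than propagated as numbers. The superplot export returns the three tidy
levels (cells, replicate means, condition summaries) that make this
structure visible.

# Problem sizes and numerical choices

Validation problem sizes are chosen for desk-scale runs: flow recovery at
5000 cells/group (Monte-Carlo error of the percent estimates well under
half a point), colocalization recovery over 30 simulated cells,
sizing across PSF FWHM 150–450 nm at 40 nm pixels, tracking at 50
tracks × 50 frames, 5 s intervals, $D = 10^4$ nm²/s. All simulator
randomness flows through a single integer seed; identical configuration
and seed reproduce outputs bit-for-bit, including the CLI's CSV files.

Degenerate inputs are contracts, not crashes: empty masks, zero-variance
channels, unmatched timepoint pairs, unpaired replicates, zero-length
profiles and sub-sampling detection scales all raise named errors or
flagged results, and the test suite pins each of these behaviours.
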