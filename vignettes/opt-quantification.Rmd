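---
title: "Quantifying cell morphology, density and viability with optical projection tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell morphology, density and viability with optical projection tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optmorph)
```

## The measurement problem

Cells embedded in a transparent hydrogel report on the material: on a
permissive matrix they spread and elongate, on a non-permissive one they
stay small and spherical. Optical projection tomography (OPT) images whole
millimeter-scale cultures — far beyond confocal depth — by rotating the
sample tube through 360° under telecentric illumination and capturing a
projection at each angle (400 projections at 0.9° steps is the acquisition
this package defaults to). Telecentric optics produce parallel rays, so the
acquisition follows the parallel-beam Radon model and filtered
back-projection (FBP) applies directly. `optmorph` implements the whole
chain — simulation, preprocessing, reconstruction, segmentation,
morphometry, statistics — as composable stages with a ground-truth phantom
generator, so each claim the pipeline makes can be checked on data where
the answer is known.

## The forward model and its conventions

A volume is a `z × y × x` array of isotropic voxels (default pitch 5 µm —
the effective pixel size is an instrument calibration we declare rather
than derive; it resolves 10–40 µm cells with ≥ 8 voxels along an axis and
is configurable everywhere). Angles are degrees, counterclockwise, angle 0
aligning detector columns with the volume x axis; a stated convention
removes the mirror/rotation ambiguity of reconstructions. `forwardProject`
computes attenuation line integrals (the post-logarithm bright-field
contract) by mass-conserving bilinear splatting: each voxel deposits its
value into the two detector bins adjacent to
`t = x cosθ + y sinθ + cor`, so per-angle projection sums equal slice sums
exactly and linearity is exact. The tests cross-check it against an
independent rotate-and-sample integrator; agreement is interpolation-grade
at generic angles, with a known bounded worst case at exactly 45° where the
splat lattice aliases.

Raw transmission imaging is the optional `toTransmission` /
`fromTransmission` layer (`I = I0 e^{-p}`). The faithful processing order
for bright-field data operates on transmission-contrast images, because
that is what a camera records: homomorphic normalization → FBP → intensity
inversion (cells, which reconstruct as dark attenuation dips, become
bright) → segmentation. Reconstruction of the post-log projections is kept
for quantitative round-trip work, where the reconstruction approximates
the attenuation volume itself and no inversion is wanted.

## Phantoms: what they emulate, and what they do not

`generatePhantom` renders non-overlapping triaxial ellipsoids (semi-axes
drawn per sorted axis from configurable ranges, default 7.5–15 µm;
orientations Haar-uniform; a voxel belongs to a cell when its center lies
inside the ellipsoid) inside the analysis cylinder of a sample tube.
Placement is rejection sampling with a retry cap (default 1000/cell) and a
minimum bounding-sphere clearance (default 10 µm): a dilute single-cell
suspension, which keeps ground-truth counts well defined after
reconstruction blur. The hydrogel itself is modeled as perfectly
transparent (value 0); dead cells are rendered at
`deadContrastFactor` × live contrast (default 0.1), emulating the contrast
loss of membrane-compromised cells, and fluorescence channels re-render the
live/dead subsets at full intensity since staining is independent of
bright-field contrast.

One geometric convention deserves emphasis: the *analysis cylinder* — the
tube lumen shrunk by a wall margin (default 2 voxels) — is simultaneously
the seeding support and the density denominator, for ground truth and for
quantification. Using one region for both sides makes density recovery a
well-posed comparison; mixing the full lumen into one side would bias the
ratio by several percent at desk-scale grids.

The illumination bias field is `1 + amplitude · g(row, col)` with `g` a
zero-mean, `|g| ≤ 1` sum of the three first-order harmonics (≤ 1 cycle per
image axis, seeded random coefficients). It deliberately lives far below
the homomorphic filter's cutoff, which is the regime the filter is designed
for; it is a stand-in for slowly varying illumination, not a camera model.
Photon noise is `noiseScale · Poisson(v / noiseScale)` — mean-preserving,
variance proportional to signal.

What the phantoms do **not** emulate: refraction and scattering, the
limited depth of focus of the objective, cell clusters and
ECM texture, emission-light propagation for fluorescence, and detector
saturation. Passing recovery tests on these phantoms therefore
demonstrates correctness of the computational chain under ideal mesoscopic
imaging, not robustness to every artifact of a physical instrument.

## Preprocessing

The homomorphic filter is log → 2D FFT → Gaussian high-emphasis transfer
`H(f) = lowGain + (highGain − lowGain)(1 − e^{−f² / 2 cutoff²})` → inverse
FFT → exp, applied identically to every projection (we read "normalize
brightness across the stack" as per-projection filtering with shared
parameters). Defaults: `cutoff = 0.02` cycles/px, `lowGain = 0.3`,
`highGain = 1`. The filter names a family rather than fixed constants, so
all three are exposed; `lowGain = 0.1` is the stronger normalization used
when we quantify bias suppression (a flat field times an amplitude-0.5
bias comes out with ≲ 15% of its original coefficient of variation at
256² frames). Because the model is multiplicative, a global gain `c`
passes through as `c^lowGain` — the log-domain linearity the tests assert.

Fluorescence stacks instead get a 2D median filter (default 3 × 3; removes
isolated hot pixels) followed by percentile brightness rescaling (defaults
0.5/99.5), in that fixed order. Live/dead channel alignment maximizes
FFT cross-correlation of mean-subtracted frames over integer shifts within
±10 px per angle; normalized correlation on integer shifts is
deterministic and sufficient for rigid drift between sequential channel
acquisitions.

## Reconstruction

`fbpReconstruct` works slice-wise on sinograms: frequency-domain ramp
filter (`2|f|` on a power-of-two zero-padded grid; optionally
Hann-apodized for noisy data; `"none"` gives plain back-projection), then
back-projection over all angles with linear detector interpolation and
weight π/N. All 400 angles of a full revolution are used directly — no
180° folding — matching the acquisition. Voxels outside the inscribed
field-of-view circle are set to zero because parallel-beam data do not
determine them. The center-of-rotation offset enters as a subpixel shift
inside the back-projection lookup (a single interpolation rather than
shift-then-interpolate, which compounds two).

The manual scalar center-of-rotation offset is the primary interface, as
an operator would use; `estimateCOR` adds an automatic estimator: in
parallel geometry a projection at θ mirrors the projection at θ + 180°
about the axis column, so cross-correlating each projection with its
mirrored opposite (parabolic subpixel peak) yields twice the offset, and
the median over all opposed pairs is robust to weak-signal rows. On
phantoms it recovers injected offsets of ±5 px to well under half a pixel.
Estimation should run on a slice with signal; the orchestration picks the
highest-energy sinogram.

## Segmentation

On the inverted (cells-bright) volume: band threshold (defaults: Otsu for
the lower bound — logged, mirroring an operator's manual min/max choice —
and the volume maximum for the upper), 3D morphological closing with a
digital ball (dilation then erosion, default radius 1), removal of
connected components smaller than `minVoxels` (default: the voxel count of
a 10 µm sphere at the current pitch — the smallest plausible cell-scale
object), and deterministic connected-component labeling (components
numbered in linear-scan order; default connectivity 26, configurable to 6
or 18). Touching-cell splitting (watershed) is deliberately out of scope:
the method targets dilute single-cell cultures, and clustered cells are a
documented limitation of the imaging itself.

## Morphometry

Radii come from second central moments: population covariance of the
cell's voxel coordinates (in µm), eigenvalues sorted descending, radius
`√(5λ)`. The √5 factor is the exact continuous-ellipsoid calibration
(a uniform ellipsoid with semi-axis a has eigenvalue a²/5), so digitized
balls report their true radius to within a voxel. Cells below 8 voxels, or
with degenerate (coplanar) covariance, carry `shape_valid = FALSE` and a
pitch/2 floor on the smallest radius rather than propagating unstable
ratios. Elongation and flatness are the radius ratios defined above — ≥ 1
by construction under sorted radii. Sample summaries use medians and
linear-interpolation quartiles (R type 7); density is an exact count over
the analysis cylinder volume; viability is the live fraction of the two
independently segmented fluorescence channels, reported to one decimal.

## Statistics

The gate is Shapiro–Wilk per group at α = 0.05: all groups normal →
one-way ANOVA with Bonferroni-adjusted pairwise t-tests (Welch by default;
the two-sample t-test variant is configurable, and a `force` argument
overrides the gate); any group non-normal → Kruskal–Wallis (tie-corrected,
via `stats::kruskal.test`) with Dunn's mean-rank z-tests, Bonferroni
adjusted — Bonferroni keeps the two branches' adjustment philosophies
parallel. Constant groups are rejected rather than given a fabricated
p-value. Over 1000 three-group null replicates the gated procedure's
empirical type-I error sits at the nominal 5% (the acceptance run prints
it).

## Problem sizes and numerical choices

The package's test and acceptance runs use desk-scale grids chosen once:
64³ voxels for reconstruction round trips, 96 × 128 × 128 at 5 µm (a
640 µm tube section, ≈ 0.145 µL analysis cylinder, ~43–145 cells at
300k–1M cells/mL) for end-to-end density recovery, and 256² frames for
illumination-correction measurements — the full 400-angle geometry
throughout. These scale the instrument's 2048² camera and 1.5 mm tube down
while preserving every ratio the claims depend on (cells per volume,
voxels per cell, angles per revolution). Tie-breaks and degenerate inputs
are handled explicitly: equal radii keep value ties (ratios only depend on
values), all-zero alignment frames get zero shift with a warning,
zero-intensity projections get an epsilon before the log, and identical
groups in a t-test return p = 1 under a documented ties policy.

## Known limitations

Quantitative fidelity of transmission-domain reconstruction relies on the
thin-object linearization; strongly absorbing samples would need the
post-log path and a measured flat field. The splat projector's 45°
lattice ripple is bounded but measurable. Density recovery assumes
segmentable, well-separated cells; at > 1M cells/mL real cultures form
clusters this package does not model. The automatic center-of-rotation
estimator presumes opposed-pair coverage (any full 360° acquisition) and a
non-empty slice. Fig-level agreement with any particular instrument's
absolute intensities is out of scope: the package's claims are about the
computational chain, verified against synthetic ground truth.
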