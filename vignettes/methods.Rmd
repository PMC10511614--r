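---
title: "Averaged wall-motion models and regional strain statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Averaged wall-motion models and regional strain statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices and limitations of
`aaastrain`.  It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` compute themselves.

## Data model

A *segmentation* is one manual masking of the aneurysm wall in the
end-diastolic 4D-ultrasound volume plus the speckle-tracked motion estimate
derived from it: a structured grid of material points — `n` rings
("heights") of `m = 36` circumferential points — with Cartesian positions
(mm) for each of `T` frames of one cardiac cycle.  Frame 1 is end-diastole
and serves as the reference configuration; it is itself a deformed state
(arteries carry axial and circumferential pre-strain), so all strains are
relative to end-diastole.  The grid is meshed into `(n-1) x m`
quadrilateral elements closed in the circumferential direction.  The
tracking software's artificial cap over the masked region (pseudo-apex) is
removed with `trim_pseudo_apex()` before analysis.

## Averaged wall-motion models

Repeated segmentations of one acquisition differ by a random error that is
large relative to AAA wall strains.  Averaging them must not average away
the mesh quality, so the package builds the average on a *homogeneous
re-mesh* rather than by snapping nearest nodes:

1. **Cylindrical unwrap.**  All segmentations are unwrapped about a single
   straight axis: the first principal direction of the first segmentation's
   reference-frame node cloud, anchored at its centroid.  The sign is fixed
   deterministically (positive component along the global axis of greatest
   cloud extent).  Because a bulged aneurysm can be nearly as wide as it is
   long, the axis frame's handedness relative to the grid's column order is
   not guaranteed; the unwrap therefore accepts either phi winding
   direction and either axial orientation.  The angular coordinate is made
   continuous across the branch cut per ring, and rings are aligned to ring
   1 by multiples of 2*pi.
2. **Homogeneous targets.**  `m_H` equally spaced angles (default 36) and
   `n_H` equally spaced axial stations (default: the smallest height count
   among the segmentations, so the re-mesh never exceeds the measured
   resolution) span the common axial interval.  The interval end is the
   worst angular position of each boundary ring — not the ring mean —
   inset by half a mean axial element length, which guarantees that every
   target lies strictly inside every segmentation's surface even when the
   boundary rings are tilted relative to the axis or perturbed by noise.
3. **Anchoring.**  Each target is located in its host element in the
   unwrapped plane and its local coordinates are obtained by inverting the
   bilinear map with a damped Newton iteration (residual tolerance 1e-10,
   at most 50 iterations, steps clamped to the cell scale, subdivision
   search as a last-ditch fallback).  Host candidates come from an exact
   ray-cast containment test with per-dimension bounding-box slack — the
   unwrapped plane mixes mm and radians, so isotropic nearest-centroid
   search is unreliable there.  Queries are tried at 2*pi (and, for
   branches starting near +pi, 4*pi) images of the angle.
4. **Tracking and averaging.**  The anchored point moves with its element,
   `H^t = sum_a N_a(r_H, s_H) x_a^t`; the reference position is the same
   combination at `t = 0`, which makes the anchor/interpolant pair exactly
   consistent.  The averaged model is the unweighted arithmetic mean over
   segmentations at every (point, frame); no outlier rejection is applied.
   Interpolation in the unwrapped plane is bilinear: monotone, no
   overshoot at sharp bulges, and exact for the per-chord scaling that
   radial pulsation produces.

## In-plane Biot strain

Wall thickness is not measurable in these data, so the wall is treated as a
membrane and only in-plane strain components are computed.  Per element and
configuration a local orthonormal frame is built at the centroid: the
circumferential axis `e2` is the normalised mean of the two circumferential
edge vectors, the longitudinal axis `e1` is the mean of the two
longitudinal edges orthogonalised against `e2` (Gram–Schmidt).  The exact
construction of these frames is an implementation choice.  Reference and
current nodes are projected into their own frames (out-of-plane warping is
discarded), the 2x2 deformation gradient `F` is evaluated at the centroid
`r = s = 0` via the shape-function derivatives and the reference Jacobian,
and the Biot strain is

    eps = U - I,   U = sqrt(F'F),

computed with the closed form
`U = (C + sqrt(det C) I) / sqrt(tr C + 2 sqrt(det C))`, falling back to an
eigendecomposition when the denominator is near zero.  Because both frames
are re-derived per configuration and `U` discards rotation, the measure is
objective: a rigid transform applied to all frames changes no component
(verified to 1e-10 in the tests against an eigendecomposition oracle, which
replaces an external finite-element cross-check).  Elements with in-plane
aspect ratio above 100 or reference area below 1e-6 mm^2 are flagged and
excluded from the distribution indices, with a logged count.  `det F <= 0`
(element inversion) is a hard error naming the element and frame.

Peak-to-peak amplitudes `max_t eps - min_t eps` (components reduced
independently, the zero reference frame included) summarise each element's
cycle; all human-facing output reports them in percent.

## Registration and calcification mapping

The moving ultrasound cloud is registered to the static CT wall cloud by
ICP: k-d tree nearest-neighbour correspondences (distance ties resolve to
the lowest static index, matching a brute-force scan), then a bounded
Levenberg–Marquardt update of all transform parameters against the current
correspondences, iterated until the RMSE changes by less than 1e-6 mm or
100 iterations.  Rotation (and scale/shear) act about the moving cloud's
centroid and the translation is initialised by superimposing the centroids,
so the default bounds — rotations ±30°, translations ±20 mm, scales
[0.8, 1.2], shears ±0.2 — are interpretable; the bounds exist because
near-symmetric fusiform shapes invite unphysiological optima.  Bound values
are package defaults (config-overridable).  Affine registration refines
from the rigid solution, which stabilises its nine extra parameters.  Note
that the scale–rotation–shear composition has 12 parameters for a 9-dof
linear map, so individual scales and shears are not identifiable — only
the composed matrix is; tests compare composed matrices.  Because the
cardiac phase of the CT scan is unknown, every ultrasound frame is
registered and the smallest-RMSE frame kept.  RMSE is directed
(ultrasound to CT, matching the ICP objective); the Hausdorff distance is
reported symmetric with both directed values alongside, since either
convention is found in practice.

Calcification mapping uses the affine result: each element is sampled on a
10x10 interior (r, s) lattice, and the covered fraction is the share of
samples within a capture radius of any calcification point.  Elements with
at least half their area covered are calcified; connected calcified patches
smaller than a configurable minimum are cleared (calcifications too small
to cover one element are neglected).  The low-level default capture radius
is half the calcification cloud's median point spacing; the pipeline
default widens it to the wall cloud's median spacing when that is larger,
because two independently sampled surfaces retain a perpendicular offset
after registration that the calcification spacing alone does not bridge.
This deterministic rule replaces a by-eye expert assignment, keeping the
half-area threshold.

## Regional statistics

Per region (calcified / non-calcified) and component, the distribution
indices are: mean and maximum amplitude (%), local strain ratio
(max/mean), and heterogeneity index (coefficient of variation, sample
n-1 standard deviation over the mean — the sd convention is a package
choice and switchable).  Ratio and heterogeneity are `NA` when undefined
(zero mean, or fewer than two elements), never infinity.  Quartiles and
medians are included for table-style reporting.

The regional comparison is a left-tailed Mann–Whitney U test (alternative:
calcified median smaller).  The exact null distribution is used for
combined samples up to 20 without ties, otherwise the normal approximation
with tie and continuity correction — the size-based switch mirrors common
packaged behaviour.  A Kolmogorov–Smirnov check against a normal with the
sample's own mean and sd (plain KS, no Lilliefors correction) is logged as
the justification for the nonparametric test; it is informational only.

## The synthetic phantom

`phantom_spec()` defines the study conditions; its defaults are fixed once
from the imaging context the package targets and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `rho0`, `bulge_a`, `bulge_sigma` | 15, 10, 12 mm | base radius + Gaussian bulge: peak diameter ~50 mm |
| `length`, `n`, `m` | 50 mm, 14, 36 | imaged vessel length and grid (504 tracked points) |
| `frames` | 20 | deformation states per cardiac cycle |
| `A` | 0.012 | peak circumferential strain (1.2 %) |
| `kappa` | 0.75 | compliance factor inside calcified patches |
| `calc_patches` | 2 patches | sized to give >= 60 fully calcified elements |
| `asym` | 0.2 | azimuthal bulge modulation |
| `sigma_n` | 0.3 mm | segmentation node noise sd |

Nodes pulsate radially, `r(x, phi, t) = rho(x, phi) (1 + A c(x, phi) w(t))`
with the raised-cosine waveform `w(t) = (1 - cos(2 pi t/T))/2`; axial
motion is off by default, which keeps the analytic truth exact: every
circumferential chord between equal-compliance nodes scales by exactly
`1 + A c w(t)`, so interior elements have true amplitude `A c` and
calcified elements strain exactly `kappa` times their neighbours.  The
azimuthal modulation keeps the shape fusiform but not perfectly
axisymmetric — on a surface of revolution, rotation about the axis would be
unidentifiable for ICP, which real aneurysms do not exhibit.

Simulated segmentations add i.i.d. Gaussian node noise (sd `sigma_n`)
independently per segmentation and frame, plus a smooth per-segmentation
bias field (amplitude `sigma_n/2`, constant over the cycle, low-order
harmonics in axial position and angle) that mimics observer-dependent
masking.  CT-like clouds are area-uniform samples of the surface at one
frame (rejection sampling), with calcification points restricted to the
patches, mapped by a known rigid/affine transform and jittered.

**What the phantom does not emulate:** speckle physics, angle-dependent
contrast, temporally correlated tracking errors, wall thickness, or
intraluminal thrombus.  Passing tests therefore demonstrate correctness of
the geometry, strain, registration and statistics machinery under a known
truth — not clinical performance on patient data.

## What averaging can and cannot recover under this noise model

The frame-independent node noise has a strong consequence that the tests
expose deliberately.  A per-configuration strain estimate divides node
noise by the element chord length (~2.6–4.4 mm here), giving per-frame
strain noise of roughly `sigma_n / chord` ≈ 7–11 %; the peak-to-peak
amplitude of ~20 such frames concentrates near 3.7 times that.  With
`sigma_n = 0.3` mm the amplitudes of single segmentations — and, reduced
by sqrt(K), of averaged models — are therefore noise-dominated relative to
a 1.2 % signal, and the 25 % compliance contrast of the calcified patches
is not reliably detectable at K = 10.  Worse, amplitude noise scales with
1/chord, so regions of different element size acquire systematically
different noise floors: a geometry–noise confound that can drive the
regional test on single noisy segmentations regardless of compliance.  The
end-to-end discrimination test in the acceptance suite documents this
honestly and currently fails under these conditions.  Reliable
discrimination at this noise amplitude would require temporally correlated
noise (a masking error constant over the cycle largely cancels in strain)
or a far smaller frame-to-frame tracking error.  The noise-free phantom,
by contrast, reproduces the expected regional contrast exactly, as the
acceptance script shows.

## Problem sizes and determinism

Tests and the acceptance script run the default 14 x 36 x 20 phantom with
K = 10 segmentations, CT wall clouds of ~2,000–10,000 points, 20-replicate
variance studies and 100-replicate power studies — sizes chosen so the
whole validation executes in minutes on one CPU while keeping every
regional sample above 60 elements.  All stochastic steps take explicit
seeds; reruns with the same seed are bit-identical.  Conventions: lengths
in mm, angles in radians internally (degrees at the command line), strains
dimensionless internally and percent in reports, indices 1-based in R with
0-based frame/height/column indices in the on-disk table format.

## Known limitations

- The straight PCA axis can be a poor unwrap axis for strongly curved or
  very stubby vessels; a curved centreline is not implemented.
- Averaging assumes all segmentations share one coordinate base (one
  acquisition); combining separate acquisitions would need pre-alignment.
- The membrane assumption ignores through-thickness strain; no stresses or
  material parameters are computed.
- ICP is local: initialisation beyond the bounded neighbourhood of the
  truth (beyond roughly ±10–30° after centroid superposition) may converge
  to a bounded but wrong optimum.
- Distribution indices are per dataset; aggregation across patients is
  left to the caller.
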