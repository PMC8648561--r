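---
title: "Simulating and analysing hierarchical phase-contrast tomography at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing hierarchical phase-contrast tomography at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiptomo)
```

## What this package models

Hierarchical phase-contrast tomography (HiP-CT) images whole fixed human
organs mounted in agar–ethanol inside a cylindrical jar: a synchrotron
parallel beam traverses the jar, free-space propagation converts phase
gradients into edge contrast at the detector, and a whole-organ scan at
~25 µm/voxel is followed by interior "zoom" scans of volumes of interest
(VOIs) at 6.5 and 1.3–2.5 µm/voxel. Interior scans are *local tomography*:
the projections are laterally truncated because the organ is wider than the
zoomed field of view, which classically produces strong low-frequency
("cupping") backgrounds. The technique's central trick is an *equivalent
reference jar* — a second container of mounting medium riding above the
sample — whose angularly averaged projections serve as flat-field
references that cancel most of that background before reconstruction.

`hiptomo` re-implements this pipeline end to end at desk scale:

1. **Phantoms** (`build_jar_phantom()`, `build_kidney_phantom()`,
   `build_alveolar_phantom()`): seeded, labelled voxel worlds with a known
   ground truth — the mounting jar, a parenchyma shell packed with
   glomerulus-like spheres, and a Voronoi-cell alveolar foam with optional
   consolidation.
2. **Acquisition** (`simulate_scan()` and friends): line integrals of the
   attenuation coefficient µ and refractive decrement δ, Fresnel
   propagation, beam profiles, Poisson + read noise, sub-frame
   accumulation, centered / half / quarter geometries, vertical series,
   and reference-jar scans.
3. **Reconstruction** (`reconstruct_scan()` and the individual operators):
   reference flat-fielding, vertical-profile residual subtraction,
   single-distance phase retrieval with an unsharp mask, extended-FOV
   sinogram stitching, filtered back-projection, ponderate vertical
   concatenation, 16-bit conversion, ring and stripe correction.
4. **Quality** (`fsc()`, `snr()`, `ssim_pairs()`, `histogram_stats()`):
   Fourier shell correlation with the ½-bit criterion and the
   9-subvolume protocol, SNR, structural similarity with group
   resampling, histogram statistics.
5. **Morphometry** (`threshold_volume()`, `chamfer_distance()`,
   `local_thickness()`, `surface_area_to_volume()`, `connectivity()`,
   `object_morphometry()`, `virtual_biopsy()`, `estimate_total_units()`,
   `morphometry_report()`): the quantitative biology applied to kidney
   and lung volumes.

## The physical model and its assumptions

**Monochromatic effective energy.** The real beamline uses a filtered
polychromatic beam characterised by an average energy; we simulate a
monochromatic beam at an effective energy (default 85 keV), so
beam-hardening is out of scope. Wavelength follows
$\lambda[\mathrm{Å}] = 12.398 / E[\mathrm{keV}]$.

**Materials.** Each label carries $(\mu, \delta, \beta)$ with
$\mu = 4\pi\beta/\lambda$ enforced exactly. Defaults (85 keV):
agar–ethanol µ = 0.018 mm⁻¹, soft tissue 0.022 mm⁻¹, dense functional
units 0.026 mm⁻¹, jar wall 0.035 mm⁻¹, with δ/β ≈ 10³. These are
*plausible placeholders* chosen to give weak absorption contrast and
strong phase contrast, as for ethanol-equilibrated fixed tissue; measured
optical constants for this preparation are not tabulated anywhere.

**Band-limited interfaces.** `phantom_property_volume()` smooths material
interfaces with a 1-voxel Gaussian before projection. Fixed organs in
mounting gel have no sub-voxel-sharp density steps, and the detector
optics have a finite point-spread; projecting raw binary labels would put
non-physical above-Nyquist content into the data that no reconstruction
could recover (with hard edges even a matched textbook
radon/filtered-back-projection pair leaves 3–4% RMS error at 256², almost
all of it edge ringing). The label volumes used by morphometry remain
binary.

**Forward projection.** Parallel-beam line integrals per axial slice,
bilinear interpolation, configurable step (default half a voxel);
$A = \int \mu \, ds$ and $\Phi = -(2\pi/\lambda)\int \delta \, ds$.
The detector intensity is
$I = |F^{-1}[F[e^{-A/2 + i\Phi}] \, e^{-i\pi\lambda D(u^2+v^2)}]|^2$,
with replicate-edge padding before the FFT; $D = 0$ returns $e^{-A}$
exactly. Counts are Poisson with per-pixel expectation
flux · I · h(x) · v(y), plus Gaussian read noise (default σ = 1 count)
and an optional fixed per-column gain-error field, the driver of ring
artefacts.

**Accumulation.** Sub-frames are averaged (not summed), so grey levels do
not depend on the accumulation count; saturated pixels are flagged and
excluded from the mean. The attenuation-dominated whole-organ protocol
uses ~10 sub-frames; zoom scans, being phase-dominated, use fewer.

## Reconstruction choices

* **Reference flat-fielding** divides each projection by the mean of the
  reference-jar frames in a centred angular window (default 100
  projections, clamped at the scan ends — the window tracks the beam in
  time, and wrapping would pair the scan's first and last projections,
  which are the furthest apart in time; a piecewise "new reference every
  100 projections" variant is selectable). Because the reference
  jar mimics the bulk absorption of the mounted organ, the quotient
  removes most of the truncation background *before* any algorithmic
  padding. Reconstructed grey levels are then attenuation *differences*
  against the mounting medium.
* **Phase retrieval** is the single-distance homogeneous-object filter,
  $t = -\ln F^{-1}[ F[I] / (1 + \pi\lambda D (\delta/\beta)(u^2+v^2))]$,
  with δ/β = 1000 by default (no published value exists for this
  preparation; the ratio is exposed in `retrieval_params()`), followed by
  an optional unsharp mask (σ = 2 px, amount 1 by default).
* **FBP** uses the discrete ramp kernel with a Hann apodisation by
  default (pure ramp selectable), linear interpolation, and zeroes the
  region outside the inscribed field-of-view circle, which the
  projections do not determine. With detector pixels in µm the output is
  µ in mm⁻¹.
* **Half-acquisition stitching** pairs each angle θ with its mirrored
  partner at θ+180° and blends the doubly covered band with linear ramp
  weights summing to one; `cor_offset_px = 0` degenerates to plain
  averaging of the two half-turns. Quarter acquisition additionally
  scales the annular scan by the ratio of means in the common bands
  before the same linear transition.
* **Vertical concatenation** estimates an integer z-shift per junction by
  cross-correlating the nominally overlapping slices (falling back to the
  nominal overlap with a warning when the correlation peak is weak) and
  blends with linear ("ponderate") weights.
* **Ring correction** works on the reconstructed slice: polar resampling
  about the rotation centre, angular median per radius, a running-median
  split into genuine radial structure versus the ring profile, and
  subtraction of the profile at every pixel radius with the slice mean
  preserved exactly. The upstream tool this emulates is only loosely
  specified ("derived from" a published method), so this polar-median
  variant is our interpretation. The profile is *not* smoothed by default:
  smoothing trades residual ring amplitude for noise robustness.
* **Stripe correction** removes isolated constant-z plane offsets by
  subtracting the difference between the per-slice mean profile and its
  running median along z; it is close to idempotent.
* **Vertical-residual subtraction** operates in the log domain (the
  upstream description does not say which; log keeps the correction
  additive in attenuation) and subtracts the mean-preserving per-row
  median over all angles and columns.

## Quality metrics

FSC shells are one frequency voxel wide up to Nyquist; the ½-bit
threshold is $T(n) = (0.2071 + 1.9102/\sqrt{n})/(1.2071 + 0.9102/\sqrt{n})$
with $n$ the effective independent voxels per shell (half the voxel count,
for Hermitian symmetry, times a window factor when the 3D Hann window is
applied). The zero-frequency shell is a single coefficient and is never
reported as a crossing. Resolution is `voxel_size / crossing_frequency`
(a crossing at 0.25 cycles/voxel with 2.5 µm voxels reads 10 µm) — the
half-period convention; period versus half-period is the classic
ambiguity of FSC reporting, so the convention is fixed here once. The
subvolume protocol draws 9 random cubes (sizes from a supplied ladder) at
identical positions in both volumes and reports mean ± SD of the
crossings, excluding (with a warning) subvolumes that never cross.

SSIM uses the standard constants (K₁ = 0.01, K₂ = 0.03, Gaussian window
σ = 1.5, dynamic range from the data percentiles). In the grouped
comparison a slice number is never paired with itself — within one volume
that is a degenerate self-comparison, and excluding it in all four groups
keeps them exchangeable under the null.

## Morphometry choices

* **Thresholds** (triangle, Yen, Otsu) operate on a 256-bin histogram of
  the data range, as the classical algorithms are defined.
* **Chamfer distance** uses the ⟨3,4,5,7⟩ weights over the
  26-neighbourhood plus the (1,1,2)-type displacements, normalised by the
  face weight. Its worst-case deviation from Euclidean distance is ±6%
  (the gauge extremes sit in the (1,1,0) and (3,1,0) directions).
* **Local thickness** is the largest-inscribed-sphere diameter computed
  by sphere painting on the exact Euclidean distance transform, with the
  half-voxel boundary correction (an n-voxel slab reports exactly n
  voxels). The painting shortcut skips voxels already covered by a larger
  sphere, which can differ on ties by scan order: thickness maps are
  reproducible, but axis permutations may disagree on ~0.1% of voxels by
  a voxel or two.
* **Surface area** uses the Crofton formula with 25 sampling directions.
  The direction-class weights were fitted to the spherical average of
  |cos| over plane orientations (residual anisotropy ±3%) and corrected
  per class for the crossing-count inflation of digitised curved
  surfaces, calibrated once on a digitised ball of radius 20 voxels;
  planes and axis-aligned boxes have unbiased counts and are unaffected.
  This is also the estimator family behind the 3D region analysis used
  for the original organ measurements, which reinforced choosing it over
  an isosurface mesh (no meshing infrastructure is needed). The ratio can
  be referenced to the phase volume (a ball reads 3/r) or to the whole
  VOI volume (the stereological surface density S_V used in the grouped
  lung comparison — the convention under which thickening septa *lower*
  the airspace value).
* **Connectivity** reports the exact Euler characteristic of the cubical
  complex of the foreground (χ = V − E + F − C) in the trabecular
  convention: connectivity = 1 − χ, density per VOI volume. This differs
  from 26-connectivity lookup-table estimators only for single-voxel
  diagonal contacts, which the in-scope phantoms do not produce.
* **Counting rule.** Virtual biopsies count an object when its centre
  (ground-truth centre or labelled-object centroid) lies inside the
  cylinder, boundary inclusive — a centre rule avoids double counting at
  biopsy edges. The whole-organ extrapolation multiplies the count by the
  parenchyma-volume ratio; its uncertainty scales the Poisson counting
  error by the same ratio.
* **Airspace size distributions.** Pointwise thickness histograms of a
  closed-cell foam are intrinsically multi-peaked (polyhedral corner
  wedges), so the "bimodality under consolidation" analysis is performed
  on per-component equivalent diameters: consolidated alveoli retain a
  tiny residual air pocket (exudate rarely fills an alveolus completely;
  generator default: pocket radius 10% of the cell diameter, which keeps
  a fully consolidated foam below 1% airspace), and these pockets form
  the second, small-diameter mode.

## What the generators emulate — and what they do not

The phantoms reproduce the *geometry* that drives the pipeline: a
cylindrical jar with weak tissue/medium contrast, spatially uniform
functional units for stereology, thin-walled foam for lung morphometry,
tubule-like rings with open lumina for SNR measurements. They do not
contain vasculature, airway trees, anisotropic fibres, realistic organ
outlines, or beam-hardening spectra. A green test therefore establishes
that the *pipeline operators* behave as specified on controlled worlds
with known truth — not that the simulation reproduces any real organ's
grey-level statistics or the numeric values measured on the multi-hundred
gigabyte organ volumes, which are out of scope by design.

The lateral-transect experiment (`scenario_lateral_transect()`) deserves a
note: the real validation measured tubule-wall SNR against the tubule's
own lumen at increasing lateral offsets. SNR against a *local* background
is deliberately insensitive to residual low-frequency background, and the
desk-scale experiment mirrors that: every offset is measured at three
azimuths, with one reference-jar scan per VOI reused across noise
repetitions, as at the beamline. Two small-phantom effects that a
multi-centimetre organ does not have are controlled explicitly: each
tubule's partial-volume contrast (which depends on how it happens to sit
on the pixel grid) is calibrated against a noise-free reconstruction of
the same VOI, and the noise seeds are common across offsets (common
random numbers), so the offset correlation reflects systematic behaviour
rather than the luck of the draw. The flat-field comparison
(`scenario_flatfield_comparison()`) contrasts the same truncated off-axis
scan through the reference-jar and classical-flat pipelines and measures
the low-frequency background amplitude over the feature-free parenchyma.

## Numerical and degenerate-input conventions

* Cylinder membership is evaluated at voxel centres, boundary inclusive;
  with inclusive ends a cylinder of length L covers L/voxel + 1 slices,
  so the voxel-count volume converges to πr²L from above as the
  resolution increases.
* `to_uint16()` maps the (0.1, 99.9) percentile window to [0, 65535]; a
  constant volume maps to the midpoint 32768 with an exactly invertible
  scale. The scale travels in a JSON sidecar next to TIFF stacks and as
  HDF5 attributes.
* Seeded operations save and restore the caller's RNG state, so a fixed
  seed makes every float32 artifact bit-reproducible without disturbing
  the session.
* Degenerate windows: a reference window of one block equals classical
  flat-field division; `unsharp_mask(amount = 0)` is the identity;
  `build_half_sinogram(o = 0)` averages the two half-turns.

## Known limitations

* No cone-beam or fan-beam geometry, no partial-coherence blur beyond the
  optional Gaussian, no iterative reconstruction, no dose model.
* The Fresnel propagator warns (rather than refusing) outside its
  near-field sampling validity.
* The Crofton weights are calibrated at the package's working resolutions
  (objects tens of voxels across); very small or very large structures
  re-expose the O(1/r) digitisation bias.
* The quarter-acquisition interface stitches a half-acquisition sinogram
  with a wider annular sinogram on a shared angular grid; it does not
  model the annular scan's separate rotation hardware.
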