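---
title: "Methods: infrared-guided microdissection from spectra to statistics"
author: "ftirlcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrared-guided microdissection from spectra to statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirlcm)
```

## The problem and the model

An FTIR imaging microscope records, for every pixel of an unstained tissue
thin-section, an absorbance spectrum `A(ν)` over 2700–950 cm⁻¹ at a nominal
4 cm⁻¹ step (438 bands on the stored grid, whose last on-grid point is
952 cm⁻¹). The package treats this cube as the primary object
(`spectral_image`): a rows × cols × bands array, a strictly monotonic
wavenumber axis stored in descending acquisition order, a pixel size in
micrometer, and the stage position of the first pixel. All band selection is
by wavenumber interval, never raw index, and the stage position of 0-based
pixel `(r, c)` is defined once, globally, as the *pixel center*
`(origin_x + (c + 0.5)·w, origin_y + (r + 0.5)·h)` with stage y downward.
The boundary polygons handed to the microdissection instrument are built
from the middles of marginal pixels, so this convention is load-bearing
everywhere.

The pipeline is: quality control → scattering correction → hierarchical
classification → region extraction and size splitting → coordinate transfer
→ pooling → differential statistics. Each step is a separate module with a
narrow contract, so every one can be validated against synthetic ground
truth independently.

## Quality control

A pixel is usable iff its signal-to-noise ratio is at least `snr_min`
**and** its amide I integral lies inside
`[amide_integral_min, amide_integral_max]`. Neither criterion has a
universal definition, so the package fixes computable ones:

* signal = maximum absorbance in the amide window (1700–1600 cm⁻¹) above
  the straight line through the window endpoints;
* noise = standard deviation of the residual after a linear detrend over
  2000–1800 cm⁻¹, a spectroscopically quiet region inside the acquisition
  range;
* a zero-noise spectrum yields infinite SNR (pass) unless it is identically
  zero, which yields 0 — so flat-but-nonzero spectra are not rejected for
  the wrong reason, while blank pixels fail on the amide criterion.

Failure codes are assigned with priority `amide-low` > `amide-high` > `snr`:
a blank (cracked) pixel fails as `amide-low` and a saturated one as
`amide-high`, regardless of what its degenerate SNR happens to be. Defaults
(`snr_min = 10`, amide integral in `[0.5, 60]` absorbance·cm⁻¹) are
configuration, not science; they are chosen so that nominal tissue passes
while blank and saturated pixels fail. The mask is recomputed from the cube,
making the operation idempotent.

## EMSC scattering correction

Spherical cellular structures superimpose a broad oscillatory Mie extinction
baseline on the chemical absorbance. The correction model over the
2300–950 cm⁻¹ fit range is linear least squares per pixel:

`z(ν) = c·m(ν) + Σⱼ bⱼ νʲ + Σᵢ gᵢ pᵢ(ν) + e(ν)`

with reference spectrum `m`, polynomial baseline of order 2 (evaluated on a
standardized wavenumber for conditioning), and `k = 7` orthonormal principal
components `pᵢ` of van de Hulst extinction curves
`Q = 2 − (4/ρ)sin ρ + (4/ρ²)(1 − cos ρ)`, `ρ = 4πrν(n−1)`, simulated on a
10 × 10 grid of radii `r ∈ [2, 8]` μm and refractive indices
`n ∈ [1.1, 1.5]`. The corrected spectrum is `(z − baseline − Mie)/c`. Design
choices worth stating:

* The non-resonant van de Hulst approximation is used; the interface keeps a
  hook for a resonant complex-index basis but that refinement is out of
  scope.
* `c > 0` is required; pixels with `c ≤ 10⁻³` are flagged degenerate and
  removed from the mask instead of being "corrected" into garbage.
* With `n_iterations > 1` the reference is replaced by the current corrected
  spectrum and the fit repeated. On undistorted input the iteration is
  stationary after the first pass (verified to 10⁻¹⁰), which is why one
  iteration is the default.
* The correction is scale-invariant: correcting `a·z` returns the same
  corrected spectrum with `c` scaled by `a`.
* A degenerate Mie grid (a single `(r, n)` point) has zero variance after
  mean-centering; the basis then falls back to the normalized common curve
  itself rather than an undefined principal component.

The corrected image lives on the fit-range grid (952–2300 cm⁻¹ on the
default axis); nominal ranges that overhang the stored grid by less than one
step are clipped rather than refused.

## Savitzky–Golay filtering

The conventional 9-point window with polynomial order 3; derivatives are
scaled by the actual wavenumber step. Edges are reflect-padded
*point-symmetrically* (odd reflection about the end sample), which keeps
straight lines straight across the boundary, so the second derivative of a
line is exactly zero everywhere including the edges. Smoothing and second
derivatives are provided for unsupervised exploration only; the classifier
consumes EMSC-corrected raw absorbance.

## The classifier cascade

Classification is hierarchical: a first random forest separates the coarse
tissue states, and each deeper level refines one parent class into finer
classes — tumour classes within pathologic tissue, then subtypes within one
tumour class. The hierarchy is data (`cascade_spec`), not code, so other
tissue systems are expressible. One forest is fitted *per refinement node*
(per parent), trained only on pixels whose ancestry passes through that
parent; prediction descends the tree. This makes the restriction property —
no pixel carries a leaf label whose parent it was not assigned — true by
construction, and the per-level assignment trail is attached to every
predicted map so tests can audit it.

Features are the fingerprint region 1800–950 cm⁻¹ (213 bands on the default
grid, descending). The prediction grid must match the training grid exactly;
a shifted axis is an error, never silently resampled. Forest defaults:
200 trees, `√B` features per split, no depth limit, out-of-bag scoring, and
per-class balanced subsampling (`strata`/`sampsize`) because tissue classes
are rarely equally abundant. Training and prediction are deterministic given
the seed. Per-sample diagnosis is the majority class among candidate
subtype pixels; when both members of a designated pair (e.g. epithelioid
and sarcomatoid) exceed a 0.20 fraction the sample is called mixed
("biphasic"). Pixel-level classification with sample-level majority calls
mirrors how slide-level diagnoses are read off index-colour maps.

## Regions, watershed, transfer, pooling

Regions of interest are 8-connected components of the target class
(8-connectivity avoids checkerboard fragmentation); a pixel is *marginal*
if one of its 4-neighbours lies outside the region. The boundary polygon is
the outer Moore contour restricted to marginal pixels, oriented
counter-clockwise in image coordinates, starting at the topmost-then-
leftmost marginal pixel — fully deterministic. Re-rasterizing the polygon
vertices recovers the marginal set exactly; interior holes are not traced
(a documented limitation; dissection shapes are outer contours).

Cutting shapes are size-limited by the instrument, so oversized regions are
split by a watershed of the Euclidean distance transform, seeded at its
regional maxima. Because watersheds over-segment, adjacent catchments are
then merged smallest-first while the merged size stays within
`max_shape_area` (default 250 000 μm², configurable); a catchment that
still exceeds the limit — a single maximum can own an arbitrarily large
basin — is bisected recursively along its principal axis. The result is
asserted to be a partition on every call: fragments are disjoint, their
union is the region, and areas and amide integrals add exactly.

Stage-to-stage transfer is a 4-parameter Helmert similarity fitted by
linear least squares to at least three non-collinear reference points;
collinearity is a conditioning error, not a warning. Anisotropic pixel
scaling and the visible–infrared rotation are handled *before* the Helmert
map by a separate aberration calibration (per-axis scale + rotation fitted
to a resolution-target grid), keeping the Helmert map strictly
4-parameter. With isotropic noise σ on n pairs the rms residual follows
`σ·√(2(n−2)/n)`, which the tests verify over 200 simulated fits.

Pooling: each sample contributes fragments until its summed amide integral
reaches a common target within a tolerance (default 2 % of the target), by
greedy largest-first packing with single-swap refinement — exact subset-sum
is NP-hard and unnecessary at these sizes. Balancing by integral rather
than by area equalizes protein amount, which is the point of measuring the
amide band in the first place; balancing by equal area remains possible by
passing unit integrals.

## Differential statistics

The pipeline order is fixed and tested: arcsinh transform
(`ln(x + √(x²+1))`), technical-replicate averaging on the transformed
scale, pooled-variance two-sided t-test on the per-sample means
(`df = n₁+n₂−2`), fold change on the *untransformed* normalized scale
(replicate-averaged; a back-transformed alternative sits behind
`fc_scale`), the significance triple (≥2 unique peptides, fold change ≥2
or ≤−2, p ≤ 0.05, all boundaries inclusive), and the Euclidean ranking
distance `d_eucl = √((log₁₀ p)² + (log₁₀ FC)²)` — the distance from the
origin of the volcano plane, so that effect size and significance rank
jointly. `d_eucl` is monotonic in both arguments and bounded below by each
of `|log₁₀ p|` and `log₁₀ FC`. Contour tiers at radii 1, 1.5 and 2 use
closed boundaries (a record exactly at a level belongs to it). No multiple-
testing correction enters the significance call; a Benjamini–Hochberg
column is emitted for information only. Ranking ties break by smaller p,
then accession, making exports byte-reproducible.

Zero pooled variance is handled explicitly (p = 1 for equal means, a
degenerate flag otherwise), and proteins with a zero group mean are
excluded from ranking rather than mapped to infinite fold changes.

## What the synthetic generators emulate — and what they do not

`generate_phantom()` builds per-pixel spectra as
`concentration × class signature + mie_fraction × Q(ν; r, n) + noise`:
Gaussian-band class signatures (three synthetic "tissue" classes differing
in amide I/II ratio, a lipid-like 1740 cm⁻¹ and a carbohydrate-like
1050 cm⁻¹ band; every signature has a positive amide I band near
1654 cm⁻¹), a uniform concentration field in `[0.7, 1.3]`, per-pixel Mie
spheres drawn from the same `(r, n)` ranges as the correction basis, i.i.d.
Gaussian noise (σ = 0.005 default), and planted blank/saturated defect
pixels. Signature amplitudes (amide I peak 0.64–0.80 absorbance) and the
default `mie_fraction = 0.05` are chosen once so that nominal tissue falls
inside the default QC acceptance band while defects fall outside — they are
plausible magnitudes for 10 μm cryosections, not fitted to any measured
spectra. The generators are pure functions of spec + seed.

What phantoms do *not* contain: real biochemical band shapes, spatially
correlated noise, water-vapor lines, resonant-Mie band distortion
(derivative-shaped artifacts at absorption bands), mosaicking seams, or
tissue texture. Passing phantom tests therefore demonstrates that the
algorithms are implemented correctly and behave as specified under
controlled violations — not that real-tissue accuracy matches any published
figure. Real-tissue performance cannot be reproduced here at all, since no
spectra are publicly deposited; the printed-value surfaces that *are*
reproducible (the nine-protein ranking distances and the 17-sample
evaluation metrics) are recomputed exactly by `scripts/acceptance.R`.

`generate_protein_table()` plants multiplicative group effects on log-normal
baselines with unit-mean log-normal run noise at a stated CV. With only
run-level noise, replicate-averaged sample values are i.i.d. within groups,
so the null t-test is calibrated (verified: rejection rate 0.05 ± 0.01 at
2000 proteins) and a planted 4-fold effect at 10 % CV is recovered
essentially always. Power tests generate all proteins with ≥2 unique
peptides so that the peptide filter — tested separately — does not confound
the statistical property.

## Numerical choices and problem sizes

* Band integrals are trapezoidal on the native grid; the optional baseline
  is the straight line through the window endpoint samples.
* EMSC design matrices are factored once (QR) and applied to all pixels of
  an image as a multi-right-hand-side solve.
* Helmert and calibration fits are plain linear least squares; degenerate
  geometry raises a conditioning error.
* Test problem sizes are the package's own choice for fast, deterministic
  suites: 48 × 48 × 438 phantoms for classification (about 500–1200
  training pixels per class), 10 train/test seed pairs for the held-out
  accuracy property, 200 seeds for the residual law, 2000 proteins for null
  calibration, 500 seeds for the fold-change interval. A full 64 × 64 × 438
  phantom preprocesses (QC + EMSC) in about a second on one CPU.

## Known limitations

* Boundary polygons trace outer contours only; regions with interior holes
  get their hole margins ignored in the exported shape.
* The watershed split guarantees the size bound and partition exactness but
  not minimal fragment count or equal fragment sizes.
* Greedy pooling can miss an exact subset that a full subset-sum search
  would find; with realistic fragment counts (tens per sample) it lands
  within tolerance in practice.
* The EMSC basis is non-resonant; strongly resonant distortions (sharp
  derivative-shaped band artifacts) are only approximated by the polynomial
  + Mie terms.
* Label maps are stored as 8-bit PNG, capping a legend at 255 classes.
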