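---
title: "Scanning diffraction imaging with diffscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning diffraction imaging with diffscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffscan)
```

## The problem

A scanning X-ray microdiffraction experiment raster-scans a microbeam
across a tissue section and records one 2D diffraction pattern per
position. Semi-crystalline tissue components — collagen, myelin,
amyloid — produce rings (isotropic packing) or centrosymmetric arc
pairs (partially oriented packing) at radii set by their lattice
spacings. Four quantities per position summarize the material:

* the **integrated intensity** of the diffraction features, proportional
  to the amount of diffracting material;
* the **d-spacing** of each ring, which identifies the material (CNS
  myelin, for instance, has a principal repeat near 160 Å);
* the **orientation angle** of the arc pair, which tracks the fiber
  axis (fibrillar assemblies) or its perpendicular (lamellar assemblies
  such as myelin — hence the rotate-90° display option);
* the **angular spread** (angle σ) of the arcs, which measures the
  degree of disorientation; a full ring means isotropy.

`diffscan` reduces a folder of detector frames to these per-position
quantities and assembles them into 2D parameter maps of the scanned
region.

## Geometry and calibration

Pixel radius `r` converts to a d-spacing through Bragg's law with the
full trigonometric forms (no small-angle approximation, so wide-angle
data are handled correctly):

    2θ = atan(r · p / S),   d = λ / (2 sin θ),

with `p` the pixel size (mm), `S` the sample-to-detector distance (mm)
and `λ` the wavelength (Å). Calibration fits a circle (algebraic Kåsa
fit plus one Gauss–Newton refinement of the geometric residual) through
points clicked on the first-order ring of a calibrant — silver behenate,
d = 58.38 Å, by default — and inverts Bragg's law for `S`. The fitted
circle center becomes the beam center. Pixel coordinates are 0-based,
`(x = column, y = row)`, with pixel centers at integers; azimuth θ runs
counter-clockwise from the +x axis of the displayed image (row 0 at
top).

## The polar field

All detection and fitting happens on the polar resampling
`I(θ, r)` of each frame about the beam center, by default on a
1° × 1 px grid. Each bin averages bilinear samples spaced about one
pixel apart along its arc; the fraction of valid (unmasked) samples is
kept as a per-bin weight. Bin values are means rather than sums so that
wedge width does not rescale profile amplitudes. Bins with no valid
sample are missing (`NA`), never zero — this distinction matters under
beamstop masks and detector gaps (any pixel below the configurable gap
sentinel, default 0, is excluded everywhere). Blank (instrumental
background) frames are subtracted before masking, clipped at zero so
that the logarithmic detection step below stays defined.

Azimuthal integration averages `I(θ, r)` over the θ bins of a wedge
(weight-weighted, wrap-aware) to give intensity versus radius; radial
integration sums over a radial band to give intensity versus azimuth.

## Ring detection

Two complementary detectors run on every frame.

**Multiple conical integration (MCI).** The pattern is integrated in
`n = 8` evenly spaced wedges of width 90° (with these defaults the
wedges overlap at 45° spacing — the only layout consistent with both
numbers). Radial peaks are found per wedge as strict local maxima with
topographic prominence above `k ×` the noise scale of the trace
(median absolute deviation of its first difference; `k = 3`), making
detection invariant to global intensity rescaling. Peaks are clustered
across wedges by radius (single linkage, 5 px tolerance); a cluster
qualifies as a ring if it appears in at least one quarter of the
wedges, `ceiling(n/4)` — with eight wedges, at least two. Because
adjacent wedges overlap and share noise, occasional spurious clusters
are expected and tolerated here: the radial fitting stage is the
gatekeeper that removes them (below).

**Log-central-difference (LCD).** The radial stencil `(−1, 2, −1)` at
offset `q0 = 10` px,

    D(θ, r) = 2 I(θ, r) − I(θ, r − q0) − I(θ, r + q0),

is the negative second finite difference along `r`: large and positive
at sharply peaked radii, zero on any background linear in `r`.
Negatives are clipped, a small `ε = 10⁻⁶` added, and `L = ln(·)` taken
to compress the dynamic range. Radii whose longest contiguous azimuthal
run above the 0.90 quantile of finite `L` reaches at least 30° qualify;
qualifying radii within 2 px group into one ring (run-length-weighted
mean radius). The quantile threshold is scale-free across exposure
levels; the run length and grouping gap are surfaced as parameters
since no canonical values exist. This detector picks up weak rings
sitting beside strong ones, which prominence-based peak finding tends
to miss.

**Merging.** The two radius lists merge by greedy nearest-pair
matching: pairs within 10 px are averaged, everything else passes
through, each input contributing at most once. MCI rings at 50, 80,
118 px with LCD rings at 82, 120, 180 px merge to 50, 81, 119, 180 px.
Greedy matching provably equals exhaustive optimal matching whenever
radii within each list are separated by more than twice the tolerance —
true for physically distinct rings — and the test suite checks the
equality against an exhaustive oracle on 200 random instances.

## Per-ring models

**Radial.** A sum of Gaussians plus a constant baseline is least-squares
fit (Levenberg–Marquardt) to the full-circle radial profile, initialized
at the merged radii, each center constrained to ±10 px of its
initializer. The ring intensity is the analytic area
`A σ √(2π)`. Fitted components are kept only if they are significant
and well-formed: amplitude above 5× the profile noise scale, width away
from both bounds (0.5–50 px), center inside the observed radial range,
and — when two components end up modelling the same peak (centers
closer than twice the wider σ) — only the larger one survives. These
checks are what makes the ring *count* per image reliable in the
presence of spurious detector candidates.

**Azimuthal.** Fiber diffraction is (at least approximately)
centrosymmetric, so each ring's azimuthal trace over the band
ring ± 2σ_r is modelled as two equal circular Gaussians locked 180°
apart with a shared width:

    I(θ) = A [g(θ; φ₀, σ_θ) + g(θ; φ₀ + 180°, σ_θ)] + c.

The orientation is `φ₀ mod 180°` (a fiber axis is headless); the angle
σ is reported in radians. The **angle fitting error** is the normalized
residual power `Σ resid² / Σ (I − c)²` — 0 for a perfect fit, about 1
when the trace has no structure beyond its baseline. Two numerical
safeguards make this definition behave:

* the amplitude/baseline split is canonicalized after fitting — any
  constant component of the wrapped arc pair is moved into the
  baseline, so a very broad Gaussian fit of a flat trace cannot
  masquerade as structure;
* if the fitted modulation is below 2.5× the pointwise noise scale the
  trace is declared structureless: the error is floored at 1 and σ_θ
  set to its upper bound (180° = π rad). The 2.5 cutoff was calibrated
  on simulated flat Poisson traces (whose fitted modulation stays below
  about 2× noise) against genuine arcs at SNR ≥ 5 (above 3.5×).

**Exclusion.** A ring is excluded as isotropic when its angle fitting
error *and* its angle σ (radians) are both ≥ 1.0. The conjunctive
reading is deliberate — a tight arc fit with large residuals, or a
noisy-but-broad fit, should not be discarded — and the comparator is a
configuration switch (`exclusionMode = "or"`) for the disjunctive
reading. Radians are the natural unit here: a 1-rad (~57°) spread
plausibly marks the onset of isotropy. The angular range reported per
ring is where the fitted model exceeds baseline plus 10% of the arc
amplitude, `φ₀ ± σ_θ √(2 ln 10)`.

## Folder mode, resume and outputs

Images are processed in natural filename order; each image not yet
named in `summary.csv` runs through the pipeline and appends one row
there (image, total intensity of selected non-excluded rings, ring
count), its rings to `rings.csv` (all rings, selected or not), and its
background statistics to `BackgroundSummary.csv` (mean and count of
pixels outside the mask, or outside `rmin` when no mask is given; gap
pixels never count). Reruns are therefore idempotent — a finished
folder is left byte-identical — and `summary.csv` without `rings.csv`
is detected as inconsistent and forces reprocessing. Per-image failures
log a warning and record a zero-ring row; the run continues. The raster
order is row-major and non-serpentine by default (a configuration
switch covers serpentine scans), and the scan grid comes from a
`key=value` setup file (`x_start/x_end/x_step`, likewise `y`), with
`round((end − start)/step) + 1` positions per axis.

## Heatmaps and interpolation

Five representations assemble the per-position results into maps:
total intensity; d-spacing of the best ring; angular range (angle σ) of
the best ring; a vector field (intensity as color, best-ring
orientation as overlay direction); and an elliptical representation
(angle σ as ellipse size). The *best ring* of a position is the
non-excluded, filter-passing ring with the lowest angle fitting error
(ties: smaller radius); the filter selects rings of interest by
d-spacing (nm) or radius (px) within a bandwidth. Cells without a
qualifying ring are missing, not zero, and orientation overlays are
absent exactly there — on a tissue map, cells without an alignment bar
mark isotropic diffraction.

Scalar maps can be interpolated with a multiquadric radial basis
function, `φ(r) = √(1 + (s r)²)`, shape parameter `s = 1`, zero
smoothing — an exact interpolant through the measured cells, filling
the gaps left when the beam is smaller than the scan step. Distances
are measured in grid-index units so behavior is invariant to the
physical step size. Missing cells are excluded from the node set rather
than imputed. Orientation fields are never interpolated: angles on a
half-circle do not average linearly. Maps export as CSV (the cells as
visible), PNG (deterministic raster with viridis colormap and glyph
overlay) or SVG.

## The synthetic generator

Every stage is testable without beamline data through a seeded
generator. A synthetic frame is

    I(x, y) = baseline + Σ A·exp(−(ρ − r₀)²/(2σ_r²))·w(θ),

with `w = 1` for isotropic rings and a centrosymmetric pair of circular
Gaussians for oriented ones, Poisson photon noise on the expectation,
and a circular beamstop mask. The default study conditions are a
192 × 192 px frame, a 2 m camera with 172 µm pixels at 1.033 Å, baseline
100 counts, arc amplitude 100 counts (SNR 10 at the peak over
background shot noise), ring σ_r = 3 px, and a 15 px beamstop. The
default scan is a 4 × 4 grid whose ring radius drifts from 55 to 65 px
across columns (a d-spacing gradient, as across a gray/white matter
boundary) with the left half oriented and the right half isotropic.
Scans are written as 16-bit TIFF series with a mask image, a setup
file, a geometry settings JSON and a ground-truth CSV; a fixed seed
reproduces the folder byte for byte.

What the generator does *not* emulate: structured instrumental
background, detector point-spread and polarization/solid-angle effects,
multiple diffraction orders with form-factor intensities, and spatially
correlated tissue texture. Passing recovery tests on these fixtures
therefore demonstrates the correctness of the reduction chain under
photon noise, not robustness to every artifact of real beamline data.

## Test problem sizes

The suite exercises single frames at 192 × 192 px (257 × 257 for
wide-radius cases), scans of 2 × 2 to 4 × 4 positions, profile-level
parameter-recovery sweeps over φ₀ ∈ {0, 15, …, 165}°,
σ_θ ∈ {5, 10, 20}° and SNR ∈ {5, 20}, and 200-instance oracle
comparisons for the merge step. These sizes keep the full suite in the
tens of seconds while leaving every code path covered; the pipeline
itself has no dimension-dependent branches, so behavior at detector
scale (e.g. 2048²) differs only in runtime.

## Known limitations

* The detector plane is assumed orthogonal to the beam — rings are
  circles, not ellipses; tilted-detector geometries are out of scope.
* HDF5 stacks are not read; frames must be a numbered TIFF series.
* One constant baseline per radial profile; strongly curved diffuse
  backgrounds are handled only through the LCD detector's linearity
  cancellation, not in the fit itself.
* Arcs are modelled as equal pairs; absorption-induced intensity
  asymmetry between the two arcs is not modelled.
* Processing is single-threaded.
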