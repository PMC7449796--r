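---
title: "Methods: ratiometric hypoxia mapping and the oxygenation decay model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric hypoxia mapping and the oxygenation decay model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiamap)
```

## The measurement and its model

A ratiometric hypoxia biosensor expresses two ubiquitous fluorophores:
GFP fused to the oxygen-dependent degradation (ODD) domain of HIF-1α/Sima,
degraded faster the more oxygen a cell sees, and a nuclear RFP that is
oxygen-independent and doubles as the segmentation signal. The per-nucleus
hypoxia response is the ratio of channel means,
`ratio = mean(GFP-ODD)/mean(RFP)`, and its inverse `ratio⁻¹ = RFP/GFP-ODD`
serves as an oxygen-availability proxy.

Oxygen reaches brain tissue from tracheoles. The package models the
oxygenation proxy as a decaying exponential in the minimum Euclidean
distance `x` (µm) from a nucleus to the tracheal system:

$$ \mathrm{ratio}^{-1}(x) \;=\; y_0 + A\,e^{-(x - x_0)/\lambda} $$

with amplitude `A` (the full range of the decay), offset `y0` (the
asymptotic, fully hypoxic value of ratio⁻¹), decay constant `λ` in µm (the
distance over which the exponential term drops to 1/e ≈ 37% of its initial
value), and `x0` a fixed reference distance — by convention the smallest
distance in the data set being fitted, so that `A` is anchored to the first
observed point. Only `A`, `y0` and `λ` are free parameters.

Assumptions worth stating: oxygen transport is treated as a single
empirical exponential (no diffusion–consumption PDE); distances are
straight-line Euclidean, not geodesic through tissue; the nucleus centroid
stands in for the cell (a surface-distance option subtracts the nuclear
radius, floored at 0). Cells are assumed well mixed within a compartment so
that whole-hemisphere normalisation (`ratio_norm = ratio / hemisphere mean`)
makes brains of different overall brightness comparable.

## Condition presets and reference calibration

Average-fit decay constants measured in the larval brain define the three
rearing-condition presets: λ = 51.8 µm under normoxia (~21% O₂), 65.8 µm
under hyperoxia (60% O₂, where decay kinetics slow as the tissue saturates),
and 53.4 µm under hypoxia (5% O₂). Amplitude and offset of the biosensor are
not published quantities; the package declares `A = 0.9` with offsets
`y0 = 0.55 / 0.90 / 0.35` (normoxia / hyperoxia / hypoxia), chosen so that
normoxic ratios span roughly 0.7 adjacent to a tracheole to 1.8 far from
one — the order of magnitude of measured compartment means — and so that
hyperoxia depresses and hypoxia elevates ratios everywhere
(`condition_preset()`).

Reference mean ratios used to calibrate recovery experiments: compartment
means 0.90 (central brain) and 1.31 (optic lobe) for the 84 h brain;
condition means 0.89/1.32 (normoxia), 0.55/0.61 (hyperoxia), 1.25/1.86
(hypoxia); and per-cell-type means (optic-lobe neuroblasts 1.51,
central-brain GMCs 0.75, neurons 0.81/1.24, glia 0.92/1.16 for
CB/OL respectively). Two entries in `celltype_reference_means()` are package
defaults rather than measurements — central-brain neuroblasts (1.05, kept
above the other central-brain types because neuroblasts are the most
hypoxic type in each compartment) and neuroepithelium (1.20 in both
compartments, distance-independent) — and are flagged as such in the
function's documentation.

## What the phantom generator emulates — and what it does not

`generate_phantom()` builds a two-compartment volume (planar split along x:
a densely tracheolated "central brain", default tracheal voxel fraction
0.02, and a sparse "optic lobe", default 0.001), a single connected
branching tracheal tree rasterized at one-voxel tube radius, and spherical
nuclei of five cell types placed without overlap (default radius
2.2 ± 0.2 µm, ≥ 1 µm surface gap — the separability the volume filter and
benchmark assume). Default voxel size is (1.0, 0.5, 0.5) µm for (z, y, x),
reflecting the anisotropic optical sectioning of confocal stacks; all
geometry downstream works in µm, never in voxel indices.

True ratios come either from the decay model applied to the exact
nucleus-to-tube distance, with multiplicative log-normal noise of mean 1
(default CV 0.10 — the biosensor's noise model is not published, so a
simple positive-valued choice is declared), or, for calibration phantoms,
from a truncated normal around configured per-type/per-compartment means
(default sd 0.15). Rendering gives each nucleus a Gaussian radial intensity
profile (σ = r/2) in RFP and the same profile times the true ratio in GFP,
so the nucleus-mean GFP/RFP equals the true ratio exactly before noise; an
additive background (0.005 of peak) and Gaussian read noise (sd 0.01 of
peak) are applied to imaging channels and clamped at zero. Marker channels
are binary and noise-free.

Deliberately not emulated: optical point-spread functions, photobleaching,
z-dependent attenuation, developmental time series, curved anatomical
compartment borders, and nucleus shape variability. Passing recovery tests
on these phantoms therefore demonstrates correctness of the measurement
chain — segmentation, ratio arithmetic, distances, fitting — not robustness
to every optical artefact of real microscopy.

Two generator constraints exist purely to keep the ground truth honest:
tree segments are 12–30 µm (never below 6 µm, about three tube diameters)
and a proposed segment is rejected unless ≥ 85% of its rasterized voxels
outside the attachment ball are new. Without these, spatially merged tubes
make the analytic skeleton length overcount what any skeletonizer — or
tracer of real images — could see.

## Numerical choices

**Segmentation.** Background subtraction is greyscale opening with a box
(default half-width 10 µm per axis), followed by separable Gaussian
smoothing (default σ 0.5 µm), Otsu thresholding on a 256-bin histogram
(fixed-threshold override available), 26-connected labelling, and a
physical volume filter (defaults 15–600 µm³). Optional splitting of
touching nuclei uses a seeded watershed: seeds are 26-neighbourhood maxima
of the Gaussian-smoothed (σ 1 µm) anisotropic Euclidean distance transform,
merged below 2 µm separation with the lowest seed id winning; flooding is
by descending distance value with FIFO tie-breaking. An all-background
channel yields an empty table with a warning, not an error.

**Ratios.** The per-nucleus ratio is the ratio of channel means, not the
mean of voxelwise ratios — dim rim voxels would otherwise dominate the
variance. Nuclei with mean RFP at or below the floor (default: background
mean + 2 background sd, estimated outside all labels) are flagged and
excluded from statistics; whether dim nuclei were excluded in comparable
manual workflows is unknown, so the rule is explicit and configurable.

**Distances.** Exhaustive exact minimisation in µm (compiled double loop);
no spatial index, so there is no approximation to audit. Tests pin
equality to an R double-loop oracle at 1e-9 µm over 20 seeds.

**Decay fitting.** Levenberg–Marquardt on vertical residuals with
initialisation `y0 ← 5% quantile of y`, `A ← max(y) − y0`, `λ ← half the
x-range`, bounds `A ≥ 0`, `λ ∈ [1e-3, 10 × x-range]`. Orthogonal distance
regression is provided as a refinement of the least-squares solution
(per-point Newton minimisation of the orthogonal distance, Nelder–Mead over
parameters); the two routes agree within 2% when x carries no noise, which
is the phantom regime. Degenerate (constant) data return `A ≈ 0` with the
decay constant flagged unidentifiable; the flag triggers whenever
`A < 2 × residual RMS`, which also catches the distance-independent
neuroepithelial response. Curve averaging across brains is pointwise on a
distance grid (1 µm steps, 0–150 µm), with an equivalent parameter set
refit to the averaged curve; averaging parameters directly would be the
alternative reading, and for fits differing only in `y0` the two coincide.

**Skeleton length.** The tracheal voxel set becomes a 26-connectivity graph
with Euclidean edge weights penalised away from the medial axis (factor
`1 + 5(1 − EDT/EDTmax)²`), so shortest paths hug the tube centreline and
parallel voxel lanes merge. Branches are peeled farthest-first on the
shortest-path tree, joining the existing skeleton at exact vertices;
polylines are smoothed with a 5-point moving average to remove lattice
zigzag before summing. Voxels within 1.6 voxel-widths of a traced branch
are captured; a candidate branch that never leaves 1.25× that distance from
the existing centreline is discarded as tube-wall thickness, whatever its
length. These two constants were calibrated on rasterized tubes of known
analytic length (straight, L-shaped, oblique, and random trees) and then
validated on held-out tree seeds, where recovered length stays within 5% of
the analytic truth.

**Statistics.** The two-group test gates on Shapiro–Wilk for each group and
Levene across groups at α = 0.05; Levene is median-centred (the robust
variant — which centring comparable workflows used is not stated).
All tests are two-sided; stars at 0.05/0.01/0.001. Histograms default to
bin width 0.05 in normalised-ratio units (a declared choice; published
histograms do not state their bins), clip out-of-range values into end bins
with a warning, and normalise to sum 1. The hypergeometric enrichment test
is the exact upper tail `P[X ≥ k]`; only the significance computation is in
scope — gene catalogues and GO membership are external inputs.

**Thresholding of the tracheal channel** is global (single Otsu or fixed
value over the volume), not per-slice; per-slice thresholding would be the
alternative for stacks with strong z-attenuation, which the phantom does
not emulate.

## Open design choices

* Distance is measured from the nucleus centroid; "distance from a cell"
  could equally mean its surface, so `add_distances(surface = TRUE)`
  subtracts the radius with a floor at zero.
* Multi-positive nuclei resolve by a declared priority
  (neuroblast > GMC > glia > neuron), motivated by marker specificity:
  Deadpan is the most restricted signal, while Prospero labels GMCs and
  immature neurons. The order is configurable in `cell_type_rules()`.
* Neuroepithelium is assigned from a region mask (the proliferation
  centres), not a marker channel; the phantom derives that mask from its
  own neuroepithelium marker channel, a stand-in for manual outlining.
* The command-line layer is deliberately thin (`simulate`, `run`, `fit`);
  the package's R functions are the primary interface, and `run_pipeline()`
  with a YAML config reproduces any CLI invocation.

## Problem sizes in the test-suite and acceptance experiments

Recovery experiments use phantoms of 128×256×256 voxels with ~1500 nuclei
(compartment means), 96×224×224 with 1500 nuclei over five equal cell-type
proportions (cell-type means, ≥300 nuclei per type), and 64×192×192 with
800 nuclei (hyperoxia), at noise CV 0.10 and truncated-normal sd 0.15
(0.10 for hyperoxia). Decay-constant recovery uses n = 5000 points on
0–150 µm with 8% multiplicative Gaussian noise; replicate bias checks use
50 × n = 3000 at CV 10%. Property suites run the distance oracle on 20
seeds, hypergeometric enumeration for all populations up to N = 25, a
200-nucleus segmentation benchmark, 2000 null replicates for the test-size
check, and a noiseless 500-nucleus closure run in which the fitted λ must
land within 1% and compartment means within 0.5% of truth. These sizes are
the package's validation design; all recovery tolerances are expressed in
standard errors of the experiment itself.

## Known limitations

* The exponential model is empirical; near saturation (hyperoxia) `λ` and
  `y0` trade off, and fits on short distance ranges (< ~1 decay constant)
  identify `λ` poorly — the identifiability flag reports, but cannot
  prevent, such designs.
* Predicted-ratio heatmaps inherit a correlation ceiling from biological
  noise: with 10% multiplicative noise the voxelwise correlation between
  predicted and true ratios cannot much exceed ~0.92 even with a perfect
  model, and only reaches 0.9 when distances span the full decay range.
* The watershed splitter assumes roughly convex nuclei; elongated or
  crescent nuclei would over-split.
* Skeleton length is accurate to a few percent for tubes ≥ ~3 tube
  diameters long; sub-resolution stubs are indistinguishable from wall
  thickness by construction.
* TIFF round-trips store intensities as 32-bit floats scaled to [0, 1]
  (scale recorded in the JSON sidecar), so values are preserved to float32
  precision (~1e-7 relative), not bit-exactly.
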