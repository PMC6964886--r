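---
title: "PeelStack: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PeelStack: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PeelStack)
```

# The model

A confocal Z-stack of a leaf acquired through the abaxial surface can be
modelled as a curved two-tissue object: an outer epidermal layer whose
top follows a smooth surface $h(y, x)$ (in slice units, z increasing
away from the objective), and a mesophyll layer lying a roughly constant
distance below it. PeelStack's job is to estimate $h$, then select the
voxels in the band $[h + o,\, h + o + d)$ for user-chosen offset $o$ and
depth $d$, so each tissue can be rendered and quantified on its own.

The method assumes:

* one channel carries a surface-delimiting marker (e.g. a plasma-membrane
  fluorophore) that is the first bright structure encountered along z;
* slice 0 is the stack entry side, nearest the objective (stacks
  acquired the other way are flipped on read with `flipZ = TRUE` or the
  CLI's `--flip-z`);
* the surface is single-valued in (y, x) — no folds or overhangs;
* tissue boundaries are, to the accuracy the user cares about, parallel
  to the surface, so a constant offset/depth band tracks them.

# Surface detection

For each (y, x) column of the (optionally pre-smoothed) marker channel,
scanning upward from z = 0, the surface is the first z at which
intensity is at or above threshold for `minRun` consecutive slices. The
crossing is recorded at the integer slice; sub-slice values arise only
from the later smoothing. Columns with no qualifying run are invalid and
filled from their nearest valid neighbour (Euclidean distance, ties to
the lexicographically smallest (y, x): deterministic and
parameter-free). The filled map is then despiked with a median filter
and smoothed with a Gaussian, and clipped to $[0, n_z - 1]$.

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `channel` | index | 1 | marker channel used for detection |
| `preSmoothSigma` | voxels | 0.5 | see below |
| `threshold` | intensity or `"otsu"` | `"otsu"` | resolved once globally on the pre-smoothed channel; per-column thresholds are unstable in dark columns |
| `minRun` | slices | 2 | one noisy voxel above threshold must not found a surface |
| `mapMedianRadius` | pixels | 2 | removes isolated column failures that survived `minRun` |
| `mapSmoothSigma` | pixels | 2 | converts the integer-slice staircase into a smooth sub-slice surface |

**Why pre-smoothing sigma 0.5 and not more.** Axial smoothing spreads
the marker's intensity into the slice above the true surface. With a
global threshold at the Otsu split, a sigma of one voxel pushes that
smeared skirt (about 30 % of shell amplitude) above threshold, so every
detected height moves one slice toward the objective — a systematic
bias, not noise, and regularization cannot remove it. At sigma 0.5 the
skirt stays near 10 % of amplitude, safely below any reasonable
threshold, while shot noise is still damped. On the sine phantom
(amplitude 3 slices, period 64 px, noise 5 % of marker intensity) the
full detect → fill → regularize chain achieves a mean height RMSE of
about 0.28 slices over 20 noise realizations; with sigma 1 the measured
RMSE is about 0.86 slices, almost entirely the one-slice bias. Users
with very noisy stacks who raise the sigma should either use a fixed
threshold above the smeared skirt or accept the bias and compensate with
the peel offset.

**Threshold and monotonicity.** Raising the threshold can only delay the
first qualifying run, so detected surfaces deepen monotonically with the
threshold; on a noiseless step profile any threshold strictly between
background and signal gives the exact crossing. Otsu on a
constant-intensity channel is refused ("no surface contrast") rather
than returning an arbitrary split.

# Peeling

The layer at offset $o$ and depth $d$ below $h$ is the half-open real
interval $[h + o, h + o + d)$; micrometre inputs are divided by the z
voxel pitch first. Integer slices are selected by
$\lceil h+o \rceil \le z < \lceil h+o+d \rceil$. Two consequences drive
this choice:

* **No double counting.** Specs $(0, d_1)$ and $(d_1, d_2)$ produce
  disjoint masks whose union is exactly $(0, d_1 + d_2)$, for any height
  map and any fractional bounds — verified exhaustively against a
  brute-force voxel enumeration. An epidermis/mesophyll split therefore
  partitions the signal.
* **Graceful clipping.** Out-of-bounds selections clip to the stack
  silently; a deep offset near the stack floor yields an empty column,
  not an error, because such columns are routine at leaf edges.

Peeled stacks are zero-filled outside the mask (not NA) so that Z-sum
projections remain well defined; display scaling is deliberately a
separate, lossy step (`exportPNG` with explicit min/max). Sum
projections accumulate in double precision and conserve the masked
voxel total exactly for integer inputs.

# Phenotype formulas

* Stomatal index $= 100 \cdot s / (s + e)$ for $s$ stomata and $e$
  other epidermal cells in a counting region; stomatal density
  $= s / \text{area}$ in mm⁻² (a 400 µm × 400 µm region is 0.16 mm²).
* ΔΔCt: per sample $\Delta Ct = Ct_{target} - Ct_{reference}$; per
  condition the arithmetic mean of $\Delta Ct$ over replicates; then
  $2^{-\Delta\Delta Ct}$ against the calibrator condition, with
  amplification efficiency fixed at 2 and no efficiency calibration.
  Averaging $\Delta Ct$ before the delta-delta step (rather than
  averaging fold-changes) is the convention adopted here; the two
  differ for noisy replicates, and users preferring the other should
  aggregate externally. The calibrator maps to exactly 1 by
  construction.
* Dual-luciferase: firefly / Renilla, invariant under instrument gain.
  A zero Renilla reading is an error (no transfection control), never a
  silent division.

Group comparisons (Welch, ANOVA + Tukey) are deliberately thin wrappers
over `stats`; nothing statistical is re-implemented.

# The synthetic phantom

`simulateStack()` builds the geometry the method assumes: a surface
model (flat, tilted plane, 2-D sine, or Gaussian bump) rasterized to the
nearest slice per pixel; an epidermal label of fixed slice thickness
directly below the surface; a dark gap; a mesophyll label beneath that.
Channel 1 paints the marker: a bright shell on the first two epidermal
slices plus a sparse (3 %) cell-wall speckle inside both tissues — the
shell is two slices so that it satisfies the detector's own default
two-slice run requirement, mimicking the axial spread of a real membrane
marker. Channel 2 paints the reporter homogeneously per tissue (defaults
80 epidermis / 40 mesophyll). Noise is additive Gaussian (default sigma
5, i.e. 5 % of the default marker intensity 100) clipped at zero, with
optional Poisson shot noise. All randomness derives from one master
seed, so stacks are bit-reproducible.

The truth object carries both the continuous surface model and the
rasterized (nearest-slice) surface actually painted into the voxel grid.
A slice-level detector can at best recover the rasterized surface, so
exactness checks compare against it; the two differ by at most half a
slice by construction.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: no point-spread function or axial elongation
beyond the two-slice shell, no depth-dependent attenuation or
scattering, no curvature-dependent marker brightness, no folds or
multi-valued surfaces, and cell walls as random speckle rather than a
connected Voronoi lattice. Parameter defaults on real stacks will need
the usual visual check of the height map and peeled projections.

# Numerical and I/O choices

* **Storage.** The TIFF codec used stores pages as 8-, 16- or 32-bit
  unsigned integers in [0, 1]. Integer stacks (max ≤ 65535) are written
  as 16-bit pages and round-trip bit-exactly. Everything else is divided
  by a power-of-two scale recorded in a JSON sidecar and written as
  32-bit pages — fixed point with absolute error ≤ scale · 2⁻³²,
  tighter than single-precision float for values within an order of
  magnitude of the scale. Height-map validity travels as an explicit
  mask page (NaN does not survive the codec) and invalid pixels are
  re-coded NA on read, so they can never leak into the valid set.
  Voxel size, channel names and layout live in the sidecar; files
  without one read with a (1, 1, 1) µm default and a warning, never an
  error.
* **Zero-based z.** All heights and offsets are zero-based slice
  coordinates with slice 0 nearest the objective; the rasterized
  surface uses nearest-slice rounding (floor(h + 0.5)), which is
  unbiased, unlike ceiling or floor.
* **Exact filters.** The height-map median filter and the Gaussian
  smoothers are written here and operate on unquantized doubles
  (replicated borders; Gaussian kernels truncated at 3 sigma and
  renormalized over in-bounds support, which preserves constants to
  rounding and makes smoothing contractive on range). Off-the-shelf
  constant-time median filters quantize [0, 1]-clipped data, which
  would corrupt slice-unit heights.
* **Determinism.** Every generator restores the caller's RNG state;
  per-stage sub-seeds are derived from one master seed; identical
  config + seed reproduce byte-identical CSVs (checked in the tests).

# Problem sizes

The validation suite uses 256 × 256 × 30 stacks for surface-recovery
benchmarks (20 noise realizations, ~3 s each), 128 × 128 stacks for
end-to-end layer quantification, 16 × 16 × 12 stacks for exhaustive
brute-force checks of mask compositionality and projection
conservation, 500 simulated counting regions for stomatal-index
recovery, and 200 seeded replicate sets for ΔΔCt recovery. These sizes
were chosen so that every property is checked against an independent
brute-force oracle or a known ground truth at full coverage.

# Limitations

Single surface per column (no adaxial/abaxial double detection); no
mesh-based surface reconstruction or deformable models; no registration,
deconvolution, or proprietary microscope formats (convert to TIFF
first); layers are bands parallel to the surface, not segmented cells;
ΔΔCt supports one reference gene per measurement (no multi-reference
geometric mean) and assumes efficiency 2.
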