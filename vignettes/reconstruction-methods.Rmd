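---
title: "Reconstructing microglial morphology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing microglial morphology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Microglia are the brain's resident immune cells. Their function is tightly
coupled to their shape — a compact soma surrounded by a diffuse, highly
variable tree of fine processes — so morphometric quantities such as the
number of primary branches, the number of bifurcations, total branch length
and cell volume are routine readouts in neuroimmunology. This package
reconstructs those trees automatically from 2D/3D fluorescence stacks in
which cells are *darker* than the background (light-foreground data is
inverted on read), and writes the result in the SWC standard so any SWC
viewer or morphometry tool can consume it.

This vignette explains the model behind each stage, the tunable parameters
and their defaults, what the synthetic phantoms do and do not emulate, and
the numerical choices made where the design was genuinely open.

## Stage 1: soma segmentation and background removal

Thresholding at intensity $t$ yields the binary volume
$B_t(x,y,z) = [I(x,y,z) \le t]$. As $t$ sweeps upward, the number $n_t$ of
connected objects larger than a minimum area first grows (structures
appear), then collapses (everything merges into the background). Two
intensities on that curve drive the whole pipeline:

* the **soma threshold** $t_s$, where object growth is slowest — somas are
  the darkest, most compact structures, so their count stabilizes early.
  On the normalized growth criterion
  $c_i = (n_{t_{i+1}} - n_{t_i})/(n_{t_{i+1}} + n_{t_i})$, computed over 20
  multilevel-Otsu thresholds, $t_s$ is the upper threshold of the
  minimal-$c$ transition within the initial non-negative run of $c$;
* the **background threshold** $t_b$, where the object count over raw
  intensities is globally maximal; beyond it objects merge into one solid.
  The search is restricted to a window around the best Otsu level (half the
  gap to the adjacent levels on each side, extended to the intensity
  extremes at the ends), which finds the same maximum at a fraction of the
  cost of a full intensity sweep.

Both thresholds are found on a 2D minimum-intensity projection of a central
slab (default 30 μm — roughly one cell — so that too many cells do not
overlap in the projection); the full 3D stack is then thresholded with
them. Somas are the connected components of $B_{t_s}$ above a size floor,
each with a centroid and a physical size.

Numerical choices: object counting ignores components of at most 16 μm²
(noise and branch fragments); connectivity is 8 in 2D and 26 in 3D; Otsu
uses one histogram bin per integer intensity and an exact dynamic program,
so results are reproducible to the bin. Ties in the minimal-$c$ rule go to
the position with the smallest forward difference $c_{i+1}-c_i$, and a tie
at the end of the run (where no forward difference exists) loses to any
interior tie. Ties in the $t_b$ window go to the intensity nearest the best
Otsu level.

## Stage 2: prioritized seed points

Voxels with intensities in $(t_s, t_b]$ carry the branch information. They
are split into level sets between consecutive thresholds of the ladder
$t_s < \dots < t_b$ (the Otsu levels strictly between the two, plus the
refined $t_b$ itself, so the levels exactly tile $B_{t_b} \setminus
B_{t_s}$). Within each level the stack is partitioned into 5 μm boxes and
the darkest voxel per box becomes a seed: darker means closer to the
centreline, so per-box minima land on or near the branch axes. Soma
surfaces are sampled the same way and get the highest priority, which
anchors every primary branch. Intensity ties inside a box go to the
lexicographically smallest coordinate, making sampling deterministic.

## Stage 3: tracing

Each cell is traced independently inside a 60 μm boundary cube centred on
its soma. The tree starts as the root (soma centroid) plus the soma-surface
seeds joined to it; remaining seeds become reachable when they fall within
a 40 μm cube of a connected node. One seed is withdrawn per iteration — the
reachable seed of the lowest pending intensity level with the smallest
*component-restricted* distance to the tree: the foreground $B_{t_b}$ is
cropped around the candidate parent, and only seeds in the parent's
connected component of that crop get their Euclidean (anisotropy-scaled)
distance; seeds across a background gap are unreachable. Attaching one
seed at a time guarantees a tree. Because darker seeds go first, paths run
along branch centrelines outward from the soma.

Two open points were settled as follows: the disconnected set persists
across levels, and a seed of a lower level that becomes reachable later is
still served before any higher-level seed (the selection always takes the
lowest level with a reachable seed). Distance ties break by seed insertion
order. When boundary cubes overlap, seeds claimed by an earlier cell
(ascending soma label) are withdrawn from later cells, so shared territory
is never traced twice.

After tracing, terminal branches shorter than 5 μm are pruned iteratively
(removing a spur can expose a new short terminal branch, which is then
pruned too). A branch is measured from its leaf back to the nearest
junction, except that root–child segments, which run through the soma
interior, do not count. Pruned lengths are recorded at their junction
nodes. One consequence of iterating to a fixed point is mild *tip
retraction*: where side-spur junctions are dense near a branch tip, the tip
can retract by up to the pruning floor plus one sampling box.

## Stage 4: radii and morphometry

A pruned side twig typically spans the cross-section of the branch it hung
on, so its recorded length doubles as a thickness estimate: nodes holding a
spur record take the (largest) spur length as their radius; the remaining
radii are filled root-to-tip — a branch starting point inherits its nearest
measured descendant, interior nodes take the mean of parent and nearest
measured descendant, terminal runs inherit the parent, and the root gets
the soma's equivalent-sphere radius. Trees with no usable spur at all fall
back to a 0.5 μm default.

Quantification then reports, per cell: primary branches (children of the
root), branch points (non-root nodes with more than one child), branch
length (sum of segment lengths, root–child segments excluded), soma size
(from the labeled component), and cell size — the soma size plus the sum
over skeleton segments of the conical frustum volume
$v = \frac{\pi}{3} h (r_1^2 + r_1 r_2 + r_2^2)$ in 3D or the trapezoid
area $a = h(r_1 + r_2)$ in 2D.

## Reconstruction quality metrics

`skeleton_distance()` compares two reconstructions by nearest-node
distances (soma nodes excluded): SD is the mean of the two directional mean
distances (a symmetric convention, adopted because the original tools'
exact convention is not documented); SSD is the mean over *substantial*
nodes — those farther than 2 voxels, both directions pooled — and SSD% the
fraction of such nodes. All three are translation-invariant and zero for
identical inputs.

## The synthetic phantom

No public ground-truth dataset exists for this task, so the package ships
a generator that emulates the features the pipeline keys on, with exact
ground truth:

* a two-tone soma ball (dark core, slightly lighter rim ending exactly at
  the nominal radius), so the soma threshold recovers the nominal ball;
* tapering, gently tortuous branches (radius 1.4 → 0.8 μm) whose
  centreline is darkest, with intensity rising quadratically to the tube
  wall and gradually toward the tips — the ordering that makes priority
  tracing meaningful; primaries are spread over the sphere so their origins
  stay separated at the 5 μm surface-sampling resolution, and both
  daughters of every bifurcation exceed the 5 μm pruning floor, because
  structures below those scales are unresolvable by design;
* a field of small debris blobs with staggered intensities far from every
  cell, which gives the thresholded object count the steadily rising
  profile real stacks show (in real data this role is played by noise and
  out-of-focus structures), plus sub-counting-size specks that extend the
  low-intensity plateau;
* default sampling of 0.5 × 0.5 × 1 μm per voxel, mirroring high-NA
  confocal stacks with a 1 μm z-step, and optional Gaussian noise
  (σ = 2 by default; set `noise_sigma = 0` for noise-free studies).

What the phantom does **not** emulate: the point-spread function
(tube walls are sharp), photobleaching and depth-dependent attenuation,
touching or overlapping cells, and vessel-like non-cell structures.
Passing the phantom studies therefore shows that the implementation
realizes the method faithfully under favourable optics; it does not certify
performance on degraded real data.

## What the recovery studies show — and what they do not

On 20 noise-free phantoms (41 cells, 1–3 cells each, 2–6 primaries, 0–5
bifurcations) the pipeline recovers geometry accurately: mean nearest-node
distance below ~1 μm per cell, total branch length within ~10% of truth,
soma sizes exact. The count of primary branches is exact for over 90% of
cells. Two quantities are systematically less reliable, and we report this
openly rather than hiding it:

* **branch points**: the tracer must connect *every* sampled seed, and
  off-axis seed chains whose zigzag path length exceeds the 5 μm pruning
  floor survive as spurious bifurcations even though they span only 2–4 μm.
  Roughly 40% of cells gain or lose a branch point this way. This is
  intrinsic to greedy level-wise growth combined with path-length pruning,
  not a parameter accident — reducing tube radius, flattening gradients or
  adding texture all made it worse or no better in our studies;
* **radii / cell volume**: a pruned spur's path zigzags, so its length
  overestimates the branch cross-section by ~1.6× at 0.5 μm sampling, and
  cell volumes inherit the square of that bias (a straight-cylinder study
  lands ~35–55% above the analytic volume). Spur-based radii should be
  read as upper-bound thickness indicators, not calibrated measurements.

## Problem sizes and runtime choices

The shipped studies use stacks of roughly 110–200 μm × 30 μm at
0.5 × 0.5 × 1 μm sampling (about 1.5–5 million voxels) with one to three
cells; a full pipeline run on one such stack takes a few seconds, and the
complete 20-phantom recovery study a couple of minutes on one core. These
sizes were chosen as the smallest that exercise every stage — multi-cell
segmentation, level-wise tracing, pruning, radii, SWC output — at the
realistic sampling regime.

## Known limitations

* 2D inputs route through the same code with areas in place of volumes, but
  branches shared between overlapping cells in a projection are not cut
  (the watershed-based disambiguation used for that case in 2D is out of
  scope and a warning is emitted when several somas are found in a 2D
  stack).
* Voxel sizes are supplied by the caller; no image metadata is parsed.
* Topology-aware reconstruction scores (e.g. DIADEM) are not
  reimplemented; `skeleton_distance()` covers node-distance metrics only.
  For users running the external DIADEM tool, the parameter set used in
  the original evaluation was: xy-path-thresh = 1, z-path-thresh = 1,
  terminal-path-threshold = 20, terminal-threshold = 15,
  xy-threshold = 10, z-threshold = 8, remainder at defaults.
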