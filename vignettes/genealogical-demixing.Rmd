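---
title: "Genealogical demixing in growing bacterial colonies: models and methods"
author: "enclavekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogical demixing in growing bacterial colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(enclavekit)
```

## The scientific problem

When a single surface-attached bacterium grows into a monolayer colony, the
first division produces two daughter cells whose descendants — the two
*progeny chains* — could in principle intermix freely as the colony expands.
Instead, they organise into two contiguous *genealogical enclaves*: each
chain keeps spatial affinity for its close kin, at the cost of the
entropically favourable mixed state. This package provides the full
computational stack needed to observe and model that phenomenon in
monolayer colonies up to the mono-to-multilayer transition (MTMT):

* a **label-free lineage tracker** for segmented time-lapse label masks;
* **enclave analytics**: cell-contact graphs, enclave polygons and the
  interface between them, a moving-box Shannon entropy with a permutation
  null, interface curvature, and invasion-front geometry;
* a **nematic orientation-field module** with winding-number detection of
  the ±1/2 topological defects typical of rod-shaped cell monolayers;
* a **coarse-grained lattice model** of enclave formation driven by
  stochastic division clocks and a shoving rule;
* a **synthetic rod-colony generator** with exact ground truth, so that
  every stage is testable without microscopy data.

## The synthetic colony generator

No public segmentation data accompany the phenomenon, so the generator is a
first-class module: it emulates the study conditions and provides the
ground truth every tracker test is scored against.

Cells are off-lattice spherocylinders (default width 0.9 µm, birth length
2.2 µm). Division durations are log-normal; the two reference
parameterisations are mean 48 ± 13 min (25 °C, slow growth) and
21 ± 6 min (37 °C, fast growth), both with coefficient of variation ≈ 0.27.
At its absolute division time a cell of length $l$ splits into two
daughters of length $l/2$ placed end-to-end at $\pm l/4$ along the mother's
axis with small angular noise (σ = 0.05 rad), so sisters are born in
contact. Frames are rendered every 3 min (the typical acquisition
interval) onto a fixed 0.1 µm/px grid shared by the whole movie.

**Elongation.** By default each cell elongates exponentially at rate
$\ln 2 / \tau$, where $\tau$ is its own sampled division duration, so every
cell doubles its birth length by the time it divides and the division
length stays near-constant across generations — the behaviour observed for
rod-shaped bacteria, which divide at a characteristic size. A fixed global
rate can be imposed through the `elongation` parameter (useful for
elongation-rate recovery tests); under a fixed rate and a stochastic
clock, division lengths drift across generations, which is not a realistic
regime for *E. coli*.

**Packing.** Overlaps created by growth and division are removed by an
iterative pairwise repulsion: for each overlapping pair the centres are
displaced along the line of minimum separation, synchronously, with a
relaxation factor of 0.6, until the largest spherocylinder overlap falls
below `overlap_tolerance` (default 0.05 µm) or the iteration cap is hit
(non-convergent frames are flagged, never silently kept). Rotational
relaxation is deliberately omitted; orientational order in these colonies
then emerges from division geometry alone, which is sufficient for testing
the analytics but underestimates the active-nematic alignment of real
colonies — a known limitation.

What the generator does *not* emulate: phase-contrast optics and
segmentation errors (masks are perfect), three-dimensional buckling
(movies end at a target cell count rather than a mechanical MTMT
criterion), nutrient gradients, and cell death. Tests passing on generator
output therefore certify the algorithms, not the robustness of upstream
segmentation.

## Label-free tracking

Tracking works on per-frame labelled masks in four stages, all in physical
units:

1. **Feature extraction.** Centroid (mean of labelled pixels), area $a_c$,
   orientation (pixel-covariance major axis), poles (extreme contour
   points along the major axis), length $l_c$ (pole to pole) and width
   $w_c \approx 4 a_c / (\pi l_c)$, cross-checked against the
   moment-equivalent ellipse minor axis.
2. **Centroid matching.** A pair is accepted when each member is the
   *only* counterpart within the cutoff $d_c$ (default 0.75 µm, about one
   cell width) — mutual uniqueness prevents chain swaps when two cells
   straddle one cutoff disc.
3. **Division detection.** An unmatched mother predicts two *dummy
   centroids* at $\pm l_c/4$ along its axis (the daughter centroids of a
   symmetric end-to-end split). A division is recorded when each dummy
   claims a distinct leftover centroid within $d_c$; competing
   interpretations are resolved by ascending total dummy distance, and a
   candidate daughter longer than 0.8 of its putative mother is rejected
   (division halves the length, so true daughters sit near 0.5).
4. **Pole rescue and division rescue.** Cells that slid rigidly (mostly at
   the expanding rim) are rescued when centroid and both pole
   displacements stay below `pole_cutoff` (default $2 d_c$). Finally, a
   drift-compensated division pass automates the manual corrections that
   label-free tracking otherwise requires: near the rim the whole
   neighbourhood can translate by ~0.5 µm per frame, which occasionally
   lets one daughter fall inside $d_c$ of its vanished mother (a false
   continuation) or pushes both daughters out of dummy range. The pass
   removes the common drift (the daughter-pair midpoint must sit within
   `pole_cutoff` of the mother) and re-applies the dummy test in the
   pair's frame, with the same length plausibility constraint.

Whatever remains unexplained is listed in `unresolved` — reported, never
dropped — and excluded from chain statistics. Chains 1 and 2 are seeded
from the exactly two cells of the first frame (t = 0 is the birth of the
founder's daughters); a first frame with any other cell count is an error
by convention. On generator movies at 3-min frames the tracker recovers
100% of tracks, chains and division events at both temperature
parameterisations; tripling the frame interval degrades accuracy
gracefully into the unresolved list.

## Enclave geometry

**Contacts.** Two cells are neighbours when their centroids are within
10 µm and the minimum distance between their boundary polygons is below
1.2 µm. The polygon distance is the exact segment-to-segment minimum; the
historical alternative — sampling points on the boundary — is sensitive to
the sampling density, which exact distances remove while keeping the same
1.2 µm tolerance.

**Enclave regions.** Every pixel of the filled colony region is assigned
to the chain of its nearest cell (two-class distance transform). This
makes the two enclave regions complementary by construction: they absorb
intercellular voids and meet along a single shared interface, so the
perimeter identity
$$L_\mathrm{interface} = \tfrac12 (P_{s1} + P_{s2} - L_\mathrm{colony})$$
holds up to raster noise (within ~5% of the directly measured interface
polyline on generator colonies). A morphological-closing construction was
considered and rejected: closed regions overlap and leave jagged,
double-counted interfaces that break the identity. Enclave fragmentation
(more than one connected component per chain) is flagged; the largest
component is kept.

Contours are smoothed with a 7-point circular moving average before
perimeter, area and centroid computation; this suppresses the chain-code
staircase (a rasterised disc's perimeter is recovered to ~0.3%) while
leaving straight edges fixed. Rasterised right-angle corners still lose
~0.2 µm each to the filter — one reason the formula-vs-measured interface
check is held to 5% on rasters, while the analytic diameter-split disc
reproduces $L_\mathrm{interface} = 2r$ to better than 1%.

**Shannon entropy.** Boxes of side $s$ (default 5.5 µm, a handful of
cells) tile the centroid bounding box at stride $s/2$; each box holding at
least one centroid contributes
$SE(B) = -p_r \ln p_r - p_g \ln p_g$ and the colony value is the mean over
those occupied boxes. Conventions chosen where the procedure is
underdetermined: the natural logarithm (so the per-box maximum is
$\ln 2 \approx 0.693$; divide by $\ln 2$ for bits), and empty boxes are
excluded from the average since they carry no arrangement information.
The permutation null re-colours the fixed positions with the fixed chain
counts; the full-scale analysis uses $2\times10^5$ iterations, and the
implementation computes them in vectorised chunks (a few seconds for a
200-cell frame). The null mean stabilises well below that — $10^3$
iterations reproduce it within 2% — which the demo mode exploits.

**Curvature and invasions.** The interface polyline is fit by smoothing
splines $x(s), y(s)$ against arc length and
$\kappa = |x'y'' - y'x''| / (x'^2+y'^2)^{3/2}$ is evaluated at 200 evenly
spaced arc-length samples (closed curves are padded periodically). The
smoothing parameter `spar` defaults to 0.7, chosen so that a rasterised
5-µm circle reproduces $\kappa = 1/r$ within 2% at the curve level;
sharper features than the raster noise scale (e.g. corners a couple of µm
apart) warrant a smaller `spar`, which the function exposes. High-curvature
points are local maxima of $|\kappa|$ above a threshold defaulting to
$1/(2 \times \text{cell width})$ — the figure-level threshold is not a
published number, so it is a free, reported parameter. An invasion region
is delimited by the two high-curvature points flanking an excursion: the
chord between them closes the interface arc into a polygon. Candidate
pairs are accepted when the arc stays on one side of its chord, exceeds
it in length at least twofold (a finger has a narrow mouth), and runs
contiguously beyond half depth; maximal disjoint excursions are kept in
decreasing arc-to-chord ratio. The mean invasion width is the mean
chord-parallel width of the polygon at seven equally spaced depth
stations.

## Orientation field and defects

The structure tensor (gradient outer product, Gaussian-averaged with
σ = cell size / 4) yields a per-pixel director $\Phi \in (-\pi/2, \pi/2]$
along elongated structures — the eigenvector of the *smaller* eigenvalue,
appropriate for bright rods. Only cell pixels with non-negligible gradient
energy are valid. The local nematic order is
$$S_R = \sqrt{\langle\cos 2\Phi\rangle_R^2 + \langle\sin 2\Phi\rangle_R^2},$$
the standard nematic scalar (the square root guarantees the printed
$0 \le S_R \le 1$ bounds and $S_R = 1$ for uniform alignment), evaluated on
square windows of roughly 3–4 cell lengths moved at one third of the
window (candidate mining uses a finer window/6 stride so a sharp core
cannot slip between window centres). Windows with $S_R \le 0.3$ that are
local minima become defect candidates; each is charged by the winding
number — director increments around a counter-clockwise square loop, each
wrapped to $(-\pi/2, \pi/2]$, summed and divided by $2\pi$, rounded to the
nearest half-integer with the raw residual reported. The loop radius
defaults to one window so that a core located at window resolution is
always enclosed, and escalates up to threefold when it crosses invalid
pixels. Defects are classed CI/CO/CB by distance to the enclave interface
($d_i$ = 1.5 µm) and to the colony outline (margin defaulting to $d_i$,
since no separate value is established), and linked across frames by
greedy same-charge nearest-neighbour matching.

## The lattice model

Cells occupy single sites of a square lattice (initially 25 × 25,
auto-expanding whenever a shove run reaches the border, so the wall is
never felt). The run starts from a chain-1 cell at the centre with its
chain-2 sister on a random Moore neighbour. Each cell carries an
*absolute* division timestamp drawn at birth (birth time + log-normal
duration) held in an event queue — equivalent to re-sorting an ascending
list each step, with exact ties broken by the lower cell id. One daughter
keeps the mother's site; the other takes a uniformly random unoccupied
site within the placement range (Chebyshev ≤ 1 by default; the range-2
variant weakens sister adhesion). When no site is free, a direction is
sampled with probability ∝ 1/(run length) — the count of contiguous
occupied sites outward to the first vacancy, diagonals counted in
Chebyshev steps — and the whole run translates outward one site (a uniform
direction variant exists). A `chain_rate_factor` > 1 multiplies chain 2's
mean division time to model growth-rate imbalance.

On-lattice demixing metrics mirror the off-lattice ones: the interenclave
contact fraction averages, over cells with at least one occupied Moore
neighbour, the share of opposite-chain neighbours; the entropy uses the
same moving-box formula on site occupants with a 4 × 4-site box (half-box
stride), a size chosen to hold a number of cells comparable to the 5.5-µm
boxes off-lattice.

One structural property worth recording: because every step advances to
the next division event, the lattice dynamics are invariant under a
rescaling of time, so the two temperature parameterisations differ only
through the *shape* of the duration distribution (CV 0.271 at 48 ± 13
versus 0.286 at 21 ± 6). Ensemble differences between them at equal
colony size are therefore intrinsically small, and the 20-seed ensemble
comparisons should be read with that in mind; the adhesion (placement
range) comparison, by contrast, is a large effect.

## Problem sizes and numerical choices used by the test suite

The packaged tests run at desk scale by design: generator colonies of
32–128 cells (a 64-cell movie is ~85 frames and runs in about a second),
20-seed lattice ensembles at 128 cells, permutation nulls of 10²–2×10⁴
iterations against the 2×10⁵ production default, 10⁴ shove trials on a
constructed occupancy, and 25-seed planted-defect recovery on 256² fields.
Degenerate inputs are handled explicitly: zero-SD clocks give
deterministic doubling; single-chain frames give zero entropy; a constant
image yields an all-invalid orientation field; all-isolated contact graphs
return `NA` with a warning; relaxation that fails to converge flags the
frame.

## Known limitations

* The generator's translational-only relaxation understates nematic
  alignment; defect statistics on generator colonies are therefore
  qualitative, and the defect detector is validated on analytic planted
  fields instead.
* Perimeters of rasterised shapes carry a small corner bias (see above);
  sub-pixel boundary extraction would remove it but is not needed at the
  tolerances used here.
* Time is reported in minutes and frames; normalisation by an
  experimentally determined MTMT time is out of scope, as is any
  statistical comparison across temperatures beyond the directional
  ensemble checks.
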