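---
title: "Methods: vascular network tracing, flow tensors and cortical flatmaps"
author: "vasculomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular network tracing, flow tensors and cortical flatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculomap)
```

This vignette documents the models and numerical choices behind the
package: what each stage computes, which parameters matter and why
their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where genuinely open design decisions
were resolved.

## Coordinate conventions

All volumes are 3D arrays with axis 1 = ML, axis 2 = DV, axis 3 = AP;
voxel `[i, j, k]` is centred at `origin + (c(i, j, k) - 0.5) * spacing`
micrometres. Graphs live in micrometre coordinates in the same frame.

## Preprocessing

Raw acquisitions are anisotropic (typically 1 × 1 × 5 µm); all
morphological operations assume isotropy, so volumes are first
resampled to 1 µm cubic voxels. `interpolate_isotropic()` uses a
Catmull–Rom cubic kernel with linear extrapolation at the borders; the
operator is exact on affine intensity profiles, which is also how the
tests verify it (a linear ramp resamples with error below 1e-6 of its
range).

Binarization follows a two-rule OR: a voxel is vessel when its
(background-subtracted) intensity reaches **6×** the *non-empty-space
average*, or **2.4×** that average after subtracting a **circular 35%
local ranking filter**. Two details are not fully determined by that
rule and are resolved here as configuration:

* *Non-empty space average*: the mean over voxels above a small
  absolute floor, default 1% of the volume's 99.9th percentile. This
  pins down "non-empty" deterministically; the floor fraction is a
  parameter of `foreground_stats()`.
* *Ranking-filter footprint*: a circular footprint of 20 µm radius,
  applied per ML–DV plane (the original imaging plane). A circular
  footprint suggests a 2D filter; radius and percentile are exposed as
  parameters, and whether the original was 2D or 3D is unknowable from
  the rule alone.

Channel subtraction clamps at zero — negative fluorescence is
non-physical — and the thresholds are applied after that clamping.

## Vessel tracing

`skeletonize()` implements topology-preserving 3D curve thinning under
the 26-neighbor foreground rule: simple points (Malandain–Bertrand
characterisation: exactly one 26-connected foreground component among
the neighbours and one 6-connected background component in the
18-neighbourhood) are deleted sequentially, in order of increasing
distance-transform value so the peel is medial, with curve endpoints
(≤ 1 foreground neighbour) preserved. Sequential deletion with
re-checking guarantees that connected components and cycles of the
mask survive — verified on torus and lattice fixtures.

Radii are Euclidean distances from centreline voxels to the nearest
background voxel (`measure_radii()`, exact separable distance
transform, anisotropy-aware). On rasterized tubes this recovers the
generating radius within one voxel, with a small negative bias
(≈ half a voxel) because the discrete surface lies inside the nearest
background voxel centre.

Graph building collapses degree-2 voxel chains into polyline segments.
Voxel chains zig-zag between axis and diagonal steps, which inflates
Euclidean polyline length by up to ~10%; interior points are therefore
smoothed with an endpoint-anchored moving average (window 5) before
lengths are measured, bringing straight-tube lengths within ~1% of
truth. Junction clusters that thinning leaves as several mutually
adjacent branch voxels are fused by the short-internode contraction
rule — internode segments shorter than max(2 × mean radius, 10 µm)
are contracted shortest-first, their end nodes merged at the segment
midpoint and incident segments re-anchored there. The alternative
reading of the cleanup (deleting the short segment and re-routing
along a new shortest path) gives the same topology on all fixtures we
tested; contraction was chosen because it is local and deterministic.

Cleanup rules, in pipeline order:

| rule | default | notes |
|---|---|---|
| endpoint reconnection | ≤ 10 µm | greedy nearest pair, each endpoint used once, never the two ends of one segment; ties break on lowest node id |
| spur (fur) pruning | < 50 µm | terminal segments only, shortest first, iterated to a fixed point; cycles and through-segments never removed; isolated short segments count as furs (`keep_isolated` flips this) |
| connectivity QC | ≥ 250 µm/node | total length over *all* nodes (branch + endpoint); whether the original ratio counted only branch nodes is not determinable, so the node set is a parameter |

## Regional metrics

Segment length is apportioned to atlas regions by arc length of the
polyline inside each region's voxels (midpoint sampling at half the
finest annotation spacing), not by whole-segment assignment — this
removes boundary artifacts and makes length exactly conservative
(Σ regions = whole-graph length, a tested invariant). Branch nodes are
assigned to the containing voxel's region. The regional mean radius is
length-weighted by default; an unweighted per-segment variant is also
reported, since "averaged radius" does not determine the weighting.
Length densities are reported in m/mm³ and µm/µm³. Density volumes use
20 µm bins smoothed with a Gaussian of σ = 2 bins; the kernel is
renormalised to unit sum, so mass is conserved away from the borders
(tested to 0.1% on interior fixtures). The large-vessel length
fraction takes its radius threshold as a parameter (5 µm for
display-scale maps, 3 µm for large-vasculature analyses — both uses
are published).

## Fluid-conductance tensors

Each 400³ µm control volume is clipped out of the graph; cut points
become boundary nodes (nodes falling exactly on a face are boundary
nodes too). Segment hydraulic conductance uses unit viscosity, and by
default the per-point series composition `1 / Σ 8·dl/(π r⁴)` along the
polyline — the physically correct composition when radius varies; a
`mean_radius` variant (π r̄⁴ / 8L) is provided because either reading
is consistent with a bare "Hagen–Poiseuille" statement. Boundary nodes
are fixed to the linear pressure profile of a unit gradient (signed so
that flow runs along the probe direction); interior nodes solve flux
conservation as a sparse SPD system (Matrix). Components with no
boundary node are excluded from the solve (they carry no flow and
would make the system singular).

The tensor is assembled by probing with the three Cartesian unit
gradients and measuring the signed flux through the three centre cut
planes; for straight spanning tubes the flux is plane-position
independent (tested), and the single-tube tensor reproduces πr⁴/8 to
numerical precision. The tensor is not symmetrised by default
(`symmetrize = TRUE` gives (k + kᵀ)/2 for display). Axis projections
are `k_pj = |k · n_pj|` (Euclidean norm), and the scalar conductance is
the mean of `|k · n|` over a deterministic golden-angle Fibonacci
sphere of 2,000 directions; for rank-1 tensors this converges to a/2
within 0.5% at that point count.

Segments that exit and re-enter the control volume are clipped into
independent pieces, each with its own boundary nodes; the original
treatment of this case is unspecified and this choice is the
conservative one (no conductance is attributed to the excursion).

## Cortical flatmap

`solve_laplace()` solves the finite-difference Laplace equation over
cortex voxels with Dirichlet values 1 on the layer-1 surface and 0 on
the layer-6b surface, by successive over-relaxation (ω = 1.9,
max-update tolerance 1e-6, iteration cap). Surfaces are identified as
layer-1 / layer-6b voxels 6-adjacent to non-cortex labels. Array faces
are treated as zero-flux cuts, *not* tissue surfaces — a volume edge
slicing through tissue must not become a Dirichlet boundary (this also
makes a half-cylinder phantom behave as the symmetric half of a full
cylinder). Zero-flux conditions arise naturally by averaging over
in-domain neighbours only.

On a slab phantom the potential is linear in depth to the half-voxel
quantisation of the Dirichlet rows; on a half-cylinder it matches
ln(ρ/r)/ln(R/r) — evaluated at the *discrete* surface radii (nominal
radius ∓ half a voxel, which is where the Dirichlet voxel centres
actually sit) the maximum error is below 2%.

Streamlines ascend the gradient (per-voxel central differences
restricted to cortex, trilinearly interpolated over in-cortex corners)
in steps of half a voxel with a budget of 10× the largest volume
dimension. A streamline that steps diagonally past the one-voxel
surface shell is accepted when a surface voxel is 26-adjacent to its
exit cell — without this, ~10% of streamlines on curved phantoms would
falsely count as unresolved. Both phantoms resolve 100% of cortex
voxels.

The flat x coordinate is the signed surface arc length in the coronal
plane, measured from the dorsal ridge (the per-coronal-plane
maximum-DV surface voxel; ties resolve to the most medial of the tied
columns). The contour is ordered by nearest-neighbour marching from
the ridge in both ML directions and smoothed as a single path with a
moving average (window 5) before arc lengths are accumulated — raw
voxel-centre paths overstate arc length by several percent
(staircase). Hit points receive a tangential sub-voxel correction
along the local contour tangent. Residual flat-x error on phantoms is
about half a voxel (~1 µm at 2 µm spacing), which floors the pointwise
azimuth check at roughly one voxel regardless of the nominal 2%
tolerance. The flat y coordinate is the AP position of the surface hit
point. Lookup grids are emitted at 10 µm (authoritative) and 20 µm.

## Cell counting and density conversion

Candidates are strict local maxima within r = 8 µm above an intensity
floor (default: the non-empty-space mean, reusing the preprocessing
statistic); plateau ties resolve to the lexicographically smallest
coordinate. Patches reproduce the published window geometry —
101 × 101 µm at 1 µm/px and 501 × 501 µm at 201 px (2.4925 µm/px,
bilinear resampling; the resampling kernel is not pinned down by the
window specification, and linear interpolation is the neutral choice)
— each with a marker plane that is 1 at the candidate position, plus
an optional 201 × 201 full-frame context. The classifier seam accepts
any `function(patches, candidate) -> label`; the bundled baseline uses
handcrafted features (centre intensity, centre-minus-median contrast,
above-half-peak blob size) and reaches F1 ≥ 0.95 on well-separated
synthetic somata. Learned models are deliberately out of scope; the
seam reproduces the candidate/patch interface so one can be dropped
in.

2D→3D conversion: the pooled factor is the 3D/2D count ratio rounded
to one decimal; per-ROI pairs additionally give mean ± SD of the
per-ROI ratios. For the published pericyte counts (840 in 2D, 1,769 in
3D) the pooled ratio 2.106 and the per-ROI mean 2.13 both round to
2.1, so the two candidate definitions of the factor coincide at the
reported precision; the worked example uses the pooled ratio.
Densities are `count_2d × factor / region volume`, with region volumes
from annotation voxel counts.

## Correlation analysis

Each ROI is one data point; per-region means are taken across animals
first, and regions failing the vessel connectivity QC are excluded and
listed. Pearson R with a two-sided t-distribution p (n − 2 df) and
Bonferroni adjustment `p_adj = min(1, m·p)`. In matrix mode m is the
number of tested pairs and is recorded in the output — the family
size used in the original correlation matrices is not stated anywhere,
so making m explicit is the only auditable choice.

## The synthetic world

The generator emulates FITC-filled vasculature imaged on an
autofluorescent background: seeded random-walk vessel trees (step
5 µm; per-step Gaussian direction perturbation = tortuosity; Bernoulli
branching per µm with children deflected 30–60° to opposite sides of a
common plane so their tubes separate promptly), constant radius per
segment (which makes radius-recovery oracles exact), rasterized as
tubes at 1 × 1 × 5 µm or any stated grid, with a shared low-frequency
background structure (25 µm correlation length, synthesised on a
coarse grid) so that channel subtraction is non-trivially exercised,
Gaussian PSF blur, and additive Gaussian noise. All randomness derives
from the single `rng_seed`; the caller's RNG state is saved and
restored.

Recovery experiments use the stated world of the tracing tolerance:
segments ≥ 60 µm, radii ≥ 2 µm, centreline separation > 12 µm
(enforced at 16 µm between non-adjacent segments, which leaves > 12 µm
between tube surfaces at the smallest radii), noise-free, in
250³ µm volumes at 1 µm isotropic resolution — the working resolution
after interpolation. Under those conditions tracing recovers
branch-node counts exactly and total length within 5% across seeds;
walks cut short by the boundary or the separation rule are dropped
from the ground truth so that the stated minimum-segment world is
actually generated.

What the generator does **not** emulate: arterial/venous tree
morphogenesis, diameter taper along branches, capillary loops, imaging
tiles and stitching artifacts, depth-dependent attenuation, or
vascular compartment labels. A green recovery test therefore
establishes correctness of the tracing machinery on well-separated
tubes, not performance on pathology or densely anastomosed capillary
beds.

Scaled-down checks: the Poisson goodness-of-fit invariant runs over
200 seeded draws as stated; the shared-latent-pattern detection
property runs 25 seeded runs (rather than 100) to keep the suite fast,
with the acceptance threshold adjusted to the matching binomial bound
(≥ 22/25).

## Known limitations

* Endpoint erosion: thinning retracts free tube ends by roughly one
  radius, so very small networks show a percent-level negative length
  bias.
* EDT radii carry a ~half-voxel negative bias; at 1 µm voxels and
  radii ≥ 2 µm this stays well inside the 15% radius tolerance.
* The azimuth coordinate is quantised at the annotation grid; flat-x
  is accurate to about half a voxel on phantoms, and the dorsal-ridge
  reference is only defined up to the tie rule on flat-topped
  contours.
* Conductance values are viscosity-normalised and not calibrated to
  physiological units; pulsatility and red-blood-cell granularity are
  out of scope.
* NRRD support is restricted to ASCII encoding, and SWC export encodes
  spanning trees (cycle closures are listed in the JSON sidecar).
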