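---
title: "Methods: spine mesh repair, the 54-feature descriptor, mixture clustering and simulation"
author: "spinemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine mesh repair, the 54-feature descriptor, mixture clustering and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinemorph)
```

Dendritic spines are micrometre-scale protrusions that carry most
excitatory synapses. Confocal reconstructions of individual spines arrive
as triangle surface meshes, frequently imperfect: fragmented into several
closed shells, or detached from the dendritic shaft insertion point that
was marked during reconstruction. `spinemorph` turns such meshes into a
fixed-length quantitative description, clusters the descriptions with
Gaussian mixtures, and generates new, watertight spine meshes from a
fitted mixture. This vignette explains the models and the choices behind
them; the README shows a worked end-to-end run.

## Repair

A spine is *fragmented* when its faces fall into more than one
edge-connected component, and *detached* when its insertion point lies
farther than a surface tolerance (default two voxels) from every vertex.

**Fragmentation** is repaired in the voxel domain. The mesh is
solid-voxelized by parity counting along lattice columns at an isotropic
spacing of 0.075 um — the in-plane voxel size of the confocal regime this
pipeline targets — on a grid aligned to the absolute lattice, which makes
re-voxelization of a repaired surface see the same sample points (the
repair operator is then idempotent to within 1% volume). A morphological
closing with a spherical structuring element joins the fragments. Two
details matter:

* *Escalation.* The default radius (3 voxels) is tried first and grown
  (up to 16 voxels) until the fragments connect. A fixed small radius
  cannot bridge gaps near the 1 um scale, and a fixed large radius would
  distort every spine to heal the occasional bad one.
* *Bridge retention.* Only the closing-added material that touches two or
  more original fragments is kept. Closing is extensive, and with large
  elements it would also fill the neck-head concavity; retaining only the
  bridges leaves the rest of the shape untouched, which keeps the
  volume-ratio quality gate meaningful.

Morphology uses exact Euclidean distance transforms (separable squared-EDT
passes), not decomposed approximate balls: octagonal structuring elements
measurably fail to bridge thin necks.

**Detachment** is repaired by slice-wise base growth: the segment from the
nearest mesh vertex to the insertion point is aligned with $-z$, the mesh
is voxelized, and each missing slice is filled with the 2D
Gaussian-blurred copy of the slice above it (sigma 1.5 voxels),
thresholded at 0.5 — blurring then thresholding shrinks or preserves a
convex section, so the regrown base tapers naturally. A 2-voxel anchor
column around the insertion axis guarantees the regrown base reaches both
the insertion point and the spine body even when a bent spine hangs lower
elsewhere. The surface is re-extracted and returned in the original pose.

Surfaces are re-extracted from voxel volumes by marching over a conforming
(Freudenthal) tetrahedral decomposition of the lattice at iso-level 0.5.
Every lattice edge crossing contributes a vertex midway between an
occupied and an empty voxel centre; the output is closed, manifold and
consistently oriented by construction, which the classic cube-by-cube
table only achieves with care. Volume error on a 10-voxel-radius sphere is
about 1.5%.

Repaired meshes are smoothed by explicit cotangent-weighted curvature
flow (10 iterations, step 0.1; the step is a fraction of the local
umbrella vector, so displacement per iteration is bounded by the local
edge span). A quality gate then discards spines whose repair changed the
enclosed volume by more than 1.5x or left more than one component —
volume ratio and component count are the operational form of "significantly
deformed or still fragmented".

## The 54-feature descriptor

The descriptor is built from the geodesic distance field $\mu(\cdot)$
from the insertion point: for every vertex, the shortest path length along
the surface. We compute it as Dijkstra shortest paths on the mesh graph
augmented with two Steiner points per edge and all-pairs connections
inside each face, so paths may cut across triangles. On a subdivided
icosphere the pole-to-pole distance is within 0.03% of $\pi$; because
every mesh edge is a graph edge, the field is exactly 1-Lipschitz along
edges.

With $\alpha = \max \mu$, the surface is partitioned into $K = 7$
equal-length intervals $r_0 = [0, \alpha/7]$,
$r_i = (i\alpha/7, (i{+}1)\alpha/7]$. The six boundary curves between
consecutive bands are extracted as edge-crossing level-set polylines
(linear interpolation along edges; if several closed loops exist at one
level, the largest-area loop is kept — spines are quasi-tubular). Each
loop is fitted by an ellipse: the best plane from the loop's two leading
principal directions, then a direct least-squares conic fit
(Halir-Flusser) in the plane, semi-axes ordered $R \ge r$. The coherence
constraint holds by construction: one fitted ellipse *is* both the top of
region $i$ and the bottom of region $i{+}1$.

The centroid chain $c_0$ (insertion point), $c_1 \dots c_6$ (ellipse
centroids), $c_7$ (the maximal-$\mu$ vertex, ties broken by lowest index)
defines vectors $h_i = c_i - c_{i-1}$. The 54 features, in canonical
order:

| group | count | definition |
|---|---|---|
| `h1..h7` | 7 | $|h_i|$, um |
| `R1..R6`, `r1..r6` | 12 | ellipse semi-axes, um |
| `cos_phi1..6` | 6 | $h_i \cdot h_{i+1} / (|h_i||h_{i+1}|)$ |
| `theta2..7` | 6 | colatitude of $h_i$ in the spine-local frame |
| `Theta1..6`, `Phi1..6` | 12 | colatitude and azimuth of ellipse normals |
| `phi_24, phi_26, phi_46` | 3 | section area ratios $R_j r_j / (R_i r_i)$ |
| `Vr1..Vr7` | 7 | region volumes: convex hull of the two boundary loops |
| `V` | 1 | total enclosed volume (divergence theorem) |

The first 36 (heights, axes, cosines, ratios, volumes) are morphological;
the 18 angles are directional. All angles live in the spine-local frame —
origin $c_0$, $+z$ along $h_1$, $+x$ along the first ellipse's major axis
— which makes the whole descriptor invariant to rigid motion of the input
(verified to $10^{-6}$ in the tests). $\theta_1$ is identically zero in
this frame and is therefore not stored; the six stored colatitudes are
$\theta_2..\theta_7$. Ellipse normal signs are chosen distally
($n_e \cdot h_e > 0$) and the major-axis sign points toward the loop's
first extracted point, a connectivity-determined and therefore
rigid-motion-invariant convention. Region volumes use the convex hull of
the two sampled boundary loops (64 points each; an incremental 3D hull
written for this package, checked against frustum/cone closed forms to
well under 2%). $V$ comes from the watertight mesh; $\sum_i V_{r,i}$ is
reported as a diagnostic — on convex tubes the two agree within 10%, on
spines with marked neck-head concavity the hull sum overestimates, which
is inherent to hull-based region volumes.

## Model-based clustering

Feature matrices are clustered by Gaussian mixtures fitted with EM:
z-scored columns by default (features mix um, radians and um^3),
k-means++ seeded restarts (`n_init`), log-sum-exp E-step, ridge
`reg = 1e-6` on covariance diagonals, convergence when the log-likelihood
gain drops below `tol` (1e-6 by default, capped at 500 iterations). The
number of components is chosen by $\mathrm{BIC} = 2\log L - k\log n$,
higher better, over `C_range`.

Covariance structure is a real decision at $d = 54$. The default is the
unconstrained (`"full"`) structure; `"diagonal"` and `"tied"` are
available. A full covariance costs $d(d{+}1)/2 = 1485$ parameters per
component — a BIC penalty near $11{,}000$ at $n = 1500$ — while the
log-likelihood gain from resolving three clusters separated by a few
pooled standard deviations in a handful of directions is an order of
magnitude smaller. BIC under the full structure therefore correctly
refuses to split moderate samples; recovering cluster counts at desk-scale
sample sizes requires the diagonal structure, and the package's
calibration experiments use it. This mirrors practice with mclust-style
searches, where parsimonious parameterizations win at small $n$.
The EM starvation guard requires $d + 2$ effective points per component
under the full structure (3 under diagonal), which prevents the classic
degenerate-spike solutions from inflating BIC.

Interpretation tools: posterior membership matrices and threshold counts;
per-cluster $|\log_{10}\det\Sigma_c|$ via Cholesky; pairwise Bhattacharyya
distances embedded in 2D by classical (Torgerson) MDS; the overlap
$\omega_{j|i} = P[\pi_i N_i(x) < \pi_j N_j(x) \mid x \sim N_i]$ estimated
by Monte Carlo (strict inequality; ties have measure zero for
non-degenerate Gaussians), with its binomial standard error; and Pearson
chi-squared contingency tests (no continuity correction) of hard labels
against categorical covariates, jointly or cluster-vs-rest.

## Simulation

`sample_features` draws from a fitted component and de-standardizes.
Draws are canonicalized where a coordinate is circular or sign-free —
azimuths wrap into $(-\pi, \pi]$, colatitudes of the $h$ directions (whose
azimuths are not part of the descriptor) take absolute values — and are
otherwise rejected-and-resampled when they violate the descriptor's
domain (negative sizes, $R < r$, $|\cos\varphi| > 1$, angles out of
range). Negative ellipse-normal colatitudes are rejected rather than
folded: folding would flip the stored azimuth by $\pi$, planting extreme
outliers in the sample. A clamping mode exists for broad fitted components
(`resample_invalid = FALSE`), used by the demonstration pipeline.

`build_skeleton` inverts the descriptor's angle conventions: $c_0$ at the
origin, $h_1$ along $+z$; each subsequent direction satisfies its
`cos_phi` with the predecessor and its `theta` in the local frame, with
the branch of positive third-frame component chosen since the azimuth is
not stored. The two angle families over-determine each direction, and
sampled vectors carry independent noise on both, so residuals up to
`angle_tol = 0.05` rad are absorbed into the free azimuth; larger
inconsistencies raise an error and the draw is redrawn.

`surface_skeleton` samples every ellipse at the same number of
parameter-uniform points (default 32) and lofts consecutive rings with
the cyclic correspondence minimizing total edge length. Between stations
it inserts Catmull-Rom-interpolated rings (2 per band) and builds rounded
end caps (3 rings, quarter-ellipse profile): a plain 6-ring loft chops
convex bulges such as the spine head, and Loop subdivision of such a loft
loses several percent of enclosed volume per generation. Loop subdivision
(default 2 rounds) uses the standard 3/8-3/8-1/8-1/8 edge stencil and
valence-dependent vertex weights (3/16 at valence 3, otherwise
$3/(8k)$). Every simulated mesh is closed, genus 0 and oriented outward;
the whole chain is deterministic given the seed.

Realism is scored by stratified 10-fold cross-validated accuracy of a
binary classifier (default: a CART tree via rpart) on the stacked
real/simulated matrix, balanced by construction; 0.5 means
indistinguishable. When both classes have equal row counts, real row $i$
and simulated row $i$ share a fold: without this pairing, a literal copy
of the real data leaks its duplicates into training folds and the score
collapses to near 0 instead of the 0.5 that "indistinguishable" must
yield.

## The synthetic-data generator

The generator exists so every stage can be tested with known ground
truth; it emulates the geometry and scale of the real material, not its
biological variability.

*Meshes* are solids of revolution (optionally with an elliptical cross
section and seeded radial roughness) along a bent, helically twisted
axis: a tapered neck joined to a spherical head, in four archetypes
(mushroom-like, thin, stubby, straight tube) spanning spine extents of
roughly 0.5-2.5 um and volumes of ~0.05-0.3 um^3, the scale regime of
adult cortical spines. Cross-section radii have closed forms, giving the
ellipse-fit oracles. Corruption operators delete a mid-neck band of faces
and re-close both sides (fragmentation) or remove the proximal cap and
leave the insertion point stranded (detachment); healing experiments draw
magnitudes uniformly from 0.2 um up to 1 um, truncated at 40% of the
spine's extent so a corruption cannot consume a short stubby spine.

*Feature populations* are Gaussian mixtures around a template descriptor.
The template is extracted from the bent mushroom-like archetype and then
projected three times through the rebuild-and-extract cycle. The
projection matters: a 6-station skeleton cannot represent every profile,
so raw extracted descriptors are not fixed points of the cycle, and
sampling around a non-fixed-point means the round-trip error would mix
representation drift with sampling noise. After projection the template
sits on the generative model's realizable set and round trips are
dominated by discretization (a few percent). Cluster means are placed on
a simplex along three morphologically consistent tangent directions
(overall scale, head-to-neck ratio, elongation), orthonormalized in the
per-coordinate-sd metric and scaled so the smallest pairwise whitened
mean distance equals the requested separation. Covariances are diagonal
with per-cluster jittered scales: 3% relative on sizes and volumes, and
angular noise kept at least ~4 standard deviations away from each
coordinate's domain boundary (the straight-joint bound for cosines, the
pole for colatitudes, the wrap cut for azimuths). The angular noise
levels are deliberately small: near-boundary Gaussians would otherwise be
visibly truncated or bimodal after wrapping, i.e. not the Gaussian
mixture the recovery experiment is calibrating against. Consequently the
generator's within-cluster *shape* variability rides on the morphological
coordinates, and passing recovery tests say nothing about clustering
angle-dominated populations.

What the generator does not emulate: surface roughness at imaging noise
levels, branched or multi-headed spines (the largest-loop rule would
silently linearize them), correlated feature noise, and the heavy-tailed
size distributions of real populations.

## Numerical choices and problem sizes

* Voxelization jitters vertices deterministically by ~1e-5 voxel (a
  coordinate hash, not the user's RNG) so lattice columns never hit mesh
  edges exactly; parity filling is then unambiguous.
* Level-set extraction nudges a level by 1e-9 relative when a vertex sits
  exactly on it.
* The quickhull uses an epsilon of 1e-10 times the point-cloud extent;
  degenerate (coplanar) inputs raise errors rather than returning
  near-zero volumes.
* Mixture fits cap EM at 500 iterations; the calibration experiments use
  `tol = 1e-4`, 200 iterations, 2 restarts, which reproduces the
  `tol = 1e-6` selections in every seed tried while keeping a full
  1:6-component sweep around twenty seconds.
* Test and acceptance problem sizes: populations of 500 spines per
  cluster for recovery, 20 spines per cluster for round trips, 50
  corrupted meshes for healing, 1e5 Monte-Carlo draws for overlap
  estimates. These sizes make every experiment reproducible on one CPU in
  minutes while keeping Monte-Carlo standard errors well inside the
  asserted tolerances.

## Known limitations

* Region volumes are convex-hull approximations; they overestimate on
  concave transitions (neck-head junction) and the $\sum V_{r,i}$ vs $V$
  diagnostic quantifies this per spine.
* The apex is the single maximal-$\mu$ vertex. On wide, flat-headed
  spines the geodesic field has a near-degenerate plateau and the apex —
  hence `h7`, `cos_phi6`, `theta7` — carries more noise than the interior
  features.
* The descriptor stores no in-plane major-axis azimuth, so rebuilt
  skeletons propagate major axes by minimal twist; spines with strongly
  twisted elliptical cross sections are not exactly recoverable.
* BIC with full covariances needs thousands of spines per cluster at
  d = 54; use the diagonal structure below that regime.
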