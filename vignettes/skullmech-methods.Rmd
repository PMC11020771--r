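---
title: "Methods: integrated skull shape, lever mechanics, planar FEA and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated skull shape, lever mechanics, planar FEA and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

skullmech chains four analyses that are usually run in separate tools:
landmark-based geometric morphometrics, jaw lever mechanics, 2D finite
element models of biting, and phylogenetic comparative statistics. This
vignette is the package's own account of the models, the parameters that
matter, the numerical choices, and what the synthetic test bed does and
does not establish.

## Landmark data and dataset variants

Landmarks arrive as TPS records (the common tpsDig dialect: `LM=`,
coordinate lines, optional `IMAGE=`, `ID=`, `SCALE=`). Raw coordinates
are multiplied by the record's scale factor to give millimetres; a
missing `SCALE=` line falls back to scale 1 with a warning rather than
an error, because uncalibrated files are common and shape (though not
size) analyses remain valid. Coordinates follow the convention that x
increases rostrally and y dorsally; this fixes the sign of every
downstream lever and load direction. Reflection of left/right-facing
specimens is never guessed: configurations are used as digitized, and
mirroring is the caller's responsibility.

A *dataset variant* declares the landmark design: `n_traditional` fixed
anatomical landmarks plus `n_curves` semilandmark curves of
`points_per_curve` points. Four presets (a–d, totals 52, 76, 206, 230)
encode the usual trade-off between landmark resolution and taxon
coverage; `subset_to_variant()` reduces a dense design to a sparser
nested one by explicit index mapping. Incomplete specimens are handled
by subsetting, never by imputing missing landmarks — estimating
coordinates for fossils would manufacture shape signal.

## Procrustes superimposition and shape PCA

`gpa()` is the standard iterative algorithm: centre each configuration,
scale to unit centroid size, rotate onto the running consensus with the
orthogonal Procrustes solution, update the consensus, repeat until the
consensus moves by less than `tol` (default 1e-8; typically 2–4
iterations). Two deliberate restrictions:

* **Rotations only.** The optimal orthogonal map is constrained to
  determinant +1. Allowing reflections would silently mirror anatomy.
* **No semilandmark sliding.** Semilandmarks are treated as fixed
  points. Sliding (by bending energy or Procrustes distance) is a
  modelling choice with its own free parameters; with densely and
  consistently sampled curves — which the synthetic generator
  guarantees and digitizing protocols approximate — fixed semilandmarks
  change results very little, and the fixed treatment keeps the
  superimposition exactly reproducible.

`pca_shapes()` takes the SVD of the centred, flattened aligned
coordinates, i.e. a PCA of the coordinate covariance about the
consensus. No tangent-space projection is applied by default (standard
practice for small shape variation; `tangent = TRUE` enables it).
Component signs are fixed deterministically — the largest-magnitude
loading entry of each component is made positive — so scores are
identical across runs and platforms.

Outlier tests are Tukey fences: Q1 − 1.5·IQR and Q3 + 1.5·IQR, with
quartiles from linear interpolation of order statistics
(`stats::quantile` type 7). Only the 1.5·IQR rule is canonical; the
quartile estimator is exposed (`quantile_type`) because at n ≈ 10 the
estimator visibly moves the fences.

## Lever mechanics

Mechanical advantage is the ratio of two Euclidean distances: jaw joint
to muscle insertion (in-lever) over jaw joint to bite point (out-lever).
Each adductor muscle group is reduced to one representative insertion
point (a region is represented by its centroid); the temporal and
quadrate groups give two MA values per taxon and
ΔMA = MA_quadrate − MA_temporal. The pterygoid group is omitted: its
attachment points are not visible in lateral view, so a 2D pipeline
cannot place them without inventing geometry. MA is invariant under
similarity transforms, so it needs no size correction.

## Plane-strain finite elements

The bite model is deliberately the simplest element that passes the
patch test: 3-node constant-strain triangles, unit thickness, in the
consistent mm–N–MPa system (strains reported as microstrain, με).
Plane *strain* is used rather than plane stress because it requires no
bone-thickness estimate. The constitutive matrix is

D = E/((1+ν)(1−2ν)) · [[1−ν, ν, 0], [ν, 1−ν, 0], [0, 0, (1−2ν)/2]],

with defaults E = 20 490 MPa and ν = 0.4 (cortical bone values widely
used for archosaur skull models). Anterior biting is modelled by fixing
the bite node dorsoventrally and the jaw-joint node completely — exactly
three constrained rigid-body degrees of freedom — and loading the
muscle attachment regions. The reduced stiffness is factorized by sparse
Cholesky; a system that is not positive definite (a free rigid mode, a
broken mesh) is an error, never regularized, and the solution is
additionally checked for consistency so a semidefinite factorization
cannot slip through.

Choices the literature leaves open, exposed as parameters:

* **Force partition.** One load condition includes both muscle groups;
  their shares are a configurable fraction (default 0.5/0.5). Within a
  group the force is split equally over the attachment nodes, each nodal
  force pointing from the node to the group's insertion target, and the
  nodal force *magnitudes* sum to the scaled total.
* **Equivalent strain.** MWAM and the intervals method need one
  non-negative scalar per element. The package uses the von Mises-type
  equivalent strain from the deviatoric plane-strain tensor,
  sqrt(2/3 · dev:dev); the signed largest-magnitude principal strain is
  kept separately for tensile/compressive maps.
* **Interval edges.** Intervals are equal-width on [0, upper) with the
  last interval open-ended; `upper` defaults in the pipeline to twice
  the largest MWAM across the study's models, which keeps every model's
  distribution on a common, data-driven scale.
* **Traction lumping.** Edge tractions are lumped equally across edge
  nodes (halved at corner nodes in the structured patch-test meshes),
  consistent with CST accuracy.

Between-model comparability uses the constant-stress scaling rule
F_B = F_A·sqrt(A_B/A_A) with the smallest model as reference (default
reference force 30 N). Operationally — and this is tested — scaling a
mesh's geometry by s and its load by s leaves the strain field unchanged
to machine precision, so size differences cannot masquerade as
performance differences. MWAM, Σ(εᵢAᵢ)/ΣAᵢ, removes element-size bias
from the model mean; the intervals method reports percent model area per
strain band (V1 lowest), always summing to 100.

## Meshing

No quality polygon mesher with hole support exists among the package's
dependencies' ecosystem, so `mesh_polygon()` implements one around
Delaunay triangulation (via deldir): boundaries are resampled to the
target edge length (over-dense digitized boundaries are coarsened
area-preservingly, so hole areas survive chord flattening), interior
points are laid on a staggered grid kept clear of boundaries, triangles
whose centroids fall outside the solid region are discarded, and one or
two Laplacian smoothing passes (interior nodes only) are followed by
re-triangulation. The mesh must reproduce the polygon solid area to
0.1% and reach a 20° minimum angle; if a coarse target edge cannot (thin
inter-fenestra struts), the mesher retries at 0.75× the edge length up
to three times before raising an error. Structured rectangle meshes
(`mesh_rect()`) and uniform refinement (`refine_mesh()`) support patch
and convergence tests.

## Phylogenetic comparative methods

Brownian tip covariance C comes from the tree (`ape::vcv.phylo`):
C[i,j] is the shared root-to-MRCA path length. Blomberg's K is the
observed ratio of the mean squared deviation from the phylogenetic (GLS)
mean to the phylogenetically whitened deviation, divided by its
expectation under Brownian motion on that tree — so K has expectation 1
under BM, K > 1 means relatives are more similar than BM predicts.
K_mult is the distance-based multivariate generalization (sums of
squared deviations across all variables in both spaces) and reduces
exactly to K for one variable; both use tip-permutation tests with the
observed statistic included in the reference set,
p = (#{K* ≥ K} + 1)/(B + 1), B = 999 by default (the conventional
choice), under a caller-supplied seed. Polytomies are allowed;
zero-length branches are allowed but flagged.

PGLS estimates β = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y via Cholesky whitening, with a
two-sided t-test on the slope and
pseudo-R²_adj = 1 − (RSS/TSS_GLS)·(n−1)/(n−2) computed in the whitened
space (TSS about the GLS intercept-only fit) — the analogue of ordinary
adjusted R². With an equal-depth star phylogeny, PGLS reduces to OLS
exactly, which the tests exploit as an oracle. The pipeline regresses
each retained PC, centroid size, fenestra ratios and skull length
against the MA and MWAM responses individually, with no multiple-testing
correction by default, mirroring how such batteries are conventionally
reported; skull length is defined as the horizontal extent
(max x − min x) of the calibrated configuration, a documented and
configurable chord choice.

## The synthetic test bed

`generate_study()` builds complete ground-truth studies: a pure-birth
tree (unit rate) rescaled to unit root-to-tip depth; per-taxon weights
for four deformation modes — snout elongation, snout depth, fenestra
size, quadrate inclination, the axes that dominate lateral-view skull
variation in small theropods — evolved by Brownian motion on that tree;
and, per taxon, a deformed template yielding mutually consistent
landmarks, a fenestrate mesh, lever points and muscle attachment
regions, plus an independent log-normal size factor. Defaults: 8 taxa,
BM rates (1, 0.5, 0.25, 0.25) per unit depth for the four modes, vertex
noise SD 0.05 mm, log-size SD 0.15, 52-landmark variant, 4 mm target
edge — sizes chosen so a study meshes and solves in seconds while the
modes produce shape variation comparable in structure (one dominant
axis, minor correlated axes) to real lateral-view datasets. All
randomness flows through one seed; regeneration is bit-identical.

What passing tests on this bed shows: every algorithmic stage is correct
against independent oracles (closed forms, brute-force enumeration,
established implementations), ground truth is recovered (PC1 tracks the
generating mode at |r| > 0.99; K and K_mult calibrate to ≈ 1 under BM;
PGLS recovers known slopes), and the full pipeline is deterministic.
What it does not show: anything about taphonomy, digitizing error
structure, 3D effects (torsion, mediolateral strain), real muscle
architecture, or the adequacy of plane-strain assumptions for any
particular fossil — those are properties of data, not of code.

## Numerical choices and limitations

* GPA tolerance 1e-8 on consensus displacement, 100-iteration cap;
  degenerate inputs (coincident points, < 2 configurations) are errors.
* PCA on exactly collinear duplicated shapes yields variance fractions
  0/1 exactly; an all-identical dataset reports all-zero fractions
  rather than 0/0.
* Intervals are half-open; a value exactly on an interior edge belongs
  to the upper band, and everything at or beyond the last edge lands in
  the top band, so no area is ever dropped.
* Permutation p-values live on the grid {1/(B+1), …, 1} and are
  deterministic under a fixed seed.
* Test-suite problem sizes: calibration uses 200 Brownian replicates on
  32-tip trees (and 64 tips for slope recovery), oracle sweeps use 1000
  random fields, and pipeline tests use 6–8 taxa at a 4–5 mm mesh edge —
  large enough for the statistics to be meaningful, small enough that
  the whole suite runs in about a minute.
* Known limitations: no semilandmark sliding, no canonical variates or
  integration/modularity tests, no 3D FEA or nonlinear materials, no
  bite-force prediction in absolute newtons, no tree inference. These
  are boundaries of scope, not TODOs.
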