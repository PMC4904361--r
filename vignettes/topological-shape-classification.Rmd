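---
title: "Classifying polyhedral shapes from incomplete graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying polyhedral shapes from incomplete graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopoly)
```

## The problem

Cryo-electron tomography reconstructs individual macromolecular objects in
three dimensions, but the limited tilt range of the stage leaves a "missing
wedge" in Fourier space: the top and bottom of every reconstructed object are
effectively cut away, as if by two parallel planes.  Bacterial
microcompartments (BMCs) and several virus capsids are convex polyhedral
shells, so a natural way to describe one reconstruction is its *polyhedral
graph* (PG): the observed vertices, the edges between them, and the faces
they bound.  Because of the missing wedge this graph is incomplete — some
edges have only one visible endpoint, some faces are open — and because the
objects vary in size and are deformed by the imaging, metric quantities
(lengths, angles) are unreliable.  tomopoly classifies such incomplete PGs
against a library of reference solids using topology alone, which is
invariant under invertible affine transformations.

## The reference library

The library contains the 123 convex solids whose faces are regular polygons,
plus their duals: 5 Platonic, 13 Archimedean, 13 Catalan and 92 Johnson
solids.  Canonical vertex coordinates (unit edge; unit *mean* edge for the
Catalan family, whose faces are planar but not regular) are packaged as text
files; `poly_library()` re-derives edges and faces from the coordinates by a
convex-hull computation that merges coplanar facets (normals within 1e-6
radians, plane offsets within 1e-8 model units).  These tolerances are loose
enough for double-precision coordinates and tight enough never to merge two
genuinely distinct faces of any library solid: the smallest dihedral angles
in the library are of order 10 degrees.  Every load validates Euler's
relation V − E + F = 2 and the packaged vertex/edge/face counts.

Eight pairs of solids have bit-identical complete topological profiles — the
five elongated ortho/gyro bicupola-type pairs (including the classical
rhombicuboctahedron / elongated square gyrobicupola pair) and three para/meta
modification pairs — so `find_duplicate_profiles()` merges the library into
115 canonical classes, labelling each group by its lowest solid id.  The
merge is computed, not hard-coded: the packaged data carry no duplicate
annotations.

## The topological profile

`compute_profile()` maps a PG to a 231-dimensional integer vector:

| block | size | content |
|---|---|---|
| global | 3 | observed vertices V; visible edges E (complete + incomplete); complete faces F |
| face type | 6 | complete faces with 3..8 edges (overflow clipped into the top bin) |
| vertex degree | 6 | complete vertices (no incident incomplete edge) of degree 3..8 |
| censored face type | 8 | faces with at least k visible edges, k = 3..10 |
| censored vertex degree | 8 | vertices with at least k visible incident edges |
| EV | 100 | complete edges by observed endpoint degrees (10 × 10) |
| FV | 100 | complete edges by observed flanking-face sizes (10 × 10) |

The censored ("at least") blocks treat partial visibility like right
censoring: a face with four visible edges and an open side is a face with *at
least* four edges, so it counts in the k = 3 and k = 4 bins.  Complete
features are included in the censored counts.  A vertex's observed degree
counts complete and incomplete incident edges; in a simulated truncation
every edge at a retained vertex is at least partially visible, so observed
degrees equal true degrees there.

Two conventions in this table were genuinely open and are worth recording:

* **E counts all visible edges.**  An incomplete edge is observed evidence,
  so the global edge count includes it.  Under this convention Euler's
  relation holds for every complete solid and fails for most truncated PGs,
  which is what makes the global block informative about truncation.
* **EV and FV enumerate complete edges only**, but use *observed* degrees
  and *observed* face sizes, so incomplete edges still influence both
  matrices through the degree of a shared endpoint or the visible size of a
  flanking face.  The total dimension fixes one copy of each matrix; this
  choice keeps the classical complete-data definition for complete solids
  while letting censored information flow in.

Both matrices are stored symmetrically with the diagonal counted once per
edge, so the upper triangle (including the diagonal) sums to the number of
complete edges — a handshake identity the test suite checks.

The profile's canonical hash is the comma-separated component list; equal
profiles have equal hashes and the profile is recoverable from its hash.

## Truncation simulation

`truncate_polyhedron()` rotates a solid about its vertex centroid by
R = Ry(φy) Rx(φx) with φ drawn uniformly on [0, 2π)² and keeps the slab
|z| ≤ d.  The plane distance is parameterized by the normalized truncation
percentage 200 (1 − d/d_max), where d_max is the circumdistance, so 20 %
truncation removes caps whose total depth is 20 % of the diameter.  The two
planes are symmetric about the centroid.  Vertices exactly on a plane are
retained (a probability-zero tie under continuous φ, broken deterministically).
Edges with one endpoint outside are clipped exactly at the plane and become
incomplete edges; their free ends lie on a truncation plane to 1e-9.  Edges
whose both endpoints are lost contribute nothing — a PG cannot represent an
edge with no observed endpoint.  The batched simulator (`generate_ttps()`)
implements the same geometry in compiled code and draws all randomness from
R's stream, so runs are reproducible under `set.seed()`.

An l-point edge-discretization oracle (`truncate_discretized()`, default
l = 50) classifies edges by which sample points survive the slab; the test
suite checks it against the exact clipping on all 123 solids.

## Classifiers

**Empirical-density Bayes.**  The distribution of truncated topological
profiles (TTPs) of a solid at a fixed truncation level has small finite
support, so it is estimated by the empirical discrete density
p̂(T | class) = count(T)/n — unbiased, with Bernoulli variance p(1−p)/n.
The Bayes rule maximizes p̂(T | class) p(class) under a uniform prior over
the 115 merged classes; ties break to the lowest class id, and a profile
never seen in training makes the classifier abstain, which evaluation counts
as an error.  Training pools the TTPs of both members of a duplicate pair
into their canonical class (the two geometries may induce different TTP
distributions even though their complete profiles coincide); test sets are
drawn from the canonical representative.

**SVM and LDA.**  `train_discriminative()` wraps a radial-kernel,
one-vs-one support vector machine (e1071/libsvm defaults: C = 1,
γ = 1/p, per-column standardization from the training data) and linear
discriminant analysis.  The profile matrix is rank-deficient — many columns
are constant or collinear (its numerical rank at 20 % truncation is a few
dozen) — so LDA is fitted after projection onto the principal components of
the training matrix with non-negligible variance; directions with zero
within-class variance but non-zero between-class separation are nudged by a
deterministic 1e-6-relative perturbation so the fit is defined.  Following
the study design, discriminative classifiers are trained on the solids with
at most 20 vertices; our library contains 63 such solids (52 Johnson, 5
Platonic, 2 Archimedean, 4 Catalan), merging to 62 classes.  This honest
count differs from the 54–55 quoted in the source study, whose selection is
not fully specified.

**Feature subsets.**  `profile_subset()` partitions the profile into
global (V, E, F), local (the rest), complete (face/vertex distributions plus
EV/FV), and incomplete (global counts plus the censored distributions)
blocks, and `feature_subset_regret()` measures the cost of classifying on a
subset relative to all features.

## Robustness to a mis-specified PG

PG extraction can miss a vertex.  The package models this two ways:

* `deletion = "stub"` (default in experiments): the vertex is not observed,
  but its incident edges remain visible as incomplete stubs — this is what
  happens when an annotator fails to mark a vertex yet still traces the
  edges that point at it.
* `deletion = "remove"` (and the `pg_delete_vertex()` operation): the vertex
  and all its incident edges vanish entirely.

The two conventions damage the profile very differently: stubs preserve
observed degrees and censored counts, removal shreds them.  Exact-match
Bayes classification collapses under either (almost no perturbed profile
matches a clean training profile), while the SVM degrades gracefully under
the stub model.  The robustness experiments and the acceptance script use
the stub model; the removal semantics remain available.

## Morphometry

The segmentation side of the pipeline is represented by directional voxel
profiles: interior/exterior indicators obtained by slicing a volume along
x, y and z, with `NA` marking slices lost to the missing wedge.
`fuse_profiles()` takes the per-voxel mean of the non-missing directions
(the least-squares fusion of the three profiles) and applies a Gaussian
filter (default σ = 1.5 voxels; the value is a smoothing choice, not fitted)
implemented as normalized convolution so all-missing voxels are filled.
`measure_shape()` thresholds the fused grid at 0.5, counts interior voxels
(volume = n × voxel volume), and fits an ellipsoid via the eigenvalues of
the centered second-moment matrix.  Axis lengths are proportional to the
*square roots* of those eigenvalues, so the sphericities sp₂ = r₂/r₁ and
sp₃ = r₃/r₁ are computed from square-rooted eigenvalues (for a 2:1:1
ellipsoid this gives 0.5, matching the axis ratio); the literal eigenvalue
ratios are reported alongside.  Centering before the moment computation is
deliberate: uncentered moments conflate location with shape.
`make_fixture()` voxelizes a truncated library solid and marks the
truncated slabs missing in the z profile, standing in for manually traced
slices.

What the synthetic data do **not** emulate: grayscale contrast, noise,
reconstruction artifacts other than the slab truncation, segmentation error
in the traced boundaries, and annotation error beyond single-vertex
deletion.  Passing tests therefore demonstrate correctness of the geometry,
features and classifiers under the stated missing-data model, not
performance on real tomograms.

## Study conditions and problem sizes

The reference conditions are truncation percentages {10, 15, 20, 25, 30},
4500 training orientations per solid and 500 test profiles per class
(`experiment_config()` defaults).  The packaged tests and the acceptance
script run a scaled-down version of the same design — 1000 training
orientations and 100 test profiles per class — which keeps the full suite
within a few minutes on one core; at 20 % truncation the number of distinct
TTPs per ≤ 20-vertex solid stops growing well before 1000 orientations, so
the empirical densities are already saturated at that size.

## Numerical choices

* Hull facet merge: 1e-6 rad / 1e-8 units; hull built on deterministically
  jittered points (1e-9 relative) so square and larger faces triangulate
  robustly, then faces are regrouped using the exact coordinates.
* Coplanarity statistic: coordinates are centered at the face centroid
  before the scatter matrix is formed; otherwise the statistic would depend
  on the distance of the face from the origin.  T = λ₃/λ₂ is 0 for planar
  inputs, 1 for isotropic ones; faces with T > 0.1 are flagged non-planar.
* Degenerate inputs: fewer than 4 points, collinear point sets (λ₂ = 0) and
  coplanar hull inputs raise errors; empty PGs profile to the zero vector.
* Truncation tie-break: |coordinate| = d retains the vertex; clipping uses a
  1e-12 slack so the d = d_max case reproduces the complete solid exactly.
* Seed handling: a single base seed expands to per-(solid, stage) substreams
  via a fixed affine map modulo 2^31 − 19, so partial pipelines are
  reproducible and independent stages do not share streams.

## Known limitations

* The classifier assumes the object is one of the 123 reference solids;
  shapes outside the library are assigned to the nearest class without
  warning (the Bayes rule may abstain, the SVM never does).
* Training and testing are matched per truncation percentage; classifying a
  PG whose true truncation level is unknown requires running several levels
  and comparing (see `match_probability()`).
* Topology-only features cannot separate the eight duplicate pairs, by
  construction; predictions are at the level of the 115 merged classes.
* The morphometry module measures size and gross shape only; it does not
  extract vertices or edges from volumes — PG extraction from real data
  remains a manual or external step.
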