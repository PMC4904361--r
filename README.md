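# tomopoly

Classification of convex polyhedral shapes from individual, incomplete
polyhedral graphs.

Cryo-electron tomography (cryo-ET) reconstructs single macromolecular objects
in 3-D, but the limited tilt range of the stage produces a *missing wedge*:
the top and bottom of each reconstructed object are effectively sliced away
by two parallel planes.  For objects with a convex polyhedral shell —
bacterial microcompartments, many virus capsids — what survives is an
incomplete **polyhedral graph** (PG): observed vertices, edges (some with
only one visible endpoint), and partially open faces.  tomopoly identifies
which reference polyhedron an incomplete PG came from, using topology only
(topology is invariant under the affine distortions that plague cryo-ET
reconstructions, where metric lengths and angles are not).

The package provides:

* the **reference library** of all 123 convex solids with regular faces and
  their duals (5 Platonic, 13 Archimedean, 13 Catalan, 92 Johnson), with
  faces re-derived from packaged coordinates by convex-hull computation;
* the **231-dimensional topological profile** of a PG: global counts
  (V, E, F), complete face-type and vertex-degree distributions, their
  right-censored "at least k" versions for incomplete features, and 10 × 10
  edge-adjacency (EV) and face-adjacency (FV) matrices;
* a **truncation simulator**: random orientation φ = (φx, φy) ~ U[0, 2π)²,
  clipping by two parallel planes at distance d from the centroid
  (truncation percentage 200 (1 − d/d_max));
* the **empirical-density Bayes classifier**: per class Θ the TTP
  distribution is estimated by p̂(T | Θ) = n⁻¹ Σᵢ I(TPᵢ = T), and a profile
  T is assigned to argmax_Θ p̂(T | Θ) p(Θ) under a uniform prior over the
  115 classes that remain after merging the 8 duplicate-profile pairs;
* **SVM / LDA classifiers** on the profile vectors with a vertex-deletion
  robustness harness, per-class misclassification m(Θ), regret relative to
  the Bayes rule, confusion matrices, PPV and cross-truncation match
  probabilities;
* **morphometry**: least-squares fusion of directional voxel profiles
  (per-voxel mean of non-missing directions + Gaussian smoothing), voxel
  volume n = #W and sphericities sp₂ = r₂/r₁, sp₃ = r₃/r₁ from the
  eigen-decomposition of the centered second-moment matrix.

## Worked example

```r
library(tomopoly)

lib <- poly_library()
#> <poly_library> 123 solids (Archimedean: 13, Catalan: 13, Johnson: 92, Platonic: 5)

cube <- lib[[2]]
compute_profile(as_pg(cube))
#> <topological_profile>
#>   V = 8, E = 12, F = 6
#>   F3..F8:    0 6 0 0 0 0
#>   V3..V8:    8 0 0 0 0 0
#>   F3+..F10+: 6 6 0 0 0 0 0 0
#>   V3+..V10+: 8 0 0 0 0 0 0 0
#>   EV: 1 entries set; FV: 1 entries set
```

The complete cube has 8 vertices, 12 edges, 6 quadrilateral faces, all
vertex degrees 3; every face has "at least 3" and "at least 4" edges, hence
F3+ = F4+ = 6.  Now truncate it at 20 % (two parallel planes, random-ish
orientation) and classify the incomplete graph:

```r
pg <- truncate_polyhedron(cube, phi = c(0.9, 2.1), percent = 20)
pg
#> <polyhedral_graph> 6 vertices, 6 complete + 6 incomplete edges,
#>   0 complete + 6 incomplete faces

cm <- find_duplicate_profiles(lib)
#> <class_map> 123 solids -> 115 classes (8 duplicate pairs)

train <- dplyr::bind_rows(lapply(lib[1:5], function(p) {
  tt <- generate_ttps(p, 500, 20, seed = p$id)
  tibble::tibble(class_label = p$id, hash = tt$hash)
}))
fit <- fit_bayes(train)
bayes_classify(fit, profile_hash(compute_profile(pg)))
#> $class
#> [1] 2          # the cube's class
#> $posterior
#>  1  2  3  4  5
#>  0  1  0  0  0
```

This particular orientation cuts off two opposite corners, leaving 6
vertices, 6 complete edges and no complete face; its profile is still
unambiguous among the five Platonic training classes, so the posterior is
concentrated on the cube.

A command-line wrapper with `build-library`, `simulate`, `evaluate`,
`classify`, `fixture` and `morphometry` subcommands is installed under
`exec/tomopoly`.

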