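test_that("orientation sampling is reproducible and uniform", {
  set.seed(5)
  a <- sample_orientation(4)
  set.seed(5)
  b <- sample_orientation(4)
  expect_equal(a, b)
  expect_true(all(a >= 0 & a < 2 * pi))
  # phi = (0, 0) induces the identity rotation
  expect_equal(tomopoly:::rotation_phi(c(0, 0)), diag(3))
  set.seed(99)
  phis <- sample_orientation(1e4)
  ks <- suppressWarnings(stats::ks.test(phis[, 1], "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("truncation at d_max reproduces the complete solid for any phi", {
  set.seed(3)
  for (nm in c("tetrahedron", "cube", "pentagonal rotunda (J6)")) {
    p <- test_solid(nm)
    pr0 <- compute_profile(as_pg(p))
    for (rep in 1:4) {
      pg <- truncate_polyhedron(p, phi = runif(2, 0, 2 * pi), d = p$d_max)
      expect_equal(length(pg$incomplete_vertex), 0, info = nm)
      expect_equal(as.integer(compute_profile(pg)), as.integer(pr0), info = nm)
    }
  }
})

test_that("truncation rejects non-positive plane distances", {
  cube <- test_solid("cube")
  expect_error(truncate_polyhedron(cube, c(0, 0), d = 0), "positive")
  expect_error(truncate_polyhedron(cube, c(0, 0), percent = 100), "percent")
})

test_that("free ends of incomplete edges lie on a truncation plane", {
  set.seed(8)
  for (nm in c("cube", "icosahedron", "sphenocorona (J86)")) {
    p <- test_solid(nm)
    for (rep in 1:5) {
      pg <- truncate_polyhedron(p, phi = runif(2, 0, 2 * pi), percent = 25)
      if (length(pg$incomplete_vertex) > 0) {
        d <- attr(pg, "d")
        expect_lt(max(abs(abs(pg$incomplete_free_end[, 3]) - d)), 1e-9)
      }
    }
  }
})

test_that("decreasing d never increases the number of observed vertices", {
  set.seed(13)
  p <- test_solid("truncated octahedron")
  phi <- runif(2, 0, 2 * pi)
  ds <- seq(p$d_max, 0.55 * p$d_max, length.out = 8)
  nv <- vapply(ds, function(d)
    nrow(truncate_polyhedron(p, phi, d = d)$vertices), integer(1))
  expect_true(all(diff(nv) <= 0))
})

test_that("exact clipping agrees with the l = 50 discretized-edge oracle", {
  set.seed(21)
  for (p in test_library()) {
    phi <- runif(2, 0, 2 * pi)
    d <- p$d_max * (1 - 20 / 200)
    pg <- truncate_polyhedron(p, phi, d = d)
    exact <- rep("dropped", nrow(p$edges))
    keepers <- abs((tomopoly:::rotation_phi(phi) %*%
                    t(sweep(p$vertices, 2, p$centroid)))[3, ]) <= d + 1e-12
    a <- p$edges[, 1]; b <- p$edges[, 2]
    exact[keepers[a] & keepers[b]] <- "complete"
    exact[xor(keepers[a], keepers[b])] <- "partial"
    oracle <- truncate_discretized(p, phi, d = d, l = 50)
    expect_equal(oracle, exact, info = p$name)
    # and the PG's own counts agree with the oracle
    expect_equal(nrow(pg$complete_edges), sum(oracle == "complete"),
                 info = p$name)
    expect_equal(length(pg$incomplete_vertex), sum(oracle == "partial"),
                 info = p$name)
  }
})

test_that("the complete profile is rotation invariant", {
  set.seed(31)
  for (nm in c("dodecahedron", "gyrobifastigium (J26)")) {
    p <- test_solid(nm)
    hashes <- vapply(1:6, function(i) {
      profile_hash(compute_profile(
        truncate_polyhedron(p, runif(2, 0, 2 * pi), d = p$d_max)))
    }, character(1))
    expect_equal(length(unique(hashes)), 1, info = nm)
  }
})

test_that("generate_ttps is deterministic given a seed", {
  p <- test_solid("square cupola (J4)")
  a <- generate_ttps(p, 25, 20, seed = 123)
  b <- generate_ttps(p, 25, 20, seed = 123)
  expect_equal(a, b)
  c <- generate_ttps(p, 25, 20, seed = 124)
  expect_false(identical(a$hash, c$hash))
})

test_that("unique-TTP counts accumulate monotonically and saturate at 0 %", {
  p <- test_solid("tetrahedron")
  tt <- generate_ttps(p, 50, 0, seed = 1)
  expect_equal(length(unique(tt$hash)), 1)
  expect_equal(tt$hash[1], profile_hash(compute_profile(as_pg(p))))
  sat <- ttp_saturation(test_solid("cube"), 400, 20, seed = 2)
  expect_true(all(diff(sat$unique_ttps) >= 0))
})

test_that("vertex deletion from a complete tetrahedron leaves one face", {
  tet <- test_solid("tetrahedron")
  set.seed(17)
  pg <- pg_delete_vertex(as_pg(tet))
  expect_equal(nrow(pg$vertices), 3)
  expect_equal(nrow(pg$complete_edges), 3)
  expect_length(pg$incomplete_vertex, 0)
  nfc <- sum(vapply(pg$faces, function(f) f$type == "complete", logical(1)))
  expect_equal(nfc, 1)
})

test_that("deleting a vertex always changes a Platonic complete profile", {
  set.seed(19)
  for (nm in c("tetrahedron", "cube", "octahedron", "dodecahedron",
               "icosahedron")) {
    p <- test_solid(nm)
    h0 <- profile_hash(compute_profile(as_pg(p)))
    for (rep in 1:4) {
      pg <- pg_delete_vertex(as_pg(p))
      expect_equal(nrow(pg$vertices), nrow(p$vertices) - 1, info = nm)
      expect_false(profile_hash(compute_profile(pg)) == h0)
    }
  }
})

test_that("stub and removal deletion conventions differ as documented", {
  p <- test_solid("icosahedron")
  stub <- generate_ttps(p, 30, 20, seed = 44, perturb = "delete-vertex",
                        deletion = "stub")
  rem <- generate_ttps(p, 30, 20, seed = 44, perturb = "delete-vertex",
                       deletion = "remove")
  none <- generate_ttps(p, 30, 20, seed = 44)
  # one fewer observed vertex either way
  expect_equal(stub$V, none$V - 1)
  expect_equal(rem$V, none$V - 1)
  # stubs keep edges to surviving vertices visible, removal discards all
  # incident edges, so visible-edge counts are ordered
  expect_true(all(stub$E <= none$E))
  expect_true(all(rem$E <= stub$E))
  expect_true(mean(rem$E) < mean(stub$E))
})
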