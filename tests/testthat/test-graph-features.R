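test_that("the profile has 231 components in the documented blocks", {
  nm <- tomopoly:::profile_names()
  expect_length(nm, 231)
  expect_equal(nm[1:3], c("V", "E", "F"))
  expect_length(grep("^F[0-9]+$", nm), 6)
  expect_length(grep("^V[0-9]+$", nm), 6)
  expect_length(grep("^F[0-9]+p$", nm), 8)
  expect_length(grep("^V[0-9]+p$", nm), 8)
  expect_length(grep("^EV_", nm), 100)
  expect_length(grep("^FV_", nm), 100)
})

test_that("the complete cube profile matches the worked example", {
  cube <- test_solid("cube")
  pr <- compute_profile(as_pg(cube))
  expect_equal(unname(pr[c("V", "E", "F")]), c(8, 12, 6))
  expect_equal(unname(pr["F4"]), 6)
  expect_equal(sum(pr[paste0("F", 3:8)]), 6)  # only quadrilaterals
  expect_equal(unname(pr["V3"]), 8)
  expect_equal(unname(pr[c("F3p", "F4p", "F5p")]), c(6, 6, 0))
  expect_equal(unname(pr[c("V3p", "V4p")]), c(8, 0))
  # complete solid: EV concentrated at (3,3), FV at (4,4)
  expect_equal(unname(pr["EV_3_3"]), 12)
  expect_equal(unname(pr["FV_4_4"]), 12)
})

test_that("the body-diagonal cube truncation reproduces the worked example", {
  cube <- test_solid("cube")
  edge <- 1  # unit-edge library
  pg <- truncate_polyhedron(cube, phi = body_diagonal_phi(), d = 0.6 * edge)
  expect_equal(nrow(pg$vertices), 6)
  expect_equal(nrow(pg$complete_edges), 6)
  expect_length(pg$incomplete_vertex, 6)
  pr <- compute_profile(pg)
  expect_equal(unname(pr["V"]), 6)
  expect_equal(unname(pr["F"]), 0)
  expect_equal(unname(pr[c("F3p", "F4p", "F5p")]), c(6, 6, 0))
  # every incomplete face shows 4 visible edges
  vis <- vapply(pg$faces, function(f) length(f$ce) + length(f$ie), integer(1))
  expect_equal(sort(unique(vis)), 4)
  expect_length(pg$faces, 6)
})

test_that("an empty PG yields the all-zero profile", {
  pg <- polyhedral_graph(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 2),
                         integer(0), matrix(numeric(0), 0, 3), list())
  pr <- compute_profile(pg)
  expect_true(all(pr == 0))
})

test_that("Euler holds for complete library profiles and may fail when truncated", {
  for (p in test_library()) {
    pr <- compute_profile(as_pg(p))
    expect_equal(unname(pr["V"] - pr["E"] + pr["F"]), 2, info = p$name)
  }
  cube <- test_solid("cube")
  pg <- truncate_polyhedron(cube, phi = body_diagonal_phi(), d = 0.6)
  pr <- compute_profile(pg)
  expect_false(pr["V"] - pr["E"] + pr["F"] == 2)
})

test_that("censored blocks are non-increasing and dominate complete counts", {
  set.seed(42)
  lib <- test_library()
  for (k in sample(seq_along(lib), 12)) {
    p <- lib[[k]]
    pg <- truncate_polyhedron(p, phi = runif(2, 0, 2 * pi), percent = 25)
    pr <- compute_profile(pg)
    fcens <- pr[paste0("F", 3:10, "p")]
    vcens <- pr[paste0("V", 3:10, "p")]
    expect_true(all(diff(fcens) <= 0), info = p$name)
    expect_true(all(diff(vcens) <= 0), info = p$name)
    fcomp <- pr[paste0("F", 3:8)]
    for (i in 1:6) {
      expect_gte(fcens[i], sum(fcomp[i:6]))
    }
  }
})

test_that("EV satisfies the handshake identity on complete edges", {
  set.seed(7)
  for (nm in c("cube", "icosahedron", "snub disphenoid (J84)")) {
    p <- test_solid(nm)
    pg <- truncate_polyhedron(p, phi = runif(2, 0, 2 * pi), percent = 20)
    pr <- compute_profile(pg)
    EV <- matrix(pr[grep("^EV_", names(pr))], 10, 10, byrow = TRUE)
    expect_equal(EV, t(EV), info = nm)
    upper <- sum(EV[upper.tri(EV, diag = TRUE)])
    expect_equal(upper, nrow(pg$complete_edges), info = nm)
    FV <- matrix(pr[grep("^FV_", names(pr))], 10, 10, byrow = TRUE)
    expect_equal(FV, t(FV), info = nm)
    expect_equal(sum(FV[upper.tri(FV, diag = TRUE)]),
                 nrow(pg$complete_edges), info = nm)
  }
})

test_that("coplanarity statistic behaves as specified", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(coplanarity_test(sq), 0)
  # regular tetrahedron: isotropic scatter, T = 1
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(coplanarity_test(tet), 1, tolerance = 1e-12)
  expect_error(coplanarity_test(sq[1:3, ]), "at least 4")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(coplanarity_test(line), "collinear")
})

test_that("coplanarity is invariant to rotation, translation and scaling", {
  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  T0 <- coplanarity_test(pts)
  for (rep in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    s <- exp(rnorm(1))
    shift <- rnorm(3)
    T1 <- coplanarity_test(s * pts %*% R + rep(shift, each = 5))
    expect_equal(T1, T0, tolerance = 1e-9)
  }
})

test_that("face validation flags merged adjacent icosahedral triangles", {
  ico <- test_solid("icosahedron")
  pg <- as_pg(ico)
  # one genuine face is planar
  f1 <- ico$faces[[1]]
  res <- validate_faces(pg, list(f1))
  expect_true(res$planar[1])
  # the union of two adjacent triangles is not
  shared <- NULL
  for (j in 2:length(ico$faces)) {
    common <- intersect(ico$faces[[1]], ico$faces[[j]])
    if (length(common) == 2) { shared <- ico$faces[[j]]; break }
  }
  quad <- union(f1, shared)
  res2 <- validate_faces(pg, list(quad))
  expect_gt(res2$T[1], 0.1)
  expect_false(res2$planar[1])
  # threshold 1 declares everything planar (T <= 1 always)
  expect_true(validate_faces(pg, list(quad), threshold = 1)$planar[1])
  expect_error(validate_faces(pg, list(c(1, 2, 999))), "unknown vertex")
})

test_that("face regularity matches the worked value and is scale invariant", {
  expect_equal(face_regularity(c(1, 2, 2)), sqrt(1 / 3) / (5 / 3),
               tolerance = 1e-12)
  expect_equal(round(face_regularity(c(1, 2, 2)), 2), 0.35)
  expect_lt(abs(face_regularity(c(1, 2, 2)) - 0.34), 0.01)
  expect_equal(face_regularity(rep(2.7, 5)), 0)
  expect_equal(face_regularity(3.1 * c(1, 2, 2)), face_regularity(c(1, 2, 2)))
  expect_error(face_regularity(c(1, -2, 2)), "positive")
  expect_error(face_regularity(2), "at least 2")
})

test_that("profile hashes are canonical and round-trip", {
  cube <- test_solid("cube")
  tet <- test_solid("tetrahedron")
  h_cube <- profile_hash(compute_profile(as_pg(cube)))
  h_tet <- profile_hash(compute_profile(as_pg(tet)))
  expect_false(h_cube == h_tet)
  back <- parse_profile_hash(h_cube)
  expect_equal(as.integer(back), as.integer(compute_profile(as_pg(cube))))
  expect_equal(profile_hash(back), h_cube)
})

test_that("symmetry-equivalent truncations share a hash", {
  cube <- test_solid("cube")
  # the z-axis and the x-axis are equivalent under the cube's symmetry group:
  # phi = (0,0) truncates along z; phi = (0, pi/2) rotates x onto z
  pr1 <- compute_profile(truncate_polyhedron(cube, c(0, 0), percent = 30))
  pr2 <- compute_profile(truncate_polyhedron(cube, c(0, pi / 2), percent = 30))
  expect_equal(profile_hash(pr1), profile_hash(pr2))
})

test_that("PG JSON interchange round-trips", {
  cube <- test_solid("cube")
  pg <- truncate_polyhedron(cube, phi = body_diagonal_phi(), d = 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_pg_json(pg, path)
  back <- read_pg_json(path)
  expect_equal(nrow(back$vertices), nrow(pg$vertices))
  expect_equal(back$complete_edges, pg$complete_edges)
  expect_equal(back$incomplete_vertex, pg$incomplete_vertex)
  expect_equal(as.integer(compute_profile(back)),
               as.integer(compute_profile(pg)))
})
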