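grid3 <- function(n, fill = 0) array(fill, c(n, n, n))

test_that("fusion takes the mean of non-missing directional values", {
  a <- grid3(4); b <- grid3(4); c <- grid3(4)
  a[2, 2, 2] <- 1; b[2, 2, 2] <- 1; c[2, 2, 2] <- 1
  dp <- directional_profiles(a, b, c)
  f <- fuse_profiles(dp, smoothing_sigma = 0)
  expect_equal(f[2, 2, 2], 1)
  b[3, 3, 3] <- 0; a[3, 3, 3] <- 1; c[3, 3, 3] <- NA
  f2 <- fuse_profiles(directional_profiles(a, b, c), smoothing_sigma = 0)
  expect_equal(f2[3, 3, 3], 0.5)
})

test_that("the fused value minimizes the least-squares criterion per voxel", {
  set.seed(2)
  n <- 5
  a <- grid3(n, runif(n^3)); b <- grid3(n, runif(n^3)); c <- grid3(n, runif(n^3))
  c[sample(n^3, 20)] <- NA
  f <- fuse_profiles(directional_profiles(a, b, c), smoothing_sigma = 0)
  grid_vals <- seq(0, 1, by = 0.001)
  for (i in sample(n^3, 10)) {
    obs <- c(a[i], b[i], c[i])
    obs <- obs[!is.na(obs)]
    L <- vapply(grid_vals, function(v) sum((v - obs)^2), numeric(1))
    expect_lt(abs(f[i] - grid_vals[which.min(L)]), 0.001)
  }
})

test_that("fusion is idempotent for identical complete profiles at sigma 0", {
  set.seed(3)
  a <- grid3(6, runif(216))
  f <- fuse_profiles(directional_profiles(a, a, a), smoothing_sigma = 0)
  expect_equal(as.numeric(f), as.numeric(a))
})

test_that("all-missing grids are rejected; smoothing fills missing voxels", {
  a <- grid3(4, NA_real_)
  expect_error(directional_profiles(a, a, a), "all-missing")
  b <- grid3(8, 0); b[4:5, 4:5, 4:5] <- 1
  miss <- b; miss[, , 7:8] <- NA
  f <- fuse_profiles(directional_profiles(miss, miss, miss),
                     smoothing_sigma = 1.5)
  expect_false(anyNA(f))
})

test_that("a digitized ball has sphericities near one", {
  n <- 48; r <- 20
  g <- seq_len(n) - (n + 1) / 2
  dist2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  ball <- array(as.numeric(dist2 <= r^2), c(n, n, n))
  s <- measure_shape(ball, spacing = 1)
  expect_lt(abs(s$sp2 - 1), 0.02)
  expect_lt(abs(s$sp3 - 1), 0.02)
  # volume close to (4/3) pi r^3
  expect_lt(abs(s$volume / (4 / 3 * pi * r^3) - 1), 0.02)
})

test_that("a 2:1:1 ellipsoid has sphericities near one half", {
  n <- 64
  g <- seq_len(n) - (n + 1) / 2
  a <- 24; b <- 12
  d <- outer(outer((g / a)^2, (g / b)^2, "+"), (g / b)^2, "+")
  ell <- array(as.numeric(d <= 1), c(n, n, n))
  s <- measure_shape(ell, spacing = 1)
  # continuous second moments of an ellipsoid scale with the axes, so the
  # square-rooted eigenvalue ratios equal the axis ratios
  expect_lt(abs(s$sp2 - 0.5), 0.03)
  expect_lt(abs(s$sp3 - 0.5), 0.03)
  expect_lt(abs(s$sp2_eigen - 0.25), 0.03)
})

test_that("sphericities are invariant to rigid rotation of the voxel cloud", {
  p <- test_solid("cube")
  f1 <- fuse_profiles(make_fixture(p, phi = c(0, 0), grid = 48),
                      smoothing_sigma = 0)
  f2 <- fuse_profiles(make_fixture(p, phi = c(0.5, 1.1), grid = 48),
                      smoothing_sigma = 0)
  s1 <- measure_shape(f1); s2 <- measure_shape(f2)
  expect_lt(abs(s1$sp2 - s2$sp2), 0.03)
  expect_lt(abs(s1$sp3 - s2$sp3), 0.03)
})

test_that("cube fixtures recover the analytic volume within 2 percent", {
  cube <- test_solid("cube")
  # a generic orientation avoids voxel-center alignment bias on the faces
  dp <- make_fixture(cube, phi = c(0.31, 0.17), grid = 64)
  f <- fuse_profiles(dp, smoothing_sigma = 0)
  s <- measure_shape(f)
  expect_lt(abs(s$volume - 1), 0.02)  # unit-edge cube
})

test_that("truncated fixtures lose volume and are filled by smoothing", {
  cube <- test_solid("cube")
  full <- measure_shape(fuse_profiles(
    make_fixture(cube, phi = body_diagonal_phi(), grid = 48),
    smoothing_sigma = 1.5))
  dp <- make_fixture(cube, phi = body_diagonal_phi(), percent = 40, grid = 48)
  expect_true(anyNA(dp$f_z))
  trunc <- measure_shape(fuse_profiles(dp, smoothing_sigma = 1.5))
  expect_lt(trunc$volume, full$volume)
  # deterministic: same call gives the identical fixture
  dp2 <- make_fixture(cube, phi = body_diagonal_phi(), percent = 40, grid = 48)
  expect_identical(dp, dp2)
})

test_that("under-resolved grids and empty interiors are rejected", {
  cube <- test_solid("cube")
  expect_error(make_fixture(cube, grid = 12), "grid too small")
  expect_error(measure_shape(grid3(4, 0)), "empty interior")
})

test_that("fixture classification recovers the true class end to end", {
  # simulated-structure check: voxelize, fuse, extract the known PG from the
  # same truncation, classify against densities trained on clean TTPs
  lib <- test_library()
  cm <- test_class_map()
  ids <- ids_with_cap(12)  # small solids keep this quick
  classes <- cm$classes[cm$classes$id %in% ids, ]
  solid_by_id <- setNames(lib, vapply(lib, function(p) p$id, integer(1)))
  train <- dplyr::bind_rows(lapply(seq_len(nrow(classes)), function(i) {
    p <- solid_by_id[[as.character(classes$id[i])]]
    tt <- generate_ttps(p, 250, 20, seed = 500 + p$id)
    tt$class_label <- classes$class_id[i]
    tt[, c("class_label", "hash")]
  }))
  fit <- fit_bayes(train)
  set.seed(77)
  hits <- 0; total <- 0
  for (i in seq_len(nrow(classes))) {
    p <- solid_by_id[[as.character(classes$id[i])]]
    phi <- runif(2, 0, 2 * pi)
    dp <- make_fixture(p, phi = phi, percent = 20, grid = 48)
    f <- fuse_profiles(dp, smoothing_sigma = 1.0)
    expect_gt(measure_shape(f)$n, 0)
    pg <- truncate_polyhedron(p, phi = phi, percent = 20)
    pred <- predict(fit, profile_hash(compute_profile(pg)))
    total <- total + 1
    if (!is.na(pred) && pred == classes$class_id[i]) hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})
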