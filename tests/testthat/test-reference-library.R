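test_that("library builds all 123 solids with the right family counts", {
  lib <- test_library()
  expect_length(lib, 123)
  fam <- table(vapply(lib, function(p) p$family, character(1)))
  expect_equal(as.integer(fam[c("Platonic", "Archimedean", "Catalan",
                                "Johnson")]),
               c(5L, 13L, 13L, 92L))
  ids <- vapply(lib, function(p) p$id, integer(1))
  expect_equal(ids, 1:123)
})

test_that("every solid satisfies Euler's relation and the handshake identities", {
  for (p in test_library()) {
    nv <- nrow(p$vertices); ne <- nrow(p$edges); nf <- length(p$faces)
    expect_equal(nv - ne + nf, 2, info = p$name)
    face_sizes <- lengths(p$faces)
    expect_true(all(face_sizes >= 3), info = p$name)
    expect_equal(sum(face_sizes), 2 * ne, info = p$name)
    deg <- tabulate(p$edges, nbins = nv)
    expect_equal(sum(deg), 2 * ne, info = p$name)
    expect_true(all(deg >= 3), info = p$name)
    # every edge flanked by exactly two faces
    expect_equal(nrow(p$edge_faces), ne, info = p$name)
    expect_true(all(p$edge_faces >= 1 & p$edge_faces <= nf), info = p$name)
  }
})

test_that("every face of every library solid passes the coplanarity test", {
  for (p in test_library()) {
    for (f in p$faces) {
      if (length(f) >= 4) {
        expect_lt(coplanarity_test(p$vertices[f, , drop = FALSE]), 1e-6)
      }
    }
  }
})

test_that("derive_faces recovers the canonical Platonic topologies", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  df <- derive_faces(cube)
  expect_length(df$faces, 6)
  expect_true(all(lengths(df$faces) == 4))
  expect_equal(nrow(df$edges), 12)

  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  df <- derive_faces(tet)
  expect_length(df$faces, 4)
  expect_equal(nrow(df$edges), 6)

  ico <- test_solid("icosahedron")
  df <- derive_faces(ico$vertices)
  expect_length(df$faces, 20)
  expect_equal(nrow(df$edges), 30)
  expect_true(all(lengths(df$faces) == 3))
})

test_that("icosahedron and cube entries match their definitions", {
  ico <- test_solid("icosahedron")
  expect_equal(nrow(ico$vertices), 12)
  expect_equal(nrow(ico$edges), 30)
  expect_length(ico$faces, 20)
  expect_true(all(lengths(ico$faces) == 3))
  expect_true(all(tabulate(ico$edges, 12) == 5))
  cube <- test_solid("cube")
  expect_equal(c(nrow(cube$vertices), nrow(cube$edges), length(cube$faces)),
               c(8, 12, 6))
})

test_that("derive_faces rejects degenerate and interior-point inputs", {
  flat <- cbind(matrix(runif(20), 10, 2), 0)
  expect_error(derive_faces(flat), "coplanar")
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_error(derive_faces(rbind(cube, c(0, 0, 0))), "interior")
  expect_error(derive_faces(cube[1:3, ]), "at least 4")
})

test_that("duplicate-profile search finds the 8 pairs and 115 classes", {
  cm <- test_class_map()
  expect_equal(nrow(cm$duplicate_pairs), 8)
  expect_equal(cm$n_classes, 115)
  # class labels partition the library
  expect_equal(nrow(cm$classes), 123)
  expect_setequal(unique(cm$classes$class_label), 1:115)
  # two solids share a class label iff their hashes are identical
  by_class <- split(cm$classes$hash, cm$classes$class_id)
  expect_true(all(vapply(by_class, function(h) length(unique(h)) == 1,
                         logical(1))))
  # idempotence: labels derived from hashes alone reproduce the map
  expect_equal(cm$classes$class_id,
               stats::ave(cm$classes$id, cm$classes$hash, FUN = min))
})

test_that("restricting to the Platonic solids yields no duplicates", {
  cm5 <- find_duplicate_profiles(poly_library(families = "Platonic"))
  expect_equal(nrow(cm5$duplicate_pairs), 0)
  expect_equal(cm5$n_classes, 5)
})

test_that("OFF export writes the standard header and round-trips", {
  cube <- test_solid("cube")
  path <- withr::local_tempfile(fileext = ".off")
  export_mesh(cube, path)
  lines <- readLines(path)
  expect_equal(lines[1], "OFF")
  expect_equal(lines[2], "8 6 12")
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 8)
  expect_equal(nrow(back$edges), 12)
  expect_length(back$faces, 6)

  tet <- test_solid("tetrahedron")
  path2 <- withr::local_tempfile(fileext = ".off")
  export_mesh(tet, path2)
  lines2 <- readLines(path2)
  expect_length(lines2, 2 + 4 + 4)  # header, counts, 4 vertices, 4 faces
})

test_that("corrupt coordinate files produce errors naming the solid", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# 1|broken|Platonic", "0 0", "1 1"), bad)
  expect_error(tomopoly:::read_solid_file(bad, 1, "broken", "Platonic"))
})
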