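#' The 123-solid reference library
#'
#' Builds the full reference library of convex solids with regular-polygon
#' faces (plus the Catalan duals): 5 Platonic, 13 Archimedean, 13 Catalan and
#' 92 Johnson solids.  Vertex coordinates are packaged with the library; edges
#' and faces are re-derived from the coordinates by convex-hull computation
#' with coplanar-facet merging ([derive_faces()]), and every solid is checked
#' against Euler's relation.
#'
#' @param families Character vector of families to load (default all four).
#' @param check Validate each solid against the packaged manifest (counts of
#'   vertices, edges and faces). Default `TRUE`.
#' @return A list of `polyhedron` objects (class `poly_library`), ordered by
#'   family (Platonic, Archimedean, Catalan, Johnson) and conventional index.
#' @examples
#' lib <- poly_library(families = "Platonic")
#' length(lib)
#' lib[[1]]
#' @export
poly_library <- function(families = c("Platonic", "Archimedean", "Catalan", "Johnson"),
                         check = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  dir <- system.file("extdata", "solids", package = "tomopoly")
  if (dir == "") stop("packaged solid library not found")
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  out <- list()
  for (entry in manifest) {
    if (!entry$family %in% families) next
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) stop("missing coordinate file for ", entry$name)
    p <- tryCatch(
      read_solid_file(path, id = entry$id, name = entry$name,
                      family = entry$family),
      error = function(e) stop("failed to load '", entry$name, "': ",
                               conditionMessage(e)))
    if (check) {
      ok <- nrow(p$vertices) == entry$V && nrow(p$edges) == entry$E &&
        length(p$faces) == entry$F
      if (!ok) stop("derived topology of '", entry$name,
                    "' disagrees with manifest")
    }
    out[[length(out) + 1L]] <- p
  }
  structure(out, class = "poly_library")
}

read_solid_file <- function(path, id, name, family) {
  lines <- readLines(path)
  dat <- lines[!startsWith(lines, "#")]
  V <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  polyhedron(V, id = id, name = name, family = family)
}

#' Construct a polyhedron from vertex coordinates
#'
#' Derives edges and polygonal faces from the convex hull of the vertex set
#' (see [derive_faces()]) and validates Euler's relation, face planarity and
#' convex position of the vertices.
#'
#' @param vertices Numeric matrix (m x 3) of vertex coordinates; every vertex
#'   must be an extreme point of the convex hull.
#' @param id,name,family Optional metadata carried along with the solid.
#' @return An object of class `polyhedron` with elements `vertices`, `edges`
#'   (two-column index matrix), `faces` (list of index cycles), `edge_faces`
#'   (flanking face indices per edge), `centroid` and `d_max` (circumdistance
#'   `max ||v - centroid||`).
#' @export
polyhedron <- function(vertices, id = NA_integer_, name = "polyhedron",
                       family = NA_character_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must be an m x 3 matrix")
  df <- derive_faces(vertices)
  nv <- nrow(vertices); ne <- nrow(df$edges); nf <- length(df$faces)
  if (nv - ne + nf != 2)
    stop("Euler's relation fails for '", name, "': V-E+F = ", nv - ne + nf)
  centroid <- colMeans(vertices)
  d_max <- max(sqrt(rowSums((vertices - rep(centroid, each = nv))^2)))
  structure(list(id = id, name = name, family = family,
                 vertices = vertices, edges = df$edges, faces = df$faces,
                 edge_faces = df$edge_faces,
                 centroid = centroid, d_max = d_max),
            class = "polyhedron")
}

#' @export
print.polyhedron <- function(x, ...) {
  cat(sprintf("<polyhedron> %s (%s)\n", x$name, x$family))
  cat(sprintf("  V = %d, E = %d, F = %d; d_max = %.4f\n",
              nrow(x$vertices), nrow(x$edges), length(x$faces), x$d_max))
  invisible(x)
}

#' @export
print.poly_library <- function(x, ...) {
  fam <- table(vapply(x, function(p) p$family, character(1)))
  cat(sprintf("<poly_library> %d solids (%s)\n", length(x),
              paste(sprintf("%s: %d", names(fam), fam), collapse = ", ")))
  invisible(x)
}

#' Derive edges and faces from vertex coordinates
#'
#' Computes the convex hull of a point set and merges hull facets that share a
#' supporting plane (normals within `angtol` radians and plane offsets within
#' `offtol` model units) into polygonal faces.  Edges are the boundaries
#' between merged faces.
#'
#' @param vertices Numeric m x 3 matrix, m >= 4, all points extreme.
#' @param angtol,offtol Facet-merge tolerances (defaults 1e-6 rad, 1e-8
#'   units).
#' @return List with `faces` (list of integer cycles, counter-clockwise seen
#'   from outside), `edges` (two-column matrix, each row sorted), and
#'   `edge_faces` (two-column matrix of flanking face indices per edge).
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' str(derive_faces(cube)$faces)
#' @export
derive_faces <- function(vertices, angtol = 1e-6, offtol = 1e-8) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 4) stop("need at least 4 points")
  ctr <- sweep(vertices, 2, colMeans(vertices))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate geometry: points are coplanar or collinear")
  res <- .cpp_hull(vertices, angtol, offtol)
  res$faces <- lapply(res$faces, as.integer)
  res
}

#' Merge duplicate complete profiles into canonical classes
#'
#' Computes the complete topological profile of every solid in a library,
#' finds all unordered pairs (or larger groups) of solids with bit-identical
#' profiles, and assigns each solid a canonical class label: the lowest solid
#' id in its group.
#'
#' @param library A `poly_library`.
#' @return A list of class `class_map`: `classes` is a tibble with one row per
#'   solid (`id`, `name`, `family`, `hash`, `class_id`, `class_label`),
#'   `duplicate_pairs` a tibble of id pairs sharing a profile, and
#'   `n_classes` the number of canonical classes.
#' @export
find_duplicate_profiles <- function(library) {
  stopifnot(inherits(library, "poly_library"))
  rows <- purrr::map(library, function(p) {
    pr <- compute_profile(as_pg(p))
    tibble::tibble(id = p$id, name = p$name, family = p$family,
                   hash = profile_hash(pr))
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::mutate(tab,
    class_id = stats::ave(.data$id, .data$hash, FUN = min))
  pairs <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(tab, .data$hash),
                     ids = list(sort(.data$id)), n = dplyr::n()),
    .data$n > 1)
  dup <- if (nrow(pairs) == 0) {
    tibble::tibble(id1 = integer(), id2 = integer())
  } else {
    dplyr::bind_rows(purrr::map(pairs$ids, function(ids) {
      cmb <- utils::combn(ids, 2)
      tibble::tibble(id1 = cmb[1, ], id2 = cmb[2, ])
    }))
  }
  classes <- sort(unique(tab$class_id))
  tab$class_label <- match(tab$class_id, classes)
  structure(list(classes = tab, duplicate_pairs = dup,
                 n_classes = length(classes)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d solids -> %d classes (%d duplicate pairs)\n",
              nrow(x$classes), x$n_classes, nrow(x$duplicate_pairs)))
  invisible(x)
}

#' Write a polyhedron as an OFF mesh file
#'
#' Standard Object File Format: header `OFF`, a counts line `V F E`, vertex
#' lines, then face lines (`k i1 ... ik`, zero-based indices).
#'
#' @param polyhedron A `polyhedron`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(polyhedron, path) {
  stopifnot(inherits(polyhedron, "polyhedron"))
  V <- polyhedron$vertices
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(V), length(polyhedron$faces),
                     nrow(polyhedron$edges)), con)
  writeLines(sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(vapply(polyhedron$faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an OFF mesh file as a polyhedron
#'
#' @param path Path to an OFF file written by [export_mesh()] (or any convex
#'   OFF mesh whose vertices are all extreme).
#' @inheritParams polyhedron
#' @return A `polyhedron` (faces re-derived from the vertex coordinates).
#' @export
read_mesh <- function(path, id = NA_integer_, name = basename(path),
                      family = NA_character_) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  V <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                             as.numeric))
  polyhedron(V, id = id, name = name, family = family)
}

#' Library manifest as a tibble
#'
#' @return One row per packaged solid: id, name, family, and the vertex, edge
#'   and face counts recorded at packaging time.
#' @export
library_manifest <- function() {
  dir <- system.file("extdata", "solids", package = "tomopoly")
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyDataFrame = FALSE)
  dplyr::bind_rows(purrr::map(man, function(e)
    tibble::tibble(id = e$id, name = e$name, family = e$family,
                   V = e$V, E = e$E, F = e$F)))
}
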