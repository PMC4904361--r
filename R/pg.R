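#' Polyhedral graphs (PGs)
#'
#' A polyhedral graph records what is observed of a convex polyhedron:
#' observed vertices with coordinates, complete edges (both endpoints
#' observed), incomplete edges (exactly one observed endpoint plus the
#' coordinate of the free end, cut off by the truncation planes), and face
#' annotations.  A complete face is a closed vertex cycle all of whose edges
#' are complete; an incomplete face carries the indices of its visible
#' (complete and partial) edges.
#'
#' @param vertices m x 3 matrix of observed vertex coordinates.
#' @param complete_edges Ec x 2 integer matrix of vertex indices.
#' @param incomplete_vertex Integer vector: the observed endpoint of each
#'   incomplete edge.
#' @param incomplete_free_end k x 3 matrix of free-end coordinates (one row
#'   per incomplete edge); may have zero rows.
#' @param faces List of face records; each is a list with `type`
#'   (`"complete"` or `"incomplete"`), and either `vertices` (the cycle, for
#'   complete faces) or `ce`/`ie` (indices of visible complete and incomplete
#'   edges).
#' @param ids Optional original vertex ids (defaults to `1:m`).
#' @return An object of class `polyhedral_graph`.
#' @export
polyhedral_graph <- function(vertices, complete_edges, incomplete_vertex,
                             incomplete_free_end, faces, ids = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) > 0) storage.mode(vertices) <- "double"
  m <- nrow(vertices)
  ce <- matrix(as.integer(complete_edges), ncol = 2)
  iv <- as.integer(incomplete_vertex)
  fe <- as.matrix(incomplete_free_end)
  if (length(iv) > 0 && (nrow(fe) != length(iv) || ncol(fe) != 3))
    stop("incomplete_free_end must be one 3-d row per incomplete edge")
  pg <- structure(list(vertices = vertices, ids = ids %||% seq_len(m),
                       complete_edges = ce, incomplete_vertex = iv,
                       incomplete_free_end = fe, faces = faces),
                  class = "polyhedral_graph")
  validate_pg(pg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pg <- function(pg) {
  m <- nrow(pg$vertices)
  ce <- pg$complete_edges
  if (nrow(ce) > 0) {
    if (any(ce < 1L) || any(ce > m))
      stop("complete edge endpoint out of range")
    if (any(ce[, 1] == ce[, 2])) stop("self-loop edge")
    key <- paste(pmin(ce[, 1], ce[, 2]), pmax(ce[, 1], ce[, 2]))
    if (anyDuplicated(key)) stop("duplicate complete edge")
  }
  if (length(pg$incomplete_vertex) > 0 &&
      (any(pg$incomplete_vertex < 1L) || any(pg$incomplete_vertex > m)))
    stop("incomplete edge endpoint out of range")
  for (f in pg$faces) {
    if (identical(f$type, "complete")) {
      cyc <- f$vertices
      if (length(cyc) < 3) stop("complete face with fewer than 3 vertices")
      if (any(cyc < 1L) || any(cyc > m)) stop("face references unknown vertex")
      kk <- cbind(pmin(cyc, c(cyc[-1], cyc[1])), pmax(cyc, c(cyc[-1], cyc[1])))
      ek <- paste(pmin(ce[, 1], ce[, 2]), pmax(ce[, 1], ce[, 2]))
      if (!all(paste(kk[, 1], kk[, 2]) %in% ek))
        stop("complete face boundary uses a non-complete edge")
    } else if (identical(f$type, "incomplete")) {
      if (length(f$ce) + length(f$ie) < 1)
        stop("incomplete face with no visible edge")
    } else stop("face type must be 'complete' or 'incomplete'")
  }
  pg
}

#' @export
print.polyhedral_graph <- function(x, ...) {
  nfc <- sum(vapply(x$faces, function(f) f$type == "complete", logical(1)))
  cat(sprintf(paste0("<polyhedral_graph> %d vertices, %d complete + %d ",
                     "incomplete edges, %d complete + %d incomplete faces\n"),
              nrow(x$vertices), nrow(x$complete_edges),
              length(x$incomplete_vertex), nfc, length(x$faces) - nfc))
  invisible(x)
}

#' Complete polyhedral graph of a polyhedron
#'
#' @param p A `polyhedron`.
#' @return The complete `polyhedral_graph` (no incomplete features).
#' @export
as_pg <- function(p) {
  stopifnot(inherits(p, "polyhedron"))
  faces <- lapply(p$faces, function(f) list(type = "complete", vertices = f))
  polyhedral_graph(p$vertices, p$edges, integer(0),
                   matrix(numeric(0), 0, 3), faces)
}

rotation_phi <- function(phi) {
  cx <- cos(phi[1]); sx <- sin(phi[1])
  cy <- cos(phi[2]); sy <- sin(phi[2])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Ry %*% Rx
}

#' Truncate a polyhedron by two parallel planes
#'
#' Rotates the solid about its vertex centroid by the rotation
#' `R = Ry(phi_y) Rx(phi_x)` and removes everything outside the slab
#' `|z| <= d`, emulating the missing wedge.  Vertices inside the slab are
#' retained (points exactly on a plane count as inside); edges with one
#' endpoint outside become incomplete edges clipped at the plane; edges
#' entirely or doubly outside are dropped.  Faces whose edges are all complete
#' stay complete; faces with at least one visible edge become incomplete.
#'
#' @param p A `polyhedron`.
#' @param phi Numeric length-2 rotation angles `(phi_x, phi_y)` in radians.
#' @param d Plane distance from the centroid along the truncation axis; must
#'   be in `(0, d_max]`.  `d = d_max` reproduces the complete solid.
#' @param percent Alternative to `d`: normalized truncation percentage
#'   `200 * (1 - d/d_max)` in `[0, 100)`.
#' @return A `polyhedral_graph` in the rotated frame (centroid at origin).
#' @examples
#' cube <- poly_library(families = "Platonic")[[2]]
#' pg <- truncate_polyhedron(cube, phi = c(0, 0), percent = 20)
#' pg
#' @export
truncate_polyhedron <- function(p, phi, d = NULL, percent = NULL) {
  stopifnot(inherits(p, "polyhedron"))
  if (is.null(d)) {
    if (is.null(percent)) stop("give either d or percent")
    if (percent < 0 || percent >= 100) stop("percent must be in [0, 100)")
    d <- p$d_max * (1 - percent / 200)
  }
  if (d <= 0) stop("d must be positive")
  R <- rotation_phi(phi)
  V <- t(R %*% t(sweep(p$vertices, 2, p$centroid)))
  keep <- abs(V[, 3]) <= d + 1e-12
  new_id <- cumsum(keep)
  ne <- nrow(p$edges)
  status <- integer(ne)  # 0 dropped, 1 complete, 2 partial
  iv <- integer(0); fe <- NULL
  ie_of_edge <- integer(ne)
  ce_rows <- NULL
  ce_of_edge <- integer(ne)
  for (e in seq_len(ne)) {
    a <- p$edges[e, 1]; b <- p$edges[e, 2]
    if (keep[a] && keep[b]) {
      status[e] <- 1L
      ce_rows <- rbind(ce_rows, c(new_id[a], new_id[b]))
      ce_of_edge[e] <- nrow(ce_rows)
    } else if (xor(keep[a], keep[b])) {
      status[e] <- 2L
      inn <- if (keep[a]) a else b
      out <- if (keep[a]) b else a
      zc <- d * sign(V[out, 3])
      t <- (zc - V[inn, 3]) / (V[out, 3] - V[inn, 3])
      pt <- V[inn, ] + t * (V[out, ] - V[inn, ])
      iv <- c(iv, new_id[inn])
      fe <- rbind(fe, pt)
      ie_of_edge[e] <- length(iv)
    }
  }
  faces <- list()
  face_edge_idx <- lapply(p$faces, function(f)
    face_edge_indices(f, p$edges))
  for (k in seq_along(p$faces)) {
    st <- status[face_edge_idx[[k]]]
    if (all(st == 1L)) {
      faces[[length(faces) + 1L]] <-
        list(type = "complete", vertices = new_id[p$faces[[k]]])
    } else if (any(st > 0L)) {
      faces[[length(faces) + 1L]] <- list(
        type = "incomplete",
        ce = ce_of_edge[face_edge_idx[[k]][st == 1L]],
        ie = ie_of_edge[face_edge_idx[[k]][st == 2L]])
    }
  }
  pg <- polyhedral_graph(V[keep, , drop = FALSE],
                         ce_rows %||% matrix(integer(0), 0, 2),
                         iv, fe %||% matrix(numeric(0), 0, 3), faces,
                         ids = p$ids %||% which(keep))
  attr(pg, "phi") <- phi
  attr(pg, "d") <- d
  pg
}

face_edge_indices <- function(face, edges) {
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  a <- face; b <- c(face[-1], face[1])
  match(paste(pmin(a, b), pmax(a, b)), key)
}

#' Classify truncated edges via l-point discretization
#'
#' Test oracle for the exact plane clipping in [truncate_polyhedron()]: each
#' edge is discretized into `l` equispaced points and classified from the
#' pattern of points falling inside the slab (`complete` if all points and
#' both endpoints survive, `partial` if some do, `dropped` otherwise).
#'
#' @inheritParams truncate_polyhedron
#' @param l Points per edge (default 50).
#' @return Character vector of per-edge statuses, in the edge order of `p`.
#' @export
truncate_discretized <- function(p, phi, d, l = 50) {
  stopifnot(inherits(p, "polyhedron"), l >= 2)
  R <- rotation_phi(phi)
  V <- t(R %*% t(sweep(p$vertices, 2, p$centroid)))
  tt <- seq(0, 1, length.out = l)
  vapply(seq_len(nrow(p$edges)), function(e) {
    a <- V[p$edges[e, 1], ]; b <- V[p$edges[e, 2], ]
    z <- a[3] + tt * (b[3] - a[3])
    inside <- abs(z) <= d + 1e-12
    inside_a <- abs(a[3]) <= d + 1e-12
    inside_b <- abs(b[3]) <= d + 1e-12
    if (inside_a && inside_b) "complete"
    else if (xor(inside_a, inside_b) && any(inside)) "partial"
    else "dropped"
  }, character(1))
}

#' Randomly delete one observed vertex from a PG
#'
#' Mis-specification model for robustness studies: a uniformly chosen
#' observed vertex is removed together with all its incident edges (complete
#' edges vanish entirely, incomplete edges anchored at it vanish); faces that
#' used the vertex become incomplete.
#'
#' @param pg A `polyhedral_graph` with at least one observed vertex.
#' @return The perturbed `polyhedral_graph`.
#' @export
pg_delete_vertex <- function(pg) {
  stopifnot(inherits(pg, "polyhedral_graph"))
  m <- nrow(pg$vertices)
  if (m < 1) stop("PG has no observed vertex")
  v <- sample.int(m, 1)
  keep <- setdiff(seq_len(m), v)
  new_id <- match(seq_len(m), keep)
  ce <- pg$complete_edges
  ce_drop <- ce[, 1] == v | ce[, 2] == v
  ie_drop <- pg$incomplete_vertex == v
  ce_map <- cumsum(!ce_drop); ce_map[ce_drop] <- NA
  ie_map <- cumsum(!ie_drop); ie_map[ie_drop] <- NA
  faces <- list()
  for (f in pg$faces) {
    if (identical(f$type, "complete")) {
      if (v %in% f$vertices) {
        eidx <- face_edge_indices_pg(f$vertices, ce)
        kept <- eidx[!ce_drop[eidx]]
        if (length(kept) > 0)
          faces[[length(faces) + 1L]] <-
            list(type = "incomplete", ce = ce_map[kept], ie = integer(0))
      } else {
        faces[[length(faces) + 1L]] <-
          list(type = "complete", vertices = new_id[f$vertices])
      }
    } else {
      ce_keep <- f$ce[!is.na(ce_map[f$ce])]
      ie_keep <- f$ie[!is.na(ie_map[f$ie])]
      if (length(ce_keep) + length(ie_keep) > 0)
        faces[[length(faces) + 1L]] <- list(
          type = "incomplete", ce = ce_map[ce_keep], ie = ie_map[ie_keep])
    }
  }
  ce_new <- ce[!ce_drop, , drop = FALSE]
  ce_new[] <- new_id[ce_new]
  polyhedral_graph(pg$vertices[keep, , drop = FALSE], ce_new,
                   new_id[pg$incomplete_vertex[!ie_drop]],
                   pg$incomplete_free_end[!ie_drop, , drop = FALSE],
                   faces, ids = pg$ids[keep])
}

face_edge_indices_pg <- function(cycle, ce) {
  key <- paste(pmin(ce[, 1], ce[, 2]), pmax(ce[, 1], ce[, 2]))
  a <- cycle; b <- c(cycle[-1], cycle[1])
  match(paste(pmin(a, b), pmax(a, b)), key)
}

#' Read / write the PG JSON interchange format
#'
#' The interchange format is a JSON object with `vertices` (list of
#' `{id, xyz}`), `complete_edges` (list of id pairs), `incomplete_edges`
#' (list of `{vertex, free_end_xyz}`), and `faces` with `complete` (vertex-id
#' cycles) and `incomplete` (lists of visible-edge references
#' `{complete: i}` / `{incomplete: j}`, 1-based).
#'
#' @param path File path.
#' @return `read_pg_json()` returns a `polyhedral_graph`; `write_pg_json()`
#'   returns `path` invisibly.
#' @export
read_pg_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ids <- vapply(j$vertices, function(v) as.integer(v$id), integer(1))
  V <- do.call(rbind, lapply(j$vertices, function(v) as.numeric(v$xyz)))
  ce <- if (length(j$complete_edges))
    do.call(rbind, lapply(j$complete_edges, function(e)
      match(as.integer(unlist(e)), ids))) else matrix(integer(0), 0, 2)
  iv <- vapply(j$incomplete_edges, function(e)
    match(as.integer(e$vertex), ids), integer(1))
  fe <- if (length(j$incomplete_edges))
    do.call(rbind, lapply(j$incomplete_edges, function(e)
      as.numeric(e$free_end_xyz))) else matrix(numeric(0), 0, 3)
  faces <- list()
  for (cyc in j$faces$complete)
    faces[[length(faces) + 1L]] <-
      list(type = "complete", vertices = match(as.integer(unlist(cyc)), ids))
  for (refs in j$faces$incomplete) {
    ce_i <- ie_i <- integer(0)
    for (r in refs) {
      if (!is.null(r$complete)) ce_i <- c(ce_i, as.integer(r$complete))
      if (!is.null(r$incomplete)) ie_i <- c(ie_i, as.integer(r$incomplete))
    }
    faces[[length(faces) + 1L]] <- list(type = "incomplete", ce = ce_i, ie = ie_i)
  }
  polyhedral_graph(V, ce, iv, fe, faces, ids = ids)
}

#' @rdname read_pg_json
#' @param pg A `polyhedral_graph`.
#' @export
write_pg_json <- function(pg, path) {
  stopifnot(inherits(pg, "polyhedral_graph"))
  ids <- pg$ids
  vertices <- purrr::map(seq_len(nrow(pg$vertices)), function(i)
    list(id = ids[i], xyz = unname(pg$vertices[i, ])))
  ce <- purrr::map(seq_len(nrow(pg$complete_edges)), function(e)
    unname(ids[pg$complete_edges[e, ]]))
  ie <- purrr::map(seq_along(pg$incomplete_vertex), function(e)
    list(vertex = ids[pg$incomplete_vertex[e]],
         free_end_xyz = unname(pg$incomplete_free_end[e, ])))
  comp <- list(); inc <- list()
  for (f in pg$faces) {
    if (identical(f$type, "complete"))
      comp[[length(comp) + 1L]] <- unname(ids[f$vertices])
    else
      inc[[length(inc) + 1L]] <- c(
        purrr::map(f$ce, function(i) list(complete = i)),
        purrr::map(f$ie, function(i) list(incomplete = i)))
  }
  jsonlite::write_json(
    list(vertices = vertices, complete_edges = ce, incomplete_edges = ie,
         faces = list(complete = comp, incomplete = inc)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
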