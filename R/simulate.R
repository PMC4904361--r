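#' Sample a random truncation orientation
#'
#' Draws `phi = (phi_x, phi_y)` independently and uniformly on `[0, 2*pi)`,
#' using R's random number stream.  The induced rotation is
#' `R = Ry(phi_y) Rx(phi_x)`.
#'
#' @param n Number of orientations.
#' @return An n x 2 matrix of angles in radians.
#' @examples
#' set.seed(1)
#' sample_orientation(2)
#' @export
sample_orientation <- function(n = 1) {
  matrix(stats::runif(2 * n, 0, 2 * pi), ncol = 2,
         dimnames = list(NULL, c("phi_x", "phi_y")))
}

solid_sim_data <- function(p) {
  edges0 <- p$edges - 1L
  faceEdges <- lapply(p$faces, function(f)
    face_edge_indices(f, p$edges) - 1L)
  list(V = sweep(p$vertices, 2, p$centroid),
       edges = edges0, faceEdges = faceEdges,
       edgeFaces = p$edge_faces - 1L)
}

#' Generate truncated topological profiles (TTPs)
#'
#' Randomly orients a solid `n` times, truncates it by two parallel planes at
#' the given truncation percentage, and computes the topological profile of
#' every truncated polyhedral graph.  Optionally mis-specifies each PG by
#' deleting one uniformly random observed vertex (with its incident edges)
#' before the profile is computed.
#'
#' All randomness is drawn from R's stream, so results are reproducible under
#' `set.seed()` (or via the `seed` argument).
#'
#' @param p A `polyhedron`.
#' @param n Number of orientations.
#' @param percent Normalized truncation percentage in `[0, 100)`.
#' @param seed Optional integer seed applied locally.
#' @param perturb `"none"` or `"delete-vertex"`.
#' @param deletion Convention for a deleted vertex's incident edges:
#'   `"stub"` (they stay visible as incomplete edges, the annotation-error
#'   model) or `"remove"` (they vanish entirely).
#' @return A tibble with `solid_id`, `name`, `family`, `percent`,
#'   `replicate`, the 231 profile columns, and `hash`.
#' @examples
#' tet <- poly_library(families = "Platonic")[[1]]
#' ttps <- generate_ttps(tet, n = 5, percent = 20, seed = 1)
#' dim(ttps)
#' @export
generate_ttps <- function(p, n, percent, seed = NULL,
                          perturb = c("none", "delete-vertex"),
                          deletion = c("stub", "remove")) {
  stopifnot(inherits(p, "polyhedron"), n >= 1)
  perturb <- match.arg(perturb)
  deletion <- match.arg(deletion)
  del_mode <- if (deletion == "stub") 0L else 2L
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- p$d_max * (1 - percent / 200)
  phis <- sample_orientation(n)
  del_u <- if (perturb == "delete-vertex") stats::runif(n) else numeric(0)
  sd <- solid_sim_data(p)
  m <- .cpp_simulate(sd$V, sd$edges, sd$faceEdges, sd$edgeFaces, phis, d, del_u, del_mode)
  colnames(m) <- profile_names()
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(
    tibble::tibble(solid_id = p$id, name = p$name, family = p$family,
                   percent = percent, replicate = seq_len(n)),
    out)
  out$hash <- apply(m, 1, paste, collapse = ",")
  out
}

#' Unique-TTP saturation curve
#'
#' Cumulative count of distinct truncated profiles as a function of the
#' number of sampled orientations; used to judge how many orientations are
#' needed before the empirical support of the TTP distribution stops growing.
#'
#' @inheritParams generate_ttps
#' @param at Orientation counts at which to report the cumulative number of
#'   unique TTPs (default: 10 log-spaced points up to `n`).
#' @return Tibble with `n` and `unique_ttps`.
#' @export
ttp_saturation <- function(p, n, percent, seed = NULL, at = NULL) {
  tt <- generate_ttps(p, n, percent, seed = seed)
  if (is.null(at))
    at <- unique(round(exp(seq(log(10), log(n), length.out = 10))))
  firsts <- !duplicated(tt$hash)
  cum <- cumsum(firsts)
  tibble::tibble(n = at, unique_ttps = cum[at])
}

#' Extract the profile matrix from a TTP tibble
#'
#' @param ttps Tibble from [generate_ttps()].
#' @return Integer matrix with 231 columns.
#' @export
ttp_matrix <- function(ttps) {
  as.matrix(ttps[, profile_names(), drop = FALSE])
}
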