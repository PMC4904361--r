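#' Topological profile of a polyhedral graph
#'
#' Computes the 231-dimensional integer feature vector of a (possibly
#' incomplete) polyhedral graph: global counts, complete face-type and
#' vertex-degree distributions, right-censored ("at least k") versions of
#' both, and the edge- and face-adjacency matrices.
#'
#' The blocks are, in order: `V, E, F` (observed vertices; all visible edges,
#' complete plus incomplete; complete faces), `F3..F8` (complete faces by
#' edge count, overflow clipped into the top bin), `V3..V8` (complete
#' vertices, i.e. vertices with no incident incomplete edge, by degree),
#' `F3p..F10p` and `V3p..V10p` (faces/vertices with at least k visible
#' edges), `EV` (10 x 10: complete edges by the observed degrees of their
#' endpoints) and `FV` (10 x 10: complete edges by the observed sizes of
#' their two flanking faces).  A vertex's observed degree counts complete and
#' incomplete incident edges; an incomplete face's observed size is its
#' number of visible edges.  `EV`/`FV` are stored symmetrically with the
#' diagonal counted once per edge.
#'
#' @param pg A `polyhedral_graph`.
#' @return An integer vector of class `topological_profile` with 231 named
#'   components.
#' @examples
#' cube <- poly_library(families = "Platonic")[[2]]
#' pr <- compute_profile(as_pg(cube))
#' pr[c("V", "E", "F", "F4", "V3")]
#' @export
compute_profile <- function(pg) {
  stopifnot(inherits(pg, "polyhedral_graph"))
  ce <- pg$complete_edges
  nf <- length(pg$faces)
  face_vis <- integer(nf)
  face_complete <- logical(nf)
  ce_faces <- matrix(0L, nrow(ce), 2)
  if (nf > 0) {
    for (k in seq_len(nf)) {
      f <- pg$faces[[k]]
      if (identical(f$type, "complete")) {
        face_vis[k] <- length(f$vertices)
        face_complete[k] <- TRUE
        eidx <- face_edge_indices_pg(f$vertices, ce)
        for (e in eidx) {
          slot <- if (ce_faces[e, 1] == 0L) 1L else 2L
          ce_faces[e, slot] <- k
        }
      } else {
        face_vis[k] <- length(f$ce) + length(f$ie)
        face_complete[k] <- FALSE
        for (e in f$ce) {
          slot <- if (ce_faces[e, 1] == 0L) 1L else 2L
          ce_faces[e, slot] <- k
        }
      }
    }
  }
  x <- .cpp_profile_pg(nrow(pg$vertices), ce, pg$incomplete_vertex,
                       face_vis, face_complete, ce_faces)
  names(x) <- profile_names()
  structure(x, class = "topological_profile")
}

profile_names <- function() {
  c("V", "E", "F",
    paste0("F", 3:8), paste0("V", 3:8),
    paste0("F", 3:10, "p"), paste0("V", 3:10, "p"),
    paste0("EV_", rep(1:10, each = 10), "_", rep(1:10, 10)),
    paste0("FV_", rep(1:10, each = 10), "_", rep(1:10, 10)))
}

#' Named index sets for the profile feature subsets
#'
#' Subsets follow the feature-categorization table: `global` is the V/E/F
#' block; `local` is everything else; `complete` collects the fully observed
#' local features (complete face/vertex distributions and the adjacency
#' matrices over complete edges); `incomplete` the censoring-aware features
#' (global counts and the at-least distributions).
#'
#' @param subset One of `"all"`, `"global"`, `"local"`, `"complete"`,
#'   `"incomplete"`.
#' @return Integer indices into the 231-component profile.
#' @export
profile_subset <- function(subset = c("all", "global", "local", "complete",
                                      "incomplete")) {
  subset <- match.arg(subset)
  switch(subset,
         all = 1:231,
         global = 1:3,
         local = 4:231,
         complete = c(4:15, 32:231),
         incomplete = c(1:3, 16:31))
}

#' @export
print.topological_profile <- function(x, ...) {
  cat("<topological_profile>\n")
  cat(sprintf("  V = %d, E = %d, F = %d\n", x[1], x[2], x[3]))
  cat("  F3..F8:   ", paste(x[4:9], collapse = " "), "\n")
  cat("  V3..V8:   ", paste(x[10:15], collapse = " "), "\n")
  cat("  F3+..F10+:", paste(x[16:23], collapse = " "), "\n")
  cat("  V3+..V10+:", paste(x[24:31], collapse = " "), "\n")
  cat(sprintf("  EV: %d entries set; FV: %d entries set\n",
              sum(x[32:131] > 0), sum(x[132:231] > 0)))
  invisible(x)
}

#' Canonical string key of a profile
#'
#' The hash is the comma-separated list of the 231 integer components in
#' fixed block order; equal profiles map to equal hashes and the profile can
#' be recovered from the hash with [parse_profile_hash()].
#'
#' @param profile A `topological_profile` (or bare integer vector of length
#'   231).
#' @return A single string.
#' @export
profile_hash <- function(profile) {
  paste(as.integer(profile), collapse = ",")
}

#' @rdname profile_hash
#' @param hash A string produced by [profile_hash()].
#' @export
parse_profile_hash <- function(hash) {
  x <- as.integer(strsplit(hash, ",", fixed = TRUE)[[1]])
  if (length(x) != 231) stop("hash does not encode 231 components")
  names(x) <- profile_names()
  structure(x, class = "topological_profile")
}

#' Coplanarity test statistic
#'
#' Centers the points at their centroid, computes the eigenvalues
#' `lambda1 >= lambda2 >= lambda3` of the 3 x 3 scatter matrix `V V^T` of the
#' centered coordinates, and returns `T = lambda3 / lambda2`.  Exactly
#' coplanar points give `T = 0`; the hypothesis of coplanarity is rejected
#' when `T` exceeds a threshold (0.1 in [validate_faces()]).
#'
#' @param points k x 3 matrix, k >= 4.
#' @return The statistic `T` in `[0, 1]`.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' coplanarity_test(sq)  # 0
#' @export
coplanarity_test <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4)
    stop("need at least 4 points (3 points are always coplanar)")
  X <- sweep(points, 2, colMeans(points))
  lam <- sort(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  if (lam[2] <= 1e-12 * max(lam[1], 1e-300))
    stop("degenerate geometry: points are collinear (lambda2 = 0)")
  max(lam[3], 0) / lam[2]
}

#' Validate candidate faces by the coplanarity test
#'
#' @param pg A `polyhedral_graph`.
#' @param candidate_faces List of vertex-id cycles (indices into the PG's
#'   observed vertices).
#' @param threshold Decision threshold on `T` (default 0.1): faces with
#'   `T > threshold` are flagged non-planar.
#' @return A tibble with one row per candidate: `face` (list column), `T`,
#'   and `planar`.
#' @export
validate_faces <- function(pg, candidate_faces, threshold = 0.1) {
  stopifnot(inherits(pg, "polyhedral_graph"))
  m <- nrow(pg$vertices)
  rows <- purrr::map(candidate_faces, function(f) {
    f <- as.integer(f)
    if (any(f < 1L) || any(f > m)) stop("face references unknown vertex id")
    Tstat <- if (length(f) == 3) 0 else
      coplanarity_test(pg$vertices[f, , drop = FALSE])
    tibble::tibble(face = list(f), T = Tstat, planar = Tstat <= threshold)
  })
  dplyr::bind_rows(rows)
}

#' Face regularity statistic
#'
#' The sample standard deviation of a face's edge lengths divided by their
#' mean (coefficient of variation, `n - 1` denominator).  Zero for a regular
#' polygon; dimensionless and scale-invariant.
#'
#' @param edge_lengths Numeric vector of at least two positive edge lengths.
#' @return The statistic `r_e`.
#' @examples
#' face_regularity(c(1, 2, 2))  # 0.34 to two decimals
#' @export
face_regularity <- function(edge_lengths) {
  if (length(edge_lengths) < 2) stop("need at least 2 edge lengths")
  if (any(edge_lengths <= 0)) stop("edge lengths must be positive")
  stats::sd(edge_lengths) / mean(edge_lengths)
}

#' Profiles as a tibble
#'
#' @param profiles A single profile or list of profiles.
#' @return A tibble with 231 named columns plus `hash`.
#' @export
profiles_tibble <- function(profiles) {
  if (inherits(profiles, "topological_profile")) profiles <- list(profiles)
  m <- do.call(rbind, lapply(profiles, as.integer))
  colnames(m) <- profile_names()
  out <- tibble::as_tibble(as.data.frame(m))
  out$hash <- apply(m, 1, paste, collapse = ",")
  out
}
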