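#' Directional voxel profiles
#'
#' Container for the three directional interior/exterior profiles obtained by
#' slicewise boundary tracing along the x, y and z axes.  Values are 1
#' (interior), 0 (exterior) or `NA` (missing, e.g. slices lost to the missing
#' wedge).
#'
#' @param f_x,f_y,f_z 3-d arrays of identical dimension with values in
#'   `{0, 1, NA}`.
#' @param spacing Edge length of a voxel in model units (default 1).
#' @return Object of class `directional_profiles`.
#' @export
directional_profiles <- function(f_x, f_y, f_z, spacing = 1) {
  if (!identical(dim(f_x), dim(f_y)) || !identical(dim(f_x), dim(f_z)))
    stop("profile grids must share dimensions")
  if (all(is.na(f_x)) && all(is.na(f_y)) && all(is.na(f_z)))
    stop("all-missing profiles")
  structure(list(f_x = f_x, f_y = f_y, f_z = f_z, spacing = spacing),
            class = "directional_profiles")
}

#' @export
print.directional_profiles <- function(x, ...) {
  cat(sprintf("<directional_profiles> %s grid, spacing %.4g\n",
              paste(dim(x$f_x), collapse = " x "), x$spacing))
  invisible(x)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution along one axis with zero padding
conv_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(a))
  n <- dim(a)[axis]
  idx_full <- lapply(dim(a), seq_len)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- idx_full; dst <- idx_full
    lo <- max(1L, 1L - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst[[axis]] <- lo:hi
    src[[axis]] <- (lo:hi) + off
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] +
      k[j] * a[src[[1]], src[[2]], src[[3]]]
  }
  out
}

gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma)
  for (axis in 1:3) a <- conv_axis(a, k, axis)
  a
}

#' Fuse directional profiles into a single rendering
#'
#' The fused value at a voxel is the mean of the non-missing directional
#' values, which minimizes the least-squares criterion
#' `sum_d (f - f_d)^2` over the observed directions.  Voxels missing in all
#' three directions are filled by the subsequent Gaussian smoothing step
#' (normalized convolution), which is applied with standard deviation
#' `smoothing_sigma` voxels.
#'
#' @param profiles A `directional_profiles`.
#' @param smoothing_sigma Gaussian sigma in voxels (default 1.5; 0 disables
#'   smoothing and leaves all-missing voxels `NA`).
#' @return A 3-d numeric array (the fused rendering `f`), with attribute
#'   `spacing`.
#' @export
fuse_profiles <- function(profiles, smoothing_sigma = 1.5) {
  stopifnot(inherits(profiles, "directional_profiles"))
  s <- array(0, dim(profiles$f_x))
  w <- array(0, dim(profiles$f_x))
  for (f in list(profiles$f_x, profiles$f_y, profiles$f_z)) {
    ok <- !is.na(f)
    s[ok] <- s[ok] + f[ok]
    w <- w + ok
  }
  f <- ifelse(w > 0, s / pmax(w, 1), NA_real_)
  if (smoothing_sigma > 0) {
    filled <- ifelse(is.na(f), 0, f)
    mask <- ifelse(is.na(f), 0, 1)
    num <- gauss3(filled, smoothing_sigma)
    den <- gauss3(mask, smoothing_sigma)
    f <- ifelse(den > 1e-12, num / den, 0)
  }
  attr(f, "spacing") <- profiles$spacing
  f
}

#' Size and shape of a fused rendering
#'
#' Collects the interior voxels `W = {(x,y,z) : f > 0.5}`, counts them
#' (`n = #W`, volume `n * spacing^3`), and fits an ellipsoid through the
#' eigen-decomposition of the centered second-moment matrix `W^T W`.  The
#' principal axis lengths are proportional to the square roots of the
#' eigenvalues, giving the sphericities `sp2 = r2/r1` and `sp3 = r3/r1`; the
#' literal eigenvalue ratios are reported alongside for comparison.
#'
#' @param f Fused grid from [fuse_profiles()] (or any numeric 3-d array).
#' @param spacing Voxel edge length (defaults to the `spacing` attribute of
#'   `f`, else 1).
#' @param threshold Interior membership threshold (default 0.5).
#' @return Object of class `shape_summary`: `n`, `volume`, `r` (axis
#'   lengths), `sp2`, `sp3`, `sp2_eigen`, `sp3_eigen`.
#' @export
measure_shape <- function(f, spacing = NULL, threshold = 0.5) {
  spacing <- spacing %||% attr(f, "spacing") %||% 1
  idx <- which(f > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty interior: no voxel exceeds the threshold")
  W <- idx * spacing
  Wc <- sweep(W, 2, colMeans(W))
  lam <- sort(eigen(crossprod(Wc) / nrow(Wc), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  lam <- pmax(lam, 0)
  r <- sqrt(lam)
  structure(list(n = nrow(W), volume = nrow(W) * spacing^3,
                 r = r, sp2 = r[2] / r[1], sp3 = r[3] / r[1],
                 sp2_eigen = lam[2] / lam[1], sp3_eigen = lam[3] / lam[1]),
            class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("<shape_summary> n = %d voxels, volume = %.4g, sp2 = %.3f, sp3 = %.3f\n",
              x$n, x$volume, x$sp2, x$sp3))
  invisible(x)
}

#' @export
glance.shape_summary <- function(x, ...) {
  tibble::tibble(n = x$n, volume = x$volume, sp2 = x$sp2, sp3 = x$sp3,
                 sp2_eigen = x$sp2_eigen, sp3_eigen = x$sp3_eigen)
}

#' Synthetic voxel fixture for a (truncated) solid
#'
#' Voxelizes a library solid on a cubic grid and produces directional
#' profiles mimicking slicewise tracing of a cryo-ET reconstruction: the
#' solid is optionally truncated by the two parallel planes (the object's
#' polar caps are absent), and the z-direction profile is additionally marked
#' missing in the truncated slabs, the region a z-stack cannot see.
#'
#' @param p A `polyhedron`.
#' @param phi Orientation angles as in [truncate_polyhedron()] (default
#'   `c(0, 0)`).
#' @param percent Truncation percentage (0 = no truncation).
#' @param grid Grid size per axis (default 64; must resolve the solid with at
#'   least 16 voxels across).
#' @param margin Fractional bounding-box margin (default 0.15).
#' @return A `directional_profiles` object.
#' @export
make_fixture <- function(p, phi = c(0, 0), percent = 0, grid = 64,
                         margin = 0.15) {
  stopifnot(inherits(p, "polyhedron"))
  R <- rotation_phi(phi)
  V <- t(R %*% t(sweep(p$vertices, 2, p$centroid)))
  d <- p$d_max * (1 - percent / 200)
  half <- max(abs(V)) * (1 + margin)
  if (grid * (max(V[, 1]) - min(V[, 1])) / (2 * half) < 16)
    stop("grid too small to resolve the solid (< 16 voxels across)")
  g <- seq(-half, half, length.out = grid)
  spacing <- g[2] - g[1]
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  # face-plane representation of the rotated solid
  inside <- rep(TRUE, nrow(pts))
  for (f in p$faces) {
    fv <- V[f, , drop = FALSE]
    ctr <- colMeans(fv)
    nrm <- crossprod_3(fv[2, ] - fv[1, ], fv[3, ] - fv[1, ])
    if (sum(nrm * ctr) < 0) nrm <- -nrm
    inside <- inside & (pts %*% nrm <= sum(nrm * fv[1, ]) + 1e-9)
  }
  if (percent > 0) inside <- inside & abs(pts[, 3]) <= d
  vol <- array(as.numeric(inside), dim = c(grid, grid, grid))
  f_x <- f_y <- f_z <- vol
  if (percent > 0) {
    slab_miss <- abs(g) > d
    f_z[, , slab_miss] <- NA_real_
  }
  directional_profiles(f_x, f_y, f_z, spacing = spacing)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
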