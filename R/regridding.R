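# Interpolation of a scattered (c_nma, c_osm) design onto an evenly
# spaced concentration grid, per wavenumber, by local plane fits.
# The target grid is strictly confined to the convex hull of the
# measured compositions: extrapolation is an error, never silent.

design_points <- function(set) {
  cbind(x = set$concentrations$c_nma, y = set$concentrations$c_osm)
}

check_not_collinear <- function(pts) {
  if (nrow(pts) < 3L) stop_ternafac("need at least 3 design points")
  d <- cbind(pts[, 1] - pts[1, 1], pts[, 2] - pts[1, 2])
  # rank of the centered design: all points collinear iff rank < 2
  if (qr(d)$rank < 2L) {
    stop_ternafac("design points are collinear: cannot interpolate a ",
                  "two-dimensional concentration grid")
  }
  invisible(TRUE)
}

#' Default evenly spaced target concentration grid
#'
#' Builds the evenly spaced grid the scattered design is interpolated
#' onto: `levels_per_axis` levels from 0 to `shrink_factor` times the
#' maximum measured level on each axis. The shrink keeps the grid
#' strictly inside the measured region, preventing unstable
#' extrapolation at the design boundary; if any node still falls
#' outside the convex hull of the measured compositions (possible with
#' preparation jitter), the shrink factor is multiplied by 0.95 and the
#' test repeated, up to 20 times.
#'
#' @param set A [scattered_spectra] design.
#' @param levels_per_axis Number of levels per concentration axis.
#' @param shrink_factor Initial shrink in `(0, 1]`.
#' @return An object of class `target_grid` with fields `c1_levels`,
#'   `c2_levels` and the final `shrink_factor` used.
#' @export
default_target_grid <- function(set, levels_per_axis = 5,
                                shrink_factor = 0.9) {
  stopifnot(inherits(set, "scattered_spectra"),
            levels_per_axis >= 2, shrink_factor > 0, shrink_factor <= 1)
  pts <- design_points(set)
  check_not_collinear(pts)
  tr <- interp::tri.mesh(pts[, 1], pts[, 2])
  max1 <- max(pts[, 1]); max2 <- max(pts[, 2])
  sf <- shrink_factor
  for (attempt in seq_len(20L)) {
    c1 <- seq(0, sf * max1, length.out = levels_per_axis)
    c2 <- seq(0, sf * max2, length.out = levels_per_axis)
    nodes <- expand.grid(x = c1, y = c2, KEEP.OUT.ATTRS = FALSE)
    inside <- interp::in.convex.hull(tr, nodes$x, nodes$y,
                                     strict = FALSE, eps = 1e-9)
    if (all(inside)) {
      return(structure(list(c1_levels = c1, c2_levels = c2,
                            shrink_factor = sf),
                       class = "target_grid"))
    }
    sf <- sf * 0.95
  }
  stop_ternafac("could not fit a ", levels_per_axis, "x",
                levels_per_axis, " grid inside the convex hull of the ",
                "design; a denser concentration design is needed")
}

#' @export
print.target_grid <- function(x, ...) {
  cat(sprintf("Target grid %dx%d (shrink %.3f)\n  c_nma: %s\n  c_osm: %s\n",
              length(x$c1_levels), length(x$c2_levels), x$shrink_factor,
              paste(signif(x$c1_levels, 4), collapse = ", "),
              paste(signif(x$c2_levels, 4), collapse = ", ")))
  invisible(x)
}

# Interpolation weights: N-vector of design weights per grid node, so
# the whole regridding is one P x N by N x (I*J) matrix product and the
# geometry is computed once and reused for every wavenumber.

weights_piecewise_linear <- function(pts, nodes) {
  tr <- interp::tri.mesh(pts[, 1], pts[, 2])
  inside <- interp::in.convex.hull(tr, nodes[, 1], nodes[, 2],
                                   strict = FALSE, eps = 1e-9)
  if (!all(inside)) {
    k <- which(!inside)[1]
    stop_ternafac(sprintf(
      "grid node (%.4g, %.4g) lies outside the convex hull of the %s",
      nodes[k, 1], nodes[k, 2], "design: refusing to extrapolate"))
  }
  found <- interp::tri.find(tr, nodes[, 1], nodes[, 2])
  centroid <- colMeans(pts)
  scale <- max(max(pts[, 1]) - min(pts[, 1]),
               max(pts[, 2]) - min(pts[, 2]))
  W <- matrix(0, nrow(pts), nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    idx <- c(found$i1[k], found$i2[k], found$i3[k])
    if (any(idx <= 0)) {
      # point-locator can miss nodes sitting exactly on a hull edge;
      # nudge towards the design centroid to locate a triangle, then
      # use exact barycentric weights of the original node
      for (eps in c(1e-12, 1e-10, 1e-8, 1e-6) * scale) {
        dir <- centroid - nodes[k, ]
        dir <- dir / sqrt(sum(dir^2))
        f2 <- interp::tri.find(tr, nodes[k, 1] + eps * dir[1],
                               nodes[k, 2] + eps * dir[2])
        idx <- c(f2$i1, f2$i2, f2$i3)
        if (all(idx > 0)) break
      }
      if (any(idx <= 0)) {
        stop_ternafac(sprintf(
          "could not locate grid node (%.4g, %.4g) in the design %s",
          nodes[k, 1], nodes[k, 2], "triangulation"))
      }
    }
    W[idx, k] <- barycentric_weights(pts[idx, , drop = FALSE],
                                     nodes[k, ])
  }
  W
}

# exact barycentric coordinates of point p in triangle tri (3 x 2)
barycentric_weights <- function(tri, p) {
  M <- cbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  lam <- solve(M, p - tri[1, ])
  c(1 - sum(lam), lam)
}

weights_mls_plane <- function(pts, nodes, k_neighbors) {
  n <- nrow(pts)
  if (k_neighbors < 3L) stop_ternafac("k_neighbors must be at least 3")
  k_neighbors <- min(k_neighbors, n)
  # hull check with the same geometry as the linear method
  tr <- interp::tri.mesh(pts[, 1], pts[, 2])
  inside <- interp::in.convex.hull(tr, nodes[, 1], nodes[, 2],
                                   strict = FALSE, eps = 1e-9)
  if (!all(inside)) {
    k <- which(!inside)[1]
    stop_ternafac(sprintf(
      "grid node (%.4g, %.4g) lies outside the convex hull of the %s",
      nodes[k, 1], nodes[k, 2], "design: refusing to extrapolate"))
  }
  W <- matrix(0, n, nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    d2 <- (pts[, 1] - nodes[k, 1])^2 + (pts[, 2] - nodes[k, 2])^2
    # stable sort; k-NN distance ties broken by input order
    nb <- order(d2, seq_len(n))[seq_len(k_neighbors)]
    X <- cbind(1, pts[nb, 1], pts[nb, 2])
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) {
      stop_ternafac("nearest design points of node (", nodes[k, 1], ", ",
                    nodes[k, 2], ") are collinear; increase k_neighbors")
    }
    # prediction at the node is linear in the neighbours' ordinates:
    # w = x0' (X'X)^-1 X'
    x0 <- c(1, nodes[k, 1], nodes[k, 2])
    W[nb, k] <- drop(x0 %*% solve(XtX, t(X)))
  }
  W
}

#' Interpolate a scattered spectra design onto a regular grid
#'
#' For every wavenumber, local planes are fit through the measured
#' `(c_nma, c_osm)` points and evaluated at the evenly spaced grid
#' nodes. Two local-plane variants are provided:
#'
#' * `"piecewise_linear"` (default): Delaunay triangulation of the
#'   design, barycentric (planar) interpolation within the containing
#'   triangle. Exact at measured points, never overshoots the triangle's
#'   vertex values, and the triangulation is built once and reused for
#'   all wavenumbers.
#' * `"mls_plane"`: per-node ordinary least-squares plane through the
#'   `k_neighbors` nearest design points (moving plane fit).
#'
#' Both reproduce any absorbance field affine in the two concentrations
#' exactly, and both are linear in the absorbances, so interpolation
#' commutes with spectral linear combinations.
#'
#' @param set A [scattered_spectra] design.
#' @param grid A `target_grid` from [default_target_grid()], or a list
#'   with `c1_levels` / `c2_levels`.
#' @param method `"piecewise_linear"` or `"mls_plane"`.
#' @param k_neighbors Neighbourhood size for `"mls_plane"`.
#' @return A [spectra_grid] of dimension `P x I x J`.
#' @export
interpolate_grid <- function(set, grid,
                             method = c("piecewise_linear", "mls_plane"),
                             k_neighbors = 6L) {
  method <- match.arg(method)
  stopifnot(inherits(set, "scattered_spectra"))
  pts <- design_points(set)
  check_not_collinear(pts)
  c1 <- grid$c1_levels; c2 <- grid$c2_levels
  nodes <- as.matrix(expand.grid(x = c1, y = c2, KEEP.OUT.ATTRS = FALSE))
  W <- switch(method,
              piecewise_linear = weights_piecewise_linear(pts, nodes),
              mls_plane = weights_mls_plane(pts, nodes, k_neighbors))
  vals <- set$absorbance %*% W   # P x (I*J)
  spectra_grid(set$wavenumbers, c1, c2,
               array(vals, dim = c(length(set$wavenumbers),
                                   length(c1), length(c2))))
}
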