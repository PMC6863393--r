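# Membrane surface reconstruction: plane fitting, rotation into the plane
# frame, and biharmonic spline interpolation onto a regular grid.

#' Construct a membrane point cloud
#'
#' A point cloud of clicked positions along the cytosolic leaflet of one
#' membrane (PM or ER) at one contact site. Coordinates are in nanometres.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) in nm.
#' @param membrane Either `"PM"` or `"ER"`.
#' @param site_id Character identifier of the contact site.
#' @return An object of class `membrane_cloud`.
#' @export
membrane_cloud <- function(points, membrane = c("PM", "ER"), site_id = "site") {
  membrane <- match.arg(membrane)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(points))) stop("coordinates must be finite")
  n_min <- if (membrane == "PM") 4L else 1L
  if (nrow(points) < n_min) {
    stop(sprintf("site '%s': %s cloud needs >= %d points", site_id, membrane, n_min))
  }
  structure(
    list(site_id = site_id, membrane = membrane, points = unname(points)),
    class = "membrane_cloud"
  )
}

#' @export
print.membrane_cloud <- function(x, ...) {
  cat(sprintf(
    "<membrane_cloud> site '%s', %s, %d points\n",
    x$site_id, x$membrane, nrow(x$points)
  ))
  invisible(x)
}

#' Total-least-squares plane fit
#'
#' Fits a plane to a 3D point cloud by minimizing orthogonal distances:
#' the plane passes through the centroid and its normal is the direction
#' of least variance (smallest eigenvector of the covariance). The normal
#' is oriented so its z component is nonnegative (ties broken by y, then x).
#'
#' @param cloud A [membrane_cloud()] or a numeric matrix of points (nm).
#' @return A list of class `plane_fit` with `centroid` (nm), `normal`
#'   (unit vector) and `rms_residual_nm`.
#' @export
fit_plane <- function(cloud) {
  pts <- if (inherits(cloud, "membrane_cloud")) cloud$points else as.matrix(cloud)
  site <- if (inherits(cloud, "membrane_cloud")) cloud$site_id else "<matrix>"
  if (nrow(pts) < 3) stop(sprintf("site '%s': plane fit needs >= 3 points", site))
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  cv <- crossprod(q) / nrow(q)
  eg <- eigen(cv, symmetric = TRUE)
  # degenerate (collinear) cloud: two vanishing eigenvalues
  scale2 <- max(eg$values[1], .Machine$double.eps)
  if (eg$values[2] / scale2 < 1e-12) {
    stop(sprintf("site '%s': points are collinear; plane undefined", site))
  }
  nrm <- eg$vectors[, 3]
  # orientation convention: z >= 0, tie-break y then x
  s <- sign(nrm[3])
  if (s == 0) s <- sign(nrm[2])
  if (s == 0) s <- sign(nrm[1])
  if (s < 0) nrm <- -nrm
  res <- as.numeric(q %*% nrm)
  structure(
    list(
      centroid = ctr,
      normal = nrm,
      rms_residual_nm = sqrt(mean(res^2))
    ),
    class = "plane_fit"
  )
}

#' Rotate a point cloud into the fitted-plane frame
#'
#' Builds the rotation that maps the plane normal onto +z and applies it
#' about the plane centroid, so the rotated cloud lies (up to residuals)
#' in a horizontal plane through the origin. The inverse transform
#' `t(rotation) %*% q + centroid` recovers the input to machine precision.
#'
#' @param cloud A [membrane_cloud()] or point matrix (nm).
#' @param plane A [fit_plane()] result.
#' @return List with `points` (rotated n x 3 matrix), `rotation` (3 x 3,
#'   world -> plane frame, det +1) and `centroid`.
#' @export
rotate_to_plane <- function(cloud, plane) {
  pts <- if (inherits(cloud, "membrane_cloud")) cloud$points else as.matrix(cloud)
  stopifnot(inherits(plane, "plane_fit"))
  R <- rotation_between(plane$normal, c(0, 0, 1))
  rotated <- sweep(pts, 2, plane$centroid) %*% t(R)
  list(points = rotated, rotation = R, centroid = plane$centroid)
}

#' Biharmonic spline surface on a regular grid
#'
#' Interpolates scattered heights z(x, y) with the biharmonic radial basis
#' (Green's function g(r) = r^2 (ln r - 1), g(0) = 0), augmented with a
#' linear polynomial term so that constant and planar height fields are
#' reproduced exactly everywhere, and evaluates the surface on a regular
#' `n_grid` x `n_grid` lattice spanning the data bounding box. A small
#' ridge term (lambda = 1e-8) on the radial block keeps the dense system
#' well conditioned. Duplicate (x, y) locations are merged by averaging
#' their heights.
#'
#' @param points_xy Numeric matrix, n x 2, planar coordinates (nm).
#' @param heights Numeric vector of n heights (nm).
#' @param n_grid Grid size per axis (default 20).
#' @param lambda Ridge added to the diagonal of the radial block.
#' @return An object of class `surface_model` with `grid_x`, `grid_y`
#'   (length `n_grid`), `grid_z` (`n_grid` x `n_grid`, rows follow
#'   `grid_x`), the spline coefficients, and the data used.
#' @seealso [evaluate_surface()]
#' @export
biharmonic_surface <- function(points_xy, heights, n_grid = 20, lambda = 1e-8) {
  xy <- as.matrix(points_xy)
  if (ncol(xy) != 2) stop("points_xy must have 2 columns")
  z <- as.numeric(heights)
  if (length(z) != nrow(xy)) stop("heights must match points_xy rows")

  # merge duplicate locations by averaging heights
  key <- paste(signif(xy[, 1], 12), signif(xy[, 2], 12))
  if (anyDuplicated(key)) {
    agg <- tapply(z, key, mean)
    keep <- !duplicated(key)
    xy <- xy[keep, , drop = FALSE]
    z <- as.numeric(agg[key[keep]])
  }
  n <- nrow(xy)
  if (n < 4) stop("biharmonic surface needs >= 4 unique points")

  G <- biharmonic_green(as.matrix(stats::dist(xy)))
  P <- cbind(1, xy)
  A <- rbind(
    cbind(G + lambda * diag(n), P),
    cbind(t(P), matrix(0, 3, 3))
  )
  rhs <- c(z, 0, 0, 0)
  coefs <- tryCatch(
    solve(A, rhs),
    error = function(e) stop("biharmonic system is singular: ", conditionMessage(e))
  )
  w <- coefs[seq_len(n)]
  poly <- coefs[n + 1:3]

  gx <- seq(min(xy[, 1]), max(xy[, 1]), length.out = n_grid)
  gy <- seq(min(xy[, 2]), max(xy[, 2]), length.out = n_grid)
  model <- structure(
    list(
      nodes = xy, weights = w, poly = poly, lambda = lambda,
      grid_x = gx, grid_y = gy, grid_z = NULL
    ),
    class = "surface_model"
  )
  gxy <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  model$grid_z <- matrix(evaluate_surface(model, gxy), n_grid, n_grid)
  model
}

#' @noRd
biharmonic_green <- function(r) {
  g <- r
  pos <- r > 0
  g[pos] <- r[pos]^2 * (log(r[pos]) - 1)
  g[!pos] <- 0
  g
}

#' Evaluate a biharmonic surface at arbitrary planar locations
#'
#' @param model A [biharmonic_surface()] result.
#' @param xy Numeric matrix, m x 2.
#' @return Numeric vector of m interpolated heights.
#' @export
evaluate_surface <- function(model, xy) {
  stopifnot(inherits(model, "surface_model"))
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must have 2 columns")
  m <- nrow(xy)
  out <- numeric(m)
  block <- max(1L, floor(2e6 / nrow(model$nodes)))
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    dx <- outer(xy[idx, 1], model$nodes[, 1], "-")
    dy <- outer(xy[idx, 2], model$nodes[, 2], "-")
    G <- biharmonic_green(sqrt(dx^2 + dy^2))
    out[idx] <- G %*% model$weights +
      model$poly[1] + model$poly[2] * xy[idx, 1] + model$poly[3] * xy[idx, 2]
  }
  out
}
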