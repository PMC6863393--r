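# Intermembrane distance statistics: PM surface model vs clicked ER points.

#' Triangulate a surface-model grid
#'
#' Splits each grid cell into two triangles with the diagonal running from
#' (i, j) to (i+1, j+1). Returns vertex matrices in the rotated (plane)
#' frame together with a flag marking triangles that touch the grid border.
#' @noRd
mesh_from_surface <- function(model) {
  ng <- length(model$grid_x)
  vx <- matrix(model$grid_x, ng, ng)
  vy <- matrix(model$grid_y, ng, ng, byrow = TRUE)
  vz <- model$grid_z
  idx <- function(i, j) (j - 1L) * ng + i
  i <- rep(seq_len(ng - 1L), times = ng - 1L)
  j <- rep(seq_len(ng - 1L), each = ng - 1L)
  verts <- cbind(as.vector(vx), as.vector(vy), as.vector(vz))
  a <- idx(i, j); b <- idx(i + 1L, j); c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  # two triangles per cell sharing the (i,j)-(i+1,j+1) diagonal
  tri <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  border_cell <- i == 1L | j == 1L | i == ng - 1L | j == ng - 1L
  list(
    v1 = verts[tri[, 1], , drop = FALSE],
    v2 = verts[tri[, 2], , drop = FALSE],
    v3 = verts[tri[, 3], , drop = FALSE],
    border = rep(border_cell, 2L)
  )
}

#' Minimum distances from points to a triangulated surface grid
#'
#' @param model A [biharmonic_surface()] result (coordinates in the rotated
#'   plane frame).
#' @param points Numeric matrix, n x 3, in the same frame.
#' @return List with `distance` (n) and `on_border` (logical n: nearest
#'   triangle touches the mesh border, i.e. the point projects at or beyond
#'   the edge of the interpolation domain).
#' @export
surface_mesh_distances <- function(model, points) {
  mesh <- mesh_from_surface(model)
  points <- as.matrix(points)
  n <- nrow(points)
  dist <- numeric(n)
  on_border <- logical(n)
  # prune triangles per point: a triangle whose nearest vertex is farther
  # than (nearest vertex overall + largest triangle extent) cannot win
  verts <- unique(rbind(mesh$v1, mesh$v2, mesh$v3))
  r_max <- sqrt(max(
    rowSums((mesh$v2 - mesh$v1)^2),
    rowSums((mesh$v3 - mesh$v2)^2),
    rowSums((mesh$v1 - mesh$v3)^2)
  ))
  for (k in seq_len(n)) {
    p <- points[k, ]
    dv1 <- sqrt(colSums((t(mesh$v1) - p)^2))
    dv2 <- sqrt(colSums((t(mesh$v2) - p)^2))
    dv3 <- sqrt(colSums((t(mesh$v3) - p)^2))
    tri_min <- pmin(dv1, dv2, dv3)
    cand <- which(tri_min <= min(tri_min) + r_max)
    d <- point_triangles_distance(
      p, mesh$v1[cand, , drop = FALSE],
      mesh$v2[cand, , drop = FALSE], mesh$v3[cand, , drop = FALSE]
    )
    best <- which.min(d)
    dist[k] <- d[best]
    on_border[k] <- mesh$border[cand[best]]
  }
  list(distance = dist, on_border = on_border)
}

#' Per-site ER-PM intermembrane distance statistics
#'
#' Reconstructs the PM surface from its clicked point cloud (total-least-
#' squares plane fit, rotation of both clouds into the plane frame,
#' biharmonic spline interpolation onto a regular `n_grid` x `n_grid`
#' lattice over the PM bounding box) and measures, for every clicked ER
#' point, the minimum Euclidean distance to the triangulated surface mesh.
#' Reported statistics are the mean, standard deviation (n - 1 denominator;
#' 0 for a single point), minimum and maximum over the ER points.
#'
#' ER points whose nearest mesh triangle lies on the mesh border fall at or
#' beyond the edge of the interpolated PM patch; they are counted but their
#' number is reported in `n_boundary` and triggers a warning.
#'
#' @param pm,er [membrane_cloud()] objects sharing a `site_id`.
#' @param n_grid Surface grid size per axis (default 20).
#' @return A list of class `distance_stats`: `site_id`, `n_er_points`,
#'   `mean_nm`, `sd_nm`, `min_nm`, `max_nm`, `n_boundary`, plus the
#'   per-point `distances_nm` and the fitted `surface`.
#' @export
site_distance_stats <- function(pm, er, n_grid = 20) {
  stopifnot(inherits(pm, "membrane_cloud"), inherits(er, "membrane_cloud"))
  if (pm$membrane != "PM" || er$membrane != "ER") {
    stop("arguments must be a PM cloud and an ER cloud, in that order")
  }
  if (!identical(pm$site_id, er$site_id)) {
    stop(sprintf(
      "site ids differ: PM '%s' vs ER '%s'", pm$site_id, er$site_id
    ))
  }
  plane <- fit_plane(pm)
  pm_rot <- rotate_to_plane(pm, plane)
  er_rot <- sweep(er$points, 2, plane$centroid) %*% t(pm_rot$rotation)
  # canonical in-plane orientation: align the grid with the projected PM
  # cloud's principal axis (180-degree ambiguity fixed by skewness) so the
  # mesh, and hence the statistics, do not depend on the world frame
  R2 <- canonical_inplane_rotation(pm_rot$points[, 1:2])
  pm_xy <- pm_rot$points[, 1:2] %*% t(R2)
  er_xyz <- cbind(er_rot[, 1:2] %*% t(R2), er_rot[, 3])
  model <- biharmonic_surface(pm_xy, pm_rot$points[, 3], n_grid = n_grid)
  md <- surface_mesh_distances(model, er_xyz)
  n_boundary <- sum(md$on_border)
  if (n_boundary > 0) {
    warning(sprintf(
      "site '%s': %d ER point(s) nearest the mesh border (extrapolation)",
      pm$site_id, n_boundary
    ))
  }
  d <- md$distance
  structure(
    list(
      site_id = pm$site_id,
      n_er_points = length(d),
      mean_nm = mean(d),
      sd_nm = if (length(d) > 1) stats::sd(d) else 0,
      min_nm = min(d),
      max_nm = max(d),
      n_boundary = n_boundary,
      distances_nm = d,
      surface = model
    ),
    class = "distance_stats"
  )
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf(
    "<distance_stats> site '%s': n = %d, mean %.2f nm (SD %.2f), range [%.2f, %.2f]\n",
    x$site_id, x$n_er_points, x$mean_nm, x$sd_nm, x$min_nm, x$max_nm
  ))
  invisible(x)
}

#' In-plane rotation aligning the grid frame with the cloud's principal axis
#'
#' Returns a proper 2 x 2 rotation mapping the dominant planar direction of
#' `xy` onto +x; the remaining 180-degree ambiguity is resolved by making
#' the third moment of the first (then second) coordinate nonnegative, a
#' convention preserved by rigid motions of the input.
#' @noRd
canonical_inplane_rotation <- function(xy) {
  ctr <- colMeans(xy)
  q <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(q), symmetric = TRUE)$vectors[, 1]
  psi <- atan2(ev[2], ev[1])
  R2 <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)  # rows: rot by -psi
  qr_ <- q %*% t(R2)
  s1 <- sum(qr_[, 1]^3)
  s2 <- sum(qr_[, 2]^3)
  flip <- s1 < -1e-9 || (abs(s1) <= 1e-9 && s2 < -1e-9)
  if (flip) R2 <- -R2  # 180-degree rotation, keeps det +1
  R2
}

#' Shortest PM-ER distance at a buckle
#'
#' The automated counterpart of a manual shortest-distance click: the
#' minimum, over the supplied ER points, of the point-to-mesh distance to
#' the PM surface. Equals the `min_nm` field of [site_distance_stats()] on
#' the same inputs.
#'
#' @param pm A PM [membrane_cloud()] or an already fitted surface pipeline
#'   input (cloud is refit internally).
#' @param er An ER [membrane_cloud()] or an n x 3 point matrix (nm).
#' @return Scalar distance in nm.
#' @export
buckle_distance <- function(pm, er) {
  if (!inherits(er, "membrane_cloud")) {
    er <- membrane_cloud(as.matrix(er), "ER",
      site_id = if (inherits(pm, "membrane_cloud")) pm$site_id else "site"
    )
  }
  stats <- suppressWarnings(site_distance_stats(pm, er))
  stats$min_nm
}

#' Combine per-site distance statistics into one table
#'
#' @param stats_list List of [site_distance_stats()] results.
#' @return data.frame with one row per site.
#' @export
distance_stats_table <- function(stats_list) {
  do.call(rbind, lapply(stats_list, function(s) {
    data.frame(
      site_id = s$site_id, n_er_points = s$n_er_points,
      mean_nm = s$mean_nm, sd_nm = s$sd_nm,
      min_nm = s$min_nm, max_nm = s$max_nm,
      n_boundary = s$n_boundary,
      stringsAsFactors = FALSE
    )
  }))
}
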