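# Shared fixtures, built in code.

# flat PM raster and parallel ER cloud at a given separation
flat_site_clouds <- function(separation, extent = 100, site_id = "s",
                             spacing = 10) {
  g <- seq(-extent / 2, extent / 2, by = spacing)
  pm <- cbind(rep(g, times = length(g)), rep(g, each = length(g)), 0)
  inner <- g[abs(g) <= extent / 2 - spacing]
  er <- cbind(rep(inner, times = length(inner)), rep(inner, each = length(inner)),
              separation)
  list(
    pm = membrane_cloud(pm, "PM", site_id),
    er = membrane_cloud(er, "ER", site_id)
  )
}

# apply a rigid motion to a cloud
transform_cloud <- function(cloud, R, t) {
  membrane_cloud(sweep(cloud$points %*% t(R), 2, t, "+"),
    cloud$membrane, cloud$site_id
  )
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# small contact volume with optional rods/coat for pipeline tests
small_contact_volume <- function(gap = 22, rods = NULL, coat = NULL,
                                 noise_sd = 0, voxel = 0.74,
                                 shape = c(96, 96, 80), seed = 1) {
  vt <- volume_truth(
    voxel_nm = voxel, pm_z_nm = 20, er_z_nm = 20 + gap, rods = rods,
    coat_thickness_nm = coat, noise_sd = noise_sd
  )
  gen_contact_volume(vt, shape, seed = seed)
}

# spanning rod table: length chosen so the rod touches both leaflets
spanning_rods <- function(x, y, tilt_deg, azimuth_deg, gap) {
  data.frame(
    x = x, y = y, tilt_deg = tilt_deg, azimuth_deg = azimuth_deg,
    length_nm = gap / cos(tilt_deg * pi / 180)
  )
}

# dense-grid oracle: evaluate the fitted spline on a fine lattice and take
# nearest-vertex distances, in the same canonical frame as the pipeline
dense_grid_oracle <- function(pm, er, n_dense = 400) {
  plane <- fit_plane(pm)
  pr <- rotate_to_plane(pm, plane)
  er_rot <- sweep(er$points, 2, plane$centroid) %*% t(pr$rotation)
  R2 <- mcsquant:::canonical_inplane_rotation(pr$points[, 1:2])
  er_c <- cbind(er_rot[, 1:2] %*% t(R2), er_rot[, 3])
  model <- biharmonic_surface(pr$points[, 1:2] %*% t(R2), pr$points[, 3])
  gx <- seq(min(model$grid_x), max(model$grid_x), length.out = n_dense)
  gy <- seq(min(model$grid_y), max(model$grid_y), length.out = n_dense)
  gxy <- cbind(rep(gx, times = n_dense), rep(gy, each = n_dense))
  V <- cbind(gxy, evaluate_surface(model, gxy))
  apply(er_c, 1, function(p) sqrt(min(colSums((t(V) - p)^2))))
}
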