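# Synthetic tomographic density volumes: two double-leaflet membranes,
# bridging rods, an optional cytosolic coat slab, and Gaussian noise.

#' Ground truth for a synthetic contact-site volume
#'
#' Membranes are rendered as pairs of parallel Gaussian-profile leaflet
#' sheets (leaflet sigma 1 nm, leaflet-centre spacing 4 nm) perpendicular
#' to the volume z axis; higher voxel value means more mass. The PM sits
#' at low z with its cytosolic leaflet at `pm_z_nm`; the ER cytosolic
#' (PM-facing) leaflet is at `er_z_nm = pm_z_nm + gap`.
#'
#' @param voxel_nm Isotropic voxel size in nm (> 0). The default 0.37 nm
#'   corresponds to a 3.7 Angstrom pixel; binned variants (e.g. 0.74) are
#'   accepted.
#' @param pm_z_nm z of the PM cytosolic leaflet centre (nm).
#' @param er_z_nm z of the ER cytosolic leaflet centre (nm); the
#'   cytosolic-leaflet gap is `er_z_nm - pm_z_nm`.
#' @param rods data.frame with columns `x`, `y` (rod axis position at the
#'   gap midplane, nm), `tilt_deg` (0-90, from the PM normal),
#'   `azimuth_deg` (direction of the tilt in the x-y plane) and
#'   `length_nm`. Rods are cylinders of `rod_radius_nm` radius centred on
#'   the gap midplane. Records whose length exceeds the gap at their tilt
#'   (i.e. `length_nm * cos(tilt) > gap`) are rejected with a message.
#' @param coat_thickness_nm Thickness of a uniform cytosolic density slab
#'   on the PM cytosolic leaflet, or `NULL` for no coat.
#' @param coat_footprint Optional list `(xmin, xmax, ymin, ymax)` in nm
#'   restricting the coat laterally; default covers the whole volume.
#' @param noise_sd Additive Gaussian noise SD (in units of the membrane
#'   peak amplitude, which is 1).
#' @param leaflet_sigma_nm,leaflet_spacing_nm Membrane rendering model.
#' @param rod_radius_nm Rod cylinder radius (nm).
#' @param coat_amplitude Density of the coat slab relative to the membrane
#'   peak (default 0.5).
#' @param coat_offset_nm Gap between the PM cytosolic leaflet centre and
#'   the start of the coat slab (default 3 nm, just outside the leaflet
#'   density).
#' @return An object of class `volume_truth`.
#' @export
volume_truth <- function(voxel_nm = 0.37, pm_z_nm, er_z_nm, rods = NULL,
                         coat_thickness_nm = NULL, coat_footprint = NULL,
                         noise_sd = 0, leaflet_sigma_nm = 1,
                         leaflet_spacing_nm = 4, rod_radius_nm = 2.5,
                         coat_amplitude = 0.5, coat_offset_nm = 3) {
  if (voxel_nm <= 0) stop("voxel_nm must be > 0")
  if (er_z_nm <= pm_z_nm) stop("er_z_nm must exceed pm_z_nm")
  if (!is.null(rods)) {
    rods <- as.data.frame(rods)
    need <- c("x", "y", "tilt_deg", "azimuth_deg", "length_nm")
    if (!all(need %in% names(rods))) {
      stop("rods needs columns ", paste(need, collapse = ", "))
    }
    if (any(rods$tilt_deg < 0 | rods$tilt_deg > 90)) {
      stop("tilt_deg must lie in [0, 90]")
    }
  }
  structure(
    list(
      voxel_nm = voxel_nm, pm_z_nm = pm_z_nm, er_z_nm = er_z_nm,
      pm_leaflets_nm = c(pm_z_nm - leaflet_spacing_nm, pm_z_nm),
      er_leaflets_nm = c(er_z_nm, er_z_nm + leaflet_spacing_nm),
      rods = rods, coat_thickness_nm = coat_thickness_nm,
      coat_footprint = coat_footprint, noise_sd = noise_sd,
      leaflet_sigma_nm = leaflet_sigma_nm,
      leaflet_spacing_nm = leaflet_spacing_nm,
      rod_radius_nm = rod_radius_nm, coat_amplitude = coat_amplitude,
      coat_offset_nm = coat_offset_nm
    ),
    class = "volume_truth"
  )
}

#' Construct a density volume container
#'
#' @param voxels 3D numeric array, dimensions (nx, ny, nz); the voxel at
#'   index (i, j, k) is centred at `origin_nm + (c(i, j, k) - 0.5) *
#'   voxel_nm`. Higher value means more mass.
#' @param voxel_nm Isotropic voxel size (nm).
#' @param origin_nm 3-vector, position of the volume corner (nm).
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(voxels, voxel_nm, origin_nm = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3, voxel_nm > 0)
  structure(
    list(voxels = voxels, voxel_nm = voxel_nm, origin_nm = origin_nm),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<density_volume> %d x %d x %d voxels, %.3g nm/voxel\n",
    d[1], d[2], d[3], x$voxel_nm
  ))
  invisible(x)
}

#' Render a synthetic contact-site volume
#'
#' Renders the two membranes, the bridging rods and the optional coat slab
#' described by a [volume_truth()] into a density volume, then adds
#' Gaussian noise. Truth tables listing each accepted rod's endpoints and
#' the coat footprint are returned alongside.
#'
#' @param truth A [volume_truth()].
#' @param shape_voxels Integer 3-vector (nx, ny, nz).
#' @param seed RNG seed for the noise.
#' @return List with `volume` (a [density_volume()]) and `truth_tables`
#'   (list: `rods` data.frame with endpoint coordinates, `coat`, leaflet
#'   positions).
#' @export
gen_contact_volume <- function(truth, shape_voxels, seed = 1L) {
  stopifnot(inherits(truth, "volume_truth"))
  shape_voxels <- as.integer(shape_voxels)
  stopifnot(length(shape_voxels) == 3, all(shape_voxels > 0))
  vx <- truth$voxel_nm
  nx <- shape_voxels[1]; ny <- shape_voxels[2]; nz <- shape_voxels[3]
  zmax <- nz * vx
  need_z <- truth$er_leaflets_nm[2] + 10
  if (truth$pm_leaflets_nm[1] < 10 || need_z > zmax) {
    stop("volume too small: membranes need a 10 nm margin in z")
  }

  zc <- (seq_len(nz) - 0.5) * vx
  profile <- numeric(nz)
  for (lz in c(truth$pm_leaflets_nm, truth$er_leaflets_nm)) {
    profile <- profile + exp(-(zc - lz)^2 / (2 * truth$leaflet_sigma_nm^2))
  }
  vol <- array(rep(profile, each = nx * ny), dim = c(nx, ny, nz))

  # coat slab on the cytosolic side of the PM cytosolic leaflet
  coat_tab <- NULL
  if (!is.null(truth$coat_thickness_nm)) {
    z0 <- truth$pm_z_nm + truth$coat_offset_nm
    z1 <- z0 + truth$coat_thickness_nm
    fp <- truth$coat_footprint
    if (is.null(fp)) fp <- list(xmin = 0, xmax = nx * vx, ymin = 0, ymax = ny * vx)
    xc <- (seq_len(nx) - 0.5) * vx
    yc <- (seq_len(ny) - 0.5) * vx
    xi <- which(xc >= fp$xmin & xc <= fp$xmax)
    yi <- which(yc >= fp$ymin & yc <= fp$ymax)
    zi <- which(zc >= z0 & zc <= z1)
    vol[xi, yi, zi] <- vol[xi, yi, zi] + truth$coat_amplitude
    coat_tab <- data.frame(
      z_start_nm = z0, z_end_nm = z1,
      thickness_nm = truth$coat_thickness_nm,
      xmin = fp$xmin, xmax = fp$xmax, ymin = fp$ymin, ymax = fp$ymax
    )
  }

  # rods: cylinders centred on the gap midplane
  rod_tab <- NULL
  if (!is.null(truth$rods) && nrow(truth$rods) > 0) {
    gap <- truth$er_z_nm - truth$pm_z_nm
    zmid <- (truth$pm_z_nm + truth$er_z_nm) / 2
    rows <- list()
    for (r in seq_len(nrow(truth$rods))) {
      rec <- truth$rods[r, ]
      theta <- rec$tilt_deg * pi / 180
      phi <- rec$azimuth_deg * pi / 180
      if (rec$length_nm * cos(theta) > gap + 1e-9) {
        message(sprintf(
          "rod %d rejected: length %.1f nm at tilt %.1f deg exceeds the %.1f nm gap",
          r, rec$length_nm, rec$tilt_deg, gap
        ))
        next
      }
      dir <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      ctr <- c(rec$x, rec$y, zmid)
      if (any(ctr < 0) || any(ctr > c(nx, ny, nz) * vx)) {
        stop(sprintf("rod %d centre lies outside the volume", r))
      }
      a <- ctr - dir * rec$length_nm / 2
      b <- ctr + dir * rec$length_nm / 2
      vol <- render_cylinder(vol, vx, a, b, truth$rod_radius_nm, 1)
      rows[[length(rows) + 1]] <- data.frame(
        rod_id = r, x = rec$x, y = rec$y,
        tilt_deg = rec$tilt_deg, azimuth_deg = rec$azimuth_deg,
        length_nm = rec$length_nm,
        x0 = a[1], y0 = a[2], z0 = a[3], x1 = b[1], y1 = b[2], z1 = b[3]
      )
    }
    if (length(rows)) rod_tab <- do.call(rbind, rows)
  }

  if (truth$noise_sd > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(length(vol), sd = truth$noise_sd), dim = dim(vol))
  }

  list(
    volume = density_volume(vol, vx),
    truth_tables = list(
      rods = rod_tab, coat = coat_tab,
      pm_leaflets_nm = truth$pm_leaflets_nm,
      er_leaflets_nm = truth$er_leaflets_nm,
      pm_z_nm = truth$pm_z_nm, er_z_nm = truth$er_z_nm,
      voxel_nm = vx
    )
  )
}

#' Add a solid cylinder of density to a volume (in place semantics)
#' @noRd
render_cylinder <- function(vol, vx, a, b, radius, amplitude) {
  dims <- dim(vol)
  lo <- pmax(floor((pmin(a, b) - radius) / vx), 0) + 1
  hi <- pmin(ceiling((pmax(a, b) + radius) / vx), dims)
  if (any(lo > hi)) return(vol)
  xi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; zi <- lo[3]:hi[3]
  xc <- (xi - 0.5) * vx; yc <- (yi - 0.5) * vx; zc <- (zi - 0.5) * vx
  pts <- cbind(
    rep(xc, times = length(yc) * length(zc)),
    rep(rep(yc, each = length(xc)), times = length(zc)),
    rep(zc, each = length(xc) * length(yc))
  )
  d <- point_segment_distance(pts, a, b)
  inside <- d <= radius
  if (any(inside)) {
    sub <- vol[xi, yi, zi]
    sub[inside] <- sub[inside] + amplitude
    vol[xi, yi, zi] <- sub
  }
  vol
}

#' Generate 4-point particle picks from a volume's rod truth table
#'
#' For each rod in the truth tables produced by [gen_contact_volume()],
#' emulates manual picking of a bridging density: point A at the rod base
#' on the ER cytosolic leaflet, point B at the rod end on the PM cytosolic
#' leaflet, and auxiliary points C (on the ER membrane) and D (on the PM)
#' placed 10 nm away from the rod along each membrane in the rod's azimuth
#' direction. Isotropic Gaussian click jitter is added to every point.
#'
#' @param truth_tables The `truth_tables` element of [gen_contact_volume()].
#' @param click_jitter_nm Isotropic Gaussian click-error SD (nm).
#' @param seed RNG seed.
#' @param tomogram_id Identifier stored in each pick.
#' @return List of [particle_pick()] objects.
#' @export
gen_particle_picks <- function(truth_tables, click_jitter_nm = 0, seed = 1L,
                               tomogram_id = "synthetic") {
  rods <- truth_tables$rods
  if (is.null(rods) || nrow(rods) == 0) stop("truth tables contain no rods")
  set.seed(as.integer(seed))
  picks <- vector("list", nrow(rods))
  for (i in seq_len(nrow(rods))) {
    r <- rods[i, ]
    # endpoint with larger z touches the ER leaflet, smaller z the PM
    ends <- rbind(c(r$x0, r$y0, r$z0), c(r$x1, r$y1, r$z1))
    er_end <- ends[which.max(ends[, 3]), ]
    pm_end <- ends[which.min(ends[, 3]), ]
    phi <- r$azimuth_deg * pi / 180
    along <- c(cos(phi), sin(phi), 0)
    A <- er_end
    B <- pm_end
    C <- er_end + 10 * along   # stays on the (flat) ER leaflet plane
    D <- pm_end + 10 * along
    if (click_jitter_nm > 0) {
      jit <- matrix(stats::rnorm(12, sd = click_jitter_nm), 4, 3)
      A <- A + jit[1, ]; B <- B + jit[2, ]; C <- C + jit[3, ]; D <- D + jit[4, ]
    }
    picks[[i]] <- particle_pick(A, B, C, D,
      particle_id = sprintf("rod%03d", r$rod_id), tomogram_id = tomogram_id
    )
  }
  picks
}

#' Threshold a synthetic volume into a binary mask
#'
#' Convenience for building segmentation masks from synthetic volumes,
#' e.g. thresholding a rendered coat slab at half its amplitude.
#'
#' @param volume A [density_volume()].
#' @param threshold Density threshold; voxels strictly above it are 1.
#' @return A [voxel_mask()].
#' @export
threshold_mask <- function(volume, threshold) {
  stopifnot(inherits(volume, "density_volume"))
  voxel_mask(array(as.integer(volume$voxels > threshold), dim(volume$voxels)),
    voxel_nm = volume$voxel_nm
  )
}
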