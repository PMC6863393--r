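# Synthetic clicked membrane point clouds with known ground truth.

#' Ground truth for one synthetic contact site
#'
#' Describes the true geometry of a PM-ER contact used by
#' [gen_membrane_site()]: the true gap between the cytosolic leaflets, the
#' ER shape over the PM (flat, tubular or locally buckled toward the PM),
#' and the click-noise level applied along the membrane normal.
#'
#' @param separation_nm True PM-ER gap between cytosolic leaflets (nm, > 0).
#' @param geometry One of `"flat"`, `"tubular"`, `"buckled"`.
#' @param tubule_radius_nm Tube radius when `geometry = "tubular"`.
#' @param buckle_depth_nm,buckle_radius_nm Depth and lateral scale of the
#'   local ER approach when `geometry = "buckled"`; the minimum gap at the
#'   buckle apex is `separation_nm - buckle_depth_nm`.
#' @param jitter_sd_nm Gaussian click-noise SD normal to the membrane (>= 0).
#' @param seed RNG seed used by the generator.
#' @return An object of class `site_truth`.
#' @export
site_truth <- function(separation_nm, geometry = c("flat", "tubular", "buckled"),
                       tubule_radius_nm = NULL, buckle_depth_nm = NULL,
                       buckle_radius_nm = NULL, jitter_sd_nm = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (separation_nm <= 0) stop("separation_nm must be > 0")
  if (jitter_sd_nm < 0) stop("jitter_sd_nm must be >= 0")
  if (geometry == "tubular" && is.null(tubule_radius_nm)) {
    stop("tubular geometry needs tubule_radius_nm")
  }
  if (geometry == "buckled") {
    if (is.null(buckle_depth_nm) || is.null(buckle_radius_nm)) {
      stop("buckled geometry needs buckle_depth_nm and buckle_radius_nm")
    }
    if (buckle_depth_nm >= separation_nm) {
      stop("buckle_depth_nm must be smaller than separation_nm")
    }
  }
  structure(
    list(
      separation_nm = separation_nm, geometry = geometry,
      tubule_radius_nm = tubule_radius_nm,
      buckle_depth_nm = buckle_depth_nm, buckle_radius_nm = buckle_radius_nm,
      jitter_sd_nm = jitter_sd_nm, seed = as.integer(seed)
    ),
    class = "site_truth"
  )
}

#' Generate clicked PM and ER point clouds for one contact site
#'
#' Emulates manual membrane tracing in tomogram slices: PM points are laid
#' on the (flat, z = 0) PM surface on a rectangular raster with ~10 nm
#' spacing along x and 5.5 nm slice spacing along y; ER points sit on a
#' surface offset from the PM by the true separation along the membrane
#' normal, modified by the site geometry (tube cross-section or Gaussian
#' buckle toward the PM). Independent Gaussian click jitter of
#' `jitter_sd_nm` is added along the normal to every point of both clouds.
#'
#' @param truth A [site_truth()].
#' @param extent_nm Lateral extent of the traced patch (square, >= 50 nm).
#' @param site_id Site identifier carried by both clouds.
#' @param xy_spacing_nm In-plane click spacing (default 10 nm).
#' @param z_spacing_nm Slice spacing (default 5.5 nm).
#' @return List with `pm` and `er` [membrane_cloud()] objects.
#' @export
gen_membrane_site <- function(truth, extent_nm, site_id = "site1",
                              xy_spacing_nm = 10, z_spacing_nm = 5.5) {
  stopifnot(inherits(truth, "site_truth"))
  if (extent_nm < 50) stop("extent_nm must be >= 50")
  half <- extent_nm / 2
  gx <- seq(-half, half, by = xy_spacing_nm)
  gy <- seq(-half, half, by = z_spacing_nm)
  if (length(gx) * length(gy) < 4) {
    stop("extent too small to yield >= 4 points per membrane")
  }
  x <- rep(gx, times = length(gy))
  y <- rep(gy, each = length(gx))

  er_z <- er_surface_height(truth, x, y)
  keep <- is.finite(er_z)
  if (sum(keep) < 1) stop("geometry leaves no ER points within the extent")

  set.seed(truth$seed)
  pm_z <- rep(0, length(x))
  if (truth$jitter_sd_nm > 0) {
    pm_z <- pm_z + stats::rnorm(length(x), sd = truth$jitter_sd_nm)
    er_z <- er_z + stats::rnorm(length(x), sd = truth$jitter_sd_nm)
  }
  list(
    pm = membrane_cloud(cbind(x, y, pm_z), "PM", site_id),
    er = membrane_cloud(cbind(x[keep], y[keep], er_z[keep]), "ER", site_id)
  )
}

#' True ER surface height above the PM plane (jitter-free)
#' @noRd
er_surface_height <- function(truth, x, y) {
  d <- truth$separation_nm
  switch(truth$geometry,
    flat = rep(d, length(x)),
    tubular = {
      # lower surface of a tube running along y, closest approach = d at x = 0
      r <- truth$tubule_radius_nm
      inside <- abs(x) <= 0.9 * r
      z <- rep(NA_real_, length(x))
      z[inside] <- d + r - sqrt(r^2 - x[inside]^2)
      z
    },
    buckled = {
      # Gaussian dimple toward the PM centred on the patch
      depth <- truth$buckle_depth_nm
      w <- truth$buckle_radius_nm
      d - depth * exp(-(x^2 + y^2) / (2 * w^2))
    }
  )
}
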