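# Bridging-particle tilt geometry from 4-point picks.

#' Construct a 4-point particle pick
#'
#' The manual annotation of one bridging density: point A at its base on
#' the ER membrane, point B at its end on the PM, and two auxiliary points
#' roughly 10 nm away from the density, C along the ER membrane and D
#' along the PM. All coordinates in nm.
#'
#' @param A,B,C,D Length-3 numeric vectors (nm).
#' @param particle_id,tomogram_id Identifiers.
#' @return An object of class `particle_pick`.
#' @export
particle_pick <- function(A, B, C, D, particle_id = "p1",
                          tomogram_id = "tomo1") {
  for (p in list(A, B, C, D)) {
    if (length(p) != 3 || !all(is.finite(p))) {
      stop("pick points must be finite length-3 vectors")
    }
  }
  if (sqrt(sum((B - A)^2)) <= 2) {
    stop(sprintf("pick '%s': |B - A| must exceed 2 nm", particle_id))
  }
  if (all(C == A)) stop("C must differ from A")
  if (all(D == B)) stop("D must differ from B")
  structure(
    list(
      A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
      D = as.numeric(D), particle_id = particle_id, tomogram_id = tomogram_id
    ),
    class = "particle_pick"
  )
}

#' Particle axis angle relative to the PM
#'
#' Fits the best (total-least-squares) plane through the four pick points,
#' projects them onto it, and measures the particle axis u = B - A against
#' the PM tangent t = D - B. The deviation from perpendicular to the PM is
#' alpha = |90 deg - angle(u, t)|, clipped to [0, 90]. The in-plane
#' rotation is the signed angle between u and the in-plane direction
#' perpendicular to the PM tangent (the "vertical" of the extraction
#' frame); rotating the frame by its negative makes the axis vertical.
#' The ER auxiliary point C enters the plane fit only.
#'
#' @param pick A [particle_pick()].
#' @return A list of class `particle_orientation`: `tilt_deviation_deg`,
#'   `inplane_rotation_deg`, `axis_length_nm`, `particle_id`.
#' @export
particle_axis_angle <- function(pick) {
  stopifnot(inherits(pick, "particle_pick"))
  pts <- rbind(pick$A, pick$B, pick$C, pick$D)
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  eg <- eigen(crossprod(q), symmetric = TRUE)
  nrm <- eg$vectors[, 3]
  proj <- q - (q %*% nrm) %*% t(nrm)  # projection onto the best plane
  u <- proj[2, ] - proj[1, ]          # B - A
  t_pm <- proj[4, ] - proj[2, ]       # D - B
  if (sqrt(sum(u^2)) < 1e-9) stop("zero-length particle axis")
  if (sqrt(sum(t_pm^2)) < 1e-9) stop("zero-length PM tangent")
  ang <- angle_between_deg(u, t_pm)
  alpha <- min(max(abs(90 - ang), 0), 90)
  # signed in-plane rotation: angle from the in-plane "vertical" to u
  t_hat <- unitize(t_pm)
  v_hat <- unitize(u - sum(u * t_hat) * t_hat)  # vertical: perp to tangent, toward u
  sin_comp <- sum(u * t_hat)
  cos_comp <- sum(u * v_hat)
  inplane <- atan2(sin_comp, cos_comp) * 180 / pi
  structure(
    list(
      tilt_deviation_deg = alpha,
      inplane_rotation_deg = inplane,
      axis_length_nm = sqrt(sum((pick$B - pick$A)^2)),
      particle_id = pick$particle_id
    ),
    class = "particle_orientation"
  )
}

#' Summarize particle orientations
#'
#' Mean and SD (n - 1 denominator; 0 for a single particle) of the tilt
#' deviations, plus a histogram over [0, 90] degrees with half-open bins
#' [k w, (k+1) w) (the top edge closed).
#'
#' @param orients List of [particle_axis_angle()] results, or a numeric
#'   vector of deviations in degrees.
#' @param bin_width_deg Histogram bin width (default 5).
#' @return A list of class `orientation_summary`: `n`, `mean_deg`,
#'   `sd_deg`, `breaks_deg`, `counts`.
#' @export
orientation_summary <- function(orients, bin_width_deg = 5) {
  a <- if (is.numeric(orients)) {
    orients
  } else {
    vapply(orients, function(o) o$tilt_deviation_deg, numeric(1))
  }
  if (length(a) < 1) stop("need at least one orientation")
  if (any(a < 0 | a > 90)) stop("deviations must lie in [0, 90] degrees")
  breaks <- seq(0, 90, by = bin_width_deg)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  bin <- findInterval(a, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  structure(
    list(
      n = length(a),
      mean_deg = mean(a),
      sd_deg = if (length(a) > 1) stats::sd(a) else 0,
      breaks_deg = breaks,
      counts = counts
    ),
    class = "orientation_summary"
  )
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf(
    "<orientation_summary> n = %d, mean %.1f deg, SD %.1f deg\n",
    x$n, x$mean_deg, x$sd_deg
  ))
  invisible(x)
}

#' Tabulate particle orientations
#'
#' @param orients List of [particle_axis_angle()] results.
#' @return data.frame with one row per particle.
#' @export
orientation_table <- function(orients) {
  do.call(rbind, lapply(orients, function(o) {
    data.frame(
      particle_id = o$particle_id,
      tilt_deviation_deg = o$tilt_deviation_deg,
      inplane_rotation_deg = o$inplane_rotation_deg,
      axis_length_nm = o$axis_length_nm,
      stringsAsFactors = FALSE
    )
  }))
}
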