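# Measurements on class averages: coat-layer thickness (FWHM) and rod
# length (cytosolic-leaflet to cytosolic-leaflet peak distance).

#' Coat-layer thickness from a class average
#'
#' Averages the class image along the membrane direction to obtain a 1D
#' density profile perpendicular to the membrane, locates the PM bilayer
#' (the two strongest leaflet peaks), and measures the extra density
#' layer on the cytosolic side of the cytosolic leaflet as the full width
#' at half maximum above the local background. The background level and
#' noise SD are estimated from the far cytosolic end of the profile. If
#' no profile point beyond the leaflet exceeds background + 3 noise SD,
#' the layer is reported absent.
#'
#' @param class_average Matrix; the image x axis (rows) is the membrane
#'   normal with the cytosol toward increasing x.
#' @param pixel_nm Pixel size (nm).
#' @param membrane_axis Image axis along the membrane normal: `"x"`
#'   (rows, default) or `"y"` (columns).
#' @return A list of class `profile_measurement` with `positions_nm`,
#'   `profile`, `peaks_nm` (detected leaflet peaks), `thickness_nm`
#'   (`NA` with `status = "no layer"` when absent) and `status`.
#' @export
layer_thickness <- function(class_average, pixel_nm,
                            membrane_axis = c("x", "y")) {
  membrane_axis <- match.arg(membrane_axis)
  img <- as.matrix(class_average)
  if (membrane_axis == "y") img <- t(img)
  prof <- rowMeans(img)
  pos <- (seq_along(prof) - 0.5) * pixel_nm

  pk <- find_peaks(prof)
  if (length(pk) < 2) stop("no resolved bilayer in the profile")
  # the bilayer: the two strongest peaks
  top2 <- sort(pk[order(prof[pk], decreasing = TRUE)][1:2])
  cyt_leaflet <- top2[2]  # cytosol toward increasing x

  # background and noise from the far cytosolic end
  tail_idx <- seq(from = max(cyt_leaflet + 1, floor(0.8 * length(prof))),
                  to = length(prof))
  bg <- stats::median(prof[tail_idx])
  noise <- stats::mad(prof[tail_idx])
  if (!is.finite(noise) || noise == 0) noise <- stats::sd(prof[tail_idx])

  # candidate layer: beyond the first dip after the cytosolic leaflet
  dip <- cyt_leaflet
  while (dip < length(prof) - 1 && prof[dip + 1] < prof[dip]) dip <- dip + 1
  region <- (dip + 1):max(tail_idx[1] - 1, dip + 1)
  above <- region[prof[region] > bg + 3 * noise]
  if (length(above) == 0) {
    return(structure(
      list(
        positions_nm = pos, profile = prof,
        peaks_nm = pos[top2], thickness_nm = NA_real_, status = "no layer"
      ),
      class = "profile_measurement"
    ))
  }
  apex <- above[which.max(prof[above])]
  half <- bg + (prof[apex] - bg) / 2
  lr <- half_crossings(prof, apex, half)
  structure(
    list(
      positions_nm = pos, profile = prof, peaks_nm = pos[top2],
      thickness_nm = (lr[2] - lr[1]) * pixel_nm,
      status = "ok"
    ),
    class = "profile_measurement"
  )
}

#' Rod length from a class average
#'
#' Takes a 1D profile along the particle's major axis (the image x axis
#' after prior-constrained alignment), averaged over `profile_width_px`
#' pixels centred on the rod, and measures the distance between the
#' cytosolic-leaflet peak of the PM and that of the ER. Leaflet peaks are
#' the local maxima flanking the widest inter-peak span (the
#' intermembrane gap); their positions are refined to sub-pixel precision
#' by parabolic interpolation.
#'
#' @param class_average Matrix; rows along the particle major axis.
#' @param pixel_nm Pixel size (nm).
#' @param profile_width_px Averaging width across the axis (default 15).
#' @return A `profile_measurement` list with `length_nm`, the profile and
#'   the two peak positions.
#' @export
rod_length <- function(class_average, pixel_nm, profile_width_px = 15) {
  img <- as.matrix(class_average)
  nc <- ncol(img)
  ctr <- (nc + 1) / 2
  half <- (profile_width_px - 1) / 2
  cols <- max(1, floor(ctr - half)):min(nc, ceiling(ctr + half))
  prof <- rowMeans(img[, cols, drop = FALSE])
  pos <- (seq_along(prof) - 0.5) * pixel_nm

  pk <- find_peaks(prof)
  # keep substantial peaks only (leaflets dominate the profile)
  pk <- pk[prof[pk] >= min(prof) + 0.25 * (max(prof) - min(prof))]
  if (length(pk) < 2) stop("fewer than 2 detectable leaflet peaks")
  # the intermembrane span: the widest gap between consecutive peaks
  gaps <- diff(pk)
  g <- which.max(gaps)
  p_lo <- refine_peak(prof, pk[g])
  p_hi <- refine_peak(prof, pk[g + 1])
  structure(
    list(
      positions_nm = pos, profile = prof,
      peaks_nm = c((p_lo - 0.5) * pixel_nm, (p_hi - 0.5) * pixel_nm),
      length_nm = (p_hi - p_lo) * pixel_nm,
      status = "ok"
    ),
    class = "profile_measurement"
  )
}

#' @export
print.profile_measurement <- function(x, ...) {
  val <- if (!is.null(x$length_nm)) {
    sprintf("length %.2f nm", x$length_nm)
  } else if (is.na(x$thickness_nm)) {
    "no layer"
  } else {
    sprintf("thickness %.2f nm", x$thickness_nm)
  }
  cat(sprintf("<profile_measurement> %s (%s)\n", val, x$status))
  invisible(x)
}

#' Indices of interior local maxima
#' @noRd
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Sub-pixel peak position by parabolic interpolation
#' @noRd
refine_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < .Machine$double.eps) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

#' Linear-interpolated half-maximum crossings around an apex
#' @noRd
half_crossings <- function(y, apex, level) {
  left <- apex
  while (left > 1 && y[left - 1] > level) left <- left - 1
  xl <- if (left == 1) 1 else {
    left - (y[left] - level) / (y[left] - y[left - 1])
  }
  right <- apex
  n <- length(y)
  while (right < n && y[right + 1] > level) right <- right + 1
  xr <- if (right == n) n else {
    right + (y[right] - level) / (y[right] - y[right + 1])
  }
  c(xl, xr)
}
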