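# Membrane path splines: chord-length-parameterized smoothing splines
# through clicked points, with arc-length evaluation and unit tangents.

#' Fit a path spline through ordered clicked points
#'
#' Fits one cubic smoothing spline per coordinate against the cumulative
#' chord length of the points (click order preserved). The smoothing
#' penalty is relaxed until the maximum residual at the control points is
#' at most `max_residual_nm` (interpolation is the fallback), then the
#' curve is reparameterized by arc length on a fine sampling.
#'
#' @param points n x 3 matrix of clicked positions (nm), in click order;
#'   typically traced in slices spaced by `z_spacing_nm`.
#' @param z_spacing_nm Nominal slice spacing of the clicks (metadata).
#' @param max_residual_nm Largest allowed residual at control points.
#' @return An object of class `path_spline` with `length_nm` and the
#'   evaluators used by [spline_point()] and [spline_tangent()].
#' @export
fit_path_spline <- function(points, z_spacing_nm = 8, max_residual_nm = 1) {
  pts <- as.matrix(points)
  if (ncol(pts) == 2) pts <- cbind(pts, 0)
  if (nrow(pts) < 3) stop("a path needs >= 3 points")
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg < .Machine$double.eps)) stop("consecutive duplicate path points")
  u <- c(0, cumsum(seg))

  fits <- lapply(1:3, function(k) smooth_coord(u, pts[, k], max_residual_nm))
  resid <- sqrt(
    (fits[[1]](u) - pts[, 1])^2 + (fits[[2]](u) - pts[, 2])^2 +
      (fits[[3]](u) - pts[, 3])^2
  )

  # arc-length reparameterization on a fine sampling
  uf <- seq(0, u[length(u)], length.out = max(200L, 20L * nrow(pts)))
  pf <- cbind(fits[[1]](uf), fits[[2]](uf), fits[[3]](uf))
  s <- c(0, cumsum(sqrt(rowSums(diff(pf)^2))))
  # warn on (approximately) self-intersecting paths
  if (nrow(pts) > 3) {
    dmin <- min(stats::dist(pts[seq(1, nrow(pts), by = 2), , drop = FALSE]))
    if (dmin < 1e-6) warning("path may self-intersect")
  }
  structure(
    list(
      control_points = pts, u = u, fits = fits,
      s_grid = s, u_grid = uf, length_nm = s[length(s)],
      z_spacing_nm = z_spacing_nm, max_residual_nm = max(resid)
    ),
    class = "path_spline"
  )
}

#' @noRd
smooth_coord <- function(u, y, max_residual_nm) {
  n <- length(u)
  if (n >= 8) {
    for (df in c(max(4, round(n / 3)), round(n * 0.6), round(n * 0.85), n)) {
      fit <- try(
        stats::smooth.spline(u, y, df = min(df, n), cv = FALSE),
        silent = TRUE
      )
      if (!inherits(fit, "try-error")) {
        res <- max(abs(stats::predict(fit, u)$y - y))
        if (res <= max_residual_nm) {
          return(function(t) stats::predict(fit, t)$y)
        }
      }
    }
  }
  f <- stats::splinefun(u, y, method = "natural")
  function(t) f(t)
}

#' Evaluate a path spline at arc-length positions
#'
#' @param spline A [fit_path_spline()] result.
#' @param s_nm Arc-length positions (nm) in `[0, spline$length_nm]`.
#' @return m x 3 matrix of positions.
#' @export
spline_point <- function(spline, s_nm) {
  stopifnot(inherits(spline, "path_spline"))
  u <- stats::approx(spline$s_grid, spline$u_grid, xout = s_nm, rule = 2)$y
  cbind(spline$fits[[1]](u), spline$fits[[2]](u), spline$fits[[3]](u))
}

#' Unit tangents of a path spline at arc-length positions
#'
#' Central finite differences on the arc-length parameterization.
#'
#' @inheritParams spline_point
#' @return m x 3 matrix of unit tangent vectors.
#' @export
spline_tangent <- function(spline, s_nm) {
  h <- max(spline$length_nm * 1e-4, 1e-3)
  p1 <- spline_point(spline, pmin(pmax(s_nm - h, 0), spline$length_nm))
  p2 <- spline_point(spline, pmin(pmax(s_nm + h, 0), spline$length_nm))
  tg <- p2 - p1
  tg / sqrt(rowSums(tg^2))
}
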