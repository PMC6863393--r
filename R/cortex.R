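# Cortical fluorescence line profiles: linearize 2-channel intensity
# along a closed cell-cortex contour and compare channels.

#' Construct a cortex contour
#'
#' An ordered closed polygon along the cell cortex in pixel coordinates
#' (sub-pixel allowed), with an explicit start point (the figure-arrow
#' position). The polygon is stored open (first vertex not repeated).
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates; a repeated
#'   closing vertex is removed.
#' @param start_index Index of the traversal start vertex.
#' @return An object of class `cortex_contour`.
#' @export
cortex_contour <- function(vertices, start_index = 1L) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2) stop("vertices must have 2 columns")
  if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-9)) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 8) stop("contour needs >= 8 vertices")
  structure(
    list(vertices = unname(v), start_index = as.integer(start_index)),
    class = "cortex_contour"
  )
}

#' Linearized intensity profile along the cell cortex
#'
#' Traverses the contour clockwise (in image coordinates, y increasing
#' downward) from its start point in arc-length steps of `step_px`. At
#' each step, each channel is sampled as the maximum bilinear-interpolated
#' intensity over a band of `+/- band_halfwidth_px` along the local inward
#' normal, capturing thin cortical signals lying slightly inside the
#' contour.
#'
#' @param image_2ch 3D array (height y, width x, 2 channels) or list of
#'   two matrices indexed `[y, x]`.
#' @param contour A [cortex_contour()] inside the image (the sampling
#'   band must not touch the border).
#' @param band_halfwidth_px Half-width of the normal band (default 2).
#' @param step_px Arc-length step (default 1).
#' @return A list of class `linear_profile`: `position_px` (strictly
#'   increasing arc length) and `intensity` (matrix, steps x channels).
#' @export
linearize_profile <- function(image_2ch, contour, band_halfwidth_px = 2,
                              step_px = 1) {
  stopifnot(inherits(contour, "cortex_contour"))
  chans <- if (is.list(image_2ch)) image_2ch else {
    lapply(seq_len(dim(image_2ch)[3]), function(k) image_2ch[, , k])
  }
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])

  v <- contour$vertices
  # rotate so traversal starts at the start point
  v <- rbind(v[contour$start_index:nrow(v), , drop = FALSE],
             v[seq_len(contour$start_index - 1L), , drop = FALSE])
  # clockwise in image coordinates (y down): shoelace area must be positive
  area <- sum(v[, 1] * c(v[-1, 2], v[1, 2]) - c(v[-1, 1], v[1, 1]) * v[, 2]) / 2
  if (area < 0) v <- rbind(v[1, , drop = FALSE], v[nrow(v):2, , drop = FALSE])

  closed <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  perim <- s[length(s)]
  steps <- seq(0, perim - step_px / 2, by = step_px)
  px <- stats::approx(s, closed[, 1], xout = steps)$y
  py <- stats::approx(s, closed[, 2], xout = steps)$y

  # local tangent (central difference with wraparound), inward normal
  np <- length(steps)
  nxt <- c(2:np, 1); prv <- c(np, 1:(np - 1))
  tx <- px[nxt] - px[prv]; ty <- py[nxt] - py[prv]
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  # for clockwise traversal (y down) the interior lies to the left in
  # (x, y-down) coordinates: inward normal = (-ty, tx) rotated sign
  ctr <- colMeans(v)
  nx <- -ty; ny <- tx
  flip <- (nx * (ctr[1] - px) + ny * (ctr[2] - py)) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]

  offs <- seq(-band_halfwidth_px, band_halfwidth_px, by = 0.5)
  sx <- sweep(outer(nx, offs), 1, px, "+")
  sy <- sweep(outer(ny, offs), 1, py, "+")
  if (any(sx < 1 | sx > w | sy < 1 | sy > h)) {
    stop("contour (plus sampling band) touches the image border")
  }
  intensity <- sapply(chans, function(ch) {
    vals <- matrix(bilinear_sample(ch, sy, sx), nrow = np)
    apply(vals, 1, max)
  })
  structure(
    list(position_px = steps, intensity = intensity),
    class = "linear_profile"
  )
}

#' Bilinear sampling of a matrix img[y, x] at fractional (y, x)
#' @noRd
bilinear_sample <- function(img, yy, xx) {
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  y0 <- pmin(pmax(y0, 1), nrow(img) - 1)
  x0 <- pmin(pmax(x0, 1), ncol(img) - 1)
  img[cbind(c(y0), c(x0))] * (1 - c(fy)) * (1 - c(fx)) +
    img[cbind(c(y0 + 1), c(x0))] * c(fy) * (1 - c(fx)) +
    img[cbind(c(y0), c(x0 + 1))] * (1 - c(fy)) * c(fx) +
    img[cbind(c(y0 + 1), c(x0 + 1))] * c(fy) * c(fx)
}

#' Pearson correlation between the two channel profiles
#'
#' @param profile A [linearize_profile()] result with two channels.
#' @return Scalar correlation; `NA` (with a warning) when a channel has
#'   zero variance.
#' @export
profile_correlation <- function(profile) {
  stopifnot(inherits(profile, "linear_profile"))
  if (ncol(profile$intensity) < 2) stop("two channels required")
  a <- profile$intensity[, 1]; b <- profile$intensity[, 2]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance channel: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Generate a synthetic 2-channel cortical ring image
#'
#' A ring of Gaussian radial cross-section (sigma `ring_sigma_px`) at the
#' given centre and radius; each channel's intensity along the ring
#' follows its angular domain specification (amplitude 1 inside a domain,
#' 0 outside, on top of `baseline`), plus Gaussian noise. The generating
#' circle polygon is returned as the contour.
#'
#' @param domains List of two; each element is a matrix with columns
#'   (start_deg, end_deg) of bright angular intervals for that channel
#'   (angles clockwise from the start point), or NULL for an empty
#'   domain.
#' @param size Image size in pixels (square).
#' @param center,radius_px Ring geometry (defaults: image centre, 40% of
#'   size).
#' @param ring_sigma_px Radial Gaussian sigma (default 2).
#' @param baseline Background intensity inside the domain model.
#' @param noise_sd Additive Gaussian noise SD.
#' @param n_vertices Vertices of the returned contour polygon.
#' @param seed RNG seed.
#' @return List with `image` (size x size x 2 array, indexed `[y, x,
#'   channel]`) and `contour` (a [cortex_contour()]).
#' @export
gen_cortex_image <- function(domains, size = 128, center = NULL,
                             radius_px = NULL, ring_sigma_px = 2,
                             baseline = 0.1, noise_sd = 0,
                             n_vertices = 180, seed = 1L) {
  if (length(domains) != 2) stop("domains must list two channels")
  if (is.null(center)) center <- c(size, size) / 2 + 0.5
  if (is.null(radius_px)) radius_px <- 0.4 * size
  set.seed(as.integer(seed))
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  dx <- xx - center[1]; dy <- yy - center[2]
  r <- sqrt(dx^2 + dy^2)
  # clockwise angle from the start point (start at angle 0 = +x axis)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  ring <- exp(-(r - radius_px)^2 / (2 * ring_sigma_px^2))
  img <- array(0, dim = c(size, size, 2))
  for (ch in 1:2) {
    amp <- matrix(baseline, size, size)
    dom <- domains[[ch]]
    if (!is.null(dom)) {
      dom <- matrix(dom, ncol = 2)
      for (d in seq_len(nrow(dom))) {
        inside <- if (dom[d, 1] <= dom[d, 2]) {
          theta >= dom[d, 1] & theta <= dom[d, 2]
        } else {
          theta >= dom[d, 1] | theta <= dom[d, 2]
        }
        amp[inside] <- amp[inside] + 1
      }
    }
    plane <- amp * ring
    if (noise_sd > 0) plane <- plane + stats::rnorm(size^2, sd = noise_sd)
    img[, , ch] <- plane
  }
  ang <- (seq_len(n_vertices) - 1) / n_vertices * 2 * pi
  contour <- cortex_contour(
    cbind(center[1] + radius_px * cos(ang), center[2] + radius_px * sin(ang)),
    start_index = 1L
  )
  list(image = img, contour = contour)
}
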