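# Internal 2D/3D image operations: trilinear sampling, rotation, shifting,
# Gaussian low-pass filtering.

#' Trilinear interpolation of a density volume at arbitrary positions
#'
#' @param volume A [density_volume()].
#' @param pts m x 3 matrix of positions in nm (volume coordinate frame).
#' @param fill Value returned outside the volume (default 0).
#' @return Numeric vector of m sampled densities.
#' @export
sample_volume <- function(volume, pts, fill = 0) {
  stopifnot(inherits(volume, "density_volume"))
  v <- volume$voxels
  dims <- dim(v)
  # continuous voxel index: centre of voxel i is at (i - 0.5) * voxel
  g <- sweep(pts, 2, volume$origin_nm) / volume$voxel_nm + 0.5
  # absorb numerical jitter at the first/last voxel centres
  eps <- 1e-6
  for (a in 1:3) {
    ga <- g[, a]
    ga[ga >= 1 - eps & ga < 1] <- 1
    ga[ga > dims[a] & ga <= dims[a] + eps] <- dims[a]
    g[, a] <- ga
  }
  i0 <- floor(g[, 1]); j0 <- floor(g[, 2]); k0 <- floor(g[, 3])
  i0 <- pmin(i0, dims[1] - 1L); j0 <- pmin(j0, dims[2] - 1L)
  k0 <- pmin(k0, dims[3] - 1L)
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 &
    i0 < dims[1] & j0 < dims[2] & k0 < dims[3]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  at <- function(di, dj, dk) {
    v[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  val <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[ok] <- val
  out
}

#' Rotate a 2D image about its centre
#'
#' Inverse-mapping rotation with bilinear interpolation; pixels mapped
#' from outside the source take `fill` (default: the image mean).
#' @noRd
rotate_image <- function(img, degrees, fill = mean(img)) {
  if (abs(degrees) < 1e-12) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  th <- -degrees * pi / 180  # inverse mapping
  ct <- cos(th); st <- sin(th)
  xi <- rep(seq_len(nr), times = nc) - cx
  yi <- rep(seq_len(nc), each = nr) - cy
  xs <- ct * xi - st * yi + cx
  ys <- st * xi + ct * yi + cy
  i0 <- floor(xs); j0 <- floor(ys)
  fx <- xs - i0; fy <- ys - j0
  ok <- i0 >= 1 & j0 >= 1 & i0 < nr & j0 < nc
  out <- rep(fill, nr * nc)
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    out[ok] <-
      img[cbind(i0k, j0k)] * (1 - fxk) * (1 - fyk) +
      img[cbind(i0k + 1, j0k)] * fxk * (1 - fyk) +
      img[cbind(i0k, j0k + 1)] * (1 - fxk) * fyk +
      img[cbind(i0k + 1, j0k + 1)] * fxk * fyk
  }
  matrix(out, nr, nc)
}

#' Shift a 2D image by integer pixels (zero-order, fill at edges)
#' @noRd
shift_image <- function(img, dx, dy, fill = mean(img)) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  xs <- seq_len(nr) - dx
  ys <- seq_len(nc) - dy
  okx <- xs >= 1 & xs <= nr
  oky <- ys >= 1 & ys <= nc
  out[okx, oky] <- img[xs[okx], ys[oky]]
  out
}

#' Separable Gaussian low-pass filter
#'
#' Sigma is derived from a resolution cutoff expressed as a full width at
#' half maximum in nm: sigma_px = lowpass_nm / (2.355 * pixel_nm).
#' @noRd
gaussian_lowpass <- function(img, lowpass_nm, pixel_nm) {
  if (is.null(lowpass_nm) || lowpass_nm <= 0) return(img)
  sigma <- lowpass_nm / (2 * sqrt(2 * log(2)) * pixel_nm)
  if (sigma < 0.3) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_reflect(t(conv_reflect(t(conv_reflect(img, k)), k)), NULL)
}

#' 1D convolution along rows with reflected edges; k NULL = identity
#' @noRd
conv_reflect <- function(img, k) {
  if (is.null(k)) return(img)
  half <- (length(k) - 1L) / 2L
  nr <- nrow(img)
  idx <- c(rev(seq_len(half)), seq_len(nr), nr - seq_len(half) + 1L)
  padded <- img[idx, , drop = FALSE]
  out <- img
  for (r in seq_len(nr)) {
    rows <- r:(r + 2L * half)
    out[r, ] <- colSums(padded[rows, , drop = FALSE] * k)
  }
  out
}
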