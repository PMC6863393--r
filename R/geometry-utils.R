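# Internal geometry helpers shared across modules.

#' Unit-normalize a vector
#' @noRd
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix mapping unit vector `from` onto unit vector `to`
#'
#' Rodrigues formula; returns a proper rotation (det = +1). Handles the
#' antiparallel case by rotating 180 degrees about any perpendicular axis.
#' @noRd
rotation_between <- function(from, to) {
  from <- unitize(from)
  to <- unitize(to)
  v <- c(
    from[2] * to[3] - from[3] * to[2],
    from[3] * to[1] - from[1] * to[3],
    from[1] * to[2] - from[2] * to[1]
  )
  c_ <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: pick a perpendicular axis
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitize(ax - sum(ax * from) * from)
    K <- skew3(ax)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew3(v / s)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' @noRd
skew3 <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

#' Distances from points to a 3D segment
#'
#' `p` is an n x 3 matrix; `a`, `b` are segment endpoints.
#' @noRd
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < .Machine$double.eps) {
    return(sqrt(rowSums(sweep(p, 2, a)^2)))
  }
  t <- (sweep(p, 2, a) %*% ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((p - proj)^2))
}

#' Distance from one point to a set of triangles
#'
#' `p` length-3; `v1`, `v2`, `v3` are m x 3 matrices of triangle vertices.
#' For each triangle the closest point is either the orthogonal projection
#' (when its barycentric coordinates are all nonnegative) or the closest
#' point on one of the three edges. Returns the m distances.
#' @noRd
point_triangles_distance <- function(p, v1, v2, v3) {
  e1 <- v2 - v1
  e2 <- v3 - v1
  w <- -sweep(v1, 2, p)  # p - v1, rowwise
  d11 <- rowSums(e1 * e1)
  d12 <- rowSums(e1 * e2)
  d22 <- rowSums(e2 * e2)
  dw1 <- rowSums(w * e1)
  dw2 <- rowSums(w * e2)
  det <- d11 * d22 - d12 * d12
  det[det < .Machine$double.eps] <- .Machine$double.eps
  s <- (d22 * dw1 - d12 * dw2) / det
  t <- (d11 * dw2 - d12 * dw1) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  out <- numeric(nrow(v1))
  if (any(inside)) {
    foot <- v1[inside, , drop = FALSE] +
      s[inside] * e1[inside, , drop = FALSE] +
      t[inside] * e2[inside, , drop = FALSE]
    out[inside] <- sqrt(colSums((t(foot) - p)^2))
  }
  if (any(!inside)) {
    idx <- which(!inside)
    pm <- matrix(p, nrow = length(idx), ncol = 3, byrow = TRUE)
    d_a <- seg_dist_rows(pm, v1[idx, , drop = FALSE], v2[idx, , drop = FALSE])
    d_b <- seg_dist_rows(pm, v2[idx, , drop = FALSE], v3[idx, , drop = FALSE])
    d_c <- seg_dist_rows(pm, v3[idx, , drop = FALSE], v1[idx, , drop = FALSE])
    out[idx] <- pmin(d_a, d_b, d_c)
  }
  out
}

#' Rowwise point-to-segment distances (p[i] vs segment a[i]-b[i])
#' @noRd
seg_dist_rows <- function(p, a, b) {
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 < .Machine$double.eps] <- .Machine$double.eps
  t <- rowSums((p - a) * ab) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  sqrt(rowSums((p - proj)^2))
}

#' Angle between two vectors in degrees, in [0, 180]
#' @noRd
angle_between_deg <- function(u, v) {
  cu <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  cu <- pmin(pmax(cu, -1), 1)
  acos(cu) * 180 / pi
}
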