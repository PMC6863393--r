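# Subvolume extraction along membrane paths or at particle picks, and
# collapse to 2D projections.

#' Construct a box stack
#'
#' A set of equally shaped subvolumes (or, after [collapse_stack()], 2D
#' images) with a per-item in-plane rotation prior and provenance.
#'
#' @param items List of 3D arrays (or 2D matrices), all the same shape.
#' @param priors_deg Numeric vector of in-plane rotation priors (degrees).
#' @param pixel_nm Pixel/voxel size (nm).
#' @param sources data.frame of per-item provenance (ids, positions).
#' @return An object of class `box_stack`.
#' @export
box_stack <- function(items, priors_deg, pixel_nm, sources = NULL) {
  if (length(items) == 0) stop("empty box stack")
  d1 <- dim(items[[1]])
  if (!all(vapply(items, function(x) identical(dim(x), d1), logical(1)))) {
    stop("all stack items must share one shape")
  }
  if (length(priors_deg) != length(items)) stop("one prior per item required")
  if (!all(is.finite(priors_deg))) stop("priors must be finite")
  structure(
    list(
      items = items, priors_deg = priors_deg, pixel_nm = pixel_nm,
      box_px = d1[1], sources = sources
    ),
    class = "box_stack"
  )
}

#' @export
print.box_stack <- function(x, ...) {
  cat(sprintf(
    "<box_stack> %d items of %s px, %.3g nm/px\n",
    length(x$items), paste(dim(x$items[[1]]), collapse = " x "), x$pixel_nm
  ))
  invisible(x)
}

#' @export
length.box_stack <- function(x) length(x$items)

#' Extract overlapping boxes along a membrane path spline
#'
#' Boxes are centred at arc-length steps `0, step_px, 2 step_px, ...`
#' along the spline. At each centre, the extraction grid is rotated so
#' that the membrane normal (the in-plane direction perpendicular to the
#' local spline tangent) is the image x axis and the tangent the image y
#' axis; the collapse (depth) axis is the volume axis `depth_axis`.
#' Sampling is trilinear. The rotation applied at each centre is retained
#' as the item's in-plane prior. Boxes extending beyond the volume are
#' dropped with a message.
#'
#' @param volume A [density_volume()].
#' @param spline A [fit_path_spline()] result (same coordinate frame).
#' @param box_px Box side in pixels (image is `box_px` x `box_px`).
#' @param step_px Arc-length step between box centres (pixels,
#'   `< box_px` so boxes overlap).
#' @param depth_axis Volume axis (1, 2 or 3) projected out by
#'   [collapse_to_2d()]; the image plane is perpendicular to it.
#' @param depth_px Box depth in pixels (default `box_px`).
#' @return A [box_stack()] of subvolumes (image x, image y, depth).
#' @export
extract_boxes_along_path <- function(volume, spline, box_px, step_px,
                                     depth_axis = 2, depth_px = box_px) {
  stopifnot(inherits(volume, "density_volume"), inherits(spline, "path_spline"))
  if (step_px >= box_px) stop("step_px must be smaller than box_px (overlap)")
  vx <- volume$voxel_nm
  if (spline$length_nm < box_px * vx) {
    stop("spline shorter than one box")
  }
  ax <- setdiff(1:3, depth_axis)  # in-plane volume axes (image frame basis)
  s_centres <- seq(0, spline$length_nm, by = step_px * vx)
  centres <- spline_point(spline, s_centres)
  tangents <- spline_tangent(spline, s_centres)

  items <- list(); priors <- numeric(0); rows <- list()
  dropped <- 0L
  for (b in seq_along(s_centres)) {
    tg2 <- tangents[b, ax]
    nrm_t <- sqrt(sum(tg2^2))
    if (nrm_t < 1e-9) {
      dropped <- dropped + 1L
      next
    }
    tg2 <- tg2 / nrm_t
    nm2 <- c(-tg2[2], tg2[1])  # in-plane normal, +90 deg from tangent
    T3 <- numeric(3); T3[ax] <- tg2
    N3 <- numeric(3); N3[ax] <- nm2
    D3 <- numeric(3); D3[depth_axis] <- 1
    box <- extract_one_box(volume, centres[b, ], N3, T3, D3, box_px, depth_px)
    if (is.null(box)) {
      dropped <- dropped + 1L
      next
    }
    items[[length(items) + 1]] <- box
    priors <- c(priors, atan2(nm2[2], nm2[1]) * 180 / pi)
    rows[[length(rows) + 1]] <- data.frame(
      s_nm = s_centres[b], x = centres[b, 1], y = centres[b, 2],
      z = centres[b, 3]
    )
  }
  if (dropped > 0) {
    message(sprintf("%d box(es) dropped (out of bounds or degenerate tangent)", dropped))
  }
  if (length(items) == 0) stop("no boxes could be extracted")
  box_stack(items, priors, vx, do.call(rbind, rows))
}

#' Extract particle boxes at 4-point picks
#'
#' One box per pick, centred at the midpoint of A (ER base) and B (PM
#' end). The image x axis is the membrane normal, the image y axis the
#' PM tangent direction of the pick, and the depth axis their cross
#' product. The per-item prior is the pick's in-plane rotation from
#' [particle_axis_angle()]. The box side is `round(box_A / (10 *
#' voxel_nm))` pixels. Out-of-bounds boxes are dropped with a message.
#'
#' @param volume A [density_volume()].
#' @param picks List of [particle_pick()] objects.
#' @param box_A Box side in Angstrom (default 444).
#' @param normal Membrane normal direction in the volume frame
#'   (default +z).
#' @return A [box_stack()] of subvolumes.
#' @export
extract_particle_boxes <- function(volume, picks, box_A = 444,
                                   normal = c(0, 0, 1)) {
  stopifnot(inherits(volume, "density_volume"))
  if (length(picks) == 0) stop("no picks supplied")
  vx <- volume$voxel_nm
  box_px <- as.integer(round(box_A / (10 * vx)))
  n_hat <- unitize(normal)
  items <- list(); priors <- numeric(0); rows <- list()
  dropped <- 0L
  for (p in picks) {
    tg <- p$D - p$B
    tg <- tg - sum(tg * n_hat) * n_hat
    if (sqrt(sum(tg^2)) < 1e-9) {
      dropped <- dropped + 1L
      next
    }
    T3 <- unitize(tg)
    D3 <- c(
      n_hat[2] * T3[3] - n_hat[3] * T3[2],
      n_hat[3] * T3[1] - n_hat[1] * T3[3],
      n_hat[1] * T3[2] - n_hat[2] * T3[1]
    )
    ctr <- (p$A + p$B) / 2
    box <- extract_one_box(volume, ctr, n_hat, T3, D3, box_px, box_px)
    if (is.null(box)) {
      dropped <- dropped + 1L
      next
    }
    orient <- particle_axis_angle(p)
    items[[length(items) + 1]] <- box
    priors <- c(priors, orient$inplane_rotation_deg)
    rows[[length(rows) + 1]] <- data.frame(
      particle_id = p$particle_id, tomogram_id = p$tomogram_id,
      x = ctr[1], y = ctr[2], z = ctr[3], stringsAsFactors = FALSE
    )
  }
  if (dropped > 0) {
    message(sprintf("%d pick box(es) dropped (out of bounds)", dropped))
  }
  if (length(items) == 0) stop("no boxes could be extracted")
  box_stack(items, priors, vx, do.call(rbind, rows))
}

#' Trilinear extraction of one oriented box; NULL when out of bounds
#' @noRd
extract_one_box <- function(volume, centre, N3, T3, D3, box_px, depth_px) {
  vx <- volume$voxel_nm
  dims <- dim(volume$voxels)
  off_i <- (seq_len(box_px) - (box_px + 1) / 2) * vx
  off_j <- (seq_len(box_px) - (box_px + 1) / 2) * vx
  off_d <- (seq_len(depth_px) - (depth_px + 1) / 2) * vx
  # bounds check on the 8 corners
  corners <- as.matrix(expand.grid(range(off_i), range(off_j), range(off_d)))
  cpos <- corners %*% rbind(N3, T3, D3)
  cpos <- sweep(cpos, 2, centre, "+")
  upper <- dims * vx
  if (any(cpos < -1e-9) || any(sweep(cpos, 2, upper) > 1e-9)) return(NULL)
  grid <- cbind(
    rep(off_i, times = box_px * depth_px),
    rep(rep(off_j, each = box_px), times = depth_px),
    rep(off_d, each = box_px * box_px)
  )
  pos <- grid %*% rbind(N3, T3, D3)
  pos <- sweep(pos, 2, centre, "+")
  array(sample_volume(volume, pos), dim = c(box_px, box_px, depth_px))
}

#' Collapse a subvolume to a 2D projection
#'
#' Sum projection along the depth (third) axis; pixel size is preserved.
#' The total intensity of the projection equals that of the subvolume.
#'
#' @param subvolume 3D array (image x, image y, depth).
#' @param prior_deg Optional in-plane prior carried along as an attribute.
#' @return Matrix (image x, image y).
#' @export
collapse_to_2d <- function(subvolume, prior_deg = NULL) {
  stopifnot(length(dim(subvolume)) == 3)
  img <- rowSums(subvolume, dims = 2)
  if (!is.null(prior_deg)) attr(img, "prior_deg") <- prior_deg
  img
}

#' Collapse every subvolume in a stack to 2D
#'
#' @param stack A [box_stack()] of 3D subvolumes.
#' @return A [box_stack()] of 2D images with the same priors and sources.
#' @export
collapse_stack <- function(stack) {
  stopifnot(inherits(stack, "box_stack"))
  imgs <- lapply(stack$items, collapse_to_2d)
  out <- stack
  out$items <- imgs
  out
}
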