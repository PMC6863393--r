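# Constrained multi-reference alignment and classification of collapsed
# 2D images, with orientation priors restraining the rotational search.

#' Align and classify a stack of collapsed 2D images
#'
#' Iterative multi-reference alignment with hard assignment. References
#' are initialized from a seeded random partition of the stack. At each
#' iteration, every image is compared to every reference over rotations
#' within `prior +/- rot_window_deg` (1 degree steps; images are stored
#' already rotated to their prior, so the search is over the residual)
#' and integer shifts within `max_shift_px`, scored by normalized
#' cross-correlation after Gaussian band-limiting to `lowpass_nm`. Each
#' image is assigned to its best-scoring reference, and references are
#' updated as the within-class means of the aligned raw images. Iteration
#' stops after `n_iter` rounds or when fewer than 1% of assignments
#' change. An emptied class is reseeded from the worst-scoring image.
#' With `k = 1` this is constrained global averaging.
#'
#' @param stack A [box_stack()] of 2D images (see [collapse_stack()]).
#' @param k Number of classes (>= 1).
#' @param rot_window_deg Half-width of the rotational search around the
#'   prior (default 15).
#' @param max_shift_px Maximum integer shift searched per axis.
#' @param lowpass_nm Resolution cutoff (FWHM of the Gaussian low-pass)
#'   used for scoring only; `NULL` disables filtering.
#' @param n_iter Maximum iterations.
#' @param seed RNG seed for the reference initialization.
#' @return A list of class `class_result`: per-item `assignment`,
#'   `rotation_deg` (refined, equals prior + residual), `shift_px`
#'   (n x 2), `score`; per-class `averages` (list of matrices), `n` and
#'   `fraction`; plus `priors_deg` and `pixel_nm`.
#' @export
align_and_classify <- function(stack, k, rot_window_deg = 15,
                               max_shift_px = 3, lowpass_nm = 2,
                               n_iter = 10, seed = 1L) {
  stopifnot(inherits(stack, "box_stack"), k >= 1)
  imgs <- stack$items
  if (length(dim(imgs[[1]])) != 2) {
    stop("stack items must be 2D images; collapse the stack first")
  }
  n <- length(imgs)
  px <- stack$pixel_nm
  box <- nrow(imgs[[1]])
  crop <- (max_shift_px + 1):(box - max_shift_px)
  if (length(crop) < 8) stop("box too small for the requested shift search")

  # search grids ordered by transform magnitude so ties (e.g. images
  # invariant along one axis) resolve to the smallest rotation and shift
  deltas <- seq(-round(rot_window_deg), round(rot_window_deg), by = 1)
  deltas <- deltas[order(abs(deltas), deltas)]
  shifts <- as.matrix(expand.grid(dx = -max_shift_px:max_shift_px,
                                  dy = -max_shift_px:max_shift_px))
  shifts <- shifts[order(rowSums(shifts^2), shifts[, 1], shifts[, 2]), ,
                   drop = FALSE]

  # precompute: filtered, rotated variants of each image (scoring copies)
  filt <- lapply(imgs, gaussian_lowpass, lowpass_nm = lowpass_nm, pixel_nm = px)
  rotated <- lapply(filt, function(f) lapply(deltas, function(d) rotate_image(f, d)))

  set.seed(as.integer(seed))
  assign_now <- sample(rep_len(seq_len(k), n))
  best_delta <- integer(n)  # index into deltas, 0 = unset
  best_shift <- matrix(0L, n, 2)
  best_score <- rep(-Inf, n)
  zero_delta <- which(deltas == 0)[1]
  if (is.na(zero_delta)) zero_delta <- which.min(abs(deltas))
  best_delta[] <- zero_delta

  refs <- update_references(imgs, assign_now, best_delta, best_shift, deltas, k)

  for (iter in seq_len(n_iter)) {
    refs_f <- lapply(refs, function(r) {
      rf <- gaussian_lowpass(r, lowpass_nm, px)
      rf[crop, crop]
    })
    prev <- assign_now
    for (i in seq_len(n)) {
      bs <- -Inf; ba <- 1L; bd <- zero_delta; bsh <- c(0L, 0L)
      for (di in seq_along(deltas)) {
        rot <- rotated[[i]][[di]]
        for (s in seq_len(nrow(shifts))) {
          win <- rot[crop - shifts[s, 1], crop - shifts[s, 2]]
          wv <- as.vector(win)
          for (cl in seq_len(k)) {
            sc <- stats::cor(wv, as.vector(refs_f[[cl]]))
            # tolerance keeps numerically tied candidates at the smaller
            # transform (the search grids are ordered by magnitude)
            if (is.finite(sc) && sc > bs + 1e-9) {
              bs <- sc; ba <- cl; bd <- di; bsh <- shifts[s, ]
            }
          }
        }
      }
      assign_now[i] <- ba
      best_delta[i] <- bd
      best_shift[i, ] <- as.integer(bsh)
      best_score[i] <- bs
    }
    # reseed empty classes from the worst-scoring images
    empty <- setdiff(seq_len(k), unique(assign_now))
    if (length(empty) > 0) {
      worst <- order(best_score)[seq_along(empty)]
      assign_now[worst] <- empty
      message(sprintf("reseeded %d empty class(es)", length(empty)))
    }
    refs <- update_references(imgs, assign_now, best_delta, best_shift, deltas, k)
    changed <- sum(assign_now != prev)
    if (iter > 1 && changed < 0.01 * n) break
  }

  rotation <- stack$priors_deg + deltas[best_delta]
  counts <- tabulate(assign_now, nbins = k)
  structure(
    list(
      assignment = assign_now,
      rotation_deg = rotation,
      residual_deg = deltas[best_delta],
      shift_px = best_shift,
      score = best_score,
      averages = refs,
      n = counts,
      fraction = counts / n,
      priors_deg = stack$priors_deg,
      pixel_nm = px
    ),
    class = "class_result"
  )
}

#' Class means of aligned raw images
#' @noRd
update_references <- function(imgs, assignment, best_delta, best_shift,
                              deltas, k) {
  box <- nrow(imgs[[1]])
  refs <- vector("list", k)
  for (cl in seq_len(k)) {
    members <- which(assignment == cl)
    if (length(members) == 0) {
      refs[[cl]] <- matrix(0, box, box)
      next
    }
    acc <- matrix(0, box, box)
    for (i in members) {
      al <- rotate_image(imgs[[i]], deltas[best_delta[i]])
      al <- shift_image(al, -best_shift[i, 1], -best_shift[i, 2])
      acc <- acc + al
    }
    refs[[cl]] <- acc / length(members)
  }
  refs
}

#' @export
print.class_result <- function(x, ...) {
  cat(sprintf(
    "<class_result> %d items in %d class(es): %s\n",
    length(x$assignment), length(x$n),
    paste(sprintf("n=%d (%.0f%%)", x$n, 100 * x$fraction), collapse = ", ")
  ))
  invisible(x)
}
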