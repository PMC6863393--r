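# Coat-coverage ratio: extra-layer volume relative to cER volume from
# voxel segmentation masks.

#' Construct a voxel segmentation mask
#'
#' @param voxels 3D array of 0/1 (or logical) values.
#' @param voxel_nm Isotropic voxel size (nm).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, voxel_nm) {
  stopifnot(length(dim(voxels)) == 3, voxel_nm > 0)
  v <- array(as.integer(voxels != 0), dim(voxels))
  if (!all(v %in% c(0L, 1L))) stop("mask values must be 0/1")
  structure(list(voxels = v, voxel_nm = voxel_nm), class = "voxel_mask")
}

#' Ratio of extra-layer volume to cER volume
#'
#' Volumes are voxel counts times voxel_nm^3; the ratio layer / cER is a
#' dimensionless measure of the extent of the PM density layer.
#'
#' @param layer [voxel_mask()] of the extra layer.
#' @param cer [voxel_mask()] of the cortical ER; must share shape and
#'   voxel size with `layer` and be nonempty.
#' @return A list of class `coverage_result`: `layer_volume_nm3`,
#'   `cer_volume_nm3`, `ratio`.
#' @export
volume_ratio <- function(layer, cer) {
  stopifnot(inherits(layer, "voxel_mask"), inherits(cer, "voxel_mask"))
  if (!identical(dim(layer$voxels), dim(cer$voxels))) {
    stop("masks must share one shape")
  }
  if (abs(layer$voxel_nm - cer$voxel_nm) > 1e-9) {
    stop("masks must share one voxel size")
  }
  n_cer <- sum(cer$voxels)
  if (n_cer == 0) stop("empty cER mask: ratio undefined")
  v3 <- layer$voxel_nm^3
  lay <- sum(layer$voxels) * v3
  cer_v <- n_cer * v3
  structure(
    list(
      layer_volume_nm3 = lay,
      cer_volume_nm3 = cer_v,
      ratio = lay / cer_v
    ),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage_result> layer %.1f nm^3 / cER %.1f nm^3 = %.4f\n",
    x$layer_volume_nm3, x$cer_volume_nm3, x$ratio
  ))
  invisible(x)
}
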