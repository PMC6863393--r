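# File I/O: MRC volumes/masks, clicked point models, pick files, colony
# tables, profiles and meshes.

#' Write a density volume or mask as MRC
#'
#' Minimal MRC2014 writer: mode 2 (32-bit float), voxel size recorded in
#' the cell dimensions (in Angstrom), little-endian with the standard
#' MAP stamp.
#'
#' @param x A [density_volume()] or [voxel_mask()].
#' @param path Output file.
#' @export
write_mrc <- function(x, path) {
  v <- x$voxels
  dims <- dim(v)
  vox_A <- x$voxel_nm * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                       # nx ny nz
  wi(2)                          # mode 2 = float32
  wi(c(0, 0, 0))                 # nxstart
  wi(dims)                       # mx my mz
  wf(dims * vox_A)               # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1, 2, 3))                 # mapc mapr maps
  wf(c(min(v), max(v), mean(v))) # dmin dmax dmean
  wi(0)                          # ispg
  wi(0)                          # nsymbt
  wi(rep(0, 25))                 # extra
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(v)))   # rms
  wi(0)                          # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16).
#'
#' @param path MRC file.
#' @param invert_contrast Negate densities on load, for inputs following
#'   the inverse cryo-EM convention (protein dark); the package convention
#'   is higher value = more mass.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path, invert_contrast = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  ri(3)  # nxstart
  mx <- ri(3)
  cella <- rf(3)
  seek(con, 1024)
  n <- prod(dims)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little", signed = TRUE)),
    "2" = rf(n),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little", signed = FALSE)),
    stop("unsupported MRC mode ", mode)
  )
  if (invert_contrast) data <- -data
  voxel_nm <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] / 10 else 1
  density_volume(array(data, dim = dims), voxel_nm = voxel_nm)
}

#' Read a clicked point model
#'
#' Whitespace-separated text with columns `object contour x y z`
#' (coordinates in nm), as exported from tomogram annotation tools.
#' Objects map to membranes and contours to sites.
#'
#' @param path Model file.
#' @return data.frame with columns object, contour, x, y, z.
#' @export
read_point_model <- function(path) {
  df <- utils::read.table(path, header = FALSE,
    col.names = c("object", "contour", "x", "y", "z")
  )
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  df
}

#' Write a clicked point model
#'
#' @param df data.frame with columns object, contour, x, y, z (nm).
#' @param path Output file.
#' @export
write_point_model <- function(df, path) {
  utils::write.table(df[, c("object", "contour", "x", "y", "z")], path,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Split a point model into membrane clouds per site
#'
#' @param df A [read_point_model()] data.frame.
#' @param membrane Membrane label assigned to all clouds.
#' @return Named list of [membrane_cloud()] objects, one per contour.
#' @export
model_to_clouds <- function(df, membrane = c("PM", "ER")) {
  membrane <- match.arg(membrane)
  lapply(split(df, df$contour), function(d) {
    membrane_cloud(as.matrix(d[, c("x", "y", "z")]), membrane,
      site_id = as.character(d$contour[1])
    )
  })
}

#' Read particle picks from a labelled text file
#'
#' Four rows per particle labelled A/B/C/D: columns
#' `particle_id label x y z` (nm).
#'
#' @param path Pick file.
#' @return List of [particle_pick()] objects.
#' @export
read_picks <- function(path) {
  df <- utils::read.table(path, header = FALSE,
    col.names = c("particle_id", "label", "x", "y", "z")
  )
  lapply(split(df, df$particle_id), function(d) {
    pt <- function(lab) {
      r <- d[d$label == lab, ]
      if (nrow(r) != 1) stop("particle needs exactly one point ", lab)
      as.numeric(r[1, c("x", "y", "z")])
    }
    particle_pick(pt("A"), pt("B"), pt("C"), pt("D"),
      particle_id = as.character(d$particle_id[1])
    )
  })
}

#' Write particle picks
#'
#' @param picks List of [particle_pick()] objects.
#' @param path Output file.
#' @export
write_picks <- function(picks, path) {
  rows <- do.call(rbind, lapply(picks, function(p) {
    data.frame(
      particle_id = p$particle_id, label = c("A", "B", "C", "D"),
      rbind(p$A, p$B, p$C, p$D)
    )
  }))
  utils::write.table(rows, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read colony plates from CSV
#'
#' CSV schema: `plate,row,col,gene,size` (a `flag` column is optional).
#'
#' @param path CSV file.
#' @return List of [colony_plate()] objects, one per plate id.
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$plate), function(d) {
    colony_plate(d[, setdiff(names(d), "plate")], plate_id = d$plate[1])
  })
}

#' Write colony plates to CSV
#'
#' @param plates A [colony_plate()] or list of them.
#' @param path Output file.
#' @export
write_plates <- function(plates, path) {
  if (inherits(plates, "colony_plate")) plates <- list(plates)
  utils::write.csv(do.call(rbind, lapply(plates, as.data.frame)), path,
    row.names = FALSE
  )
  invisible(path)
}

#' Write a 2-channel image as TIFF
#'
#' Intensities are rescaled to [0, 1] jointly across channels and written
#' as a 32-bit float multi-page TIFF (one page per channel).
#'
#' @param image 3D array (y, x, channel).
#' @param path Output file.
#' @export
write_image_tiff <- function(image, path) {
  rng <- range(image)
  scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  pages <- lapply(seq_len(dim(image)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF as a channel array
#'
#' @param path TIFF file.
#' @return 3D array (y, x, channel).
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- pages[[k]]
  out
}

#' Export a surface-model mesh as Wavefront OBJ
#'
#' Vertices are the 20 x 20 grid points; faces follow the cell diagonal
#' triangulation used for distance measurement.
#'
#' @param model A [biharmonic_surface()] result.
#' @param path Output file.
#' @export
write_surface_obj <- function(model, path) {
  ng <- length(model$grid_x)
  vx <- rep(model$grid_x, times = ng)
  vy <- rep(model$grid_y, each = ng)
  vz <- as.vector(model$grid_z)
  idx <- function(i, j) (j - 1L) * ng + i
  lines <- sprintf("v %.6f %.6f %.6f", vx, vy, vz)
  for (j in seq_len(ng - 1)) {
    for (i in seq_len(ng - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      lines <- c(lines, sprintf("f %d %d %d", a, b, cc),
                 sprintf("f %d %d %d", a, cc, d))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
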