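# Box extraction, 2D collapse, constrained alignment/classification, and
# profile measurements.

test_that("box counting along a straight path matches arithmetic", {
  # volume of 10 box-lengths along x; boxes of 16 px at half-box steps
  b <- 16
  vol <- density_volume(array(1, dim = c(10 * b, 48, 48)), voxel_nm = 1)
  pts <- cbind(seq(0, 10 * b, by = 8), 24, 24)
  sp <- fit_path_spline(pts)
  expect_message(
    stack <- extract_boxes_along_path(vol, sp, box_px = b, step_px = b / 2),
    "dropped"
  )
  expect_equal(length(stack), 19)
  # straight path: all priors equal; constant volume: all boxes identical
  expect_equal(length(unique(round(stack$priors_deg, 9))), 1)
  expect_identical(stack$items[[1]], stack$items[[2]])
})

test_that("extraction orients the membrane normal along the image x axis", {
  gv <- small_contact_volume(gap = 22, shape = c(96, 48, 80))
  pts <- cbind(seq(8, 63, by = 8), 17.5, 20)
  sp <- fit_path_spline(pts)
  stack <- extract_boxes_along_path(gv$volume, sp, box_px = 40, step_px = 8)
  img <- collapse_to_2d(stack$items[[1]])
  prof <- rowMeans(img)
  # PM leaflet peaks 4 nm apart near the box centre, along rows
  pk1 <- which.max(prof)
  masked <- prof
  masked[pmax(1, pk1 - 3):pmin(length(prof), pk1 + 3)] <- -Inf
  pk2 <- which.max(masked)
  expect_equal(abs(pk2 - pk1) * gv$volume$voxel_nm, 4, tolerance = 1)
})

test_that("particle boxes use the 444 A box size rule and drop corner picks", {
  gap <- 22
  rods <- spanning_rods(x = 35, y = 35, tilt_deg = 0, azimuth_deg = 0,
                        gap = gap)
  gv <- small_contact_volume(rods = rods, shape = c(96, 96, 80))
  picks <- gen_particle_picks(gv$truth_tables, click_jitter_nm = 0)
  stack <- extract_particle_boxes(gv$volume, picks, box_A = 444)
  expect_equal(stack$box_px, round(444 / (10 * 0.74)))

  # a pick at the volume corner is dropped and the stack shrinks
  corner <- particle_pick(c(2, 2, 30), c(2, 2, 8), c(12, 2, 30), c(12, 2, 8))
  expect_message(
    stack2 <- extract_particle_boxes(gv$volume, c(picks, list(corner))),
    "dropped"
  )
  expect_equal(length(stack2), length(stack))

  # collapsed tilt-0 rod is vertical: peak column at the image centre
  img <- collapse_to_2d(stack$items[[1]])
  mid_rows <- which(abs(seq_len(nrow(img)) - (nrow(img) + 1) / 2) < 5)
  col_prof <- colMeans(img[mid_rows, ])
  expect_equal(which.max(col_prof), ncol(img) / 2, tolerance = 1.5)
})

test_that("voxel size 0.37 nm gives a 120 px box", {
  vol <- density_volume(array(0, dim = c(8, 8, 8)), voxel_nm = 0.37)
  expect_equal(round(444 / (10 * vol$voxel_nm)), 120)
})

test_that("collapse is a sum projection preserving total intensity", {
  sub <- array(3, dim = c(8, 8, 5))
  img <- collapse_to_2d(sub)
  expect_true(all(img == 15))
  set.seed(1)
  a <- array(rnorm(8 * 8 * 5), dim = c(8, 8, 5))
  b <- array(rnorm(8 * 8 * 5), dim = c(8, 8, 5))
  expect_equal(collapse_to_2d(a) + collapse_to_2d(b), collapse_to_2d(a + b))
  expect_equal(sum(collapse_to_2d(a)), sum(a))
})

test_that("collapsed membrane profile matches the analytic leaflet model", {
  gv <- small_contact_volume(gap = 22, shape = c(32, 32, 80))
  vx <- gv$volume$voxel_nm
  depth <- 20
  sub <- gv$volume$voxels[1:20, 1:depth, ]
  img <- collapse_to_2d(aperm(sub, c(3, 1, 2)))  # project along y
  prof <- img[, 1]
  zc <- (seq_along(prof) - 0.5) * vx
  model <- depth * (
    exp(-(zc - 16)^2 / 2) + exp(-(zc - 20)^2 / 2) +
      exp(-(zc - 42)^2 / 2) + exp(-(zc - 46)^2 / 2)
  )
  expect_lt(max(abs(prof - model)), 1e-6)
})

test_that("a stack of identical images self-aligns with zero residuals", {
  gv <- small_contact_volume(gap = 22, shape = c(48, 48, 80))
  pts <- cbind(seq(4, 31, by = 4), 17.5, 20)
  sp <- fit_path_spline(pts)
  stack <- collapse_stack(
    extract_boxes_along_path(gv$volume, sp, box_px = 24, step_px = 4)
  )
  cr <- align_and_classify(stack, k = 1, rot_window_deg = 5, max_shift_px = 2,
                           n_iter = 4, seed = 1)
  expect_true(all(cr$shift_px == 0))
  expect_equal(cr$rotation_deg, stack$priors_deg)
  expect_equal(cr$averages[[1]], stack$items[[1]], tolerance = 1e-9)
  expect_equal(cr$fraction, 1)
})

test_that("refined rotations never leave the prior window", {
  set.seed(9)
  gv <- small_contact_volume(gap = 22, noise_sd = 0.3, shape = c(48, 48, 80),
                             seed = 4)
  pts <- cbind(seq(4, 31, by = 4), 17.5, 20)
  sp <- fit_path_spline(pts)
  stack <- collapse_stack(
    extract_boxes_along_path(gv$volume, sp, box_px = 24, step_px = 4)
  )
  cr <- align_and_classify(stack, k = 1, rot_window_deg = 6, max_shift_px = 2,
                           n_iter = 4, seed = 2)
  expect_true(all(abs(cr$rotation_deg - stack$priors_deg) <= 6))
})

test_that("two separable noiseless populations classify with 100% purity", {
  gap <- 22
  rods <- spanning_rods(x = 35, y = 35, tilt_deg = 0, azimuth_deg = 0,
                        gap = gap)
  with_rod <- small_contact_volume(rods = rods, shape = c(96, 96, 80))
  without <- small_contact_volume(shape = c(96, 96, 80))
  picks <- gen_particle_picks(with_rod$truth_tables, click_jitter_nm = 0)
  img_rod <- collapse_to_2d(
    extract_particle_boxes(with_rod$volume, picks)$items[[1]]
  )
  img_mem <- collapse_to_2d(
    extract_particle_boxes(without$volume, picks)$items[[1]]
  )
  items <- c(rep(list(img_rod), 6), rep(list(img_mem), 6))
  stack <- box_stack(items, priors_deg = rep(0, 12), pixel_nm = 0.74)
  cr <- align_and_classify(stack, k = 2, rot_window_deg = 3, max_shift_px = 1,
                           n_iter = 6, seed = 3)
  truth <- rep(1:2, each = 6)
  tab <- table(cr$assignment, truth)
  purity <- sum(apply(tab, 1, max)) / 12
  expect_equal(purity, 1)
  expect_equal(sum(cr$fraction), 1)
})

test_that("averaging n noisy copies reduces background noise like 1/sqrt(n)", {
  gv <- small_contact_volume(gap = 22, shape = c(48, 48, 80))
  pts <- cbind(seq(4, 31, by = 4), 17.5, 20)
  sp <- fit_path_spline(pts)
  base <- collapse_to_2d(
    extract_boxes_along_path(gv$volume, sp, box_px = 24, step_px = 4)$items[[1]]
  )
  n <- 16
  sigma <- 2
  set.seed(12)
  items <- lapply(seq_len(n), function(i) {
    base + matrix(rnorm(length(base), sd = sigma), nrow(base), ncol(base))
  })
  stack <- box_stack(items, priors_deg = rep(0, n), pixel_nm = 0.74)
  cr <- align_and_classify(stack, k = 1, rot_window_deg = 2, max_shift_px = 1,
                           n_iter = 3, seed = 5)
  resid <- cr$averages[[1]] - base
  # background region: away from the membrane signal and box edges
  bg <- resid[19:23, 3:22]
  expect_equal(sd(as.vector(bg)), sigma / sqrt(n), tolerance = 0.2)
})

test_that("coat layer thickness is measured by FWHM, scale invariantly", {
  gv <- small_contact_volume(coat = 5.2, shape = c(96, 56, 80))
  pts <- cbind(seq(15, 56, by = 8), 56 * 0.74 / 2, 20)
  sp <- fit_path_spline(pts)
  stack <- collapse_stack(
    extract_boxes_along_path(gv$volume, sp, box_px = 48, step_px = 6)
  )
  cr <- align_and_classify(stack, k = 1, max_shift_px = 2, n_iter = 3, seed = 1)
  m <- layer_thickness(cr$averages[[1]], pixel_nm = 0.74)
  expect_equal(m$thickness_nm, 5.2, tolerance = 0.74)
  # doubling contrast leaves the FWHM unchanged
  m2 <- layer_thickness(2 * cr$averages[[1]], pixel_nm = 0.74)
  expect_equal(m2$thickness_nm, m$thickness_nm, tolerance = 1e-9)
  # a coat-free membrane reports no layer
  bare <- small_contact_volume(shape = c(96, 56, 80))
  stack_b <- collapse_stack(
    extract_boxes_along_path(bare$volume, sp, box_px = 48, step_px = 6)
  )
  cr_b <- align_and_classify(stack_b, k = 1, max_shift_px = 2, n_iter = 3,
                             seed = 1)
  mb <- layer_thickness(cr_b$averages[[1]], pixel_nm = 0.74)
  expect_identical(mb$status, "no layer")
  expect_true(is.na(mb$thickness_nm))
})

test_that("rod length measures the cytosolic leaflet-to-leaflet distance", {
  for (gap in c(16.7, 22)) {
    rods <- spanning_rods(x = 35, y = 35, tilt_deg = 0, azimuth_deg = 20,
                          gap = gap)
    gv <- small_contact_volume(gap = gap, rods = rods, shape = c(96, 96, 80))
    picks <- gen_particle_picks(gv$truth_tables, click_jitter_nm = 0)
    stack <- collapse_stack(extract_particle_boxes(gv$volume, picks))
    m <- rod_length(stack$items[[1]], pixel_nm = 0.74, profile_width_px = 15)
    expect_equal(m$length_nm, gap, tolerance = 0.74)
    # intensity scaling does not change the length
    m3 <- rod_length(3 * stack$items[[1]], pixel_nm = 0.74)
    expect_equal(m3$length_nm, m$length_nm, tolerance = 1e-9)
  }
})

test_that("end-to-end rod recovery through k = 1 averaging stays within a voxel", {
  gap <- 22
  set.seed(8)
  rods <- spanning_rods(
    x = seq(30, 60, by = 15), y = c(35, 45, 35), tilt_deg = 10,
    azimuth_deg = c(0, 120, 240), gap = gap
  )
  gv <- small_contact_volume(gap = gap, rods = rods, noise_sd = 0.1,
                             shape = c(128, 128, 80), seed = 6)
  picks <- gen_particle_picks(gv$truth_tables, click_jitter_nm = 0)
  stack <- collapse_stack(extract_particle_boxes(gv$volume, picks))
  cr <- align_and_classify(stack, k = 1, max_shift_px = 2, n_iter = 4, seed = 2)
  m <- rod_length(cr$averages[[1]], pixel_nm = 0.74)
  expect_equal(m$length_nm, gap, tolerance = 0.74)
  # recovered tilt (from picks) matches the generating tilt
  a <- vapply(picks, function(p) particle_axis_angle(p)$tilt_deviation_deg,
              numeric(1))
  expect_lt(max(abs(a - 10)), 2)
})
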