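# Synthetic-data generators: analytic zero-noise behaviour, jitter
# statistics, rendering geometry, and seed reproducibility.

test_that("flat site with zero jitter lies exactly on the stated planes", {
  tr <- site_truth(22, "flat", jitter_sd_nm = 0, seed = 3)
  s <- gen_membrane_site(tr, extent_nm = 100)
  expect_true(all(s$pm$points[, 3] == 0))
  expect_true(all(s$er$points[, 3] == 22))
  expect_identical(s$pm$membrane, "PM")
  expect_identical(s$er$membrane, "ER")
})

test_that("click jitter has the requested normal-direction SD", {
  tr <- site_truth(22, "flat", jitter_sd_nm = 1, seed = 8)
  s <- gen_membrane_site(tr, extent_nm = 200)
  expect_gte(nrow(s$er$points), 100)
  expect_equal(sd(s$er$points[, 3]), 1, tolerance = 0.2)
  expect_equal(sd(s$pm$points[, 3]), 1, tolerance = 0.2)
})

test_that("buckled geometry dips by the stated depth at the apex", {
  tr <- site_truth(22, "buckled",
    buckle_depth_nm = 8, buckle_radius_nm = 20, jitter_sd_nm = 0
  )
  # extent chosen so the click raster samples the apex exactly
  s <- gen_membrane_site(tr, extent_nm = 220)
  expect_equal(min(s$er$points[, 3]), 14, tolerance = 1e-9)
  apex <- which.min(s$er$points[, 3])
  expect_equal(s$er$points[apex, 1:2], c(0, 0), ignore_attr = TRUE)
  # far from the apex the gap returns to the full separation
  far <- sqrt(rowSums(s$er$points[, 1:2]^2)) > 100
  expect_equal(max(abs(s$er$points[far, 3] - 22)), 0, tolerance = 5e-3)
})

test_that("generators are bit-identical under a fixed seed", {
  tr <- site_truth(20, "flat", jitter_sd_nm = 1.5, seed = 77)
  a <- gen_membrane_site(tr, extent_nm = 80)
  b <- gen_membrane_site(tr, extent_nm = 80)
  expect_identical(a, b)

  gv1 <- small_contact_volume(noise_sd = 0.3, shape = c(32, 32, 80), seed = 5)
  gv2 <- small_contact_volume(noise_sd = 0.3, shape = c(32, 32, 80), seed = 5)
  expect_identical(gv1$volume$voxels, gv2$volume$voxels)
})

test_that("membrane-only volume is translation invariant in x/y", {
  gv <- small_contact_volume(shape = c(24, 24, 80))
  v <- gv$volume$voxels
  ref <- v[1, 1, ]
  expect_true(all(apply(v, c(1, 2), function(zz) max(abs(zz - ref))) < 1e-12))
})

test_that("a perpendicular rod adds density along its axis between the leaflets", {
  rods <- spanning_rods(x = 35, y = 35, tilt_deg = 0, azimuth_deg = 0, gap = 22)
  gv <- small_contact_volume(rods = rods, shape = c(96, 96, 80))
  v <- gv$volume$voxels
  vx <- gv$volume$voxel_nm
  zmid <- round(31 / vx)  # between the membranes
  slab <- v[, , zmid]
  peak <- colMeans(which(slab == max(slab), arr.ind = TRUE))
  expect_equal(as.numeric((peak - 0.5) * vx), c(35, 35), tolerance = vx)
  # recorded endpoints reproduce the stated tilt
  r <- gv$truth_tables$rods[1, ]
  axis <- c(r$x1 - r$x0, r$y1 - r$y0, r$z1 - r$z0)
  tilt <- acos(axis[3] / sqrt(sum(axis^2))) * 180 / pi
  expect_equal(tilt, r$tilt_deg, tolerance = 1e-9)
})

test_that("rods longer than the gap at their tilt are rejected", {
  rods <- data.frame(x = 35, y = 35, tilt_deg = 0, azimuth_deg = 0,
                     length_nm = 30)
  expect_message(
    gv <- small_contact_volume(rods = rods, shape = c(96, 96, 80)),
    "rejected"
  )
  expect_null(gv$truth_tables$rods)
})

test_that("rendered coat slab spans the requested thickness", {
  gv <- small_contact_volume(coat = 5.2, shape = c(24, 24, 80))
  v <- gv$volume$voxels
  vx <- gv$volume$voxel_nm
  # brute-force profile scan: occupancy above half the slab amplitude,
  # beyond the leaflet density
  prof <- v[12, 12, ]
  zc <- (seq_along(prof) - 0.5) * vx
  region <- zc > 20 + 1.5 & zc < 35
  occ <- sum(prof[region] > 0.25) * vx
  expect_equal(occ, 5.2, tolerance = vx)
})

test_that("noiseless picks recover the generating tilt to machine precision", {
  gap <- 22
  rods <- spanning_rods(
    x = c(30, 40), y = c(30, 40), tilt_deg = c(0, 20),
    azimuth_deg = c(10, 245), gap = gap
  )
  gv <- small_contact_volume(rods = rods, shape = c(96, 96, 80))
  picks <- gen_particle_picks(gv$truth_tables, click_jitter_nm = 0)
  a <- vapply(picks, function(p) particle_axis_angle(p)$tilt_deviation_deg,
              numeric(1))
  expect_equal(a, c(0, 20), tolerance = 1e-9)
  # tilt-0 pick: angle between axis and PM tangent is exactly 90 degrees
  p <- picks[[1]]
  u <- p$B - p$A; t_pm <- p$D - p$B
  expect_equal(sum(u * t_pm), 0, tolerance = 1e-9)
})

test_that("jittered picks recover the mean tilt within a degree", {
  gap <- 22
  n <- 1000
  set.seed(31)
  rods <- spanning_rods(
    x = rep(35, n), y = rep(35, n), tilt_deg = 20,
    azimuth_deg = runif(n, 0, 360), gap = gap
  )
  vt <- volume_truth(voxel_nm = 0.74, pm_z_nm = 20, er_z_nm = 42, rods = rods)
  tt <- list(rods = local({
    # build the truth table without rendering the (identical) cylinders
    theta <- rods$tilt_deg * pi / 180
    phi <- rods$azimuth_deg * pi / 180
    dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    ctr <- cbind(rods$x, rods$y, 31)
    a <- ctr - dirs * rods$length_nm / 2
    b <- ctr + dirs * rods$length_nm / 2
    data.frame(
      rod_id = seq_len(n), x = rods$x, y = rods$y,
      tilt_deg = rods$tilt_deg, azimuth_deg = rods$azimuth_deg,
      length_nm = rods$length_nm,
      x0 = a[, 1], y0 = a[, 2], z0 = a[, 3],
      x1 = b[, 1], y1 = b[, 2], z1 = b[, 3]
    )
  }))
  picks <- gen_particle_picks(tt, click_jitter_nm = 1, seed = 7)
  a <- vapply(picks, function(p) particle_axis_angle(p)$tilt_deviation_deg,
              numeric(1))
  expect_equal(mean(a), 20, tolerance = 1)
})

test_that("colony generator honours its analytic special cases", {
  genes <- sprintf("g%03d", 1:100)
  # all effects 1, noise 0, factors 1: query identical to control
  tr <- plate_truth(genes, noise_sdlog = 0)
  ex <- gen_colony_experiment(tr, n_plates = 1)
  expect_identical(ex$query[[1]]$size, ex$control[[1]]$size)
  sc <- interaction_scores(ex$query, ex$control)
  expect_true(all(sc$score == 0))

  # one gene halved: its score is exactly -1
  tr2 <- plate_truth(genes, interaction_factors = c(g050 = 0.5))
  ex2 <- gen_colony_experiment(tr2, n_plates = 1)
  sc2 <- interaction_scores(ex2$query, ex2$control)
  expect_equal(sc2$score[sc2$gene == "g050"], -1)

  # a doubled row effect is removed by normalization
  tr3 <- plate_truth(genes, row_effects = c(2, rep(1, 15)),
                     interaction_factors = c(g050 = 0.5))
  ex3 <- gen_colony_experiment(tr3, n_plates = 1)
  sc3 <- interaction_scores(ex3$query, ex3$control)
  expect_equal(sc3$score[order(sc3$gene)], sc2$score[order(sc2$gene)],
               tolerance = 1e-12)
})

test_that("cortex generator produces the specified angular structure", {
  # identical domains in both channels, no noise: identical profiles
  g <- gen_cortex_image(list(rbind(c(30, 90)), rbind(c(30, 90))),
    noise_sd = 0, seed = 2
  )
  p <- linearize_profile(g$image, g$contour)
  expect_equal(p$intensity[, 1], p$intensity[, 2])

  # disjoint domains: negative profile correlation
  g2 <- gen_cortex_image(list(rbind(c(0, 170)), rbind(c(190, 350))),
    noise_sd = 0, seed = 2
  )
  p2 <- linearize_profile(g2$image, g2$contour)
  expect_lt(profile_correlation(p2), 0)

  # empty domain: flat background profile
  g3 <- gen_cortex_image(list(NULL, rbind(c(0, 90))), noise_sd = 0, seed = 2)
  p3 <- linearize_profile(g3$image, g3$contour)
  # flat up to pixel-discretization wiggle of the rendered ring
  expect_lt(diff(range(p3$intensity[, 1])), 0.01)
})
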