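test_that("centerline samples at equal arc-length spacing", {
  # circle-degenerate spiral: arc length exactly a * dtheta
  circ <- spiral_fit(center = c(0, 0, 0), axis = c(0, 0, 1),
                     radius_scale_a = 2000, growth_rate_b = 0,
                     pitch = 0, theta_range = c(0, 33500.5 / 2000))
  cl <- centerline(circ, step_um = 100)
  expect_equal(nrow(cl$points), 336)  # 33.5 mm of arc at 100 um stations
  expect_equal(cl$s_um, seq(0, 33500, by = 100))
  r <- sqrt(rowSums(cl$points[, 1:2]^2))
  expect_equal(r, rep(2000, 336), tolerance = 1e-9)
  # chord between consecutive points ~ arc step (within chord-vs-arc error)
  chords <- sqrt(rowSums(diff(cl$points)^2))
  expect_true(all(abs(chords - 100) / 100 < 0.01))

  # a genuinely winding spiral: station spacing still within 1% of the step
  sp <- spiral_fit(center = c(0, 0, 0), axis = c(0, 0, 1),
                   radius_scale_a = 1000, growth_rate_b = 0.05,
                   pitch = 150, theta_range = c(0, 7 * pi))
  cl2 <- centerline(sp, step_um = 100)
  chords2 <- sqrt(rowSums(diff(cl2$points)^2))
  expect_true(all(abs(chords2 - 100) / 100 < 0.01))
  # trapezoid oracle on densely sampled points matches the arc-length table
  th <- seq(0, 7 * pi, length.out = 200001)
  pts <- cochleaPK:::spiral_points(sp, th)
  oracle_mm <- sum(sqrt(rowSums(diff(pts)^2))) / 1000
  expect_equal(spiral_arc_length(sp), oracle_mm, tolerance = 1e-5)
  expect_equal(nrow(cl2$points), floor(oracle_mm * 1000 / 100) + 1)
})

test_that("noiseless point fixture is fitted to sub-voxel residual", {
  sp <- small_spec()
  f0 <- cochleaPK:::spec_spiral(sp, center = c(2000, 2000, 500))
  th <- seq(0, 2 * pi * sp$turns, length.out = 300)
  pts <- cochleaPK:::spiral_points(f0, th)
  arr <- array(FALSE, c(170, 170, 100))
  arr[round(pts / 25) + 1] <- TRUE
  m <- voxel_mask(arr, 25, check_connectivity = FALSE)
  fit <- fit_spiral(m)
  expect_lt(fit$rms_residual, 25)
  expect_equal(fit$growth_rate_b, sp$b, tolerance = 0.05)
})

test_that("straight tubes and empty masks are rejected", {
  arr <- array(FALSE, c(20, 20, 60))
  disc <- outer(1:20, 1:20, function(i, j) (i - 10)^2 + (j - 10)^2 <= 36)
  for (k in 1:60) arr[, , k] <- disc
  m <- voxel_mask(arr, 25)
  expect_error(fit_spiral(m), class = "degenerate_geometry")
  expect_error(voxel_mask(array(FALSE, c(3, 3, 3)), 10), class = "empty_mask")
})

test_that("synthetic phantom parameters are recovered within 5%", {
  sp <- small_spec()
  fit <- small_fit()
  expect_lt(abs(fit$radius_scale_a / sp$a_um - 1), 0.05)
  expect_lt(abs(fit$growth_rate_b / sp$b - 1), 0.05)
  expect_lt(abs(abs(fit$pitch) / sp$pitch_um_per_rad - 1), 0.05)
  expect_gt(diff(fit$theta_range) / (2 * pi), sp$turns * 0.95)
})

test_that("cross-section areas track the analytic taper within 5%", {
  gen <- small_phantom()
  prof <- small_profile()
  truth <- gen$truth_profile
  ref <- approx(truth$distance_mm, truth$area_mm2,
                xout = prof$distance_mm, rule = 2)$y
  relerr <- abs(prof$area_mm2 / ref - 1)
  expect_lt(mean(relerr), 0.05)
  # basal-wide taper: profile starts at the wide end and trends downward
  expect_gt(mean(head(prof$area_mm2, 10)), mean(tail(prof$area_mm2, 10)))
  expect_lt(abs(prof$area_mm2[1] / truth$area_mm2[1] - 1), 0.05)
})

test_that("constant-radius tube yields constant areas within 5%", {
  sp <- synthetic_cochlea_spec(a_um = 600, b = 0.05, pitch_um_per_rad = 90,
                               turns = 2.2, basal_radius_um = 150,
                               apical_radius_um = 150, voxel_size_um = 15)
  gen <- make_cochlea_mask(sp)
  prof <- cross_section_areas(gen$mask, gen$truth_fit)
  expect_true(all(abs(prof$area_mm2 / (pi * 0.15^2) - 1) < 0.05))
})

test_that("perpendicular slicing beats axis-aligned counts on oblique tubes", {
  # gently curved tube whose tangent is oblique to all voxel planes
  fit <- spiral_fit(center = c(10000, 10000, 2000), axis = c(0, 0, 1),
                    radius_scale_a = 8000, growth_rate_b = 0,
                    pitch = 5000, theta_range = c(0.2, 1.0))
  tab <- cochleaPK:::spiral_arclength_table(fit)
  s_dense <- seq(0, max(tab$s), by = 12)
  th <- approx(tab$s, tab$theta, xout = s_dense)$y
  pts <- cochleaPK:::spiral_points(fit, th)
  lo <- apply(pts, 2, min) - 400; hi <- apply(pts, 2, max) + 400
  dims <- as.integer(ceiling((hi - lo) / 25)) + 1L
  loc <- sweep(pts, 2, lo)
  vx <- cochleaPK:::.voxelize_tube(loc, rep(300, nrow(loc)), c(0, 0, 0), 25, dims)
  m <- voxel_mask(array(vx, dims), 25, check_connectivity = FALSE)
  fit_loc <- fit; fit_loc$center <- fit$center - lo
  prof <- cross_section_areas(m, fit_loc)
  mid <- prof$area_mm2[seq(5, nrow(prof) - 5)]
  expect_true(all(abs(mid / (pi * 0.3^2) - 1) < 0.05))

  # axis-aligned plane counts through a mid point are all larger
  p_mid <- cochleaPK:::spiral_points(fit_loc, median(th))
  idx <- round(p_mid / 25) + 1
  slice_area <- function(plane) {
    sl <- switch(plane,
                 x = m$voxels[idx[1], , ],
                 y = m$voxels[, idx[2], ],
                 z = m$voxels[, , idx[3]])
    lab <- cochleaPK:::.label_components_2d(sl)
    ij <- switch(plane, x = idx[2:3], y = idx[c(1, 3)], z = idx[1:2])
    sum(lab == lab[ij[1], ij[2]]) * (25 / 1000)^2
  }
  perp <- pi * 0.3^2
  for (pl in c("x", "y", "z")) expect_gt(slice_area(pl), perp * 1.05)
})

test_that("profile volume agrees with voxel counting within 10%", {
  gen <- small_phantom()
  prof <- small_profile()
  expect_equal(volume_from_profile(prof), mask_volume(gen$mask),
               tolerance = 0.10)
})
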