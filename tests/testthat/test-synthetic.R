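test_that("default phantom spec reproduces the porcine arc length", {
  sp <- synthetic_cochlea_spec()
  f0 <- cochleaPK:::spec_spiral(sp)
  expect_equal(spiral_arc_length(f0), 33.5, tolerance = 0.02)
  expect_equal(sp$turns, 3.5)
})

test_that("phantom generation is deterministic and validates resolution", {
  sp <- small_spec()
  g1 <- make_cochlea_mask(sp)
  g2 <- make_cochlea_mask(sp)
  expect_identical(g1$mask$voxels, g2$mask$voxels)
  expect_error(synthetic_cochlea_spec(apical_radius_um = 60,
                                      voxel_size_um = 25),
               class = "resolution_error")
  expect_error(synthetic_cochlea_spec(basal_radius_um = 100,
                                      apical_radius_um = 200),
               class = "invalid_params")
})

test_that("equal end radii give a constant analytic profile", {
  sp <- synthetic_cochlea_spec(basal_radius_um = 200, apical_radius_um = 200,
                               voxel_size_um = 40)
  gen <- make_cochlea_mask(sp)
  expect_equal(gen$truth_profile$area_mm2,
               rep(pi * 0.2^2, nrow(gen$truth_profile)))
})

test_that("truth profile matches the tube taper analytically", {
  gen <- small_phantom()
  tp <- gen$truth_profile
  sp <- small_spec()
  expect_equal(tp$area_mm2[1], pi * (sp$basal_radius_um / 1000)^2)
  # last station sits up to one step short of the apical tip
  expect_equal(tail(tp$area_mm2, 1), pi * (sp$apical_radius_um / 1000)^2,
               tolerance = 5e-3)
  expect_true(all(diff(tp$area_mm2) < 0))
})

test_that("default species profiles have the published lengths", {
  p <- make_default_profiles()
  expect_equal(max(p$pig$distance_mm), 33.5)
  expect_equal(max(p$human$distance_mm), 29)
  v <- c(volume_from_profile(p$pig), volume_from_profile(p$human))
  expect_lt(max(v) / min(v), 2)  # species volumes of the same order
  # shipped CSV fixtures are the same profiles
  pig_csv <- read_area_profile(system.file("extdata",
                                           "pig_st_profile_synthetic.csv",
                                           package = "cochleaPK"))
  expect_equal(pig_csv$area_mm2, p$pig$area_mm2, tolerance = 1e-9)
})

test_that("measurement noise honours the requested CV and seed", {
  expect_equal(simulate_measurements(2.5, 7, cv = 0), rep(2.5, 7))
  x <- simulate_measurements(1, 1e5, cv = 0.5, seed = 42)
  expect_equal(sd(x) / mean(x), 0.5, tolerance = 0.02)
  expect_equal(mean(x), 1, tolerance = 0.02)
  y <- simulate_measurements(1, 1e5, cv = 0.5, seed = 42)
  expect_identical(x, y)
  z <- simulate_measurements(1, 100, cv = 0.5, seed = 43)
  expect_false(identical(x[1:100], z))
})
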