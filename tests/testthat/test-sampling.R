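test_that("uniform fields give identical tubes and pools", {
  prof <- uniform_profile(30)  # 30 uL column
  s <- sequential_sample(prof, rep(4.2, nrow(prof)))
  expect_equal(s$per_tube_conc, rep(4.2, 5), tolerance = 1e-10)
  expect_equal(unname(compare_pools(s)), c(4.2, 4.2), tolerance = 1e-10)
})

test_that("a basal step profile is drawn tube by tube", {
  prof <- uniform_profile(30)  # area 1 mm2: 1 mm of length = 1 uL
  conc <- ifelse(prof$distance_mm <= 10, 10, 0)
  s <- sequential_sample(prof, conc)
  expect_equal(s$per_tube_conc[1:2], c(10, 10), tolerance = 1e-6)
  # tube 3 catches only the interpolation ramp between the 10.0 and 10.1 mm
  # stations: 0.1 uL at mean 5 ug/mL spread over 5 uL = 0.1 ug/mL
  expect_equal(s$per_tube_conc[3], 0.1, tolerance = 1e-6)
  expect_equal(s$per_tube_conc[4:5], c(0, 0), tolerance = 1e-9)
})

test_that("basally decreasing gradients give non-increasing tubes", {
  prof <- uniform_profile(30)
  conc <- exp(-prof$distance_mm / 3)
  s <- sequential_sample(prof, conc)
  expect_true(all(diff(s$per_tube_conc) <= 1e-12))
})

test_that("linear gradient pools match hand-computed weighted means", {
  prof <- uniform_profile(30)
  conc <- 1 - prof$distance_mm / 30
  s <- sequential_sample(prof, conc)
  # tube k spans x in [5(k-1), 5k] mm; mean of the linear field there
  hand <- 1 - (5 * seq_len(5) - 2.5) / 30
  expect_equal(s$per_tube_conc, hand, tolerance = 1e-6)
  pools <- compare_pools(s, list(1, 2:5))
  expect_equal(unname(pools), c(hand[1], mean(hand[2:5])), tolerance = 1e-6)
})

test_that("draws beyond the column return CSF or fail, by replacement mode", {
  prof <- uniform_profile(20)  # 20 uL
  conc <- rep(3, nrow(prof))
  s <- sequential_sample(prof, conc, replacement = "csf_zero")
  expect_equal(s$per_tube_conc, c(3, 3, 3, 3, 0), tolerance = 1e-9)
  expect_error(sequential_sample(prof, conc, replacement = "none"),
               class = "insufficient_volume")
  within <- sequential_sample(prof, conc, sampling_protocol(5, 4, list(1:4)),
                              replacement = "none")
  expect_equal(within$per_tube_conc, rep(3, 4), tolerance = 1e-9)
})

test_that("volume and mass bookkeeping are exact", {
  prof <- make_default_profiles()$pig
  conc <- 10 * exp(-prof$distance_mm / 2)
  proto <- sampling_protocol()
  s <- sequential_sample(prof, conc, proto)
  # total drawn volume is exactly n_tubes x tube_volume
  expect_equal(proto$n_tubes * proto$tube_volume_uL, 25)
  # sum of tube masses equals the mass removed from the column
  tube_mass <- sum(s$per_tube_conc * proto$tube_volume_uL) / 1000
  expect_equal(tube_mass, s$column_mass_ug, tolerance = 1e-10)
  # pooling all tubes equals the weighted mean of the drawn column,
  # independent of partition
  all_pool <- compare_pools(s, list(1:5))
  expect_equal(unname(all_pool),
               s$column_mass_ug * 1000 / 25, tolerance = 1e-10)
  p2 <- compare_pools(s, list(c(1, 3, 5), c(2, 4)))
  expect_equal(mean(s$per_tube_conc[c(1, 3, 5)]), unname(p2[1]))
  expect_error(compare_pools(s, list(1, 2:6)), class = "invalid_params")
})
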