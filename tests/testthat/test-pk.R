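test_that("middle-ear kinetics follow first-order decay", {
  dose <- dose_protocol(100)
  dhalf <- drug_params("x", 4.4e-6, 1e-7, k_me_per_h = log(2))
  expect_equal(middle_ear_concentration(0, dose, dhalf), 100)
  expect_equal(middle_ear_concentration(60, dose, dhalf), 50)
  dzero <- drug_params("x", 4.4e-6, 1e-7, k_me_per_h = 0)
  expect_equal(middle_ear_concentration(c(0, 90, 1e4), dose, dzero),
               rep(100, 3))
})

test_that("RWM flux converts permeability units correctly", {
  geom <- cochlear_geometry(uniform_profile(), rwm_area_mm2 = 2)
  dex <- drug_params("dex", 4.4e-6, 123e-9)
  # hand conversion: 123e-9 m/s * 2 mm2 = 2.46e-13 m3/s = 2.46e-7 mL/s;
  # x 100 ug/mL x 60 s/min = 1.476e-3 ug/min
  expect_equal(rwm_flux(100, 0, dex, geom), 1.476e-3, tolerance = 1e-12)
  expect_equal(rwm_flux(50, 50, dex, geom), 0)
  d2 <- dex; d2$P_rwm_m_s <- 2 * dex$P_rwm_m_s
  expect_equal(rwm_flux(100, 30, d2, geom), 2 * rwm_flux(100, 30, dex, geom))
  expect_lt(rwm_flux(0, 30, dex, geom), 0)  # back-diffusion
})

test_that("sealed tube conserves a uniform field to machine precision", {
  geom <- cochlear_geometry(uniform_profile(10))
  d <- drug_params("x", 4.4e-6, 0, k_me_per_h = 0, k_elim_per_h = 0)
  # 1000 steps at the default half-second step
  res <- simulate_transport(geom, d, dose_protocol(0),
                            t_end_min = 1000 / 120,
                            C_init = matrix(5, 100, 1))
  expect_true(all(abs(res$C[[1]] - 5) < 5e-10))
  expect_equal(sum(res$C[[1]][, ncol(res$C[[1]])] * res$V_mm3),
               sum(5 * res$V_mm3), tolerance = 1e-10)
})

test_that("zero permeability and clean perilymph stay at zero", {
  geom <- cochlear_geometry(uniform_profile(10))
  d <- drug_params("x", 4.4e-6, 0)
  res <- simulate_transport(geom, d, dose_protocol(100), t_end_min = 10)
  expect_true(all(res$C[[1]] == 0))
})

test_that("diffusion from a held basal concentration matches erfc within 1%", {
  # near-Dirichlet boundary: very large permeability pins the basal cell at
  # the (constant) source concentration
  prof <- uniform_profile(20, 0.785, dx = 0.05)
  geom <- cochlear_geometry(prof, rwm_area_mm2 = 0.785)
  d <- drug_params("x", 4.4e-6, 1, k_me_per_h = 0, k_elim_per_h = 0)
  res <- simulate_transport(geom, d, dose_protocol(100), dx_mm = 0.05,
                            t_end_min = 30)
  D <- 4.4e-6 * 6000  # mm2/min
  x <- res$x_mm
  got <- res$C[[1]][, which(res$t_min == 30)]
  ana <- 100 * erfc_ref((x - x[1]) / (2 * sqrt(D * 30)))
  sel <- ana > 5  # interior points with non-vanishing signal
  expect_lt(max(abs(got[sel] - ana[sel]) / ana[sel]), 0.01)
})

test_that("mass audit closes to 1e-6 on a full dosing run", {
  res <- dex_run_30()
  expect_lt(res$audit$residual_rel, 1e-6)
  a <- res$audit
  expect_equal(a$mass_end_ug - a$mass0_ug,
               a$influx_ug - a$returned_ug - a$eliminated_ug - a$washout_ug,
               tolerance = 1e-9)
})

test_that("the model is linear in the source concentration", {
  geom <- pig_geom()
  r1 <- dex_run_30()
  r2 <- simulate_transport(geom, dex_default(),
                           dose_protocol(370, t_end_min = 30))
  expect_equal(r2$C[[1]], 3.7 * r1$C[[1]], tolerance = 1e-10)
})

test_that("early whole-ST content matches the small-flux closed form", {
  geom <- pig_geom()
  d <- drug_params("dex", 4.4e-6, 123e-9, k_me_per_h = 0, k_elim_per_h = 0)
  res <- simulate_transport(geom, d, dose_protocol(100, t_end_min = 1))
  V_uL <- sum(res$V_mm3)
  mass_pred_ug <- 60 * 123e-9 * 2 * 100 * 1      # P*A*Cme*t
  mean_pred <- mass_pred_ug / V_uL * 1000         # ug/mL
  expect_equal(whole_st_mean(res, 1), mean_pred, tolerance = 0.15)
})

test_that("hydrolysis limits bracket the two-species model", {
  geom <- pig_geom()
  dose <- dose_protocol(4000, t_end_min = 30)
  dsp <- dsp_default(); dex <- dex_default()
  # k_hyd = 0: parent behaves exactly like the single-species run
  two <- simulate_transport(geom, list(dsp, dex), dose)
  one <- dsp_run_30()
  expect_equal(two$C$dsp, one$C$dsp, tolerance = 1e-12)
  expect_true(all(two$C$dex == 0))
  # large k_hyd converges to the pre-converted all-hydrolysis run
  fast <- dsp; fast$k_hydrolysis_per_h <- 400
  two_fast <- simulate_transport(geom, list(fast, dex), dose)
  allh <- simulate_transport(geom, list(dsp, dex), dose, hydrolysis = "all")
  expect_equal(whole_st_mean(two_fast, 30, "dex"),
               whole_st_mean(allh, 30, "dex"), tolerance = 0.05)
  expect_equal(concentration_at(two_fast, 1, 30, "dex"),
               concentration_at(allh, 1, 30, "dex"), tolerance = 0.05)
  # conversion is mass-1:1: parent loss equals product gain in the audit
  expect_equal(two_fast$audit$hydrolysed_ug[1],
               two_fast$audit$hydrolysed_ug[2], tolerance = 1e-12)
})

test_that("halving the grid step changes the 30-min mean by < 1%", {
  geom <- pig_geom()
  r1 <- dex_run_30()
  r2 <- simulate_transport(geom, dex_default(),
                           dose_protocol(100, t_end_min = 30), dx_mm = 0.05)
  expect_equal(whole_st_mean(r2, 30), whole_st_mean(r1, 30), tolerance = 0.01)
})

test_that("field summaries interpolate and volume-average correctly", {
  fk <- fake_result()
  expect_equal(whole_st_mean(fk, 0), 2)             # (3*2 + 0*1) / 3
  expect_equal(concentration_at(fk, 0.5, 0), 3)     # stored value exactly
  expect_equal(concentration_at(fk, 1.0, 5), 1.5)   # midpoint = mean
  expect_error(concentration_at(fk, 0.5, 99), class = "out_of_range")
  expect_error(concentration_at(fk, 50, 0), class = "out_of_range")
  res <- dex_run_30()
  expect_equal(concentration_at(res, res$x_mm[1], 30), res$C[[1]][1, 31])
  u <- simulate_transport(cochlear_geometry(uniform_profile(10)),
                          drug_params("x", 4.4e-6, 0, k_me_per_h = 0,
                                      k_elim_per_h = 0),
                          dose_protocol(0), t_end_min = 1,
                          C_init = matrix(7, 100, 1))
  expect_equal(whole_st_mean(u, 1), 7, tolerance = 1e-12)
})

test_that("explicit stepping guards the diffusive stability limit", {
  geom <- cochlear_geometry(uniform_profile(10))
  d <- drug_params("x", 4.4e-6, 1e-7)
  expect_error(simulate_transport(geom, d, dose_protocol(100),
                                  t_end_min = 10, dt_s = 60,
                                  method = "explicit"),
               class = "stability_error")
  ok <- simulate_transport(geom, d, dose_protocol(100), t_end_min = 2,
                           dt_s = 0.2, method = "explicit")
  ref <- simulate_transport(geom, d, dose_protocol(100), t_end_min = 2,
                            dt_s = 0.2)
  expect_equal(whole_st_mean(ok, 2), whole_st_mean(ref, 2), tolerance = 1e-3)
})

test_that("aqueduct inflow washes a sealed column toward zero", {
  geom <- cochlear_geometry(uniform_profile(10), aqueduct_flow_nL_s = 50)
  d <- drug_params("x", 4.4e-6, 0, k_me_per_h = 0, k_elim_per_h = 0)
  res <- simulate_transport(geom, d, dose_protocol(0), t_end_min = 60,
                            C_init = matrix(5, 100, 1))
  cend <- res$C[[1]][, ncol(res$C[[1]])]
  expect_true(all(cend >= 0))
  expect_lt(sum(cend * res$V_mm3), sum(5 * res$V_mm3))
  expect_lt(res$audit$residual_rel, 1e-6)
  # basal cells see fresh CSF first
  expect_lt(cend[1], cend[length(cend)])
})

test_that("DSP dosing predicts more drug in the scala than Dex dosing", {
  r_dex <- dex_run_30()
  r_dsp <- dsp_run_30()
  expect_gt(whole_st_mean(r_dsp, 30), whole_st_mean(r_dex, 30))
  expect_gt(concentration_at(r_dsp, 1, 30), concentration_at(r_dex, 1, 30))
})

test_that("apex arrival time scales as length squared on uniform tubes", {
  d <- drug_params("x", 4.4e-6, 1e-4, k_me_per_h = 0, k_elim_per_h = 0)
  t1 <- time_to_apex(cochlear_geometry(uniform_profile(8)), d,
                     dose_protocol(100), dt_min = 0.1, max_days = 3)
  t2 <- time_to_apex(cochlear_geometry(uniform_profile(16)), d,
                     dose_protocol(100), dt_min = 0.1, max_days = 3)
  expect_equal(t2 / t1, 4, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("unreachable apex is reported, not raised", {
  d <- drug_params("x", 4.4e-6, 1e-9, k_me_per_h = 0, k_elim_per_h = 0)
  expect_warning(
    t1 <- time_to_apex(cochlear_geometry(uniform_profile(30)), d,
                       dose_protocol(100), max_days = 0.01, dt_min = 0.1),
    class = "not_reached")
  expect_true(is.na(t1))
  expect_false(attr(t1, "reached"))
})
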