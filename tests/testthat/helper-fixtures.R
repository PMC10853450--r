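# shared fixtures; heavyweight objects are generated once and cached
.fx <- new.env()

small_spec <- function() {
  synthetic_cochlea_spec(a_um = 600, b = 0.05, pitch_um_per_rad = 90,
                         turns = 3.5, basal_radius_um = 180,
                         apical_radius_um = 120, voxel_size_um = 25)
}

small_phantom <- function() {
  if (is.null(.fx$ph)) .fx$ph <- make_cochlea_mask(small_spec())
  .fx$ph
}

small_fit <- function() {
  if (is.null(.fx$fit)) .fx$fit <- fit_spiral(small_phantom()$mask)
  .fx$fit
}

small_profile <- function() {
  if (is.null(.fx$prof))
    .fx$prof <- cross_section_areas(small_phantom()$mask, small_fit())
  .fx$prof
}

uniform_profile <- function(L = 30, A = 1, dx = 0.1) {
  x <- seq(0, L, by = dx)
  area_profile(x, rep(A, length(x)), source = "synthetic")
}

pig_geom <- function() {
  if (is.null(.fx$pig)) .fx$pig <- cochlear_geometry(make_default_profiles()$pig)
  .fx$pig
}

dex_default <- function() default_drugs()$dex
dsp_default <- function() default_drugs()$dsp

dex_run_30 <- function() {
  if (is.null(.fx$dex30))
    .fx$dex30 <- simulate_transport(pig_geom(), dex_default(),
                                    dose_protocol(100, t_end_min = 30))
  .fx$dex30
}

dsp_run_30 <- function() {
  if (is.null(.fx$dsp30))
    .fx$dsp30 <- simulate_transport(pig_geom(), dsp_default(),
                                    dose_protocol(4000, t_end_min = 30))
  .fx$dsp30
}

# complementary error function from the normal CDF (independent of solver)
erfc_ref <- function(x) 2 * pnorm(-sqrt(2) * x)

# hand-built two-cell result for interpolation / averaging identities
fake_result <- function() {
  structure(list(x_mm = c(0.5, 1.5), t_min = c(0, 10),
                 C = list(a = matrix(c(3, 0, 3, 0), 2, 2)),
                 C_me = c(0, 0), V_mm3 = c(2, 1), species = "a",
                 trace = NULL, audit = list(residual_rel = 0),
                 params = list()),
            class = "sim_result")
}
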