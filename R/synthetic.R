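#' Specification of a synthetic cochlea phantom
#'
#' Defines a spiral-wound tapered tube emulating a scala tympani: a
#' logarithmic spiral centerline (planar radius a e^{b theta}, axial advance
#' `pitch` per radian, `turns` full turns) swept with a tube whose radius
#' tapers linearly in arc length from `basal_radius_um` to
#' `apical_radius_um`. The defaults give a centerline arc length of ~33.5 mm
#' over 3.5 turns, the porcine scala tympani scale.
#'
#' @param a_um planar spiral radius at the basal end (theta = 0), µm.
#' @param b logarithmic growth rate per radian.
#' @param pitch_um_per_rad axial advance per radian, µm.
#' @param turns number of turns (> 1).
#' @param basal_radius_um,apical_radius_um tube radii at the two ends,
#'   basal >= apical > 0.
#' @param voxel_size_um isotropic voxel size; must not exceed
#'   `apical_radius_um / 4` so the narrow end stays resolvable.
#' @param seed stored for provenance (the phantom itself is deterministic).
#' @return an object of class `synthetic_cochlea_spec`.
#' @export
synthetic_cochlea_spec <- function(a_um = 1010, b = 0.035,
                                   pitch_um_per_rad = 160, turns = 3.5,
                                   basal_radius_um = 450,
                                   apical_radius_um = 200,
                                   voxel_size_um = 20, seed = 1L) {
  if (apical_radius_um <= 0 || basal_radius_um < apical_radius_um)
    pk_stop("invalid_params", "need basal_radius >= apical_radius > 0")
  if (turns <= 1) pk_stop("invalid_params", "need more than one turn")
  if (voxel_size_um > apical_radius_um / 4)
    pk_stop("resolution_error",
            "voxel size must be <= apical_radius_um / 4")
  structure(list(a_um = a_um, b = b, pitch_um_per_rad = pitch_um_per_rad,
                 turns = turns, basal_radius_um = basal_radius_um,
                 apical_radius_um = apical_radius_um,
                 voxel_size_um = voxel_size_um, seed = seed),
            class = "synthetic_cochlea_spec")
}

# analytic spiral_fit corresponding to a spec (centered to fit its bounding
# box with a margin; returned as ground truth)
spec_spiral <- function(spec, center = c(0, 0, 0)) {
  spiral_fit(center = center, axis = c(0, 0, 1),
             radius_scale_a = spec$a_um, growth_rate_b = spec$b,
             pitch = spec$pitch_um_per_rad,
             theta_range = c(0, 2 * pi * spec$turns),
             ref_dir = c(1, 0, 0))
}

#' Generate a voxelized synthetic cochlea with ground truth
#'
#' Voxelizes the tube described by `spec` (a voxel is foreground when its
#' center lies within the local tube radius of the centerline) and returns
#' the mask together with the exact spiral parameters and the analytic area
#' profile, for use as oracles in geometry validation.
#'
#' @param spec a [synthetic_cochlea_spec()].
#' @param profile_step_um station spacing of the analytic area profile.
#' @return a list with `mask` ([voxel_mask()]), `truth_fit` ([spiral_fit()]
#'   in the mask's µm coordinate frame), and `truth_profile`
#'   ([area_profile()]: distance from the basal end vs pi r(s)²).
#' @export
make_cochlea_mask <- function(spec, profile_step_um = 100) {
  stopifnot(inherits(spec, "synthetic_cochlea_spec"))
  vox <- spec$voxel_size_um
  f0 <- spec_spiral(spec)
  tab <- spiral_arclength_table(f0)
  S <- tab$s[length(tab$s)]

  # dense sweep samples (spacing <= voxel/2) with linearly tapering radius
  s_dense <- seq(0, S, by = vox / 2)
  th <- approx(tab$s, tab$theta, xout = s_dense)$y
  pts <- spiral_points(f0, th)
  radius <- spec$basal_radius_um +
    (spec$apical_radius_um - spec$basal_radius_um) * s_dense / S

  rmax <- max(radius)
  lo <- apply(pts, 2, min) - rmax - 2 * vox
  hi <- apply(pts, 2, max) + rmax + 2 * vox
  dims <- as.integer(ceiling((hi - lo) / vox)) + 1L
  # shift so voxel (1,1,1) center sits at coordinate 0 in the mask frame
  offset <- lo
  pts_local <- sweep(pts, 2, offset)
  vx <- .voxelize_tube(pts_local, radius, c(0, 0, 0), vox, dims)
  mask <- voxel_mask(array(vx, dims), vox, check_connectivity = FALSE)

  truth_fit <- f0
  truth_fit$center <- f0$center - offset
  s_prof <- seq(0, S, by = profile_step_um)
  r_prof <- spec$basal_radius_um +
    (spec$apical_radius_um - spec$basal_radius_um) * s_prof / S
  truth_profile <- area_profile(s_prof / 1000, pi * (r_prof / 1000)^2,
                                source = "synthetic")
  list(mask = mask, truth_fit = truth_fit, truth_profile = truth_profile)
}

#' Default scala tympani area profiles for pig and human
#'
#' Analytic log-linear tapers standing in for species geometry when no
#' segmented volume is available: porcine length 33.5 mm (3.5 turns) tapering
#' from 2.2 to 0.4 mm², human length 29 mm from 2.0 to 0.36 mm², stations
#' every 0.1 mm. These are approximate composites at the species scale, not
#' measurements of an individual ear; the same profiles ship as CSV under
#' `inst/extdata/`.
#'
#' @return a list with `pig` and `human` [area_profile()]s.
#' @export
make_default_profiles <- function() {
  mk <- function(L, A0, A1) {
    x <- seq(0, L, by = 0.1)
    area_profile(x, A0 * (A1 / A0)^(x / L), source = "synthetic")
  }
  list(pig = mk(33.5, 2.2, 0.4), human = mk(29, 2.0, 0.36))
}

#' Simulate noisy perilymph concentration measurements
#'
#' Multiplicative log-normal noise around a true concentration, with the
#' requested coefficient of variation; emulates the order-of-magnitude
#' animal-to-animal spread seen in perilymph assays. The mean of the
#' generating distribution equals `true_conc`.
#'
#' @param true_conc true concentration, µg/mL.
#' @param n_animals number of simulated animals.
#' @param cv coefficient of variation (sd/mean) of the noise, >= 0.
#' @param seed RNG seed.
#' @return numeric vector of length `n_animals`.
#' @export
simulate_measurements <- function(true_conc, n_animals, cv, seed = 1L) {
  if (cv < 0) pk_stop("invalid_params", "cv must be >= 0")
  if (cv == 0) return(rep(true_conc, n_animals))
  sdlog <- sqrt(log(1 + cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rlnorm(n_animals, meanlog = log(true_conc) - sdlog^2 / 2, sdlog = sdlog)
}
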