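#' Sequential perilymph sampling protocol
#'
#' Describes successive capillary draws from the round window: tube volume,
#' number of tubes, and how tubes are pooled for assay. The default mirrors
#' the porcine protocol of five 5-µL microhematocrit tubes with the first
#' tube reported separately from the pooled remaining four.
#'
#' @param tube_volume_uL volume of each capillary tube, µL.
#' @param n_tubes number of sequential tubes.
#' @param pooling list of integer vectors partitioning `1:n_tubes` into
#'   reported samples.
#' @return an object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(tube_volume_uL = 5, n_tubes = 5,
                              pooling = list(1, 2:5)) {
  if (tube_volume_uL <= 0) pk_stop("invalid_params", "tube volume must be > 0")
  if (n_tubes < 1) pk_stop("invalid_params", "need at least one tube")
  if (!setequal(unlist(pooling), seq_len(n_tubes)))
    pk_stop("invalid_params", "pooling must partition the tubes")
  structure(list(tube_volume_uL = tube_volume_uL, n_tubes = n_tubes,
                 pooling = pooling),
            class = "sampling_protocol")
}

#' Simulate sequential capillary draws from the basal end
#'
#' Draws are quasi-static: each tube removes the next contiguous slice of
#' the perilymph column, counted in cumulative volume from the base, so
#' successive tubes pull progressively more apical fluid toward the round
#' window. With `replacement = "csf_zero"` the column is refilled apically
#' with zero-concentration cerebrospinal fluid through the aqueduct, so
#' draws beyond the scala volume return CSF; with `"none"` the draws must
#' fit within the available perilymph.
#'
#' @param profile an [area_profile()].
#' @param conc_vs_x perilymph concentration at the sampling time: a numeric
#'   vector on the profile grid (µg/mL), e.g. a column of a
#'   [simulate_transport()] field interpolated onto `profile$distance_mm`.
#' @param protocol a [sampling_protocol()].
#' @param replacement `"csf_zero"` (default) or `"none"`.
#' @return an object of class `sample_set`: list with `per_tube_conc`,
#'   `pooled_conc`, `tube_volume_uL`, `pooling`, and `column_mass_ug` (mass
#'   removed from the column, for bookkeeping checks).
#' @export
sequential_sample <- function(profile, conc_vs_x, protocol = sampling_protocol(),
                              replacement = c("csf_zero", "none")) {
  replacement <- match.arg(replacement)
  x <- profile$distance_mm
  A <- profile$area_mm2
  if (length(conc_vs_x) != length(x))
    pk_stop("invalid_params", "conc_vs_x must be defined on the profile grid")
  if (any(conc_vs_x < 0))
    pk_stop("invalid_params", "concentrations must be non-negative")

  V_total <- volume_from_profile(profile)
  V_draw <- protocol$n_tubes * protocol$tube_volume_uL
  if (replacement == "none" && V_draw > V_total + 1e-12)
    pk_stop("insufficient_volume", sprintf(
      "draws (%.1f uL) exceed the perilymph column (%.2f uL)", V_draw, V_total))

  # refine to small slabs; A and C linear within each slab, integrals exact
  # for the piecewise-linear interpolant
  xf <- unique(sort(c(x, seq(min(x), max(x), length.out = 20000))))
  Af <- approx(x, A, xout = xf)$y
  Cf <- approx(x, conc_vs_x, xout = xf)$y
  dxf <- diff(xf)
  v_slab <- dxf * (head(Af, -1) + tail(Af, -1)) / 2
  # integral of A*C over a slab with A, C linear (product quadratic -> Simpson)
  m_slab <- dxf * ((head(Af, -1) * head(Cf, -1) + tail(Af, -1) * tail(Cf, -1)) / 3 +
                     (head(Af, -1) * tail(Cf, -1) + tail(Af, -1) * head(Cf, -1)) / 6)

  v_all <- c(v_slab, Inf)          # trailing CSF (zero concentration)
  m_all <- c(m_slab, 0)
  per_tube <- numeric(protocol$n_tubes)
  mass_removed <- 0
  j <- 1L; v_left <- v_all[1]; frac_m <- m_all[1] / max(v_all[1], 1e-300)
  for (k in seq_len(protocol$n_tubes)) {
    need <- protocol$tube_volume_uL
    mass <- 0
    while (need > 0) {
      takev <- min(need, v_left)
      mass <- mass + takev * frac_m
      v_left <- v_left - takev
      need <- need - takev
      if (v_left <= 0 && j < length(v_all)) {
        j <- j + 1L
        v_left <- v_all[j]
        frac_m <- m_all[j] / max(v_all[j], 1e-300)
      }
    }
    per_tube[k] <- mass / protocol$tube_volume_uL
    mass_removed <- mass_removed + mass
  }

  pooled <- vapply(protocol$pooling, function(g) mean(per_tube[g]), 0)
  structure(list(per_tube_conc = per_tube, pooled_conc = pooled,
                 tube_volume_uL = protocol$tube_volume_uL,
                 pooling = protocol$pooling,
                 column_mass_ug = mass_removed / 1000),  # uL*ug/mL = ng
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> per-tube conc (ug/mL):",
      paste(sprintf("%.3g", x$per_tube_conc), collapse = ", "), "\n")
  cat("  pooled:", paste(sprintf("%.3g", x$pooled_conc), collapse = ", "), "\n")
  invisible(x)
}

#' Compare pooled samples
#'
#' Volume-weighted concentrations of two (or more) pools of tubes, e.g. the
#' first 5-µL tube against the pooled next four (15 µL). With tubes of equal
#' volume the pooled value is the plain mean of member tubes.
#'
#' @param set a [sequential_sample()] result.
#' @param pooling optional pooling to apply instead of the one in `set`.
#' @return named numeric vector of pooled concentrations, µg/mL.
#' @export
compare_pools <- function(set, pooling = NULL) {
  if (is.null(pooling)) pooling <- set$pooling
  nt <- length(set$per_tube_conc)
  if (any(unlist(pooling) < 1) || any(unlist(pooling) > nt))
    pk_stop("invalid_params", "pooling indexes out of range")
  out <- vapply(pooling, function(g) mean(set$per_tube_conc[g]), 0)
  names(out) <- vapply(pooling, function(g)
    sprintf("tubes_%s", paste(range(g), collapse = "-")), "")
  out
}
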