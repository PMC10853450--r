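#' Simulate drug transport in the scala tympani
#'
#' Solves the 1D tapered-tube transport model on the area profile: diffusion
#' along the duct, first-order elimination to the vasculature, entry across
#' the round window membrane at the basal boundary driven by the decaying
#' middle-ear concentration, optional prodrug dephosphorylation
#' (parent -> product, mass 1:1), and optional CSF inflow through the
#' aqueduct. Discretisation is a mass-conservative finite-volume scheme on
#' station centers with harmonic-mean face conductances; time stepping is
#' Crank-Nicolson with two damped (backward Euler) startup steps, or
#' explicit Euler on request.
#'
#' @param geom a [cochlear_geometry()].
#' @param drugs a single [drug_params()] or a list of two (parent then
#'   product; the parent's `product` field must name the second species).
#' @param dose a [dose_protocol()]; applies to the first (injected) species.
#' @param dx_mm spatial step, mm.
#' @param output_every_min interval between stored concentration fields, min.
#' @param dt_s time step, seconds.
#' @param t_end_min horizon; defaults to `dose$t_end_min`.
#' @param method `"implicit"` (default, unconditionally stable) or
#'   `"explicit"` (raises a `stability_error` if `dt_s` exceeds the diffusive
#'   limit).
#' @param hydrolysis `NULL` to use the parent drug's `k_hydrolysis_per_h`, or
#'   `"all"` for the complete-dephosphorylation limit: the source enters
#'   through the RWM with the parent's permeability but is carried in
#'   perilymph with the product's diffusion/elimination parameters (and
#'   exchanges back across the RWM with the product's permeability).
#' @param C_init optional initial concentration matrix (stations x species),
#'   µg/mL; default 0.
#' @param constant_source if `TRUE`, hold the middle-ear concentration fixed
#'   at `C_me_0` (used for diffusion-front studies).
#' @return an object of class `sim_result` with elements `x_mm`, `t_min`,
#'   `C` (named list of stations x times matrices, one per species, µg/mL),
#'   `C_me` (middle-ear trace at `t_min`), `V_mm3` (cell volumes), `trace`
#'   (per-step basal/apical concentrations), and `audit` (mass bookkeeping).
#' @examples
#' prof <- area_profile(seq(0, 30, 0.5), rep(1, 61), source = "synthetic")
#' geom <- cochlear_geometry(prof)
#' res <- simulate_transport(geom, default_drugs()$dex, dose_protocol(100),
#'                           dx_mm = 0.5, t_end_min = 30)
#' whole_st_mean(res, 30)
#' @export
simulate_transport <- function(geom, drugs, dose, dx_mm = 0.1,
                               output_every_min = 1, dt_s = 0.5,
                               t_end_min = NULL,
                               method = c("implicit", "explicit"),
                               hydrolysis = NULL, C_init = NULL,
                               constant_source = FALSE) {
  method <- match.arg(method)
  if (inherits(drugs, "drug_params")) drugs <- list(drugs)
  if (!length(drugs) %in% 1:2)
    pk_stop("invalid_params", "drugs must be one or two drug_params")
  if (length(drugs) == 2 &&
      !identical(drugs[[1]]$product, drugs[[2]]$name))
    pk_stop("invalid_params",
            "first drug's product must name the second species")
  if (is.null(t_end_min)) t_end_min <- dose$t_end_min

  prof <- geom$profile
  L <- max(prof$distance_mm)
  n <- max(2L, round(L / dx_mm))
  x <- (seq_len(n) - 0.5) * (L / n)
  A <- resample_areas(prof, x)

  all_hyd <- identical(hydrolysis, "all")
  if (all_hyd && length(drugs) != 2)
    pk_stop("invalid_params", "hydrolysis = 'all' needs parent and product")

  # the solver carries volumes in mm3 and concentrations in ug/mL
  # (= 1e-3 ug/mm3): boundary conductances scale by 1000 so that
  # dC/dt = J / V_mL; audit masses come back 1000x and are rescaled below
  hscale <- 1000

  if (all_hyd) {
    parent <- drugs[[1]]; prodsp <- drugs[[2]]
    species <- prodsp$name
    D <- cm2s_to_mm2min(prodsp$D_cm2s) * geom$dispersion_factor
    kel <- per_h_to_per_min(prodsp$k_elim_per_h)
    h_in <- hscale * rwm_conductance(parent$P_rwm_m_s, geom$rwm_area_mm2)
    h_out <- hscale * rwm_conductance(prodsp$P_rwm_m_s, geom$rwm_area_mm2)
    kme <- per_h_to_per_min(parent$k_me_per_h)
    Cme0 <- dose$C_me_0
    khyd <- 0
  } else {
    species <- vapply(drugs, function(d) d$name, "")
    D <- vapply(drugs, function(d) cm2s_to_mm2min(d$D_cm2s), 0) *
      geom$dispersion_factor
    kel <- per_h_to_per_min(vapply(drugs, function(d) d$k_elim_per_h, 0))
    h_in <- h_out <- hscale *
      rwm_conductance(vapply(drugs, function(d) d$P_rwm_m_s, 0),
                      geom$rwm_area_mm2)
    kme <- per_h_to_per_min(drugs[[1]]$k_me_per_h)
    Cme0 <- c(dose$C_me_0, if (length(drugs) == 2) 0)
    khyd <- if (length(drugs) == 2)
      per_h_to_per_min(drugs[[1]]$k_hydrolysis_per_h) else 0
  }
  if (constant_source) kme <- 0
  ns <- length(species)

  dt <- dt_s / 60
  n_steps <- max(1L, ceiling(t_end_min / dt))
  dt <- t_end_min / n_steps
  if (method == "explicit") {
    # diffusive stability limit for the explicit scheme
    Vi <- A * (L / n)
    g <- 2 * A[-n] * A[-1] / (A[-n] + A[-1]) / diff(x)
    rate <- (c(0, g) + c(g, 0)) * max(D) / Vi
    dt_max <- 2 / max(rate + max(kel))
    if (dt > dt_max)
      pk_stop("stability_error", sprintf(
        "explicit dt = %.3g min exceeds the diffusive limit %.3g min",
        dt, dt_max))
  }

  every <- max(1L, round(output_every_min / dt))
  out_steps <- unique(c(seq(0L, n_steps, by = every), n_steps))
  trace_every <- max(1L, floor(n_steps / 20000))

  if (is.null(C_init)) C_init <- matrix(0, n, ns)
  C_init <- matrix(C_init, n, ns)

  raw <- .cn_solve(x, A, D, kel, khyd, h_in, h_out, Cme0, kme,
                   nLs_to_mm3min(geom$aqueduct_flow_nL_s),
                   C_init, dt, n_steps, as.integer(out_steps),
                   method == "implicit", as.integer(trace_every))

  t_out <- out_steps * dt
  Cl <- raw$fields
  names(Cl) <- species
  for (s in seq_len(ns)) dimnames(Cl[[s]]) <- NULL

  net_hyd <- if (ns == 2) c(-raw$hydrolysed[1], raw$hydrolysed[2]) else
    rep(0, ns)
  expected <- raw$influx - raw$outflux - raw$eliminated - raw$washout + net_hyd
  got <- raw$mass_end - raw$mass0
  # normalise by the total mass turnover of the run (shared across species:
  # a pure product species has no influx of its own)
  scale <- max(sum(abs(raw$influx) + abs(raw$hydrolysed) + abs(raw$mass0)),
               .Machine$double.eps)
  audit <- list(influx_ug = raw$influx / hscale,
                returned_ug = raw$outflux / hscale,
                eliminated_ug = raw$eliminated / hscale,
                washout_ug = raw$washout / hscale,
                hydrolysed_ug = raw$hydrolysed / hscale,
                mass0_ug = raw$mass0 / hscale,
                mass_end_ug = raw$mass_end / hscale,
                residual_rel = max(abs(got - expected) / scale))
  if (audit$residual_rel > 1e-6)
    warning(sprintf("mass audit residual %.2e exceeds 1e-6", audit$residual_rel))

  structure(list(x_mm = x, t_min = t_out, C = Cl,
                 C_me = Cme0[1] * exp(-kme * t_out),
                 V_mm3 = raw$V, species = species,
                 trace = list(t_min = raw$trace_t, C_me = raw$trace_cme,
                              C_base = raw$trace_base,
                              C_apex = raw$trace_apex),
                 audit = audit,
                 params = list(geom = geom, drugs = drugs, dose = dose,
                               dx_mm = L / n, dt_min = dt, method = method,
                               hydrolysis = if (all_hyd) "all" else khyd * 60)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> species: %s | %d stations x %d times (0-%.0f min)\n",
              paste(x$species, collapse = ", "), length(x$x_mm),
              length(x$t_min), max(x$t_min)))
  cat(sprintf("  mass audit residual: %.2e (relative)\n",
              x$audit$residual_rel))
  invisible(x)
}

resolve_species <- function(result, species) {
  if (is.numeric(species)) return(as.integer(species))
  i <- match(species, result$species)
  if (is.na(i)) pk_stop("invalid_params",
                        paste("unknown species:", species))
  i
}

# field at time t (linear interpolation between stored columns)
field_at_time <- function(result, t_min, species = 1) {
  s <- resolve_species(result, species)
  tt <- result$t_min
  if (t_min < min(tt) || t_min > max(tt))
    pk_stop("out_of_range", "t_min outside the simulated range")
  Cm <- result$C[[s]]
  j <- findInterval(t_min, tt, rightmost.closed = TRUE)
  if (tt[j] == t_min) return(Cm[, j])
  w <- (t_min - tt[j]) / (tt[j + 1] - tt[j])
  (1 - w) * Cm[, j] + w * Cm[, j + 1]
}

#' Concentration at a location and time
#'
#' Linear interpolation of the stored concentration field in both x and t.
#' "ST:1" in the summary outputs is this value at x = 1 mm.
#'
#' @param result a [simulate_transport()] result.
#' @param x_mm distance from the basal end, mm.
#' @param t_min time after injection, min.
#' @param species species name or index (default first).
#' @return concentration in µg/mL.
#' @export
concentration_at <- function(result, x_mm, t_min, species = 1) {
  xs <- result$x_mm
  if (x_mm < 0 || x_mm > max(xs) + 0.5 * (xs[2] - xs[1]))
    pk_stop("out_of_range", "x_mm outside the simulated domain")
  cf <- field_at_time(result, t_min, species)
  approx(xs, cf, xout = x_mm, rule = 2)$y
}

#' Volume-weighted mean concentration over the whole scala tympani
#'
#' The "ST All" summary: sum(C_i V_i) / sum(V_i) over all stations at a
#' given time.
#'
#' @inheritParams concentration_at
#' @return mean concentration in µg/mL.
#' @export
whole_st_mean <- function(result, t_min, species = 1) {
  cf <- field_at_time(result, t_min, species)
  sum(cf * result$V_mm3) / sum(result$V_mm3)
}

#' Base-to-apex diffusion time
#'
#' Runs a pure-diffusion-front experiment: constant middle-ear source,
#' elimination switched off, and reports the first time the apical station
#' reaches `threshold_fraction` of the running maximum basal concentration.
#'
#' @param geom a [cochlear_geometry()].
#' @param drug a [drug_params()].
#' @param dose a [dose_protocol()]; only `C_me_0` matters (the front time is
#'   independent of its value, the model being linear).
#' @param threshold_fraction arrival criterion, in (0, 1); default 0.01.
#' @param max_days simulation horizon.
#' @param dt_min,dx_mm numerical resolution (front times span days, so a
#'   coarser time step than the default solver step is appropriate).
#' @return arrival time in days, with attribute `reached`. If the horizon is
#'   exceeded the value is `NA` and a `not_reached` warning is issued.
#' @export
time_to_apex <- function(geom, drug, dose, threshold_fraction = 0.01,
                         max_days = 30, dt_min = 0.5, dx_mm = 0.1) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    pk_stop("invalid_params", "threshold_fraction must be in (0, 1)")
  drug$k_elim_per_h <- 0
  drug$k_hydrolysis_per_h <- 0
  res <- simulate_transport(geom, drug, dose, dx_mm = dx_mm,
                            output_every_min = max_days * 24 * 60,
                            dt_s = dt_min * 60,
                            t_end_min = max_days * 24 * 60,
                            constant_source = TRUE)
  tr <- res$trace
  thr <- threshold_fraction * cummax(tr$C_base[, 1])
  hit <- which(tr$C_apex[, 1] >= thr & thr > 0)
  if (!length(hit)) {
    warning(structure(class = c("not_reached", "warning", "condition"),
                      list(message = sprintf(
                        "apex did not reach %.3g of basal maximum within %g days",
                        threshold_fraction, max_days), call = sys.call())))
    return(structure(NA_real_, reached = FALSE))
  }
  j <- hit[1]
  if (j == 1) return(structure(tr$t_min[1] / 1440, reached = TRUE))
  # linear interpolation of the crossing between trace points
  f0 <- tr$C_apex[j - 1, 1] - thr[j - 1]
  f1 <- tr$C_apex[j, 1] - thr[j]
  w <- if (f1 > f0) -f0 / (f1 - f0) else 1
  t_cross <- tr$t_min[j - 1] + w * (tr$t_min[j] - tr$t_min[j - 1])
  structure(t_cross / 1440, reached = TRUE)
}
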