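#' Unit conversion helpers
#'
#' The simulator works internally in mm, minutes, and µg/mL. These helpers
#' centralise the conversions from the units in which transport constants are
#' conventionally reported: diffusion coefficients in cm²/s, membrane
#' permeabilities in m/s, cerebrospinal-fluid flow in nL/s, and first-order
#' rates in 1/h.
#'
#' @param D_cm2s diffusion coefficient in cm²/s.
#' @param P_m_s permeability in m/s.
#' @param A_mm2 membrane area in mm².
#' @param rate_per_h first-order rate in 1/h.
#' @param Q_nL_s volumetric flow in nL/s.
#' @return the converted value (mm²/min, µg/min per µg/mL, 1/min, mm³/min).
#' @name units
NULL

#' @rdname units
#' @export
cm2s_to_mm2min <- function(D_cm2s) D_cm2s * 100 * 60

#' Membrane conductance in simulator units.
#'
#' For a permeability P (m/s) acting over an area A (mm²), the flux driven by
#' a concentration difference C (µg/mL) is `J = rwm_conductance(P, A) * C`
#' in µg/min: P·A = (P·6e4 mm/min)·(A mm²) gives mm³/min, and µg/mL is
#' 1e-3 µg/mm³, so the net factor is 60·P·A.
#' @rdname units
#' @export
rwm_conductance <- function(P_m_s, A_mm2) 60 * P_m_s * A_mm2

#' @rdname units
#' @export
per_h_to_per_min <- function(rate_per_h) rate_per_h / 60

#' @rdname units
#' @export
nLs_to_mm3min <- function(Q_nL_s) Q_nL_s * 1e-3 * 60
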