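#' Drug transport parameters
#'
#' Per-species transport constants for perilymph pharmacokinetics. The round
#' window membrane (RWM) permeabilities measured ex vivo in the porcine model
#' are 123e-9 m/s for dexamethasone (Dex) and 12e-9 m/s for its phosphate
#' prodrug (DSP); see [default_drugs()].
#'
#' @param name species label, e.g. `"dex"`.
#' @param D_cm2s diffusion coefficient in perilymph, cm²/s.
#' @param P_rwm_m_s RWM permeability, m/s.
#' @param k_me_per_h first-order elimination rate of drug from the middle-ear
#'   cavity, 1/h.
#' @param k_elim_per_h first-order perilymph-to-blood elimination rate, 1/h.
#' @param k_hydrolysis_per_h first-order conversion rate of this species into
#'   its product species (dephosphorylation for DSP), 1/h; 0 if none.
#' @param product label of the product species, or `NULL`.
#' @return an object of class `drug_params`.
#' @export
drug_params <- function(name, D_cm2s, P_rwm_m_s,
                        k_me_per_h = 2.0, k_elim_per_h = 2.0,
                        k_hydrolysis_per_h = 0, product = NULL) {
  if (D_cm2s <= 0) pk_stop("invalid_params", "D must be positive")
  if (P_rwm_m_s < 0 || k_me_per_h < 0 || k_elim_per_h < 0 ||
      k_hydrolysis_per_h < 0)
    pk_stop("invalid_params", "rates and permeability must be non-negative")
  structure(list(name = name, D_cm2s = D_cm2s, P_rwm_m_s = P_rwm_m_s,
                 k_me_per_h = k_me_per_h, k_elim_per_h = k_elim_per_h,
                 k_hydrolysis_per_h = k_hydrolysis_per_h, product = product),
            class = "drug_params")
}

#' Default Dex and DSP parameter sets
#'
#' Diffusion coefficients are free-solution values for small steroids;
#' permeabilities are the ex vivo porcine RWM measurements. The middle-ear
#' and perilymph elimination rates are the package defaults discussed in the
#' methods vignette; both are plain fields and can be overridden.
#'
#' @return a list with elements `dex` and `dsp` (the latter with `product =
#'   "dex"` and dephosphorylation off by default).
#' @export
default_drugs <- function() {
  list(dex = drug_params("dex", D_cm2s = 4.4e-6, P_rwm_m_s = 123e-9),
       dsp = drug_params("dsp", D_cm2s = 4.0e-6, P_rwm_m_s = 12e-9,
                         k_hydrolysis_per_h = 0, product = "dex"))
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s: D=%.2g cm2/s, P_rwm=%.3g m/s, k_me=%.2g/h, k_elim=%.2g/h",
              x$name, x$D_cm2s, x$P_rwm_m_s, x$k_me_per_h, x$k_elim_per_h))
  if (x$k_hydrolysis_per_h > 0)
    cat(sprintf(", k_hyd=%.2g/h -> %s", x$k_hydrolysis_per_h, x$product))
  cat("\n")
  invisible(x)
}

#' Intratympanic dose protocol
#'
#' @param C_me_0 initial middle-ear concentration, µg/mL (e.g. 100 for the
#'   Dex formulation, 4000 for DSP).
#' @param injected_volume_mL injected volume, mL (assumed to fill the
#'   middle-ear cavity and stay constant).
#' @param t_end_min simulation horizon, minutes.
#' @return an object of class `dose_protocol`.
#' @export
dose_protocol <- function(C_me_0, injected_volume_mL = 1, t_end_min = 300) {
  if (C_me_0 < 0) pk_stop("invalid_params", "C_me_0 must be non-negative")
  if (injected_volume_mL <= 0)
    pk_stop("invalid_params", "injected volume must be positive")
  structure(list(C_me_0 = C_me_0, injected_volume_mL = injected_volume_mL,
                 t_end_min = t_end_min),
            class = "dose_protocol")
}

#' Cochlear geometry for the 1D simulator
#'
#' @param profile an [area_profile()] describing the scala tympani.
#' @param rwm_area_mm2 round window membrane area, mm². The oval-window entry
#'   route is folded into this single basal exchange area.
#' @param aqueduct_flow_nL_s cerebrospinal-fluid inflow through the cochlear
#'   aqueduct at the basal end, nL/s; 0 (default) disables it, consistent
#'   with CSF inflow being non-substantial at rest.
#' @param dispersion_factor factor >= 1 multiplying the diffusion
#'   coefficient, modelling oscillation-enhanced mixing; 1 = molecular
#'   diffusion only.
#' @return an object of class `cochlear_geometry`.
#' @export
cochlear_geometry <- function(profile, rwm_area_mm2 = 2,
                              aqueduct_flow_nL_s = 0, dispersion_factor = 1) {
  if (!inherits(profile, "area_profile"))
    pk_stop("invalid_params", "profile must be an area_profile")
  if (rwm_area_mm2 <= 0) pk_stop("invalid_params", "rwm_area must be positive")
  if (aqueduct_flow_nL_s < 0)
    pk_stop("invalid_params", "aqueduct flow must be non-negative")
  if (dispersion_factor < 1)
    pk_stop("invalid_params", "dispersion_factor must be >= 1")
  structure(list(profile = profile, rwm_area_mm2 = rwm_area_mm2,
                 aqueduct_flow_nL_s = aqueduct_flow_nL_s,
                 dispersion_factor = dispersion_factor),
            class = "cochlear_geometry")
}

#' Middle-ear concentration over time
#'
#' Well-mixed middle-ear cavity with first-order elimination:
#' C_me(t) = C_me_0 · exp(-k_me · t).
#'
#' @param t_min time(s) after injection, minutes.
#' @param dose a [dose_protocol()].
#' @param drug a [drug_params()] (supplies `k_me_per_h`).
#' @return concentration(s) in µg/mL.
#' @export
middle_ear_concentration <- function(t_min, dose, drug) {
  if (any(t_min < 0)) pk_stop("invalid_params", "t must be non-negative")
  dose$C_me_0 * exp(-per_h_to_per_min(drug$k_me_per_h) * t_min)
}

#' Round window membrane flux
#'
#' Permeation flux across the RWM, J = P · A · (C_me - C_base), converted to
#' µg/min. Negative values mean back-diffusion into the middle ear.
#'
#' @param C_me middle-ear concentration, µg/mL.
#' @param C_base perilymph concentration at the basal station, µg/mL.
#' @param drug a [drug_params()].
#' @param geom a [cochlear_geometry()].
#' @return flux in µg/min.
#' @export
rwm_flux <- function(C_me, C_base, drug, geom) {
  if (any(C_me < 0) || any(C_base < 0))
    pk_stop("invalid_params", "concentrations must be non-negative")
  rwm_conductance(drug$P_rwm_m_s, geom$rwm_area_mm2) * (C_me - C_base)
}
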