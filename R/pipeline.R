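#' Load a pipeline configuration
#'
#' Configurations are YAML (or JSON) files with sections `geometry`, `drugs`,
#' `dose`, and optionally `solver`, `sampling`, `stages`, `seed`, `out_dir`.
#' See `system.file("extdata", "demo_config.yaml", package = "cochleaPK")`
#' for a commented example.
#'
#' @param path YAML/JSON file path, or a list already parsed.
#' @return the validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  missing <- validate_config(cfg)
  if (length(missing))
    pk_stop("config_error", paste0("config is missing required key(s): ",
                                   paste(missing, collapse = ", ")))
  cfg
}

# returns the key paths that are absent
validate_config <- function(cfg) {
  miss <- character()
  if (is.null(cfg$geometry$profile)) miss <- c(miss, "geometry.profile")
  if (is.null(cfg$drugs)) miss <- c(miss, "drugs")
  if (is.null(cfg$dose$C_me_0)) miss <- c(miss, "dose.C_me_0")
  miss
}

config_drug <- function(d) {
  if (is.character(d)) {
    dd <- default_drugs()[[d]]
    if (is.null(dd)) pk_stop("config_error", paste("unknown drug:", d))
    return(dd)
  }
  do.call(drug_params, d)
}

config_profile <- function(gcfg, voxel_size_um = NULL) {
  p <- gcfg$profile
  if (is.character(p) && p %in% c("pig", "human"))
    return(make_default_profiles()[[p]])
  if (!is.list(p))
    pk_stop("config_error",
            "geometry.profile must be 'pig', 'human', {csv: path} or {mask: path}")
  if (!is.null(p$csv)) return(read_area_profile(p$csv))
  if (!is.null(p$mask)) {
    vs <- if (!is.null(voxel_size_um)) voxel_size_um else p$voxel_size_um
    mask <- read_mask(p$mask, vs)
    return(cross_section_areas(mask, fit_spiral(mask)))
  }
  pk_stop("config_error",
          "geometry.profile must be 'pig', 'human', {csv: path} or {mask: path}")
}

#' Run the modelling pipeline from a configuration
#'
#' Executes the requested stages in order geometry -> simulate -> sample ->
#' report, writing each stage's outputs and a run manifest under `out_dir`.
#' The manifest records the config snapshot, package version, seed, input
#' file checksums, and output paths, so a run can be reproduced exactly.
#'
#' @param config a config list or a YAML path (see [read_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with the computed objects (`profile`, `result`,
#'   `samples`, `report`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  stages <- cfg$stages %||% c("geometry", "simulate", "sample", "report")
  out_dir <- out_dir %||% cfg$out_dir %||% "cochleaPK_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  set.seed(seed)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  outputs <- character()
  inputs <- character()
  res <- samples <- report <- NULL

  # geometry
  vs <- cfg$geometry$voxel_size_um
  if (is.list(cfg$geometry$profile))
    inputs <- c(inputs, unlist(cfg$geometry$profile[c("csv", "mask")]))
  profile <- config_profile(cfg$geometry, vs)
  if ("geometry" %in% stages) {
    pth <- file.path(out_dir, "profile.csv")
    write_area_profile(profile, pth)
    outputs <- c(outputs, pth)
    logf("geometry: %d stations, %.2f mm, volume %.2f uL",
         nrow(profile), max(profile$distance_mm), volume_from_profile(profile))
  }
  geom <- cochlear_geometry(
    profile,
    rwm_area_mm2 = cfg$geometry$rwm_area_mm2 %||% 2,
    aqueduct_flow_nL_s = cfg$geometry$aqueduct_flow_nL_s %||% 0,
    dispersion_factor = cfg$geometry$dispersion_factor %||% 1)

  drugs <- lapply(cfg$drugs, config_drug)
  dose <- dose_protocol(cfg$dose$C_me_0,
                        cfg$dose$injected_volume_mL %||% 1,
                        cfg$dose$t_end_min %||% 300)
  sol <- cfg$solver %||% list()

  if (any(c("simulate", "sample", "report") %in% stages)) {
    res <- simulate_transport(geom, drugs, dose,
                              dx_mm = sol$dx_mm %||% 0.1,
                              dt_s = sol$dt_s %||% 0.5,
                              output_every_min = sol$output_every_min %||% 1,
                              hydrolysis = sol$hydrolysis)
    logf("simulate: %s to %d min; mass audit residual %.2e",
         paste(res$species, collapse = "+"), max(res$t_min),
         res$audit$residual_rel)
    for (s in res$species)
      logf("  %s: influx %.4g ug, eliminated %.4g ug, in perilymph %.4g ug",
           s, res$audit$influx_ug[match(s, res$species)],
           res$audit$eliminated_ug[match(s, res$species)],
           res$audit$mass_end_ug[match(s, res$species)])
  }
  if ("simulate" %in% stages) {
    long <- do.call(rbind, lapply(res$species, function(s) {
      data.frame(species = s,
                 x_mm = rep(res$x_mm, times = length(res$t_min)),
                 t_min = rep(res$t_min, each = length(res$x_mm)),
                 conc_ug_ml = as.vector(res$C[[s]]))
    }))
    pth <- file.path(out_dir, "concentrations.csv")
    write.csv(long, pth, row.names = FALSE)
    tr <- data.frame(t_min = res$t_min, C_me = res$C_me)
    for (s in res$species) {
      tr[[paste0("st1_", s)]] <-
        vapply(res$t_min, function(t) concentration_at(res, 1, t, s), 0)
      tr[[paste0("st_all_", s)]] <-
        vapply(res$t_min, function(t) whole_st_mean(res, t, s), 0)
    }
    pth2 <- file.path(out_dir, "summary_traces.csv")
    write.csv(tr, pth2, row.names = FALSE)
    outputs <- c(outputs, pth, pth2)
  }

  if ("sample" %in% stages) {
    scfg <- cfg$sampling %||% list()
    at <- scfg$at_min %||% 30
    proto <- sampling_protocol(scfg$tube_volume_uL %||% 5,
                               scfg$n_tubes %||% 5)
    last_sp <- res$species[length(res$species)]
    conc <- approx(res$x_mm, field_at_time(res, at, last_sp),
                   xout = profile$distance_mm, rule = 2)$y
    samples <- sequential_sample(profile, conc, proto,
                                 replacement = scfg$replacement %||% "csf_zero")
    pth <- file.path(out_dir, "samples.csv")
    write.csv(data.frame(tube = seq_along(samples$per_tube_conc),
                         volume_uL = samples$tube_volume_uL,
                         conc_ug_ml = samples$per_tube_conc),
              pth, row.names = FALSE)
    outputs <- c(outputs, pth)
    logf("sample: %d x %g uL at %g min; pooled %s",
         proto$n_tubes, proto$tube_volume_uL, at,
         paste(sprintf("%.3g", samples$pooled_conc), collapse = " / "))
  }

  if ("report" %in% stages) {
    ref <- read.csv(system.file("extdata", "reference_predictions.csv",
                                package = "cochleaPK"))
    sim <- c(st_all_30min = tryCatch(whole_st_mean(res, 30), error = function(e) NA),
             st1_30min = tryCatch(concentration_at(res, 1, 30), error = function(e) NA))
    report <- data.frame(quantity = ref$quantity, reference = ref$value,
                         units = ref$units, kind = ref$kind,
                         simulated = NA_real_)
    report$simulated[match(c("st_all_30min", "st1_30min"), ref$quantity)] <-
      sim[c("st_all_30min", "st1_30min")]
    pth <- file.path(out_dir, "report.csv")
    write.csv(report, pth, row.names = FALSE)
    outputs <- c(outputs, pth)
  }

  manifest <- list(
    package = "cochleaPK",
    version = as.character(packageVersion("cochleaPK")),
    seed = seed,
    config = cfg,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(profile = profile, result = res, samples = samples,
                 report = report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
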