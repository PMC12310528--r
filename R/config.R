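#' Run configuration
#'
#' A single nested configuration drives both simulation and detection and
#' is serialized into every report for reproducibility. All defaults are
#' the platform's standard operating values: 200 x 200 um field, 30 ms x
#' 100-frame averaging, 660/10 nm illumination on a 242.42 nm/RIU
#' resonance, the quadratic sizing calibration, the `1 + 3*sigma + 0.005`
#' threshold, and the 20 uL / 1.5 uL/min push-pull schedule.
#'
#' @param ... Named overrides of nested fields, e.g.
#'   `default_config(seed = 7, detection = list(min_area = 3))`. Supplied
#'   sublists are merged into (not replacing) the defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    fov = list(width = 200, height = 200, pixel_size = 0.1625),
    imaging = list(exposure_ms = 30, frames_averaged = 100,
                   per_frame_noise_sd = 0.0118, background_level = 30000,
                   drift = c(0, 0), psf_sigma_um = 0.21 * 0.660 / 0.95,
                   texture_sd = 0.02, texture_scale_px = 20),
    schedule = list(sample_volume = 20, fill_rate = 5, pushpull_rate = 1.5,
                    cycle_duration = 10, total_incubation = 60,
                    imaging_interval = 20, wash_rate = 5,
                    wash_duration = 5),
    lspr = list(reference_peak = 659, reference_index = 1.00,
                sensitivity = 242.42, resonance_fwhm = 120,
                peak_extinction = 0.9, baseline_extinction = 0.05,
                band_center = 660, band_fwhm = 10, medium_index = 1.33),
    calibration = list(a = 0.153, b = 7.096, c = 20.211,
                       contrast_cutoff = 18, diameter_cutoff = 200,
                       valid_contrast_range = c(0, 30)),
    detection = list(k = 3, margin = 0.005, min_area = 2, connectivity = 8,
                     contrast_stat = "peak", sigma_mode = "sample",
                     max_shift = 5, registration_min_score = 0.5,
                     floor_frac = 0.01, match_radius = 2),
    simulation = list(n_candidates = 800, rate_constant = 0.023,
                      wash_retention = 0.575, diameter_meanlog = log(100),
                      diameter_sdlog = 0.35, min_diameter = 25),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks field presence, types and invariants; errors name the offending
#' field path.
#'
#' @param cfg A configuration list.
#' @return The configuration, classed `run_config`, invisibly usable
#'   downstream.
#' @export
validate_config <- function(cfg) {
  need <- function(path) {
    node <- cfg
    for (p in strsplit(path, "$", fixed = TRUE)[[1]]) {
      if (is.null(node[[p]]))
        stop("configuration field missing: ", path, call. = FALSE)
      node <- node[[p]]
    }
    node
  }
  check <- function(path, ok) {
    val <- need(path)
    if (!isTRUE(ok(val)))
      stop("invalid configuration value at ", path, call. = FALSE)
    val
  }
  pos <- function(v) is.numeric(v) && all(v > 0)
  nonneg <- function(v) is.numeric(v) && all(v >= 0)
  check("fov$width", pos); check("fov$height", pos)
  check("fov$pixel_size", pos)
  check("imaging$frames_averaged", function(v) v >= 1)
  check("imaging$per_frame_noise_sd", nonneg)
  check("imaging$background_level", pos)
  check("imaging$drift", function(v) length(v) == 2)
  check("schedule$imaging_interval", pos)
  check("schedule$total_incubation", pos)
  if (need("schedule$total_incubation") %% need("schedule$imaging_interval")
      != 0)
    stop("invalid configuration value at schedule$imaging_interval: ",
         "must divide total_incubation", call. = FALSE)
  check("lspr$sensitivity", pos)
  check("calibration$a", pos); check("calibration$b", pos)
  check("detection$k", nonneg); check("detection$margin", nonneg)
  check("detection$min_area", pos)
  check("detection$connectivity", function(v) v %in% c(4, 8))
  check("detection$contrast_stat", function(v) v %in% c("peak", "mean"))
  check("detection$sigma_mode", function(v) v %in% c("sample", "background"))
  check("simulation$wash_retention", function(v) v >= 0 && v <= 1)
  check("seed", function(v) is.numeric(v) && length(v) == 1)
  structure(cfg, class = "run_config")
}

#' Save / load a configuration as YAML
#'
#' Round-trips exactly: `load_config(save_config(cfg, path))` equals
#' `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path File path of the YAML document.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the validated `run_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Deterministic configuration hash
#'
#' MD5 of the canonical YAML serialization; recorded in run reports so a
#' report can be traced to the exact configuration that produced it.
#'
#' @param cfg A `run_config`.
#' @return A hex digest string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f, precision = 15)
  unname(tools::md5sum(f))
}

# constructors of the domain objects a config describes
fov_from_config <- function(cfg)
  field_of_view(cfg$fov$width, cfg$fov$height, cfg$fov$pixel_size)

imaging_from_config <- function(cfg)
  imaging_config(cfg$imaging$exposure_ms, cfg$imaging$frames_averaged,
                 cfg$imaging$per_frame_noise_sd,
                 cfg$imaging$background_level, cfg$imaging$drift,
                 cfg$imaging$psf_sigma_um, cfg$imaging$texture_sd,
                 cfg$imaging$texture_scale_px)

schedule_from_config <- function(cfg)
  flow_schedule(cfg$schedule$sample_volume, cfg$schedule$fill_rate,
                cfg$schedule$pushpull_rate, cfg$schedule$cycle_duration,
                cfg$schedule$total_incubation,
                cfg$schedule$imaging_interval, cfg$schedule$wash_rate,
                cfg$schedule$wash_duration)

calibration_from_config <- function(cfg)
  sizing_calibration(cfg$calibration$a, cfg$calibration$b,
                     cfg$calibration$c, cfg$calibration$contrast_cutoff,
                     cfg$calibration$diameter_cutoff,
                     as.numeric(cfg$calibration$valid_contrast_range))

lspr_from_config <- function(cfg) {
  resp <- ri_response(cfg$lspr$reference_peak, cfg$lspr$reference_index,
                      cfg$lspr$sensitivity)
  list(response = resp,
       spectrum = lspr_spectrum(
         peak_wavelength(resp, cfg$lspr$medium_index),
         cfg$lspr$resonance_fwhm, cfg$lspr$peak_extinction,
         cfg$lspr$baseline_extinction),
       band = illumination_band(cfg$lspr$band_center, cfg$lspr$band_fwhm))
}
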