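#' End-to-end analysis of an acquisition series
#'
#' Runs the full detection chain on every frame of a series: rigid
#' registration against the background, ratiometric division, sigma
#' estimation, thresholding at `1 + k*sigma + margin`, connected-component
#' particle calling, contrast-to-diameter sizing, sEV classification, and
#' time-lapse aggregation with a before-wash/after-wash comparison.
#'
#' Sigma is estimated once per run. In `"sample"` mode (default) it is the
#' robust background sd of the first before-wash IR image — particle
#' pixels are excluded by the estimator's upper-quantile trim. In
#' `"background"` mode it comes from the IR of two particle-free
#' background frames (the series' `background_replicate`).
#'
#' @param series An [make_series()] acquisition series (or an equivalent
#'   list built from frames read off disk).
#' @param config A [default_config()] run configuration; its `detection`
#'   block controls the pipeline.
#' @return A list of class `run_report`:
#' \describe{
#'   \item{sigma, threshold}{noise estimate and the threshold object}
#'   \item{detections}{named list of classified detection tables, one per
#'     BW timepoint}
#'   \item{aw_detections}{classified AW detection table}
#'   \item{counts}{[counts_over_time()] table over the BW frames}
#'   \item{shifts}{per-frame registration shifts}
#'   \item{bw_summary}{[summarize_detections()] of the final BW frame}
#'   \item{wash}{[wash_analysis()] of final BW vs AW}
#'   \item{seed, config, config_hash}{provenance}
#' }
#' @export
analyze_series <- function(series, config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  det <- config$detection
  cal <- calibration_from_config(config)
  fov <- series$fov
  px <- if (!is.null(fov)) fov$pixel_size else config$fov$pixel_size

  align <- function(frame) {
    if (det$max_shift > 0) {
      reg <- register_images(series$background, frame,
                             max_shift = det$max_shift,
                             min_score = det$registration_min_score)
      list(img = reg$aligned, shift = reg$shift)
    } else list(img = frame, shift = c(dx = 0L, dy = 0L))
  }

  frames <- series$frames
  aligned <- lapply(frames, align)
  aligned_aw <- align(series$aw_frame)
  irs <- lapply(aligned, function(a)
    ratiometric(a$img, series$background, floor_frac = det$floor_frac))
  ir_aw <- ratiometric(aligned_aw$img, series$background,
                       floor_frac = det$floor_frac)

  sigma <- if (det$sigma_mode == "background") {
    if (is.null(series$background_replicate))
      stop("sigma_mode 'background' requires a background replicate frame")
    estimate_sigma(ratiometric(series$background_replicate,
                               series$background,
                               floor_frac = det$floor_frac))
  } else {
    estimate_sigma(irs[[1]])
  }
  thr <- detection_threshold(sigma, k = det$k, margin = det$margin)

  call_frame <- function(ir, t) {
    d <- detect_particles(ir, thr, min_area = det$min_area,
                          connectivity = det$connectivity,
                          pixel_size = px,
                          contrast_stat = det$contrast_stat,
                          timepoint = t)
    classify_particles(cal, d)
  }
  times <- series$times
  detections <- lapply(seq_along(irs), function(k)
    call_frame(irs[[k]], times[k]))
  names(detections) <- as.character(times)
  aw_detections <- call_frame(ir_aw, NA_real_)

  counts <- counts_over_time(detections, radius = det$match_radius)
  bw_final <- detections[[length(detections)]]
  structure(
    list(sigma = sigma, threshold = thr,
         detections = detections, aw_detections = aw_detections,
         counts = counts,
         shifts = c(lapply(aligned, `[[`, "shift"),
                    list(aw = aligned_aw$shift)),
         bw_summary = summarize_detections(bw_final, cal),
         wash = wash_analysis(bw_final, aw_detections, cal),
         seed = series$seed, config = config,
         config_hash = config_hash(config)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report (sigma %.5f, threshold %.5f)\n",
              x$sigma, x$threshold$value))
  print(x$counts)
  cat(sprintf("After wash: %d of %d retained (fraction %s)\n",
              x$wash$aw_count, x$wash$bw_count,
              format(round(x$wash$retained_fraction, 3))))
  invisible(x)
}

#' Simulate an acquisition series to disk
#'
#' Generates a seeded ground-truthed series from the configuration and
#' writes 16-bit TIFF frames (`background.tif`, `background_replicate.tif`,
#' `frame_<t>min.tif`, `aw.tif`), the ground-truth table (`truth.csv`) and
#' a copy of the configuration (`config.yaml`). Byte-identical across
#' repeated calls with the same configuration.
#'
#' @param config A [default_config()] run configuration.
#' @param outdir Output directory (created if absent).
#' @return The [make_series()] object, invisibly.
#' @export
simulate_run <- function(config = default_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fov <- fov_from_config(config)
  imaging <- imaging_from_config(config)
  schedule <- schedule_from_config(config)
  cal <- calibration_from_config(config)
  sim <- config$simulation
  particles <- simulate_binding(sim$n_candidates, sim$rate_constant,
                                schedule, sim$wash_retention, fov,
                                sim$diameter_meanlog, sim$diameter_sdlog,
                                sim$min_diameter, seed = config$seed)
  series <- make_series(fov, particles, imaging, schedule, cal,
                        seed = config$seed)
  write_frame_tiff(series$background, file.path(outdir, "background.tif"))
  write_frame_tiff(series$background_replicate,
                   file.path(outdir, "background_replicate.tif"))
  for (t in names(series$frames))
    write_frame_tiff(series$frames[[t]],
                     file.path(outdir, sprintf("frame_%03dmin.tif",
                                               as.integer(t))))
  write_frame_tiff(series$aw_frame, file.path(outdir, "aw.tif"))
  write_truth_csv(series, file.path(outdir, "truth.csv"))
  save_config(config, file.path(outdir, "config.yaml"))
  invisible(series)
}

#' Run detection on frames from disk
#'
#' Reads the background and sample TIFFs, runs [analyze_series()], and
#' writes per-timepoint detection CSVs, the final-frame IR image as
#' 32-bit float TIFF, and a JSON run report.
#'
#' @param background Path to the background TIFF.
#' @param frames Character vector of before-wash frame TIFF paths, in
#'   time order.
#' @param config A [default_config()] run configuration (or a path to a
#'   YAML file).
#' @param outdir Output directory.
#' @param aw Optional path to the after-wash frame TIFF.
#' @param background_replicate Optional path to a second particle-free
#'   background TIFF (needed for `sigma_mode = "background"`).
#' @param times Acquisition times (min) of `frames`; default from the
#'   configured schedule.
#' @return The [analyze_series()] run report, invisibly.
#' @export
detect_run <- function(background, frames, config = default_config(),
                       outdir, aw = NULL, background_replicate = NULL,
                       times = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  if (length(frames) < 1) stop("at least one sample frame is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(times)) {
    sched <- schedule_from_config(config)
    times <- imaging_times(sched)[seq_along(frames)]
  }
  stopifnot(length(times) == length(frames))
  bg <- read_frame_tiff(background)
  series <- list(
    background = bg,
    background_replicate = if (!is.null(background_replicate))
      read_frame_tiff(background_replicate) else NULL,
    frames = stats::setNames(lapply(frames, read_frame_tiff),
                             as.character(times)),
    aw_frame = if (!is.null(aw)) read_frame_tiff(aw) else NULL,
    times = times,
    fov = field_of_view(ncol(bg) * config$fov$pixel_size,
                        nrow(bg) * config$fov$pixel_size,
                        config$fov$pixel_size),
    seed = config$seed)
  if (is.null(series$aw_frame)) {
    # analyze without a wash frame: reuse the last BW frame and drop the
    # wash block afterwards
    series$aw_frame <- series$frames[[length(series$frames)]]
    report <- analyze_series(series, config)
    report$aw_detections <- NULL
    report$wash <- NULL
  } else {
    report <- analyze_series(series, config)
  }
  for (k in seq_along(report$detections))
    write_detections_csv(report$detections[[k]],
                         file.path(outdir, sprintf("detections_%03dmin.csv",
                                                   as.integer(times[k]))))
  if (!is.null(report$aw_detections))
    write_detections_csv(report$aw_detections,
                         file.path(outdir, "detections_aw.csv"))
  last_ir <- ratiometric(
    if (config$detection$max_shift > 0)
      register_images(bg, series$frames[[length(series$frames)]],
                      config$detection$max_shift,
                      config$detection$registration_min_score)$aligned
    else series$frames[[length(series$frames)]],
    bg, floor_frac = config$detection$floor_frac)
  write_ir_tiff(last_ir, file.path(outdir, "ir_final.tif"))
  write_report_json(report, file.path(outdir, "report.json"))
  invisible(report)
}

#' Serialize a run report to JSON
#'
#' @param report An [analyze_series()] run report.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    sigma = report$sigma,
    threshold = report$threshold$value,
    counts = report$counts,
    shifts = lapply(report$shifts, as.list),
    bw_summary = report$bw_summary[
      c("n", "contrast_mean", "contrast_sd", "diameter_mean",
        "diameter_sd", "sd_defined")],
    wash = if (!is.null(report$wash))
      list(bw_count = report$wash$bw_count,
           aw_count = report$wash$aw_count,
           retained_fraction = round(report$wash$retained_fraction, 3),
           aw_contrast_mean = report$wash$aw_summary$contrast_mean,
           aw_contrast_sd = report$wash$aw_summary$contrast_sd,
           aw_diameter_mean = report$wash$aw_summary$diameter_mean,
           aw_diameter_sd = report$wash$aw_summary$diameter_sd),
    seed = report$seed,
    config_hash = report$config_hash,
    config = unclass(report$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Aggregate replicate run reports
#'
#' Reads run-report JSON files from independent runs and summarizes the
#' final before-wash and (when present) after-wash counts as
#' mean +/- sample sd.
#'
#' @param report_paths Character vector of at least two `report.json`
#'   paths.
#' @return A list with `n_runs`, `bw` and `aw` [replicate_summary()]
#'   entries (`aw` is `NULL` when any run lacks a wash block) and the
#'   per-run counts.
#' @export
report_runs <- function(report_paths) {
  if (length(report_paths) < 2)
    stop("replicate reporting requires at least 2 runs")
  reports <- lapply(report_paths, jsonlite::read_json)
  bw_counts <- vapply(reports, function(r) {
    # counts serialize as one object per timepoint row
    cum <- vapply(r$counts, function(row) as.numeric(row$cumulative),
                  numeric(1))
    cum[length(cum)]
  }, numeric(1))
  has_aw <- all(vapply(reports, function(r) !is.null(r$wash), logical(1)))
  aw_counts <- if (has_aw)
    vapply(reports, function(r) as.numeric(r$wash$aw_count), numeric(1))
  list(n_runs = length(reports),
       bw = replicate_summary(bw_counts),
       aw = if (has_aw) replicate_summary(aw_counts),
       bw_counts = bw_counts,
       aw_counts = if (has_aw) aw_counts)
}
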