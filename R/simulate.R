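#' Synthetic acquisition-series generator
#'
#' Produces seeded, ground-truthed image series that emulate what the
#' camera records over a push-pull incubation: a particle-free background
#' frame, before-wash (BW) frames at each imaging interval in which
#' particles accumulate, and an after-wash (AW) frame containing only the
#' particles that survive the buffer rinse. Each bound particle raises
#' local transmission multiplicatively by `1 + contrast/100` at its
#' position under a Gaussian point-spread footprint, so the intensity
#' ratio of sample to background encodes the injected contrast exactly in
#' the noiseless limit.
#'
#' @name synthetic
NULL

#' Field of view
#'
#' @param width,height Physical extent of the imaged area (micrometers).
#'   Default 200 x 200 um, the sensor patch area imaged in practice.
#' @param pixel_size Pixel pitch in the sample plane (um/pixel). Default
#'   0.1625 um (a 6.5 um sCMOS pixel behind a 40x objective).
#' @return An object of class `field_of_view` with pixel-grid dimensions
#'   `nx`, `ny`.
#' @export
field_of_view <- function(width = 200, height = 200, pixel_size = 0.1625) {
  stopifnot(width > 0, height > 0, pixel_size > 0)
  structure(
    list(width = width, height = height, pixel_size = pixel_size,
         nx = as.integer(round(width / pixel_size)),
         ny = as.integer(round(height / pixel_size))),
    class = "field_of_view")
}

#' Imaging configuration
#'
#' Camera and optics parameters for frame rendering. The effective noise
#' standard deviation of a recorded frame is
#' `per_frame_noise_sd / sqrt(frames_averaged)` (as a fraction of the mean
#' background level): averaging 100 frames of 30 ms exposure reduces the
#' per-frame read/shot noise tenfold. The default per-frame noise is set
#' so that the background of the ratiometric image (which compounds the
#' noise of two averaged frames) has a standard deviation of about
#' 0.00167, i.e. a full threshold excursion `3*sigma + 0.005` of about 1%.
#'
#' @param exposure_ms Exposure per raw frame (ms).
#' @param frames_averaged Number of raw frames averaged per recorded
#'   image, >= 1.
#' @param per_frame_noise_sd Noise sd of a single raw frame as a fraction
#'   of the mean background level, >= 0.
#' @param background_level Mean background intensity (camera counts).
#' @param drift Rigid shift `(dx, dy)` in pixels applied to sample frames
#'   relative to the background frame.
#' @param psf_sigma_um Gaussian PSF sigma (um); default `0.21 * 0.660/0.95`
#'   = 0.146 um for a 0.95 NA objective at 660 nm.
#' @param texture_sd Sd of the smooth multiplicative background texture,
#'   as a fraction of the mean (fixed-pattern structure the ratiometric
#'   step must cancel).
#' @param texture_scale_px Correlation length of the texture (pixels).
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(exposure_ms = 30, frames_averaged = 100,
                           per_frame_noise_sd = 0.0118,
                           background_level = 30000,
                           drift = c(0, 0),
                           psf_sigma_um = 0.21 * 0.660 / 0.95,
                           texture_sd = 0.02, texture_scale_px = 20) {
  stopifnot(exposure_ms > 0, frames_averaged >= 1, per_frame_noise_sd >= 0,
            background_level > 0, length(drift) == 2,
            psf_sigma_um > 0, texture_sd >= 0, texture_scale_px > 0)
  structure(
    list(exposure_ms = exposure_ms,
         frames_averaged = as.integer(frames_averaged),
         per_frame_noise_sd = per_frame_noise_sd,
         background_level = background_level,
         drift = as.integer(round(drift)),
         psf_sigma_um = psf_sigma_um,
         texture_sd = texture_sd, texture_scale_px = texture_scale_px),
    class = "imaging_config")
}

#' Push-pull flow schedule
#'
#' Defaults reproduce the standard run: a 20 uL sample fills the channel
#' at 5 uL/min, then is alternately pushed and pulled at 1.5 uL/min in
#' 10-min cycles for 60 min of incubation with images every 20 min, and
#' finally washed with buffer at 5 uL/min for 5 min.
#'
#' @param sample_volume Sample volume (uL).
#' @param fill_rate Channel-filling flow rate (uL/min).
#' @param pushpull_rate Push-pull flow rate during incubation (uL/min).
#' @param cycle_duration Duration of one push (or pull) stroke (min).
#' @param total_incubation Total incubation time (min).
#' @param imaging_interval Interval between images (min); must divide the
#'   total incubation.
#' @param wash_rate Wash flow rate (uL/min).
#' @param wash_duration Wash duration (min).
#' @return An object of class `flow_schedule`.
#' @export
flow_schedule <- function(sample_volume = 20, fill_rate = 5,
                          pushpull_rate = 1.5, cycle_duration = 10,
                          total_incubation = 60, imaging_interval = 20,
                          wash_rate = 5, wash_duration = 5) {
  vals <- c(sample_volume, fill_rate, pushpull_rate, cycle_duration,
            total_incubation, imaging_interval, wash_rate, wash_duration)
  stopifnot(all(vals >= 0), imaging_interval > 0, total_incubation > 0)
  if (total_incubation %% imaging_interval != 0)
    stop("imaging_interval must divide total_incubation")
  structure(
    list(sample_volume = sample_volume, fill_rate = fill_rate,
         pushpull_rate = pushpull_rate, cycle_duration = cycle_duration,
         total_incubation = total_incubation,
         imaging_interval = imaging_interval,
         wash_rate = wash_rate, wash_duration = wash_duration),
    class = "flow_schedule")
}

#' Volume moved during one push (or pull) stroke
#'
#' @param schedule A [flow_schedule()].
#' @return Volume in uL (`pushpull_rate * cycle_duration`); 15 uL under
#'   the default schedule, enough to cycle the sample past the sensor.
#' @export
push_volume <- function(schedule) {
  stopifnot(inherits(schedule, "flow_schedule"))
  schedule$pushpull_rate * schedule$cycle_duration
}

#' Imaging timepoints of a schedule
#'
#' @param schedule A [flow_schedule()].
#' @return Vector of before-wash imaging times in minutes.
#' @export
imaging_times <- function(schedule) {
  stopifnot(inherits(schedule, "flow_schedule"))
  seq(schedule$imaging_interval, schedule$total_incubation,
      by = schedule$imaging_interval)
}

#' Simulate binding of a particle population
#'
#' Each of `n_candidates` particles binds at a time drawn from an
#' exponential waiting-time distribution with the given first-order rate
#' constant; candidates whose waiting time exceeds the incubation window
#' never bind and are omitted, so the bound times follow the exponential
#' distribution truncated to `[0, total_incubation]`. Wash survival is an
#' independent Bernoulli draw per bound particle. Positions are uniform
#' over the field and diameters log-normal (median 100 nm by default, the
#' typical sEV size), floored at the calibration intercept.
#'
#' @param n_candidates Number of particles in the sample available to
#'   bind.
#' @param rate_constant First-order binding rate (1/min), >= 0.
#' @param schedule A [flow_schedule()] supplying the incubation window.
#' @param wash_retention Probability a bound particle survives the wash,
#'   in `[0, 1]`.
#' @param fov A [field_of_view()] for particle positions.
#' @param diameter_meanlog,diameter_sdlog Log-normal diameter parameters
#'   (log-nm).
#' @param min_diameter Smallest diameter generated (nm); draws below are
#'   resampled. Must be at least the calibration intercept if contrasts
#'   are to be assigned later.
#' @param seed Integer seed; every call is fully determined by it.
#' @return A data frame of ground-truth particles: `id`, `x_um`, `y_um`,
#'   `diameter_nm`, `binding_time_min`, `survives_wash`.
#' @export
simulate_binding <- function(n_candidates, rate_constant, schedule,
                             wash_retention = 0.575,
                             fov = field_of_view(),
                             diameter_meanlog = log(100),
                             diameter_sdlog = 0.35,
                             min_diameter = 25, seed = 1) {
  stopifnot(n_candidates >= 0, rate_constant >= 0,
            inherits(schedule, "flow_schedule"),
            wash_retention >= 0, wash_retention <= 1,
            inherits(fov, "field_of_view"), min_diameter > 0)
  set.seed(seed)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      diameter_nm = numeric(0),
                      binding_time_min = numeric(0),
                      survives_wash = logical(0))
  if (n_candidates == 0 || rate_constant == 0) return(empty)
  wait <- stats::rexp(n_candidates, rate = rate_constant)
  bound <- which(wait <= schedule$total_incubation)
  n <- length(bound)
  if (n == 0) return(empty)
  d <- stats::rlnorm(n, diameter_meanlog, diameter_sdlog)
  while (any(d < min_diameter))
    d[d < min_diameter] <- stats::rlnorm(sum(d < min_diameter),
                                         diameter_meanlog, diameter_sdlog)
  data.frame(
    id = seq_len(n),
    x_um = stats::runif(n, 0, fov$width),
    y_um = stats::runif(n, 0, fov$height),
    diameter_nm = d,
    binding_time_min = wait[bound],
    survives_wash = stats::runif(n) < wash_retention)
}

# smooth multiplicative fixed-pattern field, mean 1, sd = texture_sd
make_texture <- function(fov, config, seed = 1) {
  set.seed(seed)
  if (config$texture_sd == 0) return(matrix(1, fov$ny, fov$nx))
  raw <- matrix(stats::rnorm(fov$ny * fov$nx), fov$ny, fov$nx)
  sig <- config$texture_scale_px
  sm <- EBImage::gblur(raw, sigma = sig,
                       radius = min(2L * ceiling(2 * sig) + 1L,
                                    2L * (min(fov$ny, fov$nx) %/% 2) - 1L))
  sm <- (sm - mean(sm)) / stats::sd(sm)
  1 + config$texture_sd * sm
}

#' Render one camera frame
#'
#' The noiseless image is
#' `background_level * texture(x, y) * prod_i (1 + (c_i/100) * G_i(x, y))`
#' where `c_i` is the contrast implied by particle i's diameter through
#' the calibration and `G_i` a unit-peak Gaussian of sd `psf_sigma_um`
#' centered at the particle's (sub-pixel) position, sampled at pixel
#' centers. Zero-mean Gaussian noise of sd
#' `per_frame_noise_sd * background_level / sqrt(frames_averaged)` is then
#' added. For an isolated particle centered on a pixel the noiseless peak
#' intensity ratio against the particle-free frame is exactly
#' `1 + c_i/100`; off-center positions lose at most a factor
#' `exp(-0.25 / sigma_px^2)` to pixel sampling.
#'
#' @param fov A [field_of_view()].
#' @param particles Ground-truth data frame (rows bound by the frame's
#'   time) with `x_um`, `y_um`, `diameter_nm`. Particles outside the field
#'   are skipped with a warning.
#' @param config An [imaging_config()].
#' @param cal A [sizing_calibration()] used to convert diameter to
#'   contrast.
#' @param texture Optional precomputed texture matrix (from a series);
#'   regenerated from `seed` when `NULL`.
#' @param noise Add camera noise (set `FALSE` for noiseless renders).
#' @param seed Integer seed for texture and noise.
#' @return A `ny x nx` numeric matrix of camera counts (rows = y).
#' @export
render_frame <- function(fov, particles, config, cal = sizing_calibration(),
                         texture = NULL, noise = TRUE, seed = 1) {
  stopifnot(inherits(fov, "field_of_view"),
            inherits(config, "imaging_config"),
            inherits(cal, "sizing_calibration"))
  if (is.null(texture)) texture <- make_texture(fov, config, seed)
  img <- config$background_level * texture
  if (!is.null(particles) && nrow(particles) > 0) {
    outside <- particles$x_um < 0 | particles$x_um > fov$width |
               particles$y_um < 0 | particles$y_um > fov$height
    if (any(outside)) {
      warning(sum(outside), " particle(s) outside the field of view skipped")
      particles <- particles[!outside, , drop = FALSE]
    }
    if (nrow(particles) > 0) {
      contrast <- diameter_to_contrast(cal, particles$diameter_nm)
      sig_px <- config$psf_sigma_um / fov$pixel_size
      half <- ceiling(5 * sig_px)
      for (i in seq_len(nrow(particles))) {
        # sub-pixel center in pixel units (pixel k spans [k-1, k])
        cx <- particles$x_um[i] / fov$pixel_size
        cy <- particles$y_um[i] / fov$pixel_size
        px <- max(1L, floor(cx - half) + 1L):min(fov$nx, ceiling(cx + half))
        py <- max(1L, floor(cy - half) + 1L):min(fov$ny, ceiling(cy + half))
        gx <- exp(-((px - 0.5) - cx)^2 / (2 * sig_px^2))
        gy <- exp(-((py - 0.5) - cy)^2 / (2 * sig_px^2))
        img[py, px] <- img[py, px] *
          (1 + (contrast[i] / 100) * outer(gy, gx))
      }
    }
  }
  if (noise && config$per_frame_noise_sd > 0) {
    set.seed(seed + 1L)
    sd_counts <- config$per_frame_noise_sd * config$background_level /
      sqrt(config$frames_averaged)
    img <- img + matrix(stats::rnorm(length(img), 0, sd_counts),
                        nrow(img), ncol(img))
  }
  img
}

#' Apply a rigid integer-pixel drift to an image
#'
#' Translates the image by `(dx, dy)` pixels (positive dx moves content
#' toward larger x/columns), filling exposed edges with the image median.
#'
#' @param image Numeric matrix (rows = y).
#' @param dx,dy Integer shifts in pixels; `|dx|, |dy| <= max_shift`.
#' @param max_shift Largest allowed shift (pixels).
#' @return The shifted matrix, with the applied shift in attribute
#'   `"shift"`.
#' @export
apply_drift <- function(image, dx, dy, max_shift = 10) {
  stopifnot(is.matrix(image), dx == round(dx), dy == round(dy))
  if (abs(dx) > max_shift || abs(dy) > max_shift)
    stop("drift exceeds max_shift of ", max_shift, " pixels")
  dx <- as.integer(dx); dy <- as.integer(dy)
  out <- matrix(stats::median(image), nrow(image), ncol(image))
  src_r <- seq_len(nrow(image)) - dy
  src_c <- seq_len(ncol(image)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(image)
  ok_c <- src_c >= 1 & src_c <= ncol(image)
  out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c]]
  attr(out, "shift") <- c(dx = dx, dy = dy)
  out
}

#' Generate a full acquisition series
#'
#' Renders the background frame (t = 0, particle-free), one before-wash
#' frame per imaging interval containing the particles bound by that time,
#' and one after-wash frame containing only wash survivors. All frames of
#' a series share one fixed-pattern texture (so the ratiometric step can
#' cancel it) and each frame gets independent camera noise. A configured
#' drift is applied to every sample frame relative to the background.
#'
#' @param fov A [field_of_view()].
#' @param particles Ground-truth data frame from [simulate_binding()].
#' @param config An [imaging_config()].
#' @param schedule A [flow_schedule()].
#' @param cal A [sizing_calibration()].
#' @param seed Integer seed driving texture and all per-frame noise.
#' @return An object of class `acquisition_series`: list with `background`
#'   (matrix), `background_replicate` (a second particle-free frame, for
#'   background-pair sigma estimation), `frames` (named list of BW
#'   matrices, names = minutes), `aw_frame`, `times`, `truth` (particle
#'   table with `contrast_pct` added), and the generating `fov`,
#'   `config`, `schedule`, `cal`, `seed`.
#' @export
make_series <- function(fov, particles, config, schedule,
                        cal = sizing_calibration(), seed = 1) {
  stopifnot(inherits(schedule, "flow_schedule"))
  texture <- make_texture(fov, config, seed)
  times <- imaging_times(schedule)
  background <- render_frame(fov, NULL, config, cal, texture = texture,
                             seed = seed + 100L)
  shift_if <- function(img) {
    if (any(config$drift != 0))
      apply_drift(img, config$drift[1], config$drift[2],
                  max_shift = max(abs(config$drift)))
    else img
  }
  frames <- lapply(seq_along(times), function(k) {
    bound <- particles[particles$binding_time_min <= times[k], , drop = FALSE]
    shift_if(render_frame(fov, bound, config, cal, texture = texture,
                          seed = seed + 100L + k))
  })
  names(frames) <- as.character(times)
  survivors <- particles[particles$survives_wash, , drop = FALSE]
  aw <- shift_if(render_frame(fov, survivors, config, cal, texture = texture,
                              seed = seed + 100L + length(times) + 1L))
  # particle-free replicate of the background, for background-pair sigma
  bg_rep <- render_frame(fov, NULL, config, cal, texture = texture,
                         seed = seed + 100L + length(times) + 2L)
  truth <- particles
  truth$contrast_pct <- if (nrow(truth))
    diameter_to_contrast(cal, truth$diameter_nm) else numeric(0)
  structure(
    list(background = background, background_replicate = bg_rep,
         frames = frames, aw_frame = aw,
         times = times, truth = truth, fov = fov, config = config,
         schedule = schedule, cal = cal, seed = seed),
    class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf(
    "Acquisition series: %dx%d px, %d BW frames at {%s} min + AW, %d ground-truth particles (seed %d)\n",
    x$fov$ny, x$fov$nx, length(x$frames),
    paste(x$times, collapse = ", "), nrow(x$truth), x$seed))
  invisible(x)
}
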