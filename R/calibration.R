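#' Contrast-to-diameter calibration and sEV classification
#'
#' Particle contrast (the percentage excess of the intensity ratio over 1
#' at the particle's position) is monotonically related to particle
#' diameter. The relationship is an empirical quadratic regressed against
#' nanoparticle tracking analysis:
#' `Y = a*X^2 + b*X + c`, with `X` the contrast in percent and `Y` the
#' diameter in nm. Detections are classified as small extracellular
#' vesicles (sEV) when contrast is below 18% or calibrated diameter below
#' 200 nm, large EVs otherwise.
#'
#' @name sizing
NULL

#' Construct a sizing calibration
#'
#' @param a Quadratic coefficient (nm per squared percent), > 0.
#' @param b Linear coefficient (nm per percent), > 0, so the polynomial is
#'   strictly increasing for non-negative contrast.
#' @param c Intercept (nm): the diameter assigned at zero contrast.
#' @param contrast_cutoff sEV classification cutoff on contrast (percent).
#' @param diameter_cutoff sEV classification cutoff on diameter (nm).
#' @param valid_contrast_range Contrast range (percent) over which the
#'   calibration is considered interpolating; values outside trigger a
#'   warning but are still computed.
#' @return An object of class `sizing_calibration`.
#' @examples
#' cal <- sizing_calibration()
#' contrast_to_diameter(cal, 9.1)  # 97.45 nm
#' @export
sizing_calibration <- function(a = 0.153, b = 7.096, c = 20.211,
                               contrast_cutoff = 18, diameter_cutoff = 200,
                               valid_contrast_range = c(0, 30)) {
  stopifnot(a > 0, b > 0, contrast_cutoff > 0, diameter_cutoff > 0,
            length(valid_contrast_range) == 2,
            valid_contrast_range[1] >= 0,
            diff(valid_contrast_range) > 0)
  cal <- structure(
    list(a = a, b = b, c = c,
         contrast_cutoff = contrast_cutoff,
         diameter_cutoff = diameter_cutoff,
         valid_contrast_range = valid_contrast_range),
    class = "sizing_calibration")
  # sanity: the two cutoffs must be mutually consistent, i.e. the contrast
  # rule never assigns sEV to a particle the diameter rule calls large
  if (contrast_to_diameter(cal, contrast_cutoff, warn = FALSE) >
      diameter_cutoff)
    stop("inconsistent cutoffs: diameter at the contrast cutoff exceeds ",
         "the diameter cutoff")
  cal
}

#' Map contrast to diameter
#'
#' Evaluates the calibration polynomial `Y = a*X^2 + b*X + c`.
#'
#' @param cal A [sizing_calibration()].
#' @param contrast Contrast in percent, >= 0. Vectorized.
#' @param warn Warn when contrast falls outside the calibration's valid
#'   range (extrapolation).
#' @return Diameter(s) in nm.
#' @export
contrast_to_diameter <- function(cal, contrast, warn = TRUE) {
  stopifnot(inherits(cal, "sizing_calibration"))
  if (any(contrast < 0)) stop("contrast must be non-negative")
  if (warn && any(contrast > cal$valid_contrast_range[2] |
                  contrast < cal$valid_contrast_range[1]))
    warning("contrast outside the calibration's valid range [",
            cal$valid_contrast_range[1], ", ", cal$valid_contrast_range[2],
            "]%; extrapolating")
  cal$a * contrast^2 + cal$b * contrast + cal$c
}

#' Map diameter to contrast (inverse calibration)
#'
#' Positive root of `a*X^2 + b*X + (c - Y) = 0`; exact inverse of
#' [contrast_to_diameter()] for diameters at or above the intercept `c`.
#' Used by the synthetic generator to inject particles of known size.
#'
#' @param cal A [sizing_calibration()].
#' @param diameter Diameter(s) in nm, >= `cal$c`. Vectorized.
#' @return Contrast(s) in percent.
#' @export
diameter_to_contrast <- function(cal, diameter) {
  stopifnot(inherits(cal, "sizing_calibration"))
  if (any(diameter < cal$c))
    stop("diameter below the calibration intercept (", cal$c,
         " nm) has no non-negative contrast")
  disc <- cal$b^2 - 4 * cal$a * (cal$c - diameter)
  (-cal$b + sqrt(disc)) / (2 * cal$a)
}

#' Classify detections as sEV or large EV
#'
#' A detection is an sEV when its contrast is below the contrast cutoff
#' *or* its calibrated diameter is below the diameter cutoff (inclusive
#' or); both inequalities are strict. Both component flags are kept in the
#' output alongside the final label.
#'
#' @param cal A [sizing_calibration()].
#' @param detections A detection data frame with a `contrast_pct` column
#'   (as produced by [detect_particles()]).
#' @return The data frame with added columns `diameter_nm`,
#'   `below_contrast_cutoff`, `below_diameter_cutoff` and `class`
#'   (`"sEV"` or `"largeEV"`).
#' @export
classify_particles <- function(cal, detections) {
  stopifnot(inherits(cal, "sizing_calibration"),
            is.data.frame(detections), "contrast_pct" %in% names(detections))
  if (nrow(detections) > 0 && any(detections$contrast_pct < 0))
    stop("detections must have non-negative contrast")
  d <- detections
  d$diameter_nm <- if (nrow(d)) contrast_to_diameter(cal, d$contrast_pct)
                   else numeric(0)
  d$below_contrast_cutoff <- d$contrast_pct < cal$contrast_cutoff
  d$below_diameter_cutoff <- d$diameter_nm < cal$diameter_cutoff
  d$class <- ifelse(d$below_contrast_cutoff | d$below_diameter_cutoff,
                    "sEV", "largeEV")
  d
}

#' Summary statistics of a detection set
#'
#' Mean and sample standard deviation (n - 1 denominator) of contrast and
#' of per-particle calibrated diameter, plus histogram counts.
#'
#' @param detections A detection data frame with `contrast_pct` and
#'   (after [classify_particles()]) `diameter_nm` columns. If
#'   `diameter_nm` is absent it is computed from `cal`.
#' @param cal A [sizing_calibration()] used when diameters are missing.
#' @param contrast_binwidth Histogram bin width for contrast (percent).
#' @param diameter_binwidth Histogram bin width for diameter (nm).
#' @return A list of class `detection_summary` with fields `n`,
#'   `contrast_mean`, `contrast_sd`, `diameter_mean`, `diameter_sd`,
#'   `sd_defined` (FALSE when n < 2, in which case sds are reported as 0),
#'   and histogram data frames `contrast_hist`, `diameter_hist`. With no
#'   detections an empty-summary sentinel (`n = 0`, all statistics `NA`)
#'   is returned.
#' @export
summarize_detections <- function(detections, cal = sizing_calibration(),
                                 contrast_binwidth = 1,
                                 diameter_binwidth = 10) {
  stopifnot(is.data.frame(detections))
  if (nrow(detections) == 0) {
    return(structure(list(n = 0L, contrast_mean = NA_real_,
                          contrast_sd = NA_real_, diameter_mean = NA_real_,
                          diameter_sd = NA_real_, sd_defined = FALSE,
                          contrast_hist = NULL, diameter_hist = NULL),
                     class = "detection_summary"))
  }
  x <- detections$contrast_pct
  y <- if ("diameter_nm" %in% names(detections)) detections$diameter_nm
       else contrast_to_diameter(cal, x)
  n <- length(x)
  hist_counts <- function(v, w) {
    breaks <- seq(floor(min(v) / w) * w, ceiling(max(v) / w) * w + w, by = w)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)
    data.frame(bin_left = h$breaks[-length(h$breaks)],
               bin_right = h$breaks[-1], count = h$counts)
  }
  structure(
    list(n = n,
         contrast_mean = mean(x),
         contrast_sd = if (n > 1) stats::sd(x) else 0,
         diameter_mean = mean(y),
         diameter_sd = if (n > 1) stats::sd(y) else 0,
         sd_defined = n > 1,
         contrast_hist = hist_counts(x, contrast_binwidth),
         diameter_hist = hist_counts(y, diameter_binwidth)),
    class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  if (x$n == 0) {
    cat("Empty detection summary (0 detections)\n")
    return(invisible(x))
  }
  cat(sprintf("Detections: %d\n", x$n))
  cat(sprintf("Contrast: %.2f +/- %.2f %%%s\n", x$contrast_mean,
              x$contrast_sd, if (x$sd_defined) "" else " (sd undefined, n<2)"))
  cat(sprintf("Diameter: %.2f +/- %.2f nm\n", x$diameter_mean,
              x$diameter_sd))
  invisible(x)
}
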