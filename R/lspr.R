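#' Localized surface plasmon resonance (LSPR) forward model
#'
#' The sensing surface is an array of gold nanodisks whose collective
#' electron oscillation produces a resonant extinction peak. When a
#' nanoparticle binds, the local refractive index rises, the resonance
#' red-shifts, extinction inside a narrow illumination band placed on the
#' short-wavelength shoulder drops, and transmitted intensity at the
#' particle's position increases. That transmission increase is the signal
#' the ratiometric detector picks up.
#'
#' @name lspr
NULL

#' Construct an LSPR extinction spectrum
#'
#' A single-resonance Lorentzian lineshape: extinction rises from a flat
#' baseline to `peak_extinction` at `peak_wavelength`, with full width at
#' half maximum `fwhm`.
#'
#' @param peak_wavelength Resonance peak position (nm).
#' @param fwhm Resonance linewidth, full width at half maximum (nm).
#' @param peak_extinction Extinction at the peak, a fraction in (0, 1).
#' @param baseline_extinction Off-resonance extinction, a fraction in
#'   `[0, peak_extinction)`.
#' @return An object of class `lspr_spectrum`.
#' @seealso [extinction()], [transmission_ratio()]
#' @export
lspr_spectrum <- function(peak_wavelength, fwhm = 120,
                          peak_extinction = 0.9, baseline_extinction = 0.05) {
  stopifnot(peak_wavelength > 0, fwhm > 0)
  if (!(peak_extinction > 0 && peak_extinction < 1))
    stop("peak_extinction must lie in (0, 1)")
  if (!(baseline_extinction >= 0 && baseline_extinction < peak_extinction))
    stop("baseline_extinction must lie in [0, peak_extinction)")
  structure(
    list(peak_wavelength = peak_wavelength, fwhm = fwhm,
         peak_extinction = peak_extinction,
         baseline_extinction = baseline_extinction),
    class = "lspr_spectrum")
}

#' Refractive-index response of the resonance
#'
#' Linear model for the peak position: `lambda(n) = lambda0 + S * (n - n0)`,
#' where `S` is the bulk refractive-index sensitivity in nm per refractive
#' index unit (RIU). Defaults are the measured values for the gold-nanodisk
#' surface: 659 nm in air and 242.42 nm/RIU.
#'
#' @param reference_peak Peak wavelength at the reference index (nm).
#' @param reference_index Reference refractive index (RIU).
#' @param sensitivity Peak shift per refractive-index unit (nm/RIU), > 0.
#' @return An object of class `ri_response`.
#' @export
ri_response <- function(reference_peak = 659, reference_index = 1.00,
                        sensitivity = 242.42) {
  stopifnot(reference_peak > 0, sensitivity > 0)
  structure(
    list(reference_peak = reference_peak, reference_index = reference_index,
         sensitivity = sensitivity),
    class = "ri_response")
}

#' Narrowband illumination
#'
#' Top-hat spectral band of the illumination after the bandpass filter.
#' Default is a 660/10 nm filter, placed on the left shoulder of the
#' water-immersed resonance.
#'
#' @param center Band center (nm).
#' @param fwhm Band width (nm), > 0.
#' @return An object of class `illumination_band`.
#' @export
illumination_band <- function(center = 660, fwhm = 10) {
  stopifnot(center > 0, fwhm > 0)
  structure(list(center = center, fwhm = fwhm), class = "illumination_band")
}

#' Bulk sensitivity from two peak measurements
#'
#' `S = (lambda_b - lambda_a) / (n_b - n_a)`, the slope of peak position
#' against refractive index, e.g. from peaks measured in air and in water.
#'
#' @param lambda_a,lambda_b Peak wavelengths (nm) in the two media.
#' @param n_a,n_b Refractive indices (RIU) of the two media; must differ.
#' @return Sensitivity in nm/RIU.
#' @examples
#' sensitivity_from_peaks(659, 739, 1.00, 1.33)  # 242.42
#' @export
sensitivity_from_peaks <- function(lambda_a, lambda_b, n_a, n_b) {
  if (n_a == n_b) stop("refractive indices must differ")
  (lambda_b - lambda_a) / (n_b - n_a)
}

#' Peak wavelength at a given refractive index
#'
#' @param response An [ri_response()].
#' @param n Local refractive index (RIU), > 0. Vectorized.
#' @return Peak wavelength(s) in nm, strictly increasing in `n`.
#' @export
peak_wavelength <- function(response, n) {
  stopifnot(inherits(response, "ri_response"), all(n > 0))
  response$reference_peak +
    response$sensitivity * (n - response$reference_index)
}

#' Evaluate the extinction spectrum
#'
#' `baseline + (peak - baseline) * L(lambda)` with `L` a unit-peak
#' Lorentzian of the spectrum's center and FWHM. Bounded in
#' `[baseline_extinction, peak_extinction]`, symmetric about the peak.
#'
#' @param spectrum An [lspr_spectrum()].
#' @param wavelength Wavelength(s) in nm, > 0. Vectorized.
#' @return Extinction fraction(s).
#' @export
extinction <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "lspr_spectrum"), all(wavelength > 0))
  hwhm <- spectrum$fwhm / 2
  L <- hwhm^2 / ((wavelength - spectrum$peak_wavelength)^2 + hwhm^2)
  spectrum$baseline_extinction +
    (spectrum$peak_extinction - spectrum$baseline_extinction) * L
}

#' Band-integrated transmission enhancement for a refractive-index increase
#'
#' Transmission through the sensor integrated over the illumination band,
#' for the resonance red-shifted by `S * delta_n`, relative to the
#' unshifted resonance:
#' `IR = integral_band (1 - ext_shifted) / integral_band (1 - ext_unshifted)`.
#' With the band on the short-wavelength shoulder the shift moves the
#' absorbing peak away from the band, so the ratio is >= 1 and equals 1 at
#' `delta_n = 0`. This is the physical origin of the per-pixel intensity
#' ratio measured by the detector.
#'
#' @param spectrum The unshifted [lspr_spectrum()] (medium-immersed).
#' @param response The [ri_response()] giving the shift per RIU.
#' @param band The [illumination_band()].
#' @param delta_n Local refractive-index increase (RIU), >= 0.
#' @param step Quadrature step for the trapezoidal band integral (nm).
#' @return Dimensionless intensity ratio, >= 1 on the left shoulder.
#' @export
transmission_ratio <- function(spectrum, response, band, delta_n,
                               step = 0.1) {
  stopifnot(inherits(spectrum, "lspr_spectrum"),
            inherits(response, "ri_response"),
            inherits(band, "illumination_band"),
            delta_n >= 0, step > 0)
  support <- 5 * spectrum$fwhm
  lo <- band$center - band$fwhm / 2
  hi <- band$center + band$fwhm / 2
  shifted_peak <- spectrum$peak_wavelength + response$sensitivity * delta_n
  if (hi < spectrum$peak_wavelength - support ||
      lo > shifted_peak + support)
    warning("illumination band lies outside the modeled spectral support; ",
            "transmission ratio reduces to the ratio of baselines")
  shifted <- spectrum
  shifted$peak_wavelength <- shifted_peak
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  t_shift <- trapz(grid, 1 - extinction(shifted, grid))
  t_ref <- trapz(grid, 1 - extinction(spectrum, grid))
  t_shift / t_ref
}

#' Export a spectrum as a two-column wavelength/extinction table
#'
#' @param spectrum An [lspr_spectrum()].
#' @param wavelengths Wavelength grid (nm); default spans the peak +/- 3 FWHM.
#' @param path Optional file path; if given, written as tab-separated text.
#' @return A data frame with columns `wavelength_nm`, `extinction`
#'   (invisibly when `path` is given).
#' @export
spectrum_table <- function(spectrum, wavelengths = NULL, path = NULL) {
  stopifnot(inherits(spectrum, "lspr_spectrum"))
  if (is.null(wavelengths))
    wavelengths <- seq(spectrum$peak_wavelength - 3 * spectrum$fwhm,
                       spectrum$peak_wavelength + 3 * spectrum$fwhm,
                       length.out = 601)
  tab <- data.frame(wavelength_nm = wavelengths,
                    extinction = extinction(spectrum, wavelengths))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(tab))
  }
  tab
}
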