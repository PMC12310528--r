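#' Ratiometric single-particle detection
#'
#' The detection pipeline: rigidly align the sample frame to the
#' background frame, divide to form the intensity-ratio (IR) image,
#' estimate the background IR noise sigma, threshold at
#' `IR = 1 + 3*sigma + 0.005`, and call particles as 8-connected
#' components of supra-threshold pixels. Per-particle contrast is
#' `(IR - 1) * 100%`.
#'
#' @name detection
NULL

#' Align a sample frame to a background frame
#'
#' Exhaustive search over integer-pixel shifts within `+/- max_shift`,
#' maximizing the normalized cross-correlation of the overlapping region.
#' Sub-pixel registration is deliberately not attempted: bound particles
#' are immobile and stage drift between frames is at most a few pixels.
#'
#' @param background,sample Numeric matrices of identical dimensions.
#' @param max_shift Largest shift searched (pixels), >= 0.
#' @param min_score Normalized cross-correlation below which alignment is
#'   considered failed.
#' @return A list with `aligned` (the sample shifted back into the
#'   background's frame of reference), `shift` (`c(dx, dy)` — the drift
#'   that was detected in the sample), and `score` (the correlation at
#'   the optimum).
#' @export
register_images <- function(background, sample, max_shift = 5,
                            min_score = 0.5) {
  stopifnot(is.matrix(background), is.matrix(sample),
            all(dim(background) == dim(sample)), max_shift >= 0)
  nr <- nrow(background); nc <- ncol(background)
  best <- list(score = -Inf, dx = 0L, dy = 0L)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      # sample content believed shifted by (dx, dy): compare
      # sample[r, c] with background[r - dy, c - dx] on the overlap
      r_s <- max(1, 1 + dy):min(nr, nr + dy)
      c_s <- max(1, 1 + dx):min(nc, nc + dx)
      s <- sample[r_s, c_s]
      b <- background[r_s - dy, c_s - dx]
      if (stats::sd(s) == 0 || stats::sd(b) == 0) next
      sc <- stats::cor(as.vector(s), as.vector(b))
      if (sc > best$score) best <- list(score = sc, dx = dx, dy = dy)
    }
  }
  if (!is.finite(best$score) || best$score < min_score)
    stop("alignment failure: best cross-correlation ",
         format(best$score, digits = 3), " below ", min_score)
  aligned <- apply_drift(sample, -best$dx, -best$dy,
                         max_shift = max(max_shift, 1))
  list(aligned = aligned, shift = c(dx = best$dx, dy = best$dy),
       score = best$score)
}

#' Form the ratiometric (intensity ratio) image
#'
#' `IR(p) = sample(p) / background(p)` on an aligned pair. Background
#' pixels below `floor_frac` times the background median are masked
#' invalid rather than divided (prevents blow-ups at dead pixels).
#'
#' @param sample,background Aligned numeric matrices of equal dimensions.
#' @param floor_frac Fraction of the background median below which a
#'   pixel is masked.
#' @param provenance Optional list recorded in the result (frame ids,
#'   applied shift).
#' @return An object of class `ratiometric_image`: list with `ir`
#'   (matrix, `NA` at masked pixels), `valid` (logical matrix) and
#'   `provenance`.
#' @export
ratiometric <- function(sample, background, floor_frac = 0.01,
                        provenance = list()) {
  stopifnot(is.matrix(sample), is.matrix(background),
            all(dim(sample) == dim(background)))
  floor_val <- floor_frac * stats::median(background)
  valid <- background > floor_val
  if (mean(valid) < 0.9)
    stop("degenerate input: more than 10% of background pixels below the ",
         "masking floor")
  ir <- matrix(NA_real_, nrow(sample), ncol(sample))
  ir[valid] <- sample[valid] / background[valid]
  structure(list(ir = ir, valid = valid, provenance = provenance),
            class = "ratiometric_image")
}

#' Estimate the background IR noise sigma
#'
#' Robust standard deviation of the background IR distribution:
#' `1.4826 * MAD` over valid pixels after excluding the brightest
#' `1 - exclude_quantile` fraction, so that the sparse particle pixels in
#' a sample IR image do not inflate the estimate. Deterministic.
#' Alternatively, sigma may be estimated from a particle-free
#' background-replicate IR pair (same estimator; simply pass that image).
#'
#' @param ir A [ratiometric()] image.
#' @param exclude_quantile Quantile above which pixels are excluded
#'   before the robust estimate (particle exclusion).
#' @param min_pixels Fewest valid pixels accepted.
#' @return Sigma, the robust sd of background IR values.
#' @export
estimate_sigma <- function(ir, exclude_quantile = 0.995,
                           min_pixels = 1000) {
  stopifnot(inherits(ir, "ratiometric_image"))
  v <- ir$ir[ir$valid]
  if (length(v) < min_pixels)
    stop("too few valid pixels (", length(v), " < ", min_pixels,
         ") for a sigma estimate")
  cut <- stats::quantile(v, exclude_quantile, names = FALSE)
  v <- v[v <= cut]
  stats::mad(v, constant = 1.4826)
}

#' The statistical detection threshold
#'
#' `value = 1 + k*sigma + margin`, by default `1 + 3*sigma + 0.005`:
#' three standard deviations of background IR noise plus an absolute
#' safety margin of 0.5% contrast.
#'
#' @param sigma Background IR standard deviation, >= 0.
#' @param k Sigma multiplier.
#' @param margin Additive safety margin on the IR scale.
#' @return An object of class `detection_threshold` with fields `sigma`,
#'   `k`, `margin`, `value`.
#' @export
detection_threshold <- function(sigma, k = 3, margin = 0.005) {
  stopifnot(sigma >= 0, k >= 0, margin >= 0)
  structure(list(sigma = sigma, k = k, margin = margin,
                 value = 1 + k * sigma + margin),
            class = "detection_threshold")
}

# 8- or 4-connected component labeling over the sparse supra-threshold
# pixel set (union-find); foreground is a tiny fraction of the image so a
# loop over foreground pixels is cheap and connectivity is explicit
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0)
    return(list(labels = integer(0), pixels = idx, n_components = 0L))
  nr <- nrow(mask)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]       # column-major linear index
  pos <- integer(0)
  pos[key] <- seq_len(n)                        # sparse reverse lookup
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- if (connectivity == 8)
    rbind(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  else rbind(c(0L, -1L), c(-1L, 0L))            # prior neighbors only
  nc <- ncol(mask)
  for (i in seq_len(n)) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
      if (rr < 1L || rr > nr || c2 < 1L || c2 > nc) next
      j <- pos[(c2 - 1L) * nr + rr]
      if (!is.na(j) && j > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  list(labels = labels, pixels = idx, n_components = length(unique(roots)))
}

#' Detect particles in a ratiometric image
#'
#' Pixels with `IR >= threshold` are grouped into connected components
#' (8-connectivity by default); components smaller than `min_area` pixels
#' are discarded as single-pixel noise hits. Each surviving component is
#' one detected particle with an intensity-weighted centroid (weights
#' `IR - 1`), `peak_ir` the maximum IR in the component, and contrast
#' `(peak_ir - 1) * 100`. The peak-pixel statistic preserves the size
#' encoding of a sub-diffraction particle under the PSF; per-component
#' mean is available via `contrast_stat = "mean"`.
#'
#' @param ir A [ratiometric()] image.
#' @param threshold A [detection_threshold()] (or a bare numeric IR
#'   cutoff).
#' @param min_area Smallest accepted component area (pixels).
#' @param connectivity Pixel connectivity, 4 or 8.
#' @param pixel_size Optional um/pixel scale; when given, centroids are
#'   also reported in micrometers.
#' @param contrast_stat Aggregation of component IR into contrast:
#'   `"peak"` (default) or `"mean"`.
#' @param timepoint Optional acquisition time (min) stamped on every
#'   detection.
#' @return A data frame with one row per particle: `id`, `x_px`, `y_px`,
#'   `x_um`, `y_um`, `area_px`, `peak_ir`, `contrast_pct`,
#'   `timepoint_min`, plus the pixel footprints in attribute
#'   `"footprints"` (list of row/col matrices).
#' @export
detect_particles <- function(ir, threshold, min_area = 2, connectivity = 8,
                             pixel_size = NULL,
                             contrast_stat = c("peak", "mean"),
                             timepoint = NA_real_) {
  stopifnot(inherits(ir, "ratiometric_image"))
  contrast_stat <- match.arg(contrast_stat)
  thr <- if (inherits(threshold, "detection_threshold")) threshold$value
         else as.numeric(threshold)
  mask <- !is.na(ir$ir) & ir$ir >= thr
  lab <- label_components(mask, connectivity)
  empty <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), peak_ir = numeric(0),
                      contrast_pct = numeric(0), timepoint_min = numeric(0))
  attr(empty, "footprints") <- list()
  if (lab$n_components == 0) return(empty)
  comps <- split(seq_len(nrow(lab$pixels)), lab$labels)
  keep <- vapply(comps, length, integer(1)) >= min_area
  comps <- comps[keep]
  if (length(comps) == 0) return(empty)
  rows <- lapply(comps, function(px) {
    r <- lab$pixels[px, 1]; cc <- lab$pixels[px, 2]
    vals <- ir$ir[cbind(r, cc)]
    w <- vals - 1
    if (sum(w) <= 0) w <- rep(1, length(vals))
    peak <- max(vals)
    contr <- if (contrast_stat == "peak") (peak - 1) * 100
             else (mean(vals) - 1) * 100
    data.frame(x_px = sum((cc - 0.5) * w) / sum(w),
               y_px = sum((r - 0.5) * w) / sum(w),
               area_px = length(vals), peak_ir = peak,
               contrast_pct = contr)
  })
  out <- do.call(rbind, rows)
  # stable order: raster order of the component's first pixel
  o <- order(vapply(comps, function(px)
    min((lab$pixels[px, 2] - 1) * nrow(mask) + lab$pixels[px, 1]),
    numeric(1)))
  out <- out[o, , drop = FALSE]
  footprints <- lapply(comps[o], function(px) lab$pixels[px, , drop = FALSE])
  out$id <- seq_len(nrow(out))
  out$x_um <- if (is.null(pixel_size)) NA_real_ else out$x_px * pixel_size
  out$y_um <- if (is.null(pixel_size)) NA_real_ else out$y_px * pixel_size
  out$timepoint_min <- timepoint
  out <- out[, c("id", "x_px", "y_px", "x_um", "y_um", "area_px",
                 "peak_ir", "contrast_pct", "timepoint_min")]
  rownames(out) <- NULL
  attr(out, "footprints") <- footprints
  out
}
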