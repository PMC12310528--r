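# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written with different algorithms from the
# package code paths they check.

# small field/config used throughout: 256x256 px sub-field of the sensor
tiny_fov <- function(px = 256) field_of_view(px * 0.1625, px * 0.1625, 0.1625)

tiny_config <- function(seed = 1L, px = 256, ...) {
  default_config(fov = list(width = px * 0.1625, height = px * 0.1625,
                            pixel_size = 0.1625),
                 seed = as.integer(seed), ...)
}

# wrap a bare IR matrix as a ratiometric_image
as_ir <- function(m) {
  structure(list(ir = m, valid = !is.na(m), provenance = list()),
            class = "ratiometric_image")
}

# ground-truth particles pixel-centered on a regular grid, well separated
grid_particles <- function(fov, contrasts, cal = sizing_calibration(),
                           spacing_px = 16, margin_px = 10) {
  n <- length(contrasts)
  cols <- floor((fov$nx - 2 * margin_px) / spacing_px)
  stopifnot(cols >= 1, n <= cols * floor((fov$ny - 2 * margin_px) / spacing_px))
  ix <- (seq_len(n) - 1) %% cols
  iy <- (seq_len(n) - 1) %/% cols
  px_x <- margin_px + ix * spacing_px + 1L   # pixel index
  px_y <- margin_px + iy * spacing_px + 1L
  data.frame(id = seq_len(n),
             x_um = (px_x - 0.5) * fov$pixel_size,
             y_um = (px_y - 0.5) * fov$pixel_size,
             diameter_nm = contrast_to_diameter(cal, contrasts, warn = FALSE),
             binding_time_min = 0,
             survives_wash = TRUE)
}

# brute-force BFS flood-fill labeling (independent of the package's
# union-find); scans in column-major order so component numbering matches
# the implementation's raster ordering
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 4) offs <- offs[abs(offs$dr) + abs(offs$dc) == 1, ]
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs$dr[k]; cc <- p[2] + offs$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# brute-force detection: flood-fill labels + direct per-component stats
oracle_detect <- function(ir_mat, thr, min_area = 2, connectivity = 8) {
  mask <- !is.na(ir_mat) & ir_mat >= thr
  lab <- oracle_label(mask, connectivity)
  out <- list()
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    vals <- ir_mat[px]
    w <- vals - 1
    if (sum(w) <= 0) w <- rep(1, length(vals))
    out[[length(out) + 1]] <- data.frame(
      x_px = sum((px[, 2] - 0.5) * w) / sum(w),
      y_px = sum((px[, 1] - 0.5) * w) / sum(w),
      area_px = nrow(px),
      peak_ir = max(vals),
      contrast_pct = (max(vals) - 1) * 100)
  }
  if (length(out) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), peak_ir = numeric(0),
                      contrast_pct = numeric(0)))
  df <- do.call(rbind, out)
  df$id <- seq_len(nrow(df))
  df
}

# independent fine-grid quadrature of the band-integrated transmission
# ratio: midpoint rule at 0.01 nm with the Lorentzian written out inline
oracle_transmission_ratio <- function(peak, fwhm, peak_ext, base_ext,
                                      S, band_center, band_fwhm, delta_n,
                                      step = 0.01) {
  lor <- function(lam, center) {
    h <- fwhm / 2
    base_ext + (peak_ext - base_ext) * h^2 / ((lam - center)^2 + h^2)
  }
  lo <- band_center - band_fwhm / 2
  hi <- band_center + band_fwhm / 2
  mid <- seq(lo + step / 2, hi - step / 2, by = step)
  sum(1 - lor(mid, peak + S * delta_n)) / sum(1 - lor(mid, peak))
}

# fraction of ground-truth particles with a detection within radius px
recall_of <- function(truth, detections, fov, radius = 2) {
  if (nrow(truth) == 0) return(NA_real_)
  if (nrow(detections) == 0) return(0)
  tx <- truth$x_um / fov$pixel_size
  ty <- truth$y_um / fov$pixel_size
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(sqrt((detections$x_px - tx[i])^2 +
             (detections$y_px - ty[i])^2) <= radius)
  }, logical(1))
  mean(hit)
}
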