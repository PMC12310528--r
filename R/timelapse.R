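#' Time-lapse aggregation, wash analysis and replicate statistics
#'
#' Detections from successive before-wash (BW) frames are linked by
#' nearest-centroid matching — a bound particle is immobilized, so it
#' reappears at the same position — giving cumulative binding counts that
#' are robust to a particle flickering around the threshold in a single
#' frame. The after-wash (AW) frame is compared against the final BW
#' state to quantify retention, and replicate runs are summarized as
#' mean +/- sample sd.
#'
#' @name timelapse
NULL

#' Match detections across two timepoints
#'
#' Greedy nearest-centroid matching: candidate pairs within `radius`
#' pixels are accepted in order of increasing distance (ties broken by
#' previous then current detection id); each previous detection matches
#' at most one current detection. Unmatched current detections are "new".
#'
#' @param previous,current Detection data frames (see
#'   [detect_particles()]).
#' @param radius Match radius in pixels, > 0.
#' @return A list with `matched` (data frame: `prev_id`, `cur_id`,
#'   `distance_px`) and `new` (rows of `current` with no match).
#' @export
match_detections <- function(previous, current, radius = 2) {
  stopifnot(is.data.frame(previous), is.data.frame(current), radius > 0)
  if (nrow(previous) == 0 || nrow(current) == 0) {
    return(list(matched = data.frame(prev_id = integer(0),
                                     cur_id = integer(0),
                                     distance_px = numeric(0)),
                new = current))
  }
  dx <- outer(previous$x_px, current$x_px, "-")
  dy <- outer(previous$y_px, current$y_px, "-")
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= radius, arr.ind = TRUE)
  matched <- data.frame(prev_id = integer(0), cur_id = integer(0),
                        distance_px = numeric(0))
  if (nrow(cand) > 0) {
    ord <- order(dist[cand], previous$id[cand[, 1]], current$id[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
    used_prev <- logical(nrow(previous))
    used_cur <- logical(nrow(current))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_prev[i] || used_cur[j]) next
      used_prev[i] <- TRUE; used_cur[j] <- TRUE
      matched <- rbind(matched,
                       data.frame(prev_id = previous$id[i],
                                  cur_id = current$id[j],
                                  distance_px = dist[i, j]))
    }
  }
  new_rows <- current[!current$id %in% matched$cur_id, , drop = FALSE]
  list(matched = matched, new = new_rows)
}

#' Cumulative counts over a before-wash series
#'
#' For ordered BW timepoints, counts detections that are new relative to
#' the previous timepoint (by centroid matching) and accumulates them.
#' Raw per-frame counts are reported alongside; a decrease in the raw
#' count between successive BW frames raises a data-quality warning
#' (binding is cumulative, so raw counts should not fall before the
#' wash).
#'
#' @param detection_list Named list of detection data frames, one per BW
#'   timepoint, in time order (names = minutes).
#' @param radius Match radius in pixels.
#' @return A data frame with `time_min`, `n_raw` (detections in the
#'   frame), `n_new` (unmatched against the previous frame) and
#'   `cumulative` (running total of new detections).
#' @export
counts_over_time <- function(detection_list, radius = 2) {
  stopifnot(is.list(detection_list), length(detection_list) >= 1)
  times <- as.numeric(names(detection_list))
  if (anyNA(times)) times <- seq_along(detection_list)
  if (is.unsorted(times)) stop("timepoints must be ordered")
  n_raw <- vapply(detection_list, nrow, integer(1))
  n_new <- integer(length(detection_list))
  n_new[1] <- n_raw[1]
  if (length(detection_list) > 1) {
    for (k in 2:length(detection_list)) {
      m <- match_detections(detection_list[[k - 1]], detection_list[[k]],
                            radius = radius)
      n_new[k] <- nrow(m$new)
    }
    if (any(diff(n_raw) < 0))
      warning("raw per-frame counts decrease between before-wash ",
              "timepoints; check acquisition quality")
  }
  data.frame(time_min = times, n_raw = as.integer(n_raw),
             n_new = n_new, cumulative = cumsum(n_new))
}

#' Before-wash / after-wash comparison
#'
#' @param bw_final Detections in the final before-wash frame.
#' @param aw Detections in the after-wash frame.
#' @param cal A [sizing_calibration()] for the AW contrast/size summary.
#' @return A list with `bw_count`, `aw_count` (= retained count),
#'   `retained_fraction` (`aw_count / bw_count`; `NA` sentinel when
#'   `bw_count` is 0) and `aw_summary` (a [summarize_detections()]
#'   result).
#' @export
wash_analysis <- function(bw_final, aw, cal = sizing_calibration()) {
  stopifnot(is.data.frame(bw_final), is.data.frame(aw))
  bw_n <- nrow(bw_final)
  aw_n <- nrow(aw)
  list(bw_count = bw_n, aw_count = aw_n,
       retained_fraction = if (bw_n > 0) aw_n / bw_n else NA_real_,
       aw_summary = summarize_detections(aw, cal))
}

#' Replicate mean and sample standard deviation
#'
#' Summary across independent runs (e.g. particle counts from replicate
#' devices): arithmetic mean and n-1 standard deviation.
#'
#' @param counts Numeric vector, length >= 2.
#' @param digits Rounding applied to the reported values; `0` (default)
#'   rounds to integers as counts are reported, `NULL` disables rounding.
#' @return A list with `n`, `mean`, `sd` and unrounded `mean_raw`,
#'   `sd_raw`.
#' @examples
#' replicate_summary(c(1553, 1451, 1647))  # mean 1550, sd 98
#' @export
replicate_summary <- function(counts, digits = 0) {
  if (length(counts) < 2)
    stop("replicate summary requires at least 2 runs")
  m <- mean(counts)
  s <- stats::sd(counts)
  list(n = length(counts),
       mean = if (is.null(digits)) m else round(m, digits),
       sd = if (is.null(digits)) s else round(s, digits),
       mean_raw = m, sd_raw = s)
}
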