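cal <- sizing_calibration()

fake_dets <- function(x, y, id = seq_along(x)) {
  n <- length(x)
  data.frame(id = id, x_px = x, y_px = y, x_um = rep(NA_real_, n),
             y_um = rep(NA_real_, n), area_px = rep(3L, n),
             peak_ir = rep(1.1, n), contrast_pct = rep(10, n),
             timepoint_min = rep(NA_real_, n))
}

test_that("detection matching partitions into matched and new", {
  a <- fake_dets(c(10, 20, 30), c(10, 20, 30))
  same <- match_detections(a, a)
  expect_equal(nrow(same$matched), 3)
  expect_equal(nrow(same$new), 0)
  far <- fake_dets(c(100, 120), c(100, 120))
  m <- match_detections(a, far)
  expect_equal(nrow(m$matched), 0)
  expect_equal(nrow(m$new), 2)
  # each previous detection matches at most one current detection
  close_pair <- fake_dets(c(10, 10.5), c(10, 10))
  m2 <- match_detections(fake_dets(10, 10), close_pair)
  expect_equal(nrow(m2$matched), 1)
  expect_equal(m2$matched$cur_id, 1)   # nearer one wins
  expect_equal(nrow(m2$new), 1)
})

test_that("cumulative counts accumulate new detections over time", {
  one <- counts_over_time(list(`20` = fake_dets(c(5, 15), c(5, 15))))
  expect_equal(one$cumulative, 2)
  dets <- list(`20` = fake_dets(c(5, 15), c(5, 15)),
               `40` = fake_dets(c(5, 15, 25), c(5, 15, 25)),
               `60` = fake_dets(c(5, 15, 25, 35), c(5, 15, 25, 35)))
  ct <- counts_over_time(dets)
  expect_equal(ct$n_new, c(2, 1, 1))
  expect_equal(ct$cumulative, c(2, 3, 4))
  expect_true(all(diff(ct$cumulative) >= 0))
  # empty frames give zeros
  e <- fake_dets(numeric(0), numeric(0))
  expect_equal(counts_over_time(list(`20` = e, `40` = e))$cumulative,
               c(0, 0))
  # a raw-count decrease before the wash is flagged
  expect_warning(
    counts_over_time(list(`20` = fake_dets(c(5, 15), c(5, 15)),
                          `40` = fake_dets(5, 5))),
    "decrease")
})

test_that("new-detection counts recover per-interval binding ground truth", {
  fov <- tiny_fov()
  sched <- flow_schedule()
  imaging <- imaging_config()
  # well-separated particles with known binding times
  p <- grid_particles(fov, rep(8, 36), cal)
  set.seed(81)
  p$binding_time_min <- sample(c(5, 25, 45), 36, replace = TRUE)
  p$survives_wash <- rep(c(TRUE, FALSE), 18)
  series <- make_series(fov, p, imaging, sched, cal, seed = 81)
  cfg <- tiny_config(seed = 81)
  rep_ <- analyze_series(series, cfg)
  truth_new <- as.vector(table(cut(p$binding_time_min,
                                   c(0, 20, 40, 60), right = TRUE)))
  expect_equal(rep_$counts$n_new, truth_new)
  expect_equal(rep_$counts$cumulative, cumsum(truth_new))
})

test_that("wash analysis reports retention against the final BW state", {
  bw <- fake_dets(c(5, 15, 25), c(5, 15, 25))
  full <- wash_analysis(bw, bw, cal)
  expect_equal(full$retained_fraction, 1.0)
  none <- wash_analysis(bw, bw[0, ], cal)
  expect_equal(none$retained_fraction, 0)
  expect_equal(none$aw_summary$n, 0)
  undef <- wash_analysis(bw[0, ], bw[0, ], cal)
  expect_true(is.na(undef$retained_fraction))
})

test_that("synthetic wash retention lands in the binomial interval", {
  cfg <- tiny_config(seed = 91, simulation = list(n_candidates = 400,
                                                  rate_constant = 0.04))
  fov <- panorama:::fov_from_config(cfg)
  sched <- flow_schedule()
  p <- simulate_binding(400, 0.04, sched, 0.575, fov, seed = 91)
  series <- make_series(fov, p, panorama:::imaging_from_config(cfg),
                        sched, cal, seed = 91)
  rep_ <- analyze_series(series, cfg)
  n <- rep_$wash$bw_count
  ci <- 3 * sqrt(0.575 * (1 - 0.575) / n)
  expect_lt(abs(rep_$wash$retained_fraction - 0.575), ci + 0.02)
})

test_that("replicate summaries give the mean and n-1 sd", {
  r1 <- replicate_summary(c(1553, 1451, 1647))
  expect_equal(r1$mean, 1550)
  expect_equal(r1$sd, 98)
  r2 <- replicate_summary(c(893, 857, 905))
  expect_equal(r2$mean, 885)
  expect_equal(r2$sd, 25)
  expect_equal(replicate_summary(c(7, 7, 7))$sd, 0)
  expect_error(replicate_summary(42), "at least 2")
  # invariant under permutation
  perm <- replicate_summary(c(1647, 1553, 1451))
  expect_equal(perm[c("mean", "sd")], r1[c("mean", "sd")])
})
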