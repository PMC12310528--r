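fov <- tiny_fov()
cal <- sizing_calibration()
sched <- flow_schedule()

test_that("flow schedule arithmetic and invariants", {
  expect_equal(push_volume(sched), 15)
  expect_equal(imaging_times(sched), c(20, 40, 60))
  expect_error(flow_schedule(imaging_interval = 25), "divide")
  expect_error(flow_schedule(pushpull_rate = -1))
})

test_that("binding simulation follows a truncated exponential", {
  expect_equal(nrow(simulate_binding(500, 0, sched, 0.5, fov, seed = 1)), 0)
  p_all <- simulate_binding(400, 0.05, sched, 1, fov, seed = 2)
  expect_true(all(p_all$survives_wash))
  expect_true(all(p_all$binding_time_min >= 0 &
                  p_all$binding_time_min <= 60))
  expect_true(all(p_all$x_um >= 0 & p_all$x_um <= fov$width))
  # empirical binding-time CDF vs the closed-form truncated exponential
  rate <- -log(0.25) / 60          # ~75% of candidates bind by 60 min
  p <- simulate_binding(2000, rate, sched, 0.5, fov, seed = 3)
  expect_equal(nrow(p) / 2000, 0.75, tolerance = 0.05)
  n <- nrow(p)
  for (t in c(10, 20, 30, 40, 50)) {
    theo <- (1 - exp(-rate * t)) / (1 - exp(-rate * 60))
    emp <- mean(p$binding_time_min <= t)
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / n))
  }
  # cumulative bound counts are non-decreasing in time by construction
  counts <- vapply(c(20, 40, 60),
                   function(t) sum(p$binding_time_min <= t), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("binding simulation is reproducible under its seed", {
  a <- simulate_binding(300, 0.03, sched, 0.6, fov, seed = 9)
  b <- simulate_binding(300, 0.03, sched, 0.6, fov, seed = 9)
  expect_identical(a, b)
})

test_that("noiseless frames encode particle contrast exactly", {
  cfg <- imaging_config(per_frame_noise_sd = 0)
  bg <- render_frame(fov, NULL, cfg, cal, noise = FALSE, seed = 5)
  # no particles: frame is exactly the textured background
  expect_identical(render_frame(fov, NULL, cfg, cal, noise = FALSE,
                                seed = 5), bg)
  # one pixel-centered particle at contrast 9.1%: peak ratio is exact
  p <- grid_particles(fov, 9.1, cal)
  fr <- render_frame(fov, p, cfg, cal, noise = FALSE, seed = 5)
  expect_equal(max(fr / bg), 1.091, tolerance = 1e-9)
  # many isolated pixel-centered particles: detected contrast equals
  # injected contrast to within 1e-6
  contrasts <- seq(3, 12, length.out = 24)
  p <- grid_particles(fov, contrasts, cal)
  fr <- render_frame(fov, p, cfg, cal, noise = FALSE, seed = 5)
  ir <- ratiometric(fr, bg)
  det <- detect_particles(ir, detection_threshold(0), min_area = 2)
  expect_equal(nrow(det), 24)
  m <- match_detections(
    data.frame(id = p$id, x_px = p$x_um / fov$pixel_size,
               y_px = p$y_um / fov$pixel_size), det, radius = 2)
  expect_equal(nrow(m$matched), 24)
  got <- det$contrast_pct[match(m$matched$cur_id, det$id)]
  expect_equal(got, contrasts[m$matched$prev_id], tolerance = 1e-6)
})

test_that("camera noise scales as one over the square root of frames averaged", {
  big <- field_of_view(360 * 0.1625, 360 * 0.1625, 0.1625)  # ~1.3e5 px
  cfg <- imaging_config(per_frame_noise_sd = 0.0118, frames_averaged = 100,
                        texture_sd = 0)
  quiet <- render_frame(big, NULL, cfg, cal, noise = FALSE, seed = 8)
  noisy <- render_frame(big, NULL, cfg, cal, noise = TRUE, seed = 8)
  rel_sd <- sd(noisy - quiet) / cfg$background_level
  expect_equal(rel_sd, 0.0118 / 10, tolerance = 0.02)
})

test_that("particles outside the field are skipped with a warning", {
  cfg <- imaging_config(per_frame_noise_sd = 0)
  p <- data.frame(id = 1, x_um = fov$width + 5, y_um = 5, diameter_nm = 100,
                  binding_time_min = 0, survives_wash = TRUE)
  expect_warning(fr <- render_frame(fov, p, cfg, cal, noise = FALSE,
                                    seed = 5), "outside")
  expect_identical(fr, render_frame(fov, NULL, cfg, cal, noise = FALSE,
                                    seed = 5))
})

test_that("rigid drift is an exact integer translation with bounds", {
  img <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_equal(apply_drift(img, 0, 0), img, ignore_attr = TRUE)
  shifted <- apply_drift(img, 3, -2)
  expect_equal(shifted[10, 20], img[12, 17])
  expect_error(apply_drift(img, 50, 0), "max_shift")
})

test_that("an acquisition series has the expected frames and ground truth", {
  cfg <- tiny_config(seed = 21, simulation = list(n_candidates = 150))
  fov2 <- panorama:::fov_from_config(cfg)
  p <- simulate_binding(150, 0.023, sched, 0.575, fov2, seed = 21)
  series <- make_series(fov2, p, panorama:::imaging_from_config(cfg),
                        sched, cal, seed = 21)
  expect_s3_class(series, "acquisition_series")
  expect_equal(names(series$frames), c("20", "40", "60"))
  expect_equal(dim(series$background), c(fov2$ny, fov2$nx))
  # AW ground truth is a subset of BW ground truth
  expect_true(all(series$truth$survives_wash %in% c(TRUE, FALSE)))
  expect_lte(sum(series$truth$survives_wash), nrow(series$truth))
  # empty particle list: frames equal background up to noise
  empty <- simulate_binding(0, 0.02, sched, 0.5, fov2, seed = 21)
  s0 <- make_series(fov2, empty, panorama:::imaging_from_config(cfg),
                    sched, cal, seed = 21)
  expect_lt(max(abs(s0$frames[["60"]] - s0$background)) /
              cfg$imaging$background_level, 0.01)
})

test_that("ratiometric background replicates are centered on 1", {
  cfg <- tiny_config(seed = 31)
  fov2 <- panorama:::fov_from_config(cfg)
  s <- make_series(fov2, simulate_binding(0, 0, sched, 1, fov2, seed = 31),
                   panorama:::imaging_from_config(cfg), sched, cal,
                   seed = 31)
  ir <- ratiometric(s$background_replicate, s$background)
  v <- ir$ir[ir$valid]
  expect_lt(abs(mean(v) - 1), 3 * sd(v) / sqrt(length(v)) + 1e-5)
})
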