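fov <- tiny_fov()
cal <- sizing_calibration()

test_that("registration recovers integer drift by cross-correlation", {
  set.seed(41)
  img <- 100 + 10 * matrix(rnorm(128 * 128), 128, 128)
  r0 <- register_images(img, img, max_shift = 4)
  expect_equal(unname(r0$shift), c(0L, 0L))
  expect_equal(r0$score, 1.0)
  drifted <- apply_drift(img, 3, -2)
  r <- register_images(img, drifted, max_shift = 5)
  expect_equal(unname(r$shift), c(3L, -2L))
  # central region restored exactly after de-drifting
  expect_equal(r$aligned[10:100, 10:100], img[10:100, 10:100])
  # uncorrelated images cannot be aligned
  noise <- matrix(rnorm(128 * 128), 128, 128)
  expect_error(register_images(img, noise, max_shift = 2), "alignment")
})

test_that("the ratiometric image is the pixelwise sample/background ratio", {
  bg <- matrix(1000, 32, 32)
  expect_true(all(ratiometric(bg, bg)$ir == 1))
  expect_true(all(abs(ratiometric(1.05 * bg, bg)$ir - 1.05) < 1e-12))
  bg2 <- bg; bg2[5, 5] <- 0
  ir <- ratiometric(bg, bg2)
  expect_true(is.na(ir$ir[5, 5]))
  expect_false(ir$valid[5, 5])
  expect_true(all(is.finite(ir$ir[ir$valid])))
  # mostly-dead background is degenerate
  dead <- matrix(0, 32, 32); dead[1:3, ] <- 1000
  expect_error(ratiometric(bg, dead), "degenerate")
})

test_that("sigma estimation is robust to sparse particles", {
  # noiseless identical pair
  bg <- matrix(1000, 64, 64)
  expect_equal(estimate_sigma(ratiometric(bg, bg)), 0)
  # synthetic IR with configured background sd: estimate within 10%
  cfg <- tiny_config(seed = 51)
  fov2 <- panorama:::fov_from_config(cfg)
  imaging <- panorama:::imaging_from_config(cfg)
  sched <- flow_schedule()
  p <- simulate_binding(120, 0.023, sched, 0.6, fov2, seed = 51)
  s <- make_series(fov2, p, imaging, sched, cal, seed = 51)
  ir <- ratiometric(s$frames[["60"]], s$background)
  expect_equal(estimate_sigma(ir), 0.00167, tolerance = 0.10)
  # on a particle-free image the robust estimate agrees with the plain sd
  ir0 <- ratiometric(s$background_replicate, s$background)
  expect_equal(estimate_sigma(ir0), sd(ir0$ir[ir0$valid]),
               tolerance = 0.05)
  expect_error(estimate_sigma(ratiometric(matrix(1, 10, 10),
                                          matrix(1, 10, 10))),
               "too few")
})

test_that("the detection threshold is 1 + k*sigma + margin", {
  expect_equal(detection_threshold(0)$value, 1.005)
  expect_equal(detection_threshold(0.00167)$value, 1.01001)
  expect_equal(detection_threshold(0.01)$value, 1.035)
  expect_error(detection_threshold(-0.1))
})

test_that("particle calling matches ground truth on a synthetic frame", {
  cfg <- tiny_config(seed = 61)
  fov2 <- panorama:::fov_from_config(cfg)
  imaging <- panorama:::imaging_from_config(cfg)
  p <- grid_particles(fov2, rep(9, 50), cal)
  tex <- panorama:::make_texture(fov2, imaging, 61)
  bg <- render_frame(fov2, NULL, imaging, cal, texture = tex, seed = 61)
  fr <- render_frame(fov2, p, imaging, cal, texture = tex, seed = 62)
  ir <- ratiometric(fr, bg)
  thr <- detection_threshold(estimate_sigma(ir))
  det <- detect_particles(ir, thr, pixel_size = fov2$pixel_size)
  expect_equal(nrow(det), 50)
  expect_equal(mean(det$contrast_pct), 9, tolerance = 0.05)
  expect_true(all(abs(det$contrast_pct - 9) < 1))
  expect_true(all(det$peak_ir >= thr$value))
  expect_equal(det$x_um, det$x_px * fov2$pixel_size)
})

test_that("a uniform ratio image yields no detections", {
  ir <- as_ir(matrix(1, 64, 64))
  det <- detect_particles(ir, detection_threshold(0.001))
  expect_equal(nrow(det), 0)
})

test_that("min_area suppresses single-pixel hits and connectivity is 8", {
  m <- matrix(1, 32, 32)
  m[5, 5] <- 1.1                       # lone pixel
  m[cbind(c(10, 11), c(10, 11))] <- 1.1  # diagonal pair
  det <- detect_particles(as_ir(m), 1.05, min_area = 2, connectivity = 8)
  expect_equal(nrow(det), 1)
  expect_equal(det$area_px, 2)
  det4 <- detect_particles(as_ir(m), 1.05, min_area = 2, connectivity = 4)
  expect_equal(nrow(det4), 0)          # diagonal pair splits under 4-conn
  det1 <- detect_particles(as_ir(m), 1.05, min_area = 1)
  expect_equal(nrow(det1), 2)
})

test_that("segmentation equals the brute-force flood-fill oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    ir_mat <- 1 + matrix(rnorm(64 * 64, 0, 0.005), 64, 64)
    thr <- 1.005
    det <- detect_particles(as_ir(ir_mat), thr, min_area = 2)
    orc <- oracle_detect(ir_mat, thr, min_area = 2)
    expect_equal(nrow(det), nrow(orc))
    expect_equal(det$area_px, orc$area_px)
    expect_equal(det$peak_ir, orc$peak_ir)
    expect_equal(det$contrast_pct, orc$contrast_pct)
    expect_equal(det$x_px, orc$x_px, tolerance = 1e-12)
    expect_equal(det$y_px, orc$y_px, tolerance = 1e-12)
  }
})

test_that("sub-pixel positions lose at most the PSF sampling bound", {
  cfg <- tiny_config(seed = 71)
  fov2 <- panorama:::fov_from_config(cfg)
  imaging <- imaging_config(per_frame_noise_sd = 0)
  sig_px <- imaging$psf_sigma_um / fov2$pixel_size
  loss <- exp(-0.25 / sig_px^2)        # worst case: center on a pixel corner
  set.seed(71)
  p <- grid_particles(fov2, runif(40, 5, 12), cal)
  injected <- diameter_to_contrast(cal, p$diameter_nm)
  p$x_um <- p$x_um + runif(40, -0.5, 0.5) * fov2$pixel_size
  p$y_um <- p$y_um + runif(40, -0.5, 0.5) * fov2$pixel_size
  bg <- render_frame(fov2, NULL, imaging, cal, noise = FALSE, seed = 71)
  fr <- render_frame(fov2, p, imaging, cal, noise = FALSE, seed = 71)
  det <- detect_particles(ratiometric(fr, bg), detection_threshold(0))
  expect_equal(nrow(det), 40)
  m <- match_detections(
    data.frame(id = p$id, x_px = p$x_um / fov2$pixel_size,
               y_px = p$y_um / fov2$pixel_size), det, radius = 2)
  got <- det$contrast_pct[match(m$matched$cur_id, det$id)]
  inj <- injected[m$matched$prev_id]
  expect_true(all(got <= inj + 1e-9))
  expect_true(all(got >= inj * loss - 1e-9))
})
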