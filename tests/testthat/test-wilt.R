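test_that("ExG index hits its landmark values", {
  expect_equal(exg_index(c(0, 255, 0)), 2)
  expect_equal(exg_index(c(128, 128, 128)), 0)
  expect_equal(exg_index(c(255, 0, 0)), -1)
  expect_equal(exg_index(c(0, 0, 0)), 0)  # convention for all-zero pixels
  # scale invariance: 0-1 and 0-255 encodings agree
  expect_equal(exg_index(c(0.2, 0.6, 0.1)), exg_index(c(51, 153, 25.5)))
})

test_that("plant mask uses a strict threshold", {
  grey <- array(128, c(4, 4, 3))
  expect_false(any(plant_mask(grey)))
  green <- array(0, c(4, 4, 3)); green[, , 2] <- 255
  expect_true(all(plant_mask(green)))
})

test_that("block matching: zero field on identical frames, recovery of a
          known integer shift, dimension contract", {
  f <- textured_frame()
  z <- estimate_flow(f, f, method = "block_match")
  expect_true(all(z$u == 0) && all(z$v == 0))
  expect_equal(dim(z$u), dim(f)[1:2])

  shifted <- shift_frame_rows(f, 2)  # content moves down 2 rows
  fl <- estimate_flow(f, shifted, method = "block_match")
  interior <- 24:31
  expect_true(all(fl$v[interior, interior] == 2))
  expect_true(all(fl$u[interior, interior] == 0))

  # sub-pixel backend agrees on the integer part
  fs <- estimate_flow(f, shifted, method = "dense_reference")
  expect_true(all(abs(fs$v[interior, interior] - 2) <= 0.5))

  expect_error(estimate_flow(f, f[1:10, 1:10, , drop = FALSE]),
               class = "wiltflow_dim_error")
  expect_error(estimate_flow(f, f, method = "deepflow"),
               class = "wiltflow_capability_error")
})

test_that("HOOF bins split magnitude by vertical sign", {
  mask <- matrix(TRUE, 4, 4)
  up <- list(u = matrix(0, 4, 4), v = matrix(-1, 4, 4))
  b <- hoof_bins(up, mask)
  expect_equal(b$up_sum / b$masked_pixel_count, 1)
  expect_equal(b$down_sum, 0)

  half <- list(u = matrix(0, 4, 4),
               v = matrix(rep(c(3, -3), each = 8), 4, 4))
  b <- hoof_bins(half, mask)
  expect_equal(b$up_sum / b$masked_pixel_count, 1.5)
  expect_equal(b$down_sum / b$masked_pixel_count, 1.5)

  horiz <- list(u = matrix(5, 4, 4), v = matrix(0, 4, 4))
  b <- hoof_bins(horiz, mask)
  expect_equal(b$up_sum + b$down_sum, 0)

  expect_error(hoof_bins(up, matrix(FALSE, 4, 4)),
               class = "wiltflow_mask_error")
})

test_that("delta_wilt reduces the bins with the documented sign", {
  mk <- function(up, down, n) structure(
    list(up_sum = up * n, down_sum = down * n, masked_pixel_count = n),
    class = "hoof_bins")
  expect_equal(delta_wilt(mk(1, 0, 10)), 1)
  expect_equal(delta_wilt(mk(0.7, 0.7, 10)), 0)
  expect_equal(delta_wilt(mk(0.2, 0.5, 10)), -0.3)
})

test_that("static rendered sequence quantifies to zero wilt everywhere", {
  cfg <- scenario_config(seed = 1, sensor_noise_sd = 0)
  fr <- render_frames(make_truth(rep(3, 8)), cfg)
  w <- quantify_wilt_series(fr, w = 5)
  expect_equal(nrow(w), 3)
  expect_true(all(w$delta_wilt == 0))
})

test_that("a wilting event yields negative delta_wilt and frame-order
          reversal flips its sign", {
  cfg <- scenario_config(seed = 1, sensor_noise_sd = 0)
  # droop grows 2 px per minute: clear downward motion across any 5-min pair
  fr <- render_frames(make_truth(seq(0, 14, by = 2)), cfg)
  w <- quantify_wilt_series(fr, w = 5)
  expect_true(all(w$delta_wilt < 0))

  rev_seq <- image_sequence(rev(fr$frames), fr$time, fr$plant_id)
  wr <- quantify_wilt_series(rev_seq, w = 5)
  expect_true(all(wr$delta_wilt > 0))
})

test_that("frame-order reversal negates delta_wilt exactly on a translation
          fixture", {
  a <- textured_frame()
  b <- shift_frame_rows(a, 2)
  t0 <- as.POSIXct("2024-04-01 09:00", tz = "UTC")
  fwd <- quantify_wilt_series(image_sequence(list(a, b), t0 + c(0, 60), "p"),
                              w = 1)
  bwd <- quantify_wilt_series(image_sequence(list(b, a), t0 + c(0, 60), "p"),
                              w = 1)
  expect_equal(bwd$delta_wilt, -fwd$delta_wilt, tolerance = 1e-6)
  expect_lt(fwd$delta_wilt, 0)  # downward motion = wilting sign
})

test_that("moving achromatic clouds never leak into the wilt statistic", {
  cfg <- scenario_config(seed = 1, sensor_noise_sd = 0)
  tr <- make_truth(seq(0, 7, by = 1))
  with_clouds <- quantify_wilt_series(render_frames(tr, cfg, clouds = TRUE),
                                      w = 5)
  without <- quantify_wilt_series(render_frames(tr, cfg, clouds = FALSE),
                                  w = 5)
  expect_equal(with_clouds$delta_wilt, without$delta_wilt, tolerance = 1e-6)
})

test_that("|delta_wilt| is bounded by the mean masked flow magnitude", {
  cfg <- scenario_config(seed = 13, weather = "sunny")
  ds <- simulate_scenario(cfg, flows = TRUE)
  for (i in c(1, 100, 300)) {
    fl <- ds$flows$flows[[i]]
    m <- ds$flows$mask
    bins <- hoof_bins(fl, m)
    mean_mag <- mean(sqrt(fl$u[m]^2 + fl$v[m]^2))
    expect_lte(abs(delta_wilt(bins)), mean_mag + 1e-12)
  }
})

test_that("missing partner frames are skipped and recorded", {
  cfg <- scenario_config(seed = 1, sensor_noise_sd = 0)
  fr <- render_frames(make_truth(rep(2, 10)), cfg)
  keep <- setdiff(1:10, 3)  # remove the partner of minute 8
  seq_gap <- image_sequence(fr$frames[keep], fr$time[keep], "p")
  w <- quantify_wilt_series(seq_gap, w = 5)
  expect_false(fr$time[8] %in% w$time)
  expect_true(fr$time[8] %in% attr(w, "skipped")$time)
})
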