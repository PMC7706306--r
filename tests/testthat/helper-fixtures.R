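# Shared fixtures and independent oracles, built in code at test time.

# Hand-built latent truth with a prescribed droop trajectory, for renderer
# and fast-path tests (sway 0 unless given).
make_truth <- function(wd, date = as.Date("2024-04-01"),
                       start_min = 9 * 60, sway = 0, delay = 2L) {
  tr <- data.frame(
    time = as.POSIXct(as.character(date), tz = "UTC") +
      60 * (start_min + seq_along(wd) - 1),
    stem_water = 0, leaf_water = 0, soil_reservoir = 1,
    wilt_displacement = wd, sway = rep_len(sway, length(wd)))
  attr(tr, "true_delay") <- delay
  class(tr) <- c("latent_truth", "data.frame")
  tr
}

# A minimal aligned day pair built directly from two vectors.
mk_pair <- function(x, y) {
  structure(list(time = as.POSIXct("2024-04-01 09:00", tz = "UTC") +
                   60 * (seq_along(x) - 1),
                 delta_stem = x, delta_wilt = y, n = length(x),
                 date = as.Date("2024-04-01"), plant_id = "p"),
            class = "aligned_day_pair")
}

# Brute-force lagged Pearson correlation; independent of the package's
# cross_correlation (plain cor() on explicitly shifted vectors).
brute_lag_pearson <- function(x, y, max_lag) {
  lags <- -max_lag:max_lag
  sapply(lags, function(l) {
    n <- length(x)
    if (l >= 0) cor(x[seq_len(n - l)], y[seq_len(n - l) + l])
    else cor(x[seq_len(n + l) - l], y[seq_len(n + l)])
  })
}

# Literal double-loop evaluation of the day-level cross-correlation
# estimator: global means/SDs, raw lagged product sums divided by n - |l|.
brute_cc <- function(x, y, max_lag) {
  n <- length(x)
  mu_x <- mean(x); mu_y <- mean(y)
  sd_x <- sqrt(mean((x - mu_x)^2)); sd_y <- sqrt(mean((y - mu_y)^2))
  out <- numeric(2 * max_lag + 1)
  for (i in seq_along(out)) {
    l <- i - max_lag - 1
    acc <- 0; m <- 0
    for (t in seq_len(n)) {
      tl <- t - l
      if (tl >= 1 && tl <= n) { acc <- acc + x[tl] * y[t]; m <- m + 1 }
    }
    out[i] <- (acc / m - mu_x * mu_y) / (sd_x * sd_y)
  }
  out
}

# A small textured frame: random green-ish texture block on grey background.
textured_frame <- function(h = 60, w = 60, block_rows = 20:35,
                           block_cols = 20:35, seed = 42) {
  set.seed(seed)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 120; img[, , 2] <- 120; img[, , 3] <- 120
  tex <- matrix(runif(length(block_rows) * length(block_cols), 80, 255),
                length(block_rows))
  img[block_rows, block_cols, 1] <- tex * 0.3
  img[block_rows, block_cols, 2] <- tex
  img[block_rows, block_cols, 3] <- tex * 0.3
  img
}

shift_frame_rows <- function(img, dv) {
  out <- img
  h <- dim(img)[1]
  src <- pmin(h, pmax(1, seq_len(h) - dv))
  out[, , ] <- img[src, , ]
  out
}
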