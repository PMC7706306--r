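# Scene palette. Plant colors have ExG > 0, everything else ExG <= 0, so the
# excess-green mask has exact ground truth on noise-free frames (any convex
# blend of two ExG <= 0 colors stays ExG <= 0 because 2G - R - B is linear in
# the raw channels).
.palette <- list(
  sky   = c(180, 180, 200),
  cloud = c(238, 238, 238),
  soil  = c(120, 80, 60),
  stem  = c(50, 120, 50),
  leaf  = c(60, 160, 60),
  rib   = c(40, 110, 40)
)

.canvas <- 144L
.horizon <- 100L   # first soil row
.leaf_anchors <- data.frame(row = c(60, 72, 84, 96), col = 72,
                            side = c(-1, 1, -1, 1))
.leaf_len <- 28
.leaf_halfwidth <- 5.5
.leaf_rest_elev <- 20  # degrees above horizontal

#' Leaf-tip position for a given droop
#'
#' The renderer rotates each leaf ellipse about its stem attachment point so
#' that the tip sits exactly `drop_px` rows below its rest position (rest
#' elevation `rest_elev_deg` above horizontal), until the rotation saturates
#' at vertical. Exposed so the leaf geometry can be checked independently of
#' rasterization.
#'
#' @param anchor_row,anchor_col attachment point (row grows downward).
#' @param length leaf length in pixels.
#' @param side -1 (leaf points left) or +1 (right).
#' @param drop_px vertical tip offset below rest, pixels (may be negative).
#' @param rest_elev_deg rest elevation angle, degrees.
#' @return named numeric `c(row, col)` of the leaf tip.
#' @export
leaf_tip_position <- function(anchor_row, anchor_col, length = .leaf_len,
                              side = 1, drop_px = 0,
                              rest_elev_deg = .leaf_rest_elev) {
  sinphi <- sin(rest_elev_deg * pi / 180) - drop_px / length
  sinphi <- pmin(0.95, pmax(-0.95, sinphi))
  cosphi <- sqrt(1 - sinphi^2)
  c(row = anchor_row - length * sinphi,
    col = anchor_col + side * length * cosphi)
}

# Anti-aliased ellipse composite: blend `color` into `img` with per-pixel
# coverage from an approximate signed distance to the ellipse boundary.
draw_ellipse <- function(img, cx, cy, a, b, axis_deg, color) {
  h <- dim(img)[1]; wd <- dim(img)[2]
  r0 <- max(1L, floor(cy - a - 2)); r1 <- min(h, ceiling(cy + a + 2))
  c0 <- max(1L, floor(cx - a - 2)); c1 <- min(wd, ceiling(cx + a + 2))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  X <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  Y <- matrix(rows, length(rows), length(cols)) - cy
  th <- axis_deg * pi / 180
  s <- X * cos(th) + Y * sin(th)
  q <- -X * sin(th) + Y * cos(th)
  val <- sqrt((s / a)^2 + (q / b)^2)
  cov <- pmin(1, pmax(0, 0.5 + (1 - val) * b))
  for (ch in 1:3) {
    img[rows, cols, ch] <- cov * color[ch] + (1 - cov) * img[rows, cols, ch]
  }
  img
}

draw_leaf <- function(img, anchor_row, anchor_col, side, drop_px) {
  tip <- leaf_tip_position(anchor_row, anchor_col, .leaf_len, side, drop_px)
  cx <- (anchor_col + tip["col"]) / 2
  cy <- (anchor_row + tip["row"]) / 2
  axis_deg <- atan2(tip["row"] - anchor_row, tip["col"] - anchor_col) * 180 / pi
  img <- draw_ellipse(img, cx, cy, .leaf_len / 2, .leaf_halfwidth,
                      axis_deg, .palette$leaf)
  draw_ellipse(img, cx, cy, .leaf_len / 2 - 1, 1.2, axis_deg, .palette$rib)
}

static_background <- function() {
  img <- array(0, c(.canvas, .canvas, 3))
  for (ch in 1:3) {
    img[1:(.horizon - 1), , ch] <- .palette$sky[ch]
    img[.horizon:.canvas, , ch] <- .palette$soil[ch]
  }
  img
}

draw_clouds <- function(img, minute_index) {
  specs <- data.frame(cy = c(16, 27, 36), x0 = c(20, 75, 120),
                      speed = c(0.35, 0.45, 0.30), a = c(20, 16, 18), b = 6)
  for (i in seq_len(nrow(specs))) {
    cx <- (specs$x0[i] + specs$speed[i] * minute_index) %% (.canvas + 50) - 25
    img <- draw_ellipse(img, cx, specs$cy[i], specs$a[i], specs$b[i], 0,
                        .palette$cloud)
  }
  img
}

render_one_frame <- function(drop, minute_index, background, clouds = TRUE) {
  img <- background
  if (clouds) img <- draw_clouds(img, minute_index)
  for (ch in 1:3) {
    img[55:.horizon, 71:73, ch] <- .palette$stem[ch]
  }
  for (k in seq_len(nrow(.leaf_anchors))) {
    img <- draw_leaf(img, .leaf_anchors$row[k], .leaf_anchors$col[k],
                     .leaf_anchors$side[k], drop)
  }
  img
}

#' Render a synthetic plant-day image sequence
#'
#' Produces 144x144 RGB frames (0-255) for the camera window
#' (`config$image_start` to `config$image_end`): a sky band with drifting
#' achromatic cloud ellipses, a soil band, and a plant (stem plus four leaf
#' ellipses in a green palette) whose leaves rotate downward about their stem
#' attachment points by `wilt_displacement + sway` pixels at the tip. By
#' palette construction every plant pixel has ExG > 0 and every non-plant
#' pixel ExG <= 0 on noise-free frames; the corresponding ground-truth masks
#' are attached as `attr(, "truth_mask")`.
#'
#' @param truth a `latent_truth` from [simulate_plant()].
#' @param config the matching [scenario_config()] (noise SD, windows, seed).
#' @param clouds draw moving clouds (`TRUE`) or leave the sky empty.
#' @return an `image_sequence`: list with `frames` (list of HxWx3 arrays),
#'   `time`, `plant_id`; attribute `truth_mask` is a list of logical masks.
#' @export
render_frames <- function(truth, config, clouds = TRUE) {
  stopifnot(inherits(truth, "latent_truth"))
  mod <- minute_of_day(truth$time)
  keep <- which(mod >= hm_to_min(config$image_start) &
                  mod <= hm_to_min(config$image_end))
  if (!length(keep))
    stop_wiltflow("truth covers no minutes inside the image window",
                  "wiltflow_window_error")
  drop <- truth$wilt_displacement + truth$sway
  background <- static_background()
  frames <- vector("list", length(keep))
  masks <- vector("list", length(keep))
  local_seed(config$seed + 2L, {
    for (i in seq_along(keep)) {
      t <- keep[i]
      img <- render_one_frame(drop[t], minute_index = t,
                              background = background, clouds = clouds)
      masks[[i]] <- exg_index(img) > 0
      if (config$sensor_noise_sd > 0) {
        img <- img + array(rnorm(length(img), sd = config$sensor_noise_sd),
                           dim(img))
        img <- pmin(255, pmax(0, img))
      }
      frames[[i]] <- img
    }
  })
  seq_out <- image_sequence(frames, truth$time[keep], config$plant_id)
  attr(seq_out, "truth_mask") <- masks
  seq_out
}

#' Precomputed flow fields (fast path bypassing flow estimation)
#'
#' For every minute `t` in the image window whose partner `t - w` is also in
#' the window, emits a flow field on a small raster whose plant-mask pixels
#' carry vertical displacement `drop(t) - drop(t - w)` (where
#' `drop = wilt_displacement + sway`; positive = downward in row-index
#' coordinates) and whose background pixels carry small seeded noise. This
#' lets the wilt quantification and lag analysis be exercised without a flow
#' estimator in the loop.
#'
#' @param truth a `latent_truth` from [simulate_plant()].
#' @param config the matching [scenario_config()].
#' @param w differencing window, minutes.
#' @param size raster side, pixels.
#' @param noise_sd SD of the background noise, pixels.
#' @return a `flow_sequence`: list with `time`, `w`, `mask` (logical matrix)
#'   and `flows` (list of `list(u, v)` matrices).
#' @export
synth_flow_fields <- function(truth, config, w = 5L, size = 32L,
                              noise_sd = 0.05) {
  stopifnot(inherits(truth, "latent_truth"))
  mod <- minute_of_day(truth$time)
  start_min <- hm_to_min(config$image_start)
  end_min <- hm_to_min(config$image_end)
  in_win <- mod >= start_min & mod <= end_min
  drop <- truth$wilt_displacement + truth$sway
  # pair (t - w, t): both minutes inside the window, same day
  tidx <- which(in_win)
  tidx <- tidx[tidx - w >= 1 &
                 in_win[pmax(1, tidx - w)] &
                 date_of(truth$time[pmax(1, tidx - w)]) ==
                   date_of(truth$time[tidx])]
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- ((rr - size / 2 - 2) / (size * 0.28))^2 +
    ((cc - size / 2) / (size * 0.28))^2 <= 1
  flows <- vector("list", length(tidx))
  local_seed(config$seed + 3L, {
    for (i in seq_along(tidx)) {
      t <- tidx[i]
      u <- matrix(rnorm(size * size, sd = noise_sd), size, size)
      v <- matrix(rnorm(size * size, sd = noise_sd), size, size)
      u[mask] <- 0
      v[mask] <- drop[t] - drop[t - w]
      flows[[i]] <- list(u = u, v = v)
    }
  })
  structure(list(time = truth$time[tidx], w = as.integer(w), mask = mask,
                 flows = flows, plant_id = config$plant_id),
            class = "flow_sequence")
}

#' @export
print.flow_sequence <- function(x, ...) {
  cat(sprintf("<flow_sequence> %d field(s), w = %d min, %d masked px\n",
              length(x$flows), x$w, sum(x$mask)))
  invisible(x)
}
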