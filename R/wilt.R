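#' Construct an image sequence
#'
#' @param frames list of HxWx3 RGB arrays on a 0-255 scale, equal dimensions.
#' @param time POSIXct timestamps, strictly increasing, minute resolution.
#' @param plant_id plant label.
#' @return an `image_sequence` object.
#' @export
image_sequence <- function(frames, time, plant_id = "plant") {
  stopifnot(is.list(frames), length(frames) == length(time))
  if (length(frames) == 0) stop("empty image sequence")
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims != dims[, 1]))
    stop_wiltflow("all frames must share the same dimensions",
                  "wiltflow_dim_error")
  if (is.unsorted(time, strictly = TRUE))
    stop_wiltflow("timestamps must be unique and strictly increasing",
                  "wiltflow_time_error")
  structure(list(frames = frames, time = time, plant_id = plant_id),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_sequence> %s: %d frame(s) %dx%d, %s .. %s\n",
              x$plant_id, length(x$frames), d[1], d[2],
              format(min(x$time)), format(max(x$time))))
  invisible(x)
}

#' Excess-green (ExG) index
#'
#' ExG on brightness-normalized chromatic coordinates:
#' with `r = R/(R+G+B)` etc., `ExG = 2g - r - b`, in `[-1, 2]`. Positive
#' values indicate green vegetation. All-zero (black) pixels return 0 by
#' convention. Scale-invariant, so 0-1 and 0-255 encodings give identical
#' results.
#'
#' @param x either a length-3 RGB vector or an HxWx3 array.
#' @return a scalar or an HxW matrix of ExG values.
#' @examples
#' exg_index(c(0, 255, 0))     # 2: pure green
#' exg_index(c(128, 128, 128)) # 0: achromatic
#' @export
exg_index <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  } else if (is.numeric(x) && length(x) == 3) {
    r <- x[1]; g <- x[2]; b <- x[3]
  } else stop("x must be an RGB triple or an HxWx3 array")
  total <- r + g + b
  out <- (2 * g - r - b) / total
  out[total == 0] <- 0
  out
}

#' Vegetation mask from the ExG index
#'
#' Pixels with `exg_index > threshold` (strict) are classified as plant.
#'
#' @param frame HxWx3 RGB array.
#' @param threshold ExG threshold; the conventional color-filter value is 0.
#' @return a logical HxW matrix (`TRUE` = plant).
#' @export
plant_mask <- function(frame, threshold = 0) {
  exg_index(frame) > threshold
}

to_gray <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

integral_image <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 1, w + 1)
  out[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  out
}

# Sum of m over a centered (2r+1)^2 window, truncated at the borders.
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  I <- integral_image(m)
  r1 <- pmax(1L, seq_len(h) - r); r2 <- pmin(h, seq_len(h) + r)
  c1 <- pmax(1L, seq_len(w) - r); c2 <- pmin(w, seq_len(w) + r)
  I[r2 + 1, c2 + 1] - I[r1, c2 + 1] - I[r2 + 1, c1] + I[r1, c1]
}

# shifted[i, j] = m[i + dv, j + du], replicate padding at borders
shift_image <- function(m, dv, du) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(h, pmax(1L, seq_len(h) + dv)), pmin(w, pmax(1L, seq_len(w) + du))]
}

#' Dense optical flow between two frames
#'
#' Pluggable flow stage. `block_match` is a built-in exhaustive integer-shift
#' matcher: for every pixel it selects the displacement (within
#' `+/- search` pixels in each axis) minimizing the sum of squared grayscale
#' differences over a centered `(2 patch + 1)^2` aggregation window; ties are
#' broken toward the smallest displacement (deterministic). `dense_reference`
#' adds per-axis parabolic sub-pixel refinement of the SSD minimum.
#' `deepflow` names an external dense-flow engine and raises a capability
#' error when no such backend is installed; the algorithm is deliberately not
#' re-implemented here.
#'
#' Coordinate convention: `u` is horizontal displacement (+ = rightward),
#' `v` vertical displacement (+ = downward in row-index coordinates), mapping
#' `frame_a` (earlier, t - w) toward `frame_b` (later, t).
#'
#' @param frame_a,frame_b HxWx3 RGB arrays of equal dimensions.
#' @param method `"block_match"`, `"dense_reference"` or `"deepflow"`.
#' @param search integer search radius, pixels (applies to both axes).
#' @param patch aggregation window radius, pixels.
#' @return a `flow_field`: list of matrices `u`, `v`.
#' @export
estimate_flow <- function(frame_a, frame_b,
                          method = c("block_match", "dense_reference",
                                     "deepflow"),
                          search = 4L, patch = 8L) {
  method <- match.arg(method)
  if (!identical(dim(frame_a), dim(frame_b)))
    stop_wiltflow("frame dimensions differ", "wiltflow_dim_error")
  if (method == "deepflow")
    stop_wiltflow(paste(
      "flow backend 'deepflow' is not available: no dense optical-flow",
      "engine is installed; use 'block_match' or 'dense_reference'"),
      "wiltflow_capability_error")

  ga <- to_gray(frame_a); gb <- to_gray(frame_b)
  h <- nrow(ga); w <- ncol(ga)
  grid <- expand.grid(dv = -search:search, du = -search:search)
  ord <- order(grid$dv^2 + grid$du^2, abs(grid$dv), abs(grid$du),
               grid$dv, grid$du)
  grid <- grid[ord, ]
  keep_stack <- method == "dense_reference"
  if (keep_stack) stack <- array(NA_real_, c(h, w, nrow(grid)))
  best <- matrix(Inf, h, w)
  best_k <- matrix(1L, h, w)
  for (k in seq_len(nrow(grid))) {
    d2 <- (ga - shift_image(gb, grid$dv[k], grid$du[k]))^2
    s <- box_sum(d2, patch)
    if (keep_stack) stack[, , k] <- s
    # strict improvement beyond integral-image rounding noise, so exact SSD
    # ties resolve to the earlier (smaller) shift deterministically
    upd <- s < best - 1e-3
    best[upd] <- s[upd]
    best_k[upd] <- k
  }
  v <- matrix(grid$dv[best_k], h, w)
  u <- matrix(grid$du[best_k], h, w)

  if (keep_stack) {
    # parabolic refinement along each axis where the +/-1 neighbors exist
    key <- function(dv, du) match(paste(dv, du), paste(grid$dv, grid$du))
    pix <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h))
    kv <- as.vector(best_k)
    refine <- function(dm1, dp1, base) {
      km <- key(grid$dv[kv] + dm1[1], grid$du[kv] + dm1[2])
      kp <- key(grid$dv[kv] + dp1[1], grid$du[kv] + dp1[2])
      ok <- !is.na(km) & !is.na(kp)
      off <- numeric(length(kv))
      if (any(ok)) {
        s0 <- stack[cbind(pix[ok, , drop = FALSE], kv[ok])]
        sm <- stack[cbind(pix[ok, , drop = FALSE], km[ok])]
        sp <- stack[cbind(pix[ok, , drop = FALSE], kp[ok])]
        den <- sm - 2 * s0 + sp
        o <- ifelse(den > 1e-12, 0.5 * (sm - sp) / den, 0)
        off[ok] <- pmin(0.5, pmax(-0.5, o))
      }
      base + matrix(off, h, w)
    }
    v <- refine(c(-1, 0), c(1, 0), v)
    u <- refine(c(0, -1), c(0, 1), u)
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' Two-bin histogram of oriented optical flow over the plant mask
#'
#' Each masked pixel's flow vector contributes its Euclidean magnitude to the
#' downward bin if `v > 0` (down-screen motion, i.e. wilting), to the upward
#' bin if `v < 0` (recovery), and to neither if `v = 0` (purely horizontal
#' motion is uninformative for wilting).
#'
#' @param flow a `flow_field` (or list with matrices `u`, `v`).
#' @param mask logical plant mask of matching dimensions.
#' @return a `hoof_bins` list: `up_sum`, `down_sum`, `masked_pixel_count`.
#' @export
hoof_bins <- function(flow, mask) {
  if (!identical(dim(flow$v), dim(mask)))
    stop_wiltflow("flow and mask dimensions differ", "wiltflow_dim_error")
  if (!any(mask))
    stop_wiltflow("empty plant mask: no plant area", "wiltflow_mask_error")
  u <- flow$u[mask]; v <- flow$v[mask]
  mag <- sqrt(u^2 + v^2)
  structure(list(up_sum = sum(mag[v < 0]),
                 down_sum = sum(mag[v > 0]),
                 masked_pixel_count = sum(mask)),
            class = "hoof_bins")
}

#' Relative wilting scalar from HOOF bins
#'
#' `delta_wilt = (up_sum - down_sum) / masked_pixel_count`, in pixels per
#' masked pixel. Positive = net upward motion (recovery from wilting);
#' negative = net downward motion (wilting).
#'
#' @param bins a `hoof_bins` object.
#' @return numeric scalar.
#' @export
delta_wilt <- function(bins) {
  if (bins$masked_pixel_count <= 0)
    stop_wiltflow("masked_pixel_count must be positive", "wiltflow_mask_error")
  (bins$up_sum - bins$down_sum) / bins$masked_pixel_count
}

# Area-style downscale to target x target; block mean for integer ratios,
# bilinear sampling otherwise.
resize_frame <- function(frame, target = 144L) {
  d <- dim(frame)
  if (d[1] == target && d[2] == target) return(frame)
  if (d[1] %% target == 0 && d[2] %% target == 0) {
    fr <- d[1] %/% target; fc <- d[2] %/% target
    out <- array(0, c(target, target, 3))
    for (ch in 1:3) {
      m <- frame[, , ch]
      m <- rowsum(m, rep(seq_len(target), each = fr)) / fr
      m <- t(rowsum(t(m), rep(seq_len(target), each = fc)) / fc)
      out[, , ch] <- m
    }
    return(out)
  }
  ri <- (seq_len(target) - 0.5) * d[1] / target + 0.5
  ci <- (seq_len(target) - 0.5) * d[2] / target + 0.5
  r0 <- pmin(d[1] - 1L, pmax(1L, floor(ri))); fr <- ri - r0
  c0 <- pmin(d[2] - 1L, pmax(1L, floor(ci))); fc <- ci - c0
  FR <- matrix(fr, target, target)
  FC <- matrix(fc, target, target, byrow = TRUE)
  out <- array(0, c(target, target, 3))
  for (ch in 1:3) {
    m <- frame[, , ch]
    out[, , ch] <- (1 - FR) * (1 - FC) * m[r0, c0] +
      FR * (1 - FC) * m[r0 + 1, c0] +
      (1 - FR) * FC * m[r0, c0 + 1] +
      FR * FC * m[r0 + 1, c0 + 1]
  }
  out
}

#' Quantify relative leaf wilting over an image sequence
#'
#' For every frame at time `t` whose partner at `t - w` exists, estimates
#' optical flow from the `(t - w, t)` pair, masks it with the ExG mask of the
#' later frame, aggregates the masked vectors into two HOOF bins and reduces
#' them to the per-pixel wilting scalar [delta_wilt()]. Frames larger than
#' 144x144 are downscaled first. Timestamps with a missing partner (or an
#' empty mask) are skipped and recorded in the `skipped` attribute. To keep
#' the matcher affordable the flow is computed on the bounding box of the
#' plant mask plus a margin; pixels outside the mask never contribute to the
#' wilt statistic.
#'
#' @param images an [image_sequence()].
#' @param w differencing window, minutes.
#' @param stride evaluation cadence, minutes.
#' @param method flow backend, see [estimate_flow()].
#' @param exg_threshold ExG mask threshold.
#' @param search,patch matcher parameters, see [estimate_flow()].
#' @param roi_margin margin (pixels) around the mask bounding box.
#' @return a `wilt_series` data frame: `time`, `delta_wilt`, `up`, `down`,
#'   `masked_pixels`; attributes `w` and `skipped`.
#' @export
quantify_wilt_series <- function(images, w = 5L, stride = 1L,
                                 method = "block_match", exg_threshold = 0,
                                 search = 4L, patch = 8L, roi_margin = 12L) {
  stopifnot(inherits(images, "image_sequence"))
  if (w < 1 || stride < 1) stop("w and stride must be >= 1 minute")
  if (length(images$frames) < 2)
    stop_wiltflow("need at least two frames", "wiltflow_input_error")
  frames <- lapply(images$frames, resize_frame)
  tnum <- as.numeric(images$time)
  rows <- list(); skipped <- list()
  eval_idx <- seq(1L, length(frames), by = stride)
  for (t in eval_idx) {
    j <- match(tnum[t] - 60 * w, tnum)
    if (is.na(j)) {
      if (tnum[t] - 60 * w >= tnum[1])
        skipped[[length(skipped) + 1]] <-
          data.frame(time = images$time[t], reason = "missing partner frame")
      next
    }
    mask <- plant_mask(frames[[t]], exg_threshold)
    if (!any(mask)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(time = images$time[t], reason = "empty plant mask")
      next
    }
    rr <- range(which(rowSums(mask) > 0))
    cr <- range(which(colSums(mask) > 0))
    r0 <- max(1L, rr[1] - roi_margin); r1 <- min(nrow(mask), rr[2] + roi_margin)
    c0 <- max(1L, cr[1] - roi_margin); c1 <- min(ncol(mask), cr[2] + roi_margin)
    fa <- frames[[j]][r0:r1, c0:c1, , drop = FALSE]
    fb <- frames[[t]][r0:r1, c0:c1, , drop = FALSE]
    flow <- estimate_flow(fa, fb, method = method, search = search,
                          patch = patch)
    bins <- hoof_bins(flow, mask[r0:r1, c0:c1])
    rows[[length(rows) + 1]] <- data.frame(
      time = images$time[t], delta_wilt = delta_wilt(bins),
      up = bins$up_sum, down = bins$down_sum,
      masked_pixels = bins$masked_pixel_count)
  }
  if (!length(rows))
    stop_wiltflow("no frame pairs available at window w", "wiltflow_input_error")
  out <- do.call(rbind, rows)
  attr(out, "w") <- as.integer(w)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(time = as.POSIXct(character(), tz = "UTC"),
               reason = character())
  attr(out, "plant_id") <- images$plant_id
  class(out) <- c("wilt_series", "data.frame")
  out
}

#' Wilt series from precomputed flow fields
#'
#' Applies the mask/HOOF/reduction stages of [quantify_wilt_series()] to a
#' [synth_flow_fields()] fast-path sequence, bypassing flow estimation.
#'
#' @param flows a `flow_sequence`.
#' @return a `wilt_series` data frame (see [quantify_wilt_series()]).
#' @export
quantify_wilt_from_flows <- function(flows) {
  stopifnot(inherits(flows, "flow_sequence"))
  n <- length(flows$flows)
  dw <- up <- dn <- numeric(n)
  for (i in seq_len(n)) {
    bins <- hoof_bins(flows$flows[[i]], flows$mask)
    dw[i] <- delta_wilt(bins); up[i] <- bins$up_sum; dn[i] <- bins$down_sum
  }
  out <- data.frame(time = flows$time, delta_wilt = dw, up = up, down = dn,
                    masked_pixels = sum(flows$mask))
  attr(out, "w") <- flows$w
  attr(out, "skipped") <- data.frame(
    time = as.POSIXct(character(), tz = "UTC"), reason = character())
  attr(out, "plant_id") <- flows$plant_id %||% "plant"
  class(out) <- c("wilt_series", "data.frame")
  out
}
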