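#' Align wilt and stem difference series for one plant-day
#'
#' Takes the intersection of timestamps at which both `delta_wilt` and
#' `delta_stem` are defined inside the daily analysis window (09:00-17:00,
#' the camera operating window, endpoints included). Days whose common grid
#' has more than `max_gap` missing interior minutes are rejected: lagged
#' cross-correlation is not applicable across gaps.
#'
#' @param wilt a `wilt_series`.
#' @param dstem a `delta_series` from [delta_stem()].
#' @param date the day to align (anything `as.Date` accepts).
#' @param window character 2-vector "HH:MM" start/end (inclusive).
#' @param max_gap maximum tolerated interior gap, minutes.
#' @return an `aligned_day_pair` (list: `time`, `delta_stem`, `delta_wilt`,
#'   `n`, `date`, `plant_id`), or a `day_skipped` object carrying the skip
#'   reason when the day cannot be analyzed (not an error).
#' @export
align_day <- function(wilt, dstem, date, window = c("09:00", "17:00"),
                      max_gap = 0L) {
  date <- as.Date(date)
  w0 <- hm_to_min(window[1]); w1 <- hm_to_min(window[2])
  pick <- function(df) {
    mod <- minute_of_day(df$time)
    df[date_of(df$time) == date & mod >= w0 & mod <= w1, , drop = FALSE]
  }
  wd <- pick(wilt); sd_ <- pick(dstem)
  skip <- function(reason)
    structure(list(reason = reason), class = "day_skipped")
  if (!nrow(wd)) return(skip("no wilt data in window"))
  if (!nrow(sd_)) return(skip("no stem data in window"))
  common <- intersect(as.numeric(wd$time), as.numeric(sd_$time))
  if (!length(common)) return(skip("empty timestamp intersection"))
  common <- sort(common)
  interior_missing <- sum(diff(common) / 60 - 1)
  if (interior_missing > max_gap)
    return(skip(sprintf("%d missing interior minute(s)", interior_missing)))
  iw <- match(common, as.numeric(wd$time))
  is_ <- match(common, as.numeric(sd_$time))
  structure(list(time = wd$time[iw],
                 delta_stem = sd_$delta[is_],
                 delta_wilt = wd$delta_wilt[iw],
                 n = length(common), date = date,
                 plant_id = attr(wilt, "plant_id") %||% "plant"),
            class = "aligned_day_pair")
}

#' Lagged cross-correlation between stem and wilt differences
#'
#' For lags `l` in `[-max_lag, max_lag]`,
#' `C(l) = ((1/(n - |l|)) * sum_t dstem(t - l) * dwilt(t) - mu_s * mu_w) /
#' (sigma_s * sigma_w)`, where the means and (population) standard deviations
#' are computed once over the whole day and the lagged product sum runs over
#' all overlapping `t`. Positive `l` pairs the wilt value with the *earlier*
#' stem value, so a peak at `l > 0` means stem variation precedes leaf
#' wilting. With `method = "pearson"` the plain Pearson correlation over the
#' overlap is computed instead (sensitivity variant). Lags with overlap
#' below 10 points are returned as `NA`.
#'
#' @param pair an `aligned_day_pair` (or list with `delta_stem`,
#'   `delta_wilt`).
#' @param max_lag maximum absolute lag, minutes.
#' @param method `"global"` (day-level moments, the default estimator) or
#'   `"pearson"` (per-overlap).
#' @param alpha significance level for the per-lag confidence bounds.
#' @return a `cross_correlogram` data frame (`lag`, `c`, `ci`), attributes
#'   `n`, `mu`, `sigma`, `method`.
#' @export
cross_correlation <- function(pair, max_lag = 60L,
                              method = c("global", "pearson"),
                              alpha = 0.01) {
  method <- match.arg(method)
  x <- pair$delta_stem; y <- pair$delta_wilt
  n <- length(x)
  stopifnot(length(y) == n)
  mu_x <- mean(x); mu_y <- mean(y)
  sd_x <- sqrt(mean((x - mu_x)^2)); sd_y <- sqrt(mean((y - mu_y)^2))
  if (sd_x == 0 || sd_y == 0)
    stop_wiltflow("zero variance: cross-correlation undefined",
                  "wiltflow_variance_error")
  lags <- seq.int(-max_lag, max_lag)
  cc <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l >= 0) { xs <- x[seq_len(n - l)]; ys <- y[seq_len(n - l) + l] }
    else        { xs <- x[seq_len(n + l) - l]; ys <- y[seq_len(n + l)] }
    m <- length(xs)
    if (m < 10) next
    cc[i] <- if (method == "global") {
      (sum(xs * ys) / m - mu_x * mu_y) / (sd_x * sd_y)
    } else {
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
      else stats::cor(xs, ys)
    }
  }
  out <- data.frame(lag = lags, c = cc, ci = ci_bounds(n, lags, alpha))
  attr(out, "n") <- n
  attr(out, "mu") <- c(stem = mu_x, wilt = mu_y)
  attr(out, "sigma") <- c(stem = sd_x, wilt = sd_y)
  attr(out, "method") <- method
  attr(out, "date") <- pair$date
  attr(out, "plant_id") <- pair$plant_id
  class(out) <- c("cross_correlogram", "data.frame")
  out
}

#' Per-lag confidence bounds for the null of independent series
#'
#' Under an independent-noise null the correlation estimate at lag `l` is
#' approximately normal with standard deviation `1 / sqrt(n - |l|)`, giving
#' the two-sided bound `z_{1 - alpha/2} / sqrt(n - |l|)` (z = 2.5758 for
#' alpha = 0.01). Lags with `n <= |l|` are undefined (`NA`).
#'
#' @param n number of paired points.
#' @param lags integer lag vector.
#' @param alpha significance level (default 0.01: 99% bounds).
#' @return numeric vector of bounds, one per lag.
#' @export
ci_bounds <- function(n, lags = 0L, alpha = 0.01) {
  z <- stats::qnorm(1 - alpha / 2)
  m <- n - abs(lags)
  ifelse(m > 0, z / sqrt(m), NA_real_)
}

#' Peak of a cross-correlogram
#'
#' Returns the maximum correlation and its lag, optionally restricting the
#' search to non-negative lags. Exact ties are broken toward the smallest
#' `|l|`, then toward positive `l`.
#'
#' @param cc a `cross_correlogram`.
#' @param restrict_nonneg if `TRUE`, search only lags `l >= 0`.
#' @return named list `r_max`, `l_max`.
#' @export
cc_peak <- function(cc, restrict_nonneg = FALSE) {
  sub <- cc[!is.na(cc$c), , drop = FALSE]
  if (restrict_nonneg) sub <- sub[sub$lag >= 0, , drop = FALSE]
  if (!nrow(sub))
    stop_wiltflow("no defined lag in the search range", "wiltflow_input_error")
  o <- order(-sub$c, abs(sub$lag), -(sub$lag > 0))
  list(r_max = sub$c[o[1]], l_max = sub$lag[o[1]])
}

#' Per-plant-day lag summary table
#'
#' For every (plant, date) pair with alignable data, computes the
#' cross-correlogram, both the unrestricted and the `l >= 0`-restricted peak,
#' and the daily mean PPFD/VPD over 09:00-19:00. Skipped days are recorded
#' with reasons in the `skipped` attribute; correlograms are returned in the
#' `correlograms` attribute (long format).
#'
#' @param wilt a `wilt_series` (or list of them, one per plant).
#' @param dstem a `delta_series` (or list matching `wilt`).
#' @param env an `env_series` covering the same dates.
#' @param dates dates to process; defaults to all dates present in `wilt`.
#' @param max_lag maximum absolute lag, minutes.
#' @param window daily analysis window (inclusive), "HH:MM".
#' @param max_gap maximum tolerated interior gap per day, minutes.
#' @return a `lag_summary` data frame: `plant_id`, `date`, `r_max`, `l_max`,
#'   `r_max_nonneg`, `l_max_nonneg`, `n`, `mean_ppfd`, `mean_vpd`.
#' @export
summarize_days <- function(wilt, dstem, env, dates = NULL, max_lag = 60L,
                           window = c("09:00", "17:00"), max_gap = 0L) {
  wilt_list <- if (inherits(wilt, "wilt_series")) list(wilt) else wilt
  dstem_list <- if (inherits(dstem, "delta_series")) list(dstem) else dstem
  stopifnot(length(wilt_list) == length(dstem_list))
  rows <- list(); skips <- list(); cgrams <- list()
  for (p in seq_along(wilt_list)) {
    wp <- wilt_list[[p]]; sp <- dstem_list[[p]]
    pid <- attr(wp, "plant_id") %||% sprintf("plant%d", p)
    # enumerate from both series so stem-only days (e.g. missing images)
    # surface as skip records rather than vanishing silently
    dts <- dates %||% unique(c(date_of(wp$time), date_of(sp$time)))
    for (d in as.list(dts)) {
      pair <- align_day(wp, sp, d, window = window, max_gap = max_gap)
      if (inherits(pair, "day_skipped")) {
        skips[[length(skips) + 1]] <- data.frame(
          plant_id = pid, date = as.Date(d), reason = pair$reason)
        next
      }
      cc <- tryCatch(cross_correlation(pair, max_lag = max_lag),
                     wiltflow_variance_error = function(e) NULL)
      if (is.null(cc)) {
        skips[[length(skips) + 1]] <- data.frame(
          plant_id = pid, date = as.Date(d), reason = "zero variance")
        next
      }
      pk <- cc_peak(cc); pk0 <- cc_peak(cc, restrict_nonneg = TRUE)
      me <- mean_env(env, date = d)
      rows[[length(rows) + 1]] <- data.frame(
        plant_id = pid, date = as.Date(d),
        r_max = pk$r_max, l_max = pk$l_max,
        r_max_nonneg = pk0$r_max, l_max_nonneg = pk0$l_max,
        n = pair$n, mean_ppfd = me$mean_ppfd, mean_vpd = me$mean_vpd)
      cg <- data.frame(plant_id = pid, date = as.Date(d),
                       lag_min = cc$lag, c = cc$c, ci99 = cc$ci)
      cgrams[[length(cgrams) + 1]] <- cg
    }
  }
  if (!length(rows))
    stop_wiltflow("no valid plant-days", "wiltflow_input_error")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(plant_id = character(), date = as.Date(character()),
               reason = character())
  attr(out, "correlograms") <- do.call(rbind, cgrams)
  class(out) <- c("lag_summary", "data.frame")
  out
}
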