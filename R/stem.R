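#' Short-term stem-diameter differences
#'
#' `delta(t) = stem(t) - stem(t - w)` wherever both samples exist, removing
#' diurnal trends so only short-term (irrigation-driven) variation remains.
#' Gaps propagate: no interpolation is performed, and timestamps whose
#' partner `t - w` is missing produce no value.
#'
#' @param stem a `stem_series` data frame (`time`, `diameter_mm`).
#' @param w differencing window, minutes (>= 1).
#' @return a `delta_series` data frame (`time`, `delta`), attribute `w`.
#' @export
delta_stem <- function(stem, w = 5L) {
  if (w < 1) stop("w must be >= 1 minute")
  if (nrow(stem) < w + 1)
    stop_wiltflow("stem series shorter than w + 1 samples",
                  "wiltflow_input_error")
  tnum <- as.numeric(stem$time)
  j <- match(tnum - 60 * w, tnum)
  ok <- !is.na(j)
  out <- data.frame(time = stem$time[ok],
                    delta = stem$diameter_mm[ok] -
                      stem$diameter_mm[j[ok]])
  attr(out, "w") <- as.integer(w)
  class(out) <- c("delta_series", "data.frame")
  out
}

#' Relative stem diameter since the last irrigation
#'
#' `rsr = stem_t / max(stem_{t-n}, ..., stem_t)`: the current diameter
#' divided by the running maximum over the window since the last irrigation,
#' current value included, so the result always lies in `(0, 1]` and equals 1
#' immediately after a reset.
#'
#' @param stem_window numeric vector of diameters since the last irrigation,
#'   oldest first, current value last; all > 0.
#' @return the RSR value.
#' @examples
#' rsr(c(0.500, 0.498)) # 0.996
#' @export
rsr <- function(stem_window) {
  if (!length(stem_window))
    stop_wiltflow("empty RSR window", "wiltflow_input_error")
  if (any(stem_window <= 0)) stop("stem diameters must be positive")
  stem_window[length(stem_window)] / max(stem_window)
}

#' Detect sunrise from the PPFD trace
#'
#' Sunrise is the first timestamp at which PPFD reaches `threshold`
#' (default 14.8 umol s-1 m-2).
#'
#' @param env an `env_series` or a data frame with `time` and `ppfd`.
#' @param threshold PPFD threshold.
#' @return the sunrise POSIXct timestamp, or `NULL` if never reached.
#' @export
detect_sunrise <- function(env, threshold = 14.8) {
  hit <- which(env$ppfd >= threshold)
  if (!length(hit)) return(NULL)
  env$time[hit[1]]
}

#' Convert illuminance to PPFD
#'
#' Scattered-light sensors report lux; PPFD (umol s-1 m-2) is obtained by
#' dividing by the conversion factor 54 appropriate for daylight spectra.
#'
#' @param lux illuminance, lux (>= 0, vectorized).
#' @return PPFD in umol s-1 m-2.
#' @export
lux_to_ppfd <- function(lux) {
  if (any(lux < 0)) stop("lux must be non-negative")
  lux / 54
}

#' Run the RSR threshold irrigation controller over a stem trace
#'
#' At every minute within the active window `[sunrise, cutoff)` (sunrise
#' detected per day from the PPFD trace at 14.8 umol s-1 m-2) the controller
#' computes the RSR over the window since the last irrigation; if
#' `rsr < t_rsr` it emits an irrigation event and resets the window, so the
#' trace value at the reset is 1.0000 and the next minute starts a fresh
#' window. Outside the active window no events are issued. The RSR window
#' also restarts after any gap in the stem grid (conservative handling,
#' recorded in the trace).
#'
#' @param stem a `stem_series` (`time`, `diameter_mm`).
#' @param ppfd numeric PPFD vector on the same grid as `stem` (or an
#'   `env_series` covering it).
#' @param t_rsr threshold fraction in `(0, 1]`.
#' @param cutoff end of the active window, "HH:MM".
#' @param volume_ml reported volume per event.
#' @return list with `events` (an `irrigation_log`) and `trace` (data frame:
#'   `time`, `rsr`, `rsr_pre`, `elapsed_min`, `event`, `active`).
#' @export
run_rsr_controller <- function(stem, ppfd, t_rsr = 0.9975, cutoff = "19:00",
                               volume_ml = 15) {
  if (is.data.frame(ppfd)) {
    m <- match(as.numeric(stem$time), as.numeric(ppfd$time))
    if (any(is.na(m)))
      stop_wiltflow("stem and PPFD grids do not match", "wiltflow_grid_error")
    ppfd <- ppfd$ppfd[m]
  }
  if (length(ppfd) != nrow(stem))
    stop_wiltflow("stem and PPFD grids do not match", "wiltflow_grid_error")
  n <- nrow(stem)
  mod <- minute_of_day(stem$time)
  dates <- date_of(stem$time)
  cutoff_min <- hm_to_min(cutoff)
  sunrise_mod <- tapply(seq_len(n), dates, function(idx) {
    hit <- idx[ppfd[idx] >= 14.8]
    if (length(hit)) mod[hit[1]] else NA_integer_
  })
  sr <- sunrise_mod[as.character(dates)]
  active <- !is.na(sr) & mod >= sr & mod < cutoff_min

  gap_before <- c(FALSE, diff(as.numeric(stem$time)) != 60)
  d <- stem$diameter_mm
  rsr_pre <- numeric(n); rsr_post <- numeric(n); elapsed <- integer(n)
  event <- logical(n)
  run_max <- -Inf; win_start <- 1L
  for (t in seq_len(n)) {
    if (gap_before[t]) { run_max <- -Inf; win_start <- t }
    run_max <- max(run_max, d[t])
    r <- d[t] / run_max
    rsr_pre[t] <- r
    elapsed[t] <- t - win_start
    if (active[t] && r < t_rsr) {
      event[t] <- TRUE
      run_max <- -Inf
      win_start <- t + 1L
      rsr_post[t] <- 1.0
    } else rsr_post[t] <- r
  }
  events <- data.frame(time = stem$time[event],
                       volume_ml = rep(volume_ml, sum(event)))
  class(events) <- c("irrigation_log", "data.frame")
  list(events = events,
       trace = data.frame(time = stem$time, rsr = rsr_post,
                          rsr_pre = rsr_pre, elapsed_min = elapsed,
                          event = event, active = active))
}
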