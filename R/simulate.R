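#' Simulate a water-stressed plant under RSR irrigation control
#'
#' Discrete-time (1-min) soil -> stem -> leaf reservoir chain. Transpiration
#' demand is `E(t) = transpiration_gain * (ppfd / ppfd_amplitude) *
#' min(vpd, vpd_plateau)` (the plateau encodes stomatal closure under high
#' VPD). Root uptake restores the stem water pool `W` toward 0 at rate
#' `uptake_rate`, limited by soil availability `S / (S + soil_halfsat)`, so
#' the stem dries out progressively between irrigations and recovers after
#' each event. Stem diameter is `stem_baseline + growth + shrink_gain * W +
#' noise`. The leaf water status is a first-order low-pass (time constant
#' `leaf_time_constant_tau`) of `W` delayed by `transport_delay_D` minutes —
#' the latent transport delay the lag analysis recovers — and leaf droop is
#' `wilt_displacement = -coupling_gamma * leaf_water` (pixels, monotone
#' non-increasing in leaf water). An independent whole-plant sway channel
#' (`leaf_jitter_sd`) models wind/camera micro-motion.
#'
#' Irrigation follows the relative stem diameter rule: within
#' `[sunrise, cutoff)` (sunrise = first minute with PPFD >= 14.8), when the
#' current diameter falls below `t_rsr` times the running maximum since the
#' last event, one `irrigation_volume` is added to the soil and the RSR
#' window resets (RSR = 1.0000 at the reset).
#'
#' @param config a [scenario_config()].
#' @param env an `env_series` from [generate_environment()]; must be a
#'   gap-free minute grid.
#' @return a list with elements `stem` (`stem_series`: time, diameter_mm),
#'   `truth` (`latent_truth`: time, stem_water, leaf_water, soil_reservoir,
#'   wilt_displacement, sway; attribute `true_delay`), `irrigation`
#'   (`irrigation_log`: time, volume_ml) and `rsr` (trace: time, rsr,
#'   rsr_pre, elapsed_min, event, active).
#' @export
simulate_plant <- function(config, env) {
  stopifnot(inherits(config, "scenario_config"), inherits(env, "env_series"))
  dt <- diff(as.numeric(env$time))
  if (length(dt) && any(dt != 60))
    stop_wiltflow("environment series must be a gap-free 1-min grid",
                  "wiltflow_grid_error")
  n <- nrow(env)
  local_seed(config$seed + 1L, {
    stem_noise <- rnorm(n, sd = config$stem_noise_sd)
    sway <- rnorm(n, sd = config$leaf_jitter_sd)

    mod <- minute_of_day(env$time)
    dates <- date_of(env$time)
    cutoff_min <- hm_to_min(config$cutoff)
    # per-day sunrise: first minute with PPFD >= 14.8
    sunrise_mod <- tapply(seq_len(n), dates, function(idx) {
      hit <- idx[env$ppfd[idx] >= 14.8]
      if (length(hit)) mod[hit[1]] else NA_integer_
    })
    sr_for_row <- sunrise_mod[as.character(dates)]
    active <- !is.na(sr_for_row) & mod >= sr_for_row & mod < cutoff_min

    alpha <- 1 - exp(-1 / config$leaf_time_constant_tau)
    D <- config$transport_delay_D
    E <- config$transpiration_gain *
      (env$ppfd / max(config$ppfd_amplitude, 1e-12)) *
      pmin(env$vpd, config$vpd_plateau)

    W <- numeric(n); S <- numeric(n); lw <- numeric(n)
    stem <- numeric(n)
    rsr_pre <- numeric(n); rsr_post <- numeric(n); elapsed <- integer(n)
    event <- logical(n)
    s_cur <- config$soil_initial
    w_cur <- 0; lw_cur <- 0
    win_start <- 1L; run_max <- -Inf
    growth_per_min <- config$growth_rate / 1440

    for (t in seq_len(n)) {
      avail <- s_cur / (s_cur + config$soil_halfsat)
      uptake <- min(s_cur, config$uptake_rate * max(0, -w_cur) * avail)
      w_cur <- w_cur + uptake - E[t]
      s_cur <- s_cur - uptake
      W[t] <- w_cur
      stem[t] <- config$stem_baseline + growth_per_min * (t - 1) +
        config$shrink_gain * w_cur + stem_noise[t]

      # RSR over the window since the last irrigation, current value included
      run_max <- max(run_max, stem[t])
      r <- stem[t] / run_max
      rsr_pre[t] <- r
      elapsed[t] <- t - win_start
      if (active[t] && r < config$t_rsr) {
        event[t] <- TRUE
        s_cur <- s_cur + config$irrigation_volume
        win_start <- t + 1L          # next window starts fresh: next rsr = 1
        run_max <- -Inf
        rsr_post[t] <- 1.0           # trace value at the reset
      } else {
        rsr_post[t] <- r
      }

      wd_idx <- max(1L, t - D)
      lw_cur <- lw_cur + alpha * (W[wd_idx] - lw_cur)
      lw[t] <- lw_cur
      S[t] <- s_cur
    }

    stem_df <- data.frame(time = env$time, diameter_mm = stem)
    class(stem_df) <- c("stem_series", "data.frame")
    truth <- data.frame(
      time = env$time, stem_water = W, leaf_water = lw, soil_reservoir = S,
      wilt_displacement = -config$coupling_gamma * lw, sway = sway
    )
    attr(truth, "true_delay") <- D
    class(truth) <- c("latent_truth", "data.frame")
    irr <- data.frame(time = env$time[event],
                      volume_ml = rep(15, sum(event)))  # nominal dose
    class(irr) <- c("irrigation_log", "data.frame")
    rsr_trace <- data.frame(time = env$time, rsr = rsr_post,
                            rsr_pre = rsr_pre, elapsed_min = elapsed,
                            event = event, active = active)
    list(stem = stem_df, truth = truth, irrigation = irr, rsr = rsr_trace)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_environment()] then [simulate_plant()],
#' optionally adding the fast-path flow fields ([synth_flow_fields()]) and/or
#' rendered frames ([render_frames()]).
#'
#' @param config a [scenario_config()].
#' @param flows if `TRUE`, attach precomputed flow fields (fast path).
#' @param frames if `TRUE`, attach rendered 144x144 image sequences.
#' @param w flow window (minutes) for the fast path.
#' @return a list of class `synthetic_dataset` with elements `config`, `env`,
#'   `stem`, `truth`, `irrigation`, `rsr`, and optionally `flows`, `frames`.
#' @export
simulate_scenario <- function(config, flows = FALSE, frames = FALSE, w = 5L) {
  env <- generate_environment(config)
  sim <- simulate_plant(config, env)
  ds <- c(list(config = config, env = env), sim)
  if (flows)  ds$flows  <- synth_flow_fields(sim$truth, config, w = w)
  if (frames) ds$frames <- render_frames(sim$truth, config)
  class(ds) <- "synthetic_dataset"
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d min, %d irrigation event(s)%s%s\n",
              x$config$plant_id, nrow(x$env), nrow(x$irrigation),
              if (!is.null(x$flows)) ", flow fast path" else "",
              if (!is.null(x$frames)) ", rendered frames" else ""))
  invisible(x)
}
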