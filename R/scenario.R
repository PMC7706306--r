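#' Scenario configuration for the synthetic greenhouse
#'
#' Bundles every tunable of the synthetic-data generator: the weather regime,
#' the plant water-transport parameters (most importantly the stem-to-leaf
#' transport delay `transport_delay_D`, the latent quantity the downstream
#' lag analysis tries to recover), the stem geometry, the irrigation
#' controller threshold and the sensor noise levels. Identical configurations
#' (including `seed`) always produce bit-identical datasets.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param n_days number of simulated days.
#' @param weather `"sunny"`, `"cloudy"` or `"mixed"` (per-day coin flip).
#' @param ppfd_amplitude clear-sky peak PPFD (umol s-1 m-2) of scattered
#'   light above the plant. Greenhouse scattered-light sensors read far below
#'   open-sky values; 300 is a bright spring day.
#' @param cloud_strength cloud attenuation strength in `[0, 1]`; `NULL` picks
#'   a regime default (0.15 sunny, 0.75 cloudy).
#' @param transport_delay_D water-transport delay stem -> leaf, minutes >= 0.
#' @param leaf_time_constant_tau first-order smoothing time constant
#'   (minutes, > 0) applied to the delayed stem water status.
#' @param coupling_gamma leaf-tip pixels of droop per unit stem water
#'   deficit (>= 0); 0 decouples wilting from the stem entirely.
#' @param stem_baseline stem diameter at t = 0, mm.
#' @param growth_rate secular stem growth, mm per day.
#' @param shrink_gain mm of stem shrinkage per unit water deficit.
#' @param irrigation_volume soil-reservoir units added per irrigation event
#'   (reported as 15 ml per unit in the irrigation log).
#' @param t_rsr relative stem diameter threshold in `(0, 1]` below which the
#'   controller irrigates.
#' @param sensor_noise_sd additive per-channel image noise SD (0-255 scale).
#' @param stem_noise_sd dendrometer noise SD, mm.
#' @param leaf_jitter_sd SD (pixels) of whole-plant vertical micro-motion
#'   (wind / camera sway), independent of water status.
#' @param vpd_plateau transpiration saturates above this VPD (kPa);
#'   represents stomatal closure under high evaporative demand.
#' @param transpiration_gain soil units transpired per minute at unit
#'   normalized light and 1 kPa effective VPD.
#' @param uptake_rate root uptake rate constant (1/min).
#' @param soil_halfsat soil half-saturation constant for uptake limitation.
#' @param soil_initial initial soil reservoir, units.
#' @param day_start,day_end solar day boundaries, "HH:MM" (photoperiod).
#' @param image_start,image_end camera operating window, "HH:MM".
#' @param cutoff irrigation controller stop time, "HH:MM".
#' @param start_date first simulated date.
#' @param plant_id label carried through all outputs.
#' @return an object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(seed = 1L,
                            n_days = 1L,
                            weather = c("sunny", "cloudy", "mixed"),
                            ppfd_amplitude = 300,
                            cloud_strength = NULL,
                            transport_delay_D = 2L,
                            leaf_time_constant_tau = 1,
                            coupling_gamma = 80,
                            stem_baseline = 10,
                            growth_rate = 0.05,
                            shrink_gain = 1.3,
                            irrigation_volume = 0.5,
                            t_rsr = 0.9975,
                            sensor_noise_sd = 0,
                            stem_noise_sd = 0.002,
                            leaf_jitter_sd = 0.2,
                            vpd_plateau = 4,
                            transpiration_gain = 0.04,
                            uptake_rate = 0.3,
                            soil_halfsat = 2,
                            soil_initial = 2,
                            day_start = "06:00",
                            day_end = "18:30",
                            image_start = "09:00",
                            image_end = "17:00",
                            cutoff = "19:00",
                            start_date = as.Date("2024-04-01"),
                            plant_id = "plant1") {
  weather <- match.arg(weather)
  if (is.null(cloud_strength))
    cloud_strength <- switch(weather, sunny = 0.15, cloudy = 0.75, mixed = NA)
  assert_scalar_num(seed, "seed")
  assert_scalar_num(n_days, "n_days", lower = 1)
  assert_scalar_num(ppfd_amplitude, "ppfd_amplitude", lower = 0)
  if (weather != "mixed")
    assert_scalar_num(cloud_strength, "cloud_strength", lower = 0, upper = 1)
  assert_scalar_num(transport_delay_D, "transport_delay_D", lower = 0)
  assert_scalar_num(leaf_time_constant_tau, "leaf_time_constant_tau",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(coupling_gamma, "coupling_gamma", lower = 0)
  assert_scalar_num(stem_baseline, "stem_baseline", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(t_rsr, "t_rsr", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_scalar_num(sensor_noise_sd, "sensor_noise_sd", lower = 0)
  assert_scalar_num(stem_noise_sd, "stem_noise_sd", lower = 0)
  assert_scalar_num(leaf_jitter_sd, "leaf_jitter_sd", lower = 0)
  cfg <- list(
    seed = as.integer(seed), n_days = as.integer(n_days), weather = weather,
    ppfd_amplitude = ppfd_amplitude, cloud_strength = cloud_strength,
    transport_delay_D = as.integer(round(transport_delay_D)),
    leaf_time_constant_tau = leaf_time_constant_tau,
    coupling_gamma = coupling_gamma, stem_baseline = stem_baseline,
    growth_rate = growth_rate, shrink_gain = shrink_gain,
    irrigation_volume = irrigation_volume, t_rsr = t_rsr,
    sensor_noise_sd = sensor_noise_sd, stem_noise_sd = stem_noise_sd,
    leaf_jitter_sd = leaf_jitter_sd, vpd_plateau = vpd_plateau,
    transpiration_gain = transpiration_gain, uptake_rate = uptake_rate,
    soil_halfsat = soil_halfsat, soil_initial = soil_initial,
    day_start = day_start, day_end = day_end,
    image_start = image_start, image_end = image_end, cutoff = cutoff,
    start_date = as.Date(start_date), plant_id = plant_id
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s, %d day(s), %s; D = %d min, tau = %g min, gamma = %g px\n",
    x$plant_id, x$n_days, x$weather, x$transport_delay_D,
    x$leaf_time_constant_tau, x$coupling_gamma))
  invisible(x)
}

#' Vapor-pressure deficit from temperature and relative humidity
#'
#' Tetens saturation vapor pressure:
#' `es(T) = 0.6108 * exp(17.27 T / (T + 237.3))` kPa, and
#' `vpd = es(T) * (1 - rh / 100)`.
#'
#' @param temperature air temperature, degrees C (vectorized).
#' @param rh relative humidity, percent in `[0, 100]`.
#' @return VPD in kPa, always >= 0.
#' @examples
#' vpd_from_t_rh(25, 50) # ~1.58 kPa
#' @export
vpd_from_t_rh <- function(temperature, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100))
    stop_wiltflow("relative humidity must lie in [0, 100]",
                  "wiltflow_domain_error")
  if (any(!is.finite(temperature)) || any(temperature < -20 | temperature > 60))
    stop_wiltflow("temperature outside supported range [-20, 60] C",
                  "wiltflow_domain_error")
  es <- 0.6108 * exp(17.27 * temperature / (temperature + 237.3))
  pmax(0, es * (1 - rh / 100))
}

#' Generate a synthetic greenhouse environment trace
#'
#' Minute-resolution PPFD, temperature, relative humidity and VPD for
#' `config$n_days` days. Clear-sky PPFD is a half-sine between `day_start`
#' and `day_end` scaled by `ppfd_amplitude` and attenuated by a clipped AR(1)
#' cloud process of strength `cloud_strength`; temperature is a diurnal
#' sinusoid peaking mid-afternoon with relative humidity in anti-phase, and
#' VPD follows from [vpd_from_t_rh()].
#'
#' @param config a [scenario_config()].
#' @return a data frame of class `env_series` with columns `time`, `ppfd`,
#'   `temperature`, `rh`, `vpd` and (attribute) per-day `weather`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  local_seed(config$seed, {
    n_days <- config$n_days
    day_weather <- if (config$weather == "mixed") {
      sample(c("sunny", "cloudy"), n_days, replace = TRUE)
    } else rep(config$weather, n_days)
    strength <- ifelse(day_weather == "sunny", 0.15, 0.75)
    if (config$weather != "mixed") strength <- rep(config$cloud_strength, n_days)

    t_sr <- hm_to_min(config$day_start)
    t_ss <- hm_to_min(config$day_end)
    m <- 0:1439
    out <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      # clipped AR(1) cloud attenuation in (0, 1]
      z <- numeric(1440)
      z[1] <- rnorm(1)
      innov <- rnorm(1439, sd = sqrt(1 - 0.97^2))
      for (i in 2:1440) z[i] <- 0.97 * z[i - 1] + innov[i - 1]
      k <- pmin(1, pmax(0, strength[d] * (0.7 + 0.5 * z)))
      cloud <- 1 - 0.9 * k

      base <- pmax(0, sin(pi * (m - t_sr) / (t_ss - t_sr)))
      base[m < t_sr | m > t_ss] <- 0
      ppfd <- config$ppfd_amplitude * base * cloud

      ampfac <- 0.4 + 0.6 * mean(cloud)
      s <- sin(2 * pi * (m - 480) / 1440)  # peaks 14:00
      temperature <- 22 + 6 * ampfac * s
      rh <- pmin(95, pmax(30, 70 - 25 * ampfac * s))
      out[[d]] <- data.frame(
        time = minute_grid(config$start_date + (d - 1), m),
        ppfd = ppfd, temperature = temperature, rh = rh,
        vpd = vpd_from_t_rh(temperature, rh)
      )
    }
    env <- do.call(rbind, out)
    attr(env, "weather") <- day_weather
    class(env) <- c("env_series", "data.frame")
    env
  })
}
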