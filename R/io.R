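fmt_time <- function(time) format(time, "%Y-%m-%dT%H:%M", tz = "UTC")

parse_time <- function(x, path) {
  t <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                              "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")),
    error = function(e) as.POSIXct(rep(NA_character_, length(x)), tz = "UTC"))
  bad <- which(is.na(t))
  if (length(bad))
    stop_wiltflow(sprintf("%s: unparseable timestamp at data row %d ('%s')",
                          path, bad[1], x[bad[1]]), "wiltflow_schema_error")
  t
}

check_time_order <- function(t, path) {
  d <- which(duplicated(t))
  if (length(d))
    stop_wiltflow(sprintf(
      "%s: duplicated timestamp at row %d (counting the header line)",
      path, d[1] + 1L), "wiltflow_schema_error")
  if (is.unsorted(t))
    stop_wiltflow(sprintf(
      "%s: timestamps not in increasing order (first at data row %d)",
      path, which(diff(as.numeric(t)) < 0)[1] + 1L),
      "wiltflow_schema_error")
}

#' Read a minute-resolution sensor CSV
#'
#' Schemas: `stem` (`timestamp`, `diameter_mm`), `env` (`timestamp`,
#' `ppfd` *or* `lux`, `temperature_c`, `rh_pct`, optional `vpd_kpa`) and
#' `irrigation` (`timestamp`, `volume_ml`). Timestamps are ISO-8601 local
#' clock times at minute resolution; duplicates and non-monotone order are
#' rejected with the offending row named. When an env file carries `lux` but
#' no `ppfd`, PPFD is derived via [lux_to_ppfd()] and flagged in the
#' `derived` attribute; a missing `vpd_kpa` is derived via
#' [vpd_from_t_rh()]. Grid gaps are recorded in the `gaps` attribute.
#'
#' @param path CSV file path.
#' @param schema one of `"stem"`, `"env"`, `"irrigation"`.
#' @return the typed series (`stem_series`, `env_series` or
#'   `irrigation_log`).
#' @export
read_sensor_csv <- function(path, schema = c("stem", "env", "irrigation")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- switch(schema, stem = c("timestamp", "diameter_mm"),
                 env = c("timestamp", "temperature_c", "rh_pct"),
                 irrigation = c("timestamp", "volume_ml"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_wiltflow(sprintf("%s: missing column(s) %s", path,
                          paste(missing_cols, collapse = ", ")),
                  "wiltflow_schema_error")
  t <- parse_time(df$timestamp, path)
  check_time_order(t, path)
  gaps <- which(diff(as.numeric(t)) > 60)
  derived <- character()
  out <- switch(schema,
    stem = {
      s <- data.frame(time = t, diameter_mm = df$diameter_mm)
      class(s) <- c("stem_series", "data.frame")
      s
    },
    env = {
      if (!"ppfd" %in% names(df)) {
        if (!"lux" %in% names(df))
          stop_wiltflow(sprintf("%s: env schema needs a ppfd or lux column",
                                path), "wiltflow_schema_error")
        df$ppfd <- lux_to_ppfd(df$lux)
        derived <- c(derived, "ppfd from lux (factor 54)")
      }
      if (!"vpd_kpa" %in% names(df)) {
        df$vpd_kpa <- vpd_from_t_rh(df$temperature_c, df$rh_pct)
        derived <- c(derived, "vpd from temperature/rh (Tetens)")
      }
      e <- data.frame(time = t, ppfd = df$ppfd,
                      temperature = df$temperature_c, rh = df$rh_pct,
                      vpd = df$vpd_kpa)
      class(e) <- c("env_series", "data.frame")
      e
    },
    irrigation = {
      i <- data.frame(time = t, volume_ml = df$volume_ml)
      class(i) <- c("irrigation_log", "data.frame")
      i
    })
  attr(out, "gaps") <- t[gaps]
  attr(out, "derived") <- derived
  out
}

#' Write the synthetic dataset's sensor CSVs (and optionally frames)
#'
#' Emits the same schemas [read_sensor_csv()] reads — `stem.csv`, `env.csv`,
#' `irrigation.csv` — plus, when frames are attached, an `images/` directory
#' of PNGs named `<plant>_<YYYYMMDD>-<HHMM>.png`.
#'
#' @param dataset a `synthetic_dataset` from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(timestamp = fmt_time(dataset$stem$time),
                              diameter_mm = dataset$stem$diameter_mm),
                   file.path(dir, "stem.csv"), row.names = FALSE)
  utils::write.csv(data.frame(timestamp = fmt_time(dataset$env$time),
                              ppfd = dataset$env$ppfd,
                              temperature_c = dataset$env$temperature,
                              rh_pct = dataset$env$rh,
                              vpd_kpa = dataset$env$vpd),
                   file.path(dir, "env.csv"), row.names = FALSE)
  utils::write.csv(data.frame(timestamp = fmt_time(dataset$irrigation$time),
                              volume_ml = dataset$irrigation$volume_ml),
                   file.path(dir, "irrigation.csv"), row.names = FALSE)
  if (!is.null(dataset$frames)) {
    imgdir <- file.path(dir, "images")
    dir.create(imgdir, showWarnings = FALSE)
    fr <- dataset$frames
    for (i in seq_along(fr$frames)) {
      fn <- sprintf("%s_%s.png", fr$plant_id,
                    format(fr$time[i], "%Y%m%d-%H%M", tz = "UTC"))
      png::writePNG(fr$frames[[i]] / 255, file.path(imgdir, fn))
    }
  }
  invisible(dir)
}

#' Read a plant image directory
#'
#' Loads PNG frames named `<plant>_<YYYYMMDD>-<HHMM>.png`, sorts them by
#' timestamp, resizes any frame that is not 144x144 to the working
#' resolution, and enumerates missing minutes between the first and last
#' frame in the `gaps` attribute. JPEG inputs are not supported (no JPEG
#' reader is available) and raise a capability error.
#'
#' @param path directory of frames.
#' @param plant_id restrict to one plant label (default: the only one
#'   present; multiple labels without a filter is an error).
#' @return an [image_sequence()] with a `gaps` attribute.
#' @export
read_image_dir <- function(path, plant_id = NULL) {
  files <- list.files(path, pattern = "_[0-9]{8}-[0-9]{4}\\.(png|jpg|jpeg)$",
                      full.names = TRUE)
  if (!length(files))
    stop_wiltflow(sprintf("no '<plant>_<YYYYMMDD>-<HHMM>' images under %s",
                          path), "wiltflow_input_error")
  if (any(grepl("\\.(jpg|jpeg)$", files)))
    stop_wiltflow("JPEG frames are not supported (PNG only)",
                  "wiltflow_capability_error")
  base <- basename(files)
  m <- regmatches(base, regexec("^(.+)_([0-9]{8})-([0-9]{4})\\.png$", base))
  plant <- vapply(m, `[`, "", 2)
  stamp <- as.POSIXct(paste0(vapply(m, `[`, "", 3),
                             vapply(m, `[`, "", 4)),
                      format = "%Y%m%d%H%M", tz = "UTC")
  if (!is.null(plant_id)) {
    keep <- plant == plant_id
    files <- files[keep]; stamp <- stamp[keep]; plant <- plant[keep]
    if (!length(files))
      stop_wiltflow(sprintf("no frames for plant '%s'", plant_id),
                    "wiltflow_input_error")
  } else if (length(unique(plant)) > 1) {
    stop_wiltflow("multiple plant labels present; pass plant_id",
                  "wiltflow_input_error")
  }
  o <- order(stamp)
  files <- files[o]; stamp <- stamp[o]
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    resize_frame(img[, , 1:3, drop = FALSE] * 255)
  })
  seq_out <- image_sequence(frames, stamp, plant_id = plant[1])
  full <- seq(stamp[1], stamp[length(stamp)], by = 60)
  attr(seq_out, "gaps") <- full[!full %in% stamp]
  seq_out
}

#' Pipeline run configuration
#'
#' Exactly one of `scenario` (a [scenario_config()] for synthetic runs) or
#' `inputs` (named list with paths `image_dir`, `stem_csv`, `env_csv`) must
#' be supplied.
#'
#' @param scenario a [scenario_config()], or `NULL`.
#' @param inputs named list of input paths, or `NULL`.
#' @param w differencing window, minutes.
#' @param max_lag maximum cross-correlation lag, minutes.
#' @param flow flow backend: `"synthetic"` (fast path, scenario runs only),
#'   `"block_match"`, `"dense_reference"`, `"deepflow"`.
#' @param exg_threshold ExG mask threshold.
#' @param t_rsr RSR controller threshold (reporting; scenario runs take it
#'   from the scenario).
#' @param sunrise_ppfd sunrise detection threshold, umol s-1 m-2.
#' @param out_dir output directory for the results bundle.
#' @param seed seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = NULL, inputs = NULL, w = 5L, max_lag = 60L,
                       flow = c("synthetic", "block_match", "dense_reference",
                                "deepflow"),
                       exg_threshold = 0, t_rsr = 0.9975, sunrise_ppfd = 14.8,
                       out_dir = tempfile("wiltflow_run_"), seed = 1L) {
  flow <- match.arg(flow)
  if (is.null(scenario) == is.null(inputs))
    stop("exactly one of 'scenario' or 'inputs' must be given")
  if (!is.null(inputs) && flow == "synthetic")
    stop("flow = 'synthetic' requires a scenario (no real-image fast path)")
  structure(list(scenario = scenario, inputs = inputs, w = as.integer(w),
                 max_lag = as.integer(max_lag), flow = flow,
                 exg_threshold = exg_threshold, t_rsr = t_rsr,
                 sunrise_ppfd = sunrise_ppfd, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

manifest_of <- function(config) {
  cfg <- unclass(config)
  cfg$scenario <- if (!is.null(cfg$scenario)) {
    s <- unclass(cfg$scenario); s$start_date <- as.character(s$start_date); s
  }
  list(package = "wiltflow",
       version = as.character(utils::packageVersion("wiltflow")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config = cfg)
}

#' Run the full pipeline
#'
#' simulate/load -> wilt quantification -> stem differencing -> per-day
#' lagged cross-correlation -> regression of `r_max` / `l_max` against daily
#' mean PPFD and VPD. Writes `wilt.csv`, `delta_stem.csv`,
#' `correlograms.csv`, `summary.csv`, `regression.csv` and `manifest.json`
#' into `config$out_dir` and returns the results in memory.
#'
#' Regressions need several plant-days; with fewer than 6 rows the regression
#' stage is skipped (recorded in the bundle) rather than fitted on
#' unidentifiable data.
#'
#' @param config a [run_config()].
#' @return a `results_bundle` list: `summary`, `correlograms`, `wilt`,
#'   `delta_stem`, `regressions`, `skipped`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$scenario)) {
    ds <- simulate_scenario(config$scenario,
                            flows = config$flow == "synthetic",
                            frames = config$flow != "synthetic",
                            w = config$w)
    env <- ds$env; stem <- ds$stem
    wilt <- if (config$flow == "synthetic") {
      quantify_wilt_from_flows(ds$flows)
    } else {
      quantify_wilt_series(ds$frames, w = config$w, method = config$flow,
                           exg_threshold = config$exg_threshold)
    }
  } else {
    env <- read_sensor_csv(config$inputs$env_csv, "env")
    stem <- read_sensor_csv(config$inputs$stem_csv, "stem")
    images <- read_image_dir(config$inputs$image_dir)
    wilt <- quantify_wilt_series(images, w = config$w, method = config$flow,
                                 exg_threshold = config$exg_threshold)
  }
  dstem <- delta_stem(stem, w = config$w)
  summary <- summarize_days(wilt, dstem, env, max_lag = config$max_lag)

  regressions <- list()
  if (nrow(summary) >= 6) {
    for (resp in c("r_max", "l_max")) {
      for (pred in c("mean_ppfd", "mean_vpd")) {
        fit <- tryCatch(select_model(summary[[pred]], summary[[resp]]),
                        error = function(e) NULL)
        if (!is.null(fit))
          regressions[[paste(resp, "vs", pred)]] <- fit
      }
    }
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  utils::write.csv(cbind(timestamp = fmt_time(wilt$time),
                         wilt[-1], w = attr(wilt, "w")),
                   file.path(od, "wilt.csv"), row.names = FALSE)
  utils::write.csv(cbind(timestamp = fmt_time(dstem$time), dstem[-1],
                         w = attr(dstem, "w")),
                   file.path(od, "delta_stem.csv"), row.names = FALSE)
  utils::write.csv(attr(summary, "correlograms"),
                   file.path(od, "correlograms.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(summary), file.path(od, "summary.csv"),
                   row.names = FALSE)
  reg_rows <- do.call(rbind, lapply(names(regressions), function(nm) {
    fit <- regressions[[nm]]
    data.frame(response = sub(" vs.*", "", nm),
               predictor = sub(".*vs ", "", nm),
               family = fit$family,
               params = as.character(jsonlite::toJSON(fit$params,
                                                      auto_unbox = TRUE,
                                                      digits = NA)),
               r2 = fit$r_squared,
               p = regression_pvalue(fit),
               n = fit$n, selected = TRUE)
  }))
  if (is.null(reg_rows))
    reg_rows <- data.frame(response = character(), predictor = character(),
                           family = character(), params = character(),
                           r2 = numeric(), p = numeric(), n = integer(),
                           selected = logical())
  utils::write.csv(reg_rows, file.path(od, "regression.csv"),
                   row.names = FALSE)
  manifest <- manifest_of(config)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(summary = summary,
                 correlograms = attr(summary, "correlograms"),
                 wilt = wilt, delta_stem = dstem, regressions = regressions,
                 skipped = attr(summary, "skipped"), manifest = manifest,
                 out_dir = od),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d plant-day(s), %d skipped, %d regression(s); outputs in %s\n",
              nrow(x$summary), nrow(x$skipped), length(x$regressions),
              x$out_dir))
  invisible(x)
}
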