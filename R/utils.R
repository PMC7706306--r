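# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators never perturb user code.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Clock times are timezone-naive local times; represented as UTC POSIXct so
# arithmetic is pure minute arithmetic with no DST surprises.
minute_grid <- function(date, minutes = 0:1439) {
  as.POSIXct(as.character(date), tz = "UTC") + 60 * minutes
}

minute_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  lt$hour * 60L + lt$min
}

date_of <- function(time) as.Date(time, tz = "UTC")

# "HH:MM" -> minutes after midnight
hm_to_min <- function(hm) {
  parts <- strsplit(hm, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

stop_wiltflow <- function(msg, class) {
  stop(structure(
    class = c(class, "wiltflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper)
    stop(sprintf("'%s' = %g outside its valid range", name, x))
  invisible(x)
}
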