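#' Daily arithmetic means of the environment
#'
#' Arithmetic mean of the available minute samples in the half-open window
#' `[09:00, 19:00)` (the daytime range relevant to transpiration), one row
#' per date. Missing minutes are simply excluded; the fraction of the window
#' actually covered is reported.
#'
#' @param env an `env_series` (columns `time`, `ppfd`, `vpd`, optionally
#'   `temperature`, `rh`).
#' @param date restrict to one date (default: all dates present).
#' @param window character 2-vector "HH:MM"; start inclusive, end exclusive.
#' @return data frame: `date`, `mean_ppfd`, `mean_vpd`, `coverage`.
#' @export
mean_env <- function(env, date = NULL, window = c("09:00", "19:00")) {
  w0 <- hm_to_min(window[1]); w1 <- hm_to_min(window[2])
  mod <- minute_of_day(env$time)
  sub <- env[mod >= w0 & mod < w1, , drop = FALSE]
  if (!is.null(date)) sub <- sub[date_of(sub$time) == as.Date(date), ,
                                 drop = FALSE]
  if (!nrow(sub))
    stop_wiltflow("no environment samples inside the window",
                  "wiltflow_input_error")
  sp <- split(sub, date_of(sub$time))
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    date = date_of(d$time[1]),
    mean_ppfd = mean(d$ppfd),
    mean_vpd = mean(d$vpd),
    coverage = nrow(d) / (w1 - w0))))
  rownames(out) <- NULL
  out
}

fit_k <- c(linear = 1L, log = 1L, quadratic = 2L, exponential = 2L,
           piecewise_linear = 3L)

new_fit_result <- function(family, params, fitted, y, n) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop_wiltflow("constant response: R-squared undefined",
                  "wiltflow_fit_error")
  k <- fit_k[[family]]
  r2 <- 1 - ss_res / ss_tot
  structure(list(family = family, params = params, r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - k - 1),
                 n = n, k = k, fitted = fitted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: R2 = %.4f (n = %d)\n  params: %s\n",
              x$family, x$r_squared, x$n,
              paste(sprintf("%s = %.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

fit_piecewise <- function(x, y) {
  # continuous two-segment line with a fitted breakpoint tau:
  # y = b1 + a1*x + (a2 - a1)*max(x - tau, 0); tau profiled over interior
  # quantiles of x, then refined locally (the profile SSE is piecewise smooth)
  xs <- sort(unique(x))
  if (length(xs) < 4) stop_wiltflow("too few distinct x for a breakpoint",
                                    "wiltflow_fit_error")
  sse_at <- function(tau) {
    h <- pmax(x - tau, 0)
    f <- stats::lm.fit(cbind(1, x, h), y)
    sum(f$residuals^2)
  }
  lo <- xs[2]; hi <- xs[length(xs) - 1]
  grid <- unique(stats::quantile(x, probs = seq(0.05, 0.95, length.out = 25),
                                 names = FALSE))
  grid <- grid[grid > lo - 1e-12 & grid < hi + 1e-12]
  if (!length(grid)) grid <- (lo + hi) / 2
  sses <- vapply(grid, sse_at, numeric(1))
  best <- which.min(sses)
  bracket <- c(grid[max(1, best - 1)], grid[min(length(grid), best + 1)])
  tau <- if (diff(bracket) > 1e-10) {
    stats::optimize(sse_at, interval = bracket)$minimum
  } else grid[best]
  h <- pmax(x - tau, 0)
  f <- stats::lm.fit(cbind(1, x, h), y)
  b1 <- f$coefficients[1]; a1 <- f$coefficients[2]
  a2 <- a1 + f$coefficients[3]
  fitted <- b1 + a1 * x + (a2 - a1) * h
  list(params = list(a1 = unname(a1), b1 = unname(b1), a2 = unname(a2),
                     tau = unname(tau)),
       fitted = fitted)
}

fit_exponential <- function(x, y) {
  # y = a * exp(b * x) + c, initialized from a log-linearization with the
  # offset pinned just below min(y); Levenberg-Marquardt refinement
  rng <- diff(range(y))
  c0 <- min(y) - 0.05 * max(rng, abs(min(y)), 1e-8)
  z <- pmax(y - c0, 1e-10)
  lf <- stats::lm.fit(cbind(1, x), log(z))
  start <- list(a = unname(exp(lf$coefficients[1])),
                b = unname(lf$coefficients[2]), c = unname(c0))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x) + c, data = data.frame(x = x, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_wiltflow(paste("exponential fit failed:", conditionMessage(e)),
                    "wiltflow_fit_error"))
  p <- as.list(stats::coef(fit))
  list(params = p, fitted = p$a * exp(p$b * x) + p$c)
}

#' Fit one regression family
#'
#' Least-squares fit of one of the five candidate families used to relate
#' per-day correlation summaries to daily mean environment: straight line,
#' second-order polynomial, continuous two-segment (piecewise) line with a
#' fitted breakpoint, logarithmic `a*ln(x) + b`, and exponential
#' `a*exp(b*x) + c`. `r_squared = 1 - SS_res / SS_tot` (raw, with the
#' adjusted value reported alongside).
#'
#' @param x,y predictor and response vectors.
#' @param family one of `"linear"`, `"quadratic"`, `"piecewise_linear"`,
#'   `"log"`, `"exponential"`.
#' @return a `fit_result`: `family`, `params`, `r_squared`,
#'   `adj_r_squared`, `n`, `k` (predictor-side parameter count), `fitted`.
#' @export
fit_family <- function(x, y, family = c("linear", "quadratic",
                                        "piecewise_linear", "log",
                                        "exponential")) {
  family <- match.arg(family)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < fit_k[[family]] + 2)
    stop_wiltflow("too few points for this family", "wiltflow_fit_error")
  res <- switch(family,
    linear = {
      f <- stats::lm.fit(cbind(1, x), y)
      list(params = list(a = unname(f$coefficients[2]),
                         b = unname(f$coefficients[1])),
           fitted = unname(cbind(1, x) %*% f$coefficients)[, 1])
    },
    quadratic = {
      f <- stats::lm.fit(cbind(1, x, x^2), y)
      list(params = list(a = unname(f$coefficients[3]),
                         b = unname(f$coefficients[2]),
                         c = unname(f$coefficients[1])),
           fitted = unname(cbind(1, x, x^2) %*% f$coefficients)[, 1])
    },
    log = {
      if (any(x <= 0))
        stop_wiltflow("log family requires all x > 0", "wiltflow_fit_error")
      f <- stats::lm.fit(cbind(1, log(x)), y)
      list(params = list(a = unname(f$coefficients[2]),
                         b = unname(f$coefficients[1])),
           fitted = unname(cbind(1, log(x)) %*% f$coefficients)[, 1])
    },
    piecewise_linear = fit_piecewise(x, y),
    exponential = fit_exponential(x, y)
  )
  new_fit_result(family, res$params, res$fitted, y, n)
}

#' Select the best regression family by R-squared
#'
#' Fits every requested family (failures are tolerated and recorded) and
#' returns the successful fit with maximal raw R-squared; ties within 1e-9
#' are broken toward the family with fewer parameters.
#'
#' @param x,y predictor and response vectors.
#' @param families character vector of families to try.
#' @return the winning `fit_result`; attribute `all_fits` holds every
#'   successful fit, attribute `failures` the error messages.
#' @export
select_model <- function(x, y, families = c("linear", "quadratic",
                                            "piecewise_linear", "log",
                                            "exponential")) {
  fits <- list(); fails <- character()
  for (fam in families) {
    f <- tryCatch(fit_family(x, y, fam), error = function(e) e)
    if (inherits(f, "fit_result")) fits[[fam]] <- f
    else fails[fam] <- conditionMessage(f)
  }
  if (!length(fits))
    stop_wiltflow("every regression family failed", "wiltflow_fit_error")
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  k <- vapply(fits, function(f) f$k, integer(1))
  best_r2 <- max(r2)
  cand <- which(r2 >= best_r2 - 1e-9)
  winner <- cand[which.min(k[cand])]
  out <- fits[[winner]]
  attr(out, "all_fits") <- fits
  attr(out, "failures") <- fails
  out
}

#' Overall-F p-value for a fitted regression
#'
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))` with `k` the number of
#' predictor-side parameters (the breakpoint counts for the piecewise
#' family); the p-value comes from the F(k, n - k - 1) distribution. This is
#' a pragmatic overall-significance test for the selected model.
#'
#' @param fit a `fit_result`.
#' @return p-value in `(0, 1]`.
#' @export
regression_pvalue <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  n <- fit$n; k <- fit$k
  if (n <= k + 1)
    stop_wiltflow("not enough residual degrees of freedom",
                  "wiltflow_fit_error")
  r2 <- min(fit$r_squared, 1 - 1e-15)
  f <- (r2 / k) / ((1 - r2) / (n - k - 1))
  stats::pf(f, k, n - k - 1, lower.tail = FALSE)
}
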