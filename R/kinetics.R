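# Growth kinetics from single-particle events: moving-window OLS growth
# rates with 95% confidence intervals, bilinear change-point detection by
# SSE minimization, and linear-versus-exponential growth-law comparison.
# All regressions run on single-particle (time, volume) events inside the
# exclusion bounds, not on per-file summaries; windows and the breakpoint
# scan use prefix-sum normal equations (O(n + windows)) with globally
# centered coordinates for numerical stability.

# prefix sums of centered x, y and their products for fast interval OLS
prefix_moments <- function(x, y) {
  list(mx = mean(x), my = mean(y),
       sx = cumsum(x - mean(x)), sy = cumsum(y - mean(y)),
       sxx = cumsum((x - mean(x))^2), syy = cumsum((y - mean(y))^2),
       sxy = cumsum((x - mean(x)) * (y - mean(y))))
}

# OLS on events i0..i1 (1-based inclusive) from prefix moments:
# slope, sse, Sxx, n
interval_ols <- function(pm, i0, i1) {
  n <- i1 - i0 + 1L
  if (n < 2L) return(list(n = n, slope = NA_real_, sse = NA_real_,
                          Sxx = 0, intercept = NA_real_))
  at <- function(s, i) if (i >= 1L) s[i] else 0
  Sx <- at(pm$sx, i1) - at(pm$sx, i0 - 1L)
  Sy <- at(pm$sy, i1) - at(pm$sy, i0 - 1L)
  Sxx <- at(pm$sxx, i1) - at(pm$sxx, i0 - 1L) - Sx^2 / n
  Syy <- at(pm$syy, i1) - at(pm$syy, i0 - 1L) - Sy^2 / n
  Sxy <- at(pm$sxy, i1) - at(pm$sxy, i0 - 1L) - Sx * Sy / n
  if (Sxx <= 0) return(list(n = n, slope = NA_real_, sse = NA_real_,
                            Sxx = 0, intercept = NA_real_))
  slope <- Sxy / Sxx
  sse <- max(0, Syy - Sxy^2 / Sxx)
  list(n = n, slope = slope, sse = sse, Sxx = Sxx,
       intercept = (pm$my + Sy / n) - slope * (pm$mx + Sx / n))
}

#' Moving-window growth rates
#'
#' Ordinary least-squares slope of volume (um^3) on time (min) over all
#' included single-particle events in a sliding window (60 min shifted every
#' 3 min by default), with the 95% confidence half-width from the standard
#' slope-error formula and the t quantile. Windows with fewer than two
#' distinct event times yield `NA`.
#'
#' @param events A `pulse_events` data frame; only included (unflagged)
#'   events are used.
#' @param window_min Window length in minutes (default 60).
#' @param step_min Window shift in minutes (default 3).
#' @return A data frame of class `growth_rate_series` with columns
#'   `center_min`, `slope_um3_per_min`, `ci95_half`, `n`.
#' @export
windowed_growth_rate <- function(events, window_min = 60, step_min = 3) {
  ev <- included(events)
  if (!nrow(ev)) cond_error("no included events",
                            "coultertrace_empty_error")
  ord <- order(ev$time_s)
  t_min <- ev$time_s[ord] / 60
  v <- ev$volume_um3[ord]
  pm <- prefix_moments(t_min, v)
  t0 <- t_min[1L]; t1 <- t_min[length(t_min)]
  if (t1 - t0 < window_min)
    starts <- t0
  else
    starts <- seq(t0, t1 - window_min, by = step_min)
  res <- lapply(starts, function(s) {
    i0 <- findInterval(s, t_min, left.open = TRUE) + 1L
    i1 <- findInterval(s + window_min, t_min)
    o <- interval_ols(pm, i0, i1)
    ci <- if (o$n > 2 && o$Sxx > 0)
      stats::qt(0.975, o$n - 2) * sqrt(o$sse / (o$n - 2) / o$Sxx)
    else NA_real_
    c(center = s + window_min / 2, slope = o$slope, ci = ci, n = o$n)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("center_min", "slope_um3_per_min", "ci95_half", "n")
  structure(out, class = c("growth_rate_series", "data.frame"),
            window_min = window_min, step_min = step_min)
}

#' @export
print.growth_rate_series <- function(x, ...) {
  cat(sprintf(
    "<growth_rate_series> %d windows (%g min, step %g min); mean slope %.4g um^3/min\n",
    nrow(x), attr(x, "window_min"), attr(x, "step_min"),
    mean(x$slope_um3_per_min, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.growth_rate_series <- function(object, ...) {
  s <- object$slope_um3_per_min
  out <- c(windows = nrow(object), mean = mean(s, na.rm = TRUE),
           sd = stats::sd(s, na.rm = TRUE),
           min = min(s, na.rm = TRUE), max = max(s, na.rm = TRUE))
  class(out) <- "summary.growth_rate_series"
  out
}

#' @export
print.summary.growth_rate_series <- function(x, ...) {
  cat(sprintf(
    "growth rates over %d windows: mean %.4g, sd %.4g, range [%.4g, %.4g] um^3/min\n",
    x["windows"], x["mean"], x["sd"], x["min"], x["max"]))
  invisible(x)
}

#' @export
plot.growth_rate_series <- function(x, ...) {
  graphics::plot(x$center_min, x$slope_um3_per_min, type = "l",
                 xlab = "window center (min)",
                 ylab = expression(growth ~ rate ~ (mu * m^3 / min)), ...)
  graphics::arrows(x$center_min, x$slope_um3_per_min - x$ci95_half,
                   x$center_min, x$slope_um3_per_min + x$ci95_half,
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Bilinear change-point detection
#'
#' For each candidate split time the data are broken in two and a separate
#' linear regression is fitted to each part; the total sum of squared errors
#' (SSE) as a function of the split time is minimized, and the minimizer is
#' the detected rate-change point. Candidates leaving fewer than two
#' distinct event times on either side are skipped. The change is deemed
#' significant when the relative SSE reduction versus a single global line
#' exceeds `sig_threshold`.
#'
#' @param events A `pulse_events` data frame (included events used).
#' @param grid Candidate split times in seconds; default: every `grid_step_s`
#'   across the span, excluding `edge_exclude_min` minutes at each edge.
#' @param event_time_s Optional known perturbation time (seconds); when
#'   given, the result reports the lag `best_time - event_time`.
#' @param grid_step_s Default grid spacing (30 s).
#' @param edge_exclude_min Margin excluded at each end for the default grid
#'   (5 min; one-sided fits at the extreme edges are unstable).
#' @param sig_threshold Relative SSE reduction declaring significance
#'   (default 0.01).
#' @return An object of class `breakpoint_fit` with the SSE curve
#'   (`candidate_s`, `sse`), `best_time_s`, `sse_single`, `rel_reduction`,
#'   `significant`, per-side fits at the optimum, and `lag_min` when
#'   `event_time_s` was supplied.
#' @export
bilinear_breakpoint <- function(events, grid = NULL, event_time_s = NULL,
                                grid_step_s = 30, edge_exclude_min = 5,
                                sig_threshold = 0.01) {
  ev <- included(events)
  if (nrow(ev) < 4L) cond_error("too few included events",
                                "coultertrace_empty_error")
  ord <- order(ev$time_s)
  ts <- ev$time_s[ord]
  v <- ev$volume_um3[ord]
  if (is.null(grid)) {
    lo <- ts[1L] + edge_exclude_min * 60
    hi <- ts[length(ts)] - edge_exclude_min * 60
    if (lo >= hi) cond_error("data span too short for the default grid",
                             "coultertrace_config_error")
    grid <- seq(lo, hi, by = grid_step_s)
  }
  if (min(grid) < ts[1L] || max(grid) > ts[length(ts)])
    cond_error("candidate grid lies outside the data span",
               "coultertrace_config_error")
  pm <- prefix_moments(ts / 60, v)
  t_min <- ts / 60
  n <- length(ts)
  single <- interval_ols(pm, 1L, n)
  sse <- vapply(grid, function(g) {
    k <- findInterval(g / 60, t_min, left.open = TRUE)  # events before g
    left <- interval_ols(pm, 1L, k)
    right <- interval_ols(pm, k + 1L, n)
    if (left$Sxx <= 0 || right$Sxx <= 0) return(NA_real_)
    left$sse + right$sse
  }, numeric(1))
  if (all(is.na(sse)))
    cond_error("no candidate leaves two distinct times on each side",
               "coultertrace_config_error")
  best_i <- which.min(sse)  # earliest minimum on ties
  best <- grid[best_i]
  rel <- (single$sse - sse[best_i]) / single$sse
  k <- findInterval(best / 60, t_min, left.open = TRUE)
  fit <- list(left = interval_ols(pm, 1L, k),
              right = interval_ols(pm, k + 1L, n))
  out <- list(candidate_s = grid, sse = sse, best_time_s = best,
              sse_single = single$sse, rel_reduction = rel,
              significant = rel > sig_threshold,
              sig_threshold = sig_threshold,
              slope_before = fit$left$slope, slope_after = fit$right$slope,
              event_time_s = event_time_s,
              lag_min = if (!is.null(event_time_s))
                (best - event_time_s) / 60 else NA_real_)
  class(out) <- "breakpoint_fit"
  out
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> rate change at %.2f min (SSE reduction %.2f%%, %s)\n",
    x$best_time_s / 60, 100 * x$rel_reduction,
    if (x$significant) "significant" else "not significant"))
  cat(sprintf("  slope %.4g -> %.4g um^3/min\n",
              x$slope_before, x$slope_after))
  if (!is.null(x$event_time_s))
    cat(sprintf("  lag after event at %.1f min: %.2f min\n",
                x$event_time_s / 60, x$lag_min))
  invisible(x)
}

#' @export
coef.breakpoint_fit <- function(object, ...) {
  c(best_time_s = object$best_time_s, slope_before = object$slope_before,
    slope_after = object$slope_after)
}

#' @export
plot.breakpoint_fit <- function(x, ...) {
  graphics::plot(x$candidate_s / 60, x$sse, type = "l",
                 xlab = "candidate split (min)", ylab = "total SSE", ...)
  graphics::abline(v = x$best_time_s / 60, col = "red3", lty = 2)
  invisible(x)
}

#' Linear versus exponential growth-law fits
#'
#' Fits `y = a x + b` by OLS and `y = A exp(b x)` by Levenberg-Marquardt
#' nonlinear least squares (initialized from a log-linear OLS fit; if the
#' nonlinear fit fails to converge the log-linear parameters are reported
#' with a flag). R^2 for both models is computed on the original,
#' untransformed scale so the two are directly comparable.
#'
#' @param time Predictor (e.g. minutes).
#' @param value Response (e.g. a bound or mode volume trajectory); must be
#'   positive for the exponential model.
#' @param models Which models to fit.
#' @return An object of class `growth_model_fits`: per-model list with
#'   `params`, `r_squared`, `converged`, plus the data.
#' @export
fit_growth_models <- function(time, value,
                              models = c("linear", "exponential")) {
  if (length(time) < 3L)
    cond_error("need at least 3 points", "coultertrace_config_error")
  models <- match.arg(models, several.ok = TRUE)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- function(fitted) 1 - sum((value - fitted)^2) / ss_tot
  fits <- list()
  if ("linear" %in% models) {
    fl <- stats::lm(value ~ time)
    fits$linear <- list(
      params = c(a = unname(stats::coef(fl)[2L]),
                 b = unname(stats::coef(fl)[1L])),
      r_squared = r2(stats::fitted(fl)), converged = TRUE)
  }
  if ("exponential" %in% models) {
    if (any(value <= 0))
      cond_error("exponential model requires positive values",
                 "coultertrace_config_error")
    ll <- stats::lm(log(value) ~ time)
    start <- list(A = exp(unname(stats::coef(ll)[1L])),
                  b = unname(stats::coef(ll)[2L]))
    fe <- tryCatch(
      minpack.lm::nlsLM(value ~ A * exp(b * time), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fe)) {
      p <- stats::coef(fe)
      fits$exponential <- list(params = c(A = unname(p["A"]),
                                          b = unname(p["b"])),
                               r_squared = r2(stats::fitted(fe)),
                               converged = TRUE)
    } else {
      fits$exponential <- list(
        params = c(A = start$A, b = start$b),
        r_squared = r2(start$A * exp(start$b * time)),
        converged = FALSE)
    }
  }
  structure(list(fits = fits, time = time, value = value),
            class = "growth_model_fits")
}

#' @export
print.growth_model_fits <- function(x, ...) {
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("%-11s R^2 = %.4f  (%s)%s\n", nm, f$r_squared,
                paste(sprintf("%s = %.5g", names(f$params), f$params),
                      collapse = ", "),
                if (f$converged) "" else " [log-linear fallback]"))
  }
  invisible(x)
}

#' Model-comparison table for bound/mode trajectories
#'
#' Fits both growth laws to every `(level, side)` bound trajectory and the
#' mode trajectory of a [bound_series()] table, mirroring the layout of a
#' bounds-by-models R^2 comparison.
#'
#' @param bs A [bound_series()] data frame.
#' @param t_max_min Restrict to file times at or below this (minutes);
#'   default all.
#' @return Data frame with columns `series`, `r2_linear`, `r2_exponential`.
#' @export
growth_model_table <- function(bs, t_max_min = Inf) {
  bs <- bs[bs$time_s / 60 <= t_max_min, ]
  series <- list()
  for (lv in sort(unique(bs$level))) {
    sub <- bs[bs$level == lv, ]
    series[[sprintf("%g%% lower", lv)]] <- sub[c("time_s", "lower")]
    series[[sprintf("%g%% upper", lv)]] <- sub[c("time_s", "upper")]
  }
  md <- bs[bs$level == bs$level[1L], ]
  series[["mode"]] <- md[c("time_s", "mode_volume")]
  rows <- lapply(names(series), function(nm) {
    s <- series[[nm]]
    fit <- fit_growth_models(s[[1L]] / 60, s[[2L]])
    data.frame(series = nm, r2_linear = fit$fits$linear$r_squared,
               r2_exponential = fit$fits$exponential$r_squared)
  })
  do.call(rbind, rows)
}
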