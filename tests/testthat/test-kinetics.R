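# Moving-window growth rates, bilinear change points, growth-law fits.

test_that("windowed slopes reproduce exact lines and constants", {
  t <- seq(0, 120, by = 0.5)  # minutes
  ev <- make_events(t * 60, 30 + 0.5 * t)
  gr <- windowed_growth_rate(ev, 60, 3)
  expect_equal(gr$slope_um3_per_min, rep(0.5, nrow(gr)), tolerance = 1e-9)
  expect_true(all(gr$ci95_half < 1e-6))

  evc <- make_events(t * 60, rep(40, length(t)))
  grc <- windowed_growth_rate(evc, 60, 3)
  expect_equal(grc$slope_um3_per_min, rep(0, nrow(grc)), tolerance = 1e-12)
})

test_that("windowed OLS matches the lm() oracle per window", {
  set.seed(51)
  n <- 4000
  ts <- sort(stats::runif(n, 0, 7200))
  v <- 50 + 0.1 * ts / 60 + stats::rnorm(n, 0, 5)
  ev <- make_events(ts, v)
  gr <- windowed_growth_rate(ev, 60, 15)
  for (i in seq_len(nrow(gr))) {
    s <- (gr$center_min[i] - 30) * 60
    sel <- ts >= s & ts <= s + 3600
    fit <- stats::lm(v[sel] ~ I(ts[sel] / 60))
    expect_equal(gr$slope_um3_per_min[i], unname(stats::coef(fit)[2]),
                 tolerance = 1e-9)
    se <- summary(fit)$coefficients[2, 2]
    expect_equal(gr$ci95_half[i],
                 stats::qt(0.975, sum(sel) - 2) * se, tolerance = 1e-9)
  }
})

test_that("windows without two distinct times yield NA", {
  ev <- make_events(c(0, 0, 7200, 7205), c(10, 11, 12, 13))
  gr <- windowed_growth_rate(ev, 30, 30)
  expect_true(any(is.na(gr$slope_um3_per_min)))
})

test_that("slope variance shrinks as the window grows", {
  set.seed(52)
  ts <- sort(stats::runif(20000, 0, 3 * 3600))
  v <- 40 + 0.2 * ts / 60 + stats::rnorm(20000, 0, 6)
  ev <- make_events(ts, v)
  sds <- vapply(c(15, 30, 60, 120), function(w)
    stats::sd(windowed_growth_rate(ev, w, 3)$slope_um3_per_min,
              na.rm = TRUE), numeric(1))
  expect_true(all(diff(sds) < 0))
  # parameter recovery: mean slope near the true rate
  gr60 <- windowed_growth_rate(ev, 60, 3)
  expect_equal(mean(gr60$slope_um3_per_min), 0.2, tolerance = 0.05)
})

test_that("bilinear scan recovers a noise-free two-segment break", {
  t1 <- seq(0, 60, by = 0.25); t2 <- seq(60.25, 120, by = 0.25)  # minutes
  v <- c(rep(500, length(t1)), 500 - 0.6 * (t2 - 60))
  ev <- make_events(c(t1, t2) * 60, v)
  grid <- seq(10, 110, by = 0.5) * 60
  bp <- bilinear_breakpoint(ev, grid = grid)
  # both segments are exact lines when split at 60 min (ties -> earliest)
  expect_equal(bp$best_time_s, 3600)
  expect_lt(min(bp$sse, na.rm = TRUE), 1e-6)
  expect_true(bp$significant)
  expect_equal(bp$slope_before, 0, tolerance = 1e-6)
  expect_equal(bp$slope_after, -0.6, tolerance = 1e-3)

  # reversing the input order changes nothing
  bp_rev <- bilinear_breakpoint(ev[rev(seq_len(nrow(ev))), ], grid = grid)
  expect_equal(bp_rev$best_time_s, bp$best_time_s)
  expect_equal(bp_rev$sse, bp$sse)

  # lag bookkeeping
  bp_l <- bilinear_breakpoint(ev, grid = grid, event_time_s = 3600)
  expect_equal(bp_l$lag_min, (bp_l$best_time_s - 3600) / 60)
})

test_that("single-line noisy data shows no significant change point", {
  set.seed(53)
  ts <- sort(stats::runif(20000, 0, 7200))
  v <- 900 + stats::rnorm(20000, 0, 120)
  bp <- bilinear_breakpoint(make_events(ts, v))
  expect_false(bp$significant)
  expect_lt(bp$rel_reduction, 0.01)
})

test_that("breakpoint location is unbiased over stochastic replicates", {
  best <- vapply(1:11, function(s) {
    set.seed(100 + s)
    ts <- sort(stats::runif(40000, 0, 7200))
    tm <- ts / 60
    v <- ifelse(tm < 70, 600, 600 - 1.5 * (tm - 70)) +
      stats::rnorm(40000, 0, 10)
    bilinear_breakpoint(make_events(ts, v), grid_step_s = 30)$best_time_s
  }, numeric(1))
  expect_lte(abs(stats::median(best) - 70 * 60), 30)
})

test_that("growth-law fits are exact on their own models and comparable", {
  t <- seq(0, 100, by = 2)
  lin <- fit_growth_models(t, 3 + 0.7 * t)
  expect_equal(lin$fits$linear$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(lin$fits$linear$params["a"]), 0.7, tolerance = 1e-9)

  ex <- fit_growth_models(t, 5 * exp(0.02 * t))
  expect_equal(ex$fits$exponential$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(ex$fits$exponential$params["b"]), 0.02,
               tolerance = 1e-6)

  expect_error(fit_growth_models(t, 3 - 0.5 * t),
               class = "coultertrace_config_error")
  expect_error(fit_growth_models(1:2, c(1, 2)),
               class = "coultertrace_config_error")

  # exponential trajectory with multiplicative noise: R2_exp > R2_lin
  set.seed(54)
  y <- 20 * exp(0.006 * seq(0, 240, by = 3)) *
    exp(stats::rnorm(81, 0, 0.01))
  fits <- fit_growth_models(seq(0, 240, by = 3), y)
  expect_gt(fits$fits$exponential$r_squared, fits$fits$linear$r_squared)
})
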