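# Debris detection and interpolation.

test_that("debris flags follow the neighbor-ratio rule", {
  cfg <- debris_config()
  # middle ratios 1.0375 and 1.0323, both above 1.025 -> flagged
  f1 <- coultertrace:::debris_flags(c(40.0, 41.5, 40.2), cfg)
  expect_identical(f1$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(f1$ratio_prev[2], 41.5 / 40.0)
  expect_equal(f1$ratio_next[2], 41.5 / 40.2)
  # ratios 1.020 and 1.005 -> not flagged
  f2 <- coultertrace:::debris_flags(c(40.0, 40.8, 40.6), cfg)
  expect_false(any(f2$flagged))
  # constant bounds -> nothing flagged
  f3 <- coultertrace:::debris_flags(rep(40, 6), cfg)
  expect_false(any(f3$flagged))
  # "either" rule flags a file exceeding against only one neighbor
  cfg_e <- debris_config(neighbor_rule = "either")
  f4 <- coultertrace:::debris_flags(c(40.0, 41.5, 41.4), cfg_e)
  expect_identical(f4$flagged[2], TRUE)
  expect_false(coultertrace:::debris_flags(c(40.0, 41.5, 41.4),
                                           cfg)$flagged[2])
  # first and last files are never flagged
  f5 <- coultertrace:::debris_flags(c(80, 40, 40, 40, 80), cfg_e)
  expect_false(f5$flagged[1] || f5$flagged[5])
  expect_error(coultertrace:::debris_flags(c(1, 2), cfg),
               class = "coultertrace_config_error")
})

test_that("a simulated single-file inflation is detected end to end", {
  cfg <- small_sim(seed = 41, pulses = 20000, total_min = 30,
                   debris = data.frame(file_index = 4, inflation = 0.05))
  tc <- as_timecourse(generate_timecourse(cfg))
  rep <- detect_debris_files(tc)
  expect_identical(which(rep$flagged), 4L)
  # sub-threshold inflation is not flagged
  cfg2 <- small_sim(seed = 41, pulses = 20000, total_min = 30,
                    debris = data.frame(file_index = 4, inflation = 0.012))
  rep2 <- detect_debris_files(as_timecourse(generate_timecourse(cfg2)))
  expect_false(any(rep2$flagged))
})

test_that("interpolation mixes neighbor quantiles and counts", {
  sim <- generate_timecourse(small_sim(seed = 42, pulses = 1000,
                                       total_min = 15))
  f <- sim$files
  # identical neighbors reproduce the neighbor distribution
  interp <- interpolate_file(f[[1]], f[[1]], start_time_s = 200)
  ev_n <- pulse_events(load_timecourse(list(f[[1]])))
  ev_n <- filter_noise_floor(ev_n, 0.02)
  vn <- sort(ev_n$volume_um3[!ev_n$noise_excluded])
  vi <- sort(pulse_events(load_timecourse(list(interp)))$volume_um3)
  expect_equal(length(vi), length(vn))
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(stats::quantile(vi, qs), stats::quantile(vn, qs),
               tolerance = 0.002)

  # timestamps reconstruct to within one tick of the linear spacing
  ti <- sort(pulse_events(load_timecourse(list(interp)))$time_s)
  m <- length(ti)
  # (single-file timecourse: epoch is the file's own start)
  intended <- interp$header$duration_s * seq_len(m) / (m + 1)
  expect_lte(max(abs(ti - intended)), 0.2 + 1e-9)

  # neighbor counts 1000 and 2000 -> 1500 pulses
  ha <- instrument_header(start_time_s = 0)
  hb <- instrument_header(start_time_s = 400)
  mk_uniform <- function(hdr, n, lo, hi) {
    v <- seq(lo, hi, length.out = n)
    h <- pmax(0, round(coultertrace:::diameter_to_height(
      coultertrace:::volume_to_diameter(v), hdr)))
    measurement_file(hdr, cbind(h, 0, 0, 0, 0),
                     cbind(150000, n))
  }
  fa <- mk_uniform(ha, 1000, 10, 20)
  fb <- mk_uniform(hb, 2000, 14, 24)
  out <- interpolate_file(fa, fb, start_time_s = 200,
                          fcfg = filter_config(noise_floor_fraction = 0))
  expect_equal(nrow(out$pulses), 1500)
  # uniform [10,20] and [14,24] -> quantiles uniform on ~[12,22]
  vo <- pulse_events(load_timecourse(list(out)))$volume_um3
  expect_equal(min(vo), 12, tolerance = 0.02)
  expect_equal(max(vo), 22, tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(vo, "punif", 12, 22))
  expect_gt(ks$p.value, 0.01)

  expect_error(interpolate_file(out, fb), "raw",
               class = "coultertrace_qc_error")
})

test_that("clean_timecourse replaces flagged files and is idempotent", {
  cfg <- small_sim(seed = 43, pulses = 4000, total_min = 40,
                   debris = data.frame(file_index = 5, inflation = 0.06))
  tc <- as_timecourse(generate_timecourse(cfg))
  qc <- clean_timecourse(tc)
  expect_identical(which(qc$report$replaced), 5L)
  expect_identical(qc$timecourse$files[[5]]$provenance, "interpolated")
  # untouched files are the originals
  expect_identical(qc$timecourse$files[[1]], tc$files[[1]])
  # idempotent: cleaning again changes nothing
  qc2 <- clean_timecourse(qc$timecourse)
  expect_false(any(qc2$report$flagged))

  # no flags -> identity
  tc0 <- as_timecourse(generate_timecourse(small_sim(seed = 44,
                                                     pulses = 3000,
                                                     total_min = 25)))
  qc0 <- clean_timecourse(tc0)
  expect_false(any(qc0$report$flagged))
  expect_identical(qc0$timecourse$files, tc0$files)
})

test_that("consecutive flagged files interpolate with time weights", {
  cfg <- small_sim(seed = 45, pulses = 20000, total_min = 40,
                   debris = data.frame(file_index = c(5, 6),
                                       inflation = c(0.06, 0.06)))
  tc <- as_timecourse(generate_timecourse(cfg))
  # a run of equally inflated files only exceeds against its outer
  # neighbors, so detection of runs needs the "either" rule
  qc <- clean_timecourse(tc, debris_config(neighbor_rule = "either"))
  expect_identical(which(qc$report$replaced), c(5L, 6L))
  # replacement modes sit between the bracketing files' modes, ordered
  mode_of <- function(f) {
    ev <- pulse_events(load_timecourse(list(f)))
    build_histogram(filter_noise_floor(ev, 0.02))$mode_volume
  }
  m4 <- mode_of(tc$files[[4]]); m7 <- mode_of(tc$files[[7]])
  m5 <- mode_of(qc$timecourse$files[[5]])
  m6 <- mode_of(qc$timecourse$files[[6]])
  lo <- min(m4, m7) * 0.98; hi <- max(m4, m7) * 1.02
  expect_true(m5 > lo && m5 < hi && m6 > lo && m6 < hi)
})

test_that("a majority of flagged files aborts cleaning", {
  cfg <- small_sim(seed = 46, pulses = 2000, total_min = 17,
                   debris = data.frame(file_index = c(2, 3, 4),
                                       inflation = c(0.08, 0.16, 0.24)))
  tc <- as_timecourse(generate_timecourse(cfg))
  expect_error(clean_timecourse(tc, debris_config(neighbor_rule = "either")),
               "occlusion", class = "coultertrace_qc_error")
})
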