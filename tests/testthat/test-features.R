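# Histograms, bound pairs, subpopulation peaks/tracks, colormaps.

test_that("histogram mode handles single events, ties and known shapes", {
  h1 <- build_histogram(42, smooth_bw = 0)
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$mode_volume, h1$mids[which.max(h1$counts)])
  expect_true(abs(h1$mode_volume - 42) < diff(range(h1$edges)))

  # uniform counts: tie resolves to the lowest-volume bin midpoint
  hu <- build_histogram(seq(10.5, 29.5, by = 1), bins = 20,
                        range = c(10, 30), scale = "linear", smooth_bw = 0)
  expect_true(all(hu$counts == 1))
  expect_equal(hu$mode_volume, hu$mids[1])

  # log-normal sample, linear bins: mode near the analytic density mode
  set.seed(31)
  mu <- log(40); sg <- 0.2
  v <- stats::rlnorm(30000, mu, sg)
  hl <- build_histogram(v, bins = 128, scale = "linear")
  analytic <- exp(mu - sg^2)
  bwl <- diff(hl$edges)[findInterval(analytic, hl$edges)]
  expect_true(abs(hl$mode_volume - analytic) < 2 * bwl)
  # log bins estimate the log-volume density mode, exp(mu)
  hg <- build_histogram(v, bins = 128)
  bwg <- diff(log(hg$edges))[1]
  expect_true(abs(log(hg$mode_volume) - mu) < 2 * bwg)

  expect_error(build_histogram(numeric(0)),
               class = "coultertrace_empty_error")
})

test_that("bound pairs interpolate crossings nearest the mode", {
  h <- make_hist(seq(10, 70, by = 10), c(5, 25, 60, 100, 55, 30, 10))
  bp <- bound_pair(h, 25)
  expect_equal(bp$lower, 20)        # exact hit on the 25% target
  expect_equal(bp$upper, 62.5)      # interpolated between (60,30),(70,10)
  expect_equal(bp$mode_volume, 40)

  # level 100 collapses to the mode on both sides
  bp100 <- bound_pair(h, 100)
  expect_equal(bp100$lower, h$mode_volume)
  expect_equal(bp100$upper, h$mode_volume)

  # no crossing on a side -> clamped to the data extremum
  hmono <- make_hist(seq(10, 50, by = 10), c(80, 90, 100, 95, 85))
  bp80 <- bound_pair(hmono, 82)
  expect_true(bp80$upper_clamped)
  expect_equal(bp80$upper, 50)
})

test_that("bound pairs agree with a brute-force scan on random histograms", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    mids <- seq(10, by = 2, length.out = n)
    counts <- stats::rpois(n, lambda = sample(5:60, 1)) + 1
    h <- make_hist(mids, counts)
    level <- stats::runif(1, 5, 95)
    bp <- bound_pair(h, level)
    or <- bound_pair_oracle(mids, counts, level)
    expect_equal(bp$lower, unname(or["lower"]), tolerance = 1e-12)
    expect_equal(bp$upper, unname(or["upper"]), tolerance = 1e-12)
    expect_true(bp$lower <= h$mode_volume && h$mode_volume <= bp$upper)
  }
})

test_that("subpopulation peaks recover mixture components", {
  set.seed(33)
  h1 <- build_histogram(stats::rlnorm(20000, log(40), 0.15), bins = 128)
  pk <- find_subpopulation_modes(h1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$volume, h1$mode_volume)

  v <- c(stats::rlnorm(10000, log(30), 0.12),
         stats::rlnorm(10000, log(90), 0.12))
  h2 <- build_histogram(v, bins = 128)
  pk2 <- find_subpopulation_modes(h2)
  expect_equal(nrow(pk2), 2)
  # under log binning each component peaks at its geometric mean
  modes <- c(30, 90)
  bw <- diff(log(h2$edges))[1]
  expect_true(all(abs(log(pk2$volume) - log(modes)) < 3 * bw))

  # peaks closer than the separation threshold merge into one
  pk_wide <- find_subpopulation_modes(h2, min_separation = 128)
  expect_equal(nrow(pk_wide), 1)
})

test_that("subpopulation assignment splits an equal mixture ~50/50", {
  set.seed(34)
  v <- c(stats::rlnorm(5000, log(30), 0.1), stats::rlnorm(5000, log(90), 0.1))
  ev <- make_events(seq_along(v), v)
  h <- build_histogram(v, bins = 128)
  pk <- find_subpopulation_modes(h)
  asg <- assign_subpopulations(ev, pk, h)
  expect_equal(sum(asg$fractions), 1)
  expect_equal(unname(asg$fractions[1]), 0.5, tolerance = 0.03)

  # single peak: everything in one track
  ev1 <- make_events(1:5000, stats::rlnorm(5000, log(40), 0.1))
  h1 <- build_histogram(ev1$volume_um3, bins = 64)
  one <- assign_subpopulations(ev1, find_subpopulation_modes(h1), h1)
  expect_equal(unname(one$fractions), 1)

  # boundary tie goes to the lower-volume track
  evb <- make_events(1, 50)
  asgb <- assign_subpopulations(evb, pk, h)
  grp <- findInterval(50, asg$boundaries, left.open = TRUE) + 1L
  expect_identical(asgb$labels, paste0("P", grp))
  evx <- make_events(1, asg$boundaries[1])
  expect_identical(assign_subpopulations(evx, pk, h)$labels, "P1")
})

test_that("mode tracking follows, splits and starts tracks", {
  # stationary peak: one constant track
  tr <- track_modes(rep(list(40), 5))
  expect_equal(unique(tr$track), 1)
  expect_equal(tr$volume, rep(40, 5))

  # a peak that splits: original track follows the nearest branch,
  # a new track starts at the split
  pf <- list(c(40), c(41), c(42, 55), c(43, 60))
  tr2 <- track_modes(pf)
  expect_equal(sort(unique(tr2$track)), c(1, 2))
  expect_equal(tr2$volume[tr2$track == 1], c(40, 41, 42, 43))
  expect_equal(tr2$file_index[tr2$track == 2], c(3, 4))

  # single file: one track per peak, length 1
  tr3 <- track_modes(list(c(30, 70)))
  expect_equal(nrow(tr3), 2)
  expect_equal(sort(tr3$volume), c(30, 70))

  # a jump beyond the limit starts a new track instead of following
  tr4 <- track_modes(list(40, 80))
  expect_equal(length(unique(tr4$track)), 2)
})

test_that("colormap columns are normalized and match sliced histograms", {
  set.seed(35)
  ev <- make_events(stats::runif(5000, 0, 600),
                    stats::rlnorm(5000, log(40), 0.2))
  tedges <- seq(0, 600, by = 150)
  vedges <- exp(seq(log(10), log(160), length.out = 65))
  cm <- colormap_matrix(ev, tedges, vedges)
  cs <- colSums(cm$values)
  expect_equal(unname(cs), rep(1, 4), tolerance = 1e-12)

  # one event -> a single cell equal to 1
  cm1 <- colormap_matrix(make_events(10, 40), tedges, vedges)
  expect_equal(sum(cm1$values == 1), 1)
  expect_equal(sum(cm1$values), 1)

  # unnormalized column equals build_histogram on that time slice
  slice <- ev$volume_um3[ev$time_s >= 150 & ev$time_s < 300]
  h <- build_histogram(slice, edges = vedges, smooth_bw = 0)
  n2 <- sum(ev$time_s >= 150 & ev$time_s < 300 &
            ev$volume_um3 >= min(vedges) & ev$volume_um3 <= max(vedges))
  expect_equal(cm$values[, 2] * n2, as.numeric(h$counts))
})

test_that("bound-pair distance widens as the spread grows", {
  set.seed(36)
  widths <- vapply(c(0.08, 0.12, 0.16, 0.22), function(sg) {
    h <- build_histogram(stats::rlnorm(20000, log(50), sg), bins = 128)
    bp <- bound_pair(h, 25)
    bp$upper - bp$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
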