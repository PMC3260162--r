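# Shared fixtures: all synthetic inputs are built in code at test time.

# a small, fast simulation config (bead-like unless overridden)
small_sim <- function(seed = 1, pulses = 2000, total_min = 30, ...) {
  cfg <- preset("beads4um", seed = seed)
  cfg$pulses_per_file <- pulses
  cfg$total_min <- total_min
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}

# events table built directly from (time, volume) vectors
make_events <- function(time_s, volume_um3, file_index = 1L) {
  d <- (6 * volume_um3 / pi)^(1 / 3)
  ev <- data.frame(file_index = file_index, time_s = time_s,
                   height_counts = NA_real_, diameter_um = d,
                   volume_um3 = volume_um3,
                   noise_excluded = FALSE, bounds_excluded = FALSE)
  class(ev) <- c("pulse_events", "data.frame")
  ev
}

# histogram object built from explicit midpoints and counts (no smoothing),
# for exercising bound_pair against hand-computable shapes
make_hist <- function(mids, counts) {
  step <- diff(mids)[1]
  edges <- c(mids - step / 2, mids[length(mids)] + step / 2)
  mi <- which.max(counts)
  structure(list(edges = edges, mids = mids, counts = counts,
                 smoothed = as.numeric(counts), mode_volume = mids[mi],
                 mode_count = counts[mi], mode_bin = mi, n = sum(counts),
                 smooth_bw = 0), class = "volume_histogram")
}

# independent brute-force oracle for bound pairs: walk every adjacent
# midpoint pair outward from the mode and find the first crossing of the
# target level by linear interpolation
bound_pair_oracle <- function(mids, y, level) {
  mi <- which.max(y)
  target <- level / 100 * y[mi]
  lower <- mids[1]
  if (mi > 1) {
    for (j in seq(mi - 1, 1)) {
      if (y[j] <= target) {
        lower <- if (y[j + 1] == y[j]) mids[j] else
          mids[j] + (target - y[j]) / (y[j + 1] - y[j]) * (mids[j + 1] - mids[j])
        break
      }
    }
  }
  upper <- mids[length(mids)]
  if (mi < length(y)) {
    for (j in seq(mi + 1, length(y))) {
      if (y[j] <= target) {
        upper <- if (y[j - 1] == y[j]) mids[j] else
          mids[j] + (target - y[j]) / (y[j - 1] - y[j]) * (mids[j - 1] - mids[j])
        break
      }
    }
  }
  c(lower = lower, upper = upper)
}
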