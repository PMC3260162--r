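# Raw pulses -> timestamped single-particle volume events, plus the two
# event filters used before any rate analysis: the per-file noise floor
# (lowest 2% by volume) and the exclusion bound pair (typically 10% of the
# histogram mode). Filters flag events rather than delete them so colormaps
# can still show excluded data.

#' Assign per-pulse timestamps from a time section
#'
#' The instrument records elapsed time and cumulative pulse count at fixed
#' ticks (every 200 ms). The m pulses arriving within a tick interval
#' `(t[k-1], t[k]]` are linearly distributed across it at
#' `t[k-1] + j * (t[k] - t[k-1]) / m`, `j = 1..m`, so every assigned time is
#' within one tick width of the true arrival time.
#'
#' @param ticks Two-column matrix `(elapsed_ms, cumulative_count)`.
#' @param file_start_s Absolute start of the file in seconds; added to every
#'   timestamp.
#' @return Numeric vector of timestamps in seconds, one per pulse.
#' @export
assign_pulse_times <- function(ticks, file_start_s = 0) {
  ticks <- as.matrix(ticks)
  if (!nrow(ticks)) return(numeric(0))
  cum <- ticks[, 2L]
  if (any(diff(cum) < 0))
    cond_error("cumulative pulse counts decrease within the time section",
               "coultertrace_consistency_error")
  new <- diff(c(0, cum))
  t_prev <- c(0, ticks[-nrow(ticks), 1L])
  dt <- ticks[, 1L] - t_prev
  j <- sequence(new)
  ms <- rep.int(t_prev, new) + j * rep.int(dt / pmax(new, 1), new)
  file_start_s + ms / 1000
}

#' Convert pulse height to spherical-equivalent diameter
#'
#' The instrument's native size output is the Heywood (spherical-equivalent)
#' diameter computed from the peak height of each resistive pulse:
#' `d = Kd * (gain * height / (current * counts_per_volt))^(1/3)`,
#' with all constants taken from the file header. The conversion is strictly
#' increasing in height and maps zero height to zero diameter.
#'
#' @param height Pulse height(s) in counts, non-negative.
#' @param header An [instrument_header()].
#' @return Diameter(s) in micrometers.
#' @export
height_to_diameter <- function(height, header) {
  with(header, Kd * (gain * height / (current * counts_per_volt))^(1 / 3))
}

# Inverse of height_to_diameter; used by the simulator and the interpolator
# to encode volumes back into integer pulse records.
diameter_to_height <- function(diameter, header) {
  with(header, (diameter / Kd)^3 * current * counts_per_volt / gain)
}

#' Sphere volume from diameter
#'
#' @param d Diameter(s) in micrometers.
#' @return Volume(s) in cubic micrometers, `pi/6 * d^3`.
#' @export
diameter_to_volume <- function(d) pi / 6 * d^3

volume_to_diameter <- function(v) (6 * v / pi)^(1 / 3)

#' Decode a timecourse into single-particle volume events
#'
#' Runs height decoding, the diameter/volume conversion and per-pulse
#' timestamp assignment over every file of a timecourse, producing one tidy
#' event table. Files are processed one at a time so raw pulse tables can be
#' released as soon as they are decoded.
#'
#' @param tc A `coulter_timecourse` (or a single [measurement_file()]).
#' @return A data frame of class `pulse_events` with columns `file_index`,
#'   `time_s`, `height_counts`, `diameter_um`, `volume_um3`,
#'   `noise_excluded`, `bounds_excluded`.
#' @export
pulse_events <- function(tc) {
  if (inherits(tc, "measurement_file")) tc <- load_timecourse(list(tc))
  stopifnot(inherits(tc, "coulter_timecourse"))
  per_file <- lapply(seq_along(tc$files), function(i) {
    f <- tc$files[[i]]
    n <- n_pulses(f)
    if (!n) return(NULL)
    h <- decode_height(f$pulses, f$header)
    d <- height_to_diameter(h, f$header)
    data.frame(file_index = i,
               time_s = assign_pulse_times(f$ticks, tc$offsets_s[i]),
               height_counts = h,
               diameter_um = d,
               volume_um3 = diameter_to_volume(d),
               noise_excluded = FALSE,
               bounds_excluded = FALSE)
  })
  ev <- do.call(rbind, per_file)
  if (is.null(ev)) ev <- data.frame(
    file_index = integer(0), time_s = numeric(0), height_counts = numeric(0),
    diameter_um = numeric(0), volume_um3 = numeric(0),
    noise_excluded = logical(0), bounds_excluded = logical(0))
  class(ev) <- c("pulse_events", "data.frame")
  ev
}

#' Event filter configuration
#'
#' @param noise_floor_fraction Fraction of each file's events, smallest by
#'   volume, flagged as instrument noise (default 0.02, i.e. the lowest 2%).
#' @param exclusion_bound_level Bound-pair level (percent of the histogram
#'   mode) defining the exclusion bounds for rate analysis (default 10).
#' @param bins,smooth_bw Histogram binning and smoothing used when deriving
#'   the exclusion bounds; see [build_histogram()].
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(noise_floor_fraction = 0.02,
                          exclusion_bound_level = 10,
                          bins = 256, smooth_bw = 3) {
  if (noise_floor_fraction < 0 || noise_floor_fraction >= 1)
    cond_error("noise_floor_fraction must be in [0, 1)",
               "coultertrace_config_error")
  if (exclusion_bound_level <= 0 || exclusion_bound_level > 100)
    cond_error("exclusion_bound_level must be in (0, 100]",
               "coultertrace_config_error")
  structure(list(noise_floor_fraction = noise_floor_fraction,
                 exclusion_bound_level = exclusion_bound_level,
                 bins = bins, smooth_bw = smooth_bw),
            class = "filter_config")
}

#' Flag the per-file noise floor
#'
#' Within each file, exactly `floor(fraction * N)` events — those of smallest
#' volume — are flagged as instrument noise. Ties are broken by original
#' record order (stable), and event order is never changed.
#'
#' @param events A `pulse_events` data frame.
#' @param fraction Fraction to flag; default 0.02.
#' @return `events` with `noise_excluded` set.
#' @export
filter_noise_floor <- function(events, fraction = 0.02) {
  events$noise_excluded <- FALSE
  for (fi in unique(events$file_index)) {
    idx <- which(events$file_index == fi)
    k <- floor(fraction * length(idx))
    if (k > 0) {
      ord <- idx[order(events$volume_um3[idx], method = "radix")]
      events$noise_excluded[ord[seq_len(k)]] <- TRUE
    }
  }
  events
}

#' Flag events outside a bound pair
#'
#' Events with volume strictly below `bounds$lower` or strictly above
#' `bounds$upper` are flagged; events exactly on a bound are retained
#' (closed interval).
#'
#' @param events A `pulse_events` data frame.
#' @param bounds A [bound_pair()] result, or any list with `lower` and
#'   `upper` volumes.
#' @return `events` with `bounds_excluded` set.
#' @export
apply_exclusion_bounds <- function(events, bounds) {
  stopifnot(bounds$lower <= bounds$upper)
  events$bounds_excluded <- events$volume_um3 < bounds$lower |
    events$volume_um3 > bounds$upper
  events
}

#' Apply the standard per-file filters
#'
#' Flags the per-file noise floor, then derives each file's exclusion bound
#' pair (level `cfg$exclusion_bound_level`, default the 10% bound pair, from
#' a histogram of that file's noise-filtered events) and flags events
#' outside it. This is the standard preparation before growth-rate analysis.
#'
#' @param events A `pulse_events` data frame.
#' @param cfg A [filter_config()].
#' @return `events` with both flag columns set.
#' @export
apply_filters <- function(events, cfg = filter_config()) {
  events <- filter_noise_floor(events, cfg$noise_floor_fraction)
  events$bounds_excluded <- FALSE
  for (fi in unique(events$file_index)) {
    idx <- which(events$file_index == fi & !events$noise_excluded)
    if (length(idx) < 2L) next
    h <- build_histogram(events$volume_um3[idx], bins = cfg$bins,
                         smooth_bw = cfg$smooth_bw)
    bp <- bound_pair(h, cfg$exclusion_bound_level)
    out <- events$volume_um3[idx] < bp$lower | events$volume_um3[idx] > bp$upper
    events$bounds_excluded[idx[out]] <- TRUE
  }
  events
}

included <- function(events) {
  events[!events$noise_excluded & !events$bounds_excluded, , drop = FALSE]
}

#' Write an event table as CSV
#'
#' @param events A `pulse_events` data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read a plain `(time, volume)` event table
#'
#' Interoperability entry point: accepts a CSV with at least `time_s` and
#' `volume_um3` columns and returns a `pulse_events` data frame (heights and
#' diameters back-filled from volume where absent).
#'
#' @param path CSV path.
#' @return A `pulse_events` data frame.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "volume_um3") %in% names(df)))
    stop_format("event CSV needs 'time_s' and 'volume_um3' columns")
  if (is.null(df$file_index)) df$file_index <- 1L
  if (is.null(df$diameter_um)) df$diameter_um <- volume_to_diameter(df$volume_um3)
  if (is.null(df$height_counts)) df$height_counts <- NA_real_
  if (is.null(df$noise_excluded)) df$noise_excluded <- FALSE
  if (is.null(df$bounds_excluded)) df$bounds_excluded <- FALSE
  df <- df[c("file_index", "time_s", "height_counts", "diameter_um",
             "volume_um3", "noise_excluded", "bounds_excluded")]
  class(df) <- c("pulse_events", "data.frame")
  df
}
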