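# Per-file volume histograms and bound pairs. A bound pair at level X is the
# pair of volumes, one on each side of the histogram mode, at which the
# (smoothed) count crosses X% of the mode count; bound pairs track the small-
# and large-cell flanks of a distribution through a timecourse.

#' Build a volume histogram
#'
#' Bins event volumes (256 log-spaced bins over the data range by default;
#' log spacing suits the multiplicative spread of size distributions) and
#' smooths the counts with a Gaussian kernel of the given bandwidth in bins
#' (edge-renormalized; bandwidth 0 means no smoothing). The mode is the
#' midpoint of the bin maximizing the smoothed counts, ties resolved toward
#' the lowest volume.
#'
#' @param volumes Numeric vector of volumes (um^3), or a `pulse_events` data
#'   frame, in which case only included (unflagged) events are used.
#' @param bins Number of bins.
#' @param range Optional `c(lo, hi)` volume range; defaults to the data range.
#' @param scale `"log"` (default) or `"linear"` bin spacing.
#' @param edges Optional explicit bin edges, overriding `bins`/`range`/`scale`.
#' @param smooth_bw Gaussian kernel bandwidth in bins (default 3; 0 = raw).
#' @return An object of class `volume_histogram` with fields `edges`, `mids`,
#'   `counts`, `smoothed`, `mode_volume`, `mode_count`.
#' @export
build_histogram <- function(volumes, bins = 256, range = NULL,
                            scale = c("log", "linear"), edges = NULL,
                            smooth_bw = 3) {
  scale <- match.arg(scale)
  if (is.data.frame(volumes)) volumes <- included(volumes)$volume_um3
  volumes <- volumes[is.finite(volumes)]
  if (!length(volumes))
    cond_error("cannot build a histogram from zero included events",
               "coultertrace_empty_error")
  if (is.null(edges)) {
    if (is.null(range)) range <- base::range(volumes)
    if (range[1L] >= range[2L]) {  # degenerate (single value) data
      range <- range[1L] * c(0.995, 1.005)
      if (range[2L] <= range[1L]) range <- c(-0.5, 0.5) + range[1L]
    }
    edges <- if (scale == "log" && range[1L] > 0)
      exp(seq(log(range[1L]), log(range[2L]), length.out = bins + 1L))
    else seq(range[1L], range[2L], length.out = bins + 1L)
  }
  edges <- sort(edges)
  nb <- length(edges) - 1L
  # bin j covers [edges[j], edges[j+1]); last bin closed above
  bin <- findInterval(volumes, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  counts <- tabulate(bin[keep], nbins = nb)
  smoothed <- smooth_counts(counts, smooth_bw)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  mi <- which.max(smoothed)  # first max = lowest-volume tie winner
  structure(list(edges = edges, mids = mids, counts = counts,
                 smoothed = smoothed, mode_volume = mids[mi],
                 mode_count = smoothed[mi], mode_bin = mi,
                 n = sum(counts), smooth_bw = smooth_bw),
            class = "volume_histogram")
}

# Gaussian smoothing over bin index with edge renormalization so mass near
# the boundaries is not deflated.
smooth_counts <- function(counts, bw) {
  if (bw <= 0 || length(counts) < 2L) return(as.numeric(counts))
  half <- ceiling(4 * bw)
  k <- stats::dnorm(-half:half, sd = bw)
  n <- length(counts)
  num <- stats::convolve(c(numeric(half), counts, numeric(half)),
                         rev(k), type = "filter")
  den <- stats::convolve(c(numeric(half), rep(1, n), numeric(half)),
                         rev(k), type = "filter")
  num / den
}

#' @export
print.volume_histogram <- function(x, ...) {
  cat(sprintf(
    "<volume_histogram> %d events in %d bins [%.3g, %.3g] um^3; mode %.4g um^3\n",
    x$n, length(x$counts), x$edges[1L], x$edges[length(x$edges)],
    x$mode_volume))
  invisible(x)
}

#' @export
plot.volume_histogram <- function(x, log = "x", ...) {
  graphics::plot(x$mids, x$counts, type = "h", log = log,
                 xlab = expression(volume ~ (mu * m^3)), ylab = "count", ...)
  graphics::lines(x$mids, x$smoothed, col = "red3", lwd = 2)
  graphics::abline(v = x$mode_volume, lty = 2)
  invisible(x)
}

#' Bound pair at a level
#'
#' Finds the two volumes, one on each side of the mode, at which the
#' (smoothed) counts cross `level`% of the mode count. Crossings are the
#' ones nearest the mode, located by linear interpolation between bin
#' midpoints. If a side never falls below the target, that side is clamped
#' to the data extremum and flagged.
#'
#' @param hist A [build_histogram()] result.
#' @param level Percent of the mode count, in `(0, 100]`. Level 100 returns
#'   the mode itself on both sides.
#' @param smoothed Use smoothed counts (default) or raw counts.
#' @return An object of class `bound_pair` with fields `level`, `lower`,
#'   `upper`, `mode_volume`, `mode_count`, `lower_clamped`, `upper_clamped`.
#' @export
bound_pair <- function(hist, level, smoothed = TRUE) {
  stopifnot(inherits(hist, "volume_histogram"))
  if (level <= 0 || level > 100)
    cond_error("level must be in (0, 100]", "coultertrace_config_error")
  y <- if (smoothed) hist$smoothed else as.numeric(hist$counts)
  mids <- hist$mids
  mi <- which.max(y)
  target <- level / 100 * y[mi]
  cross <- function(side) {
    js <- if (side < 0) rev(seq_len(mi - 1L)) else
      seq(mi + 1L, length.out = max(0L, length(y) - mi))
    for (j in js) {
      if (y[j] <= target) {
        jn <- j - side  # neighbor toward the mode, with y >= target
        if (y[jn] == y[j]) return(list(v = mids[j], clamped = FALSE))
        v <- mids[j] + (target - y[j]) / (y[jn] - y[j]) * (mids[jn] - mids[j])
        return(list(v = v, clamped = FALSE))
      }
    }
    list(v = if (side < 0) mids[1L] else mids[length(mids)], clamped = TRUE)
  }
  if (level == 100) {
    lo <- hi <- list(v = mids[mi], clamped = FALSE)
  } else {
    lo <- cross(-1L)
    hi <- cross(+1L)
  }
  structure(list(level = level, lower = lo$v, upper = hi$v,
                 mode_volume = mids[mi], mode_count = y[mi],
                 lower_clamped = lo$clamped, upper_clamped = hi$clamped),
            class = "bound_pair")
}

#' @export
print.bound_pair <- function(x, ...) {
  cat(sprintf("<bound_pair> %g%%: [%.4g, %.4g] um^3 (mode %.4g)%s\n",
              x$level, x$lower, x$upper, x$mode_volume,
              if (x$lower_clamped || x$upper_clamped) " [clamped]" else ""))
  invisible(x)
}

#' Per-file bound-pair series
#'
#' Computes a bound pair at one or more levels for every file of a
#' timecourse (after the per-file noise-floor filter), the per-file feature
#' series used for subpopulation tracking and growth-law fitting.
#'
#' @param events A `pulse_events` data frame (noise filter applied if not
#'   already).
#' @param levels Bound-pair levels in percent.
#' @param cfg A [filter_config()] controlling binning/smoothing.
#' @return Data frame with columns `file_index`, `level`, `lower`, `upper`,
#'   `mode_volume`, `time_s` (file midpoint time).
#' @export
bound_series <- function(events, levels = c(10, 25, 33),
                         cfg = filter_config()) {
  if (!any(events$noise_excluded))
    events <- filter_noise_floor(events, cfg$noise_floor_fraction)
  out <- list()
  for (fi in sort(unique(events$file_index))) {
    sel <- events$file_index == fi & !events$noise_excluded
    v <- events$volume_um3[sel]
    if (length(v) < 2L) next
    h <- build_histogram(v, bins = cfg$bins, smooth_bw = cfg$smooth_bw)
    tmid <- mean(range(events$time_s[sel]))
    for (lv in levels) {
      bp <- bound_pair(h, lv)
      out[[length(out) + 1L]] <- data.frame(
        file_index = fi, level = lv, lower = bp$lower, upper = bp$upper,
        mode_volume = bp$mode_volume, time_s = tmid)
    }
  }
  do.call(rbind, out)
}
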