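# Debris-file detection and replacement. Partial aperture occlusions show up
# as an abrupt inflation of a file's size distribution relative to its
# neighbors; such files are detected by comparing the 25% bound pair against
# both neighbors and replaced by data interpolated between the neighboring
# files' empirical volume distributions, written as new files flagged
# "interpolated".

#' Debris-detection configuration
#'
#' @param bound_level Bound-pair level compared between neighbors (percent
#'   of mode; default 25).
#' @param ratio_threshold A file is debris when its bound exceeds this
#'   multiple of the neighbors' (default 1.025). Ratios equal to the
#'   threshold (within a 1e-6 numerical tolerance) count as exceeding.
#' @param neighbor_rule `"both"` (default): the bound must exceed the
#'   threshold against both neighbors, which targets transient single-file
#'   spikes and does not false-flag steady growth of a few percent per file;
#'   `"either"`: exceeding against at least one neighbor suffices.
#' @param compare_side Which member of the bound pair is compared: `"upper"`
#'   (default; occlusions inflate the large-volume tail), `"lower"`, or
#'   `"either"` (flag if either side triggers).
#' @return A list of class `debris_config`.
#' @export
debris_config <- function(bound_level = 25, ratio_threshold = 1.025,
                          neighbor_rule = c("both", "either"),
                          compare_side = c("upper", "lower", "either")) {
  if (ratio_threshold <= 1)
    cond_error("ratio_threshold must be > 1", "coultertrace_config_error")
  structure(list(bound_level = bound_level,
                 ratio_threshold = ratio_threshold,
                 neighbor_rule = match.arg(neighbor_rule),
                 compare_side = match.arg(compare_side)),
            class = "debris_config")
}

# Flag a per-file bound-value series. First and last files have only one
# neighbor and are never flagged. Boundary-inclusive comparison (>= within
# 1e-6) so a bound exactly at threshold-times-neighbor counts as exceeding.
debris_flags <- function(bounds, cfg = debris_config()) {
  n <- length(bounds)
  if (n < 3L)
    cond_error("debris detection needs at least 3 files",
               "coultertrace_config_error")
  rp <- c(NA, bounds[-1L] / bounds[-n])          # vs previous
  rn <- c(bounds[-n] / bounds[-1L], NA)          # vs next
  ex_p <- rp > cfg$ratio_threshold - 1e-6
  ex_n <- rn > cfg$ratio_threshold - 1e-6
  fl <- if (cfg$neighbor_rule == "both") ex_p & ex_n else ex_p | ex_n
  fl[c(1L, n)] <- FALSE
  fl[is.na(fl)] <- FALSE
  list(flagged = fl, ratio_prev = rp, ratio_next = rn)
}

file_bound_values <- function(tc, cfg, fcfg = filter_config()) {
  vapply(tc$files, function(f) {
    ev <- pulse_events(load_timecourse(list(f)))
    ev <- filter_noise_floor(ev, fcfg$noise_floor_fraction)
    v <- ev$volume_um3[!ev$noise_excluded]
    if (length(v) < 2L) return(c(NA_real_, NA_real_))
    h <- build_histogram(v, bins = fcfg$bins, smooth_bw = fcfg$smooth_bw)
    bp <- bound_pair(h, cfg$bound_level)
    c(lower = bp$lower, upper = bp$upper)
  }, numeric(2))
}

#' Detect debris-corrupted files
#'
#' Computes each file's bound pair at `cfg$bound_level` (after the per-file
#' noise-floor filter) and flags file i when its compared bound exceeds
#' `cfg$ratio_threshold` times the corresponding bound of its neighbors,
#' according to `cfg$neighbor_rule`. The first and last files, having only
#' one neighbor, are never flagged.
#'
#' @param tc A `coulter_timecourse` with at least 3 files.
#' @param cfg A [debris_config()].
#' @param fcfg A [filter_config()] for the noise floor and binning.
#' @return Data frame with columns `file_index`, `bound_value`,
#'   `ratio_prev`, `ratio_next`, `flagged`.
#' @export
detect_debris_files <- function(tc, cfg = debris_config(),
                                fcfg = filter_config()) {
  if (length(tc$files) < 3L)
    cond_error("debris detection needs at least 3 files",
               "coultertrace_config_error")
  bv <- file_bound_values(tc, cfg, fcfg)
  sides <- switch(cfg$compare_side, upper = 2L, lower = 1L, either = 1:2)
  res <- lapply(sides, function(s) debris_flags(bv[s, ], cfg))
  fl <- Reduce(`|`, lapply(res, `[[`, "flagged"))
  main <- if (cfg$compare_side == "lower") res[[1L]] else
    res[[length(res)]]  # report the upper side's ratios unless lower-only
  bval <- if (cfg$compare_side == "lower") bv[1L, ] else bv[2L, ]
  data.frame(file_index = seq_along(tc$files), bound_value = bval,
             ratio_prev = main$ratio_prev, ratio_next = main$ratio_next,
             flagged = fl)
}

#' Interpolate a replacement file from two neighbors
#'
#' Builds a synthetic recording standing in for a debris-corrupted file. The
#' pulse count is the (weighted) mean of the neighbors' noise-filtered
#' counts; volumes are midpoint-quantile interpolations between the
#' neighbors' empirical volume distributions (`v_j` mixes the two neighbors'
#' `j/(m+1)` quantiles); timestamps are linearly spaced across the replaced
#' file's full duration. The result carries provenance `"interpolated"`.
#'
#' @param prev,nxt Unflagged raw [measurement_file()] neighbors.
#' @param start_time_s,duration_s Recording interval of the replaced file;
#'   default: midway between the neighbors with `prev`'s duration.
#' @param weight Weight on `prev`'s quantiles (default 0.5; runs of flagged
#'   files use time-proportional weights).
#' @param fcfg A [filter_config()] for the noise-floor fraction.
#' @return A [measurement_file()] with provenance `"interpolated"`.
#' @export
interpolate_file <- function(prev, nxt, start_time_s = NULL,
                             duration_s = NULL, weight = 0.5,
                             fcfg = filter_config()) {
  for (f in list(prev, nxt))
    if (f$provenance != "raw")
      cond_error("interpolation neighbors must be raw files",
                 "coultertrace_qc_error")
  if (is.null(duration_s)) duration_s <- prev$header$duration_s
  if (is.null(start_time_s))
    start_time_s <- (prev$header$start_time_s + prev$header$duration_s +
                       nxt$header$start_time_s - duration_s) / 2
  vols <- lapply(list(prev, nxt), function(f) {
    ev <- pulse_events(load_timecourse(list(f)))
    ev <- filter_noise_floor(ev, fcfg$noise_floor_fraction)
    sort(ev$volume_um3[!ev$noise_excluded])
  })
  m <- round(weight * length(vols[[1L]]) + (1 - weight) * length(vols[[2L]]))
  if (m < 1L) cond_error("neighbors have no included events",
                         "coultertrace_qc_error")
  p <- seq_len(m) / (m + 1)
  v <- weight * stats::quantile(vols[[1L]], p, names = FALSE, type = 7) +
    (1 - weight) * stats::quantile(vols[[2L]], p, names = FALSE, type = 7)
  header <- prev$header
  header$start_time_s <- start_time_s
  header$duration_s <- duration_s
  # encode volumes back to integer pulse records (only the height field is
  # meaningful; the other four values are zero)
  h <- diameter_to_height(volume_to_diameter(v), header)
  raw1 <- pmax(0, round(h) - header$correction_factor)
  times_s <- duration_s * seq_len(m) / (m + 1)
  # spread quantiles across the file so the time-marginal is flat: shuffle
  # deterministically by stride so neighboring times span the distribution
  stride <- max(1L, floor(sqrt(m)))
  perm <- order((seq_len(m) - 1L) %% stride, (seq_len(m) - 1L) %/% stride)
  pulses <- cbind(raw1[perm], 0, 0, 0, 0)
  tick <- prev$tick_width_ms
  elapsed <- seq(tick, duration_s * 1000, by = tick)
  cum <- findInterval(elapsed, times_s * 1000)
  cum[length(cum)] <- m
  measurement_file(header, pulses, cbind(elapsed, cum), tick,
                   provenance = "interpolated")
}

#' Detect and replace debris files in a timecourse
#'
#' Single pass: detect debris files, then replace each run of flagged files
#' from the nearest unflagged bracketing neighbors (time-proportional
#' quantile weights within a run). Input files are not modified; the
#' returned timecourse contains interpolated replacements.
#'
#' @param tc A `coulter_timecourse`.
#' @param cfg A [debris_config()].
#' @param fcfg A [filter_config()].
#' @return List of class `qc_clean` with `timecourse` (cleaned) and `report`
#'   (the detection table plus a `replaced` column).
#' @export
clean_timecourse <- function(tc, cfg = debris_config(),
                             fcfg = filter_config()) {
  report <- detect_debris_files(tc, cfg, fcfg)
  fl <- report$flagged
  if (mean(fl) > 0.5)
    stop_qc(sprintf(
      "%d of %d files flagged as debris (>50%%): likely persistent occlusion",
      sum(fl), length(fl)))
  files <- tc$files
  report$replaced <- FALSE
  if (any(fl)) {
    runs <- rle(fl)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]
      left <- files[[i0 - 1L]]; right <- files[[i1 + 1L]]
      tl <- left$header$start_time_s; tr <- right$header$start_time_s
      for (i in seq(i0, i1)) {
        ti <- files[[i]]$header$start_time_s
        w <- (tr - ti) / (tr - tl)
        files[[i]] <- interpolate_file(
          left, right, start_time_s = ti,
          duration_s = files[[i]]$header$duration_s, weight = w, fcfg = fcfg)
        report$replaced[i] <- TRUE
      }
    }
  }
  out <- tc
  out$files <- files
  structure(list(timecourse = out, report = report), class = "qc_clean")
}

#' @export
print.qc_clean <- function(x, ...) {
  cat(sprintf("<qc_clean> %d of %d files replaced by interpolation\n",
              sum(x$report$replaced), nrow(x$report)))
  if (any(x$report$flagged))
    print(x$report[x$report$flagged, ])
  invisible(x)
}

#' Write a QC report as CSV
#'
#' @param qc A [clean_timecourse()] result.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_qc_csv <- function(qc, path) {
  utils::write.csv(qc$report, path, row.names = FALSE)
  invisible(path)
}
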