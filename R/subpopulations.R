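# Multi-peaked distributions: local-peak detection on smoothed histograms,
# per-event subpopulation assignment, nearest-neighbor mode tracking across
# files, and the colormap matrix (per-file relative volume distribution)
# used to draw full timecourses.

#' Find subpopulation modes as local histogram peaks
#'
#' Local maxima of the smoothed counts whose topographic prominence exceeds
#' `min_prominence` times the global mode count; peaks closer than
#' `min_separation` bins to a taller retained peak are merged into it.
#'
#' @param hist A [build_histogram()] result.
#' @param min_prominence Minimum prominence as a fraction of the global mode
#'   count (default 0.05).
#' @param min_separation Minimum spacing between retained peaks, in bins
#'   (default 8).
#' @return Data frame with columns `volume`, `count`, `bin`, sorted by
#'   volume; at least one row (the global mode).
#' @export
find_subpopulation_modes <- function(hist, min_prominence = 0.05,
                                     min_separation = 8) {
  y <- hist$smoothed
  n <- length(y)
  if (n < 3L)
    return(data.frame(volume = hist$mode_volume, count = hist$mode_count,
                      bin = hist$mode_bin))
  # local maxima: strictly above the previous bin, at least the next
  cand <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] &
                y[-c(1L, n)] >= y[-c(1L, 2L)]) + 1L
  if (y[1L] > y[2L]) cand <- c(1L, cand)
  if (y[n] > y[n - 1L]) cand <- c(cand, n)
  if (!length(cand)) cand <- which.max(y)
  prom <- vapply(cand, function(p) peak_prominence(y, p), numeric(1))
  keep <- cand[prom >= min_prominence * max(y)]
  if (!length(keep)) keep <- cand[which.max(prom)]
  # enforce separation: keep taller peaks first
  keep <- keep[order(-y[keep])]
  sel <- integer(0)
  for (p in keep)
    if (!length(sel) || all(abs(sel - p) >= min_separation))
      sel <- c(sel, p)
  sel <- sort(sel)
  data.frame(volume = hist$mids[sel], count = y[sel], bin = sel)
}

# Topographic prominence: height above the higher of the two lowest saddles
# on the way to higher terrain (or the series edge).
peak_prominence <- function(y, p) {
  h <- y[p]
  left <- if (p > 1L) {
    seg <- y[seq_len(p - 1L)]
    higher <- which(seg > h)
    min(seg[seq(from = if (length(higher)) max(higher) else 1L,
                to = p - 1L)])
  } else h
  right <- if (p < length(y)) {
    seg <- y[seq(p + 1L, length(y))]
    higher <- which(seg > h)
    min(seg[seq_len(if (length(higher)) min(higher) else length(seg))])
  } else h
  h - max(left, right)
}

#' Assign events to subpopulations
#'
#' Region boundaries are placed at the minima of the smoothed counts between
#' adjacent peaks; each included event is assigned to the enclosing region.
#' An event exactly on a boundary joins the lower-volume track.
#'
#' @param events A `pulse_events` data frame (one file's worth).
#' @param peaks Result of [find_subpopulation_modes()].
#' @param hist The histogram the peaks came from.
#' @param labels Optional track labels (default `"P1"`, `"P2"`, ...).
#' @return List with `labels` (per included event), `boundaries` (volumes),
#'   and `fractions` (per track, summing to 1).
#' @export
assign_subpopulations <- function(events, peaks, hist, labels = NULL) {
  stopifnot(nrow(peaks) >= 1L)
  k <- nrow(peaks)
  if (is.null(labels)) labels <- paste0("P", seq_len(k))
  bnd <- numeric(0)
  if (k > 1L) {
    bnd <- vapply(seq_len(k - 1L), function(i) {
      lo <- peaks$bin[i]; hi <- peaks$bin[i + 1L]
      seg <- seq(lo, hi)
      hist$mids[seg[which.min(hist$smoothed[seg])]]
    }, numeric(1))
  }
  v <- included(events)$volume_um3
  grp <- findInterval(v, bnd, left.open = TRUE) + 1L
  fr <- tabulate(grp, nbins = k) / max(length(v), 1L)
  list(labels = labels[grp], boundaries = bnd,
       fractions = stats::setNames(fr, labels))
}

#' Track subpopulation modes across files
#'
#' Associates peaks between consecutive files by nearest neighbor, subject
#' to a maximum relative volume jump per file. Peaks with no association
#' start new tracks; a track missing a match in a file records a gap and
#' stays eligible for matching in later files.
#'
#' @param per_file_peaks List (one element per file, in time order) of
#'   numeric vectors of peak volumes, or of [find_subpopulation_modes()]
#'   data frames.
#' @param max_jump Maximum relative change in mode volume between matched
#'   peaks in consecutive observations (default 0.15).
#' @return A data frame of class `subpop_tracks` with columns `track`,
#'   `file_index`, `volume`.
#' @export
track_modes <- function(per_file_peaks, max_jump = 0.15) {
  vols <- lapply(per_file_peaks, function(p)
    if (is.data.frame(p)) p$volume else as.numeric(p))
  last <- numeric(0)   # last matched volume per track
  rows <- list()
  for (fi in seq_along(vols)) {
    pv <- vols[[fi]]
    if (!length(pv)) next
    assigned_track <- rep(NA_integer_, length(pv))
    if (length(last)) {
      cand <- expand.grid(track = seq_along(last), peak = seq_along(pv))
      cand$rel <- abs(pv[cand$peak] - last[cand$track]) / last[cand$track]
      cand <- cand[cand$rel <= max_jump, , drop = FALSE]
      cand <- cand[order(cand$rel), , drop = FALSE]
      used_t <- logical(length(last)); used_p <- logical(length(pv))
      for (r in seq_len(nrow(cand))) {
        tr <- cand$track[r]; pk <- cand$peak[r]
        if (!used_t[tr] && !used_p[pk]) {
          assigned_track[pk] <- tr
          used_t[tr] <- TRUE; used_p[pk] <- TRUE
        }
      }
    }
    for (pk in seq_along(pv)) {
      tr <- assigned_track[pk]
      if (is.na(tr)) {            # new track
        last <- c(last, pv[pk])
        tr <- length(last)
      } else last[tr] <- pv[pk]
      rows[[length(rows) + 1L]] <- data.frame(track = tr, file_index = fi,
                                              volume = pv[pk])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track, out$file_index), ]
  rownames(out) <- NULL
  class(out) <- c("subpop_tracks", "data.frame")
  out
}

#' Colormap matrix of a volume timecourse
#'
#' Bins events in time and volume and normalizes each time column to sum to
#' one, giving the relative fraction of particles at each volume within each
#' measurement interval — the quantity a timecourse colormap displays.
#' Empty time columns are all zero.
#'
#' @param events A `pulse_events` data frame.
#' @param time_edges Time bin edges in seconds (e.g. one bin per 150 s file).
#' @param volume_edges Volume bin edges in um^3.
#' @param include_excluded Include flagged events (default FALSE).
#' @return An object of class `colormap_matrix`: list with `time_edges`,
#'   `volume_edges` and `values` (volume bins x time bins).
#' @export
colormap_matrix <- function(events, time_edges, volume_edges,
                            include_excluded = FALSE) {
  stopifnot(!is.unsorted(time_edges, strictly = TRUE),
            !is.unsorted(volume_edges, strictly = TRUE))
  ev <- if (include_excluded) events else included(events)
  ti <- findInterval(ev$time_s, time_edges, rightmost.closed = TRUE)
  vi <- findInterval(ev$volume_um3, volume_edges, rightmost.closed = TRUE)
  nt <- length(time_edges) - 1L
  nv <- length(volume_edges) - 1L
  ok <- ti >= 1L & ti <= nt & vi >= 1L & vi <= nv
  m <- matrix(0, nrow = nv, ncol = nt)
  if (any(ok)) {
    tab <- table(factor(vi[ok], levels = seq_len(nv)),
                 factor(ti[ok], levels = seq_len(nt)))
    m <- matrix(as.numeric(tab), nrow = nv)
    cs <- colSums(m)
    nz <- cs > 0
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, cs[nz], "/")
  }
  structure(list(time_edges = time_edges, volume_edges = volume_edges,
                 values = m), class = "colormap_matrix")
}

#' @export
plot.colormap_matrix <- function(x, log = "", ...) {
  tmid <- (x$time_edges[-1L] + x$time_edges[-length(x$time_edges)]) / 2
  vmid <- (x$volume_edges[-1L] + x$volume_edges[-length(x$volume_edges)]) / 2
  graphics::image(tmid / 60, vmid, t(x$values), log = log,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (min)",
                  ylab = expression(volume ~ (mu * m^3)), ...)
  invisible(x)
}
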