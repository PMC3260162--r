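# Reading, writing and stitching instrument-style pulse files.
#
# The canonical on-disk format is a plain-text "fixture dialect" that carries
# every field the analysis needs from a Multisizer-style recording: a header
# of calibration constants, a pulse table of five integer values per particle
# (the first is the pulse-height component), and a time section recording
# elapsed milliseconds and cumulative pulse counts at fixed ticks. The vendor
# binary layout can be slotted in later behind `dialect = "native-adapter"`
# without touching any analysis code.

FILE_MAGIC <- "coultertrace-pulse-file 1"
PULSE_CAP <- 525000L
COUNTS_PER_VOLT <- 838870

cond_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coultertrace_error")))
}
stop_format <- function(msg) cond_error(msg, "coultertrace_format_error")
stop_qc <- function(msg) cond_error(msg, "coultertrace_qc_error")

#' Instrument header constants
#'
#' Calibration and acquisition constants carried in the header of every
#' recording. `Kd`, `gain` and `current` enter the pulse-height to diameter
#' conversion; `counts_per_volt` is the instrument's fixed digitizer constant
#' (838 870 counts per volt); `correction_factor` is added to the first
#' encoded pulse value when decoding heights.
#'
#' @param Kd Calibration constant (um * V^(-1/3) scale), positive.
#' @param gain Dimensionless amplifier gain, positive.
#' @param current Aperture current in instrument units, positive.
#' @param counts_per_volt Digitizer counts per volt; defaults to 838 870.
#' @param aperture_diameter_um Aperture diameter in micrometers.
#' @param start_time_s Recording start, seconds since the timecourse epoch.
#' @param duration_s Recording length in seconds (typically 150).
#' @param correction_factor Integer counts added to the first pulse value.
#' @return An object of class `instrument_header`.
#' @export
instrument_header <- function(Kd = 10, gain = 2, current = 800,
                              counts_per_volt = COUNTS_PER_VOLT,
                              aperture_diameter_um = 100,
                              start_time_s = 0, duration_s = 150,
                              correction_factor = 0) {
  for (nm in c("Kd", "gain", "current", "counts_per_volt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      cond_error(sprintf("header constant '%s' must be a positive number", nm),
                 "coultertrace_config_error")
  }
  if (duration_s <= 0) cond_error("duration_s must be > 0",
                                  "coultertrace_config_error")
  if (start_time_s < 0) cond_error("start_time_s must be >= 0",
                                   "coultertrace_config_error")
  structure(list(Kd = as.numeric(Kd), gain = as.numeric(gain),
                 current = as.numeric(current),
                 counts_per_volt = as.numeric(counts_per_volt),
                 aperture_diameter_um = as.numeric(aperture_diameter_um),
                 start_time_s = as.numeric(start_time_s),
                 duration_s = as.numeric(duration_s),
                 correction_factor = as.numeric(correction_factor)),
            class = "instrument_header")
}

HEADER_FIELDS <- c("Kd", "gain", "current", "counts_per_volt",
                   "aperture_diameter_um", "start_time_s", "duration_s",
                   "correction_factor")

#' A single instrument recording
#'
#' Bundles a header, the raw pulse table (one row per particle, five
#' non-negative integer values; only the first, the pulse-height component,
#' is used by the analysis) and the time section (elapsed milliseconds and
#' cumulative pulse count at every tick, 200 ms by default).
#'
#' @param header An [instrument_header()].
#' @param pulses Numeric matrix with 5 columns, or NULL for an empty file.
#' @param ticks Two-column matrix `(elapsed_ms, cumulative_count)`;
#'   elapsed strictly increasing, counts non-decreasing and ending at the
#'   number of pulse rows.
#' @param tick_width_ms Tick spacing in milliseconds (default 200).
#' @param provenance `"raw"` for recorded data, `"interpolated"` for files
#'   synthesized by debris interpolation.
#' @return An object of class `measurement_file`.
#' @export
measurement_file <- function(header, pulses = NULL, ticks = NULL,
                             tick_width_ms = 200, provenance = "raw") {
  stopifnot(inherits(header, "instrument_header"))
  if (is.null(pulses)) pulses <- matrix(numeric(0), ncol = 5L)
  pulses <- as.matrix(pulses)
  if (ncol(pulses) != 5L)
    stop_format("pulse records must have exactly five values per row")
  if (nrow(pulses) && any(pulses < 0))
    stop_format("pulse record values must be non-negative")
  n <- nrow(pulses)
  if (is.null(ticks)) {
    ticks <- default_ticks(n, header$duration_s, tick_width_ms)
  }
  ticks <- as.matrix(ticks)
  colnames(ticks) <- c("elapsed_ms", "cumulative_count")
  if (nrow(ticks)) {
    if (any(diff(ticks[, 1L]) <= 0))
      stop_format("time section elapsed_ms must be strictly increasing")
    if (any(diff(ticks[, 2L]) < 0))
      stop_format("time section cumulative counts must be non-decreasing")
    if (ticks[nrow(ticks), 2L] != n)
      stop_format(sprintf(
        "time section ends at %d pulses but the file has %d pulse records",
        ticks[nrow(ticks), 2L], n))
  } else if (n > 0) {
    stop_format("non-empty pulse table requires a time section")
  }
  provenance <- match.arg(provenance, c("raw", "interpolated"))
  structure(list(header = header, pulses = unname(pulses), ticks = ticks,
                 tick_width_ms = as.numeric(tick_width_ms),
                 provenance = provenance),
            class = "measurement_file")
}

# Evenly distribute n pulses over the time section as a fallback when no
# explicit section is supplied (simulator always supplies one).
default_ticks <- function(n, duration_s, tick_width_ms) {
  elapsed <- seq(tick_width_ms, duration_s * 1000, by = tick_width_ms)
  if (!length(elapsed)) return(matrix(numeric(0), ncol = 2L))
  cum <- round(n * elapsed / max(elapsed))
  cum[length(cum)] <- n
  cbind(elapsed_ms = elapsed, cumulative_count = cummax(cum))
}

n_pulses <- function(file) nrow(file$pulses)

#' Decode the pulse-height component of raw pulse records
#'
#' The height in digitizer counts is the sum of the header's correction
#' factor and the first of the five values recorded per particle, clamped at
#' zero (a pulse cannot have negative amplitude).
#'
#' @param record Numeric vector of five values, or an n x 5 matrix.
#' @param header An [instrument_header()] supplying the correction factor.
#' @return Numeric vector of heights in counts.
#' @export
decode_height <- function(record, header) {
  v1 <- if (is.matrix(record)) record[, 1L] else {
    if (length(record) != 5L)
      stop_format("a raw pulse record has exactly five values")
    record[1L]
  }
  pmax(0, header$correction_factor + v1)
}

fmt_num <- function(x) {
  # shortest representation that round-trips a double exactly
  vapply(x, function(v) {
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

#' Write a recording in the fixture dialect
#'
#' Serializes a [measurement_file()] as plain text: a magic line, a header
#' block of `key = value` lines, the pulse table (five integers per row) and
#' the time section. Files read back with [read_measurement_file()] are
#' field-for-field identical, and the provenance flag persists so
#' interpolated files remain distinguishable from raw recordings.
#'
#' @param file A [measurement_file()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_measurement_file <- function(file, path) {
  stopifnot(inherits(file, "measurement_file"))
  n <- n_pulses(file)
  if (n > PULSE_CAP)
    stop_format(sprintf(
      "file has %d pulses; the native file cap is %d pulses per file",
      n, PULSE_CAP))
  h <- file$header
  out <- c(
    FILE_MAGIC,
    "[header]",
    paste(HEADER_FIELDS, "=", fmt_num(unlist(h[HEADER_FIELDS]))),
    paste("provenance =", file$provenance),
    paste("tick_width_ms =", fmt_num(file$tick_width_ms)),
    sprintf("[pulses] %d", n))
  con <- base::file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  if (n > 0) {
    writeLines(apply(format(file$pulses, scientific = FALSE, trim = TRUE),
                     1L, paste, collapse = " "), con)
  }
  writeLines(sprintf("[timesection] %d", nrow(file$ticks)), con)
  if (nrow(file$ticks)) {
    writeLines(paste(fmt_num(file$ticks[, 1L]),
                     format(file$ticks[, 2L], scientific = FALSE,
                            trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a recording
#'
#' Parses a fixture-dialect pulse file into a [measurement_file()]. A missing
#' header constant, a truncated pulse block, or a time section whose final
#' cumulative count disagrees with the pulse table raises a format error
#' naming the problem.
#'
#' @param path Path to a file written by [write_measurement_file()] (or the
#'   simulator).
#' @param dialect On-disk layout; only `"fixture"` is implemented. The
#'   `"native-adapter"` slot is reserved for a transcription of the vendor
#'   binary layout.
#' @return A [measurement_file()].
#' @export
read_measurement_file <- function(path, dialect = c("fixture",
                                                    "native-adapter")) {
  dialect <- match.arg(dialect)
  if (dialect == "native-adapter")
    stop_format("the native binary adapter is not implemented; use 'fixture'")
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1L] != FILE_MAGIC)
    stop_format(sprintf("'%s' does not declare the fixture dialect magic",
                        path))
  if (length(lines) < 2L || lines[2L] != "[header]")
    stop_format("missing [header] section")
  i <- 3L
  hdr <- list()
  while (i <= length(lines) && !startsWith(lines[i], "[")) {
    kv <- strsplit(sub(" *= *", "\x01", lines[i]), "\x01", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) hdr[[kv[1L]]] <- kv[2L]
    i <- i + 1L
  }
  for (f in HEADER_FIELDS)
    if (is.null(hdr[[f]]))
      stop_format(sprintf("header is missing required constant '%s'", f))
  header <- instrument_header(
    Kd = as.numeric(hdr$Kd), gain = as.numeric(hdr$gain),
    current = as.numeric(hdr$current),
    counts_per_volt = as.numeric(hdr$counts_per_volt),
    aperture_diameter_um = as.numeric(hdr$aperture_diameter_um),
    start_time_s = as.numeric(hdr$start_time_s),
    duration_s = as.numeric(hdr$duration_s),
    correction_factor = as.numeric(hdr$correction_factor))
  provenance <- if (is.null(hdr$provenance)) "raw" else hdr$provenance
  tick_width <- if (is.null(hdr$tick_width_ms)) 200 else
    as.numeric(hdr$tick_width_ms)

  if (i > length(lines) || !startsWith(lines[i], "[pulses]"))
    stop_format("missing [pulses] section")
  n <- as.integer(sub("\\[pulses\\] *", "", lines[i]))
  i <- i + 1L
  if (i + n - 1L > length(lines))
    stop_format(sprintf(
      "truncated pulse block: expected %d records, file ends at line %d",
      n, length(lines)))
  pulses <- if (n > 0) {
    vals <- scan(text = lines[i:(i + n - 1L)], what = numeric(),
                 quiet = TRUE)
    if (length(vals) != 5L * n)
      stop_format(sprintf(
        "truncated pulse block near line %d: expected %d values, got %d",
        i, 5L * n, length(vals)))
    matrix(vals, ncol = 5L, byrow = TRUE)
  } else matrix(numeric(0), ncol = 5L)
  i <- i + n
  if (i > length(lines) || !startsWith(lines[i], "[timesection]"))
    stop_format("missing [timesection] section")
  m <- as.integer(sub("\\[timesection\\] *", "", lines[i]))
  i <- i + 1L
  ticks <- if (m > 0) {
    if (i + m - 1L > length(lines))
      stop_format("truncated time section")
    tv <- scan(text = lines[i:(i + m - 1L)], what = numeric(), quiet = TRUE)
    matrix(tv, ncol = 2L, byrow = TRUE)
  } else matrix(numeric(0), ncol = 2L)
  measurement_file(header, pulses, ticks, tick_width, provenance)
}

#' @export
print.measurement_file <- function(x, ...) {
  cat(sprintf(
    "<measurement_file> %d pulses, %.0f s from t = %.0f s (%s)\n",
    n_pulses(x), x$header$duration_s, x$header$start_time_s, x$provenance))
  invisible(x)
}

#' Assemble recordings into a timecourse
#'
#' Stitches several recordings onto one absolute time axis. The commercial
#' software resets every file's clock to zero; here each file keeps its
#' absolute start time, files are sorted by start, and flush gaps between
#' files are preserved rather than compressed. The timecourse epoch is the
#' start time of the earliest file.
#'
#' @param files List of [measurement_file()] objects, or a character vector
#'   of paths to read.
#' @param dialect Passed to [read_measurement_file()] when `files` are paths.
#' @return An object of class `coulter_timecourse`: a list with `files`
#'   (sorted by start time), `epoch_s` and per-file `offsets_s`.
#' @export
load_timecourse <- function(files, dialect = "fixture") {
  if (is.character(files))
    files <- lapply(files, read_measurement_file, dialect = dialect)
  if (!length(files)) cond_error("need at least one file",
                                 "coultertrace_config_error")
  stopifnot(all(vapply(files, inherits, logical(1), "measurement_file")))
  starts <- vapply(files, function(f) f$header$start_time_s, numeric(1))
  ord <- order(starts)
  files <- files[ord]
  starts <- starts[ord]
  ends <- starts + vapply(files, function(f) f$header$duration_s, numeric(1))
  if (length(files) > 1L) {
    ov <- which(starts[-1L] < ends[-length(ends)])
    if (length(ov))
      cond_error(sprintf(
        "recording intervals overlap between files %s",
        paste(sprintf("(%d,%d)", ov, ov + 1L), collapse = ", ")),
        "coultertrace_consistency_error")
    cal <- vapply(files, function(f)
      with(f$header, paste(Kd, gain, current, counts_per_volt,
                           aperture_diameter_um)), character(1))
    if (length(unique(cal)) > 1L)
      warning("files do not share aperture/calibration constants")
  }
  epoch <- starts[1L]
  structure(list(files = files, epoch_s = epoch, offsets_s = starts - epoch),
            class = "coulter_timecourse")
}

#' @export
print.coulter_timecourse <- function(x, ...) {
  n <- vapply(x$files, n_pulses, numeric(1))
  cat(sprintf(
    "<coulter_timecourse> %d files, %.0f pulses, span %.1f min (epoch %.0f s)\n",
    length(x$files), sum(n), timecourse_span(x) / 60, x$epoch_s))
  if (any(vapply(x$files, function(f) f$provenance, character(1)) ==
          "interpolated"))
    cat("  contains interpolated (debris-replaced) files\n")
  invisible(x)
}

timecourse_span <- function(tc) {
  last <- tc$files[[length(tc$files)]]
  last$header$start_time_s + last$header$duration_s - tc$epoch_s
}
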