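# Seeded simulator of instrument-style timecourses with known ground truth.
# Emulates the acquisition structure of a continuous run: back-to-back 150 s
# files separated by flush gaps (~75% duty cycle), Poisson pulse counts,
# populations with log-normal biological size spread and configurable growth
# laws, multiplicative instrument noise on diameter, a sub-threshold junk
# fraction feeding the noise-floor filter, optional single-file debris
# inflations, and an optional treatment that switches the mean-volume
# trajectory to a new slope after a response lag. Volumes are encoded back
# to integer pulse heights through the header constants, so simulated files
# exercise the full decode path.

#' Population specification for the simulator
#'
#' @param weight Mixing fraction (weights over populations must sum to 1).
#' @param mean_volume Mean volume in um^3 at time zero.
#' @param cv Coefficient of variation of the log-normal biological size
#'   spread.
#' @param growth Growth law of the mean volume: `"none"`, `"linear"`
#'   (`rate` in um^3/min) or `"exponential"` (`rate` in 1/min).
#' @param rate Growth rate (units per `growth`).
#' @param label Population label carried into the ground truth.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(weight = 1, mean_volume = 40, cv = 0.15,
                            growth = c("none", "linear", "exponential"),
                            rate = 0, label = "pop") {
  growth <- match.arg(growth)
  if (cv < 0) cond_error("cv must be >= 0", "coultertrace_config_error")
  structure(list(weight = weight, mean_volume = mean_volume, cv = cv,
                 growth = growth, rate = rate, label = label),
            class = "population_spec")
}

#' Simulation configuration
#'
#' @param populations List of [population_spec()]s; weights must sum to 1.
#' @param measurement_cv Multiplicative instrument noise (SD, fractional) on
#'   measured diameter (default 0.01).
#' @param pulses_per_file Expected pulses per file (Poisson; default 20 000).
#' @param file_duration_s Recording length per file (default 150 s).
#' @param gap_s Flush gap between files (default 50 s, i.e. ~75% duty).
#' @param total_min Total timecourse span in minutes.
#' @param noise_floor_weight Fraction of events replaced by sub-threshold
#'   junk (default 0.02, matched to the noise-floor filter's 2%).
#' @param debris Optional data frame `(file_index, inflation)`: the named
#'   file's volumes are multiplied by `1 + inflation`, emulating a partial
#'   aperture occlusion.
#' @param treatment Optional list `(time_s, lag_s, post_slope)`: at
#'   `time_s + lag_s` every population's mean-volume trajectory switches to
#'   a linear decline/rise of `post_slope` um^3/min from its value at the
#'   switch.
#' @param header An [instrument_header()] used for all files.
#' @param tick_ms Time-section tick width (default 200 ms).
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(populations, measurement_cv = 0.01,
                              pulses_per_file = 20000,
                              file_duration_s = 150, gap_s = 50,
                              total_min = 120, noise_floor_weight = 0.02,
                              debris = NULL, treatment = NULL,
                              header = instrument_header(), tick_ms = 200,
                              seed = 1L) {
  if (inherits(populations, "population_spec"))
    populations <- list(populations)
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8)
    cond_error("population weights must sum to 1",
               "coultertrace_config_error")
  for (f in c(measurement_cv, noise_floor_weight))
    if (f < 0 || f > 1) cond_error("fractions must lie in [0, 1]",
                                   "coultertrace_config_error")
  if (file_duration_s <= 0 || gap_s < 0 || total_min * 60 < file_duration_s)
    cond_error("inconsistent durations", "coultertrace_config_error")
  structure(list(populations = populations, measurement_cv = measurement_cv,
                 pulses_per_file = pulses_per_file,
                 file_duration_s = file_duration_s, gap_s = gap_s,
                 total_min = total_min,
                 noise_floor_weight = noise_floor_weight,
                 debris = debris, treatment = treatment, header = header,
                 tick_ms = tick_ms, seed = as.integer(seed)),
            class = "simulation_config")
}

# mean-volume trajectory of population p at time t (minutes), including the
# treatment switch
mean_volume_at <- function(pop, t_min, treatment = NULL) {
  base <- function(tm) switch(pop$growth,
    none = rep(pop$mean_volume, length(tm)),
    linear = pop$mean_volume + pop$rate * tm,
    exponential = pop$mean_volume * exp(pop$rate * tm))
  if (is.null(treatment)) return(base(t_min))
  t_break <- (treatment$time_s + treatment$lag_s) / 60
  out <- base(pmin(t_min, t_break))
  late <- t_min > t_break
  out[late] <- out[late] + treatment$post_slope * (t_min[late] - t_break)
  out
}

#' Generate a simulated timecourse with ground truth
#'
#' Draws every file of the configured timecourse (all randomness from one
#' stream seeded by `cfg$seed`, in documented order: per file, the Poisson
#' count, arrival times, population assignment, biological spread, junk
#' flags and volumes, then instrument noise) and encodes volumes to integer
#' pulse heights through the header constants.
#'
#' The ground truth records, per pulse, the true arrival time and the
#' volume implied by its encoded (integer) height, the population label and
#' the file index; attributes carry the treatment response time and debris
#' file indices.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `sim_timecourse`: `files` (list of
#'   [measurement_file()]), `truth` (data frame), `config`.
#' @export
generate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  dur <- cfg$file_duration_s
  starts <- seq(0, cfg$total_min * 60 - dur, by = dur + cfg$gap_s)
  K <- length(cfg$populations)
  wts <- vapply(cfg$populations, `[[`, numeric(1), "weight")
  min_mean <- min(vapply(cfg$populations, `[[`, numeric(1), "mean_volume"))
  files <- vector("list", length(starts))
  truth <- vector("list", length(starts))
  pid0 <- 0L
  for (i in seq_along(starts)) {
    n <- stats::rpois(1L, cfg$pulses_per_file)
    t_s <- sort(stats::runif(n, starts[i], starts[i] + dur))
    pop <- sample.int(K, n, replace = TRUE, prob = wts)
    mv <- numeric(n)
    for (k in seq_len(K))
      mv[pop == k] <- mean_volume_at(cfg$populations[[k]],
                                     t_s[pop == k] / 60, cfg$treatment)
    cvs <- vapply(cfg$populations, `[[`, numeric(1), "cv")[pop]
    sdlog <- sqrt(log(1 + cvs^2))
    v <- mv * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    lab <- vapply(cfg$populations, `[[`, character(1), "label")[pop]
    junk <- stats::runif(n) < cfg$noise_floor_weight
    nj <- sum(junk)
    if (nj) {
      v[junk] <- exp(stats::runif(nj, log(0.01 * min_mean),
                                  log(0.1 * min_mean)))
      lab[junk] <- "noise"
    }
    if (!is.null(cfg$debris)) {
      hit <- cfg$debris$file_index == i
      if (any(hit)) v <- v * (1 + cfg$debris$inflation[which(hit)[1L]])
    }
    d <- volume_to_diameter(v) *
      pmax(1e-6, 1 + stats::rnorm(n, 0, cfg$measurement_cv))
    raw1 <- pmax(0, round(diameter_to_height(d, cfg$header)) -
                   cfg$header$correction_factor)
    true_v <- diameter_to_volume(
      height_to_diameter(decode_height(cbind(raw1, 0, 0, 0, 0), cfg$header),
                         cfg$header))
    elapsed <- seq(cfg$tick_ms, dur * 1000, by = cfg$tick_ms)
    cum <- findInterval(elapsed, (t_s - starts[i]) * 1000)
    cum[length(cum)] <- n
    header <- cfg$header
    header$start_time_s <- starts[i]
    header$duration_s <- dur
    files[[i]] <- measurement_file(header, cbind(raw1, 0, 0, 0, 0),
                                   cbind(elapsed, cum), cfg$tick_ms, "raw")
    truth[[i]] <- data.frame(pulse_id = pid0 + seq_len(n), file_index = i,
                             true_time_s = t_s, true_volume_um3 = true_v,
                             population = lab)
    pid0 <- pid0 + n
  }
  truth <- do.call(rbind, truth)
  attr(truth, "response_time_s") <- if (!is.null(cfg$treatment))
    cfg$treatment$time_s + cfg$treatment$lag_s else NA_real_
  attr(truth, "debris_files") <- if (!is.null(cfg$debris))
    cfg$debris$file_index else integer(0)
  structure(list(files = files, truth = truth, config = cfg),
            class = "sim_timecourse")
}

#' @export
print.sim_timecourse <- function(x, ...) {
  cat(sprintf(
    "<sim_timecourse> %d files, %d pulses, %g min (seed %d)\n",
    length(x$files), nrow(x$truth), x$config$total_min, x$config$seed))
  invisible(x)
}

#' Convert a simulation to a timecourse
#'
#' @param sim A [generate_timecourse()] result (or a list of
#'   [measurement_file()]s).
#' @return A `coulter_timecourse`.
#' @export
as_timecourse <- function(sim) {
  if (inherits(sim, "sim_timecourse")) sim <- sim$files
  load_timecourse(sim)
}

#' Named simulation presets
#'
#' Ready-made configurations emulating the canonical sample types of a
#' continuous volume-timecourse study:
#'
#' * `beads4um`: 4.000 um diameter polystyrene beads with 0.033 um diameter
#'   SD, no growth, 2 h — the measurement-error / rate-resolution control.
#' * `g1_arrest`: a single G1-arrested yeast-like population growing
#'   linearly.
#' * `bimodal_arrest`: three arrest subpopulations (slow-growing, G1-like,
#'   metaphase-like) with size-dependent linear rates that diverge over 3 h.
#' * `synchronized`: a small synchronized population growing exponentially
#'   (0.005 /min) over 4 h, for growth-law comparison.
#' * `drug_response`: a large mammalian-like population (900 um^3, CV 15%),
#'   constant for 60 min, treated at 60 min, responding after a 9.7 min lag
#'   with a linear decline of 2.25 um^3/min (~15% of the mean per hour)
#'   over a 2 h course.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
preset <- function(name = c("beads4um", "g1_arrest", "bimodal_arrest",
                            "synchronized", "drug_response"), seed = 1L) {
  name <- match.arg(name)
  bead_v <- diameter_to_volume(4)
  bead_cv <- 3 * 0.033 / 4  # volume CV from diameter CV (small-CV limit)
  switch(name,
    beads4um = simulation_config(
      population_spec(1, bead_v, bead_cv, "none", label = "beads"),
      measurement_cv = 0.01, total_min = 120, seed = seed),
    g1_arrest = simulation_config(
      population_spec(1, 40, 0.25, "linear", rate = 0.2, label = "G1"),
      total_min = 120, seed = seed),
    bimodal_arrest = simulation_config(
      list(population_spec(0.2, 25, 0.10, "linear", rate = 0.02,
                           label = "SG"),
           population_spec(0.5, 45, 0.10, "linear", rate = 0.15,
                           label = "G1"),
           population_spec(0.3, 80, 0.10, "linear", rate = 0.35,
                           label = "M")),
      total_min = 180, seed = seed),
    synchronized = simulation_config(
      population_spec(1, 20, 0.15, "exponential", rate = 0.005,
                      label = "sync"),
      total_min = 240, seed = seed),
    drug_response = simulation_config(
      population_spec(1, 900, 0.15, "none", label = "L1210"),
      treatment = list(time_s = 3600, lag_s = 582, post_slope = -2.25),
      total_min = 120, seed = seed))
}

#' Write simulated files to disk
#'
#' @param sim A [generate_timecourse()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(sim$files), function(i) {
    p <- file.path(dir, sprintf("%s_%03d.ctp", prefix, i))
    write_measurement_file(sim$files[[i]], p)
    p
  }, character(1))
  utils::write.csv(sim$truth, file.path(dir, paste0(prefix, "_truth.csv")),
                   row.names = FALSE)
  invisible(paths)
}
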