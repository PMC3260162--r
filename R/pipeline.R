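# Batch-processing front end: one configuration object drives the ordered
# stages load -> decode -> times -> filters -> QC/interpolation -> features
# -> kinetics, writing each stage's outputs and a manifest. Raw pulse tables
# are decoded file-by-file and released, so only the compact event table is
# held across stages.

RUN_CONFIG_KEYS <- list(
  input = c("paths", "dialect"),
  filters = c("noise_floor_fraction", "exclusion_bound_level", "bins",
              "smooth_bw"),
  debris = c("bound_level", "ratio_threshold", "neighbor_rule",
             "compare_side", "enabled"),
  kinetics = c("window_min", "step_min", "grid_step_s", "edge_exclude_min",
               "sig_threshold", "event_time_s", "breakpoint"),
  features = c("bound_levels", "track_max_jump"),
  colormap = c("time_bin_s", "volume_bins"),
  output = c("dir"),
  top = c("input", "filters", "debris", "kinetics", "features", "colormap",
          "output", "log_level", "seed"))

#' Pipeline run configuration
#'
#' Builds and validates the configuration document for [run_pipeline()].
#' Unknown keys at any level are rejected; every default equals the standard
#' analysis parameters (2% noise floor, 10% exclusion level, 25%/1.025
#' debris criterion, 60 min/3 min windows, 150 s files).
#'
#' @param x A named list, or a path to a YAML/JSON file holding one.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  bad <- setdiff(names(x), RUN_CONFIG_KEYS$top)
  if (length(bad))
    cond_error(paste("unknown config keys:", paste(bad, collapse = ", ")),
               "coultertrace_usage_error")
  for (sec in c("input", "filters", "debris", "kinetics", "features",
                "colormap", "output")) {
    bad <- setdiff(names(x[[sec]]), RUN_CONFIG_KEYS[[sec]])
    if (length(bad))
      cond_error(sprintf("unknown keys in '%s': %s", sec,
                         paste(bad, collapse = ", ")),
                 "coultertrace_usage_error")
  }
  get2 <- function(sec, key, default) {
    v <- x[[sec]][[key]]
    if (is.null(v)) default else v
  }
  cfg <- list(
    input = list(paths = x$input$paths,
                 dialect = get2("input", "dialect", "fixture")),
    filters = filter_config(
      noise_floor_fraction = get2("filters", "noise_floor_fraction", 0.02),
      exclusion_bound_level = get2("filters", "exclusion_bound_level", 10),
      bins = get2("filters", "bins", 256),
      smooth_bw = get2("filters", "smooth_bw", 3)),
    debris = debris_config(
      bound_level = get2("debris", "bound_level", 25),
      ratio_threshold = get2("debris", "ratio_threshold", 1.025),
      neighbor_rule = get2("debris", "neighbor_rule", "both"),
      compare_side = get2("debris", "compare_side", "upper")),
    debris_enabled = isTRUE(get2("debris", "enabled", TRUE)),
    kinetics = list(
      window_min = get2("kinetics", "window_min", 60),
      step_min = get2("kinetics", "step_min", 3),
      grid_step_s = get2("kinetics", "grid_step_s", 30),
      edge_exclude_min = get2("kinetics", "edge_exclude_min", 5),
      sig_threshold = get2("kinetics", "sig_threshold", 0.01),
      event_time_s = x$kinetics$event_time_s,
      breakpoint = isTRUE(get2("kinetics", "breakpoint",
                               !is.null(x$kinetics$event_time_s)))),
    features = list(
      bound_levels = get2("features", "bound_levels", c(10, 25, 33)),
      track_max_jump = get2("features", "track_max_jump", 0.15)),
    colormap = list(time_bin_s = get2("colormap", "time_bin_s", 150),
                    volume_bins = get2("colormap", "volume_bins", 128)),
    output = list(dir = get2("output", "dir", "coultertrace-out")),
    log_level = if (is.null(x$log_level)) "info" else x$log_level,
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed))
  class(cfg) <- "run_config"
  cfg
}

pipe_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[coultertrace] ", sprintf(...))
}

#' Run the full processing pipeline
#'
#' Executes every stage over the input files and writes CSV outputs plus a
#' `manifest.json` recording the package version, seed, configuration and
#' per-stage counts. On a stage failure, outputs written so far are kept and
#' the manifest marks the failed stage.
#'
#' @param cfg A [run_config()] (or the list/path it accepts).
#' @param timecourse Optionally, an already-loaded `coulter_timecourse`
#'   (e.g. from the simulator), bypassing file input.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(cfg, timecourse = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(package = "coultertrace",
                   version = as.character(utils::packageVersion("coultertrace")),
                   seed = cfg$seed, stages = list())
  stage <- "load"
  result <- tryCatch({
    tc <- if (!is.null(timecourse)) timecourse else {
      if (!length(cfg$input$paths))
        cond_error("no input files", "coultertrace_usage_error")
      load_timecourse(cfg$input$paths, cfg$input$dialect)
    }
    manifest$stages$load <- list(files = length(tc$files))
    pipe_log(cfg, "loaded %d files", length(tc$files))

    stage <- "qc"
    qc <- NULL
    if (cfg$debris_enabled && length(tc$files) >= 3L) {
      qc <- clean_timecourse(tc, cfg$debris, cfg$filters)
      tc <- qc$timecourse
      out$qc <- file.path(cfg$output$dir, "qc_report.csv")
      write_qc_csv(qc, out$qc)
      manifest$stages$qc <- list(flagged = sum(qc$report$flagged),
                                 replaced = sum(qc$report$replaced))
      pipe_log(cfg, "qc: %d files replaced", sum(qc$report$replaced))
    }

    stage <- "decode"
    events <- pulse_events(tc)
    manifest$stages$decode <- list(pulses = nrow(events))
    pipe_log(cfg, "decoded %d pulses", nrow(events))

    stage <- "filters"
    events <- apply_filters(events, cfg$filters)
    out$events <- file.path(cfg$output$dir, "events.csv")
    write_events_csv(events, out$events)
    manifest$stages$filters <- list(
      noise_excluded = sum(events$noise_excluded),
      bounds_excluded = sum(events$bounds_excluded),
      included = sum(!events$noise_excluded & !events$bounds_excluded))

    stage <- "features"
    bs <- bound_series(events, cfg$features$bound_levels, cfg$filters)
    out$bounds <- file.path(cfg$output$dir, "bound_series.csv")
    utils::write.csv(bs, out$bounds, row.names = FALSE)
    vr <- range(included(events)$volume_um3)
    cm <- colormap_matrix(
      events,
      time_edges = seq(min(events$time_s), max(events$time_s) + 1e-9,
                       length.out = max(2L, 1L + ceiling(
                         diff(range(events$time_s)) / cfg$colormap$time_bin_s))),
      volume_edges = exp(seq(log(vr[1L]), log(vr[2L]),
                             length.out = cfg$colormap$volume_bins + 1L)))
    out$colormap <- file.path(cfg$output$dir, "colormap.csv")
    utils::write.table(cm$values, out$colormap, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    manifest$stages$features <- list(bound_rows = nrow(bs))

    stage <- "kinetics"
    gr <- windowed_growth_rate(events, cfg$kinetics$window_min,
                               cfg$kinetics$step_min)
    out$rates <- file.path(cfg$output$dir, "growth_rates.csv")
    utils::write.csv(as.data.frame(gr), out$rates, row.names = FALSE)
    manifest$stages$kinetics <- list(windows = nrow(gr))
    if (cfg$kinetics$breakpoint) {
      bp <- bilinear_breakpoint(events,
                                event_time_s = cfg$kinetics$event_time_s,
                                grid_step_s = cfg$kinetics$grid_step_s,
                                edge_exclude_min = cfg$kinetics$edge_exclude_min,
                                sig_threshold = cfg$kinetics$sig_threshold)
      out$sse <- file.path(cfg$output$dir, "sse_curve.csv")
      utils::write.csv(data.frame(candidate_s = bp$candidate_s,
                                  sse = bp$sse),
                       out$sse, row.names = FALSE)
      manifest$stages$kinetics$best_time_s <- bp$best_time_s
      manifest$stages$kinetics$significant <- bp$significant
      if (!is.null(cfg$kinetics$event_time_s))
        manifest$stages$kinetics$lag_min <- bp$lag_min
    }
    manifest$status <- "ok"
    out
  }, coultertrace_error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    e
  })
  out$manifest <- file.path(cfg$output$dir, "manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (inherits(result, "condition")) stop(result)
  invisible(out)
}
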