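# Run configuration and the staged pipeline chaining
# simulate -> detect -> track -> analyze -> classify.

#' Build a run configuration
#'
#' @param out_dir Output directory; every stage writes its artifacts here.
#' @param seed Master seed; all stage randomness derives from it.
#' @param simulate List of arguments for the simulation stage: `program`,
#'   `mode`, `acquisition` (preset name or argument list), `motion`
#'   (argument list), plus overrides for [simulate_movie()].
#' @param detect List: `diameter_xy` (micrometers), `diameter_z`,
#'   `channel`, `quality` (threshold or NULL).
#' @param track List: `max_step`, `max_gap`, `memory`.
#' @param analyze List: `debounce`, `min_separation`, `min_duration`,
#'   `n_radial_frames`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       simulate = list(), detect = list(), track = list(),
                       analyze = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = utils::modifyList(
      list(program = "canonical", mode = "wildtype",
           acquisition = "custom", motion = list()), simulate),
    detect = utils::modifyList(
      list(diameter_xy = 0.5, diameter_z = NULL, channel = "dots",
           quality = NULL), detect),
    track = utils::modifyList(
      list(max_step = 1.0, max_gap = 1L, memory = 0.8), track),
    analyze = utils::modifyList(
      list(debounce = 2L, min_separation = 1.0, min_duration = 3L,
           n_radial_frames = 10L), analyze))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL   # machine-local path; not part of the scientific config
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, stage, needed_by) {
  p <- artifact(cfg, name)
  if (!file.exists(p))
    stop("dependency error: stage '", needed_by, "' needs artifact '", name,
         "' produced by stage '", stage, "'")
  p
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, each writing its artifacts under
#' `config$out_dir`: `simulate` (movie + ground-truth tables), `detect`
#' (spots.csv), `track` (nucleus.csv, drift.csv, tracks.csv), `analyze`
#' (stage_intervals.csv, velocities.csv), `classify` (events.csv,
#' classification.json). Stage dependencies are checked and violations
#' abort with a stage-named error; identical configurations and seeds
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("simulate", "detect", "track", "analyze", "classify")`.
#' @return Invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "detect", "track",
                                    "analyze", "classify")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  hash <- config_hash(config)
  written <- character()
  log_msg <- function(...) message("[declustr] ", ...)

  if ("simulate" %in% stages) {
    log_msg("simulate: program=", config$simulate$program,
            " mode=", config$simulate$mode, " seed=", config$seed)
    acq <- if (is.character(config$simulate$acquisition))
      acquisition_config(config$simulate$acquisition)
    else do.call(acquisition_config, config$simulate$acquisition)
    mot <- do.call(motion_config, config$simulate$motion)
    sched <- simulate_decluster_schedule(config$simulate$program)
    extras <- config$simulate[setdiff(names(config$simulate),
                                      c("program", "mode", "acquisition",
                                        "motion"))]
    sim <- do.call(simulate_movie, c(
      list(schedule = sched, motion = mot, acq = acq,
           mode = config$simulate$mode, seed = config$seed), extras))
    write_movie(sim$movie, artifact(config, "movie.ome.tif"))
    write_tables(sim$truth[c("dots", "events", "drift", "nucleus")],
                 config$out_dir, config_hash = hash)
    written <- c(written, artifact(config, "movie.ome.tif"))
  }

  if ("detect" %in% stages) {
    mp <- require_artifact(config, "movie.ome.tif", "simulate", "detect")
    log_msg("detect: diameter_xy=", config$detect$diameter_xy)
    m <- read_movie(mp)
    dz <- config$detect$diameter_z %||% (2 * config$detect$diameter_xy)
    spots <- detect_spots_movie(m, channel = config$detect$channel,
                                estimated_xy_diameter = config$detect$diameter_xy,
                                estimated_z_diameter = dz,
                                quality_threshold = config$detect$quality)
    write_tables(list(spots = spots), config$out_dir, config_hash = hash)
    written <- c(written, artifact(config, "spots.csv"))
  }

  if ("track" %in% stages) {
    sp <- require_artifact(config, "spots.csv", "detect", "track")
    mp <- require_artifact(config, "movie.ome.tif", "simulate", "track")
    log_msg("track: max_step=", config$track$max_step,
            " memory=", config$track$memory)
    spots <- read_table_csv(sp)
    m <- read_movie(mp)
    seg <- segment_nucleus_movie(m)
    tr <- link_tracks(spots, max_gap = config$track$max_gap,
                      max_step = config$track$max_step,
                      motion_memory = config$track$memory)
    dc <- correct_drift(tr, seg$table)
    write_tables(list(nucleus = seg$table, tracks = dc$tracks,
                      drift_estimate = dc$drift),
                 config$out_dir, config_hash = hash)
    written <- c(written, artifact(config, "tracks.csv"))
  }

  if ("analyze" %in% stages) {
    tp <- require_artifact(config, "tracks.csv", "track", "analyze")
    mp <- require_artifact(config, "movie.ome.tif", "simulate", "analyze")
    log_msg("analyze")
    tracks <- read_table_csv(tp)
    m <- read_movie(mp)
    counts <- as.data.frame(table(factor(tracks$frame,
                                         levels = seq_len(n_frames(m)) - 1L)))
    counts <- data.frame(frame = as.integer(as.character(counts$Var1)),
                         count = counts$Freq)
    iv <- dot_stage_intervals(counts, m$frame_interval,
                              debounce = config$analyze$debounce)
    vel <- compute_velocities(tracks, m$frame_interval)
    write_tables(list(dot_counts = counts, stage_intervals = iv,
                      velocities = vel),
                 config$out_dir, config_hash = hash)
    written <- c(written, artifact(config, "stage_intervals.csv"))
  }

  if ("classify" %in% stages) {
    tp <- require_artifact(config, "tracks.csv", "track", "classify")
    log_msg("classify")
    tracks <- read_table_csv(tp)
    class(tracks) <- c("tracks", "data.frame")
    # program semantics are defined from the three-dot stage {Aa, Ab, XY4}
    # on; for movies that start earlier, restrict the lineage to frames
    # from the first three-dot frame
    cnt <- table(tracks$frame)
    t3 <- suppressWarnings(min(as.integer(names(cnt))[cnt >= 3]))
    if (is.finite(t3)) tracks <- tracks[tracks$frame >= t3, , drop = FALSE]
    ev <- detect_splits_fusions(tracks,
                                association_radius = config$analyze$min_separation)
    cl <- tryCatch(classify_decluster_program(tracks, ev),
                   error = function(e)
                     list(program = "other", notes = conditionMessage(e)))
    write_tables(list(events = ev), config$out_dir, config_hash = hash)
    summary_path <- artifact(config, "classification.json")
    jsonlite::write_json(list(
      program = cl$program,
      identities = as.list(cl$identities %||% list()),
      notes = cl$notes %||% "",
      config_hash = hash, seed = config$seed),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, summary_path)
  }
  invisible(written)
}
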