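#' Write / read a sensor trace as CSV plus a JSON segment sidecar
#'
#' The CSV holds columns `t, ats1..ats8` (times in seconds, voltages in
#' volts); the sidecar `<path>.segments.json` records the sampling rate,
#' supply rail and the `no_load` / `seated_p1` / `test` spans.
#'
#' @param trace a `sensor_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv`: `path`, invisibly. `read_trace_csv`: the
#'   reconstructed `sensor_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(fs = attr(trace, "fs"),
               supply_max = attr(trace, "supply_max"),
               segments = attr(trace, "segments"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".segments.json")

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- read.csv(path)
  need <- c("t", paste0("ats", 1:8))
  if (!all(need %in% names(df)))
    stop("malformed trace CSV: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("segment sidecar not found: ", side, call. = FALSE)
  meta <- jsonlite::fromJSON(side)
  structure(df[, need], fs = meta$fs,
            segments = as.data.frame(meta$segments),
            supply_max = meta$supply_max,
            class = c("sensor_trace", "data.frame"))
}

#' Write / read a cohort posture fixture as CSV
#'
#' Columns `participant, ti1, ti2, ti3`; postures serialised as tokens
#' P1..P8.
#'
#' @param cohort a [generate_fixture_cohort()] data.frame.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, colClasses = c(participant = "integer",
                                      ti1 = "character", ti2 = "character",
                                      ti3 = "character"))
  for (col in c("ti1", "ti2", "ti3")) {
    bad <- which(!(df[[col]] %in% POSTURES))
    if (length(bad))
      stop(sprintf("invalid posture token '%s' at row %d, column %s",
                   df[[col]][bad[1L]], bad[1L], col), call. = FALSE)
  }
  structure(df, class = c("cohort_fixture", "data.frame"))
}

#' Write / read classified cohort results as CSV
#'
#' Columns `participant, ti1, ti2, ti3, status`; unclassified intervals are
#' empty fields.
#'
#' @param results a [classify_cohort()] data.frame.
#' @param path CSV file path.
#' @export
write_results_csv <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = "")
  need <- c("participant", "ti1", "ti2", "ti3", "status")
  if (!all(need %in% names(df)))
    stop("malformed results CSV", call. = FALSE)
  ok <- df$status == "OK"
  for (col in c("ti1", "ti2", "ti3")) {
    bad <- which(ok & !(df[[col]] %in% POSTURES))
    if (length(bad))
      stop(sprintf("invalid posture token '%s' at row %d, column %s",
                   df[[col]][bad[1L]], bad[1L], col), call. = FALSE)
  }
  structure(df[, need], class = c("cohort_results", "data.frame"))
}

#' Serialize a calibration profile to JSON
#'
#' Schema: `{"ats1": {"v_zero": .., "v_maxload": .., "threshold": ..}, ...}`.
#'
#' @param profile a [calibration_profile()].
#' @param path JSON file path.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  obj <- lapply(seq_len(8L), function(ch) list(
    v_zero = unname(profile$v_zero[ch]),
    v_maxload = unname(profile$v_maxload[ch]),
    threshold = unname(profile$threshold[ch])))
  names(obj) <- paste0("ats", 1:8)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  grab <- function(field) vapply(paste0("ats", 1:8),
                                 function(ch) obj[[ch]][[field]], numeric(1))
  structure(list(v_zero = grab("v_zero"), v_maxload = grab("v_maxload"),
                 threshold = grab("threshold")),
            class = "calibration_profile")
}

#' Serialize a transition report to JSON
#'
#' Blocks `n`, `transition_tables` (8 x 8 count matrices, rows P1..P8),
#' `mcnemar`, `bowker`, `distributions`, `triples`.  Byte-identical across
#' runs on the same input.
#'
#' @param report a [transition_report()].
#' @param path JSON file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "transition_report"))
  obj <- list(
    n = report$n,
    transition_tables = lapply(report$transition_tables, function(m) {
      mm <- unclass(m)
      attributes(mm) <- attributes(m)[c("dim", "dimnames")]
      mm
    }),
    mcnemar = report$mcnemar,
    bowker = report$bowker,
    distributions = lapply(report$distributions, as.list),
    triples = report$triples
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Export one contingency table as CSV (rows and columns P1..P8)
#'
#' @param table a `transition_table`.
#' @param path CSV file path.
#' @export
write_table_csv <- function(table, path) {
  m <- as_transition_table(table)
  df <- data.frame(posture = rownames(m), unclass(m)[,], check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects the tunable parameters of the pipeline in one validated list,
#' optionally overridden from a YAML file whose top-level keys match the
#' argument names.
#'
#' @param fs sampling frequency, Hz (default 45).
#' @param schedule_file path to a schedule config (default: the packaged
#'   timing table).
#' @param cutoff moving-average cutoff, Hz.
#' @param corrected_p7,swap_p4_p5 posture-lookup options, see
#'   [posture_patterns()].
#' @param mcnemar_variant see [mcnemar_cc()].
#' @param noise_sd,drift_rate sensor-model options for simulation.
#' @param seed integer seed for all randomness.
#' @param yaml optional YAML file of overrides.
#' @return named list of class `run_config`.
#' @export
run_config <- function(fs = 45, schedule_file = NULL, cutoff = 1,
                       corrected_p7 = TRUE, swap_p4_p5 = FALSE,
                       mcnemar_variant = "cc", noise_sd = 0.02,
                       drift_rate = 0, seed = 1, yaml = NULL) {
  cfg <- list(fs = fs, schedule_file = schedule_file, cutoff = cutoff,
              corrected_p7 = corrected_p7, swap_p4_p5 = swap_p4_p5,
              mcnemar_variant = mcnemar_variant, noise_sd = noise_sd,
              drift_rate = drift_rate, seed = seed)
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml, call. = FALSE)
    over <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  if (cfg$fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (!is.null(cfg$schedule_file) && !file.exists(cfg$schedule_file))
    stop("schedule file not found: ", cfg$schedule_file, call. = FALSE)
  structure(cfg, class = "run_config")
}

config_schedule <- function(cfg) {
  if (is.null(cfg$schedule_file)) build_schedule()
  else build_schedule(read_schedule_config(cfg$schedule_file))
}

config_lookup <- function(cfg) {
  posture_lookup(corrected_p7 = cfg$corrected_p7, swap_p4_p5 = cfg$swap_p4_p5)
}
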