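#' Modal activation pattern within a time window
#'
#' The analysis reports a single activation combination per interval; the
#' aggregation rule used here is the modal per-sample 8-tuple: the pattern
#' observed at the largest number of samples whose timestamps fall in the
#' half-open window.  Ties are broken by earliest occurrence within the
#' window, which keeps the rule deterministic.
#'
#' @param series an [activation_series()].
#' @param window numeric `c(start, end)`, seconds on the series' own time
#'   axis (half-open).
#' @return integer 0/1 vector of length 8 (the winning pattern).
#' @export
interval_pattern <- function(series, window) {
  stopifnot(inherits(series, "activation_series"))
  idx <- which(series$t >= window[1L] & series$t < window[2L])
  if (length(idx) == 0L)
    stop("window does not overlap the series", call. = FALSE)
  m <- as.matrix(series[idx, paste0("ats", 1:8)])
  keys <- m %*% 2L^(7:0)  # integer code per sample, channel 1 most significant
  counts <- table(keys)
  best <- as.numeric(names(counts)[counts == max(counts)])
  win <- if (length(best) == 1L) best else best[which.min(match(best, keys))]
  as.integer(m[match(win, keys), ])
}

#' Quality control of a recording
#'
#' Flags the hardware faults that force a recording to be discarded:
#' missing samples in the test segment, voltages outside the supply range,
#' or a channel with zero variance over the whole recording (a sensor stuck
#' at one level never responds to the calibration manoeuvres).
#'
#' @param trace a raw `sensor_trace` (calibration segments included).
#' @param profile optional [calibration_profile()] (unused by the checks but
#'   accepted so the QC step can sit after calibration in the pipeline).
#' @return `"OK"` or `"SENSOR_FAILURE"`.
#' @export
qc_trace <- function(trace, profile = NULL) {
  stopifnot(inherits(trace, "sensor_trace"))
  v <- trace_channels(trace)
  test <- trace_segment_idx(trace, "test")
  if (anyNA(v[test, ])) return("SENSOR_FAILURE")
  supply <- attr(trace, "supply_max")
  if (!is.null(supply) && any(v < 0 | v > supply, na.rm = TRUE))
    return("SENSOR_FAILURE")
  variances <- apply(v, 2L, var, na.rm = TRUE)
  if (any(is.na(variances)) || any(variances == 0)) return("SENSOR_FAILURE")
  "OK"
}

#' Classify one participant's recording
#'
#' Full per-participant pipeline: QC, per-test calibration from the trace's
#' own no-load and seated-P1 segments, 1 Hz moving-average filtering, binary
#' activation, modal pattern per analysis interval, posture lookup.
#' A participant is excluded listwise: any sensor failure, or any interval
#' whose modal pattern is not one of the eight recognised combinations,
#' removes them from downstream statistics.
#'
#' @param trace a `sensor_trace` with calibration segments.
#' @param schedule the [build_schedule()] the trace was recorded under.
#' @param lookup a [posture_lookup()].
#' @param cutoff moving-average cutoff in Hz (default 1).
#' @param participant id carried through to the result (default `NA`).
#' @return An object of class `participant_result`: list with `participant`,
#'   `ti1`, `ti2`, `ti3` (posture labels or `NA` when not classified) and
#'   `status` (`"OK"`, `"SENSOR_FAILURE"`, `"UNRECOGNIZED_POSTURE"`).
#' @export
classify_participant <- function(trace, schedule, lookup = posture_lookup(),
                                 cutoff = 1, participant = NA_integer_) {
  stopifnot(inherits(schedule, "stroop_schedule"))
  res <- list(participant = participant,
              ti1 = NA_character_, ti2 = NA_character_, ti3 = NA_character_,
              status = "OK")
  class(res) <- "participant_result"
  if (qc_trace(trace) != "OK") {
    res$status <- "SENSOR_FAILURE"
    return(res)
  }
  profile <- calibration_profile(trace)
  act <- activation_series(moving_average(trace, cutoff), profile)
  w <- interval_windows(schedule)
  test_start <- attr(trace, "segments")
  test_start <- test_start$start[test_start$segment == "test"]
  for (nm in names(w)) {
    pat <- interval_pattern(act, test_start + w[[nm]])
    res[[nm]] <- classify_pattern(pat, lookup)
  }
  if (any(unlist(res[c("ti1", "ti2", "ti3")]) == "UNRECOGNIZED"))
    res$status <- "UNRECOGNIZED_POSTURE"
  res
}

#' @export
print.participant_result <- function(x, ...) {
  cat(sprintf("participant %s: %s", x$participant, x$status))
  if (x$status != "SENSOR_FAILURE")
    cat(sprintf("  (TI1=%s, TI2=%s, TI3=%s)", x$ti1, x$ti2, x$ti3))
  cat("\n")
  invisible(x)
}

#' Classify a whole cohort of recordings
#'
#' @param traces list of `sensor_trace` objects (as from
#'   [cohort_to_traces()]); names are used as participant ids when present.
#' @inheritParams classify_participant
#' @param verbose log excluded participants with the reason (default FALSE).
#' @return data.frame of class `cohort_results` with columns
#'   `participant, ti1, ti2, ti3, status`.
#' @export
classify_cohort <- function(traces, schedule, lookup = posture_lookup(),
                            cutoff = 1, verbose = FALSE) {
  ids <- if (is.null(names(traces))) seq_along(traces) else names(traces)
  rows <- lapply(seq_along(traces), function(i) {
    r <- classify_participant(traces[[i]], schedule, lookup, cutoff,
                              participant = ids[i])
    if (verbose && r$status != "OK")
      warning(sprintf("participant %s excluded: %s", ids[i], r$status),
              call. = FALSE, immediate. = TRUE)
    data.frame(participant = as.character(r$participant),
               ti1 = r$ti1, ti2 = r$ti2, ti3 = r$ti3, status = r$status,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("cohort_results", "data.frame"))
}

#' Keep only fully classified participants
#'
#' @param results a [classify_cohort()] data.frame.
#' @return the rows with status `"OK"`.
#' @export
ok_results <- function(results) {
  results[results$status == "OK", , drop = FALSE]
}
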