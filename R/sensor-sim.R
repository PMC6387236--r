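#' Sensor model for the instrumented chair
#'
#' Describes the electrical behaviour of the eight analog tactile pressure
#' sensors.  Each channel has an inverted two-level response: it outputs its
#' no-load baseline `v_zero` when unloaded and drops to `v_maxload` when
#' pressed; the sensors are used as switches, so no continuous load-response
#' curve is modelled.  Gaussian noise and an optional linear drift are added
#' on top; outputs are clipped to `[0, supply_max]`.
#'
#' Baselines differ channel to channel (each sensor reads differently); when
#' not supplied they are drawn uniformly from `v_zero_range` /
#' `v_maxload_range` using `seed`.
#'
#' @param v_zero,v_maxload numeric length 8 (or 1, recycled): per-channel
#'   baselines in volts; `NULL` to draw from the ranges.
#' @param noise_sd additive Gaussian noise standard deviation, volts; scalar
#'   or length 8 for per-channel noise.
#' @param drift_rate linear drift, volts per second (applied to all channels).
#' @param supply_max supply rail, volts; outputs are clipped to `[0, supply_max]`.
#' @param v_zero_range,v_maxload_range sampling ranges for unset baselines.
#' @param seed integer used only to draw unset baselines.
#' @return An object of class `sensor_model`.
#' @export
#' @examples
#' m <- sensor_model(seed = 1)
#' m$v_zero - m$v_maxload  # per-channel dynamic range
sensor_model <- function(v_zero = NULL, v_maxload = NULL,
                         noise_sd = 0.02, drift_rate = 0,
                         supply_max = 3.6,
                         v_zero_range = c(2.8, 3.3),
                         v_maxload_range = c(0.8, 1.3),
                         seed = NULL) {
  if (is.null(v_zero) || is.null(v_maxload)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    if (is.null(v_zero))
      v_zero <- runif(8L, v_zero_range[1L], v_zero_range[2L])
    if (is.null(v_maxload))
      v_maxload <- runif(8L, v_maxload_range[1L], v_maxload_range[2L])
  }
  v_zero <- rep_len(v_zero, 8L)
  v_maxload <- rep_len(v_maxload, 8L)
  noise_sd <- rep_len(noise_sd, 8L)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (any(v_maxload >= v_zero))
    stop("inverted response requires v_maxload < v_zero on every channel",
         call. = FALSE)
  if (any(v_maxload < 0) || any(v_zero > supply_max))
    stop("baselines must satisfy 0 <= v_maxload < v_zero <= supply_max",
         call. = FALSE)
  structure(list(v_zero = v_zero, v_maxload = v_maxload,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 supply_max = supply_max),
            class = "sensor_model")
}

#' Posture script: ground-truth posture as a function of time
#'
#' @param posture character vector of posture labels (P1..P8).
#' @param start,end numeric vectors, segment bounds in seconds from test
#'   start; segments must be ordered, non-overlapping and contiguous.
#' @return data.frame of class `posture_script`.
#' @export
posture_script <- function(posture, start, end) {
  stopifnot(length(posture) == length(start), length(start) == length(end))
  if (length(posture) == 0L) stop("empty posture script", call. = FALSE)
  if (any(posture == "UNRECOGNIZED"))
    stop("posture scripts carry ground truth and cannot contain UNRECOGNIZED",
         call. = FALSE)
  stop_if_not_postures(posture)
  if (any(end <= start)) stop("script segments need end > start", call. = FALSE)
  if (is.unsorted(start) || any(utils::head(end, -1L) > start[-1L] + 1e-9))
    stop("script segments must be ordered and non-overlapping", call. = FALSE)
  structure(data.frame(posture = posture, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("posture_script", "data.frame"))
}

#' Simulate an eight-channel chair recording
#'
#' Produces the voltage trace a test session yields: a no-load calibration
#' segment (chair empty), a seated-P1 calibration segment (all sensors
#' pressed), then the scripted test segment.  During the test, channels
#' marked active in the current posture's activation pattern sit at
#' `v_maxload`, inactive ones at `v_zero`, plus noise and drift; everything
#' is clipped to `[0, supply_max]` (the clipped fraction is recorded in the
#' `clipped_frac` attribute).
#'
#' @param script a [posture_script()]; its time axis starts at the test
#'   segment, i.e. after the calibration segments.
#' @param model a [sensor_model()].
#' @param fs sampling frequency, Hz (default 45).
#' @param seed integer; same seed, same trace.
#' @param calib_len seconds per calibration segment, length 2
#'   `(no_load, seated_p1)` or scalar (default 2 s each).
#' @param lookup [posture_lookup()] used to translate scripted postures into
#'   channel loads.
#' @return An object of class `sensor_trace`: data.frame `t, ats1..ats8`
#'   with attributes `fs`, `segments` (data.frame `segment, start, end`),
#'   `supply_max`, `clipped_frac`.
#' @export
#' @examples
#' tr <- simulate_trace(posture_script("P6", 0, 10),
#'                      sensor_model(noise_sd = 0, seed = 1), seed = 1)
#' range(tr$ats1)  # seat channel pressed during the test
simulate_trace <- function(script, model, fs = 45, seed = NULL,
                           calib_len = c(2, 2), lookup = posture_lookup()) {
  stopifnot(inherits(script, "posture_script"), inherits(model, "sensor_model"))
  if (fs <= 0) stop("sampling frequency must be positive", call. = FALSE)
  calib_len <- rep_len(calib_len, 2L)
  if (any(calib_len <= 0)) stop("calibration segments need positive length",
                                call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  test_len <- max(script$end)
  seg <- data.frame(
    segment = c("no_load", "seated_p1", "test"),
    start = c(0, calib_len[1L], sum(calib_len)),
    end = c(calib_len[1L], sum(calib_len), sum(calib_len) + test_len)
  )
  n <- floor(seg$end[3L] * fs - 1e-9) + 1L
  t <- (seq_len(n) - 1L) / fs

  pat <- attr(lookup, "patterns")
  loaded <- matrix(FALSE, n, 8L)           # TRUE -> channel pressed
  loaded[t >= seg$start[2L] & t < seg$end[2L], ] <- TRUE  # seated-P1 calib
  in_test <- t >= seg$start[3L]
  tt <- t - seg$start[3L]                  # time within the test segment
  for (k in seq_len(nrow(script))) {
    m <- in_test & tt >= script$start[k] - 1e-9 & tt < script$end[k] - 1e-9
    loaded[m, ] <- rep(pat[script$posture[k], ] == 1L, each = sum(m))
  }

  v <- matrix(rep(model$v_zero, each = n), n, 8L)
  v[loaded] <- matrix(rep(model$v_maxload, each = n), n, 8L)[loaded]
  if (any(model$noise_sd > 0))
    v <- v + matrix(rnorm(n * 8L, sd = rep(model$noise_sd, each = n)), n, 8L)
  if (model$drift_rate != 0) v <- v + model$drift_rate * t
  clipped <- v < 0 | v > model$supply_max
  v <- pmin(pmax(v, 0), model$supply_max)

  out <- data.frame(t = t, v)
  names(out) <- c("t", paste0("ats", 1:8))
  structure(out, fs = fs, segments = seg, supply_max = model$supply_max,
            clipped_frac = mean(clipped),
            class = c("sensor_trace", "data.frame"))
}

trace_channels <- function(trace) as.matrix(trace[, paste0("ats", 1:8)])

trace_segment_idx <- function(trace, segment) {
  seg <- attr(trace, "segments")
  row <- seg[seg$segment == segment, ]
  if (nrow(row) == 0L)
    stop("trace has no annotated '", segment, "' segment", call. = FALSE)
  which(trace$t >= row$start & trace$t < row$end)
}

#' Inject a sensor failure into a trace
#'
#' Emulates the hardware faults that force a recording to be discarded:
#' a sensor stuck at its no-load level (`STUCK_ZERO`), stuck at full load
#' (`STUCK_FULL`), or dropping samples (`DROPOUT`, set to `NA`).
#'
#' @param trace a [simulate_trace()] object.
#' @param channel channel index 1..8.
#' @param mode `"STUCK_ZERO"`, `"STUCK_FULL"` or `"DROPOUT"`.
#' @param model the [sensor_model()] supplying the stuck levels; required for
#'   the STUCK modes.
#' @param span `c(start, end)` seconds over which the fault acts (default:
#'   the whole recording).
#' @return the modified trace.
#' @export
inject_failure <- function(trace, channel,
                           mode = c("STUCK_ZERO", "STUCK_FULL", "DROPOUT"),
                           model = NULL, span = NULL) {
  stopifnot(inherits(trace, "sensor_trace"))
  mode <- match.arg(mode)
  if (length(channel) != 1L || channel < 1L || channel > 8L)
    stop("channel must be a single index in 1..8", call. = FALSE)
  idx <- if (is.null(span)) seq_len(nrow(trace)) else
    which(trace$t >= span[1L] & trace$t < span[2L])
  col <- paste0("ats", channel)
  if (mode == "DROPOUT") {
    trace[[col]][idx] <- NA_real_
  } else {
    if (is.null(model))
      stop("STUCK modes need the sensor model for the stuck level", call. = FALSE)
    lvl <- if (mode == "STUCK_ZERO") model$v_zero[channel] else model$v_maxload[channel]
    trace[[col]][idx] <- lvl
  }
  trace
}

#' Generate a cohort of posture triples pinned to two transition tables
#'
#' Builds `N` participants (N = grand total of `table_12`) whose
#' (TI1, TI2) pair counts reproduce `table_12` exactly and whose (TI2, TI3)
#' pair counts reproduce `table_23` exactly.  TI3 is coupled to TI1 only
#' through TI2: within each TI2 posture group the TI3 assignments of
#' `table_23`'s corresponding row are distributed over the group's
#' participants in ascending participant-id order, so the construction is
#' deterministic.
#'
#' @param table_12 8 x 8 counts for the first transition (defaults to the
#'   published cohort, [transition_counts_ti12()]).
#' @param table_23 8 x 8 counts for the second transition; its row margins
#'   must equal `table_12`'s column margins.
#' @return data.frame of class `cohort_fixture` with columns
#'   `participant, ti1, ti2, ti3`.
#' @export
#' @examples
#' cohort <- generate_fixture_cohort()
#' nrow(cohort)  # 83
generate_fixture_cohort <- function(table_12 = transition_counts_ti12(),
                                    table_23 = transition_counts_ti23()) {
  table_12 <- as_transition_table(table_12)
  table_23 <- as_transition_table(table_23)
  mid_out <- colSums(table_12)
  mid_in <- rowSums(table_23)
  if (any(mid_out != mid_in)) {
    bad <- POSTURES[which(mid_out != mid_in)[1L]]
    stop(sprintf(
      "margin mismatch at %s: %d participants reach it in the first transition but %d leave it in the second",
      bad, mid_out[bad], mid_in[bad]), call. = FALSE)
  }
  n <- sum(table_12)
  if (n == 0L)
    return(structure(data.frame(participant = integer(), ti1 = character(),
                                ti2 = character(), ti3 = character(),
                                stringsAsFactors = FALSE),
                     class = c("cohort_fixture", "data.frame")))
  # expand table_12 cells in row-major order -> (ti1, ti2) per participant
  cells <- expand.grid(ti2 = POSTURES, ti1 = POSTURES,
                       stringsAsFactors = FALSE)[, c("ti1", "ti2")]
  reps <- as.vector(t(table_12))
  ti1 <- rep(cells$ti1, reps)
  ti2 <- rep(cells$ti2, reps)
  ti3 <- character(n)
  for (j in POSTURES) {
    grp <- which(ti2 == j)          # ascending participant id
    ti3[grp] <- rep(POSTURES, table_23[j, ])
  }
  structure(data.frame(participant = seq_len(n), ti1 = ti1, ti2 = ti2,
                       ti3 = ti3, stringsAsFactors = FALSE),
            class = c("cohort_fixture", "data.frame"))
}

#' Turn a cohort of posture triples into full chair recordings
#'
#' Each participant's script holds the TI1 posture from test start up to the
#' start of TI2, the TI2 posture up to the start of TI3, and the TI3 posture
#' to the end of the test, so instruction gaps inherit the preceding posture.
#' Per-participant seeds are derived from `seed` plus the participant id.
#'
#' @param cohort a [generate_fixture_cohort()] data.frame (columns
#'   `participant, ti1, ti2, ti3`).
#' @param schedule a [build_schedule()] object.
#' @param model a [sensor_model()].
#' @param seed integer base seed.
#' @param ... passed to [simulate_trace()] (e.g. `calib_len`, `lookup`).
#' @return list of `sensor_trace` objects, one per participant, named by id.
#' @export
cohort_to_traces <- function(cohort, schedule, model, seed = 1, ...) {
  stopifnot(inherits(schedule, "stroop_schedule"))
  if (nrow(cohort) == 0L) return(list())
  w <- interval_windows(schedule)
  total <- total_duration(schedule)
  traces <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    script <- posture_script(
      posture = c(p$ti1, p$ti2, p$ti3),
      start = c(0, w$ti2[["start"]], w$ti3[["start"]]),
      end = c(w$ti2[["start"]], w$ti3[["start"]], total)
    )
    simulate_trace(script, model, seed = (seed + p$participant) %% .Machine$integer.max, ...)
  })
  names(traces) <- cohort$participant
  traces
}
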