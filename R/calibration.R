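#' Per-channel no-load baseline
#'
#' Mean voltage of each channel over the trace's annotated no-load segment,
#' the preliminary acquisition taken with nobody on the chair.
#'
#' @param trace a `sensor_trace`.
#' @param min_len minimum usable segment length in seconds (default 0.5).
#' @return named numeric vector `ats1..ats8`, volts.
#' @export
estimate_vzero <- function(trace, min_len = 0.5) {
  idx <- trace_segment_idx(trace, "no_load")
  if (length(idx) < min_len * attr(trace, "fs"))
    stop("no-load segment shorter than ", min_len, " s", call. = FALSE)
  colMeans(trace_channels(trace)[idx, , drop = FALSE])
}

#' Per-channel full-load baseline
#'
#' Mean voltage over the seated-P1 calibration segment, during which the
#' participant sits fully against the backrest so every sensor is pressed
#' and each channel sits at its loaded level.  The mean (not the per-sample
#' minimum) is used so noise does not bias the baseline downward.
#'
#' @inheritParams estimate_vzero
#' @return named numeric vector `ats1..ats8`, volts.
#' @export
estimate_vmaxload <- function(trace, min_len = 0.5) {
  idx <- trace_segment_idx(trace, "seated_p1")
  if (length(idx) < min_len * attr(trace, "fs"))
    stop("seated-P1 segment shorter than ", min_len, " s", call. = FALSE)
  colMeans(trace_channels(trace)[idx, , drop = FALSE])
}

#' Adaptive activation threshold
#'
#' The activation threshold of a channel sits at 50% of the range between
#' its loaded and unloaded baselines: `v_maxload + 0.5 * (v_zero - v_maxload)`.
#' Vectorised over channels.
#'
#' @param v_zero,v_maxload baselines in volts.
#' @return threshold(s) in volts.
#' @export
#' @examples
#' compute_threshold(3.0, 1.0)  # 2.0
compute_threshold <- function(v_zero, v_maxload) {
  if (any(v_maxload >= v_zero))
    stop("sensor not discriminating: v_maxload must be below v_zero",
         call. = FALSE)
  v_maxload + 0.5 * (v_zero - v_maxload)
}

#' Calibrate a trace: baselines and thresholds for all eight channels
#'
#' Runs [estimate_vzero()], [estimate_vmaxload()] and [compute_threshold()]
#' on the trace's own calibration segments; thresholds are therefore
#' per-channel and per-test.
#'
#' @inheritParams estimate_vzero
#' @return An object of class `calibration_profile`: list with numeric
#'   vectors `v_zero`, `v_maxload`, `threshold` (length 8 each).
#' @export
calibration_profile <- function(trace, min_len = 0.5) {
  vz <- estimate_vzero(trace, min_len)
  vm <- estimate_vmaxload(trace, min_len)
  structure(list(v_zero = vz, v_maxload = vm,
                 threshold = compute_threshold(vz, vm)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("Calibration profile (volts):\n")
  print(round(rbind(v_zero = x$v_zero, v_maxload = x$v_maxload,
                    threshold = x$threshold), 4))
  invisible(x)
}

#' Moving-average low-pass filter
#'
#' Smooths each channel with a centred moving average whose window length is
#' chosen so the filter's -3 dB point falls at `cutoff`:
#' `N = round(0.443 * fs / cutoff)` (N = 20 at 45 Hz and 1 Hz).  The output
#' has the same length as the input; near the edges the window shrinks to
#' the available samples.  `NA` samples propagate (a window containing an
#' `NA` yields `NA`), so sensor dropouts survive filtering.
#'
#' @param trace a `sensor_trace`.
#' @param cutoff -3 dB cutoff frequency, Hz; must be below Nyquist.
#' @return the filtered trace (same class and attributes).
#' @export
moving_average <- function(trace, cutoff = 1) {
  stopifnot(inherits(trace, "sensor_trace"))
  fs <- attr(trace, "fs")
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  n_win <- max(1L, as.integer(round(0.443 * fs / cutoff)))
  before <- (n_win - 1L) %/% 2L
  after <- n_win - 1L - before
  n <- nrow(trace)
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  for (col in paste0("ats", 1:8)) {
    x <- trace[[col]]
    cs <- cumsum(ifelse(is.na(x), 0, x))
    nas <- cumsum(is.na(x))
    tot <- cs[hi] - c(0, cs)[lo]
    bad <- (nas[hi] - c(0, nas)[lo]) > 0L
    out <- tot / (hi - lo + 1L)
    out[bad] <- NA_real_
    trace[[col]] <- out
  }
  trace
}

#' Binary activation series from a filtered trace
#'
#' A channel is active (pressed) at a sample when its filtered voltage lies
#' strictly below the channel threshold — the sensors respond inverted, so
#' pressing pulls the voltage down.  Values exactly at the threshold count
#' as inactive.
#'
#' @param filtered a (typically [moving_average()]-filtered) `sensor_trace`.
#' @param profile a [calibration_profile()].
#' @return An object of class `activation_series`: data.frame `t,
#'   ats1..ats8` of logicals, with the trace's `fs` and `segments`
#'   attributes retained.
#' @export
activation_series <- function(filtered, profile) {
  stopifnot(inherits(filtered, "sensor_trace"),
            inherits(profile, "calibration_profile"))
  if (length(profile$threshold) != 8L)
    stop("profile must cover all 8 channels", call. = FALSE)
  v <- trace_channels(filtered)
  act <- sweep(v, 2L, profile$threshold, `<`)
  out <- data.frame(t = filtered$t, act)
  names(out) <- c("t", paste0("ats", 1:8))
  structure(out, fs = attr(filtered, "fs"),
            segments = attr(filtered, "segments"),
            class = c("activation_series", "data.frame"))
}
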