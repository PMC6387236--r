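#' Default Stroop schedule configuration
#'
#' The timing table of the administered Stroop test: three phases (colour
#' names printed in black, congruent colours, incongruent colours), with the
#' number of words per slide increasing within each phase and a fixed display
#' time per slide.  Twenty-four word slides in total; the test lasts 85 s
#' excluding instruction screens.
#'
#' @return A data.frame with columns `phase` (one of `"BLACK"`,
#'   `"CONGRUENT"`, `"INCONGRUENT"`), `words`, `n_slides`, `seconds`.
#' @export
#' @examples
#' cfg <- default_stroop_config()
#' sum(cfg$n_slides)  # 24 word slides
default_stroop_config <- function() {
  data.frame(
    phase = rep(c("BLACK", "CONGRUENT", "INCONGRUENT"), c(4L, 4L, 6L)),
    words = c(3, 4, 5, 6, 3, 4, 5, 6, 3, 4, 5, 6, 9, 12),
    n_slides = c(2, 2, 1, 1, 2, 2, 1, 1, 2, 2, 2, 2, 2, 2),
    seconds = c(2, 2.5, 3, 3.5, 2, 2.5, 3, 3.5, 2.5, 3, 3.5, 4, 6, 8),
    stringsAsFactors = FALSE
  )
}

PHASES <- c("BLACK", "CONGRUENT", "INCONGRUENT")

#' Build a Stroop schedule from a phase/words/slides/seconds table
#'
#' Expands a configuration table (one row per (phase, word-count) block) into
#' the ordered sequence of slides shown to the participant.  Instruction
#' screens — the initial task instructions and the mid-test instructions
#' shown before the incongruent phase — carry no slides of their own; their
#' durations shift the timing of everything after them.
#'
#' @param config data.frame with columns `phase`, `words`, `n_slides`,
#'   `seconds`; defaults to [default_stroop_config()].
#' @param lead_in seconds of instruction screen before the first slide.
#' @param mid_instruction seconds of instruction screen between the congruent
#'   and incongruent phases.
#' @return An object of class `stroop_schedule`: a list with `slides`
#'   (data.frame `phase`, `words`, `duration`, `start`, `end` — times in
#'   seconds from test start), `lead_in`, `mid_instruction`.
#' @export
#' @examples
#' sched <- build_schedule()
#' nrow(sched$slides)      # 24
#' total_duration(sched)   # 85
build_schedule <- function(config = default_stroop_config(),
                           lead_in = 0, mid_instruction = 0) {
  if (!is.data.frame(config) || nrow(config) == 0L)
    stop("schedule config must be a non-empty data.frame", call. = FALSE)
  need <- c("phase", "words", "n_slides", "seconds")
  if (!all(need %in% names(config)))
    stop("schedule config needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(config$phase %in% PHASES))
    stop("unknown phase token in config", call. = FALSE)
  if (any(config$seconds <= 0) || any(config$words < 1) ||
      any(config$n_slides < 1))
    stop("config rows need positive slide count, word count and duration",
         call. = FALSE)
  if (lead_in < 0 || mid_instruction < 0)
    stop("instruction durations must be non-negative", call. = FALSE)
  ord <- match(config$phase, PHASES)
  if (is.unsorted(ord))
    stop("phases must appear in order BLACK, CONGRUENT, INCONGRUENT",
         call. = FALSE)

  idx <- rep(seq_len(nrow(config)), config$n_slides)
  slides <- data.frame(
    phase = config$phase[idx],
    words = config$words[idx],
    duration = config$seconds[idx],
    stringsAsFactors = FALSE
  )
  # mid-test instruction screen sits just before the first incongruent slide
  first_incon <- match("INCONGRUENT", slides$phase)
  offset <- lead_in +
    if (is.na(first_incon)) 0 else
      c(rep(0, first_incon - 1L),
        rep(mid_instruction, nrow(slides) - first_incon + 1L))
  slides$end <- offset + cumsum(slides$duration)
  slides$start <- slides$end - slides$duration
  slides <- slides[, c("phase", "words", "duration", "start", "end")]

  structure(list(slides = slides, lead_in = lead_in,
                 mid_instruction = mid_instruction),
            class = "stroop_schedule")
}

#' @export
print.stroop_schedule <- function(x, ...) {
  cat(sprintf("Stroop schedule: %d slides, %.1f s total (lead-in %.1f s, mid-instruction %.1f s)\n",
              nrow(x$slides), total_duration(x), x$lead_in, x$mid_instruction))
  tab <- table(factor(x$slides$phase, levels = PHASES))
  cat("  slides per phase:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Total duration of a Stroop schedule
#'
#' Sum of all slide display times plus instruction-screen durations.
#'
#' @param schedule a [build_schedule()] object.
#' @return seconds (numeric scalar).
#' @export
total_duration <- function(schedule) {
  stopifnot(inherits(schedule, "stroop_schedule"))
  sum(schedule$slides$duration) + schedule$lead_in + schedule$mid_instruction
}

#' Derive the three analysis intervals from a Stroop schedule
#'
#' The analysis segments the test into intervals of increasing cognitive
#' engagement: TI1 covers the black and congruent slides (plain reading),
#' TI2 the incongruent slides carrying few words (3–6), TI3 the incongruent
#' slides carrying many words (9–12).  Windows are half-open `[start, end)`
#' in seconds from test start.
#'
#' @param schedule a [build_schedule()] object containing all three phases.
#' @return An object of class `interval_windows`: a named list `ti1`, `ti2`,
#'   `ti3`, each `c(start, end)`.
#' @export
#' @examples
#' w <- interval_windows(build_schedule())
#' vapply(w, diff, numeric(1))  # durations 31, 26, 28
interval_windows <- function(schedule) {
  stopifnot(inherits(schedule, "stroop_schedule"))
  s <- schedule$slides
  if (!all(PHASES %in% s$phase))
    stop("schedule must contain BLACK, CONGRUENT and INCONGRUENT slides",
         call. = FALSE)
  in1 <- s$phase %in% c("BLACK", "CONGRUENT")
  in2 <- s$phase == "INCONGRUENT" & s$words <= 6
  in3 <- s$phase == "INCONGRUENT" & s$words >= 9
  if (!any(in2) || !any(in3))
    stop("incongruent phase must contain both few-word and many-word slides",
         call. = FALSE)
  win <- function(m) c(start = min(s$start[m]), end = max(s$end[m]))
  structure(list(ti1 = win(in1), ti2 = win(in2), ti3 = win(in3)),
            class = "interval_windows")
}

#' @export
print.interval_windows <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%s: [%.1f, %.1f) s  (%.1f s)\n", toupper(nm),
                x[[nm]][["start"]], x[[nm]][["end"]], diff(x[[nm]])))
  invisible(x)
}

#' Read a schedule configuration from YAML or JSON
#'
#' The file holds a list of rows `{phase, words, n_slides, seconds}`.  The
#' packaged default (`system.file("extdata", "stroop_schedule.yaml",
#' package = "sitpose")`) mirrors [default_stroop_config()] exactly.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return data.frame suitable for [build_schedule()].
#' @export
read_schedule_config <- function(path) {
  if (!file.exists(path)) stop("schedule config not found: ", path,
                               call. = FALSE)
  rows <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  else
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  rows$phase <- as.character(rows$phase)
  for (col in c("words", "n_slides", "seconds"))
    rows[[col]] <- as.numeric(rows[[col]])
  rownames(rows) <- NULL
  rows[, c("phase", "words", "n_slides", "seconds")]
}
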