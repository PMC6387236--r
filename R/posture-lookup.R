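#' Activation patterns of the eight recognised sitting postures
#'
#' Each posture is identified by which of the eight pressure sensors are
#' pressed: ATS1–ATS4 on the seat, ATS5–ATS8 on the backrest.  The published
#' pattern table contains one defect: it assigns the identical pattern
#' `11000011` to both P7 ("front of the seat, not leaning on the backrest")
#' and P8 ("front of the seat plus the upper backrest"), contradicting P7's
#' verbal description.  With `corrected_p7 = TRUE` (default) P7 becomes
#' `11000000` — seat front only, no backrest contact — which restores
#' injectivity; `FALSE` keeps the table exactly as published (and
#' [posture_lookup()] will refuse to build a lookup from it).
#'
#' A second oddity: P4 ("right leg crossed, not leaning back") carries the
#' seat half-pattern that P3's description implies, and vice versa for P5.
#' The published patterns are kept by default; `swap_p4_p5 = TRUE` applies
#' the description-consistent variant.
#'
#' @param corrected_p7 logical; repair the duplicated P7 pattern (default TRUE).
#' @param swap_p4_p5 logical; swap the seat halves of P4 and P5 (default FALSE).
#' @return 8 x 8 integer 0/1 matrix, rows P1..P8, columns ATS1..ATS8.
#' @export
#' @examples
#' posture_patterns()["P6", ]  # seat pressed, backrest free
posture_patterns <- function(corrected_p7 = TRUE, swap_p4_p5 = FALSE) {
  pat <- rbind(
    P1 = c(1, 1, 1, 1, 1, 1, 1, 1),
    P2 = c(0, 1, 0, 1, 1, 1, 1, 1),
    P3 = c(1, 0, 1, 0, 1, 1, 1, 1),
    P4 = c(1, 0, 1, 0, 0, 0, 0, 0),
    P5 = c(0, 1, 0, 1, 0, 0, 0, 0),
    P6 = c(1, 1, 1, 1, 0, 0, 0, 0),
    P7 = c(1, 1, 0, 0, 0, 0, 1, 1),
    P8 = c(1, 1, 0, 0, 0, 0, 1, 1)
  )
  colnames(pat) <- paste0("ats", 1:8)
  if (corrected_p7) pat["P7", ] <- c(1, 1, 0, 0, 0, 0, 0, 0)
  if (swap_p4_p5) {
    tmp <- pat["P4", ]
    pat["P4", ] <- pat["P5", ]
    pat["P5", ] <- tmp
  }
  storage.mode(pat) <- "integer"
  pat
}

#' Build the activation-pattern to posture lookup
#'
#' @inheritParams posture_patterns
#' @return An object of class `posture_lookup`: a named character vector
#'   mapping 8-character pattern keys (e.g. `"11110000"`) to posture labels,
#'   with the pattern matrix and flags attached as attributes.
#' @export
#' @examples
#' lk <- posture_lookup()
#' classify_pattern(c(1, 1, 1, 1, 0, 0, 0, 0), lk)  # "P6"
posture_lookup <- function(corrected_p7 = TRUE, swap_p4_p5 = FALSE) {
  pat <- posture_patterns(corrected_p7, swap_p4_p5)
  keys <- apply(pat, 1L, paste, collapse = "")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)]
    clash <- names(keys)[keys %in% dup]
    stop("activation pattern ", dup[1L], " is assigned to more than one posture (",
         paste(clash, collapse = ", "),
         "); use corrected_p7 = TRUE for an injective lookup", call. = FALSE)
  }
  map <- stats::setNames(names(keys), keys)
  structure(map, patterns = pat, corrected_p7 = corrected_p7,
            swap_p4_p5 = swap_p4_p5, class = "posture_lookup")
}

pattern_key <- function(pattern) {
  paste(as.integer(as.logical(pattern)), collapse = "")
}

#' Classify one activation pattern
#'
#' Exact lookup of an ordered 8-bit activation vector; anything outside the
#' eight recognised combinations maps to `"UNRECOGNIZED"`.
#'
#' @param pattern logical or 0/1 vector of length 8 (ATS1..ATS8).
#' @param lookup a [posture_lookup()] object.
#' @return Posture label: `"P1"`..`"P8"` or `"UNRECOGNIZED"`.
#' @export
classify_pattern <- function(pattern, lookup = posture_lookup()) {
  stopifnot(inherits(lookup, "posture_lookup"))
  if (length(pattern) != 8L)
    stop("activation pattern must have exactly 8 channels", call. = FALSE)
  hit <- unname(lookup[pattern_key(pattern)])
  if (is.na(hit)) "UNRECOGNIZED" else hit
}
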