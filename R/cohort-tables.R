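#' Published posture-transition counts for the 83-participant cohort
#'
#' The two 8 x 8 contingency tables of posture transitions observed in the
#' study cohort: rows give the posture in the earlier interval, columns the
#' posture in the later interval.  `transition_counts_ti12()` covers the
#' TI1 to TI2 transition, `transition_counts_ti23()` covers TI2 to TI3.
#' Both sum to 83 participants and their margins are consistent (the TI2
#' margin is shared).  These tables are the reference input for
#' [generate_fixture_cohort()].
#'
#' @return 8 x 8 integer matrix with dimnames P1..P8, class
#'   `transition_table`, attribute `n` = 83.
#' @export
#' @examples
#' sum(transition_counts_ti12())  # 83
transition_counts_ti12 <- function() {
  m <- matrix(c(
    31, 2, 1, 0, 0, 9, 2, 3,
     0, 1, 0, 1, 0, 1, 0, 0,
     2, 0, 1, 0, 0, 1, 0, 1,
     0, 1, 0, 0, 0, 0, 0, 0,
     1, 0, 0, 0, 1, 0, 0, 0,
     3, 0, 0, 0, 0, 2, 0, 1,
     0, 1, 0, 0, 0, 3, 0, 2,
     7, 1, 0, 0, 0, 1, 0, 3
  ), nrow = 8, byrow = TRUE, dimnames = list(POSTURES, POSTURES))
  as_transition_table(m)
}

#' @rdname transition_counts_ti12
#' @export
transition_counts_ti23 <- function() {
  m <- matrix(c(
    14, 0, 0, 1, 0, 21, 1, 7,
     1, 0, 0, 1, 0,  2, 2, 0,
     1, 1, 0, 0, 0,  0, 0, 0,
     0, 0, 0, 0, 0,  1, 0, 0,
     1, 0, 0, 0, 0,  0, 0, 0,
     4, 0, 0, 0, 0,  6, 0, 7,
     0, 0, 0, 0, 0,  0, 1, 1,
     4, 1, 0, 1, 0,  1, 1, 2
  ), nrow = 8, byrow = TRUE, dimnames = list(POSTURES, POSTURES))
  as_transition_table(m)
}

#' Coerce a matrix of counts to a transition table
#'
#' @param m 8 x 8 matrix of non-negative integer counts (rows: earlier
#'   interval posture, columns: later interval posture).
#' @return the matrix with dimnames P1..P8, class `transition_table` and
#'   attribute `n` (participant total).
#' @export
as_transition_table <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(8L, 8L)))
    stop("a transition table is 8 x 8", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("transition counts must be non-negative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(POSTURES, POSTURES)
  structure(m, n = sum(m), class = c("transition_table", class(m)))
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Posture transition table (N = %d)\n", attr(x, "n")))
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}
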