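#' Posture-transition contingency table between two intervals
#'
#' Cell (i, j) counts the participants adopting posture Pi in the earlier
#' interval and Pj in the later one; the diagonal holds the participants who
#' did not move.  All supplied results must have status `"OK"` — excluded
#' participants never enter the statistics.
#'
#' @param results a [classify_cohort()] data.frame (or any data.frame with
#'   posture columns and a `status` column).
#' @param from,to column names of the two intervals (default `"ti1"`,
#'   `"ti2"`).
#' @return a `transition_table` (see [as_transition_table()]).
#' @export
build_transition_table <- function(results, from = "ti1", to = "ti2") {
  if (!is.null(results$status) && any(results$status != "OK"))
    stop("transition tables only accept fully classified (status OK) results",
         call. = FALSE)
  stop_if_not_postures(results[[from]])
  stop_if_not_postures(results[[to]])
  m <- table(factor(results[[from]], levels = POSTURES),
             factor(results[[to]], levels = POSTURES))
  as_transition_table(unclass(m))
}

#' Continuity-corrected McNemar test for one posture pair
#'
#' For a pair (Pi, Pj), `b` participants moved i to j and `c` moved j to i
#' between the two intervals; the test asks whether the flow is symmetric.
#' The statistic is the Edwards-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` with 1 df, with *no* clamping of the
#' corrected difference at zero — when `b = c` the numerator is `(-1)^2 = 1`.
#' Alternative conventions are available: `"uncorrected"` uses
#' `(b - c)^2 / (b + c)`; `"exact"` uses the two-sided exact binomial test
#' of `b` successes in `b + c` trials at p = 1/2.
#'
#' @param b,c discordant counts (non-negative integers, `b + c > 0`).
#' @param variant `"cc"` (default), `"uncorrected"` or `"exact"`.
#' @return An object of class `mcnemar_result`: list with `b`, `c`,
#'   `statistic` (`NA` for the exact variant), `df`, `p`, `variant`.
#' @export
#' @examples
#' mcnemar_cc(9, 3)$statistic  # 25/12
mcnemar_cc <- function(b, c, variant = c("cc", "uncorrected", "exact")) {
  variant <- match.arg(variant)
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("discordant counts must be non-negative integers", call. = FALSE)
  if (b + c == 0)
    stop("no discordant pairs: McNemar test undefined for b + c = 0",
         call. = FALSE)
  if (variant == "exact") {
    p <- binom.test(b, b + c, p = 0.5)$p.value
    stat <- NA_real_
  } else {
    num <- if (variant == "cc") (abs(b - c) - 1)^2 else (b - c)^2
    stat <- num / (b + c)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c, statistic = stat, df = 1L, p = p,
                 variant = variant),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b=%d c=%d, X^2=%s, p=%s\n", x$variant, x$b, x$c,
              if (is.na(x$statistic)) "-" else format(round(x$statistic, 4)),
              format_p(x$p)))
  invisible(x)
}

#' Display rounding for p-values
#'
#' Rounds to `digits` decimals for tabulation.  Chi-square tails of
#' half-integer statistics land exactly on half-points of the display grid
#' (e.g. 0.4795 for a corrected statistic of 0.5); such boundary values are
#' tabulated rounding toward zero, the convention of truncating displays, so
#' a (1,1) discordant pair shows as 0.479.
#'
#' @param p numeric vector of probabilities.
#' @param digits display decimals (default 3).
#' @return numeric vector of rounded values.
#' @export
round_p <- function(p, digits = 3) {
  scaled <- p * 10^digits
  at_half <- abs(scaled - floor(scaled) - 0.5) < 1e-3
  ifelse(at_half, floor(scaled) / 10^digits, round(p, digits))
}

format_p <- function(p) {
  ifelse(p < 0.001, sprintf("%.4f", round_p(p, 4)), sprintf("%.3f", round_p(p, 3)))
}

#' Posture pairs eligible for pairwise McNemar testing
#'
#' A pair enters the pairwise analysis only when the eligibility condition
#' holds: both discordant counts are strictly positive (`min(b, c) >= 1`).
#' Pairs in which all movement runs one way (or none) are excluded.
#'
#' @param table a `transition_table`.
#' @return data.frame with columns `from`, `to` (`from < to` in posture
#'   order), `b` (count from-to), `c` (count to-from).
#' @export
#' @examples
#' eligible_pairs(transition_counts_ti12())$from
eligible_pairs <- function(table) {
  table <- as_transition_table(table)
  out <- list()
  for (i in 1:7) for (j in (i + 1):8) {
    b <- table[i, j]; c <- table[j, i]
    if (min(b, c) >= 1L)
      out[[length(out) + 1L]] <- data.frame(
        from = POSTURES[i], to = POSTURES[j], b = b, c = c,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(from = character(), to = character(),
                      b = integer(), c = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Pairwise McNemar tests over all eligible pairs of a transition table
#'
#' @param table a `transition_table`.
#' @param variant passed to [mcnemar_cc()].
#' @return data.frame `from, to, b, c, statistic, p, p_display, band`;
#'   `band` labels each result `"significant"` (p < 0.05),
#'   `"of interest"` (0.05 <= p < 0.10) or `"ns"`.
#' @export
mcnemar_pairs <- function(table, variant = "cc") {
  pairs <- eligible_pairs(table)
  if (nrow(pairs) == 0L) {
    pairs$statistic <- numeric()
    pairs$p <- numeric()
    pairs$p_display <- character()
    pairs$band <- character()
    return(pairs)
  }
  tests <- Map(mcnemar_cc, pairs$b, pairs$c, MoreArgs = list(variant = variant))
  pairs$statistic <- vapply(tests, `[[`, numeric(1), "statistic")
  pairs$p <- vapply(tests, `[[`, numeric(1), "p")
  pairs$p_display <- format_p(pairs$p)
  pairs$band <- ifelse(pairs$p < 0.05, "significant",
                       ifelse(pairs$p < 0.10, "of interest", "ns"))
  pairs
}

#' Bowker's global test of symmetry
#'
#' Tests whether the transition table is symmetric (no net directional
#' posture flow): `X^2 = sum over i < j of (n_ij - n_ji)^2 / (n_ij + n_ji)`,
#' summing only the pairs with `n_ij + n_ji > 0`; the degrees of freedom
#' equal the number of pairs included.
#'
#' @param table a `transition_table` with at least one discordant pair.
#' @return An object of class `bowker_result`: list `statistic`, `df`, `p`.
#' @export
bowker <- function(table) {
  table <- as_transition_table(table)
  stat <- 0
  df <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    s <- table[i, j] + table[j, i]
    if (s > 0L) {
      stat <- stat + (table[i, j] - table[j, i])^2 / s
      df <- df + 1L
    }
  }
  if (df == 0L)
    stop("fully diagonal table: no off-diagonal movement to test",
         call. = FALSE)
  structure(list(statistic = stat, df = df,
                 p = pchisq(stat, df = df, lower.tail = FALSE)),
            class = "bowker_result")
}

#' @export
print.bowker_result <- function(x, ...) {
  cat(sprintf("Bowker symmetry: X^2 = %.3f, df = %d, p = %s\n",
              x$statistic, x$df, format_p(x$p)))
  invisible(x)
}

#' Posture distribution in one interval
#'
#' @param results OK-status [classify_cohort()] rows.
#' @param interval `"ti1"`, `"ti2"` or `"ti3"`.
#' @return named numeric vector of proportions over P1..P8 (sums to 1).
#' @export
interval_distribution <- function(results, interval) {
  if (nrow(results) == 0L) stop("no participants", call. = FALSE)
  if (!is.null(results$status) && any(results$status != "OK"))
    stop("distributions only accept fully classified results", call. = FALSE)
  x <- results[[interval]]
  stop_if_not_postures(x)
  tab <- table(factor(x, levels = POSTURES))
  stats::setNames(as.vector(tab) / sum(tab), POSTURES)
}

#' Classify a posture triple as no-transition, monotonic or non-monotonic
#'
#' Across the three intervals a participant either never moves
#' (`NO_TRANSITION`), moves without ever revisiting a departed posture
#' (`MONOTONIC`), or returns to a posture previously left — with three
#' intervals, necessarily the starting one (`NON_MONOTONIC`).
#'
#' @param triple character vector of three posture labels.
#' @return one of `"NO_TRANSITION"`, `"MONOTONIC"`, `"NON_MONOTONIC"`.
#' @export
#' @examples
#' classify_triple(c("P1", "P6", "P1"))  # NON_MONOTONIC
classify_triple <- function(triple) {
  stopifnot(length(triple) == 3L)
  stop_if_not_postures(triple)
  if (triple[1L] == triple[2L] && triple[2L] == triple[3L]) "NO_TRANSITION"
  else if (triple[3L] == triple[1L] && triple[2L] != triple[1L]) "NON_MONOTONIC"
  else "MONOTONIC"
}

#' Full transition report for a classified cohort
#'
#' Bundles everything the transition analysis produces: both contingency
#' tables, pairwise McNemar results over the eligible pairs, Bowker global
#' symmetry tests, per-interval posture distributions, and the triple
#' classification counts.
#'
#' @param results OK-status [classify_cohort()] rows.
#' @param variant McNemar variant, see [mcnemar_cc()].
#' @return An object of class `transition_report`: nested list with blocks
#'   `n`, `transition_tables`, `mcnemar`, `bowker`, `distributions`,
#'   `triples`.
#' @export
transition_report <- function(results, variant = "cc") {
  results <- ok_results(results)
  if (nrow(results) == 0L) stop("no OK participants to analyse", call. = FALSE)
  t12 <- build_transition_table(results, "ti1", "ti2")
  t23 <- build_transition_table(results, "ti2", "ti3")
  bw <- function(tab) tryCatch({
    b <- bowker(tab)
    list(statistic = b$statistic, df = b$df, p = b$p)
  }, error = function(e) NULL)
  triples <- vapply(seq_len(nrow(results)), function(i)
    classify_triple(c(results$ti1[i], results$ti2[i], results$ti3[i])),
    character(1))
  triple_counts <- table(factor(triples, levels = c(
    "NO_TRANSITION", "MONOTONIC", "NON_MONOTONIC")))
  structure(list(
    n = nrow(results),
    transition_tables = list(ti1_ti2 = t12, ti2_ti3 = t23),
    mcnemar = list(ti1_ti2 = mcnemar_pairs(t12, variant),
                   ti2_ti3 = mcnemar_pairs(t23, variant)),
    bowker = list(ti1_ti2 = bw(t12), ti2_ti3 = bw(t23)),
    distributions = list(ti1 = interval_distribution(results, "ti1"),
                         ti2 = interval_distribution(results, "ti2"),
                         ti3 = interval_distribution(results, "ti3")),
    triples = as.list(triple_counts)
  ), class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("Transition report, %d participants\n", x$n))
  for (nm in names(x$mcnemar)) {
    cat(sprintf("\n%s pairwise McNemar (%d eligible pairs):\n",
                toupper(gsub("_", "-", nm)), nrow(x$mcnemar[[nm]])))
    print(x$mcnemar[[nm]][, c("from", "to", "b", "c", "p_display", "band")],
          row.names = FALSE)
    if (!is.null(x$bowker[[nm]]))
      cat(sprintf("  Bowker: X^2 = %.3f, df = %d, p = %s\n",
                  x$bowker[[nm]]$statistic, x$bowker[[nm]]$df,
                  format_p(x$bowker[[nm]]$p)))
  }
  cat("\nTriples:",
      paste(sprintf("%s=%d", names(x$triples), unlist(x$triples)),
            collapse = ", "), "\n")
  invisible(x)
}
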