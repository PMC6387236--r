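test_that("transition tables count posture pairs cell by cell", {
  cohort <- generate_fixture_cohort()
  res <- results_from_triples(split(as.matrix(cohort[, c("ti1", "ti2", "ti3")]),
                                    seq_len(nrow(cohort))))
  t12 <- build_transition_table(res, "ti1", "ti2")
  expect_equal(t12["P1", "P1"], 31L, ignore_attr = TRUE)
  expect_equal(t12["P8", "P1"], 7L, ignore_attr = TRUE)
  expect_equal(unclass(t12)[,], unclass(transition_counts_ti12())[,])
  expect_equal(attr(t12, "n"), 83L)

  same <- results_from_triples(rep(list(c("P1", "P1", "P1")), 3))
  tt <- build_transition_table(same)
  expect_equal(tt["P1", "P1"], 3L, ignore_attr = TRUE)
  expect_equal(sum(tt), 3L)

  empty <- results_from_triples(list(c("P1", "P1", "P1")))[0, ]
  expect_equal(sum(build_transition_table(empty)), 0L)
})

test_that("non-OK participants are refused by the table builder", {
  res <- results_from_triples(list(c("P1", "P6", "P8")))
  res$status <- "SENSOR_FAILURE"
  expect_error(build_transition_table(res), "OK")
})

test_that("the continuity-corrected McNemar statistic matches the published convention", {
  r <- mcnemar_cc(9, 3)
  expect_equal(r$statistic, 25 / 12)
  expect_equal(round_p(r$p), 0.149)
  # b = c: the corrected difference is NOT clamped at zero
  r11 <- mcnemar_cc(1, 1)
  expect_equal(r11$statistic, 0.5)
  expect_equal(round_p(r11$p), 0.479)
  # |b - c| = 1: corrected difference 0
  r12 <- mcnemar_cc(1, 2)
  expect_equal(r12$statistic, 0)
  expect_equal(r12$p, 1)
  expect_error(mcnemar_cc(0, 0), "discordant")
})

test_that("McNemar is symmetric in (b, c) and monotone in the imbalance", {
  for (b in 0:6) for (c in 0:6) {
    if (b + c == 0) next
    expect_equal(mcnemar_cc(b, c)$statistic, mcnemar_cc(c, b)$statistic)
    expect_equal(mcnemar_cc(b, c)$p, mcnemar_cc(c, b)$p)
  }
  # at fixed b + c the statistic is non-decreasing in |b - c| (the unclamped
  # correction makes |b - c| = 0 and 2 coincide, so not strictly)
  tot <- 10
  stats <- vapply(0:5, function(c) mcnemar_cc(tot - c, c)$statistic, numeric(1))
  expect_true(all(diff(stats) <= 0))  # c rising -> imbalance falling
  ps <- vapply(0:5, function(c) mcnemar_cc(tot - c, c)$p, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("the corrected statistic agrees with the base-R McNemar test when b != c", {
  # stats::mcnemar.test applies the same Edwards correction on asymmetric
  # 2x2 tables but silently drops it when b = c, where the conventions
  # diverge; cross-check on the asymmetric configurations
  for (bc in list(c(9, 3), c(3, 7), c(21, 4), c(7, 1), c(1, 2))) {
    ours <- mcnemar_cc(bc[1], bc[2])
    ref <- stats::mcnemar.test(matrix(c(5, bc[2], bc[1], 5), 2))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, unname(ref$p.value))
  }
})

test_that("exact and uncorrected variants are available but distinct", {
  expect_equal(mcnemar_cc(1, 1, variant = "uncorrected")$statistic, 0)
  ex <- mcnemar_cc(9, 3, variant = "exact")
  expect_equal(ex$p, stats::binom.test(9, 12, 0.5)$p.value)
  expect_true(is.na(ex$statistic))
})

test_that("pair eligibility requires both discordant counts positive", {
  e12 <- eligible_pairs(transition_counts_ti12())
  expect_equal(paste(e12$from, e12$to, sep = "-"),
               c("P1-P3", "P1-P6", "P1-P8", "P2-P4", "P6-P8"))
  e23 <- eligible_pairs(transition_counts_ti23())
  expect_equal(paste(e23$from, e23$to, sep = "-"),
               c("P1-P6", "P1-P8", "P6-P8", "P7-P8"))
  diag_only <- diag(8)
  expect_equal(nrow(eligible_pairs(diag_only)), 0)
})

test_that("pairwise p-values reproduce the published tables after display rounding", {
  m12 <- mcnemar_pairs(transition_counts_ti12())
  expect_equal(m12$p_display, c("1.000", "0.149", "0.343", "0.479", "0.479"))
  m23 <- mcnemar_pairs(transition_counts_ti23())
  expect_equal(m23$p_display, c("0.001", "0.546", "0.077", "0.479"))
  expect_equal(m23$band, c("significant", "ns", "of interest", "ns"))
})

test_that("Bowker equals the brute-force pairwise sum and standard df", {
  for (tab in list(transition_counts_ti12(), transition_counts_ti23())) {
    got <- bowker(tab)
    ref <- bowker_brute(unclass(tab)[,])
    expect_equal(got$statistic, ref$stat)
    expect_equal(got$df, ref$df)
    expect_equal(got$p, pchisq(ref$stat, ref$df, lower.tail = FALSE))
  }
  # identity: the statistic is the sum of UNcorrected pairwise McNemar
  # statistics over pairs with any discordance
  tab <- transition_counts_ti23()
  acc <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    if (tab[i, j] + tab[j, i] > 0)
      acc <- acc + mcnemar_cc(tab[i, j], tab[j, i],
                              variant = "uncorrected")$statistic
  }
  expect_equal(bowker(tab)$statistic, acc)
})

test_that("Bowker handles symmetric, minimal and degenerate tables", {
  sym <- matrix(0L, 8, 8)
  sym[1, 2] <- sym[2, 1] <- 3L
  sym[3, 5] <- sym[5, 3] <- 1L
  b <- bowker(sym)
  expect_equal(b$statistic, 0)
  expect_equal(b$p, 1)
  single <- matrix(0L, 8, 8)
  single[1, 2] <- 2L
  b1 <- bowker(single)
  expect_equal(b1$statistic, 2)
  expect_equal(b1$df, 1L)
  expect_error(bowker(diag(8)), "diagonal")
})

test_that("interval distributions match the cohort margins", {
  cohort <- generate_fixture_cohort()
  res <- cohort
  res$status <- "OK"
  d2 <- interval_distribution(res, "ti2")
  expect_equal(sum(d2), 1)
  expect_equal(round(100 * d2[["P1"]]), 53)
  d3 <- interval_distribution(res, "ti3")
  expect_equal(round(100 * d3[["P1"]]), 30)
  expect_equal(round(100 * sum(d3[c("P6", "P7", "P8")])), 64)
  one <- results_from_triples(list(c("P1", "P1", "P1")))
  expect_equal(interval_distribution(one, "ti1")[["P1"]], 1)
  expect_error(interval_distribution(one[0, ], "ti1"), "no participants")
})

test_that("posture triples classify as no-transition, monotonic or non-monotonic", {
  expect_equal(classify_triple(c("P1", "P1", "P1")), "NO_TRANSITION")
  expect_equal(classify_triple(c("P1", "P6", "P1")), "NON_MONOTONIC")
  expect_equal(classify_triple(c("P1", "P6", "P8")), "MONOTONIC")
  expect_equal(classify_triple(c("P1", "P1", "P6")), "MONOTONIC")
  expect_equal(classify_triple(c("P1", "P6", "P6")), "MONOTONIC")
  # exhaustive: NON_MONOTONIC iff start revisited after leaving
  for (a in c("P1", "P2")) for (b in c("P1", "P2", "P3"))
    for (c in c("P1", "P2", "P3")) {
      cls <- classify_triple(c(a, b, c))
      if (a == b && b == c) expect_equal(cls, "NO_TRANSITION")
      else if (a == c && a != b) expect_equal(cls, "NON_MONOTONIC")
      else expect_equal(cls, "MONOTONIC")
    }
})

test_that("the transition report bundles all analysis blocks deterministically", {
  cohort <- generate_fixture_cohort()
  res <- cohort
  res$status <- "OK"
  rep1 <- transition_report(res)
  expect_equal(rep1$n, 83)
  expect_equal(nrow(rep1$mcnemar$ti1_ti2), 5)
  expect_equal(nrow(rep1$mcnemar$ti2_ti3), 4)
  expect_equal(sum(unlist(rep1$triples)), 83)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report_json(rep1, f1)
  write_report_json(transition_report(res), f2)
  expect_identical(readLines(f1), readLines(f2))
  # margin conservation on fixture data: TI1-TI2 column sums = TI2-TI3 row sums
  expect_equal(colSums(rep1$transition_tables$ti1_ti2),
               rowSums(rep1$transition_tables$ti2_ti3))
})
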