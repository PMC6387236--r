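test_that("baselines are segment means and recover the model exactly when noiseless", {
  m <- flat_model()
  tr <- one_posture_trace("P6", model = m)
  expect_equal(unname(estimate_vzero(tr)), rep(3.0, 8))
  expect_equal(unname(estimate_vmaxload(tr)), rep(1.0, 8))
  pr <- calibration_profile(tr)
  expect_equal(unname(pr$threshold), rep(2.0, 8))
})

test_that("noisy baseline estimates concentrate at the standard-error rate", {
  # 2 s at 45 Hz = 90 samples; mean of N(3, 0.05^2) is within
  # 3 * 0.05 / sqrt(90) of 3 with probability ~0.997 per channel
  m <- flat_model(noise_sd = 0.05)
  tr <- one_posture_trace("P1", model = m, seed = 2024)
  vz <- estimate_vzero(tr)
  expect_true(all(abs(vz - 3.0) < 4 * 0.05 / sqrt(90)))
})

test_that("traces without usable calibration segments are rejected", {
  m <- flat_model()
  tr <- one_posture_trace("P1", model = m)
  seg <- attr(tr, "segments")
  attr(tr, "segments") <- seg[seg$segment != "no_load", ]
  expect_error(estimate_vzero(tr), "no_load")
  short <- one_posture_trace("P1", model = m)
  attr(short, "segments")$end[2] <- attr(short, "segments")$start[2] + 0.2
  expect_error(estimate_vmaxload(short), "shorter")
})

test_that("the activation threshold is the midpoint of the baseline range", {
  expect_equal(compute_threshold(3.0, 1.0), 2.0)
  expect_equal(compute_threshold(3.3, 1.1), 2.2)
  expect_error(compute_threshold(1.0, 1.0), "discriminating")
  # vectorised over channels
  expect_equal(compute_threshold(c(3, 3.3), c(1, 1.1)), c(2, 2.2))
  # invariant under affine rescaling of both baselines
  a <- 1.7; b <- 0.3
  expect_equal(compute_threshold(a * 3.0 + b, a * 1.0 + b),
               a * compute_threshold(3.0, 1.0) + b)
})

test_that("moving average has unit DC gain and the designed kernel", {
  m <- flat_model()
  tr <- one_posture_trace("P1", model = m, secs = 5)
  filt <- moving_average(tr, 1)
  # constants (within each long segment, away from edges) are unchanged
  inner <- tr$t > 2.5 & tr$t < 3.5
  expect_equal(filt$ats1[inner], tr$ats1[inner])
  # filtering twice changes nothing on constants (idempotent on DC)
  expect_equal(moving_average(filt, 1)$ats1[inner], filt$ats1[inner])

  # unit impulse -> plateau of 1/N with N = round(0.443 * 45 / 1) = 20
  tr0 <- tr
  for (ch in paste0("ats", 1:8)) tr0[[ch]] <- 0
  tr0$ats1[100] <- 1
  imp <- moving_average(tr0, 1)$ats1
  expect_equal(max(imp), 1 / 20)
  expect_equal(sum(imp > 0), 20)
})

test_that("the 1 Hz gain matches the Dirichlet-kernel closed form", {
  m <- flat_model()
  tr <- one_posture_trace("P1", model = m, secs = 20)
  f <- 1; fs <- 45
  for (ch in paste0("ats", 1:8)) tr[[ch]] <- sin(2 * pi * f * tr$t)
  filt <- moving_average(tr, 1)
  # fit amplitude on interior samples (full windows only)
  keep <- seq(30, nrow(tr) - 30)
  X <- cbind(sin(2 * pi * f * tr$t[keep]), cos(2 * pi * f * tr$t[keep]))
  beta <- qr.solve(X, filt$ats1[keep])
  gain <- sqrt(sum(beta^2))
  expect_equal(gain, ma_gain(f, fs, 20), tolerance = 1e-6)
  expect_equal(ma_gain(f, fs, 20), 0.7059, tolerance = 1e-4)
})

test_that("cutoff at or above Nyquist is rejected", {
  tr <- one_posture_trace("P1", model = flat_model())
  expect_error(moving_average(tr, 22.5), "Nyquist")
})

test_that("NA samples propagate through the filter", {
  m <- flat_model()
  tr <- inject_failure(one_posture_trace("P1", model = m), 3, "DROPOUT",
                       span = c(5, 6))
  filt <- moving_average(tr, 1)
  expect_true(anyNA(filt$ats3))
  expect_false(anyNA(filt$ats2))
  # NA region is the dropout dilated by the window, not the whole trace
  expect_false(anyNA(filt$ats3[filt$t < 4.5]))
})

test_that("activation is strict: below threshold pressed, at threshold not", {
  m <- flat_model()
  tr <- one_posture_trace("P6", model = m)
  pr <- calibration_profile(tr)  # thresholds exactly 2.0
  raw <- tr
  act <- activation_series(raw, pr)  # unfiltered: values exactly 1 or 3
  test_idx <- raw$t >= 4
  expect_true(all(act$ats1[test_idx]))        # 1.0 < 2.0
  expect_true(all(!act$ats5[test_idx]))       # 3.0 > 2.0
  # value exactly at the threshold counts as inactive
  at_thr <- raw
  at_thr$ats1[] <- 2.0
  expect_true(all(!activation_series(at_thr, pr)$ats1))
})

test_that("noiseless posture segments reproduce the activation pattern at every interior sample", {
  m <- flat_model()
  pat <- posture_patterns()
  for (p in rownames(pat)) {
    tr <- one_posture_trace(p, secs = 5, model = m)
    act <- activation_series(moving_average(tr, 1), calibration_profile(tr))
    interior <- act$t > 4.5 & act$t < 8.5  # > N samples clear of boundaries
    got <- as.matrix(act[interior, paste0("ats", 1:8)])
    expect_true(all(got == matrix(pat[p, ] == 1, sum(interior), 8,
                                  byrow = TRUE)), info = p)
  }
})
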