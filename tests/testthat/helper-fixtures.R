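# Shared fixtures: built in code, nothing read from disk.

# noiseless model with fixed, easy-to-reason-about baselines
flat_model <- function(v_zero = 3.0, v_maxload = 1.0, noise_sd = 0, ...) {
  sensor_model(v_zero = rep(v_zero, 8), v_maxload = rep(v_maxload, 8),
               noise_sd = noise_sd, ...)
}

# single-posture trace with default 2 s calibration segments
one_posture_trace <- function(posture = "P1", secs = 10, model = flat_model(),
                              fs = 45, seed = 1) {
  simulate_trace(posture_script(posture, 0, secs), model, fs = fs, seed = seed)
}

# tiny all-OK results table from posture triples
results_from_triples <- function(triples) {
  df <- as.data.frame(do.call(rbind, triples), stringsAsFactors = FALSE)
  names(df) <- c("ti1", "ti2", "ti3")
  df$participant <- as.character(seq_len(nrow(df)))
  df$status <- "OK"
  df[, c("participant", "ti1", "ti2", "ti3", "status")]
}

# brute-force Bowker oracle: direct double loop over all 28 posture pairs
bowker_brute <- function(m) {
  stat <- 0; df <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    s <- m[i, j] + m[j, i]
    if (s > 0) {
      stat <- stat + (m[i, j] - m[j, i])^2 / s
      df <- df + 1
    }
  }
  list(stat = stat, df = df)
}

# Dirichlet-kernel closed form for the moving-average amplitude gain
ma_gain <- function(f, fs, n_win) {
  abs(sin(pi * f * n_win / fs) / (n_win * sin(pi * f / fs)))
}
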