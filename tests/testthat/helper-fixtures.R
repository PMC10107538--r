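# Programmatic fixtures shared across test files.  Everything is generated
# in code; no binary data ships with the package.

# multichannel sinusoid recording
sine_rec <- function(freq = 5, amp = 10, dur = 120, fs = 256,
                     channels = c("F3", "F4", "C3", "C4"), phase = 0) {
  t <- seq_len(dur * fs) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * t + phase), length(channels)),
              ncol = length(channels))
  eeg_recording(x, fs, channels)
}

# band-limited (or raw) Gaussian noise recording
noise_rec <- function(sd = 10, dur = 120, fs = 256,
                      channels = c("F3", "F4"), seed = 1, band = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(dur * fs * length(channels), sd = sd),
              ncol = length(channels))
  rec <- eeg_recording(x, fs, channels)
  if (!is.null(band))
    rec <- eeg_recording(neoseize:::band_filter(rec, band), fs, channels)
  rec
}

# constructed burst-suppression: burst_s at burst_amp (noise SD), supp_s at
# supp_amp, n_cycles cycles
bs_rec <- function(burst_s = 5, supp_s = 20, burst_amp = 50, supp_amp = 1,
                   n_cycles = 10, fs = 256, channels = c("F3", "F4"),
                   seed = 3) {
  set.seed(seed)
  env <- rep(c(rep(burst_amp, burst_s * fs), rep(supp_amp, supp_s * fs)),
             n_cycles)
  x <- matrix(rnorm(length(env) * length(channels)),
              ncol = length(channels)) * env
  eeg_recording(x, fs, channels)
}

# small labelled feature matrix with a separable signal
toy_design <- function(n = 40, p = 8, shift = 2, prev = 0.4, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, prev)
  while (sum(y) < 3 || sum(1 - y) < 3) y <- rbinom(n, 1, prev)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:3] <- X[, 1:3] + shift * y
  rownames(X) <- sprintf("S%03d", seq_len(n))
  list(X = X, y = y)
}

prediction_set <- function(prob, label) {
  data.frame(subject_id = seq_along(prob), probability = prob, label = label)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
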