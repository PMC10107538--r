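# EDF round trips, epoch selection, artifact masking, aEEG montage.

test_that("EDF write/read round-trips labels, rate, length and amplitudes", {
  set.seed(2)
  fs <- 256
  labs <- c("F3", "F4", "C3", "C4", "Cz", "T3", "T4", "O1", "O2")
  d <- matrix(rnorm(fs * 20 * 9, sd = 30), ncol = 9)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, d, fs, labs)
  r <- read_edf(f)
  expect_identical(r$channel_labels, labs)
  expect_equal(r$fs, fs)
  expect_equal(nrow(r$data), nrow(d))
  # quantization-step oracle: physical range is max|x| * 1.001, 16 bits
  step <- 2 * max(abs(d)) * 1.001 / 65535
  expect_lt(max(abs(r$data - d)), step)

  # 10 uV sine: error below 0.1 uV and below one quantization step
  t <- seq_len(fs * 10) / fs
  s <- matrix(10 * sin(2 * pi * 3 * t), ncol = 1)
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(f2, s, fs, "C3")
  r2 <- read_edf(f2)
  expect_lt(max(abs(r2$data - s)), 0.1)
  expect_lt(max(abs(r2$data - s)), 2 * 10 * 1.001 / 65535)
})

test_that("read_eeg normalizes labels and enforces montage presence", {
  set.seed(3)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, matrix(rnorm(256 * 5 * 4), ncol = 4), 256,
            c("EEG F3-REF", "EEG C3-REF", "EEG F4-REF", "EEG C4-REF"))
  rec <- read_eeg(f)
  expect_setequal(rec$channel_labels, c("F3", "C3", "F4", "C4"))
  expect_equal(ncol(rec$data), 4)

  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(f2, matrix(rnorm(256 * 5 * 2), ncol = 2), 256,
            c("ECG", "EMG chin"))
  expect_error(read_eeg(f2), "fewer than two montage channels")
})

test_that("select_epoch honours age limit, seizure guard and usability", {
  rec <- noise_rec(dur = 4 * 3600, fs = 256, channels = "C3", seed = 4)
  rec$age_at_start <- 3

  ep <- select_epoch(rec)
  expect_equal(ep$start_age_h, 3)           # earliest window

  # first seizure at 9 h: any selected epoch must end at or before 8 h
  sz <- seizure_annotation(cbind(9, 10))
  ep2 <- select_epoch(rec, sz)
  expect_lte(ep2$start_age_h + 1, 8 + 1e-9)

  rec$age_at_start <- 13                    # entirely after 12 h of age
  expect_error(select_epoch(rec), "after 12 h of age")
  rec$age_at_start <- 3
  expect_error(select_epoch(rec, seizure_annotation(cbind(3.5, 4))),
               "first seizure")

  # deterministic and idempotent
  expect_identical(select_epoch(rec), select_epoch(rec))
})

test_that("relaxing min_usable never selects a later epoch", {
  for (seed in 1:5) {
    set.seed(seed)
    n_art <- 4
    a0 <- sort(runif(n_art, 0, 3.5 * 3600))
    ai <- cbind(a0, a0 + runif(n_art, 300, 1500))
    rec <- noise_rec(dur = 4 * 3600, fs = 250, channels = "C3", seed = seed)
    rec$artifact_intervals <- neoseize:::normalize_intervals(ai)
    rec$age_at_start <- 2
    starts <- vapply(c(0.9, 0.7, 0.5, 0.3), function(mu) {
      tryCatch(select_epoch(rec, min_usable = mu)$start_age_h,
               error = function(e) Inf)
    }, 0)
    expect_true(all(diff(starts) <= 1e-9))
  }
})

test_that("mask_artifacts crops, flags and preserves clean content", {
  rec <- noise_rec(dur = 600, fs = 250, channels = c("F3", "F4"), seed = 5)
  rec$age_at_start <- 3
  ep <- select_epoch(rec, duration_s = 300)
  m <- mask_artifacts(rec, ep)
  expect_equal(nrow(m$data), 300 * 250)
  expect_true(all(m$mask))
  expect_equal(m$data, rec$data[seq_len(300 * 250), ])

  rec$artifact_intervals <- neoseize:::normalize_intervals(cbind(0, 150))
  ep2 <- select_epoch(rec, duration_s = 300, min_usable = 0.4)
  expect_equal(ep2$usable_fraction, 0.5)
  m2 <- mask_artifacts(rec, ep2)
  expect_equal(mean(m2$mask), 0.5)
})

test_that("masked corrupted segment leaves band power nearly unchanged", {
  fs <- 256
  t <- seq_len(fs * 300) / fs
  clean <- matrix(10 * sin(2 * pi * 3 * t), ncol = 1)
  rec_clean <- eeg_recording(clean, fs, "C3")
  p_clean <- spectral_powers(rec_clean)$power["delta"]

  corrupted <- clean
  third <- (fs * 100 + 1):(fs * 200)
  corrupted[third, 1] <- corrupted[third, 1] + rnorm(length(third), sd = 300)
  rec_cor <- eeg_recording(corrupted, fs, "C3",
                           artifact_intervals = cbind(100, 200))
  ep <- select_epoch(rec_cor, duration_s = 300, min_usable = 0.5)
  m <- mask_artifacts(rec_cor, ep)
  p_masked <- spectral_powers(m)$power["delta"]
  expect_lt(abs(p_masked - p_clean) / p_clean, 0.05)
})

test_that("aEEG montage is the elementwise bipolar difference", {
  set.seed(6)
  x <- matrix(rnorm(256 * 10 * 4), ncol = 4)
  rec <- eeg_recording(x, 256, c("F3", "C3", "F4", "C4"))
  ae <- to_aeeg_montage(rec)
  expect_equal(ncol(ae$data), 2)
  expect_equal(ae$data[, 1], x[, 1] - x[, 2])
  expect_equal(ae$data[, 2], x[, 3] - x[, 4])

  # F3 == C3 -> left bipolar channel identically zero
  x2 <- x; x2[, 2] <- x2[, 1]
  ae2 <- to_aeeg_montage(eeg_recording(x2, 256, c("F3", "C3", "F4", "C4")))
  expect_true(all(ae2$data[, 1] == 0))

  # linearity: C3 = -F3 doubles the amplitude
  x3 <- x; x3[, 2] <- -x3[, 1]
  ae3 <- to_aeeg_montage(eeg_recording(x3, 256, c("F3", "C3", "F4", "C4")))
  expect_equal(ae3$data[, 1], 2 * x[, 1])

  # commutes with scalar gain
  ae_g <- to_aeeg_montage(eeg_recording(3 * x, 256,
                                        c("F3", "C3", "F4", "C4")))
  expect_equal(ae_g$data, 3 * ae$data)

  expect_error(to_aeeg_montage(eeg_recording(x[, 1:2], 256, c("F3", "C3"))),
               "missing")
})

test_that("annotation CSV readers parse both dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(onset_s = c(10, 50), duration_s = c(5, 8),
                       label = "movement"), f, row.names = FALSE)
  a <- read_artifact_annotations(f)
  expect_equal(a[, "end_s"], c(15, 58))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("A", "A", "B"),
                       start_h = c(14, 16, 20), end_h = c(14.1, 16.2, 20.5)),
            f2, row.names = FALSE)
  sa <- read_seizure_annotations(f2, subject = "A")
  expect_equal(nrow(sa), 2)
  expect_error(seizure_annotation(cbind(10, 10.001)), "shorter")
})
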