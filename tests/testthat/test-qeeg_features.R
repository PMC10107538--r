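# Quantitative-EEG estimators against closed-form and constructed oracles.

test_that("sinusoid band power matches the A^2/2 oracle", {
  rec <- sine_rec(freq = 2, amp = 10, dur = 120, fs = 256, channels = "C3")
  sp <- spectral_powers(rec)
  expect_rel(sp$power["delta"], 50, 0.02)       # Parseval: A^2/2
  expect_gte(sp$relative["delta"], 0.99)
})

test_that("zero signal flags undefined spectral features", {
  rec <- eeg_recording(matrix(0, 256 * 120, 2), 256, c("F3", "F4"))
  sp <- spectral_powers(rec)
  expect_equal(unname(sp$power), rep(0, 4))
  expect_true(all(is.na(sp$flatness)))
  expect_true(is.na(sp$sef))
})

test_that("band-limited white noise: high flatness, SEF95 near band edge", {
  rec <- noise_rec(sd = 10, dur = 120, fs = 256, seed = 8, band = c(1, 30))
  sp <- spectral_powers(rec)
  expect_true(all(sp$flatness >= 0.9))
  # flat-PSD oracle: 1 + 0.95 * 29 = 28.55 Hz, window leakage shifts it
  # slightly down
  expect_gt(sp$sef, 27.5)
  expect_lt(sp$sef, 29.0)
})

test_that("all windows masked raises insufficient-data error", {
  rec <- noise_rec(dur = 120, fs = 256, seed = 9)
  rec$mask <- rep(FALSE, nrow(rec$data))
  expect_error(spectral_powers(rec), "masked|insufficient")
})

test_that("rEEG margins equal peak-to-peak and asymmetry follows gain", {
  rec <- sine_rec(freq = 5, amp = 10, dur = 120, fs = 256)
  re <- range_eeg(rec)
  for (v in c(re$lower, re$median, re$upper)) expect_rel(v, 20, 0.05)
  expect_lt(re$asymmetry, 1e-9)

  # right channels 3x left -> |3 - 1| / (3 + 1) = 0.5
  x <- rec$data; x[, c(2, 4)] <- 3 * x[, c(2, 4)]   # F4, C4
  re3 <- range_eeg(eeg_recording(x, 256, rec$channel_labels))
  expect_equal(re3$asymmetry, 0.5, tolerance = 1e-6)

  z <- eeg_recording(matrix(0, 256 * 60, 2), 256, c("F3", "F4"))
  rez <- range_eeg(z)
  expect_equal(unname(rez$median), 0)
  expect_true(is.na(rez$asymmetry))
})

test_that("IBI detector recovers constructed burst-suppression", {
  ib <- detect_ibis(bs_rec())
  expect_gt(ib$percentage, 75); expect_lt(ib$percentage, 85)
  expect_gt(ib$median_s, 19); expect_lt(ib$median_s, 21)
  expect_equal(ib$count, 10)

  set.seed(10)
  cont <- eeg_recording(matrix(rnorm(250 * 120, sd = 50), ncol = 1),
                        250, "C3")
  expect_equal(detect_ibis(cont)$percentage, 0)
  expect_equal(detect_ibis(cont)$count, 0)

  low <- eeg_recording(matrix(rnorm(250 * 120, sd = 1), ncol = 1),
                       250, "C3")
  il <- detect_ibis(low)
  expect_equal(il$percentage, 100)
  expect_equal(il$count, 1)
  expect_equal(il$max_s, 120)
})

test_that("amplitude moments match the Gaussian oracle and flag constants", {
  rec <- noise_rec(sd = 10, dur = 240, fs = 256, seed = 11)
  m <- amplitude_moments(rec, c(1, 30))
  expect_lt(abs(m$kurtosis - 3), 0.2)          # non-excess convention
  expect_lt(abs(m$skewness), 0.1)              # symmetric signal

  # rare large spikes raise kurtosis
  x <- rec$data
  idx <- sample(nrow(x), 30)
  x[idx, ] <- x[idx, ] + 100
  m2 <- amplitude_moments(eeg_recording(x, 256, c("F3", "F4")), c(1, 30))
  expect_gt(m2$kurtosis, m$kurtosis)

  z <- eeg_recording(matrix(1, 256 * 60, 1), 256, "C3")
  mz <- amplitude_moments(z, c(1, 30))
  expect_true(is.na(mz$kurtosis))
})

test_that("Higuchi FD hits smooth-curve, periodic and white-noise limits", {
  ramp <- eeg_recording(matrix(seq(0, 100, length.out = 256 * 64), ncol = 1),
                        256, "C3")
  fd_ramp <- fractal_dimension(ramp, band_scheme(fd_band = c(0, 127)))
  expect_lt(abs(fd_ramp - 1), 0.05)

  wn <- noise_rec(sd = 10, dur = 120, fs = 256, seed = 12)
  expect_lt(abs(fractal_dimension(wn) - 2), 0.1)

  s5 <- sine_rec(freq = 5, amp = 10, dur = 120, fs = 250, channels = "C3")
  expect_lt(fractal_dimension(s5), 1.3)

  z <- eeg_recording(matrix(0, 256 * 60, 1), 256, "C3")
  expect_true(is.na(fractal_dimension(z)))
})

test_that("connectivity: identical, independent and scaled hemispheres", {
  set.seed(13)
  a <- rnorm(250 * 300)
  id <- eeg_recording(cbind(a, a) * 10, 250, c("F3", "F4"))
  cn <- connectivity(id)
  expect_true(all(cn$bsi < 1e-9))
  expect_true(all(cn$coherence > 1 - 1e-9))

  ind <- noise_rec(sd = 10, dur = 300, fs = 250, seed = 14)
  cni <- connectivity(ind)
  expect_true(all(cni$bsi <= 0.15))
  expect_true(all(cni$coherence <= 0.2))

  # right power 4x left at every frequency: |4 - 1| / (4 + 1) = 0.6
  sc <- eeg_recording(cbind(a, 2 * a), 250, c("F3", "F4"))
  expect_equal(unname(connectivity(sc)$bsi), rep(0.6, 4), tolerance = 1e-9)

  # single hemisphere flagged unavailable
  left <- eeg_recording(matrix(a, ncol = 1), 250, "F3")
  cnl <- connectivity(left)
  expect_true(all(is.na(cnl$bsi)))
  expect_match(attr(cnl, "unavailable"), "hemisphere")
})

test_that("extract_features assembles base, weighted and adjusting blocks", {
  rec <- noise_rec(sd = 20, dur = 120, fs = 256,
                   channels = c("F3", "F4", "C3", "C4"), seed = 15)
  fv <- extract_features(rec, asm_before_epoch = 1)
  expect_identical(names(fv), qeeg_feature_names())
  expect_equal(unname(fv["asm_before_epoch"]), 1)
  expect_equal(unname(fv["hypothermia_at_epoch"]), 0)

  # continuous record: IBI percentage 0 -> weighted block all zero
  expect_equal(unname(fv["ibi_percentage"]), 0)
  wgt <- fv[startsWith(names(fv), "wgt_")]
  expect_true(all(wgt == 0, na.rm = TRUE))

  # weighted block is exactly base * ibi_fraction on a discontinuous record
  fb <- extract_features(bs_rec(channels = c("F3", "F4", "C3", "C4")))
  base_names <- setdiff(
    grep("^wgt_|^asm|^hypo", names(fb), invert = TRUE, value = TRUE),
    c("ibi_max", "ibi_median", "ibi_percentage", "ibi_count"))
  expect_equal(unname(fb[paste0("wgt_", base_names)]),
               unname(fb[base_names] * fb["ibi_percentage"] / 100))
})

test_that("seizure-class epochs have lower delta power and higher IBI share", {
  d <- eeg_class_defaults()
  f0 <- extract_features(generate_eeg(d$nonseizure, 300, 250, 8, seed = 16))
  f1 <- extract_features(generate_eeg(d$seizure, 300, 250, 8, seed = 17))
  expect_lt(f1["spectral_power_delta"], f0["spectral_power_delta"])
  expect_gt(f1["ibi_percentage"], f0["ibi_percentage"])
})

test_that("scale equivariance across gains 0.5, 2, 10", {
  rec <- noise_rec(sd = 8, dur = 120, fs = 256,
                   channels = c("F3", "F4", "C3", "C4"), seed = 18)
  f1 <- extract_features(rec)
  for (g in c(0.5, 2, 10)) {
    rg <- eeg_recording(g * rec$data, rec$fs, rec$channel_labels)
    fg <- extract_features(rg)
    for (b in paste0("spectral_power_", c("delta", "theta", "alpha", "beta")))
      expect_rel(fg[b], g^2 * f1[b], 1e-6)
    for (m in c("reeg_lower", "reeg_median", "reeg_upper"))
      expect_rel(fg[m], g * f1[m], 1e-6)
    inv <- c(paste0("spectral_relative_power_", c("delta", "theta", "alpha",
                                                  "beta")),
             paste0("spectral_flatness_", c("delta", "theta", "alpha",
                                            "beta")),
             "spectral_edge_frequency", "fractal_dimension",
             paste0("bsi_", c("delta", "theta", "alpha", "beta")),
             paste0("coherence_mean_", c("delta", "theta", "alpha", "beta")),
             paste0("amplitude_kurtosis_", c("delta", "theta", "alpha",
                                             "beta")))
    expect_equal(unname(fg[inv]), unname(f1[inv]), tolerance = 1e-6)
  }
})

test_that("Parseval consistency and channel-permutation invariance", {
  rec <- noise_rec(sd = 10, dur = 180, fs = 256,
                   channels = c("F3", "F4", "C3", "C4"), seed = 19)
  sp <- spectral_powers(rec)
  filt <- neoseize:::band_filter(rec, c(1, 30))
  expect_rel(sum(sp$power), median(apply(filt, 2, var)), 0.1)

  perm <- c(2, 1, 4, 3)                 # swap within-hemisphere roles
  rp <- eeg_recording(rec$data[, c(3, 4, 1, 2)], rec$fs,
                      rec$channel_labels[c(3, 4, 1, 2)])
  sp2 <- spectral_powers(rp)
  expect_equal(sp$power, sp2$power, tolerance = 1e-9)
  expect_equal(sp$sef, sp2$sef, tolerance = 1e-9)
})

test_that("masked injected artifacts leave features within 5%", {
  rec <- noise_rec(sd = 12, dur = 300, fs = 250,
                   channels = c("F3", "F4"), seed = 20)
  f_clean <- extract_features(rec)

  x <- rec$data
  bad <- (250 * 120 + 1):(250 * 140)
  x[bad, ] <- x[bad, ] + 400
  dirty <- eeg_recording(x, 250, c("F3", "F4"),
                         artifact_intervals = cbind(120, 140))
  ep <- select_epoch(dirty, duration_s = 300, max_age_h = 24)
  f_masked <- extract_features(mask_artifacts(dirty, ep))

  for (nm in c("spectral_power_delta", "spectral_power_theta",
               "reeg_median", "spectral_edge_frequency",
               "fractal_dimension"))
    expect_rel(f_masked[nm], f_clean[nm], 0.05)
})

test_that("band scheme validates and offers the narrow alternative", {
  b <- band_scheme()
  expect_equal(b$delta, c(1, 4))
  expect_equal(b$alpha, c(7, 13))
  n <- band_scheme("narrow")
  expect_equal(n$delta, c(0.5, 3))
  expect_equal(n$alpha, c(8, 12))
  expect_error(band_scheme(delta = c(4, 1)), "ordered")
})
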