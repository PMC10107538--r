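# Time-domain background estimators: range EEG, interburst intervals,
# amplitude moments, Higuchi fractal dimension, and the assembled feature
# vector.

# non-overlapping window view of a channel matrix; returns list(mat = array
# win_len x nwin x nch, usable = logical nwin)
nonoverlap_windows <- function(x, mask, fs, win_s = 2) {
  wl <- round(win_s * fs)
  nwin <- floor(nrow(x) / wl)
  if (nwin < 1) stop("insufficient data: record shorter than one window")
  idx <- seq_len(nwin * wl)
  arr <- array(x[idx, , drop = FALSE], dim = c(wl, nwin, ncol(x)))
  usable <- if (is.null(mask)) rep(TRUE, nwin) else
    colSums(matrix(mask[idx], nrow = wl)) == wl
  list(arr = arr, usable = usable, win_s = win_s)
}

#' Range EEG (rEEG) margins and asymmetry
#'
#' The signal is band-limited to the rEEG band (1-20 Hz) and cut into 2-s
#' non-overlapping windows; the per-window amplitude range (max - min) is
#' the rEEG sample.  Margins are the 5th / 50th / 95th percentiles of
#' window ranges pooled over channels.  Asymmetry is the median over
#' homologous left/right pairs and windows of `|R - L| / (R + L)` on the
#' per-window ranges.
#'
#' @param rec masked [eeg_recording()].
#' @param bands a [band_scheme()] (supplies `reeg_band`).
#' @return list `lower`, `median`, `upper` (uV), `asymmetry`
#'   (dimensionless; `NA`-flagged when undefined, e.g. zero signal or a
#'   single hemisphere).
#' @export
range_eeg <- function(rec, bands = band_scheme()) {
  xf <- band_filter(rec, bands$reeg_band)
  w <- nonoverlap_windows(xf, rec$mask, rec$fs)
  if (sum(w$usable) < 5) stop("insufficient data: fewer than 5 usable windows")
  arr <- w$arr[, w$usable, , drop = FALSE]
  rng <- apply(arr, c(2, 3), function(v) max(v) - min(v))  # win x ch
  q <- quantile(rng, c(0.05, 0.5, 0.95), names = FALSE)

  li <- match(LEFT_CHANNELS, rec$channel_labels)
  ri <- match(RIGHT_CHANNELS, rec$channel_labels)
  ok <- !is.na(li) & !is.na(ri)
  asym <- NA_real_
  if (any(ok)) {
    L <- rng[, li[ok], drop = FALSE]; R <- rng[, ri[ok], drop = FALSE]
    den <- L + R
    a <- abs(R - L)[den > 0] / den[den > 0]
    if (length(a)) asym <- median(a)
  }
  list(lower = q[1], median = q[2], upper = q[3], asymmetry = asym)
}

#' Detect interburst intervals (IBIs)
#'
#' Envelope-based burst/suppression segmentation: a moving-RMS amplitude
#' envelope (0.5-s window, broadband 0.5-30 Hz signal) is computed per
#' channel; the across-channel maximum envelope is thresholded.  The
#' threshold adapts to the two amplitude modes of the record (Otsu split of
#' the log-envelope); when the envelope is effectively unimodal the
#' absolute suppression ceiling `low_amp_uV` decides whether the record is
#' continuous activity (no IBIs) or continuous suppression (one IBI).
#' Sub-threshold runs are merged across gaps shorter than 0.5 s
#' (hysteresis) and kept when at least `min_ibi_s` long across all
#' channels simultaneously.
#'
#' @param rec masked [eeg_recording()].
#' @param min_ibi_s minimum IBI duration in seconds (clinical definition:
#'   discontinuity = intervals longer than 6 s).
#' @param low_amp_uV absolute envelope ceiling (uV RMS) for suppression
#'   when no burst/suppression bimodality is found.
#' @return list of class `ibi_annotation`: `intervals` (matrix of
#'   `(start_s, end_s)` relative to epoch start), `max_s`, `median_s`,
#'   `percentage` (of usable epoch time), `count`.
#' @export
detect_ibis <- function(rec, min_ibi_s = 6, low_amp_uV = 5) {
  fs <- rec$fs
  xf <- band_filter(rec, c(0.5, 30))
  wl <- round(0.5 * fs)
  # centred moving-RMS envelope via cumulative sums (edges carry the first/
  # last full window so no spurious low-amplitude mode appears there)
  moving_rms <- function(v) {
    cs <- c(0, cumsum(v^2))
    n <- length(v)
    core <- sqrt(pmax((cs[(wl + 1):(n + 1)] - cs[1:(n - wl + 1)]) / wl, 0))
    lead <- wl %/% 2
    c(rep(core[1], lead), core,
      rep(core[length(core)], n - length(core) - lead))
  }
  env <- apply(xf, 2, moving_rms)
  env_max <- do.call(pmax, as.data.frame(env))  # AND rule: all channels low

  usable <- if (is.null(rec$mask)) rep(TRUE, length(env_max)) else rec$mask
  le <- log10(pmax(env_max[usable], 1e-3))
  thr <- otsu_threshold(le)
  lo_mode <- mean(le[le <= thr]); hi_mode <- mean(le[le > thr])
  if (!is.finite(thr) || !is.finite(lo_mode) || !is.finite(hi_mode) ||
      (hi_mode - lo_mode) < log10(2)) {
    # unimodal envelope: continuous activity or continuous suppression
    thr <- log10(low_amp_uV)
  }
  low <- env_max < 10^thr & usable

  # hysteresis: close sub-0.5-s gaps inside suppression
  r <- rle(low)
  gap <- !r$values & r$lengths < wl
  gap[1] <- gap[length(gap)] <- FALSE
  r$values[gap] <- TRUE
  low <- inverse.rle(r)

  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_ibi_s * fs
  iv <- cbind(start_s = (starts[keep] - 1) / fs, end_s = ends[keep] / fs)
  lens <- iv[, 2] - iv[, 1]
  usable_s <- sum(usable) / fs
  structure(list(intervals = iv,
                 max_s = if (length(lens)) max(lens) else 0,
                 median_s = if (length(lens)) median(lens) else 0,
                 percentage = 100 * sum(lens) / usable_s,
                 count = nrow(iv)),
            class = "ibi_annotation")
}

# Otsu's between-class variance maximising split on a numeric sample
otsu_threshold <- function(x, nbins = 64) {
  if (diff(range(x)) < 1e-12) return(Inf)
  h <- hist(x, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts); m <- h$mids
  w0 <- cumsum(p); mu <- cumsum(p * m); mt <- mu[length(mu)]
  v <- (mt * w0 - mu)^2 / (w0 * (1 - w0))
  v[!is.finite(v)] <- -Inf
  h$mids[which.max(v)]
}

#' Band-filtered amplitude skewness and kurtosis
#'
#' Sample skewness and kurtosis of the band-filtered signal, per channel,
#' aggregated by the median.  Kurtosis uses the non-excess convention
#' (Gaussian signal = 3).  A constant (zero-variance) channel is
#' `NA`-flagged.
#'
#' @param rec masked [eeg_recording()].
#' @param band `(lo, hi)` Hz.
#' @return list `skewness`, `kurtosis`.
#' @export
amplitude_moments <- function(rec, band) {
  xf <- band_filter(rec, band)
  if (!is.null(rec$mask)) xf <- xf[rec$mask, , drop = FALSE]
  mom <- function(v) {
    s <- sd(v)
    # constant input arrives here as numerical dust after DC removal
    if (!is.finite(s) || s < 1e-10) return(c(NA_real_, NA_real_))
    z <- (v - mean(v)) / s
    c(mean(z^3), mean(z^4))
  }
  m <- apply(xf, 2, mom)
  list(skewness = agg_channels(m[1, ]), kurtosis = agg_channels(m[2, ]))
}

#' Higuchi fractal dimension
#'
#' Higuchi's curve-length estimator with `k_max = 6`, computed per 2-s
#' window on the 1-30 Hz band-limited signal resampled to 64 Hz, and
#' median-pooled over windows and channels.  The resampling step matters:
#' at the native 250/256 Hz the 30-Hz-limited signal is ~4x oversampled
#' and curve lengths saturate, compressing every FD toward 1; at 64 Hz a
#' band-limited white signal recovers the literature value FD ~ 2 and a
#' smooth curve gives FD near 1.
#'
#' @param rec masked [eeg_recording()].
#' @param bands a [band_scheme()] (supplies `fd_band`).
#' @param k_max largest curve reconstruction interval.
#' @param fs_fd analysis rate for the estimator (Hz).
#' @return scalar FD estimate in `[1, 2]` (`NA` for a constant signal).
#' @export
fractal_dimension <- function(rec, bands = band_scheme(), k_max = 6,
                              fs_fd = 64) {
  xf <- band_filter(rec, bands$fd_band)
  # linear-interpolation resample (safe: signal band-limited below fs_fd/2)
  n <- nrow(xf)
  t_old <- (seq_len(n) - 1) / rec$fs
  t_new <- seq(0, t_old[n], by = 1 / fs_fd)
  xf <- apply(xf, 2, function(v) stats::approx(t_old, v, t_new)$y)
  mask <- rec$mask
  if (!is.null(mask))
    mask <- mask[pmin(n, floor(t_new * rec$fs) + 1)]
  w <- nonoverlap_windows(xf, mask, fs_fd)
  arr <- w$arr[, w$usable, , drop = FALSE]
  wl <- dim(arr)[1]
  X <- matrix(arr, nrow = wl)              # wl x (nwin*nch)
  live <- apply(X, 2, function(v) diff(range(v)) > 0)
  if (!any(live)) return(NA_real_)
  X <- X[, live, drop = FALSE]
  logL <- matrix(0, k_max, ncol(X))
  for (k in seq_len(k_max)) {
    Lm <- matrix(0, k, ncol(X))
    for (m in seq_len(k)) {
      idx <- seq(m, wl, by = k)
      ni <- length(idx) - 1
      d <- abs(X[idx[-1], , drop = FALSE] - X[idx[-length(idx)], , drop = FALSE])
      Lm[m, ] <- colSums(d) * (wl - 1) / (ni * k) / k
    }
    logL[k, ] <- log(colMeans(Lm))
  }
  lk <- log(1 / seq_len(k_max))
  fd <- as.vector(crossprod(lk - mean(lk), logL - rep(colMeans(logL),
                                                      each = k_max))) /
    sum((lk - mean(lk))^2)
  median(fd)
}

QEEG_BASE_FEATURES <- c(
  paste0("spectral_power_", BAND_NAMES),
  paste0("spectral_relative_power_", BAND_NAMES),
  paste0("spectral_flatness_", BAND_NAMES),
  paste0("spectral_difference_", BAND_NAMES),
  "spectral_edge_frequency",
  "reeg_lower", "reeg_median", "reeg_upper", "reeg_asymmetry",
  "ibi_max", "ibi_median", "ibi_percentage", "ibi_count",
  paste0("amplitude_skewness_", BAND_NAMES),
  paste0("amplitude_kurtosis_", BAND_NAMES),
  "fractal_dimension",
  paste0("bsi_", BAND_NAMES),
  paste0("coherence_mean_", BAND_NAMES))

QEEG_IBI_FEATURES <- c("ibi_max", "ibi_median", "ibi_percentage", "ibi_count")

#' Names of the assembled quantitative-EEG feature columns
#'
#' Frozen column order of [extract_features()]: the base battery, the
#' IBI-weighted copies (`wgt_` prefix, base features excluding the IBI
#' statistics multiplied by the IBI fraction), then the two adjusting
#' features.
#' @return character vector of column names.
#' @export
qeeg_feature_names <- function() {
  c(QEEG_BASE_FEATURES,
    paste0("wgt_", setdiff(QEEG_BASE_FEATURES, QEEG_IBI_FEATURES)),
    "asm_before_epoch", "hypothermia_at_epoch")
}

#' Extract the full quantitative-EEG feature vector
#'
#' Runs every background estimator on a masked epoch and assembles the
#' feature vector: base battery, IBI-weighted block (all non-IBI features
#' multiplied by IBI percentage / 100; identically zero when the record is
#' fully continuous), and the anti-seizure-medication and hypothermia
#' adjusting features.  The identical code path serves the full montage
#' and the 2-channel bipolar aEEG montage.
#'
#' @param rec masked [eeg_recording()] (from [mask_artifacts()], or any
#'   recording treated as fully usable).
#' @param bands a [band_scheme()].
#' @param asm_before_epoch 0/1: any anti-seizure medication before the
#'   epoch.
#' @param hypothermia_at_epoch 0/1: therapeutic hypothermia ongoing at the
#'   epoch.
#' @return named numeric vector (length `length(qeeg_feature_names())`);
#'   undefined estimates are `NA` and the names of flagged features are in
#'   attribute `flags`.
#' @export
extract_features <- function(rec, bands = band_scheme(),
                             asm_before_epoch = 0,
                             hypothermia_at_epoch = 0) {
  st <- stft(rec)
  sp <- spectral_powers(rec, bands, st = st)
  cn <- connectivity(rec, bands, st = st)
  re <- range_eeg(rec, bands)
  ibi <- detect_ibis(rec)
  fd <- fractal_dimension(rec, bands)
  mom <- lapply(BAND_NAMES, function(b) amplitude_moments(rec, bands[[b]]))

  v <- c(sp$power, sp$relative, sp$flatness, sp$spectral_difference,
         sp$sef, re$lower, re$median, re$upper, re$asymmetry,
         ibi$max_s, ibi$median_s, ibi$percentage, ibi$count,
         vapply(mom, `[[`, 0, "skewness"),
         vapply(mom, `[[`, 0, "kurtosis"),
         fd, cn$bsi, cn$coherence)
  names(v) <- QEEG_BASE_FEATURES

  wgt <- v[setdiff(QEEG_BASE_FEATURES, QEEG_IBI_FEATURES)] *
    (v["ibi_percentage"] / 100)
  names(wgt) <- paste0("wgt_", names(wgt))
  out <- c(v, wgt,
           asm_before_epoch = as.numeric(asm_before_epoch),
           hypothermia_at_epoch = as.numeric(hypothermia_at_epoch))
  attr(out, "flags") <- names(out)[is.na(out)]
  out
}
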