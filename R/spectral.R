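# Short-time Fourier machinery shared by the spectral estimators.
#
# All spectral features are computed from one Welch decomposition: 2-s
# Hamming windows with 50% overlap, periodogram scaling such that the
# one-sided PSD integrates to signal variance (Parseval).  Windows that
# overlap the artifact mask are dropped before any averaging.

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Short-time Fourier transform of a masked recording
#'
#' @param rec an [eeg_recording()] (the `$mask` field, if set, marks usable
#'   samples).
#' @param win_s window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @param fmax retain frequency bins up to `fmax` Hz.
#' @return list: `coef` complex array (freq x window x channel), `freqs`,
#'   `psd_scale` multiplying `|coef|^2` to one-sided PSD in uV^2/Hz,
#'   `win_start_s` window start times, `usable` logical per window.
#' @keywords internal
stft <- function(rec, win_s = 2, overlap = 0.5, fmax = 32) {
  n <- nrow(rec$data); nch <- ncol(rec$data)
  nfft <- round(win_s * rec$fs)
  hop <- round(nfft * (1 - overlap))
  if (n < nfft) stop("insufficient data: record shorter than one window")
  starts <- seq(1, n - nfft + 1, by = hop)
  w <- hamming_window(nfft)
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * rec$fs / nfft
  keepf <- freqs <= fmax
  usable <- if (is.null(rec$mask)) rep(TRUE, length(starts)) else
    vapply(starts, function(s) all(rec$mask[s:(s + nfft - 1)]), TRUE)

  idx <- outer(0:(nfft - 1), starts, "+")      # nfft x nwin
  kf <- which(keepf)
  coef <- array(0i, dim = c(length(kf), length(starts), nch))
  for (ch in seq_len(nch)) {
    seg <- matrix(rec$data[idx, ch], nrow = nfft) * w
    X <- stats::mvfft(seg)
    coef[, , ch] <- X[kf, , drop = FALSE]
  }
  list(coef = coef, freqs = freqs[keepf],
       psd_scale = 2 / (rec$fs * sum(w^2)),
       win_start_s = (starts - 1) / rec$fs, usable = usable)
}

# PSD per window (freq x window x channel), usable windows only
stft_psd <- function(st) {
  if (!any(st$usable)) stop("insufficient data: all windows masked")
  (abs(st$coef[, st$usable, , drop = FALSE])^2) * st$psd_scale
}

agg_channels <- function(x) if (all(is.na(x))) NA_real_ else
  median(x, na.rm = TRUE)

#' Band-wise spectral features
#'
#' Welch PSD (2-s Hamming windows, 50% overlap, mask-overlapping windows
#' dropped) reduced to, per band: absolute power (PSD integral, uV^2),
#' relative power (share of the four-band total), spectral flatness
#' (geometric over arithmetic PSD mean), and spectral difference (median
#' over consecutive window pairs of the mean absolute PSD change in the
#' band, normalised by total 0.5-30 Hz power).  The spectral edge frequency
#' is the frequency below which 95% of the 0.5-30 Hz power lies.
#' Channel-wise values are aggregated by the median.
#'
#' @param rec masked [eeg_recording()] (>= 60 s usable).
#' @param bands a [band_scheme()].
#' @param st optional precomputed [stft()] (reused across estimators).
#' @return list with `power`, `relative`, `flatness`, `spectral_difference`
#'   (named per band), `sef`, and the per-channel matrices in
#'   `$per_channel`.  Features undefined on a degenerate (e.g. all-zero)
#'   signal are `NA`.
#' @export
spectral_powers <- function(rec, bands = band_scheme(), st = NULL) {
  if (is.null(st)) st <- stft(rec)
  check_min_usable(rec, st)
  P <- stft_psd(st)                       # freq x win x ch
  df <- st$freqs[2] - st$freqs[1]
  nch <- dim(P)[3]
  Pbar <- apply(P, c(1, 3), mean)         # time-averaged PSD: freq x ch

  tot_bins <- which(st$freqs > 0.5 & st$freqs <= 30)
  tot_pow_ch <- colSums(Pbar[tot_bins, , drop = FALSE]) * df

  pow <- rel <- flat <- sdif <- matrix(NA_real_, nch, 4,
                                       dimnames = list(NULL, BAND_NAMES))
  for (b in seq_along(BAND_NAMES)) {
    bi <- band_bins(st$freqs, bands[[BAND_NAMES[b]]])
    pb <- Pbar[bi, , drop = FALSE]
    pow[, b] <- colSums(pb) * df
    am <- colMeans(pb)
    gm <- exp(colMeans(log(pmax(pb, 1e-300))))
    flat[, b] <- ifelse(am > 0, gm / am, NA_real_)
    if (dim(P)[2] >= 2) {
      dP <- abs(P[bi, -1, , drop = FALSE] - P[bi, -dim(P)[2], , drop = FALSE])
      md <- apply(dP, c(2, 3), mean)      # winpair x ch
      sdif[, b] <- ifelse(tot_pow_ch > 0,
                          apply(md, 2, median) / tot_pow_ch, NA_real_)
    }
  }
  four_tot <- rowSums(pow)
  rel[] <- ifelse(four_tot > 0, pow / four_tot, NA_real_)

  # SEF95 with linear interpolation inside the crossing bin
  sef_ch <- vapply(seq_len(nch), function(ch) {
    p <- Pbar[tot_bins, ch]
    if (sum(p) <= 0) return(NA_real_)
    cum <- cumsum(p) / sum(p)
    k <- which(cum >= 0.95)[1]
    f1 <- st$freqs[tot_bins[k]]
    if (k == 1) return(f1)
    c0 <- cum[k - 1]
    st$freqs[tot_bins[k - 1]] + df * (0.95 - c0) / (cum[k] - c0)
  }, 0)

  zero <- four_tot <= 0
  flat[zero, ] <- NA_real_

  list(power = apply(pow, 2, agg_channels),
       relative = apply(rel, 2, agg_channels),
       flatness = apply(flat, 2, agg_channels),
       spectral_difference = apply(sdif, 2, agg_channels),
       sef = agg_channels(sef_ch),
       per_channel = list(power = pow, relative = rel, flatness = flat,
                          spectral_difference = sdif, sef = sef_ch))
}

check_min_usable <- function(rec, st, min_s = 60) {
  win_s <- 1 / (st$freqs[2] - st$freqs[1])
  if (sum(st$usable) * win_s / 2 < min_s)   # 50% overlap
    stop("insufficient data: fewer than ", min_s, " s usable")
}

#' Inter-hemispheric connectivity: brain symmetry index and coherence
#'
#' BSI per band is the mean over band frequencies of
#' `|(P_R - P_L) / (P_R + P_L)|` where `P_L`, `P_R` are hemisphere-averaged
#' Welch PSDs.  Coherence per band is the magnitude-squared coherence of
#' homologous electrode pairs (F3/F4, C3/C4, T3/T4, O1/O2, P3/P4),
#' averaged over band frequencies and aggregated over pairs by the median.
#' For the 2-channel bipolar montage the single pair F3-C3 / F4-C4 is used.
#'
#' @inheritParams spectral_powers
#' @return list with `bsi` and `coherence` (named per band), or both `NA`
#'   with attribute `unavailable` if only one hemisphere is present.
#' @export
connectivity <- function(rec, bands = band_scheme(), st = NULL) {
  li <- which(rec$channel_labels %in% LEFT_CHANNELS)
  ri <- which(rec$channel_labels %in% RIGHT_CHANNELS)
  if (!length(li) || !length(ri)) {
    out <- list(bsi = stats::setNames(rep(NA_real_, 4), BAND_NAMES),
                coherence = stats::setNames(rep(NA_real_, 4), BAND_NAMES))
    attr(out, "unavailable") <- "single hemisphere only"
    return(out)
  }
  if (is.null(st)) st <- stft(rec)
  check_min_usable(rec, st)
  X <- st$coef[, st$usable, , drop = FALSE]

  PL <- apply(abs(X[, , li, drop = FALSE])^2, 1, mean)
  PR <- apply(abs(X[, , ri, drop = FALSE])^2, 1, mean)
  ratio <- ifelse(PL + PR > 0, abs(PR - PL) / (PR + PL), NA_real_)

  pairs <- Filter(function(p) all(p %in% rec$channel_labels),
                  HOMOLOGOUS_PAIRS)
  msc <- NULL
  for (p in pairs) {
    a <- X[, , match(p[1], rec$channel_labels)]
    b <- X[, , match(p[2], rec$channel_labels)]
    sxy <- rowMeans(a * Conj(b))
    sxx <- rowMeans(abs(a)^2); syy <- rowMeans(abs(b)^2)
    msc <- cbind(msc, ifelse(sxx * syy > 0,
                             abs(sxy)^2 / (sxx * syy), NA_real_))
  }
  bsi <- coh <- stats::setNames(rep(NA_real_, 4), BAND_NAMES)
  for (b in BAND_NAMES) {
    bi <- band_bins(st$freqs, bands[[b]])
    bsi[b] <- mean(ratio[bi])
    coh[b] <- median(colMeans(msc[bi, , drop = FALSE]))
  }
  list(bsi = bsi, coherence = coh)
}

#' Zero-phase band-pass filter (frequency-domain)
#'
#' Brick-wall band-pass by zeroing FFT bins outside `(lo, hi]`.  Masked
#' samples are zeroed before transforming so that high-amplitude artifacts
#' cannot leak into usable segments; downstream estimators additionally
#' drop windows overlapping the mask.
#'
#' @param rec an [eeg_recording()].
#' @param band `(lo, hi)` Hz.
#' @return matrix of filtered data (same shape as `rec$data`).
#' @keywords internal
band_filter <- function(rec, band) {
  n <- nrow(rec$data)
  # the forward transform is shared across the band-filter bank through a
  # per-recording cache (reference semantics via environment)
  cache <- rec$fftcache
  if (!is.null(cache) && !is.null(cache$X)) {
    X <- cache$X
  } else {
    x <- rec$data
    if (!is.null(rec$mask)) x[!rec$mask, ] <- 0
    X <- stats::mvfft(x)
    if (!is.null(cache)) cache$X <- X
  }
  f <- c(0, seq_len(n - 1)) / n * rec$fs
  f <- pmin(f, rec$fs - f)                 # two-sided frequency axis
  keep <- f > band[1] & f <= band[2]
  X[!keep, ] <- 0i
  Re(stats::mvfft(X, inverse = TRUE)) / n
}
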