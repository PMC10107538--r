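# Synthetic cohort generator: class-conditional clinical tables,
# burst-suppression EEG, qualitative flags and seizure annotations, so the
# full pipeline is testable without clinical recordings.
#
# Calibration of the class-conditional defaults (documented in the methods
# vignette): burst/suppression amplitudes from the group-median band powers
# and IBI percentages; per-subject jitter log-SDs from the printed IQR
# ratios (sdlog = log(q75/q25) / 1.349); spectral slope from the fractal
# dimension medians via FD ~ (5 - slope) / 2; inter-hemispheric coupling
# from the coherence medians (msc ~ coupling^2); asymmetry-gain spread from
# the BSI medians.  These are calibration targets, not claims.

#' Parameters of the synthetic cohort generator
#'
#' @param n_subjects number of infants.
#' @param prevalence seizure-class probability (reference cohort: 53/162).
#' @param fs sampling rate, 250 or 256 Hz.
#' @param eeg_duration_s length of each synthetic record (the 1-h analysis
#'   epoch plus slack for epoch scanning).
#' @param epoch_duration_s analysis epoch length used downstream.
#' @param eeg named list of per-class (`nonseizure`, `seizure`) EEG
#'   background parameter lists; see [eeg_class_defaults()].
#' @param artifact_rate_per_h expected annotated artifact intervals per
#'   hour of recording.
#' @param missingness named per-field missing probabilities (defaults
#'   follow the reference cohort's observed n per field).
#' @param seed integer seed governing every draw.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(n_subjects = 162, prevalence = 53 / 162,
                             fs = 250, eeg_duration_s = 3900,
                             epoch_duration_s = 3600,
                             eeg = eeg_class_defaults(),
                             artifact_rate_per_h = 1.5,
                             missingness = NULL, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n_subjects >= 2,
            eeg_duration_s >= epoch_duration_s)
  miss <- clinical_missing_defaults()
  if (!is.null(missingness)) miss[names(missingness)] <- missingness
  if (any(unlist(miss) < 0 | unlist(miss) > 1))
    stop("missingness rates must lie in [0, 1]")
  structure(list(n_subjects = n_subjects, prevalence = prevalence,
                 fs = fs, eeg_duration_s = eeg_duration_s,
                 epoch_duration_s = epoch_duration_s, eeg = eeg,
                 artifact_rate_per_h = artifact_rate_per_h,
                 missingness = miss, seed = as.integer(seed)),
            class = "generator_params")
}

#' Class-conditional EEG background defaults
#'
#' Amplitudes are root-mean-square in uV; durations are medians in seconds
#' of log-normal renewal distributions; `*_sdlog` entries are per-subject
#' jitter log-SDs; `dur_sdlog` is the within-record renewal spread;
#' `slope` is the 1/f PSD exponent; `coupling` in `[0, 1]` mixes a common
#' source into every channel; `asym_sdlog` is the SD of the per-subject
#' log amplitude gain of the right hemisphere; `swc_prob` is the
#' probability of sleep-wake cycling in the first 12 h.
#' @return named list with elements `nonseizure` and `seizure`.
#' @export
eeg_class_defaults <- function() {
  list(
    nonseizure = list(burst_amp_uV = 10, supp_amp_uV = 4,
                      amp_sdlog = 0.46,
                      burst_dur_s = 45, burst_sdlog = 0.6,
                      ibi_dur_s = 3, ibi_sdlog = 1.2,
                      dur_sdlog = 0.75,
                      slope = 2.1, slope_sd = 0.15,
                      coupling = 0.23, asym_sdlog = 0.30,
                      swc_prob = 0.147),
    seizure    = list(burst_amp_uV = 6.5, supp_amp_uV = 2.8,
                      amp_sdlog = 0.97,
                      burst_dur_s = 2.5, burst_sdlog = 0.5,
                      ibi_dur_s = 20, ibi_sdlog = 0.9,
                      dur_sdlog = 0.75,
                      slope = 1.7, slope_sd = 0.15,
                      coupling = 0.26, asym_sdlog = 0.35,
                      swc_prob = 0.019))
}

#' Programmed mean interburst fraction of an EEG parameter set
#'
#' Expected fraction of time in the suppressed state under the log-normal
#' renewal process: `E[ibi] / (E[ibi] + E[burst])` with
#' `E = median * exp(dur_sdlog^2 / 2)`.
#' @param p a single-subject (or class) EEG parameter list.
#' @return scalar in (0, 1).
#' @export
ibi_fraction <- function(p) {
  m <- exp(p$dur_sdlog^2 / 2)
  eb <- p$burst_dur_s * m; ei <- p$ibi_dur_s * m
  ei / (ei + eb)
}

# clinical field specs: class-conditional families calibrated to the
# reference cohort's by-group summaries (normal for continuous, Bernoulli /
# categorical for discrete, binomial(10, p) for ordinal Apgar)
clinical_field_specs <- function() {
  list(
    intrapartum_complications = list(type = "bern", p = c(0.835, 0.925)),
    suspected_fetal_distress  = list(type = "bern", p = c(0.745, 0.721)),
    gestational_age = list(type = "norm", mean = c(39.93, 40.18),
                           sd = c(1.29, 1.37), lim = c(36, 43)),
    delivery_mode = list(type = "cat",
                         levels = c("unassisted_vaginal", "assisted_vaginal",
                                    "elective_cs", "emergency_cs"),
                         p = rbind(c(0.275, 0.385, 0.046, 0.294),
                                   c(0.302, 0.377, 0.057, 0.264))),
    male_gender = list(type = "bern", p = c(0.670, 0.566)),
    birth_weight = list(type = "norm", mean = c(3508, 3507),
                        sd = c(608, 609), lim = c(1500, 6000)),
    apgar_1  = list(type = "binom10", p = c(0.20, 0.12)),
    apgar_5  = list(type = "binom10", p = c(0.40, 0.30)),
    apgar_10 = list(type = "binom10", p = c(0.60, 0.40)),
    assisted_ventilation_10min = list(type = "bern", p = c(0.596, 0.830)),
    lowest_cord_ph = list(type = "norm", mean = c(7.01, 6.99),
                          sd = c(0.19, 0.20), lim = c(6.01, 7.99)),
    first_base_excess = list(type = "norm", mean = c(-14.8, -17.1),
                             sd = c(5.3, 6.4), lim = c(-35, 5)),
    first_lactate = list(type = "norm", mean = c(10.9, 13.5),
                         sd = c(3.9, 4.7), lim = c(0.5, 30)))
}

# observed-n per field in the reference cohort (n = 162) -> missing rates
clinical_missing_defaults <- function() {
  list(intrapartum_complications = 0, suspected_fetal_distress = 1 - 145 / 162,
       gestational_age = 0, delivery_mode = 0, male_gender = 0,
       birth_weight = 0, apgar_1 = 1 - 157 / 162, apgar_5 = 1 - 157 / 162,
       apgar_10 = 1 - 144 / 162,
       assisted_ventilation_10min = 1 - 160 / 162,
       lowest_cord_ph = 1 - 137 / 162, first_base_excess = 1 - 121 / 162,
       first_lactate = 1 - 102 / 162)
}

rtrunc_norm <- function(n, mean, sd, lim) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lim[1] | x > lim[2]))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate one synthetic EEG record
#'
#' Two-state (burst / interburst) log-normal renewal process modulating
#' band-limited 1/f-coloured noise.  All channels share the renewal state;
#' each channel mixes a common source (weight `sqrt(coupling)`) with an
#' independent source; right-hemisphere channels are multiplied by
#' `asym_gain`.  Optional annotated artifact intervals carry a
#' high-amplitude transient so that masking is consequential.
#'
#' @param p single-subject EEG parameter list (see [eeg_class_defaults()];
#'   an `asym_gain` element, default 1, multiplies the right hemisphere).
#' @param duration_s record length (>= 60).
#' @param fs 250 or 256 Hz.
#' @param n_channels 2, 4, 6 or 8 (paired montage channels, in the order
#'   F3, F4, C3, C4, T3, T4, O1, O2).
#' @param age_at_start age in hours at the first sample.
#' @param artifact_rate_per_h expected artifact intervals per hour.
#' @param seed optional seed applied locally.
#' @return an [eeg_recording()].
#' @export
generate_eeg <- function(p, duration_s = 3600, fs = 250, n_channels = 8,
                         age_at_start = 0, artifact_rate_per_h = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_s < 60) stop("duration_s must be at least 60")
  if (!fs %in% c(250, 256)) stop("fs must be 250 or 256 Hz")
  if (p$burst_amp_uV <= 0 || p$supp_amp_uV <= 0)
    stop("amplitudes must be positive")
  chs <- c("F3", "F4", "C3", "C4", "T3", "T4", "O1", "O2")[seq_len(n_channels)]
  n <- round(duration_s * fs)
  gain <- if (is.null(p$asym_gain)) 1 else p$asym_gain

  # renewal state sequence (TRUE = burst), shared across channels
  f_burst <- 1 - ibi_fraction(p)
  state <- runif(1) < f_burst
  durs <- numeric(0); states <- logical(0); tot <- 0
  while (tot < duration_s) {
    d <- rlnorm(1, log(if (state) p$burst_dur_s else p$ibi_dur_s),
                p$dur_sdlog)
    durs <- c(durs, d); states <- c(states, state)
    tot <- tot + d; state <- !state
  }
  amp_step <- rep(ifelse(states, p$burst_amp_uV, p$supp_amp_uV),
                  times = pmax(1, round(durs * fs)))[seq_len(n)]
  if (length(amp_step) < n)
    amp_step <- c(amp_step, rep(amp_step[length(amp_step)],
                                n - length(amp_step)))
  # 0.5-s raised ramp between states
  wl <- round(0.5 * fs)
  env <- as.numeric(stats::filter(amp_step, rep(1 / wl, wl), sides = 2))
  env[is.na(env)] <- amp_step[is.na(env)]

  colored <- function(m) {
    x <- matrix(rnorm(n * m), n, m)
    f <- c(0, seq_len(n - 1)) / n * fs
    f <- pmin(f, fs - f)
    shape <- ifelse(f >= 0.5 & f <= 30, f^(-p$slope / 2), 0)
    X <- stats::mvfft(x) * shape
    y <- Re(stats::mvfft(X, inverse = TRUE)) / n
    sweep(y, 2, apply(y, 2, sd), "/")
  }
  src <- colored(n_channels + 1)
  cpl <- min(max(p$coupling, 0), 1)
  data <- sqrt(cpl) * src[, 1] %o% rep(1, n_channels) +
    sqrt(1 - cpl) * src[, -1, drop = FALSE]
  data <- data * env
  right <- chs %in% RIGHT_CHANNELS
  data[, right] <- data[, right] * gain

  ai <- NULL
  n_art <- if (artifact_rate_per_h > 0)
    stats::rpois(1, artifact_rate_per_h * duration_s / 3600) else 0
  if (n_art > 0) {
    a0 <- sort(runif(n_art, 0, duration_s - 30))
    ai <- cbind(a0, pmin(a0 + runif(n_art, 5, 30), duration_s))
    for (k in seq_len(n_art)) {
      i0 <- max(1, round(ai[k, 1] * fs)); i1 <- min(n, round(ai[k, 2] * fs))
      data[i0:i1, ] <- data[i0:i1, ] + 200 * rnorm(i1 - i0 + 1)
    }
  }
  eeg_recording(data, fs, chs, age_at_start = age_at_start,
                artifact_intervals = ai)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject seizure labels at the given prevalence, per-subject
#' EEG background parameters jittered around the class defaults, the
#' class-conditional clinical table with its missingness pattern,
#' qualitative-EEG flags derived deterministically from each subject's own
#' EEG parameters, and seizure annotations (placed after the analysis
#' epoch plus a 1-h guard) for seizure-class subjects.  EEG waveforms are
#' not materialised here; realise them per subject with [cohort_eeg()].
#'
#' @param params a [generator_params()].
#' @return list of class `synthetic_cohort` with `subject_id`, `labels`,
#'   `clinical`, `qualitative`, `adjusters`, `seizures`, `eeg_params`,
#'   `params`.
#' @export
generate_cohort <- function(params = generator_params()) {
  set.seed(params$seed)
  n <- params$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  labels <- rbinom(n, 1, params$prevalence)
  if (n >= 20 && length(unique(labels)) == 1L) {
    warning("degenerate single-class draw; resampling labels once")
    labels <- rbinom(n, 1, params$prevalence)
  }

  # per-subject EEG parameters around class defaults
  cls <- ifelse(labels == 1, "seizure", "nonseizure")
  ep <- lapply(seq_len(n), function(i) {
    d <- params$eeg[[cls[i]]]
    list(burst_amp_uV = d$burst_amp_uV * rlnorm(1, 0, d$amp_sdlog),
         supp_amp_uV = d$supp_amp_uV * rlnorm(1, 0, d$amp_sdlog / 2),
         burst_dur_s = d$burst_dur_s * rlnorm(1, 0, d$burst_sdlog),
         ibi_dur_s = d$ibi_dur_s * rlnorm(1, 0, d$ibi_sdlog),
         dur_sdlog = d$dur_sdlog,
         slope = rnorm(1, d$slope, d$slope_sd),
         coupling = min(max(rnorm(1, d$coupling, 0.05), 0), 1),
         asym_gain = exp(rnorm(1, 0, d$asym_sdlog)))
  })
  eeg_params <- do.call(rbind, lapply(ep, function(x)
    as.data.frame(x)))
  eeg_params <- cbind(subject_id = ids, eeg_params)

  # clinical table
  specs <- clinical_field_specs()
  clin <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (f in names(specs)) {
    s <- specs[[f]]; k <- labels + 1
    clin[[f]] <- switch(s$type,
      bern = rbinom(n, 1, s$p[k]),
      norm = {
        v <- numeric(n)
        for (g in 1:2) if (any(k == g))
          v[k == g] <- rtrunc_norm(sum(k == g), s$mean[g], s$sd[g], s$lim)
        v
      },
      binom10 = rbinom(n, 10, s$p[k]),
      cat = {
        v <- character(n)
        for (g in 1:2) if (any(k == g))
          v[k == g] <- sample(s$levels, sum(k == g), replace = TRUE,
                              prob = s$p[g, ])
        v
      })
  }
  clin <- inject_missingness(clin, params$missingness)

  # qualitative flags derived from each subject's own EEG parameters
  ibi_med <- eeg_params$ibi_dur_s
  frac <- vapply(ep, ibi_fraction, 0)
  burst_pp <- 6 * eeg_params$burst_amp_uV      # ~peak-to-peak of Gaussian
  supp_pp <- 6 * eeg_params$supp_amp_uV
  qual <- data.frame(
    subject_id = ids,
    discontinuity_abnormal = as.integer(ibi_med > 6),
    discontinuity_gt10s = as.integer(ibi_med > 10),
    low_voltage_or_isoelectric =
      as.integer(burst_pp <= 25 | (frac > 0.5 & supp_pp <= 25)),
    asymmetry_or_asynchrony =
      as.integer(abs(log(eeg_params$asym_gain)) > log(2)),
    swc_first_12h = as.integer(
      rbinom(n, 1, vapply(cls, function(cl) params$eeg[[cl]]$swc_prob, 0))))

  adjusters <- data.frame(
    subject_id = ids,
    asm_before_epoch = rbinom(n, 1, c(0.156, 0.264)[labels + 1]),
    hypothermia_at_epoch = rbinom(n, 1, c(0.743, 0.981)[labels + 1]))

  # recording start age: log-normal, median 4.7 h, IQR-calibrated spread,
  # truncated so a 1-h epoch before 12 h of age always exists
  dur_h <- params$eeg_duration_s / 3600
  age0 <- pmin(rlnorm(n, log(4.7), 0.628), 12 - dur_h - 0.1)

  # seizure annotations: onset log-normal median 14.4 h, clamped beyond the
  # record end + 1-h guard; events spread over a log-normal seizure period
  sz <- NULL
  for (i in which(labels == 1)) {
    onset <- max(rlnorm(1, log(14.4), 0.477), age0[i] + dur_h + 1.05)
    n_ev <- max(1, round(rlnorm(1, log(21), 1.374)))
    period_h <- rlnorm(1, log(25.3), 1.2)
    starts <- sort(c(onset, onset + runif(n_ev - 1, 0, period_h)))
    durs_s <- pmax(rlnorm(n_ev, log(109), 1.11), 10)
    ev <- cbind(start_h = starts, end_h = starts + durs_s / 3600)
    ev <- merge_events(ev)
    sz <- rbind(sz, data.frame(subject_id = ids[i],
                               start_h = ev[, 1], end_h = ev[, 2]))
  }
  if (is.null(sz))
    sz <- data.frame(subject_id = character(0), start_h = numeric(0),
                     end_h = numeric(0))

  structure(list(subject_id = ids, labels = labels, clinical = clin,
                 qualitative = qual, adjusters = adjusters, seizures = sz,
                 eeg_params = eeg_params, age_at_start_h = age0,
                 eeg_seeds = params$seed + 1000L + seq_len(n),
                 params = params),
            class = "synthetic_cohort")
}

merge_events <- function(ev) {
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (k in seq_len(nrow(ev))[-1]) {
    if (ev[k, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], ev[k, 2])
    else out <- rbind(out, ev[k, , drop = FALSE])
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, seizure fraction %.3f, seed %d\n",
              length(x$labels), mean(x$labels), x$params$seed))
  invisible(x)
}

#' Realise one subject's EEG record
#'
#' Deterministically regenerates subject `i`'s waveform from its stored
#' parameters and per-subject seed.
#' @param cohort a [generate_cohort()] result.
#' @param i subject index (or id).
#' @return an [eeg_recording()].
#' @export
cohort_eeg <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subject_id)
  p <- as.list(cohort$eeg_params[i, -1])
  generate_eeg(p, duration_s = cohort$params$eeg_duration_s,
               fs = cohort$params$fs,
               age_at_start = cohort$age_at_start_h[i],
               artifact_rate_per_h = cohort$params$artifact_rate_per_h,
               seed = cohort$eeg_seeds[i])
}

#' Seizure annotation of one subject
#' @inheritParams cohort_eeg
#' @return a [seizure_annotation()] (empty for non-seizure subjects).
#' @export
cohort_seizures <- function(cohort, i) {
  if (is.numeric(i)) i <- cohort$subject_id[i]
  ev <- cohort$seizures[cohort$seizures$subject_id == i, c("start_h", "end_h")]
  seizure_annotation(ev)
}

#' Inject missing-completely-at-random cells
#'
#' Each cell of each named column is independently set to `NA` with that
#' column's rate.
#' @param table a data frame.
#' @param rates named list/vector of per-column missing probabilities.
#' @param seed optional local seed.
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(unlist(rates) > 1 | unlist(rates) < 0))
    stop("missingness rates must lie in [0, 1]")
  for (f in intersect(names(rates), names(table))) {
    r <- rates[[f]]
    if (r > 0) table[[f]][runif(nrow(table)) < r] <- NA
  }
  table
}

#' Extract quantitative-EEG features for every cohort subject
#'
#' Per subject: realise the EEG, select the earliest admissible epoch
#' (before 12 h of age, >= 1 h before the first seizure), mask artifacts,
#' optionally reduce to the 2-channel bipolar aEEG montage, and run
#' [extract_features()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param bands a [band_scheme()].
#' @param montage `"ceeg"` (full montage) or `"aeeg"` (F3-C3 / F4-C4).
#' @param epoch_duration_s analysis epoch length (defaults to the
#'   generator's).
#' @param min_usable minimum usable fraction for epoch selection.
#' @param verbose print progress every 25 subjects.
#' @return data frame: `subject_id` plus [qeeg_feature_names()] columns.
#' @export
cohort_qeeg_features <- function(cohort, bands = band_scheme(),
                                 montage = c("ceeg", "aeeg"),
                                 epoch_duration_s = NULL,
                                 min_usable = 0.5, verbose = FALSE) {
  montage <- match.arg(montage)
  if (is.null(epoch_duration_s))
    epoch_duration_s <- cohort$params$epoch_duration_s
  n <- length(cohort$subject_id)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- cohort_eeg(cohort, i)
    ep <- select_epoch(rec, cohort_seizures(cohort, i),
                       duration_s = epoch_duration_s,
                       min_usable = min_usable)
    mrec <- mask_artifacts(rec, ep)
    if (montage == "aeeg") mrec <- to_aeeg_montage(mrec)
    rows[[i]] <- extract_features(
      mrec, bands,
      asm_before_epoch = cohort$adjusters$asm_before_epoch[i],
      hypothermia_at_epoch = cohort$adjusters$hypothermia_at_epoch[i])
    if (verbose && i %% 25 == 0) message("  qEEG features: ", i, "/", n)
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject_id = cohort$subject_id, out)
}
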