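#' Multichannel EEG recording container
#'
#' In-memory representation of a continuous multichannel EEG: a samples x
#' channels matrix in microvolts, the sampling rate, the infant's age at the
#' start of the recording and any annotated artifact intervals.  Intervals
#' are half-open `[start_s, end_s)` in seconds from record start.
#'
#' @param data numeric matrix, samples x channels, microvolts.
#' @param fs sampling rate in Hz (250 or 256 in the cohorts this package
#'   models; any positive rate is accepted).
#' @param channel_labels electrode names drawn from the neonatal 10:20
#'   montage (F3, F4, C3, C4, Cz, T3, T4, O1/P3, O2/P4).
#' @param age_at_start age in hours after birth at the first sample.
#' @param artifact_intervals two-column matrix or data frame of
#'   `(start_s, end_s)` intervals flagged unusable, or `NULL`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, age_at_start = 0,
                          artifact_intervals = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (fs <= 0) stop("fs must be positive")
  if (ncol(data) != length(channel_labels))
    stop("channel_labels length must match number of data columns")
  bad <- setdiff(channel_labels, MONTAGE_CHANNELS)
  if (length(bad))
    stop("channel labels outside the montage set: ",
         paste(bad, collapse = ", "))
  dur <- nrow(data) / fs
  ai <- normalize_intervals(artifact_intervals)
  if (nrow(ai) && any(ai[, 1] < 0 | ai[, 2] > dur + 1e-9))
    stop("artifact intervals fall outside the record duration")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 age_at_start = age_at_start,
                 artifact_intervals = ai,
                 mask = NULL,
                 fftcache = new.env(parent = emptyenv())),
            class = "eeg_recording")
}

normalize_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)))
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  x <- as.matrix(x)[, 1:2, drop = FALSE]
  storage.mode(x) <- "double"
  if (any(x[, 2] <= x[, 1])) stop("interval end must exceed start")
  colnames(x) <- c("start_s", "end_s")
  x[order(x[, 1]), , drop = FALSE]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %.1f s @ %g Hz, age %.2f h, %d artifact interval(s)\n",
              ncol(x$data), nrow(x$data) / x$fs, x$fs, x$age_at_start,
              nrow(x$artifact_intervals)))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length of the record in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' Read an EEG recording from an EDF file
#'
#' Reads an EDF/EDF+ file, keeps the channels whose labels match the
#' neonatal montage (labels such as `"EEG F3-REF"` are normalized to
#' `"F3"`), and returns an [eeg_recording()].  At least two montage channels
#' must be present.
#'
#' @param path EDF file path.
#' @param age_at_start age in hours after birth at the first sample.
#' @param artifact_intervals optional `(start_s, end_s)` intervals, e.g.
#'   from [read_artifact_annotations()].
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, age_at_start = 0, artifact_intervals = NULL) {
  raw <- read_edf(path)
  norm <- normalize_channel_label(raw$channel_labels)
  keep <- which(!is.na(norm))
  if (length(keep) < 2)
    stop("EDF file contains fewer than two montage channels (",
         paste(raw$channel_labels, collapse = ", "), ")")
  eeg_recording(raw$data[, keep, drop = FALSE], raw$fs, norm[keep],
                age_at_start = age_at_start,
                artifact_intervals = artifact_intervals)
}

normalize_channel_label <- function(labels) {
  up <- toupper(gsub("EEG|REF|[^A-Za-z0-9]", "", labels))
  hit <- match(up, toupper(MONTAGE_CHANNELS))
  # fall back to substring match for labels like "F3-C3" is deliberately NOT
  # done: bipolar channels are derived, not read
  ifelse(is.na(hit), NA_character_, MONTAGE_CHANNELS[hit])
}

#' Read artifact or seizure annotations from CSV
#'
#' Artifact files carry `onset_s` (or `onset_h`) and `duration_s` columns;
#' seizure files carry `start_h`/`end_h` (or `onset_h`/`duration_s`) in
#' hours after birth.  Extra columns (e.g. `label`, `subject_id`) are
#' ignored unless `subject` is given, in which case rows are filtered on
#' `subject_id`.
#'
#' @param path CSV path.
#' @param subject optional subject id filter.
#' @return `read_artifact_annotations`: matrix of `(start_s, end_s)`;
#'   `read_seizure_annotations`: a [seizure_annotation()].
#' @export
read_artifact_annotations <- function(path, subject = NULL) {
  d <- read.csv(path)
  if (!is.null(subject) && "subject_id" %in% names(d))
    d <- d[d$subject_id == subject, , drop = FALSE]
  onset <- if ("onset_s" %in% names(d)) d$onset_s else d$onset_h * 3600
  cbind(start_s = onset, end_s = onset + d$duration_s)
}

#' @rdname read_artifact_annotations
#' @export
read_seizure_annotations <- function(path, subject = NULL) {
  d <- read.csv(path)
  if (!is.null(subject) && "subject_id" %in% names(d))
    d <- d[d$subject_id == subject, , drop = FALSE]
  if ("start_h" %in% names(d)) {
    seizure_annotation(cbind(start_h = d$start_h, end_h = d$end_h))
  } else {
    seizure_annotation(cbind(start_h = d$onset_h,
                             end_h = d$onset_h + d$duration_s / 3600))
  }
}

#' Electrographic seizure annotation
#'
#' Events are `(start_h, end_h)` in hours after birth.  Events shorter than
#' `min_duration_s` (the 10-s electrographic minimum) are rejected.
#'
#' @param events two-column matrix/data frame of start/end hours; may have
#'   zero rows.
#' @param min_duration_s minimum admissible event duration in seconds.
#' @return object of class `seizure_annotation` (matrix with attributes).
#' @export
seizure_annotation <- function(events = NULL, min_duration_s = 10) {
  if (is.null(events) || NROW(events) == 0) {
    ev <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start_h", "end_h")))
  } else {
    ev <- as.matrix(events)[, 1:2, drop = FALSE]
    storage.mode(ev) <- "double"
    colnames(ev) <- c("start_h", "end_h")
    if (any(ev[, 2] <= ev[, 1]))
      stop("seizure end must exceed start")
    if (any((ev[, 2] - ev[, 1]) * 3600 < min_duration_s - 1e-9))
      stop("seizure events shorter than ", min_duration_s, " s")
    ev <- ev[order(ev[, 1]), , drop = FALSE]
  }
  structure(ev, class = c("seizure_annotation", "matrix"))
}

#' Select the analysis epoch
#'
#' Scans candidate windows of `duration_s` seconds forward from the start of
#' the record in `step_s` steps and returns the earliest window that (i)
#' ends at or before `max_age_h` hours of age, (ii) ends at least `guard_h`
#' hours before the first annotated seizure, and (iii) has at least
#' `min_usable` of its samples outside artifact intervals.
#'
#' @param rec an [eeg_recording()].
#' @param seizures a [seizure_annotation()] (may be empty).
#' @param duration_s epoch length in seconds (default one hour).
#' @param max_age_h latest admissible age, in hours, of the epoch end.
#' @param guard_h required gap, in hours, between epoch end and first
#'   seizure onset.
#' @param min_usable minimum usable (non-artifact) fraction of the window.
#' @param step_s scan granularity in seconds.
#' @return list of class `epoch_selection` with `start_age_h`, `start_s`
#'   (seconds from record start), `duration_s`, `usable_fraction`.
#' @export
select_epoch <- function(rec, seizures = seizure_annotation(),
                         duration_s = 3600, max_age_h = 12, guard_h = 1,
                         min_usable = 0.5, step_s = 60) {
  dur <- rec_duration(rec)
  if (dur < duration_s)
    stop("record (", round(dur), " s) shorter than requested epoch")
  first_sz_h <- if (nrow(seizures)) seizures[1, "start_h"] else Inf
  latest_end_h <- min(max_age_h, first_sz_h - guard_h)

  starts <- seq(0, dur - duration_s, by = step_s)
  fail <- c(age = 0L, usable = 0L)
  for (t0 in starts) {
    end_age_h <- rec$age_at_start + (t0 + duration_s) / 3600
    if (end_age_h > latest_end_h + 1e-9) { fail["age"] <- fail["age"] + 1L; next }
    uf <- usable_fraction(rec, t0, t0 + duration_s)
    if (uf < min_usable) { fail["usable"] <- fail["usable"] + 1L; next }
    return(structure(list(start_age_h = rec$age_at_start + t0 / 3600,
                          start_s = t0, duration_s = duration_s,
                          usable_fraction = uf),
                     class = "epoch_selection"))
  }
  why <- if (fail["age"] == length(starts)) {
    if (is.finite(first_sz_h) && first_sz_h - guard_h < max_age_h)
      sprintf("every window ends within %g h of the first seizure (onset %.2f h)",
              guard_h, first_sz_h)
    else
      sprintf("every window ends after %g h of age", max_age_h)
  } else {
    sprintf("no age-admissible window reaches usable fraction %g", min_usable)
  }
  stop("no qualifying epoch: ", why)
}

usable_fraction <- function(rec, start_s, end_s) {
  ai <- rec$artifact_intervals
  if (!nrow(ai)) return(1)
  lo <- pmax(ai[, 1], start_s); hi <- pmin(ai[, 2], end_s)
  masked <- sum(pmax(hi - lo, 0))
  # intervals are stored sorted but may overlap; merge before summing
  if (nrow(ai) > 1) {
    iv <- cbind(lo, hi)[hi > lo, , drop = FALSE]
    if (nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      merged <- iv[1, , drop = FALSE]
      for (k in 2:nrow(iv)) {
        if (iv[k, 1] <= merged[nrow(merged), 2])
          merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
        else merged <- rbind(merged, iv[k, ])
      }
      masked <- sum(merged[, 2] - merged[, 1])
    }
  }
  1 - masked / (end_s - start_s)
}

#' Crop a recording to an epoch and flag artifact samples
#'
#' Returns the epoch-cropped recording with a logical `mask` (TRUE =
#' usable).  Downstream estimators skip masked samples; short-time spectral
#' estimators drop every analysis window that overlaps the mask.
#'
#' @param rec an [eeg_recording()].
#' @param epoch an `epoch_selection` from [select_epoch()].
#' @return an [eeg_recording()] with `$mask` set.
#' @export
mask_artifacts <- function(rec, epoch) {
  i0 <- round(epoch$start_s * rec$fs)
  n <- round(epoch$duration_s * rec$fs)
  if (i0 < 0 || i0 + n > nrow(rec$data)) stop("epoch outside record")
  data <- rec$data[(i0 + 1):(i0 + n), , drop = FALSE]
  mask <- rep(TRUE, n)
  ai <- rec$artifact_intervals
  for (k in seq_len(nrow(ai))) {
    a <- max(0, floor((ai[k, 1] - epoch$start_s) * rec$fs))
    b <- min(n, ceiling((ai[k, 2] - epoch$start_s) * rec$fs))
    if (b > a) mask[(a + 1):b] <- FALSE
  }
  if (!any(mask)) stop("epoch empty: usable fraction is 0")
  out <- eeg_recording(data, rec$fs, rec$channel_labels,
                       age_at_start = epoch$start_age_h)
  out$mask <- mask
  out
}

#' Derive the 2-channel bipolar aEEG montage
#'
#' Builds the bipolar pair F3-C3 (left) and F4-C4 (right) used by
#' amplitude-integrated EEG devices, by elementwise subtraction of the
#' referential channels.
#'
#' @param rec an [eeg_recording()] containing F3, C3, F4, C4.
#' @return a 2-channel [eeg_recording()] with labels `F3` and `F4` standing
#'   for the bipolar derivations F3-C3 and F4-C4 (left/right hemisphere);
#'   the bipolar origin is recorded in attribute `derivations`.
#' @export
to_aeeg_montage <- function(rec) {
  need <- c("F3", "C3", "F4", "C4")
  miss <- setdiff(need, rec$channel_labels)
  if (length(miss))
    stop("aEEG montage needs F3, C3, F4, C4; missing: ",
         paste(miss, collapse = ", "))
  ix <- match(need, rec$channel_labels)
  data <- cbind(rec$data[, ix[1]] - rec$data[, ix[2]],
                rec$data[, ix[3]] - rec$data[, ix[4]])
  out <- eeg_recording(data, rec$fs, c("F3", "F4"),
                       age_at_start = rec$age_at_start,
                       artifact_intervals = rec$artifact_intervals)
  out$mask <- rec$mask
  attr(out, "derivations") <- c("F3-C3", "F4-C4")
  out
}
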