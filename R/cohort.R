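# Clinical / qualitative predictor assembly, preprocessing rules, and
# seizure-burden summaries.

#' One-hot encode categorical columns
#'
#' Character/factor columns become 0/1 indicator columns with the reference
#' level dropped; `unassisted_vaginal` is used as reference when present
#' (otherwise the first level).  `NA`s propagate to every indicator.
#' @param table data frame (a `subject_id` column is passed through).
#' @return data frame with numeric columns only.
#' @keywords internal
encode_one_hot <- function(table) {
  res <- if ("subject_id" %in% names(table))
    table[, "subject_id", drop = FALSE]
  else data.frame(row.names = seq_len(nrow(table)))
  for (f in setdiff(names(table), "subject_id")) {
    v <- table[[f]]
    if (is.character(v) || is.factor(v)) {
      lev <- unique(stats::na.omit(as.character(v)))
      ref <- if ("unassisted_vaginal" %in% lev) "unassisted_vaginal" else lev[1]
      for (l in setdiff(lev, ref))
        res[[paste0(f, "_", l)]] <- as.numeric(v == l)
    } else {
      res[[f]] <- as.numeric(v)
    }
  }
  res
}

#' Preprocess a predictor table: drop sparse columns, mean-impute
#'
#' Categorical fields are one-hot encoded first.  Columns whose missing
#' fraction exceeds `missing_threshold` are dropped and reported; every
#' remaining missing cell is replaced by the column mean over observed
#' values.
#'
#' @param table data frame (optionally with `subject_id`).
#' @param missing_threshold drop columns with missing fraction strictly
#'   above this value.
#' @return list: `table` (imputed), `report` with `dropped` column names
#'   and `means` used for imputation.
#' @export
preprocess_table <- function(table, missing_threshold = 0.5) {
  enc <- encode_one_hot(table)
  num_cols <- setdiff(names(enc), "subject_id")
  if (!length(num_cols)) stop("no predictor columns to preprocess")
  if (all(vapply(num_cols, function(f) all(is.na(enc[[f]])), TRUE)))
    stop("all predictor values missing")
  frac <- vapply(num_cols, function(f) mean(is.na(enc[[f]])), 0)
  dropped <- num_cols[frac > missing_threshold]
  enc <- enc[, setdiff(names(enc), dropped), drop = FALSE]
  means <- c()
  for (f in setdiff(names(enc), "subject_id")) {
    m <- mean(enc[[f]], na.rm = TRUE)
    means[f] <- m
    enc[[f]][is.na(enc[[f]])] <- m
  }
  list(table = enc, report = list(dropped = dropped, means = means))
}

#' Seizure-burden summary metrics
#'
#' Total burden in minutes, maximum burden within any sliding 60-min
#' window (evaluated exactly at event-boundary window positions), status
#' epilepticus (burden > 30 min within one hour), seizure period (first
#' onset to last offset) and the median per-event duration.
#'
#' @param ann a [seizure_annotation()].
#' @return list of class `seizure_metrics`.
#' @export
seizure_metrics <- function(ann) {
  if (!nrow(ann))
    return(structure(list(n_seizures = 0L, total_burden_min = 0,
                          max_hourly_burden_min = 0,
                          status_epilepticus = FALSE,
                          seizure_period_h = 0, median_duration_s = 0),
                     class = "seizure_metrics"))
  s <- ann[, "start_h"]; e <- ann[, "end_h"]
  burden_at <- function(t0) {           # minutes of seizure in [t0, t0+1h]
    sum(pmax(pmin(e, t0 + 1) - pmax(s, t0), 0)) * 60
  }
  cand <- unique(c(s, e - 1))
  maxb <- max(vapply(cand, burden_at, 0))
  structure(list(n_seizures = nrow(ann),
                 total_burden_min = sum(e - s) * 60,
                 max_hourly_burden_min = maxb,
                 status_epilepticus = maxb > 30,
                 seizure_period_h = max(e) - min(s),
                 median_duration_s = median((e - s) * 3600)),
            class = "seizure_metrics")
}

#' Assemble the per-mode design matrices for modelling
#'
#' Single modes (`clinical`, `qual`, `quant`) yield one feature matrix;
#' combination modes (`clinical+qual`, `clinical+quant`) yield the two
#' single-mode matrices side by side for late fusion -- feature columns
#' are never concatenated across modes.  Categorical clinical fields are
#' one-hot encoded; missing values are retained (imputation happens inside
#' each training fold).
#'
#' @param mode one of `clinical`, `qual`, `quant`, `clinical+qual`,
#'   `clinical+quant`.
#' @param labels named 0/1 vector or data frame (`subject_id`, `label`).
#' @param clinical,qualitative,qeeg data frames keyed by `subject_id`.
#' @return list: `mode`, `matrices` (named list of numeric matrices with
#'   subject rownames), `y`, `subject_id`.
#' @export
assemble_design <- function(mode = c("clinical", "qual", "quant",
                                     "clinical+qual", "clinical+quant"),
                            labels, clinical = NULL, qualitative = NULL,
                            qeeg = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(labels)) {
    ids <- labels$subject_id; y <- labels$label
  } else {
    ids <- names(labels); y <- as.numeric(labels)
  }
  if (is.null(ids)) stop("labels must carry subject ids")

  need <- strsplit(mode, "+", fixed = TRUE)[[1]]
  tabs <- list(clinical = clinical, qual = qualitative, quant = qeeg)
  mats <- list()
  for (m in need) {
    t <- tabs[[m]]
    if (is.null(t)) stop("mode ", mode, " requires the ", m, " table")
    missing_ids <- setdiff(ids, t$subject_id)
    if (length(missing_ids))
      stop("subjects absent from the ", m, " table: ",
           paste(missing_ids, collapse = ", "))
    t <- t[match(ids, t$subject_id), , drop = FALSE]
    enc <- encode_one_hot(t)
    X <- as.matrix(enc[, setdiff(names(enc), "subject_id"), drop = FALSE])
    rownames(X) <- ids
    mats[[m]] <- X
  }
  list(mode = mode, matrices = mats, y = y, subject_id = ids)
}
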