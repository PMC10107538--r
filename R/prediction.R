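# Nested leave-one-out model training and late-stage probability fusion.

#' Model specification
#'
#' Frozen learner configurations: clinical and qualitative models use a
#' random forest with 100 trees and depth grid \{1,2,3,4\}; the
#' quantitative model uses gradient boosting with 40 iterations, learning
#' rate 0.1 and depth grid \{2,...,6\}.
#'
#' @param learner `"random_forest"` or `"gradient_boosting"`.
#' @param n_trees,learning_rate,depth_grid override the frozen defaults.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(learner = c("random_forest", "gradient_boosting"),
                       n_trees = NULL, learning_rate = NULL,
                       depth_grid = NULL) {
  learner <- match.arg(learner)
  if (learner == "random_forest") {
    spec <- list(learner = learner,
                 n_trees = n_trees %||% 100L,
                 learning_rate = NA_real_,
                 depth_grid = depth_grid %||% 1:4)
  } else {
    spec <- list(learner = learner,
                 n_trees = n_trees %||% 40L,
                 learning_rate = learning_rate %||% 0.1,
                 depth_grid = depth_grid %||% 2:6)
  }
  structure(spec, class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default spec for each design-matrix mode
mode_spec <- function(mode) {
  if (mode == "quant") model_spec("gradient_boosting")
  else model_spec("random_forest")
}

#' Nested leave-one-out cross-validation
#'
#' The outer loop leaves each subject out in turn.  On the remaining
#' subjects, tree depth is selected by stratified 10-fold cross-validation
#' repeated 5 times (a fresh random fold split per repetition), scoring
#' each depth by the mean out-of-fold Matthews correlation coefficient at
#' threshold 0.5, ties broken toward the shallower tree.  The winning
#' depth is refit on all n-1 subjects and applied to the held-out subject.
#' Mean imputation of missing features is fit inside each outer training
#' set.  Every probability is therefore produced by a model never trained
#' on that subject.
#'
#' @param X numeric matrix (subjects x features; `NA` allowed).
#' @param y 0/1 labels.
#' @param spec a [model_spec()].
#' @param n_folds,n_rep inner cross-validation layout.
#' @param newdata optional matrix of the same shape as `X`; when supplied,
#'   the held-out subject's features are taken from `newdata` at
#'   prediction time (training always uses `X`).  This is the hook used by
#'   the leakage audit.
#' @param subject_ids optional ids (default rownames of `X`).
#' @return data frame of class `prediction_set`: `subject_id`,
#'   `probability`, `label`, `chosen_depth`.
#' @export
nested_loocv <- function(X, y, spec, n_folds = 10, n_rep = 5,
                         newdata = NULL, subject_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) < 20) stop("nested LOOCV needs at least 20 subjects")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!is.null(newdata)) {
    newdata <- as.matrix(newdata)
    storage.mode(newdata) <- "double"
  }
  res <- cpp_nested_loocv(X, y, spec$learner == "random_forest",
                          as.integer(spec$n_trees),
                          ifelse(is.na(spec$learning_rate), 0,
                                 spec$learning_rate),
                          as.integer(spec$depth_grid),
                          as.integer(n_folds), as.integer(n_rep),
                          newdata)
  ids <- subject_ids %||% rownames(X) %||% sprintf("S%04d", seq_len(nrow(X)))
  structure(data.frame(subject_id = ids, probability = res$probability,
                       label = y, chosen_depth = res$chosen_depth,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

#' Late-stage logit fusion of two probability vectors
#'
#' Inverse-logit of the unweighted mean of the two logits; inputs are
#' clipped to `[1e-6, 1 - 1e-6]`.  Symmetric, monotone in each argument,
#' `fuse(p, p) = p` and `fuse(p, 1 - p) = 0.5`.
#'
#' @param pA,pB probabilities (vectorised).
#' @return fused probabilities.
#' @export
fuse <- function(pA, pB) {
  clip <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  stats::plogis((stats::qlogis(clip(pA)) + stats::qlogis(clip(pB))) / 2)
}

#' Run the models of an assembled design
#'
#' Single-mode designs are fit with the mode's frozen [model_spec()];
#' combination designs fit the two single-mode models independently under
#' the same nested LOOCV and fuse their out-of-fold probabilities with
#' [fuse()] (late fusion; feature columns are never concatenated).
#'
#' @param design result of [assemble_design()].
#' @param n_folds,n_rep inner cross-validation layout.
#' @return a `prediction_set`; for combination modes the per-component
#'   sets are attached as attribute `components`.
#' @export
run_prediction <- function(design, n_folds = 10, n_rep = 5) {
  parts <- lapply(names(design$matrices), function(m)
    nested_loocv(design$matrices[[m]], design$y, mode_spec(m),
                 n_folds = n_folds, n_rep = n_rep,
                 subject_ids = design$subject_id))
  names(parts) <- names(design$matrices)
  if (length(parts) == 1L) return(parts[[1]])
  out <- parts[[1]]
  out$probability <- fuse(parts[[1]]$probability, parts[[2]]$probability)
  out$chosen_depth <- NA_integer_
  attr(out, "components") <- parts
  out
}
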