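# Evaluation machinery: confusion matrices, precision/recall/F1 with macro
# and weighted aggregation, sequence-level stratified k-fold cross-validation
# of the full pipeline, and the accuracy-versus-window-size curve.

#' Build a confusion matrix
#'
#' @param truth,prediction Character vectors of true and predicted class
#'   names (same length).
#' @param classes Class universe fixing row/column order; default the
#'   10-class registry.
#' @return An integer matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, prediction,
                             classes = exercise_classes()$class) {
  if (length(truth) != length(prediction)) {
    abort_validation("`truth` and `prediction` must have the same length.")
  }
  tab <- table(
    factor(truth, levels = classes),
    factor(prediction, levels = classes)
  )
  m <- matrix(as.integer(tab), nrow = length(classes),
    dimnames = list(truth = classes, predicted = classes)
  )
  m
}

#' Evaluation metrics from a confusion matrix
#'
#' Per class: precision `cm[c,c] / colsum_c`, recall `cm[c,c] / rowsum_c`,
#' and their harmonic mean F1. Aggregates: accuracy `trace / total`, macro
#' averages (unweighted mean over classes with defined values) and
#' support-weighted averages. A class no decision was ever assigned to has
#' undefined precision; it is reported as 0 and flagged
#' (`precision_defined = FALSE`), never silently dropped.
#'
#' @param cm A square counts matrix (rows = truth, columns = predicted),
#'   e.g. from [confusion_matrix()].
#' @return An `eval_report` object; `tidy()` gives the per-class table,
#'   `glance()` the one-row summary.
#' @export
#' @examples
#' compute_metrics(matrix(c(8, 3, 2, 7), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))
#' ))
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort_validation("Confusion matrix must be square.")
  if (any(cm < 0)) abort_validation("Confusion matrix counts must be >= 0.")
  total <- sum(cm)
  if (total == 0) {
    abort_validation("Confusion matrix is empty (no decisions).")
  }
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  diagv <- diag(cm)
  colsum <- colSums(cm)
  rowsum <- rowSums(cm)
  precision_defined <- colsum > 0
  recall_defined <- rowsum > 0
  precision <- unname(ifelse(precision_defined, diagv / colsum, 0))
  recall <- unname(ifelse(recall_defined, diagv / rowsum, 0))
  precision_defined <- unname(precision_defined)
  recall_defined <- unname(recall_defined)
  denom <- precision + recall
  f1 <- ifelse(denom > 0, 2 * precision * recall / denom, 0)
  per_class <- tibble::tibble(
    class = classes,
    support = as.integer(rowsum),
    precision = precision,
    recall = recall,
    f1 = f1,
    precision_defined = precision_defined,
    recall_defined = recall_defined
  )
  macro <- function(v, defined) mean(v[defined])
  w <- rowsum / total
  structure(
    list(
      confusion = cm,
      per_class = per_class,
      accuracy = sum(diagv) / total,
      macro_precision = macro(precision, precision_defined),
      macro_recall = macro(recall, recall_defined),
      macro_f1 = macro(f1, precision_defined | recall_defined),
      weighted_precision = sum(w * precision),
      weighted_recall = sum(w * recall),
      weighted_f1 = sum(w * f1),
      n_decisions = total
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %d decisions, accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f>\n",
    x$n_decisions, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1
  ))
  print(x$per_class)
  invisible(x)
}

#' Per-class metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `class`, `support`, `precision`, `recall`, `f1` and
#'   definedness flags.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, macro and weighted precision/recall/F1
#'   and `n_decisions`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    weighted_precision = x$weighted_precision,
    weighted_recall = x$weighted_recall,
    weighted_f1 = x$weighted_f1,
    n_decisions = x$n_decisions
  )
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (all metrics), `confusion.csv` and
#' `per_class.csv` into a directory.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(
      as.list(glance(report)),
      list(per_class = tidy(report))
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cm <- tibble::as_tibble(as.data.frame.matrix(report$confusion),
    .name_repair = "minimal"
  )
  cm <- dplyr::bind_cols(tibble::tibble(truth = rownames(report$confusion)), cm)
  readr::write_csv(cm, file.path(dir, "confusion.csv"), progress = FALSE)
  readr::write_csv(tidy(report), file.path(dir, "per_class.csv"),
    progress = FALSE
  )
  invisible(dir)
}

# Stratified fold assignment at the sequence level. Returns integer fold ids.
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      abort_validation(sprintf(
        "Class '%s' has only %d sequence(s); %d-fold stratification needs at least %d.",
        cls, length(idx), k, k
      ))
    }
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the labelled sequences into `k` folds stratified by class at the
#' sequence level (all frames of a video stay on one side of every split),
#' trains the CNN on each training portion and scores the held-out sequences
#' window by window. The pooled report sums the per-fold confusion matrices,
#' so pooled accuracy is `trace / total` of the summed matrix. The decision
#' unit throughout is the ensemble window.
#'
#' @param seqs Named list of labelled [pose_sequence()] objects (e.g.
#'   `simulate_dataset()$sequences` or [load_dataset()]).
#' @param k Number of folds (default 5; must be >= 2).
#' @param model_config A [cnn_config()].
#' @param ensemble_cfg An [ensemble_config()].
#' @param angles,standardize Feature options.
#' @param seed Seed controlling fold assignment and each fold's training.
#' @return A list with `folds` (list of `eval_report`), `pooled`
#'   (`eval_report` over the summed confusion matrix) and `assignments`
#'   (tibble `sequence_id, label, fold`).
#' @export
stratified_kfold_evaluate <- function(seqs, k = 5,
                                      model_config = cnn_config(),
                                      ensemble_cfg = ensemble_config(),
                                      angles = default_angle_set(),
                                      standardize = FALSE,
                                      seed = NULL) {
  if (k < 2) abort_validation("`k` must be at least 2.")
  labels <- vapply(
    seqs, function(s) pose_label(s) %||% NA_character_, character(1)
  )
  if (anyNA(labels)) {
    abort_validation("Every sequence must carry a label for cross-validation.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  folds <- .stratified_folds(labels, k)
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  assignments <- tibble::tibble(
    sequence_id = ids, label = labels, fold = folds
  )
  classes <- model_config$classes
  reports <- vector("list", k)
  pooled_cm <- matrix(0L, length(classes), length(classes),
    dimnames = list(truth = classes, predicted = classes)
  )
  for (f in seq_len(k)) {
    train_seqs <- seqs[folds != f]
    test_seqs <- seqs[folds == f]
    feats <- extract_dataset_features(
      train_seqs,
      angles = angles, standardize = standardize
    )
    model <- train_cnn(feats, model_config, seed = NULL)
    truth <- character(0)
    pred <- character(0)
    for (s in test_seqs) {
      dec <- suppressWarnings(classify_stream(
        model, s, ensemble_cfg,
        angles = angles, standardize = standardize
      ))
      if (nrow(dec) == 0) next
      truth <- c(truth, rep(pose_label(s), nrow(dec)))
      pred <- c(pred, dec$predicted)
    }
    cm <- confusion_matrix(truth, pred, classes)
    reports[[f]] <- compute_metrics(cm)
    pooled_cm <- pooled_cm + cm
  }
  list(
    folds = reports,
    pooled = compute_metrics(pooled_cm),
    assignments = assignments
  )
}

#' Window accuracy as a function of the window size
#'
#' Scores labelled test sequences with [classify_stream()] at each candidate
#' window size `K` (stride `K`, non-overlapping) and reports the fraction of
#' correct window decisions. `K = 1` is single-frame accuracy; the curve
#' shows how much pooling more frames into one soft vote buys.
#'
#' @param model A trained `cnn_model`.
#' @param seqs Named list of labelled test sequences.
#' @param frame_counts Candidate window sizes (duplicates are dropped).
#'   Default `c(1, 5, 10, 20, 30, 45, 60)`.
#' @param angles,standardize Feature options.
#' @return A tibble `K, accuracy, n_windows`; window sizes longer than every
#'   test sequence are skipped with a warning.
#' @export
accuracy_vs_frames <- function(model, seqs,
                               frame_counts = c(1, 5, 10, 20, 30, 45, 60),
                               angles = default_angle_set(),
                               standardize = FALSE) {
  frame_counts <- sort(unique(as.integer(frame_counts)))
  labels <- vapply(
    seqs, function(s) pose_label(s) %||% NA_character_, character(1)
  )
  if (anyNA(labels)) {
    abort_validation("Every sequence must carry a label.")
  }
  # score frames once, reuse across all K
  probs_list <- purrr::map(seqs, function(s) {
    feats <- extract_features(s, angles = angles, standardize = standardize)
    X <- .feature_matrix(feats, model$config$input_length)
    .cnn_predict_matrix(model$params, model$config, X)
  })
  classes <- model$config$classes
  rows <- list()
  for (K in frame_counts) {
    cfg <- ensemble_config(window = K, stride = K)
    correct <- 0L
    n_win <- 0L
    for (i in seq_along(probs_list)) {
      probs <- probs_list[[i]]
      starts <- .window_starts(nrow(probs), cfg)
      for (s in starts) {
        v <- soft_vote(probs[s:(s + K - 1L), , drop = FALSE])
        n_win <- n_win + 1L
        if (identical(v$predicted, labels[[i]])) correct <- correct + 1L
      }
    }
    if (n_win == 0L) {
      rlang::warn(sprintf(
        "Window size %d exceeds every test sequence; skipped.", K
      ))
      next
    }
    rows <- c(rows, list(tibble::tibble(
      K = K, accuracy = correct / n_win, n_windows = n_win
    )))
  }
  dplyr::bind_rows(rows)
}
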