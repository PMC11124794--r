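# Soft-voting ensemble over frames: per-frame class-probability vectors are
# summed over a K-frame window (summing and averaging pick the same argmax)
# and the window's class is the argmax, ties broken by lowest class index.

#' Ensemble window configuration
#'
#' @param window Number of frames pooled into one decision (default 30).
#' @param stride Step between window starts; defaults to `window`
#'   (non-overlapping decisions). `stride = 1` gives a sliding, per-frame
#'   verdict for latency-sensitive streaming.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(window = 30L, stride = window) {
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (is.na(window) || window < 1L) {
    abort_config("`window` must be a positive integer.")
  }
  if (is.na(stride) || stride < 1L) {
    abort_config("`stride` must be a positive integer.")
  }
  structure(list(window = window, stride = stride), class = "ensemble_config")
}

#' Soft vote over per-frame probability vectors
#'
#' Sums the class-probability vectors element-wise and predicts the class
#' with the largest summed score. Ties are broken by the lowest class index.
#' Dividing the scores by the number of frames (averaging) never changes the
#' decision.
#'
#' @param probs A numeric matrix (rows = frames, columns = classes), or a
#'   data frame of probability columns. Column names, when present, name the
#'   classes.
#' @return A list with `scores` (named numeric vector of summed
#'   probabilities), `predicted` (class name or column index if unnamed) and
#'   `n_frames`.
#' @export
#' @examples
#' soft_vote(rbind(c(0.6, 0.4), c(0.2, 0.8), c(0.3, 0.7)))
soft_vote <- function(probs) {
  if (is.data.frame(probs)) probs <- as.matrix(probs)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (nrow(probs) == 0) {
    abort_validation("soft_vote() needs at least one probability vector.")
  }
  if (!is.numeric(probs) || anyNA(probs)) {
    abort_validation("Probability vectors must be numeric and NA-free.")
  }
  scores <- colSums(probs)
  best <- which.max(scores) # first maximum = lowest class index on ties
  predicted <- if (!is.null(colnames(probs))) colnames(probs)[best] else best
  list(
    scores = scores,
    predicted = predicted,
    n_frames = nrow(probs)
  )
}

# Window starts (1-based) for n frames. Windows are [s, s + K).
.window_starts <- function(n, cfg) {
  if (n < cfg$window) {
    return(integer(0))
  }
  seq(1L, n - cfg$window + 1L, by = cfg$stride)
}

#' Classify a pose sequence window by window
#'
#' Extracts the per-frame attribute vectors, scores each frame with the CNN
#' and pools each block of `window` consecutive frames by [soft_vote()] into
#' one decision. Sequences shorter than the window yield zero decisions (with
#' a warning). Frames whose feature extraction produced NaN angles (lenient
#' degenerate-joint mode) are excluded from their window's vote; a window
#' with no valid frame yields no decision.
#'
#' @param model A trained `cnn_model`.
#' @param seq A [pose_sequence()].
#' @param config An [ensemble_config()].
#' @param angles,standardize,degenerate Passed to [extract_features()].
#' @return A tibble with one row per window: `sequence_id`, `window_start`,
#'   `window_end` (0-based, half-open), `predicted` and one `score_<i>`
#'   column per class index.
#' @export
classify_stream <- function(model, seq, config = ensemble_config(),
                            angles = default_angle_set(),
                            standardize = FALSE,
                            degenerate = c("error", "nan")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(seq, "pose_sequence")) seq <- pose_sequence(seq)
  feats <- extract_features(
    seq,
    angles = angles, standardize = standardize, degenerate = degenerate
  )
  X <- .feature_matrix(feats, model$config$input_length)
  valid <- stats::complete.cases(X)
  probs <- matrix(NA_real_, nrow(X), length(model$config$classes))
  if (any(valid)) {
    probs[valid, ] <- .cnn_predict_matrix(
      model$params, model$config, X[valid, , drop = FALSE]
    )
  }
  colnames(probs) <- model$config$classes
  n <- nrow(probs)
  starts <- .window_starts(n, config)
  if (length(starts) == 0) {
    rlang::warn(sprintf(
      "Sequence '%s' has %d frame(s), shorter than the %d-frame window: no decisions.",
      seq$sequence_id[[1]], n, config$window
    ))
  }
  score_cols <- paste0("score_", seq_along(model$config$classes) - 1L)
  rows <- list()
  dropped <- 0L
  for (s in starts) {
    idx <- s:(s + config$window - 1L)
    w <- probs[idx, , drop = FALSE]
    w <- w[stats::complete.cases(w), , drop = FALSE]
    if (nrow(w) == 0) {
      dropped <- dropped + 1L
      next
    }
    v <- soft_vote(w)
    row <- tibble::tibble(
      sequence_id = seq$sequence_id[[1]],
      window_start = s - 1L,
      window_end = s + config$window - 1L,
      predicted = v$predicted
    )
    row[score_cols] <- as.list(unname(v$scores))
    rows <- c(rows, list(row))
  }
  if (dropped > 0) {
    rlang::warn(sprintf(
      "%d window(s) had no valid frames and yielded no decision.", dropped
    ))
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(
      sequence_id = character(), window_start = integer(),
      window_end = integer(), predicted = character()
    )
    out[score_cols] <- purrr::map(score_cols, ~numeric(0))
    return(out)
  }
  dplyr::bind_rows(rows)
}

#' Single verdict for a whole sequence
#'
#' Majority vote over the window decisions of [classify_stream()]; ties are
#' broken by the classes' total summed scores, then by lowest class index.
#' If the sequence is shorter than the window (no decisions), it falls back
#' to one soft vote over all frames.
#'
#' @inheritParams classify_stream
#' @return A single class name.
#' @export
classify_sequence <- function(model, seq, config = ensemble_config(),
                              angles = default_angle_set(),
                              standardize = FALSE,
                              degenerate = c("error", "nan")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(seq, "pose_sequence")) seq <- pose_sequence(seq)
  decisions <- withCallingHandlers(
    classify_stream(
      model, seq, config,
      angles = angles, standardize = standardize, degenerate = degenerate
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  classes <- model$config$classes
  if (nrow(decisions) == 0) {
    feats <- extract_features(
      seq,
      angles = angles, standardize = standardize, degenerate = degenerate
    )
    X <- .feature_matrix(feats, model$config$input_length)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(X) == 0) {
      abort_validation("No valid frames to classify.")
    }
    probs <- .cnn_predict_matrix(model$params, model$config, X)
    return(soft_vote(probs)$predicted)
  }
  votes <- table(factor(decisions$predicted, levels = classes))
  top <- max(votes)
  contenders <- names(votes)[votes == top]
  if (length(contenders) == 1) {
    return(contenders)
  }
  score_cols <- paste0("score_", seq_along(classes) - 1L)
  totals <- colSums(as.matrix(decisions[score_cols]))
  names(totals) <- classes
  contenders[which.max(totals[contenders])]
}

#' Write window decisions to CSV
#'
#' @param decisions Tibble from [classify_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  readr::write_csv(decisions, path, progress = FALSE)
  invisible(path)
}
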