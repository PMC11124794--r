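#' Construct a pose sequence
#'
#' A pose sequence is a long tibble with one row per landmark per frame and
#' columns `sequence_id`, `frame`, `landmark`, `x`, `y`, `z` and optionally
#' `visibility`. The tibble carries the frame rate and an optional exercise
#' label as attributes and has class `pose_sequence`, so it flows through
#' dplyr pipelines like any tibble but validates its invariants on
#' construction: every frame holds exactly the 22 registry landmarks, all
#' coordinates are finite, and frame indices are strictly increasing.
#'
#' Coordinates may be image-normalized (MediaPipe's default) or metric; the
#' joint-angle features are scale-invariant, so no particular unit is
#' enforced, only finiteness.
#'
#' @param data A data frame with columns `frame`, `landmark`, `x`, `y`, `z`
#'   and optionally `visibility` and `sequence_id`.
#' @param sequence_id Sequence identifier; defaults to the `sequence_id`
#'   column of `data` (which must then be constant).
#' @param fps Frames per second (positive real). Default 30.
#' @param label Optional exercise class label (validated against
#'   [exercise_classes()]).
#' @return A `pose_sequence` tibble.
#' @seealso [read_sequence()], [simulate_sequence()]
#' @export
pose_sequence <- function(data, sequence_id = NULL, fps = 30, label = NULL) {
  data <- tibble::as_tibble(data)
  needed <- c("frame", "landmark", "x", "y", "z")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort_validation(paste0(
      "Pose data is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (is.null(sequence_id)) {
    if ("sequence_id" %in% names(data)) {
      ids <- unique(data$sequence_id)
      if (length(ids) != 1) {
        abort_validation("`data` contains more than one sequence_id.")
      }
      sequence_id <- as.character(ids)
    } else {
      sequence_id <- "seq"
    }
  }
  if (nrow(data) == 0) {
    abort_validation("A pose sequence must contain at least one frame.")
  }
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort_validation("`fps` must be a single positive number.")
  }
  if (!is.null(label)) {
    label <- normalize_class(label)
    if (length(label) != 1) abort_validation("`label` must be a single class.")
  }

  data$sequence_id <- sequence_id
  for (col in intersect(c("x", "y", "z", "visibility"), names(data))) {
    data[[col]] <- unname(as.numeric(data[[col]]))
  }
  data$frame <- as.integer(data$frame)
  if (anyNA(data$frame) || any(data$frame < 0)) {
    abort_validation("Frame indices must be non-negative integers.")
  }
  .assert_finite(data$x, "x coordinates")
  .assert_finite(data$y, "y coordinates")
  .assert_finite(data$z, "z coordinates")
  if ("visibility" %in% names(data) && !all(is.na(data$visibility))) {
    v <- data$visibility[!is.na(data$visibility)]
    if (!is.numeric(data$visibility) || any(v < 0 | v > 1)) {
      abort_validation("`visibility` values must lie in [0, 1].")
    }
  }

  bad_names <- setdiff(unique(data$landmark), .LANDMARK_NAMES)
  if (length(bad_names) > 0) {
    abort_validation(paste0(
      "Unknown landmark name(s): ", paste(sQuote(bad_names), collapse = ", "), "."
    ))
  }

  data <- dplyr::arrange(
    data,
    .data$frame, match(.data$landmark, .LANDMARK_NAMES)
  )

  counts <- table(data$frame)
  if (any(counts != 22L)) {
    bad <- names(counts)[counts != 22L]
    abort_validation(paste0(
      "Every frame must contain exactly the 22 body landmarks; frame(s) ",
      paste(utils::head(bad, 5), collapse = ", "), " do not."
    ))
  }
  dup <- dplyr::summarise(
    dplyr::group_by(data, .data$frame),
    dup = anyDuplicated(.data$landmark) > 0, .groups = "drop"
  )
  if (any(dup$dup)) {
    abort_validation("Duplicated landmark within a frame.")
  }

  keep <- intersect(
    c("sequence_id", "frame", "landmark", "x", "y", "z", "visibility"),
    names(data)
  )
  out <- data[keep]
  attr(out, "fps") <- as.numeric(fps)
  attr(out, "label") <- label
  class(out) <- c("pose_sequence", class(tibble::tibble()))
  out
}

#' @export
print.pose_sequence <- function(x, ...) {
  lab <- pose_label(x)
  cat(sprintf(
    "<pose_sequence '%s': %d frames @ %g fps%s>\n",
    x$sequence_id[[1]], n_frames(x), pose_fps(x),
    if (is.null(lab)) "" else paste0(", label: ", lab)
  ))
  NextMethod()
}

#' Pose-sequence accessors
#'
#' @param x A `pose_sequence`.
#' @return `n_frames()` the number of frames; `pose_fps()` the frame rate;
#'   `pose_label()` the exercise label or `NULL`.
#' @export
n_frames <- function(x) length(unique(x$frame))

#' @rdname n_frames
#' @export
pose_fps <- function(x) attr(x, "fps", exact = TRUE) %||% 30

#' @rdname n_frames
#' @export
pose_label <- function(x) attr(x, "label", exact = TRUE)

# Dense numeric view: array (frames x 22 landmarks x 3 coords), frames sorted.
# Relies on pose_sequence() having sorted rows by (frame, registry order).
.pose_array <- function(seq) {
  frames <- unique(seq$frame)
  n <- length(frames)
  m <- cbind(seq$x, seq$y, seq$z) # (n*22) x 3, landmark fastest within frame
  a <- array(0, dim = c(n, 22L, 3L))
  for (d in 1:3) {
    a[, , d] <- matrix(m[, d], nrow = n, ncol = 22L, byrow = TRUE)
  }
  dimnames(a) <- list(NULL, .LANDMARK_NAMES, c("x", "y", "z"))
  attr(a, "frames") <- frames
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
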