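# Fixed registries: the 22 non-facial MediaPipe Pose landmarks and the 10
# exercise classes. Both orders are load-bearing (feature column order and
# class-probability column order) and must never depend on the locale.

.LANDMARK_NAMES <- c(
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

# MediaPipe Pose indices 11..32, aligned with .LANDMARK_NAMES.
.LANDMARK_INDICES <- 11:32

# Case-insensitive alphabetical order; indices 0..9.
.CLASS_NAMES <- c(
  "arm raise", "bicycle crunch", "bird dog", "curl", "fly",
  "leg raise", "overhead press", "push-up", "squat", "superman"
)

#' Registry of the 22 body landmarks
#'
#' The MediaPipe Pose model emits 33 landmarks; indices 0--10 describe the
#' face and are not used for exercise classification. This registry fixes the
#' names and order of the remaining 22 body landmarks (indices 11--32). The
#' order defines the layout of the 66-coordinate feature block.
#'
#' @return A tibble with columns `landmark` (name) and `index` (MediaPipe
#'   Pose index, 11--32).
#' @export
#' @examples
#' mediapipe_landmarks()
mediapipe_landmarks <- function() {
  tibble::tibble(landmark = .LANDMARK_NAMES, index = .LANDMARK_INDICES)
}

#' Registry of the 10 exercise classes
#'
#' The classifier distinguishes ten repetitive exercises. Class indices are
#' assigned alphabetically (case-insensitive) and are fixed: they define the
#' order of class-probability vectors and of `score_*` columns in decision
#' tables.
#'
#' @return A tibble with columns `class` (name, lower case) and `index`
#'   (0--9).
#' @export
#' @examples
#' exercise_classes()
exercise_classes <- function() {
  tibble::tibble(class = .CLASS_NAMES, index = 0:9)
}

#' Map exercise labels to canonical class names
#'
#' Labels are matched case-insensitively against the class registry
#' ("Superman" and "superman" are the same class).
#'
#' @param x Character vector of labels.
#' @return Character vector of canonical (lower-case) class names.
#' @export
normalize_class <- function(x) {
  out <- tolower(trimws(x))
  bad <- setdiff(unique(out), .CLASS_NAMES)
  if (length(bad) > 0) {
    abort_validation(paste0(
      "Unknown exercise label(s): ", paste(sQuote(bad), collapse = ", "),
      ". Accepted classes: ", paste(.CLASS_NAMES, collapse = ", "), "."
    ))
  }
  out
}

# landmark name -> MediaPipe index (named integer vector)
.landmark_index_map <- function() {
  stats::setNames(.LANDMARK_INDICES, .LANDMARK_NAMES)
}

# MediaPipe index -> landmark name (named character vector)
.index_landmark_map <- function() {
  stats::setNames(.LANDMARK_NAMES, as.character(.LANDMARK_INDICES))
}
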