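#' Euclidean distance between 3-D points
#'
#' Body-segment lengths are plain Euclidean distances between landmark
#' coordinates; they feed the law-of-cosines joint angles.
#'
#' @param p,q Numeric length-3 vectors, or n x 3 matrices for vectorized use.
#' @return Non-negative distance(s).
#' @export
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
euclidean_distance <- function(p, q) {
  p <- .as_points(p)
  q <- .as_points(q)
  .assert_finite(p, "Point coordinates")
  .assert_finite(q, "Point coordinates")
  sqrt(rowSums((p - q)^2))
}

.as_points <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3) abort_validation("Points must have 3 columns (x, y, z).")
    p
  } else {
    if (length(p) != 3) abort_validation("A point must have 3 coordinates.")
    matrix(as.numeric(p), nrow = 1)
  }
}

#' Joint angle at a vertex landmark
#'
#' The interior angle of the triangle p1--p2--p3 at the vertex `p2`, computed
#' by the law of cosines from the three pairwise Euclidean distances
#' `a = |p1 p2|`, `b = |p2 p3|`, `c = |p3 p1|`:
#' \deqn{\angle p_1 p_2 p_3 = \frac{180}{\pi}\,
#'   \arccos\!\left(\frac{a^2 + b^2 - c^2}{2ab}\right)}
#' The arccos argument is clamped to \[-1, 1\] to absorb floating-point
#' overshoot on near-collinear joints. The result is in degrees, in
#' \[0, 180\], and is invariant under translation, rotation and uniform
#' scaling of the three points.
#'
#' @param p1,p2,p3 Numeric length-3 points or n x 3 matrices; `p2` is the
#'   vertex (the joint).
#' @param degenerate What to do when `p1` or `p3` coincides with the vertex
#'   (a zero-length segment): `"error"` (default) or `"nan"` (return `NaN`,
#'   for noisy real captures; downstream windows skip NaN frames).
#' @return Angle(s) in degrees in \[0, 180\].
#' @export
#' @examples
#' joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
joint_angle <- function(p1, p2, p3, degenerate = c("error", "nan")) {
  degenerate <- match.arg(degenerate)
  p1 <- .as_points(p1)
  p2 <- .as_points(p2)
  p3 <- .as_points(p3)
  a <- euclidean_distance(p1, p2)
  b <- euclidean_distance(p2, p3)
  cc <- euclidean_distance(p3, p1)
  bad <- a == 0 | b == 0
  if (any(bad)) {
    if (degenerate == "error") {
      abort_validation(paste0(
        "Degenerate joint: a limb segment has zero length (",
        sum(bad), " occurrence(s))."
      ))
    }
  }
  cosang <- (a^2 + b^2 - cc^2) / (2 * a * b)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- 180 / pi * acos(cosang)
  ang[bad] <- NaN
  ang
}

#' The default set of 12 joint angles
#'
#' Twelve bilaterally symmetric limb-joint angles computed per frame, each
#' defined by three landmarks with the middle one as the vertex:
#' elbow (shoulder--elbow--wrist), shoulder (elbow--shoulder--hip),
#' hip (shoulder--hip--knee), knee (hip--knee--ankle),
#' ankle (knee--ankle--foot_index) and wrist (elbow--wrist--index), on each
#' body side. Any tibble with columns `angle`, `p1`, `p2`, `p3` referencing
#' registry landmarks can be supplied instead wherever an angle set is
#' accepted.
#'
#' @return A 12-row tibble with columns `angle`, `p1`, `p2` (vertex), `p3`.
#' @export
default_angle_set <- function() {
  base <- tibble::tribble(
    ~joint, ~a, ~vertex, ~b,
    "elbow", "shoulder", "elbow", "wrist",
    "shoulder", "elbow", "shoulder", "hip",
    "hip", "shoulder", "hip", "knee",
    "knee", "hip", "knee", "ankle",
    "ankle", "knee", "ankle", "foot_index",
    "wrist", "elbow", "wrist", "index"
  )
  sides <- tidyr::crossing(side = c("left", "right"), base)
  out <- tibble::tibble(
    angle = paste(sides$side, sides$joint, sep = "_"),
    p1 = paste(sides$side, sides$a, sep = "_"),
    p2 = paste(sides$side, sides$vertex, sep = "_"),
    p3 = paste(sides$side, sides$b, sep = "_")
  )
  # fixed order: left block then right block, joints in the order above
  ord <- c(
    "left_elbow", "left_shoulder", "left_hip", "left_knee", "left_ankle",
    "left_wrist", "right_elbow", "right_shoulder", "right_hip", "right_knee",
    "right_ankle", "right_wrist"
  )
  out[match(ord, out$angle), ]
}

.validate_angle_set <- function(angles) {
  angles <- tibble::as_tibble(angles)
  needed <- c("angle", "p1", "p2", "p3")
  if (!all(needed %in% names(angles))) {
    abort_config("An angle set needs columns angle, p1, p2, p3.")
  }
  lm <- c(angles$p1, angles$p2, angles$p3)
  bad <- setdiff(unique(lm), .LANDMARK_NAMES)
  if (length(bad) > 0) {
    abort_config(paste0(
      "Angle set references unknown landmark(s): ",
      paste(sQuote(bad), collapse = ", "), "."
    ))
  }
  same <- angles$p1 == angles$p2 | angles$p2 == angles$p3 | angles$p1 == angles$p3
  if (any(same)) {
    abort_config("Each angle needs three distinct landmarks.")
  }
  angles
}

#' Feature column names
#'
#' @param angles An angle-set tibble; default [default_angle_set()].
#' @return Character vector `f000` ... (66 coordinate features followed by
#'   one per angle; length 78 with the default set).
#' @export
feature_names <- function(angles = default_angle_set()) {
  sprintf("f%03d", seq_len(66 + nrow(angles)) - 1L)
}

#' Describe each feature column
#'
#' @inheritParams feature_names
#' @return A tibble with columns `feature`, `kind` (`"coordinate"` or
#'   `"angle"`) and `meaning` (e.g. `"left_knee.x"` or the angle name).
#' @export
feature_dictionary <- function(angles = default_angle_set()) {
  coords <- paste(
    rep(.LANDMARK_NAMES, each = 3), rep(c("x", "y", "z"), times = 22),
    sep = "."
  )
  tibble::tibble(
    feature = feature_names(angles),
    kind = rep(c("coordinate", "angle"), c(66L, nrow(angles))),
    meaning = c(coords, angles$angle)
  )
}

#' Extract the per-frame attribute vectors from a pose sequence
#'
#' For every frame, concatenates the 66 raw landmark coordinates (22
#' landmarks x (x, y, z), in registry order) with the joint angles in
#' degrees (12 by default), giving the 78-attribute vector the per-frame
#' classifier consumes.
#'
#' @param seq A [pose_sequence()] (or a data frame acceptable to
#'   `pose_sequence()`).
#' @param angles Angle-set tibble; default [default_angle_set()].
#' @param standardize If `TRUE`, coordinate columns are centred and scaled by
#'   their per-sequence mean and standard deviation across frames. Angles are
#'   never standardized (they are already translation- and scale-invariant).
#'   Default `FALSE`: the classifier is trained on raw coordinates.
#' @param degenerate Degenerate-joint policy passed to [joint_angle()].
#' @return A tibble with columns `sequence_id`, `frame`, `f000`...`f077`
#'   (with the default angle set). Column meanings: [feature_dictionary()].
#' @export
extract_features <- function(seq, angles = default_angle_set(),
                             standardize = FALSE,
                             degenerate = c("error", "nan")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(seq, "pose_sequence")) seq <- pose_sequence(seq)
  angles <- .validate_angle_set(angles)
  a <- .pose_array(seq)
  frames <- attr(a, "frames")
  n <- length(frames)

  # coordinate block: column (l-1)*3 + d, landmark-major
  coords <- matrix(aperm(a, c(1, 3, 2)), nrow = n, ncol = 66L)

  if (isTRUE(standardize)) {
    mu <- colMeans(coords)
    sdv <- apply(coords, 2, stats::sd)
    if (n == 1) sdv[] <- 1
    sdv[sdv == 0 | is.na(sdv)] <- 1
    coords <- sweep(sweep(coords, 2, mu, "-"), 2, sdv, "/")
  }

  ang <- matrix(NA_real_, nrow = n, ncol = nrow(angles))
  for (j in seq_len(nrow(angles))) {
    ang[, j] <- joint_angle(
      a[, angles$p1[j], , drop = TRUE],
      a[, angles$p2[j], , drop = TRUE],
      a[, angles$p3[j], , drop = TRUE],
      degenerate = degenerate
    )
  }
  n_nan <- sum(!stats::complete.cases(ang))
  if (n_nan > 0) {
    rlang::inform(sprintf(
      "extract_features: %d frame(s) with degenerate joints yielded NaN angles.",
      n_nan
    ))
  }

  mat <- cbind(coords, ang)
  colnames(mat) <- feature_names(angles)
  out <- tibble::tibble(
    sequence_id = seq$sequence_id[[1]],
    frame = frames
  )
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

#' Extract features for a single frame
#'
#' @param frame A one-frame pose data frame (22 landmark rows).
#' @inheritParams extract_features
#' @return A named numeric vector of length `66 + nrow(angles)`.
#' @export
extract_frame_features <- function(frame, angles = default_angle_set(),
                                   degenerate = c("error", "nan")) {
  ft <- extract_features(frame, angles = angles, degenerate = degenerate)
  v <- as.numeric(ft[1, feature_names(angles)])
  stats::setNames(v, feature_names(angles))
}

#' Extract features for every sequence in a dataset
#'
#' Maps [extract_features()] over a list of labelled sequences and stacks the
#' results, attaching each sequence's label. This is the tabular training set
#' for [train_cnn()]: one row per frame, each frame inheriting its sequence's
#' label.
#'
#' @param seqs A list of [pose_sequence()] objects (e.g. from
#'   [load_dataset()] or [simulate_dataset()]).
#' @inheritParams extract_features
#' @return A tibble `sequence_id, frame, label, f000...`.
#' @export
extract_dataset_features <- function(seqs, angles = default_angle_set(),
                                     standardize = FALSE,
                                     degenerate = c("error", "nan")) {
  purrr::map_dfr(seqs, function(s) {
    ft <- extract_features(
      s,
      angles = angles, standardize = standardize, degenerate = degenerate
    )
    ft$label <- pose_label(s) %||% NA_character_
    dplyr::relocate(ft, "label", .after = "frame")
  })
}

#' Write a feature matrix to CSV
#'
#' @param features Tibble from [extract_features()] or
#'   [extract_dataset_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}
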