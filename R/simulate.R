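# Synthetic skeleton-motion generator.
#
# Each exercise class is caricatured by a periodic joint-angle signature:
# for every joint of the default 12-angle set,
#   angle(t) = clamp(baseline + amplitude * sin(2*pi*frequency*t + phase),
#                    5, 175) degrees,
# plus a whole-body trunk pitch (90 deg = upright, 0 deg = lying) and an
# optional vertical bob of the pelvis. Forward kinematics turns the angle
# trajectories into 22 landmark positions per frame over a fixed-segment
# skeleton. Each body side's limb chain lies in a plane parallel to the
# sagittal (x-y) plane, so the interior angles measured back from the
# landmarks by joint_angle() reproduce the input trajectories exactly; small
# fixed z offsets separate the sides and the finger landmarks. Gaussian
# coordinate noise and occasional outlier frames (pose-estimator glitches)
# are applied last.

#' Skeleton template: fixed segment lengths
#'
#' Segment lengths in metres of the simulated skeleton. Shoulder and hip
#' half-widths are equal (`body_width`), which keeps each body side's limb
#' chain exactly planar -- the property that makes generated joint angles
#' measurable back from the landmarks without error.
#'
#' @param body_width Shoulder/hip width (default 0.34).
#' @param torso Hip-to-shoulder length (0.52).
#' @param upper_arm,forearm,hand Arm segment lengths (0.30, 0.26, 0.18).
#' @param thigh,shank,foot,heel Leg segment lengths (0.42, 0.42, 0.22, 0.07).
#' @return A `skeleton_template` list.
#' @export
skeleton_template <- function(body_width = 0.34, torso = 0.52,
                              upper_arm = 0.30, forearm = 0.26, hand = 0.18,
                              thigh = 0.42, shank = 0.42, foot = 0.22,
                              heel = 0.07) {
  tpl <- list(
    body_width = body_width, torso = torso, upper_arm = upper_arm,
    forearm = forearm, hand = hand, thigh = thigh, shank = shank,
    foot = foot, heel = heel
  )
  if (any(unlist(tpl) <= 0)) {
    abort_config("All skeleton segment lengths must be positive.")
  }
  structure(tpl, class = "skeleton_template")
}

#' Landmark noise model
#'
#' Additive zero-mean Gaussian noise on every coordinate, plus outlier
#' frames: with probability `outlier_rate` a frame's landmarks are jittered
#' with `outlier_scale` times the base standard deviation, emulating a
#' pose-estimator glitch -- the failure mode the frame ensemble is designed
#' to absorb.
#'
#' @param coordinate_sigma Standard deviation of the per-coordinate noise,
#'   in the template's units. Default 0.0052 (1 percent of the default torso
#'   length).
#' @param outlier_rate Probability that a frame is an outlier. Default 0.05.
#' @param outlier_scale Noise multiplier on outlier frames. Default 10.
#' @return A `noise_model` list.
#' @export
noise_model <- function(coordinate_sigma = 0.0052, outlier_rate = 0.05,
                        outlier_scale = 10) {
  if (coordinate_sigma < 0) abort_config("`coordinate_sigma` must be >= 0.")
  if (outlier_rate < 0 || outlier_rate >= 1) {
    abort_config("`outlier_rate` must lie in [0, 1).")
  }
  structure(
    list(
      coordinate_sigma = coordinate_sigma,
      outlier_rate = outlier_rate,
      outlier_scale = outlier_scale
    ),
    class = "noise_model"
  )
}

.JOINT_NAMES <- c(
  "left_elbow", "left_shoulder", "left_hip", "left_knee", "left_ankle",
  "left_wrist", "right_elbow", "right_shoulder", "right_hip", "right_knee",
  "right_ankle", "right_wrist"
)

# joints: named list joint -> c(baseline, amplitude, frequency, phase_left,
# phase_right); expanded to both sides.
.make_signature <- function(trunk_pitch, joints, bob_amp = 0, bob_freq = 0.4) {
  rows <- purrr::imap_dfr(joints, function(v, nm) {
    tibble::tibble(
      joint = paste(c("left", "right"), nm, sep = "_"),
      baseline = v[[1]], amplitude = v[[2]], frequency = v[[3]],
      phase = c(v[[4]], if (length(v) >= 5) v[[5]] else v[[4]])
    )
  })
  rows <- rows[match(.JOINT_NAMES, rows$joint), ]
  list(
    trunk_pitch = trunk_pitch,
    root_bob = list(amplitude = bob_amp, frequency = bob_freq),
    joints = rows
  )
}

#' Default class signatures
#'
#' Hand-designed periodic joint-angle signatures, one per exercise class,
#' each caricaturing the exercise's dominant joint motion (squat: large knee
#' and hip oscillation plus a pelvis bob; curl: elbow oscillation only;
#' bicycle crunch and bird dog: anti-phase left/right limbs while lying;
#' and so on). Every pair of classes differs by at least 15 degrees in some
#' joint's baseline or amplitude, which [validate_signatures()] enforces.
#'
#' @return A named list, one element per class, each with `trunk_pitch`
#'   (degrees; 90 = upright, 0 = horizontal), `root_bob`
#'   (`amplitude` in metres, `frequency` in Hz) and a 12-row `joints` tibble
#'   (`joint`, `baseline`, `amplitude` in degrees, `frequency` in Hz,
#'   `phase` in radians).
#' @export
default_signatures <- function() {
  pi_ <- pi
  sigs <- list(
    "arm raise" = .make_signature(90, list(
      elbow = c(170, 5, 0.5, 0), shoulder = c(90, 80, 0.5, 0),
      hip = c(172, 3, 0.5, 0), knee = c(172, 3, 0.5, 0),
      ankle = c(90, 3, 0.5, 0), wrist = c(170, 3, 0.5, 0)
    )),
    "bicycle crunch" = .make_signature(0, list(
      elbow = c(60, 10, 1, 0), shoulder = c(40, 10, 1, 0),
      hip = c(110, 40, 1, 0, pi_), knee = c(100, 55, 1, 0, pi_),
      ankle = c(95, 5, 1, 0), wrist = c(165, 3, 1, 0)
    )),
    "bird dog" = .make_signature(0, list(
      elbow = c(160, 10, 0.4, 0), shoulder = c(90, 70, 0.4, 0, pi_),
      hip = c(100, 50, 0.4, pi_, 0), knee = c(120, 45, 0.4, pi_, 0),
      ankle = c(90, 5, 0.4, 0), wrist = c(170, 3, 0.4, 0)
    )),
    "curl" = .make_signature(90, list(
      elbow = c(95, 70, 0.6, 0), shoulder = c(18, 6, 0.6, 0),
      hip = c(172, 3, 0.6, 0), knee = c(172, 3, 0.6, 0),
      ankle = c(88, 3, 0.6, 0), wrist = c(168, 5, 0.6, 0)
    )),
    "fly" = .make_signature(90, list(
      elbow = c(150, 12, 0.5, 0), shoulder = c(85, 38, 0.5, 0),
      hip = c(170, 4, 0.5, 0), knee = c(170, 4, 0.5, 0),
      ankle = c(90, 3, 0.5, 0), wrist = c(160, 6, 0.5, 0)
    )),
    "leg raise" = .make_signature(0, list(
      elbow = c(168, 5, 0.5, 0), shoulder = c(22, 5, 0.5, 0),
      hip = c(130, 42, 0.5, 0), knee = c(172, 4, 0.5, 0),
      ankle = c(110, 5, 0.5, 0), wrist = c(170, 3, 0.5, 0)
    )),
    "overhead press" = .make_signature(90, list(
      elbow = c(110, 58, 0.5, 0), shoulder = c(125, 42, 0.5, 0),
      hip = c(174, 3, 0.5, 0), knee = c(174, 3, 0.5, 0),
      ankle = c(90, 3, 0.5, 0), wrist = c(165, 8, 0.5, 0)
    )),
    "push-up" = .make_signature(0, list(
      elbow = c(120, 52, 0.6, 0), shoulder = c(52, 25, 0.6, 0),
      hip = c(168, 5, 0.6, 0), knee = c(172, 3, 0.6, 0),
      ankle = c(68, 5, 0.6, 0), wrist = c(150, 8, 0.6, 0)
    )),
    "squat" = .make_signature(90, list(
      elbow = c(168, 5, 0.4, 0), shoulder = c(42, 12, 0.4, 0),
      hip = c(115, 48, 0.4, pi_), knee = c(120, 52, 0.4, pi_),
      ankle = c(80, 15, 0.4, pi_), wrist = c(170, 3, 0.4, 0)
    ), bob_amp = 0.18, bob_freq = 0.4),
    "superman" = .make_signature(0, list(
      elbow = c(170, 4, 0.4, 0), shoulder = c(150, 22, 0.4, 0),
      hip = c(158, 16, 0.4, 0), knee = c(170, 4, 0.4, 0),
      ankle = c(120, 8, 0.4, 0), wrist = c(172, 3, 0.4, 0)
    ))
  )
  validate_signatures(sigs)
}

#' Validate a signature registry
#'
#' Checks every class has all 12 joints with non-negative amplitudes and
#' positive frequencies, and that every pair of classes is separated by at
#' least 15 degrees in some joint's baseline or amplitude (so classes are
#' kinematically distinguishable by construction).
#'
#' @param signatures A named list of class signatures (see
#'   [default_signatures()]).
#' @return `signatures`, invisibly usable, after validation.
#' @export
validate_signatures <- function(signatures) {
  for (cls in names(signatures)) {
    s <- signatures[[cls]]
    j <- tibble::as_tibble(s$joints)
    if (!setequal(j$joint, .JOINT_NAMES) || nrow(j) != 12L) {
      abort_config(paste0(
        "Signature for ", sQuote(cls), " must define exactly the 12 joints."
      ))
    }
    if (any(j$amplitude < 0)) {
      abort_config(paste0(sQuote(cls), ": amplitudes must be >= 0."))
    }
    if (any(j$frequency <= 0)) {
      abort_config(paste0(sQuote(cls), ": frequencies must be > 0."))
    }
  }
  cls <- names(signatures)
  for (i in seq_along(cls)) {
    for (k in seq_len(i - 1L)) {
      a <- signatures[[cls[i]]]$joints
      b <- signatures[[cls[k]]]$joints
      b <- b[match(a$joint, b$joint), ]
      sep <- max(abs(a$baseline - b$baseline), abs(a$amplitude - b$amplitude))
      if (sep < 15) {
        abort_config(sprintf(
          "Signatures for '%s' and '%s' differ by less than 15 degrees in every joint baseline and amplitude.",
          cls[i], cls[k]
        ))
      }
    }
  }
  invisible(signatures)
}

# Evaluate a signature's 12 joint-angle trajectories at frame times t (sec).
# Returns matrix (n, 12) with columns .JOINT_NAMES, clamped to [5, 175].
.signature_angles <- function(sig, t) {
  j <- sig$joints
  out <- matrix(NA_real_, length(t), 12L, dimnames = list(NULL, .JOINT_NAMES))
  for (r in seq_len(nrow(j))) {
    ang <- j$baseline[r] +
      j$amplitude[r] * sin(2 * pi * j$frequency[r] * t + j$phase[r])
    out[, j$joint[r]] <- pmin(175, pmax(5, ang))
  }
  out
}

# Forward kinematics: angle matrix (n x 12) + trunk/bob -> array (n, 22, 3).
.forward_kinematics <- function(ang, trunk_pitch, bob_y, tpl) {
  n <- nrow(ang)
  d2r <- pi / 180
  cosd <- function(a) cos(a * d2r)
  sind <- function(a) sin(a * d2r)
  half <- tpl$body_width / 2
  out <- array(
    NA_real_,
    dim = c(n, 22L, 3L), dimnames = list(NULL, .LANDMARK_NAMES, NULL)
  )
  root_x <- rep(0, n)
  root_y <- bob_y
  sh_x <- root_x + tpl$torso * cosd(trunk_pitch)
  sh_y <- root_y + tpl$torso * sind(trunk_pitch)
  set <- function(name, x, y, z) {
    out[, name, 1] <<- x
    out[, name, 2] <<- y
    out[, name, 3] <<- rep_len(z, n)
  }
  for (side in c("left", "right")) {
    zs <- if (side == "left") half else -half
    zdir <- if (side == "left") 1 else -1
    g <- function(joint) ang[, paste(side, joint, sep = "_")]
    set(paste0(side, "_hip"), root_x, root_y, zs)
    set(paste0(side, "_shoulder"), sh_x, sh_y, zs)
    # leg chain
    a_thigh <- trunk_pitch - g("hip")
    knee_x <- root_x + tpl$thigh * cosd(a_thigh)
    knee_y <- root_y + tpl$thigh * sind(a_thigh)
    set(paste0(side, "_knee"), knee_x, knee_y, zs)
    a_shank <- a_thigh + 180 - g("knee")
    ankle_x <- knee_x + tpl$shank * cosd(a_shank)
    ankle_y <- knee_y + tpl$shank * sind(a_shank)
    set(paste0(side, "_ankle"), ankle_x, ankle_y, zs)
    a_foot <- a_shank + 180 - g("ankle")
    set(
      paste0(side, "_foot_index"),
      ankle_x + tpl$foot * cosd(a_foot), ankle_y + tpl$foot * sind(a_foot), zs
    )
    set(
      paste0(side, "_heel"),
      ankle_x - tpl$heel * cosd(a_foot), ankle_y - tpl$heel * sind(a_foot), zs
    )
    # arm chain
    a_upper <- trunk_pitch + 180 + g("shoulder")
    elbow_x <- sh_x + tpl$upper_arm * cosd(a_upper)
    elbow_y <- sh_y + tpl$upper_arm * sind(a_upper)
    set(paste0(side, "_elbow"), elbow_x, elbow_y, zs)
    a_fore <- a_upper + 180 - g("elbow")
    wrist_x <- elbow_x + tpl$forearm * cosd(a_fore)
    wrist_y <- elbow_y + tpl$forearm * sind(a_fore)
    set(paste0(side, "_wrist"), wrist_x, wrist_y, zs)
    a_hand <- a_fore + 180 - g("wrist")
    set(
      paste0(side, "_index"),
      wrist_x + tpl$hand * cosd(a_hand), wrist_y + tpl$hand * sind(a_hand), zs
    )
    set(
      paste0(side, "_pinky"),
      wrist_x + 0.9 * tpl$hand * cosd(a_hand),
      wrist_y + 0.9 * tpl$hand * sind(a_hand), zs + 0.03 * zdir
    )
    set(
      paste0(side, "_thumb"),
      wrist_x + 0.45 * tpl$hand * cosd(a_hand),
      wrist_y + 0.45 * tpl$hand * sind(a_hand), zs - 0.02 * zdir
    )
  }
  out
}

#' Simulate one labelled pose sequence
#'
#' Evaluates the class's joint-angle signature over time, converts the
#' trajectories into 22 landmark positions per frame by forward kinematics
#' over the skeleton template, applies coordinate noise and outlier frames,
#' and returns a labelled [pose_sequence()]. With the same seed the output
#' is bit-identical.
#'
#' @param class Exercise class name (see [exercise_classes()]).
#' @param n_frames Number of frames (default 120).
#' @param fps Frame rate (default 30).
#' @param template A [skeleton_template()].
#' @param noise A [noise_model()]; use `noise_model(0, 0)` for noiseless
#'   kinematics.
#' @param signatures Signature registry (default [default_signatures()]).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param sequence_id Identifier for the sequence (default derived from the
#'   class).
#' @return A labelled `pose_sequence`.
#' @export
simulate_sequence <- function(class, n_frames = 120, fps = 30,
                              template = skeleton_template(),
                              noise = noise_model(),
                              signatures = default_signatures(),
                              seed = NULL, sequence_id = NULL) {
  class <- normalize_class(class)
  if (length(class) != 1) abort_validation("`class` must be a single label.")
  if (!class %in% names(signatures)) {
    abort_validation(paste0("No signature registered for class ", sQuote(class), "."))
  }
  if (n_frames < 1) abort_validation("`n_frames` must be >= 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  sig <- signatures[[class]]
  t <- (seq_len(n_frames) - 1L) / fps
  ang <- .signature_angles(sig, t)
  bob <- sig$root_bob$amplitude *
    sin(2 * pi * sig$root_bob$frequency * t + pi / 2)
  a <- .forward_kinematics(ang, sig$trunk_pitch, bob, template)

  if (noise$coordinate_sigma > 0) {
    a <- a + array(
      stats::rnorm(length(a), 0, noise$coordinate_sigma), dim = dim(a)
    )
  }
  if (noise$outlier_rate > 0) {
    is_outlier <- stats::runif(n_frames) < noise$outlier_rate
    if (any(is_outlier)) {
      k <- sum(is_outlier)
      a[is_outlier, , ] <- a[is_outlier, , , drop = FALSE] + array(
        stats::rnorm(
          k * 22L * 3L, 0,
          noise$outlier_scale * max(noise$coordinate_sigma, 1e-6)
        ),
        dim = c(k, 22L, 3L)
      )
    }
  }

  sequence_id <- sequence_id %||% paste0(gsub("[^a-z]+", "_", class), "_sim")
  df <- tibble::tibble(
    sequence_id = sequence_id,
    frame = rep(seq_len(n_frames) - 1L, each = 22L),
    landmark = rep(.LANDMARK_NAMES, times = n_frames),
    x = as.vector(t(a[, , 1])),
    y = as.vector(t(a[, , 2])),
    z = as.vector(t(a[, , 3]))
  )
  pose_sequence(df, fps = fps, label = class)
}

#' Simulate a balanced labelled dataset
#'
#' Generates `sequences_per_class` sequences for each requested class, with
#' per-sequence seeds derived from the master seed (and recorded in the
#' manifest, so any single sequence can be regenerated). With `dir` set, the
#' sequences are written to disk via [write_sequence()] together with a
#' `manifest.csv`; otherwise everything is returned in memory.
#'
#' @param classes Character vector of class names (default all 10).
#' @param sequences_per_class Sequences per class (default 5).
#' @param n_frames,fps,template,noise,signatures As [simulate_sequence()].
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @param format `"csv"` or `"jsonl"` for on-disk sequences.
#' @return A list with `sequences` (named list of `pose_sequence`) and
#'   `manifest` (tibble `sequence_id, label, path, seed`; `path` is `NA`
#'   when nothing was written).
#' @export
simulate_dataset <- function(classes = exercise_classes()$class,
                             sequences_per_class = 5, n_frames = 120,
                             fps = 30, template = skeleton_template(),
                             noise = noise_model(),
                             signatures = default_signatures(),
                             seed = NULL, dir = NULL, format = "csv") {
  classes <- normalize_class(classes)
  if (sequences_per_class < 1) {
    abort_validation("`sequences_per_class` must be >= 1.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  grid <- tidyr::crossing(label = classes, rep = seq_len(sequences_per_class))
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  grid$sequence_id <- sprintf(
    "%s_%03d", gsub("[^a-z]+", "_", grid$label), grid$rep
  )
  seqs <- purrr::pmap(
    list(grid$label, grid$seed, grid$sequence_id),
    function(lab, sd, id) {
      simulate_sequence(
        lab,
        n_frames = n_frames, fps = fps, template = template, noise = noise,
        signatures = signatures, seed = sd, sequence_id = id
      )
    }
  )
  names(seqs) <- grid$sequence_id
  manifest <- tibble::tibble(
    sequence_id = grid$sequence_id, label = grid$label,
    path = NA_character_, seed = grid$seed
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "jsonl") "jsonl" else "csv"
    manifest$path <- paste0(manifest$sequence_id, ".", ext)
    purrr::walk2(seqs, manifest$path, function(s, p) {
      write_sequence(s, file.path(dir, p), format = format)
    })
    readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  }
  list(sequences = seqs, manifest = manifest)
}

# ---- signature registry serialization --------------------------------------

#' Read / write a signature registry file
#'
#' The registry file is YAML mapping each class to `trunk_pitch`,
#' `root_bob: {amplitude, frequency}` and `joints`, the latter mapping each
#' of the 12 joint names to `{baseline, amplitude, frequency, phase}`.
#'
#' @param signatures A signature registry list.
#' @param path File path.
#' @return `read_signature_registry()` returns a validated registry list;
#'   `write_signature_registry()` returns `path` invisibly.
#' @export
write_signature_registry <- function(signatures, path) {
  validate_signatures(signatures)
  out <- lapply(signatures, function(s) {
    j <- tibble::as_tibble(s$joints)
    joints <- lapply(seq_len(nrow(j)), function(i) {
      list(
        baseline = j$baseline[i], amplitude = j$amplitude[i],
        frequency = j$frequency[i], phase = j$phase[i]
      )
    })
    names(joints) <- j$joint
    list(
      trunk_pitch = s$trunk_pitch,
      root_bob = s$root_bob,
      joints = joints
    )
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_signature_registry
#' @export
read_signature_registry <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("Signature registry not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  sigs <- lapply(raw, function(s) {
    joints <- purrr::imap_dfr(s$joints, function(v, nm) {
      tibble::tibble(
        joint = nm, baseline = v$baseline, amplitude = v$amplitude,
        frequency = v$frequency, phase = v$phase %||% 0
      )
    })
    joints <- joints[match(.JOINT_NAMES, joints$joint), ]
    list(
      trunk_pitch = s$trunk_pitch,
      root_bob = list(
        amplitude = s$root_bob$amplitude %||% 0,
        frequency = s$root_bob$frequency %||% 0.4
      ),
      joints = joints
    )
  })
  names(sigs) <- names(raw)
  validate_signatures(sigs)
}
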