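test_that("simulation is bit-reproducible from its seed", {
  a <- simulate_sequence("bicycle crunch", n_frames = 25, seed = 7)
  b <- simulate_sequence("bicycle crunch", n_frames = 25, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_sequence("bicycle crunch", n_frames = 25, seed = 8)
  expect_false(identical(a$x, c$x))
  expect_error(simulate_sequence("plank"), class = "poseclass_validation_error")
})

test_that("noiseless kinematics keep every segment length rigid", {
  s <- simulate_sequence("push-up", n_frames = 50, noise = noise_model(0, 0),
    seed = 3)
  a <- poseclass:::.pose_array(s)
  segs <- list(
    c("left_shoulder", "left_elbow"), c("left_elbow", "left_wrist"),
    c("right_hip", "right_knee"), c("right_knee", "right_ankle"),
    c("left_hip", "left_shoulder"), c("right_ankle", "right_foot_index")
  )
  for (seg in segs) {
    d <- euclidean_distance(a[, seg[1], ], a[, seg[2], ])
    expect_lt(max(d) - min(d), 1e-6)
  }
})

test_that("generated angles re-measured from landmarks match the signatures (closed loop)", {
  sigs <- default_signatures()
  for (cls in c("squat", "curl", "bird dog", "leg raise")) {
    s <- simulate_sequence(cls, n_frames = 45, noise = noise_model(0, 0),
      seed = 13)
    ft <- extract_features(s)
    measured <- as.matrix(ft[sprintf("f%03d", 66:77)])
    colnames(measured) <- default_angle_set()$angle
    t <- (0:44) / 30
    wanted <- poseclass:::.signature_angles(sigs[[cls]], t)
    expect_lt(max(abs(measured[, colnames(wanted)] - wanted)), 1e-3)
  }
})

test_that("class-specific kinematics are visible in the measured joint ranges", {
  knee_range <- function(cls) {
    s <- simulate_sequence(cls, n_frames = 75, noise = noise_model(0, 0),
      seed = 17)
    ft <- extract_features(s)
    k <- ft[[sprintf("f%03d", 66 + match("left_knee", default_angle_set()$angle) - 1)]]
    diff(range(k))
  }
  expect_gt(knee_range("squat"), knee_range("curl"))
})

test_that("signatures of every class pair are kinematically separated", {
  sigs <- default_signatures()
  expect_setequal(names(sigs), exercise_classes()$class)
  expect_silent(validate_signatures(sigs))
  # breaking the separation triggers the validator
  twin <- sigs
  twin[["curl"]] <- twin[["squat"]]
  expect_error(validate_signatures(twin), class = "poseclass_config_error")
})

test_that("signature registries round-trip through YAML", {
  sigs <- default_signatures()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_signature_registry(sigs, path)
  back <- read_signature_registry(path)
  expect_equal(names(back), names(sigs))
  for (cls in names(sigs)) {
    expect_equal(back[[cls]]$trunk_pitch, sigs[[cls]]$trunk_pitch)
    expect_equal(
      as.data.frame(back[[cls]]$joints), as.data.frame(sigs[[cls]]$joints)
    )
  }
})

test_that("dataset generation is balanced, seeded and manifest-complete", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(
    sequences_per_class = 2, n_frames = 12, seed = 29, dir = dir
  )
  expect_equal(nrow(ds$manifest), 20)
  expect_equal(as.vector(table(ds$manifest$label)), rep(2L, 10))
  expect_true(all(c("sequence_id", "label", "path", "seed") %in%
    names(ds$manifest)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # same master seed => byte-identical files
  dir2 <- withr::local_tempdir()
  simulate_dataset(sequences_per_class = 2, n_frames = 12, seed = 29,
    dir = dir2)
  for (p in ds$manifest$path) {
    expect_identical(
      readLines(file.path(dir, p)), readLines(file.path(dir2, p)),
      label = p
    )
  }
  # the recorded per-sequence seed regenerates that sequence exactly
  row <- ds$manifest[7, ]
  regen <- simulate_sequence(
    row$label,
    n_frames = 12, seed = row$seed, sequence_id = row$sequence_id
  )
  on_disk <- read_sequence(file.path(dir, row$path))
  expect_identical(regen$x, on_disk$x)

  expect_error(simulate_dataset(sequences_per_class = 0),
    class = "poseclass_validation_error")
})

test_that("outlier frames are rare, large deviations from the clean trajectory", {
  clean <- simulate_sequence("fly", n_frames = 400, noise = noise_model(0, 0),
    seed = 41)
  noisy <- simulate_sequence("fly", n_frames = 400,
    noise = noise_model(0.005, 0.05), seed = 41)
  dev <- abs(noisy$x - clean$x)
  per_frame <- tapply(dev, noisy$frame, max)
  n_outliers <- sum(per_frame > 0.005 * 4) # far beyond base noise
  expect_gt(n_outliers, 2)
  expect_lt(n_outliers / 400, 0.15)
})
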