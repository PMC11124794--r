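test_that("landmark registry is a bijection onto MediaPipe indices 11-32", {
  reg <- mediapipe_landmarks()
  expect_equal(nrow(reg), 22)
  expect_equal(sort(reg$index), 11:32)
  expect_false(anyDuplicated(reg$landmark) > 0)
  # round trip name -> index -> name
  fwd <- poseclass:::.landmark_index_map()
  bwd <- poseclass:::.index_landmark_map()
  expect_identical(unname(bwd[as.character(fwd[reg$landmark])]), reg$landmark)
  expect_identical(unname(fwd[bwd[as.character(11:32)]]), 11:32)
})

test_that("class registry maps the 10 exercises to indices 0-9 alphabetically", {
  cls <- exercise_classes()
  expect_equal(nrow(cls), 10)
  expect_equal(cls$index, 0:9)
  expect_equal(cls$class, sort(cls$class, method = "radix"))
  expect_equal(normalize_class(c("Superman", "SQUAT")), c("superman", "squat"))
  expect_error(normalize_class("plank"), class = "poseclass_validation_error")
})

test_that("pose sequences round-trip exactly through CSV and JSONL", {
  s <- simulate_sequence("fly", n_frames = 7, noise = noise_model(0.01, 0.1),
    seed = 7, sequence_id = "rt")
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_sequence(s, path)
    s2 <- read_sequence(path)
    expect_identical(s2$x, s$x, label = fmt)
    expect_identical(s2$y, s$y)
    expect_identical(s2$z, s$z)
    expect_identical(s2$frame, s$frame)
    expect_identical(s2$landmark, s$landmark)
    expect_equal(n_frames(s2), 7)
  }
})

test_that("visibility is preserved through the round trip", {
  df <- toy_frame_df("curl")
  df$visibility <- round(stats::runif(nrow(df)), 6)
  s <- pose_sequence(df, fps = 24)
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_sequence(s, path)
    s2 <- read_sequence(path)
    expect_identical(s2$visibility, s$visibility, label = fmt)
  }
})

test_that("facial landmarks (indices 0-10) are dropped, leaving the 22 body points", {
  df <- toy_frame_df("squat")
  path <- withr::local_tempfile(fileext = ".csv")
  # write a full 33-landmark MediaPipe dump: body rows by index + facial rows
  body <- df
  body$landmark <- as.character(
    poseclass:::.landmark_index_map()[body$landmark]
  )
  facial <- body[1:11, ]
  facial$landmark <- as.character(0:10)
  readr::write_csv(rbind(facial, body), path)
  s <- read_sequence(path)
  expect_equal(nrow(s), 22)
  expect_setequal(s$landmark, mediapipe_landmarks()$landmark)
})

test_that("invalid sequence files are rejected with informative errors", {
  df <- toy_frame_df("squat")
  # a frame missing the left knee
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df[df$landmark != "left_knee", ], path)
  expect_error(read_sequence(path), "22 body landmarks",
    class = "poseclass_validation_error")
  # malformed coordinate names the offending line
  path2 <- withr::local_tempfile(fileext = ".csv")
  lines <- readr::format_csv(df)
  lines <- sub("^toy,0,left_elbow,[^,]*", "toy,0,left_elbow,notanumber",
    strsplit(lines, "\n")[[1]])
  writeLines(lines, path2)
  err <- expect_error(read_sequence(path2), class = "poseclass_parse_error")
  expect_match(conditionMessage(err), "line")
  # unknown landmark name
  df3 <- df
  df3$landmark[df3$landmark == "left_pinky"] <- "left_flipper"
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df3, path3)
  expect_error(read_sequence(path3), class = "poseclass_parse_error")
  # empty sequences cannot be constructed
  expect_error(pose_sequence(df[0, ]), class = "poseclass_validation_error")
})

test_that("manifests validate labels and uniqueness", {
  dir <- withr::local_tempdir()
  mf <- tibble::tibble(
    sequence_id = paste0("s", 1:10),
    label = exercise_classes()$class,
    path = paste0("s", 1:10, ".csv")
  )
  readr::write_csv(mf, file.path(dir, "manifest.csv"))
  got <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(got), 10)
  expect_equal(got$label, exercise_classes()$class)
  expect_true(all(startsWith(got$path, dir))) # relative paths resolved

  bad <- mf
  bad$label[3] <- "plank"
  readr::write_csv(bad, file.path(dir, "bad.csv"))
  err <- expect_error(
    read_manifest(file.path(dir, "bad.csv")),
    class = "poseclass_validation_error"
  )
  expect_match(conditionMessage(err), "arm raise") # lists accepted names

  dup <- mf
  dup$sequence_id[2] <- "s1"
  readr::write_csv(dup, file.path(dir, "dup.csv"))
  expect_error(
    read_manifest(file.path(dir, "dup.csv")), "Duplicate",
    class = "poseclass_validation_error"
  )
})
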