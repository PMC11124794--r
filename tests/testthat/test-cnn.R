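# independent layer-by-layer recurrence used as the shape oracle
brute_force_shapes <- function(input_length, filters, k, p) {
  sizes <- integer(0)
  L <- input_length
  for (f in filters) {
    if (L < k) return(NULL)
    L <- L - k + 1
    sizes <- c(sizes, L)
    L <- floor(L / p)
    if (L < 1) return(NULL)
    sizes <- c(sizes, L)
  }
  list(sizes = sizes, flatten = L * filters[length(filters)])
}

test_that("the reference stack reproduces the published layer sizes", {
  shapes <- compute_layer_shapes(cnn_config())
  conv_pool <- shapes$size[shapes$type %in% c("conv1d", "maxpool1d")]
  expect_equal(conv_pool, c(76, 38, 36, 18, 16, 8, 6, 3))
  expect_equal(shapes$size[shapes$type == "flatten"], 768)
  expect_equal(shapes$maps[shapes$type == "conv1d"], c(32, 64, 128, 256))
  expect_equal(shapes$maps[shapes$type == "dense"], 512)
  expect_equal(shapes$maps[shapes$type == "dense_softmax"], 10)
})

test_that("shape arithmetic agrees with a brute-force recurrence on random stacks", {
  withr::local_seed(5)
  for (i in 1:40) {
    input_length <- sample(6:128, 1)
    filters <- sample(c(4, 8, 16, 32), sample(1:4, 1), replace = TRUE)
    oracle <- brute_force_shapes(input_length, filters, 3, 2)
    cfg <- try(
      cnn_config(
        input_length = input_length, classes = c("a", "b"),
        conv_filters = filters
      ),
      silent = TRUE
    )
    if (is.null(oracle)) {
      expect_error(compute_layer_shapes(cfg), class = "poseclass_config_error")
    } else {
      shapes <- compute_layer_shapes(cfg)
      expect_equal(
        shapes$size[shapes$type %in% c("conv1d", "maxpool1d")], oracle$sizes
      )
      expect_equal(shapes$size[shapes$type == "flatten"], oracle$flatten)
    }
  }
  # single conv(k3) + pool(2) on input 8: 8 -> 6 -> 3
  small <- compute_layer_shapes(
    cnn_config(input_length = 8, classes = c("a", "b"), conv_filters = 4)
  )
  expect_equal(small$size[small$type %in% c("conv1d", "maxpool1d")], c(6, 3))
  # kernel exceeding the input is a configuration error
  expect_error(
    cnn_config(input_length = 2, classes = c("a", "b")),
    class = "poseclass_config_error"
  )
})

test_that("model construction is seed-deterministic and shape-consistent", {
  cfg <- cnn_config(seed = 123)
  m1 <- build_cnn(cfg)
  m2 <- build_cnn(cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params[["dense.W"]]), c(768L, 512L))
  expect_equal(dim(m1$params[["out.W"]]), c(512L, 10L))
  expect_equal(dim(m1$params[["conv1.W"]]), c(3L, 32L))
  expect_equal(dim(m1$params[["conv4.W"]]), c(3L * 128L, 256L))
  m3 <- build_cnn(cfg, seed = 124)
  expect_false(identical(m1$params, m3$params))
})

test_that("a two-class toy with distinct angle signatures trains to high accuracy", {
  ds <- simulate_dataset(
    classes = c("squat", "curl"), sequences_per_class = 4,
    n_frames = 40, noise = noise_model(0.003, 0), seed = 31
  )
  feats <- extract_dataset_features(ds$sequences)
  cfg <- cnn_config(classes = c("curl", "squat"), epochs = 8, seed = 32)
  model <- train_cnn(feats, cfg)
  expect_gte(dplyr::last(tidy(model)$accuracy), 0.95)
  expect_equal(nrow(tidy(model)), 8) # one log row per epoch
  # seeded retraining reproduces the fit exactly
  model2 <- train_cnn(feats, cfg)
  expect_identical(model$params, model2$params)
})

test_that("training rejects malformed inputs", {
  ds <- simulate_dataset(
    classes = c("squat", "curl"), sequences_per_class = 1,
    n_frames = 10, noise = noise_model(0, 0), seed = 33
  )
  feats <- extract_dataset_features(ds$sequences)
  cfg <- cnn_config(classes = c("curl", "squat"), epochs = 1, seed = 1)
  # wrong vector length
  expect_error(
    train_cnn(feats[-which(names(feats) == "f077")], cfg),
    "77",
    class = "poseclass_validation_error"
  )
  # single-class data
  only_squat <- feats[feats$label == "squat", ]
  err <- expect_error(
    train_cnn(only_squat, cfg),
    class = "poseclass_validation_error"
  )
  expect_match(conditionMessage(err), "curl") # names the missing class
  # labels outside the registry
  cfg10 <- cnn_config(epochs = 1, seed = 1)
  err2 <- expect_error(
    train_cnn(feats, cfg10),
    class = "poseclass_validation_error"
  )
  expect_match(conditionMessage(err2), "absent")
})

test_that("predictions are normalized, deterministic and order-preserving", {
  model <- shared_model()
  ds <- shared_dataset()
  feats <- extract_features(ds$test$sequences[[1]])
  p <- predict(model, feats)
  probs <- as.matrix(p[exercise_classes()$class])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  # purity: same input, same output
  expect_identical(predict(model, feats), p)
  # batch order preserved: row i equals the single-frame prediction
  fcols <- sprintf("f%03d", 0:77)
  for (i in c(1, 7, 20)) {
    expect_equal(
      unname(predict_frame(model, as.numeric(feats[i, fcols]))),
      unname(probs[i, ])
    )
  }
  # untrained model refuses to predict
  expect_error(
    predict(build_cnn(cnn_config(seed = 1)), feats),
    class = "poseclass_state_error"
  )
})

test_that("checkpoints round-trip bit-exactly and detect corruption", {
  model <- shared_model()
  dir <- withr::local_tempdir()
  save_model(model, dir)
  loaded <- load_model(dir)
  expect_identical(loaded$params, model$params)
  ds <- shared_dataset()
  feats <- extract_features(ds$test$sequences[[3]])
  expect_identical(predict(loaded, feats), predict(model, feats))
  # truncated weights
  w <- file.path(dir, "weights.rds")
  raw <- readBin(w, "raw", file.size(w))
  writeBin(raw[1:100], w)
  expect_error(load_model(dir), class = "poseclass_integrity_error")
  # weights inconsistent with the stored registry
  dir2 <- withr::local_tempdir()
  save_model(model, dir2)
  cfg_path <- file.path(dir2, "config.json")
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  meta$config$classes <- meta$config$classes[1:5]
  jsonlite::write_json(meta, cfg_path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(dir2), class = "poseclass_integrity_error")
})

test_that("dropout masks only the hidden dense layer and training still works", {
  ds <- simulate_dataset(
    classes = c("fly", "superman"), sequences_per_class = 2,
    n_frames = 20, noise = noise_model(0.002, 0), seed = 51
  )
  feats <- extract_dataset_features(ds$sequences)
  cfg <- cnn_config(
    classes = c("fly", "superman"), epochs = 3, dropout = 0.5, seed = 52
  )
  model <- train_cnn(feats, cfg)
  expect_true(model$trained)
  # inference ignores dropout: repeated predictions identical
  p1 <- predict(model, feats)
  expect_identical(p1, predict(model, feats))
  expect_error(cnn_config(dropout = 1), class = "poseclass_config_error")
})
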