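# Shared fixtures, built in code. Heavyweight objects (a trained model on a
# small 10-class dataset) are created once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# one noiseless frame of a given class as a plain tibble (not yet validated)
toy_frame_df <- function(class = "squat", frame = 0L, id = "toy") {
  s <- simulate_sequence(
    class,
    n_frames = 1, noise = noise_model(0, 0), seed = 99, sequence_id = id
  )
  df <- tibble::as_tibble(s)
  df$frame <- as.integer(frame)
  df
}

# a small but full 10-class training set + a held-out test set with outliers
shared_dataset <- function() {
  if (!is.null(.fixture_cache$dataset)) {
    return(.fixture_cache$dataset)
  }
  train <- simulate_dataset(
    sequences_per_class = 4, n_frames = 60,
    noise = noise_model(0.0052, 0.05), seed = 401
  )
  test <- simulate_dataset(
    sequences_per_class = 5, n_frames = 120,
    noise = noise_model(0.0052, 0.10), seed = 402
  )
  .fixture_cache$dataset <- list(train = train, test = test)
  .fixture_cache$dataset
}

# a 10-class CNN trained once on the shared training set
shared_model <- function() {
  if (!is.null(.fixture_cache$model)) {
    return(.fixture_cache$model)
  }
  ds <- shared_dataset()
  feats <- extract_dataset_features(ds$train$sequences)
  cfg <- cnn_config(epochs = 6, seed = 403)
  .fixture_cache$model <- train_cnn(feats, cfg)
  .fixture_cache$model
}

random_point <- function(n = 1) matrix(stats::runif(3 * n, -2, 2), ncol = 3)

# random 3-d rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}
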