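test_that("metrics match hand computations on small matrices", {
  # perfect diagonal
  perfect <- diag(c(5L, 3L, 7L))
  rownames(perfect) <- colnames(perfect) <- c("a", "b", "c")
  r <- compute_metrics(perfect)
  expect_equal(r$accuracy, 1)
  expect_true(all(tidy(r)$precision == 1 & tidy(r)$recall == 1 &
    tidy(r)$f1 == 1))

  # worked 2-class example: [[8,2],[3,7]]
  cm <- matrix(c(8L, 3L, 2L, 7L), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))
  r2 <- compute_metrics(cm)
  expect_equal(r2$accuracy, 0.75)
  pc <- tidy(r2)
  expect_equal(pc$precision[pc$class == "a"], 8 / 11)
  expect_equal(pc$recall[pc$class == "a"], 0.8)
  expect_equal(pc$precision[pc$class == "b"], 7 / 9)
  expect_equal(pc$recall[pc$class == "b"], 0.7)
  f1a <- 2 * (8 / 11) * 0.8 / ((8 / 11) + 0.8)
  expect_equal(pc$f1[pc$class == "a"], f1a)

  # a class never predicted: precision undefined -> 0 with a flag
  cm3 <- matrix(c(4L, 2L, 0L, 0L), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))
  r3 <- compute_metrics(cm3)
  pc3 <- tidy(r3)
  expect_equal(pc3$precision[pc3$class == "b"], 0)
  expect_false(pc3$precision_defined[pc3$class == "b"])
  expect_true(pc3$precision_defined[pc3$class == "a"])

  expect_error(compute_metrics(matrix(0L, 3, 3)),
    class = "poseclass_validation_error")
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  withr::local_seed(19)
  for (i in 1:100) {
    n_cls <- sample(2:6, 1)
    cm <- matrix(rpois(n_cls^2, 4), n_cls, n_cls)
    diag(cm) <- diag(cm) + rpois(n_cls, 6) # keep it non-degenerate
    if (sum(cm) == 0) next
    rownames(cm) <- colnames(cm) <- letters[1:n_cls]
    got <- compute_metrics(cm)
    # caret takes rows = prediction, columns = reference
    ref <- caret::confusionMatrix(as.table(t(cm)))
    expect_equal(got$accuracy, unname(ref$overall["Accuracy"]))
    by_class <- as.matrix(ref$byClass)
    ref_prec <- if (n_cls == 2) ref$byClass["Precision"] else by_class[, "Precision"]
    ref_rec <- if (n_cls == 2) ref$byClass["Recall"] else by_class[, "Recall"]
    pc <- tidy(got)
    if (n_cls == 2) {
      # caret reports the positive class only in the binary case
      expect_equal(pc$precision[1], unname(ref_prec))
      expect_equal(pc$recall[1], unname(ref_rec))
    } else {
      defined <- pc$precision_defined
      expect_equal(pc$precision[defined], unname(ref_prec[defined]))
      expect_equal(pc$recall, unname(ref_rec))
    }
  }
})

test_that("confusion matrices are permutation-equivariant in the class labels", {
  withr::local_seed(23)
  classes <- exercise_classes()$class
  truth <- sample(classes, 200, replace = TRUE)
  pred <- sample(classes, 200, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  perm <- sample(classes)
  cm_perm <- confusion_matrix(truth, pred, classes = perm)
  expect_equal(cm_perm[classes, classes], cm[classes, classes])
  expect_equal(sort(unname(rowSums(cm_perm))), sort(unname(rowSums(cm))))
  expect_equal(sum(diag(cm_perm)), sum(diag(cm)))
})

test_that("stratified folds are balanced at the sequence level and seed-stable", {
  ds <- simulate_dataset(
    sequences_per_class = 5, n_frames = 5, noise = noise_model(0, 0),
    seed = 71
  )
  labels <- vapply(ds$sequences, pose_label, character(1))
  withr::with_seed(5, {
    folds <- poseclass:::.stratified_folds(labels, 5)
  })
  tab <- table(labels, folds)
  expect_true(all(tab == 1)) # each fold holds exactly 1 sequence per class
  withr::with_seed(5, {
    folds2 <- poseclass:::.stratified_folds(labels, 5)
  })
  expect_identical(folds, folds2)
  expect_error(
    poseclass:::.stratified_folds(labels[1:9], 5),
    class = "poseclass_validation_error"
  )
  expect_error(
    stratified_kfold_evaluate(ds$sequences, k = 1),
    class = "poseclass_validation_error"
  )
})

test_that("the accuracy-vs-window curve dedupes sizes, skips oversized windows", {
  model <- shared_model()
  ds <- shared_dataset()
  seqs <- ds$test$sequences[c("squat_001", "curl_001", "fly_001")]
  expect_warning(
    curve <- accuracy_vs_frames(model, seqs, c(1, 30, 30, 500)),
    "skipped"
  )
  expect_equal(curve$K, c(1, 30))
  expect_equal(curve$n_windows[curve$K == 30], 12) # 3 sequences x 4 windows

  # K = 1 is single-frame accuracy, computed independently
  feats <- extract_dataset_features(seqs)
  preds <- predict(model, feats, type = "class")
  frame_acc <- mean(preds$.pred_class == feats$label)
  expect_equal(curve$accuracy[curve$K == 1], frame_acc)
})
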