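# Per-frame 1-D convolutional classifier.
#
# Reference stack (input length 78, one channel):
#   conv(32, k3) - pool(2) - conv(64, k3) - pool(2) - conv(128, k3) - pool(2)
#   - conv(256, k3) - pool(2) - flatten(768) - dense(512, relu)
#   - dense(n_classes, softmax)
# Convolutions are "valid" (no padding, stride 1): output length L - k + 1.
# Max pooling has size 2 and floor division: output length floor(L / 2).
#
# The network is implemented directly with base matrix algebra: convolutions
# are lowered to GEMM via im2col, so the heavy lifting runs in BLAS. Training
# uses Adam on the categorical cross-entropy, with minibatch shuffling driven
# by R's RNG (seed-reproducible in single-threaded BLAS mode).

#' Configuration of the per-frame CNN
#'
#' @param input_length Length of the per-frame attribute vector (default 78:
#'   66 coordinates + 12 joint angles).
#' @param classes Character vector of class names the output layer predicts
#'   (default the 10-exercise registry, width 10).
#' @param conv_filters Channel counts of the conv blocks (each block is a
#'   valid convolution followed by max pooling). Default `c(32, 64, 128, 256)`.
#' @param kernel_size Convolution kernel size (default 3).
#' @param pool_size Max-pool size (default 2, floor division).
#' @param dense_units Width of the hidden fully connected layer (default 512).
#' @param dropout Dropout rate applied between the hidden dense layer and the
#'   output layer during training only. Default 0 (off).
#' @param epochs,batch_size,learning_rate Adam training hyperparameters
#'   (defaults 50, 64, 1e-3).
#' @param validation_split Fraction of *sequences* held out for per-epoch
#'   validation (frames of one sequence never straddle the split). Default 0.
#' @param seed Integer seed controlling weight initialization, shuffling and
#'   dropout. `NULL` leaves the RNG stream alone.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_length = 78L,
                       classes = exercise_classes()$class,
                       conv_filters = c(32L, 64L, 128L, 256L),
                       kernel_size = 3L,
                       pool_size = 2L,
                       dense_units = 512L,
                       dropout = 0,
                       epochs = 50L,
                       batch_size = 64L,
                       learning_rate = 1e-3,
                       validation_split = 0,
                       seed = NULL) {
  cfg <- list(
    input_length = as.integer(input_length),
    classes = as.character(classes),
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    dense_units = as.integer(dense_units),
    dropout = as.numeric(dropout),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate),
    validation_split = as.numeric(validation_split),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  if (cfg$input_length < cfg$kernel_size) {
    abort_config("`input_length` must be at least `kernel_size`.")
  }
  if (length(cfg$classes) < 2) {
    abort_config("The classifier needs at least 2 classes.")
  }
  if (anyDuplicated(cfg$classes) > 0) {
    abort_config("`classes` must be distinct.")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    abort_config("`dropout` must lie in [0, 1).")
  }
  if (any(cfg$conv_filters < 1) || cfg$kernel_size < 1 || cfg$pool_size < 1) {
    abort_config("Filter counts, kernel and pool sizes must be positive.")
  }
  structure(cfg, class = "cnn_config")
}

#' Per-layer output sizes of the CNN
#'
#' Applies the shape arithmetic of the stack: a valid convolution maps length
#' `L` to `L - k + 1`; max pooling maps `L` to `floor(L / p)`; flatten width
#' is the last length times the last channel count. With the reference
#' configuration (input 78) the sizes are
#' 76, 38, 36, 18, 16, 8, 6, 3 and the flatten width is 768.
#'
#' @param config A [cnn_config()].
#' @return A tibble with columns `layer`, `type`, `maps`, `size`,
#'   `kernel` mirroring the architecture table; conv/pool rows carry their
#'   kernel/pool size.
#' @export
#' @examples
#' compute_layer_shapes(cnn_config())
compute_layer_shapes <- function(config = cnn_config()) {
  k <- config$kernel_size
  p <- config$pool_size
  L <- config$input_length
  rows <- list(tibble::tibble(
    layer = "In", type = "input", maps = 1L, size = L, kernel = NA_integer_
  ))
  maps <- 1L
  for (i in seq_along(config$conv_filters)) {
    if (L < k) {
      abort_config(sprintf(
        "Layer C%d: input length %d is smaller than kernel size %d.",
        i, L, k
      ))
    }
    L <- L - k + 1L
    maps <- config$conv_filters[i]
    rows <- c(rows, list(tibble::tibble(
      layer = sprintf("C%d", 2L * i - 1L), type = "conv1d",
      maps = maps, size = L, kernel = k
    )))
    L <- L %/% p
    if (L < 1L) {
      abort_config(sprintf("Pooling S%d would empty the signal.", 2L * i))
    }
    rows <- c(rows, list(tibble::tibble(
      layer = sprintf("S%d", 2L * i), type = "maxpool1d",
      maps = maps, size = L, kernel = p
    )))
  }
  flat <- L * maps
  rows <- c(rows, list(
    tibble::tibble(
      layer = "F", type = "flatten", maps = NA_integer_, size = flat,
      kernel = NA_integer_
    ),
    tibble::tibble(
      layer = "D1", type = "dense", maps = config$dense_units,
      size = NA_integer_, kernel = NA_integer_
    ),
    tibble::tibble(
      layer = "Out", type = "dense_softmax",
      maps = length(config$classes), size = NA_integer_, kernel = NA_integer_
    )
  ))
  dplyr::bind_rows(rows)
}

# flat named list of parameter arrays
.init_params <- function(config) {
  k <- config$kernel_size
  params <- list()
  in_ch <- 1L
  for (i in seq_along(config$conv_filters)) {
    out_ch <- config$conv_filters[i]
    fan_in <- k * in_ch
    lim <- sqrt(6 / fan_in) # He uniform (relu)
    params[[sprintf("conv%d.W", i)]] <-
      matrix(stats::runif(fan_in * out_ch, -lim, lim), fan_in, out_ch)
    params[[sprintf("conv%d.b", i)]] <- numeric(out_ch)
    in_ch <- out_ch
  }
  shapes <- compute_layer_shapes(config)
  flat <- shapes$size[shapes$type == "flatten"]
  lim <- sqrt(6 / flat)
  params[["dense.W"]] <-
    matrix(stats::runif(flat * config$dense_units, -lim, lim),
      flat, config$dense_units
    )
  params[["dense.b"]] <- numeric(config$dense_units)
  n_cls <- length(config$classes)
  lim <- sqrt(6 / (config$dense_units + n_cls)) # Glorot for softmax layer
  params[["out.W"]] <-
    matrix(stats::runif(config$dense_units * n_cls, -lim, lim),
      config$dense_units, n_cls
    )
  params[["out.b"]] <- numeric(n_cls)
  params
}

#' Build an (untrained) CNN model
#'
#' Allocates and seeds the parameter tensors; shapes follow
#' [compute_layer_shapes()]. The model must be trained with [train_cnn()]
#' before prediction.
#'
#' @param config A [cnn_config()].
#' @param seed Overrides `config$seed` for the initialization.
#' @return A `cnn_model` object.
#' @export
build_cnn <- function(config = cnn_config(), seed = config$seed) {
  if (!inherits(config, "cnn_config")) {
    abort_config("`config` must come from cnn_config().")
  }
  shapes <- compute_layer_shapes(config)
  if (!is.null(seed)) withr::local_seed(seed)
  params <- .init_params(config)
  structure(
    list(
      config = config, shapes = shapes, params = params,
      trained = FALSE, log = NULL
    ),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model: input %d -> %d classes, %s, %s>\n",
    x$config$input_length, length(x$config$classes),
    paste0("conv ", paste(x$config$conv_filters, collapse = "-")),
    if (x$trained) sprintf("trained (%d epochs)", nrow(x$log)) else "untrained"
  ))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward / backward ------------------------------------------------------

# im2col for an array A of dim (B, L, C): matrix (B*L_out, k*C), column order
# kernel-offset fastest within channel; rows ordered batch fastest within
# output position. Matches the (k*C_in, C_out) weight layout.
.im2col <- function(A, k) {
  d <- dim(A)
  B <- d[1]; L <- d[2]; C <- d[3]
  L_out <- L - k + 1L
  rows_bt <- as.vector(outer(seq_len(B), B * (0:(L_out - 1L)), "+"))
  off <- as.vector(outer(B * (0:(k - 1L)), B * L * (0:(C - 1L)), "+"))
  idx <- outer(rows_bt, off, "+")
  # index with the flattened vector: a matrix index with ncol == 3 would be
  # read as per-dimension coordinates into the 3-d array
  out <- A[as.vector(idx)]
  dim(out) <- dim(idx)
  out
}

# Forward pass. Returns list(probs, cache) where cache holds what backward
# needs. X: matrix (B, input_length). dropmask: NULL or (B, dense_units)
# 0/1 matrix (training only).
.cnn_forward <- function(params, config, X, dropmask = NULL,
                         keep_cache = FALSE) {
  B <- nrow(X)
  k <- config$kernel_size
  p <- config$pool_size
  A <- array(X, dim = c(B, ncol(X), 1L))
  cache <- list(conv = list())
  for (i in seq_along(config$conv_filters)) {
    W <- params[[sprintf("conv%d.W", i)]]
    b <- params[[sprintf("conv%d.b", i)]]
    Xc <- .im2col(A, k)
    Z <- Xc %*% W
    Z <- sweep(Z, 2, b, "+")
    relu_mask <- Z > 0
    Z[!relu_mask] <- 0
    L_out <- dim(A)[2] - k + 1L
    C_out <- ncol(W)
    Zc <- array(Z, dim = c(B, L_out, C_out))
    L_p <- L_out %/% p
    # max pool (p = 2 in the reference stack; general p via apply over windows)
    if (p == 2L) {
      odd <- Zc[, seq(1L, 2L * L_p, 2L), , drop = FALSE]
      even <- Zc[, seq(2L, 2L * L_p, 2L), , drop = FALSE]
      mask <- odd >= even
      P <- even
      P[mask] <- odd[mask]
    } else {
      P <- array(-Inf, dim = c(B, L_p, C_out))
      mask <- NULL
      for (j in seq_len(p)) {
        cand <- Zc[, seq(j, by = p, length.out = L_p), , drop = FALSE]
        P <- pmax(P, cand)
      }
    }
    if (keep_cache) {
      cache$conv[[i]] <- list(
        Xc = Xc, relu_mask = relu_mask, pool_mask = mask,
        dims_in = dim(A), dims_conv = c(B, L_out, C_out), Zc = if (p != 2L) Zc
      )
    }
    A <- P
  }
  flat_dim <- dim(A)[2] * dim(A)[3]
  Fm <- matrix(A, nrow = B, ncol = flat_dim)
  H <- Fm %*% params[["dense.W"]]
  H <- sweep(H, 2, params[["dense.b"]], "+")
  h_mask <- H > 0
  H[!h_mask] <- 0
  Hd <- H
  if (!is.null(dropmask)) {
    Hd <- H * dropmask / (1 - config$dropout)
  }
  S <- Hd %*% params[["out.W"]]
  S <- sweep(S, 2, params[["out.b"]], "+")
  S <- S - apply(S, 1, max)
  E <- exp(S)
  probs <- E / rowSums(E)
  if (keep_cache) {
    cache$Fm <- Fm
    cache$h_mask <- h_mask
    cache$Hd <- Hd
    cache$pool_dims <- dim(A)
  }
  list(probs = probs, cache = if (keep_cache) cache)
}

# Backward pass for mean categorical cross-entropy. y: integer class 1..C.
.cnn_backward <- function(params, config, fwd, y, dropmask = NULL) {
  probs <- fwd$probs
  cache <- fwd$cache
  B <- nrow(probs)
  k <- config$kernel_size
  p <- config$pool_size
  grads <- list()
  dS <- probs
  dS[cbind(seq_len(B), y)] <- dS[cbind(seq_len(B), y)] - 1
  dS <- dS / B
  grads[["out.W"]] <- crossprod(cache$Hd, dS)
  grads[["out.b"]] <- colSums(dS)
  dH <- tcrossprod(dS, params[["out.W"]])
  if (!is.null(dropmask)) {
    dH <- dH * dropmask / (1 - config$dropout)
  }
  dH[!cache$h_mask] <- 0
  grads[["dense.W"]] <- crossprod(cache$Fm, dH)
  grads[["dense.b"]] <- colSums(dH)
  dF <- tcrossprod(dH, params[["dense.W"]])
  dA <- array(dF, dim = cache$pool_dims)
  for (i in rev(seq_along(config$conv_filters))) {
    cc <- cache$conv[[i]]
    B_ <- cc$dims_conv[1]; L_out <- cc$dims_conv[2]; C_out <- cc$dims_conv[3]
    L_p <- dim(dA)[2]
    dZc <- array(0, dim = cc$dims_conv)
    if (p == 2L) {
      mask <- cc$pool_mask
      dZc[, seq(1L, 2L * L_p, 2L), ] <- dA * mask
      dZc[, seq(2L, 2L * L_p, 2L), ] <- dA * !mask
    } else {
      # general pool: route gradient to the max entry of each window
      P <- array(-Inf, dim = dim(dA))
      for (j in seq_len(p)) {
        P <- pmax(P, cc$Zc[, seq(j, by = p, length.out = L_p), , drop = FALSE])
      }
      taken <- array(FALSE, dim = dim(dA))
      for (j in seq_len(p)) {
        sel <- seq(j, by = p, length.out = L_p)
        hit <- (cc$Zc[, sel, , drop = FALSE] == P) & !taken
        dZc[, sel, ][hit] <- dA[hit]
        taken <- taken | hit
      }
    }
    dZ <- matrix(dZc, nrow = B_ * L_out, ncol = C_out)
    dZ[!cc$relu_mask] <- 0
    W <- params[[sprintf("conv%d.W", i)]]
    grads[[sprintf("conv%d.W", i)]] <- crossprod(cc$Xc, dZ)
    grads[[sprintf("conv%d.b", i)]] <- colSums(dZ)
    dXc <- tcrossprod(dZ, W)
    C_in <- cc$dims_in[3]
    L_in <- cc$dims_in[2]
    dA_prev <- array(0, dim = cc$dims_in)
    for (j in seq_len(k)) {
      cols <- j + k * (0:(C_in - 1L))
      block <- array(dXc[, cols], dim = c(B_, L_out, C_in))
      sl <- j:(j + L_out - 1L)
      dA_prev[, sl, ] <- dA_prev[, sl, , drop = FALSE] + block
    }
    dA <- dA_prev
  }
  grads
}

.adam_init <- function(params) {
  list(
    m = lapply(params, function(x) array(0, dim = dim(x) %||% length(x))),
    v = lapply(params, function(x) array(0, dim = dim(x) %||% length(x))),
    t = 0L
  )
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

.feature_matrix <- function(data, input_length) {
  fcols <- grep("^f\\d+$", names(data), value = TRUE)
  if (length(fcols) == 0) {
    abort_validation("`data` has no feature columns (f000, f001, ...).")
  }
  fcols <- fcols[order(fcols)]
  if (length(fcols) != input_length) {
    abort_validation(sprintf(
      "Feature vectors have length %d but the model expects %d attributes.",
      length(fcols), input_length
    ))
  }
  X <- as.matrix(data[fcols])
  storage.mode(X) <- "double"
  X
}

#' Train the per-frame CNN
#'
#' Trains the classifier on per-frame feature vectors; every frame carries
#' its sequence's exercise label (frame-level supervision). Optimisation is
#' Adam on the categorical cross-entropy with minibatch shuffling. If
#' `validation_split > 0`, whole sequences (never individual frames) are held
#' out and scored after each epoch, so no frames of one video leak across the
#' split.
#'
#' @param data A tibble with a `label` column, feature columns
#'   `f000`..., and (optionally, needed for a validation split) a
#'   `sequence_id` column — the output of [extract_dataset_features()].
#' @param config A [cnn_config()].
#' @param model Optionally a pre-built [build_cnn()] model to (re)train.
#' @param seed Overrides `config$seed`.
#' @return A trained `cnn_model`; `tidy()` returns the per-epoch training
#'   log, `glance()` a one-row summary.
#' @export
train_cnn <- function(data, config = cnn_config(), model = NULL,
                      seed = config$seed) {
  if (!inherits(config, "cnn_config")) {
    abort_config("`config` must come from cnn_config().")
  }
  if (!"label" %in% names(data)) {
    abort_validation("`data` must have a `label` column.")
  }
  labels <- normalize_class(data$label)
  extra <- setdiff(unique(labels), config$classes)
  if (length(extra) > 0) {
    abort_validation(paste0(
      "Labels not in the model's class registry: ",
      paste(sQuote(extra), collapse = ", "), "."
    ))
  }
  missing_cls <- setdiff(config$classes, unique(labels))
  if (length(missing_cls) > 0) {
    abort_validation(paste0(
      "Class(es) absent from the training data: ",
      paste(sQuote(missing_cls), collapse = ", "),
      ". Every class in the registry needs training frames."
    ))
  }
  if (length(unique(labels)) < 2) {
    abort_validation("Training needs at least 2 distinct classes.")
  }
  X <- .feature_matrix(data, config$input_length)
  y <- match(labels, config$classes)

  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(model)) {
    model <- build_cnn(config, seed = NULL) # draws from the local stream
  } else {
    if (!identical(model$config$classes, config$classes) ||
      model$config$input_length != config$input_length) {
      abort_config("`model` was built for a different configuration.")
    }
  }
  params <- model$params

  # optional validation split, by sequence
  val_idx <- integer(0)
  if (config$validation_split > 0) {
    if (!"sequence_id" %in% names(data)) {
      abort_validation("A validation split needs a `sequence_id` column.")
    }
    ids <- unique(data$sequence_id)
    n_val <- max(1L, round(config$validation_split * length(ids)))
    val_ids <- sample(ids, n_val)
    val_idx <- which(data$sequence_id %in% val_ids)
  }
  train_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]

  n <- nrow(Xtr)
  bs <- min(config$batch_size, n)
  state <- .adam_init(params)
  log_rows <- vector("list", config$epochs)
  use_dropout <- config$dropout > 0

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    total_correct <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      dropmask <- NULL
      if (use_dropout) {
        dropmask <- matrix(
          stats::rbinom(length(idx) * config$dense_units, 1, 1 - config$dropout),
          nrow = length(idx)
        )
      }
      fwd <- .cnn_forward(params, config, Xb, dropmask, keep_cache = TRUE)
      pb <- pmax(fwd$probs[cbind(seq_along(yb), yb)], 1e-12)
      total_loss <- total_loss - sum(log(pb))
      total_correct <- total_correct +
        sum(max.col(fwd$probs, ties.method = "first") == yb)
      grads <- .cnn_backward(params, config, fwd, yb, dropmask)
      upd <- .adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    row <- tibble::tibble(
      epoch = epoch,
      loss = total_loss / n,
      accuracy = total_correct / n
    )
    if (length(val_idx) > 0) {
      vp <- .cnn_predict_matrix(params, config, X[val_idx, , drop = FALSE])
      pv <- pmax(vp[cbind(seq_along(val_idx), y[val_idx])], 1e-12)
      row$val_loss <- -mean(log(pv))
      row$val_accuracy <-
        mean(max.col(vp, ties.method = "first") == y[val_idx])
    }
    log_rows[[epoch]] <- row
  }

  model$params <- params
  model$trained <- TRUE
  model$log <- dplyr::bind_rows(log_rows)
  model$n_train_frames <- n
  model
}

# chunked inference to bound im2col memory
.cnn_predict_matrix <- function(params, config, X, chunk = 1024L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(config$classes))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- .cnn_forward(
      params, config, X[idx, , drop = FALSE]
    )$probs
  }
  colnames(out) <- config$classes
  out
}

#' Predict per-frame class probabilities
#'
#' @param object A trained `cnn_model`.
#' @param newdata A tibble with feature columns `f000`... (extra columns such
#'   as `sequence_id`/`frame` are carried through), or a numeric matrix with
#'   `input_length` columns.
#' @param type `"prob"` (default) for one probability column per class, or
#'   `"class"` for a single `.pred_class` column.
#' @param ... Unused.
#' @return A tibble; probability rows are non-negative and sum to 1.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) {
    abort_state("The model has not been trained yet; call train_cnn().")
  }
  if (is.matrix(newdata)) {
    if (ncol(newdata) != object$config$input_length) {
      abort_validation(sprintf(
        "Feature vectors have length %d but the model expects %d attributes.",
        ncol(newdata), object$config$input_length
      ))
    }
    X <- newdata
    meta <- NULL
  } else {
    X <- .feature_matrix(newdata, object$config$input_length)
    meta_cols <- intersect(c("sequence_id", "frame", "label"), names(newdata))
    meta <- if (length(meta_cols) > 0) newdata[meta_cols]
  }
  if (anyNA(X)) {
    abort_validation(
      "Feature matrix contains NA/NaN; drop or impute NaN frames first."
    )
  }
  probs <- .cnn_predict_matrix(object$params, object$config, X)
  out <- tibble::as_tibble(probs)
  if (type == "class") {
    out <- tibble::tibble(
      .pred_class = object$config$classes[max.col(probs, ties.method = "first")]
    )
  }
  if (!is.null(meta)) out <- dplyr::bind_cols(meta, out)
  out
}

#' Class probabilities for one frame
#'
#' @param model A trained `cnn_model`.
#' @param features Numeric feature vector of length `input_length` (e.g. from
#'   [extract_frame_features()]).
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
predict_frame <- function(model, features) {
  if (!isTRUE(model$trained)) {
    abort_state("The model has not been trained yet; call train_cnn().")
  }
  if (length(features) != model$config$input_length) {
    abort_validation(sprintf(
      "Feature vector has length %d but the model expects %d attributes.",
      length(features), model$config$input_length
    ))
  }
  p <- .cnn_predict_matrix(
    model$params, model$config, matrix(as.numeric(features), nrow = 1)
  )
  stats::setNames(as.numeric(p), model$config$classes)
}

# ---- persistence ------------------------------------------------------------

.CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `config.json` (the full configuration,
#' the class registry, per-parameter shapes and a format version) and
#' `weights.rds` (the parameter arrays, bit-exact). On load the weight shapes
#' are verified against the stored configuration; any mismatch or truncation
#' raises an integrity error.
#'
#' @param model A trained `cnn_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_model()` returns `dir` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, dir) {
  if (!inherits(model, "cnn_model")) {
    abort_validation("`model` must be a cnn_model.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  meta <- list(
    format_version = .CHECKPOINT_VERSION,
    package_version = as.character(utils::packageVersion("poseclass")),
    config = cfg,
    trained = model$trained,
    param_shapes = lapply(model$params, function(x) dim(x) %||% length(x))
  )
  jsonlite::write_json(
    meta, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  saveRDS(model$params, file.path(dir, "weights.rds"))
  if (!is.null(model$log)) {
    readr::write_csv(model$log, file.path(dir, "training_log.csv"),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  w_path <- file.path(dir, "weights.rds")
  if (!file.exists(cfg_path) || !file.exists(w_path)) {
    abort_integrity(paste0(
      dir, " is not a checkpoint directory (config.json/weights.rds missing)."
    ))
  }
  meta <- tryCatch(
    jsonlite::read_json(cfg_path, simplifyVector = TRUE),
    error = function(e) abort_integrity(paste0("Corrupt config.json: ", conditionMessage(e)))
  )
  if (!identical(as.integer(meta$format_version), .CHECKPOINT_VERSION)) {
    abort_integrity("Unsupported checkpoint format version.")
  }
  cfg <- meta$config
  config <- cnn_config(
    input_length = cfg$input_length, classes = cfg$classes,
    conv_filters = cfg$conv_filters, kernel_size = cfg$kernel_size,
    pool_size = cfg$pool_size, dense_units = cfg$dense_units,
    dropout = cfg$dropout, epochs = cfg$epochs, batch_size = cfg$batch_size,
    learning_rate = cfg$learning_rate,
    validation_split = cfg$validation_split,
    seed = if (is.null(cfg$seed)) NULL else cfg$seed
  )
  params <- tryCatch(
    readRDS(w_path),
    error = function(e) {
      abort_integrity(paste0("Corrupt or truncated weights file: ", w_path))
    }
  )
  want <- lapply(meta$param_shapes, as.integer)
  got <- lapply(params, function(x) as.integer(dim(x) %||% length(x)))
  if (!identical(names(want), names(got)) ||
    !all(mapply(identical, want, got))) {
    abort_integrity("Weight shapes do not match the stored configuration.")
  }
  model <- build_cnn(config, seed = 0L)
  check <- lapply(model$params, function(x) as.integer(dim(x) %||% length(x)))
  if (!identical(check, got)) {
    abort_integrity(
      "Stored class registry/configuration is inconsistent with the weights."
    )
  }
  model$params <- params
  model$trained <- isTRUE(meta$trained)
  log_path <- file.path(dir, "training_log.csv")
  if (file.exists(log_path)) {
    model$log <- readr::read_csv(log_path,
      col_types = readr::cols(), progress = FALSE
    )
  }
  model
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy the training log of a CNN fit
#'
#' @param x A trained `cnn_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `loss`, `accuracy` and,
#'   when a validation split was used, `val_loss`, `val_accuracy`.
#' @method tidy cnn_model
#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$log)) {
    return(tibble::tibble(
      epoch = integer(), loss = numeric(), accuracy = numeric()
    ))
  }
  x$log
}

#' One-row summary of a CNN fit
#'
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @return A tibble with `n_parameters`, `input_length`, `n_classes`,
#'   `epochs`, final `loss` and `accuracy`.
#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_params(x),
    input_length = x$config$input_length,
    n_classes = length(x$config$classes),
    epochs = if (is.null(x$log)) 0L else nrow(x$log),
    loss = if (is.null(x$log)) NA_real_ else dplyr::last(x$log$loss),
    accuracy = if (is.null(x$log)) NA_real_ else dplyr::last(x$log$accuracy)
  )
}
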