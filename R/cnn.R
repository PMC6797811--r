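#' CNN architecture configuration
#'
#' The 10-layer network: three convolution layers (5x5 kernels,
#' same-padding, stride 1, ReLU), each followed by a max-pooling layer
#' (non-overlapping windows), a dropout layer between the third pooling
#' layer and the first fully connected layer, two fully connected layers,
#' and a final softmax activation. Input is a single-channel 200 x 200
#' image.
#'
#' Defaults (8/16/32 channels; 4x4, 2x2, 2x2 pools; 64 hidden units;
#' dropout 0.5) are sized for CPU training at desk scale; all of them are
#' configurable.
#'
#' @param n_classes Number of output classes.
#' @param channels Feature maps per convolution layer (length 3).
#' @param kernel Odd square kernel size shared by the convolution layers.
#' @param pools Pooling window (= stride) per stage (length 3).
#' @param fc_hidden Hidden units of the first fully connected layer.
#' @param dropout Dropout probability (0 disables).
#' @param input_size Input image side length.
#' @return A `cnn_architecture` list including the derived feature-map
#'   sizes and flattened dimension.
#' @export
cnn_architecture <- function(n_classes, channels = c(8, 16, 32), kernel = 5,
                             pools = c(4, 2, 2), fc_hidden = 64,
                             dropout = 0.5, input_size = 200) {
  stopifnot(length(channels) == 3, length(pools) == 3, kernel %% 2 == 1,
            n_classes >= 2, fc_hidden >= 1, dropout >= 0, dropout < 1,
            all(channels >= 1), all(pools >= 1))
  sizes <- integer(4)
  sizes[1] <- as.integer(input_size)
  for (l in 1:3) {
    sizes[l + 1] <- sizes[l] %/% pools[l]
    if (sizes[l + 1] < 1)
      stop("shape error: pooling stage ", l, " collapses the feature map")
  }
  flat <- sizes[4]^2 * channels[3]
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 pools = as.integer(pools), fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 input_size = as.integer(input_size),
                 map_sizes = sizes, flat_dim = as.integer(flat)),
            class = "cnn_architecture")
}

#' LeNet-style baseline configuration
#'
#' LeNet-5 expressed in the same three-conv-block schema (6/16/120 feature
#' maps, 5x5 kernels, 2x2 pools, 84 hidden units, no dropout), used as the
#' comparison baseline at synthetic scale.
#'
#' @param n_classes Number of output classes.
#' @return A `cnn_architecture`.
#' @export
cnn_lenet_architecture <- function(n_classes) {
  cnn_architecture(n_classes, channels = c(6, 16, 120), kernel = 5,
                   pools = c(2, 2, 2), fc_hidden = 84, dropout = 0)
}

#' Trainable parameter count of an architecture
#'
#' Sum of kernel + bias counts over the three convolution layers and the
#' two fully connected layers.
#'
#' @param arch A [cnn_architecture()].
#' @return Integer parameter count.
#' @export
cnn_count_params <- function(arch) {
  cin <- c(1L, arch$channels[1:2])
  conv <- sum(arch$channels * cin * arch$kernel^2 + arch$channels)
  fc <- arch$fc_hidden * arch$flat_dim + arch$fc_hidden +
    arch$n_classes * arch$fc_hidden + arch$n_classes
  as.integer(conv + fc)
}

#' Build (initialize) a CNN model
#'
#' He-normal initialization for all weights, zero biases; deterministic
#' given the seed.
#'
#' @param arch A [cnn_architecture()].
#' @param seed Integer seed.
#' @return A `cnn_model` list with `arch` and `weights`.
#' @export
cnn_build <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  set.seed(seed)
  cin <- c(1L, arch$channels[1:2])
  he <- function(nr, nc, fan_in)
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  w <- list()
  for (l in 1:3) {
    fan <- cin[l] * arch$kernel^2
    w[[2 * l - 1]] <- he(arch$channels[l], fan, fan)
    w[[2 * l]] <- numeric(arch$channels[l])
  }
  w[[7]] <- he(arch$fc_hidden, arch$flat_dim, arch$flat_dim)
  w[[8]] <- numeric(arch$fc_hidden)
  w[[9]] <- he(arch$n_classes, arch$fc_hidden, arch$fc_hidden)
  w[[10]] <- numeric(arch$n_classes)
  structure(list(arch = arch, weights = w), class = "cnn_model")
}

#' Adam training configuration
#'
#' Adam with learning rate 0.001, first/second moment decay rho1 = 0.9 and
#' rho2 = 0.999, stability constant delta = 1e-8, batch size 64. The
#' additional constant `epsilon_reported = 0.001` is stored for the record
#' but plays no role in the update (delta is the denominator stability
#' term).
#'
#' @param learning_rate,rho1,rho2,delta Adam hyperparameters.
#' @param epsilon_reported Stored, unused.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Seed for shuffling, dropout and (via [cnn_build()]) init.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, rho1 = 0.9, rho2 = 0.999,
                            delta = 1e-8, epsilon_reported = 0.001,
                            batch_size = 64, epochs = 100, seed = 1L) {
  stopifnot(learning_rate > 0, rho1 >= 0, rho1 < 1, rho2 >= 0, rho2 < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, rho1 = rho1, rho2 = rho2,
                 delta = delta, epsilon_reported = epsilon_reported,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

.as_batch_cube <- function(x, idx, input_size) {
  aperm(x[idx, , , drop = FALSE], c(2, 3, 1))
}

.check_images <- function(x, input_size) {
  if (length(dim(x)) != 3 || dim(x)[2] != input_size ||
      dim(x)[3] != input_size)
    stop("shape error: images must be n x ", input_size, " x ", input_size)
}

# One forward/backward pass over a batch; grads are summed over the batch.
.cnn_batch <- function(model, xb, yb, mask = NULL, grad = TRUE) {
  cpp_cnn_batch(xb, as.integer(yb), model$weights, model$arch,
                if (is.null(mask)) matrix(0, 0, 0) else mask, grad)
}

#' Predict classes for a batch of images
#'
#' @param model A `cnn_model`.
#' @param x Array `n x S x S` of images (pixel values in any consistent
#'   scale; training and prediction should use the same scale).
#' @param labels Optional label names for the output.
#' @param batch_size Evaluation batch size.
#' @return List with `class` (1-based argmax index, ties broken towards the
#'   lowest index), `label` (if `labels` given) and `prob` (`n x K` matrix,
#'   rows summing to 1).
#' @export
cnn_predict <- function(model, x, labels = NULL, batch_size = 64) {
  stopifnot(inherits(model, "cnn_model"))
  .check_images(x, model$arch$input_size)
  n <- dim(x)[1]
  prob <- matrix(0, n, model$arch$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1)
    out <- .cnn_batch(model, .as_batch_cube(x, idx, model$arch$input_size),
                      integer(0), mask = NULL, grad = FALSE)
    prob[idx, ] <- t(out$probs)
  }
  cls <- apply(prob, 1, which.max)
  res <- list(class = cls, prob = prob)
  if (!is.null(labels)) res$label <- labels[cls]
  res
}

.adam_init <- function(w) lapply(w, function(p) list(m = p * 0, v = p * 0))

.adam_step <- function(weights, grads, state, t, cfg) {
  for (i in seq_along(weights)) {
    g <- grads[[i]]
    state[[i]]$m <- cfg$rho1 * state[[i]]$m + (1 - cfg$rho1) * g
    state[[i]]$v <- cfg$rho2 * state[[i]]$v + (1 - cfg$rho2) * g^2
    mhat <- state[[i]]$m / (1 - cfg$rho1^t)
    vhat <- state[[i]]$v / (1 - cfg$rho2^t)
    weights[[i]] <- weights[[i]] -
      cfg$learning_rate * mhat / (sqrt(vhat) + cfg$delta)
  }
  list(weights = weights, state = state)
}

#' Train a CNN with Adam and best-on-test checkpointing
#'
#' Mini-batch Adam on categorical cross-entropy. Each epoch records the
#' mean training loss (cost), the training error (1 - accuracy, measured on
#' the training-pass forward outputs, dropout active) and the test error
#' (dropout inactive). The weights achieving the minimum test error are
#' retained as the best model. Fully deterministic given `cfg$seed`.
#'
#' @param model A `cnn_model` from [cnn_build()].
#' @param x_train,y_train Training images (`n x S x S`) and 1-based integer
#'   labels.
#' @param x_test,y_test Test split, evaluated every epoch.
#' @param cfg A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return A `cnn_fit`: `model` (best weights), `final_model`, `history`
#'   data.frame (epoch, cost, train_error, test_error), `best_epoch`.
#' @export
cnn_train <- function(model, x_train, y_train, x_test, y_test,
                      cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "training_config"))
  .check_images(x_train, model$arch$input_size)
  .check_images(x_test, model$arch$input_size)
  n <- dim(x_train)[1]
  if (n == 0 || dim(x_test)[1] == 0)
    stop("configuration error: empty training or test split")
  stopifnot(length(y_train) == n, length(y_test) == dim(x_test)[1],
            all(y_train >= 1), all(y_train <= model$arch$n_classes))
  set.seed(cfg$seed)
  state <- .adam_init(model$weights)
  t <- 0
  p_drop <- model$arch$dropout
  flat <- model$arch$flat_dim
  history <- data.frame(epoch = integer(), cost = numeric(),
                        train_error = numeric(), test_error = numeric())
  best <- list(err = Inf, epoch = NA_integer_, weights = NULL)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(n)
    cost_sum <- 0
    correct <- 0L
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[s:min(n, s + cfg$batch_size - 1)]
      nb <- length(idx)
      mask <- if (p_drop > 0)
        matrix((runif(flat * nb) >= p_drop) / (1 - p_drop), flat, nb)
      xb <- .as_batch_cube(x_train, idx, model$arch$input_size)
      out <- .cnn_batch(model, xb, y_train[idx], mask, grad = TRUE)
      cost_sum <- cost_sum + out$loss
      correct <- correct +
        sum(apply(out$probs, 2, which.max) == y_train[idx])
      grads <- lapply(out$grads, function(g) g / nb)
      t <- t + 1
      upd <- .adam_step(model$weights, grads, state, t, cfg)
      model$weights <- upd$weights
      state <- upd$state
    }
    pred <- cnn_predict(model, x_test, batch_size = cfg$batch_size)
    test_err <- mean(pred$class != y_test)
    history[ep, ] <- list(ep, cost_sum / n, 1 - correct / n, test_err)
    if (test_err < best$err) {
      best$err <- test_err
      best$epoch <- ep
      best$weights <- model$weights
    }
    if (verbose)
      message(sprintf("epoch %3d  cost %.4f  train_err %.3f  test_err %.3f",
                      ep, cost_sum / n, 1 - correct / n, test_err))
  }
  structure(list(model = structure(list(arch = model$arch,
                                        weights = best$weights),
                                   class = "cnn_model"),
                 final_model = model, history = history,
                 best_epoch = best$epoch),
            class = "cnn_fit")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files with a versioned header
#' (`format = "pulsecnn-ckpt-1"`).
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint path.
#' @return `cnn_load()` returns the `cnn_model`.
#' @export
cnn_save <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(list(format = "pulsecnn-ckpt-1", arch = unclass(model$arch),
               weights = model$weights), path)
  invisible(path)
}

#' @rdname cnn_save
#' @export
cnn_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pulsecnn-ckpt-1"))
    stop("unrecognized checkpoint format")
  structure(list(arch = structure(x$arch, class = "cnn_architecture"),
                 weights = x$weights),
            class = "cnn_model")
}
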