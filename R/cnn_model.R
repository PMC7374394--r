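#' Training configuration for the 1D CNN
#'
#' Plain mini-batch stochastic gradient descent with cross-entropy loss and
#' rectified-linear activations; training stops at the epoch budget or as
#' soon as the mean training loss drops below `loss_threshold`.
#'
#' @param learning_rate SGD step size, > 0.
#' @param epochs epoch budget, >= 1.
#' @param batch_size mini-batch size.
#' @param loss_threshold stop early once mean epoch training loss falls
#'   below this value.
#' @param momentum classical momentum coefficient in \[0, 1) (0 = vanilla
#'   SGD).
#' @param clip_norm rescale each mini-batch gradient to this global L2 norm
#'   when it exceeds it (`Inf` disables clipping); guards the small-batch
#'   SGD updates against the occasional exploding step.
#' @param normalize z-normalize each piece (zero mean, unit variance) before
#'   training and prediction.
#' @param pool_size max-pooling width after each convolution block (1
#'   disables pooling).
#' @param seed optional integer seed for weight initialization and batch
#'   shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.05, epochs = 15,
                            batch_size = 32, loss_threshold = 0.02,
                            momentum = 0.9, clip_norm = 5,
                            normalize = TRUE,
                            pool_size = 2, seed = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (clip_norm <= 0) stop("clip_norm must be > 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_threshold = loss_threshold, momentum = momentum,
                 clip_norm = clip_norm, normalize = isTRUE(normalize),
                 pool_size = as.integer(pool_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "training_config")
}

# valid 1D convolution output length
conv_out_len <- function(len, ks) len - ks + 1L

#' Build the parameterized 1D CNN architecture
#'
#' One convolution block per layer of the hyperparameter vector: valid (no
#' padding) 1 x ks convolution with kc kernels, stride 1, ReLU, then
#' non-overlapping max-pooling of width `pool_size` (skipped automatically
#' for a block whose feature map would collapse below one sample).  The
#' convolutional stack is flattened into two ReLU dense layers of widths
#' `dlnc[1]` and `dlnc[2]` and a softmax output layer.  Weights use
#' He-normal initialization; the layout and parameter count are a pure
#' function of the inputs.
#'
#' @param hp an [hp_vector()].
#' @param input_length number of samples per piece.
#' @param n_classes number of output classes (default 5).
#' @param pool_size max-pooling width (1 disables pooling).
#' @param seed optional integer seed for the weight draw.
#' @return An object of class `cnn_model` with the layer list, per-layer
#'   shapes and total parameter count.
#' @export
build_model <- function(hp, input_length, n_classes = 5L, pool_size = 2L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  layers <- list()
  len <- as.integer(input_length)
  channels <- 1L
  for (d in seq_along(hp$ks)) {
    ks <- hp$ks[d]; kc <- hp$kc[d]
    out_len <- conv_out_len(len, ks)
    if (out_len < 1L)
      stop(sprintf(
        "conv layer %d: kernel size %d collapses the %d-sample feature map",
        d, ks, len))
    fan_in <- ks * channels
    pooled <- pool_size > 1L && out_len %/% pool_size >= 1L
    layers[[length(layers) + 1L]] <-
      list(type = "conv", ks = ks, in_channels = channels, out_channels = kc,
           in_len = len, out_len = out_len, pool = pooled,
           pool_size = if (pooled) pool_size else 1L,
           W = he(fan_in, kc, fan_in), b = numeric(kc))
    len <- if (pooled) out_len %/% pool_size else out_len
    channels <- kc
  }
  flat <- len * channels
  dims <- c(flat, hp$dlnc, n_classes)
  for (i in 1:3) {
    layers[[length(layers) + 1L]] <-
      list(type = if (i < 3) "dense" else "output",
           W = he(dims[i], dims[i + 1], dims[i]), b = numeric(dims[i + 1]))
  }
  n_par <- sum(vapply(layers, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  structure(list(hp = hp, layers = layers, input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes), flat_dim = flat,
                 n_parameters = n_par, trained = FALSE, diverged = FALSE,
                 loss_curve = numeric(0)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("1D CNN: input %d samples -> %d classes, %s parameters%s\n",
              x$input_length, x$n_classes,
              format(x$n_parameters, big.mark = ","),
              if (x$trained) " (trained)" else ""))
  for (l in x$layers) {
    if (l$type == "conv")
      cat(sprintf("  conv ks=%d kc=%d: %d -> %d%s\n", l$ks, l$out_channels,
                  l$in_len, l$out_len,
                  if (l$pool) sprintf(" -> pool/%d -> %d", l$pool_size,
                                      l$out_len %/% l$pool_size) else ""))
    else
      cat(sprintf("  %s %d -> %d\n", l$type, nrow(l$W), ncol(l$W)))
  }
  invisible(x)
}

# im2col for a batch: activations A are (N, L, C); returns the
# (N * L_out) x (ks * C) matrix whose row (t-1)*N + n holds the window of
# sample n at output position t, columns ordered k within channel.
im2col <- function(A, ks, out_len) {
  n <- dim(A)[1]; channels <- dim(A)[3]
  M <- matrix(0, n * out_len, ks * channels)
  for (c in seq_len(channels)) {
    Ac <- A[, , c, drop = TRUE]
    if (is.null(dim(Ac))) Ac <- matrix(Ac, nrow = n)
    for (k in seq_len(ks)) {
      M[, (c - 1L) * ks + k] <- as.vector(Ac[, k:(k + out_len - 1L),
                                             drop = FALSE])
    }
  }
  M
}

col2im <- function(dM, ks, out_len, n, in_len, channels) {
  dA <- array(0, c(n, in_len, channels))
  for (c in seq_len(channels)) {
    for (k in seq_len(ks)) {
      dA[, k:(k + out_len - 1L), c] <- dA[, k:(k + out_len - 1L), c] +
        matrix(dM[, (c - 1L) * ks + k], n, out_len)
    }
  }
  dA
}

cnn_forward <- function(model, X, keep = FALSE) {
  n <- nrow(X)
  cache <- if (keep) list() else NULL
  A <- array(X, c(n, ncol(X), 1L))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      M <- im2col(A, l$ks, l$out_len)
      Z <- sweep(M %*% l$W, 2L, l$b, "+")
      relu_mask <- Z > 0
      Z[!relu_mask] <- 0
      Anew <- array(Z, c(n, l$out_len, l$out_channels))
      if (l$pool) {
        p <- l$pool_size
        L2 <- l$out_len %/% p
        idx <- (seq_len(L2) - 1L) * p
        P <- array(Anew[, idx + 1L, , drop = FALSE],
                   c(n, L2, l$out_channels))
        arg <- array(1L, c(n, L2, l$out_channels))
        for (o in 2:p) {
          So <- array(Anew[, idx + o, , drop = FALSE],
                      c(n, L2, l$out_channels))
          better <- So > P
          P[better] <- So[better]
          arg[better] <- o
        }
        if (keep) cache[[i]] <- list(M = M, relu = relu_mask, arg = arg)
        A <- P
      } else {
        if (keep) cache[[i]] <- list(M = M, relu = relu_mask)
        A <- Anew
      }
    } else {
      if (is.array(A) && length(dim(A)) == 3L) A <- matrix(A, n)
      Z <- sweep(A %*% l$W, 2L, l$b, "+")
      if (l$type == "dense") {
        relu_mask <- Z > 0
        Z[!relu_mask] <- 0
        if (keep) cache[[i]] <- list(A_in = A, relu = relu_mask)
      } else {
        if (keep) cache[[i]] <- list(A_in = A)
      }
      A <- Z
    }
  }
  # softmax over logits
  A <- A - apply(A, 1, max)
  E <- exp(A)
  probs <- E / rowSums(E)
  list(probs = probs, cache = cache)
}

# Backpropagation.  Each step consumes d_out, the loss gradient with respect
# to the layer's own output (post-ReLU, post-pool; an N x flat matrix), and
# leaves in d_out the gradient with respect to the layer's input.
cnn_backward <- function(model, X, Y_onehot, fwd) {
  n <- nrow(X)
  grads <- vector("list", length(model$layers))
  d_out <- NULL
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cc <- fwd$cache[[i]]
    if (l$type == "output") {
      dZ <- (fwd$probs - Y_onehot) / n   # softmax + cross-entropy gradient
      grads[[i]] <- list(dW = crossprod(cc$A_in, dZ), db = colSums(dZ))
      d_out <- dZ %*% t(l$W)
    } else if (l$type == "dense") {
      dZ <- d_out * cc$relu
      grads[[i]] <- list(dW = crossprod(cc$A_in, dZ), db = colSums(dZ))
      d_out <- dZ %*% t(l$W)
    } else {  # conv block: unpool, ReLU mask, weight grads, then col2im
      if (l$pool) {
        p <- l$pool_size
        L2 <- l$out_len %/% p
        dP <- array(d_out, c(n, L2, l$out_channels))
        dPre <- array(0, c(n, l$out_len, l$out_channels))
        for (o in seq_len(p)) {
          sel <- cc$arg == o
          tmp <- array(0, c(n, L2, l$out_channels))
          tmp[sel] <- dP[sel]
          dPre[, (seq_len(L2) - 1L) * p + o, ] <- tmp
        }
      } else {
        dPre <- array(d_out, c(n, l$out_len, l$out_channels))
      }
      dZc <- matrix(dPre, n * l$out_len, l$out_channels) * cc$relu
      grads[[i]] <- list(dW = crossprod(cc$M, dZc), db = colSums(dZc))
      if (i > 1L) {
        dM <- dZc %*% t(l$W)
        dA <- col2im(dM, l$ks, l$out_len, n, l$in_len, l$in_channels)
        d_out <- matrix(dA, n)
      }
    }
  }
  grads
}

normalize_pieces <- function(X) {
  mu <- rowMeans(X)
  sd <- sqrt(rowMeans((X - mu)^2))
  sd[sd < 1e-8] <- 1
  (X - mu) / sd
}

labels_to_onehot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Train the 1D CNN with mini-batch SGD
#'
#' Shuffled mini-batches, cross-entropy loss, classical momentum.  Training
#' stops when the epoch budget is exhausted or the mean epoch loss falls
#' below the configured threshold.  A training run whose loss becomes
#' non-finite is marked diverged; [make_objective()] maps such runs to a
#' recognition rate of 0 so the optimizer simply discards them.
#'
#' @param model a [build_model()] result.
#' @param X pieces x samples training matrix.
#' @param y factor of training labels (levels = the model's classes).
#' @param config a [training_config()].
#' @return The trained model, with `loss_curve` (mean loss per epoch),
#'   `trained = TRUE` and a `diverged` flag.
#' @export
train_model <- function(model, X, y, config = training_config()) {
  if (nrow(X) == 0L) stop("training split is empty")
  if (nlevels(y) != model$n_classes)
    stop("label factor must have exactly the model's classes as levels")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$normalize) X <- normalize_pieces(X)
  Y <- labels_to_onehot(y, model$n_classes)
  n <- nrow(X)
  vel <- lapply(model$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
  loss_curve <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fwd <- cnn_forward(model, Xb, keep = TRUE)
      p_true <- rowSums(fwd$probs * Yb)
      loss <- -mean(log(pmax(p_true, 1e-12)))
      batch_losses <- c(batch_losses, loss)
      if (!is.finite(loss)) {
        model$diverged <- TRUE
        model$trained <- TRUE
        model$loss_curve <- loss_curve
        return(model)
      }
      grads <- cnn_backward(model, Xb, Yb, fwd)
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g)
          sum(g$dW^2) + sum(g$db^2), numeric(1))))
        if (gnorm > config$clip_norm) {
          scale <- config$clip_norm / gnorm
          grads <- lapply(grads, function(g)
            list(dW = g$dW * scale, db = g$db * scale))
        }
      }
      for (i in seq_along(model$layers)) {
        vel[[i]]$W <- config$momentum * vel[[i]]$W -
          config$learning_rate * grads[[i]]$dW
        vel[[i]]$b <- config$momentum * vel[[i]]$b -
          config$learning_rate * grads[[i]]$db
        model$layers[[i]]$W <- model$layers[[i]]$W + vel[[i]]$W
        model$layers[[i]]$b <- model$layers[[i]]$b + vel[[i]]$b
      }
    }
    epoch_loss <- mean(batch_losses)
    loss_curve <- c(loss_curve, epoch_loss)
    if (!is.finite(epoch_loss)) {
      model$diverged <- TRUE
      break
    }
    if (epoch_loss < config$loss_threshold) break
  }
  model$trained <- TRUE
  model$loss_curve <- loss_curve
  model$normalize <- config$normalize
  model
}

#' Predict class labels for signal pieces
#'
#' @param object a trained [cnn_model].
#' @param X pieces x samples matrix.
#' @param type `"class"` (default) for labels, `"prob"` for the softmax
#'   probability matrix.
#' @param ... unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.cnn_model <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (isTRUE(object$normalize)) X <- normalize_pieces(X)
  probs <- cnn_forward(object, X)$probs
  if (type == "prob") return(probs)
  factor(pattern_types()[max.col(probs, ties.method = "first")],
         levels = pattern_types())
}

#' Evaluate recognition rate and confusion matrix
#'
#' @param model a trained [cnn_model] (or any object accepted by
#'   `predictions`), or a factor of predictions when `predictions = TRUE`.
#' @param X pieces x samples evaluation matrix (ignored when `model` is
#'   already a factor of predictions).
#' @param y factor of true labels over the five classes.
#' @return List of class `evaluation_result` with `rate` (percent correct),
#'   `confusion` (5 x 5 count matrix, rows = truth, columns = prediction)
#'   and `n`.
#' @export
evaluate_model <- function(model, X, y) {
  if (length(y) == 0L) stop("evaluation split is empty")
  if (any(is.na(y)) || !all(levels(y) %in% pattern_types()))
    stop("labels outside the five pattern classes")
  preds <- if (is.factor(model)) model else predict(model, X)
  confusion <- table(truth = factor(y, levels = pattern_types()),
                     prediction = factor(preds, levels = pattern_types()))
  rate <- 100 * sum(diag(confusion)) / length(y)
  structure(list(rate = rate, confusion = unclass(confusion),
                 n = length(y)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Recognition rate: %.1f%% on %d pieces\n", x$rate, x$n))
  print(x$confusion)
  invisible(x)
}

#' Build the recognition-rate objective for the optimizer
#'
#' Returns the function the Harmony Search engine maximizes: given a
#' hyperparameter vector it builds the CNN, trains it on the training split
#' and returns the validation recognition rate in percent.  Per
#' hyperparameter vector, the weight-initialization/shuffling seed is derived
#' deterministically from `base_seed` and the tuple, so re-evaluating the
#' same architecture yields the same rate (unless `redraw_split` is set, in
#' which case the learning pool is re-split at random before every
#' training).  Build or training failures, and diverged runs, score 0 with a
#' warning.
#'
#' @param ds a split [generate_dataset()] result.
#' @param config a [training_config()].
#' @param redraw_split re-draw the train/validation partition of the
#'   learning pool before each evaluation.
#' @param val_fraction validation fraction used when re-drawing.
#' @param base_seed integer seed the per-architecture training seeds are
#'   derived from.
#' @return Function `hp_vector -> recognition rate in [0, 100]`.
#' @export
make_objective <- function(ds, config = training_config(),
                           redraw_split = FALSE, val_fraction = 0.2,
                           base_seed = 0L) {
  if (is.null(ds$split)) stop("dataset has no split; call split_dataset() first")
  function(hp) {
    tryCatch({
      if (redraw_split) {
        pool_idx <- which(ds$split %in% c("train", "validation"))
        n_val <- round(val_fraction * length(pool_idx))
        val_idx <- sample(pool_idx, n_val)
        tr_idx <- setdiff(pool_idx, val_idx)
        tr <- list(x = ds$signals[tr_idx, , drop = FALSE],
                   y = ds$labels[tr_idx])
        va <- list(x = ds$signals[val_idx, , drop = FALSE],
                   y = ds$labels[val_idx])
      } else {
        tr <- dataset_split(ds, "train")
        va <- dataset_split(ds, "validation")
      }
      cfg <- config
      cfg$seed <- (as.integer(base_seed) +
                     sum(hp_as_integer(hp) * seq_along(hp_as_integer(hp)) * 131L)) %%
        2147483587L
      model <- build_model(hp, input_length = ncol(tr$x),
                           n_classes = nlevels(tr$y),
                           pool_size = cfg$pool_size, seed = cfg$seed)
      model <- train_model(model, tr$x, tr$y, cfg)
      if (model$diverged) {
        warning(sprintf("training diverged on %s; scoring 0", format(hp)))
        return(0)
      }
      evaluate_model(model, va$x, va$y)$rate
    }, error = function(e) {
      warning(sprintf("objective failed on %s (%s); scoring 0",
                      format(hp), conditionMessage(e)))
      0
    })
  }
}
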