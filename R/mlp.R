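#' Stratified train/test split
#'
#' Randomly partitions a labeled feature table into disjoint train and test
#' sets, stratified by class so both sets preserve the class balance. With
#' 400 + 400 examples and the default fraction this yields 280 + 280 training
#' and 120 + 120 test rows.
#'
#' @param data `data.frame` with a `label` column; remaining columns are
#'   features.
#' @param train_fraction Fraction assigned to the training set (default 0.7).
#' @param seed Optional integer seed making the split reproducible.
#' @return A list with `train` and `test` data.frames.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = NULL) {
  if (!"label" %in% names(data))
    stop("'data' must have a 'label' column", call. = FALSE)
  if (nrow(data) == 0L) stop("'data' is empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  classes <- unique(data$label)
  train_idx <- integer()
  for (cl in classes) {
    idx <- which(data$label == cl)
    if (length(idx) < 2L)
      stop("class '", cl, "' has fewer than 2 members; cannot stratify",
           call. = FALSE)
    n_tr <- round(length(idx) * train_fraction)
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a backpropagation multilayer perceptron
#'
#' A feed-forward network with one hidden layer of logistic-sigmoid units and
#' two sigmoid output units (one per class), trained by full-batch gradient
#' descent with momentum on the mean-squared error between outputs and one-hot
#' targets. Training runs for at most `cycles` epochs and stops early when the
#' epoch-to-epoch loss improvement falls below `epsilon`. Features are
#' standardized internally (the scaling is stored in the model and re-applied
#' at prediction time). Weights are initialized uniformly in \[-0.5, 0.5\]
#' from the seeded generator, so identical seeds and data give bitwise
#' identical models and loss traces.
#'
#' @param data `data.frame` with a `label` column (exactly 2 classes) and
#'   numeric feature columns, or a numeric matrix plus `labels`.
#' @param labels Class labels when `data` is a bare matrix.
#' @param hidden Hidden-layer size (default 10).
#' @param cycles Maximum training epochs (default 500).
#' @param learning_rate Gradient-descent step size (default 0.3).
#' @param momentum Momentum coefficient on the previous update (default 0.2).
#' @param epsilon Stop when the loss improves by less than this
#'   (default 1e-5).
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `mlp_model`: weights (`W1`, `b1`, `W2`, `b2`),
#'   `classes`, the feature standardization (`center`, `scale`),
#'   `feature_names`, the hyperparameters and the per-epoch `loss_trace`.
#' @export
train_mlp <- function(data, labels = NULL, hidden = 10L, cycles = 500L,
                      learning_rate = 0.3, momentum = 0.2, epsilon = 1e-5,
                      seed = NULL) {
  if (is.data.frame(data)) {
    if (!"label" %in% names(data))
      stop("'data' must have a 'label' column", call. = FALSE)
    labels <- data$label
    X <- as.matrix(data[, setdiff(names(data), "label"), drop = FALSE])
  } else {
    X <- as.matrix(data)
    if (is.null(labels)) stop("'labels' required", call. = FALSE)
  }
  if (any(c(cycles, learning_rate, momentum, epsilon) < 0))
    stop("hyperparameters must be non-negative", call. = FALSE)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L)
    stop("exactly two classes required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  n <- nrow(X)
  d <- ncol(X)
  Tm <- cbind(as.numeric(labels == classes[1L]),
              as.numeric(labels == classes[2L]))

  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")

  if (!is.null(seed)) set.seed(seed)
  H <- as.integer(hidden)
  W1 <- matrix(stats::runif(d * H, -0.5, 0.5), d, H)
  b1 <- stats::runif(H, -0.5, 0.5)
  W2 <- matrix(stats::runif(H * 2L, -0.5, 0.5), H, 2L)
  b2 <- stats::runif(2L, -0.5, 0.5)
  vW1 <- matrix(0, d, H); vb1 <- numeric(H)
  vW2 <- matrix(0, H, 2L); vb2 <- numeric(2L)

  trace <- numeric(0)
  for (cycle in seq_len(max(1L, as.integer(cycles)))) {
    Hid <- sigmoid(sweep(Xs %*% W1, 2L, b1, "+"))
    Out <- sigmoid(sweep(Hid %*% W2, 2L, b2, "+"))
    loss <- mean((Out - Tm)^2)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss); lower 'learning_rate' (",
           learning_rate, ")", call. = FALSE)
    trace <- c(trace, loss)
    if (cycle > 1L && (trace[cycle - 1L] - loss) < epsilon) break

    dOut <- (Out - Tm) * Out * (1 - Out) * (2 / (n * 2L))
    gW2 <- crossprod(Hid, dOut); gb2 <- colSums(dOut)
    dHid <- (dOut %*% t(W2)) * Hid * (1 - Hid)
    gW1 <- crossprod(Xs, dHid); gb1 <- colSums(dHid)

    vW1 <- momentum * vW1 - learning_rate * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - learning_rate * gb1; b1 <- b1 + vb1
    vW2 <- momentum * vW2 - learning_rate * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - learning_rate * gb2; b2 <- b2 + vb2
  }

  dimnames(W1) <- NULL; dimnames(W2) <- NULL
  names(b1) <- NULL; names(b2) <- NULL
  structure(
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes,
         center = center, scale = scl, feature_names = colnames(X),
         hyperparameters = list(hidden = H, cycles = as.integer(cycles),
                                learning_rate = learning_rate,
                                momentum = momentum, epsilon = epsilon),
         loss_trace = trace),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-2 sigmoid network, classes: %s\n",
              nrow(x$W1), ncol(x$W1), paste(x$classes, collapse = "/")))
  cat(sprintf("  trained %d cycle(s), final loss %.3g\n",
              length(x$loss_trace),
              if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA))
  invisible(x)
}

mlp_forward <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  Hid <- sigmoid(sweep(Xs %*% model$W1, 2L, model$b1, "+"))
  sigmoid(sweep(Hid %*% model$W2, 2L, model$b2, "+"))
}

#' Predict with a trained MLP
#'
#' The predicted class is the output unit with the larger activation
#' (ties go to the first class); the confidence is the winning unit's
#' activation, in \[0, 1\]. Batch prediction equals row-wise prediction.
#'
#' @param object An [mlp_model][train_mlp()].
#' @param newdata Named numeric feature vector, matrix or `data.frame`
#'   (one row per example).
#' @param ... Unused.
#' @return `data.frame` with columns `class` and `confidence`.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) &&
      all(object$feature_names %in% colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  if (ncol(X) != nrow(object$W1))
    stop("feature dimension ", ncol(X), " does not match model input ",
         nrow(object$W1), call. = FALSE)
  storage.mode(X) <- "double"
  Out <- mlp_forward(object, X)
  win <- max.col(Out, ties.method = "first")
  data.frame(class = object$classes[win],
             confidence = Out[cbind(seq_len(nrow(Out)), win)],
             stringsAsFactors = FALSE)
}

#' Save / load an MLP model as JSON
#'
#' The model (layer shapes, weights, feature scaling, class names and
#' hyperparameters) is stored as a single JSON document so the training and
#' detection stages compose across sessions and the command line.
#'
#' @param model An [mlp_model][train_mlp()].
#' @param path JSON file path.
#' @return `write_mlp()` returns `path` invisibly; `read_mlp()` returns the
#'   restored `mlp_model`.
#' @export
write_mlp <- function(model, path) {
  obj <- list(
    type = "spikemf_mlp", classes = model$classes,
    feature_names = model$feature_names,
    center = model$center, scale = model$scale,
    dims = list(input = nrow(model$W1), hidden = ncol(model$W1), output = 2L),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    hyperparameters = model$hyperparameters, loss_trace = model$loss_trace
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "spikemf_mlp"))
    stop("not a spikemf MLP model file: ", path, call. = FALSE)
  structure(
    list(W1 = matrix(unlist(obj$W1), obj$dims$input, obj$dims$hidden),
         b1 = as.numeric(obj$b1),
         W2 = matrix(unlist(obj$W2), obj$dims$hidden, 2L),
         b2 = as.numeric(obj$b2),
         classes = obj$classes,
         center = stats::setNames(as.numeric(obj$center), obj$feature_names),
         scale = stats::setNames(as.numeric(obj$scale), obj$feature_names),
         feature_names = obj$feature_names,
         hyperparameters = obj$hyperparameters,
         loss_trace = as.numeric(obj$loss_trace)),
    class = "mlp_model"
  )
}
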