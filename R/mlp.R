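#' Multilayer perceptron configuration
#'
#' @param n_inputs Number of input neurons (spectral points).
#' @param n_outputs Number of output neurons (classes, or 1 for
#'   regression).
#' @param hidden Integer vector of hidden layer sizes (1 or 2 layers,
#'   2-250 neurons each).
#' @param dropout Dropout rate in `[0, 1)` applied to hidden activations
#'   during training (inverted dropout, expectation preserving).
#' @param task `"classification"` (softmax output, categorical
#'   cross-entropy) or `"regression"` (ReLU output, mean squared error;
#'   the ReLU head keeps concentrations nonnegative).
#' @param lr,beta1,beta2,eps ADAM hyperparameters (defaults 0.001, 0.9,
#'   0.999, 1e-8).
#' @param max_epochs Maximum training epochs (full-batch).
#' @param patience Early-stopping patience: training stops once the
#'   validation loss has failed to improve for more than `patience`
#'   consecutive epochs; the best-validation weights are restored.
#' @return An `mlp_config`.
#' @export
mlp_config <- function(n_inputs, n_outputs, hidden = 32L, dropout = 0,
                       task = c("classification", "regression"),
                       lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       max_epochs = 600L, patience = 50L) {
  task <- match.arg(task)
  hidden <- as.integer(hidden)
  if (!length(hidden) %in% 1:2)
    stop("`hidden` must give 1 or 2 hidden layers", call. = FALSE)
  if (any(hidden < 1L)) stop("hidden layers need >= 1 neuron",
                             call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must lie in [0, 1)", call. = FALSE)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs), hidden = hidden,
                 dropout = dropout, task = task, lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "mlp_config")
}

#' Initialize MLP weights (He-uniform)
#'
#' ReLU-appropriate He-uniform initialization `U(+-sqrt(6/fan_in))`, zero
#' biases; for regression the output bias starts at `out_bias` (typically
#' the training-response mean) so the ReLU output unit begins in its active
#' region.
#'
#' @param config An [mlp_config()].
#' @param seed Optional integer seed.
#' @param out_bias Initial output bias (default 0).
#' @return An `mlp_model` with untrained weights.
#' @export
mlp_init <- function(config, seed = NULL, out_bias = 0) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(config$n_inputs, config$hidden, config$n_outputs)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    lim <- sqrt(6 / fan_in)
    W <- matrix(stats::runif(fan_in * dims[l + 1L], -lim, lim),
                fan_in, dims[l + 1L])
    b <- rep(0, dims[l + 1L])
    if (l == length(layers)) b <- rep(out_bias, dims[l + 1L])
    layers[[l]] <- list(W = W, b = b)
  }
  structure(list(weights = layers, config = config, history = NULL,
                 stopped_epoch = NA_integer_, best_epoch = NA_integer_,
                 window = NULL),
            class = "mlp_model")
}

relu <- function(Z) Z * (Z > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Inverted dropout mask
#'
#' Entries are zero with probability `rate` and `1/(1 - rate)` otherwise,
#' so the mask has unit expectation and inference needs no rescaling.
#'
#' @param n,m Mask dimensions.
#' @param rate Drop probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return An n x m numeric matrix.
#' @export
dropout_mask <- function(n, m, rate, seed = NULL) {
  if (rate < 0 || rate >= 1)
    stop("`rate` must lie in [0, 1): rate 1 drops every unit",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(matrix(1, n, m))
  matrix((stats::runif(n * m) >= rate) / (1 - rate), n, m)
}

#' Forward pass through an MLP
#'
#' Hidden layers use ReLU; the output layer is softmax (classification,
#' rows summing to 1) or ReLU (regression, nonnegative). Dropout masks are
#' drawn (from the current RNG stream) only when `training = TRUE`.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix, `ncol(X) == n_inputs` (rows = samples).
#' @param training Apply dropout and keep the cache for backpropagation?
#' @return List with `output` and (when training) `cache`.
#' @export
mlp_forward <- function(model, X, training = FALSE) {
  X <- as.matrix(X)
  cfg <- model$config
  if (ncol(X) != cfg$n_inputs)
    stop("input has ", ncol(X), " columns, expected ", cfg$n_inputs,
         call. = FALSE)
  L <- length(model$weights)
  A <- X
  Zs <- vector("list", L); As <- vector("list", L + 1L)
  masks <- vector("list", L)
  As[[1L]] <- A
  for (l in seq_len(L)) {
    lay <- model$weights[[l]]
    Z <- sweep(A %*% lay$W, 2L, lay$b, "+")
    Zs[[l]] <- Z
    if (l < L) {
      A <- relu(Z)
      if (training && cfg$dropout > 0) {
        mk <- dropout_mask(nrow(A), ncol(A), cfg$dropout)
        masks[[l]] <- mk
        A <- A * mk
      }
    } else {
      A <- if (cfg$task == "classification") softmax_rows(Z) else relu(Z)
    }
    As[[l + 1L]] <- A
  }
  out <- list(output = A)
  if (training) out$cache <- list(Z = Zs, A = As, masks = masks)
  out
}

#' Categorical cross-entropy loss
#'
#' Mean over samples of `-log p(true class)`; probabilities are clipped at
#' 1e-12 below so a zero probability at the true class yields a large
#' finite loss rather than infinity.
#'
#' @param prob Matrix of predicted class probabilities (rows sum to 1).
#' @param target One-hot matrix, or a factor/character vector of true
#'   classes matching `colnames(prob)`.
#' @return Scalar loss (>= 0).
#' @export
cce_loss <- function(prob, target) {
  if (!is.matrix(target)) target <- one_hot(target, colnames(prob))
  p_true <- rowSums(prob * target)
  mean(-log(pmax(p_true, 1e-12)))
}

mse_loss <- function(pred, y) mean((as.numeric(pred) - as.numeric(y))^2)

#' One-hot encode class labels
#'
#' @param y Factor or character vector.
#' @param levels Class levels defining the column order.
#' @return n x K indicator matrix.
#' @export
one_hot <- function(y, levels = NULL) {
  y <- as.character(y)
  if (is.null(levels)) levels <- sort(unique(y))
  Y <- matrix(0, length(y), length(levels),
              dimnames = list(NULL, levels))
  Y[cbind(seq_along(y), match(y, levels))] <- 1
  Y
}

#' Loss and analytic gradients of an MLP on a batch
#'
#' Backpropagation through the ReLU hidden layers and the softmax/CCE or
#' ReLU/MSE head. With `training = TRUE` dropout masks are drawn and shared
#' between the forward and backward pass.
#'
#' @param model An `mlp_model`.
#' @param X Input batch.
#' @param Y One-hot target matrix (classification) or numeric response
#'   (regression).
#' @param training Apply dropout?
#' @return List with `loss`, `grads` (same structure as `model$weights`)
#'   and `output`.
#' @export
mlp_backprop <- function(model, X, Y, training = TRUE) {
  cfg <- model$config
  fw <- mlp_forward(model, X, training = TRUE)
  if (!training)               # cache needed, but no dropout requested
    fw <- mlp_forward(strip_dropout(model), X, training = TRUE)
  out <- fw$output; cache <- fw$cache
  n <- nrow(as.matrix(X))
  L <- length(model$weights)
  if (cfg$task == "classification") {
    if (!is.matrix(Y)) Y <- one_hot(Y, colnames(out))
    loss <- cce_loss(out, Y)
    dZ <- (out - Y) / n
  } else {
    y <- as.numeric(Y)
    loss <- mse_loss(out, y)
    dZ <- (out - matrix(y, ncol = 1L)) * (2 / n) * (cache$Z[[L]] > 0)
  }
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A_prev <- cache$A[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% t(model$weights[[l]]$W)
      if (!is.null(cache$masks[[l - 1L]])) dA <- dA * cache$masks[[l - 1L]]
      dZ <- dA * (cache$Z[[l - 1L]] > 0)
    }
  }
  list(loss = loss, grads = grads, output = out)
}

strip_dropout <- function(model) {
  model$config$dropout <- 0
  model
}

#' One ADAM update step
#'
#' Standard adaptive-moment update with bias correction
#' (m-hat = m/(1 - beta1^t), v-hat = v/(1 - beta2^t)); with zero gradients
#' and zero state the parameters are left unchanged.
#'
#' @param weights List of layers (`W`, `b`).
#' @param grads Matching gradient structure.
#' @param state ADAM state from [adam_init()] (zero first/second moments).
#' @param t Step counter (1-based).
#' @param lr,beta1,beta2,eps ADAM hyperparameters.
#' @return List with updated `weights` and `state`.
#' @export
adam_step <- function(weights, grads, state, t, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(weights)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[nm]] / (1 - beta1^t)
      vhat <- state$v[[l]][[nm]] / (1 - beta2^t)
      weights[[l]][[nm]] <- weights[[l]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = weights, state = state)
}

#' @rdname adam_step
#' @export
adam_init <- function(weights) {
  zero <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
  list(m = zero, v = zero)
}

#' Train an MLP with ADAM and early stopping
#'
#' Full-batch training. After every epoch the validation loss (dropout off)
#' is evaluated; training stops when it has failed to improve for more than
#' `patience` consecutive epochs (patience 0 therefore stops at the first
#' non-improving epoch) or at `max_epochs`. The weights of the best
#' validation epoch are restored.
#'
#' @param config An [mlp_config()].
#' @param X,y Training inputs and targets (factor/character for
#'   classification, numeric for regression).
#' @param X_val,y_val Validation data (disjoint from training).
#' @param seed Integer seed (weight init and dropout draws).
#' @param class_levels Class level order for classification (default:
#'   sorted unique training labels).
#' @return A trained `mlp_model` with `history` (per-epoch train/val loss),
#'   `stopped_epoch` and `best_epoch`.
#' @export
mlp_train <- function(config, X, y, X_val, y_val, seed = 1L,
                      class_levels = NULL) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  if (nrow(X) == 0L || nrow(X_val) == 0L)
    stop("training and validation sets must be nonempty", call. = FALSE)
  set.seed(seed)
  if (config$task == "classification") {
    if (is.null(class_levels)) class_levels <- sort(unique(as.character(y)))
    Y <- one_hot(y, class_levels)
    Y_val <- one_hot(y_val, class_levels)
    if (ncol(Y) != config$n_outputs)
      stop("n_outputs does not match the number of classes", call. = FALSE)
    out_bias <- 0
  } else {
    Y <- as.numeric(y); Y_val <- as.numeric(y_val)
    out_bias <- mean(Y)
  }
  model <- mlp_init(config, seed = NULL, out_bias = out_bias)
  state <- adam_init(model$weights)
  best_loss <- Inf; best_weights <- model$weights; best_epoch <- 0L
  bad <- 0L
  hist_train <- numeric(0); hist_val <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    bp <- mlp_backprop(model, X, Y, training = TRUE)
    upd <- adam_step(model$weights, bp$grads, state, epoch,
                     lr = config$lr, beta1 = config$beta1,
                     beta2 = config$beta2, eps = config$eps)
    model$weights <- upd$weights
    state <- upd$state
    val_out <- mlp_forward(model, X_val, training = FALSE)$output
    val_loss <- if (config$task == "classification")
      cce_loss(val_out, Y_val) else mse_loss(val_out, Y_val)
    hist_train <- c(hist_train, bp$loss)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_weights <- model$weights
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) break
    }
  }
  model$weights <- best_weights
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_loss = hist_train,
                              val_loss = hist_val)
  model$stopped_epoch <- length(hist_train)
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_loss
  model$class_levels <- if (config$task == "classification") class_levels
  model
}

#' Predict with a trained MLP
#'
#' @param model Trained `mlp_model`.
#' @param X Input matrix.
#' @param type `"response"` (probabilities / concentrations) or `"class"`
#'   (classification only: the argmax class label).
#' @return Matrix of outputs, numeric vector (regression), or character
#'   vector of classes.
#' @export
mlp_predict <- function(model, X, type = c("response", "class")) {
  type <- match.arg(type)
  out <- mlp_forward(model, X, training = FALSE)$output
  if (model$config$task == "classification") {
    colnames(out) <- model$class_levels
    if (type == "class")
      return(model$class_levels[max.col(out, ties.method = "first")])
    out
  } else {
    as.numeric(out)
  }
}

#' Seeded train/validation/test split with largest-remainder rounding
#'
#' Splits are disjoint and exhaustive; sizes follow the fractions with
#' largest-remainder rounding (per stratum when stratified).
#'
#' @param n Number of samples, or a label vector (required when
#'   `stratify = TRUE`).
#' @param fractions Numeric vector of 2 or 3 fractions summing to 1.
#' @param seed Integer seed.
#' @param stratify Stratify on the labels in `n`?
#' @return Named list of index vectors (`train`, `val`, `test` — `val`
#'   omitted for 2-way splits).
#' @export
split_data <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                       stratify = FALSE) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  if (!length(fractions) %in% 2:3)
    stop("2 or 3 fractions expected", call. = FALSE)
  labels <- if (length(n) > 1L) as.character(n) else rep("all", n)
  N <- length(labels)
  if (N < length(fractions)) stop("too few samples to split", call. = FALSE)
  if (!stratify) labels <- rep("all", N)
  set.seed(seed)
  nm <- if (length(fractions) == 3L) c("train", "val", "test")
        else c("train", "test")
  out <- stats::setNames(vector("list", length(fractions)), nm)
  for (s in nm) out[[s]] <- integer(0)
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    m <- length(idx)
    exact <- m * fractions
    sizes <- floor(exact)
    rem <- exact - sizes
    for (extra in seq_len(m - sum(sizes)))
      { j <- which.max(rem); sizes[j] <- sizes[j] + 1L; rem[j] <- -1 }
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (k in seq_along(nm))
      if (sizes[k] > 0L)
        out[[nm[k]]] <- c(out[[nm[k]]], idx[starts[k]:stops[k]])
  }
  empty <- fractions > 0 & vapply(out, length, integer(1)) == 0L
  if (any(empty))
    stop("split '", nm[which(empty)[1L]], "' is empty at n = ", N,
         call. = FALSE)
  out
}

#' Candidate starts of a sliding spectral window
#'
#' @param p Number of spectral points.
#' @param window Window length (<= p).
#' @param step Forward step between candidate starts.
#' @return Integer vector of 1-based start indices
#'   (`floor((p - window)/step) + 1` of them).
#' @export
sliding_windows <- function(p, window, step = 2L) {
  if (window > p) stop("`window` exceeds the number of points",
                       call. = FALSE)
  seq.int(1L, p - window + 1L, by = step)
}

#' Sliding-window spectral variable selection
#'
#' Slides a fixed-length window across the axis in steps of `step` points
#' and scores each candidate region with `evaluator` on the validation
#' split; the window with the lowest validation error wins (ties broken
#' towards the leftmost window). The default evaluators are deliberately
#' cheap: nearest-class-centroid error for classification and a 2-latent-
#' variable PLS1 validation RMSE for regression.
#'
#' @param X_train,y_train Training inputs/targets.
#' @param X_val,y_val Validation inputs/targets.
#' @param window Window length in points (default 62).
#' @param step Step between window starts (default 2).
#' @param task `"classification"` or `"regression"` (selects the default
#'   evaluator).
#' @param evaluator Optional `function(Xtr, ytr, Xva, yva) -> error`.
#' @return List with `start`, `cols` (selected column indices) and
#'   `errors` (per-candidate validation error).
#' @export
sliding_window_selection <- function(X_train, y_train, X_val, y_val,
                                     window = 62L, step = 2L,
                                     task = c("classification",
                                              "regression"),
                                     evaluator = NULL) {
  task <- match.arg(task)
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (is.null(evaluator))
    evaluator <- if (task == "classification") eval_centroid else eval_pls
  starts <- sliding_windows(ncol(X_train), window, step)
  errs <- vapply(starts, function(s) {
    cols <- s:(s + window - 1L)
    evaluator(X_train[, cols, drop = FALSE], y_train,
              X_val[, cols, drop = FALSE], y_val)
  }, numeric(1))
  best <- starts[which.min(errs)]
  list(start = best, cols = best:(best + window - 1L), errors = errs,
       starts = starts)
}

# Nearest-class-centroid misclassifications over the validation samples
# plus leave-one-out over the training samples. Pooling both splits keeps
# the window score stable when the validation split is only a handful of
# samples; the test split is never touched.
eval_centroid <- function(Xtr, ytr, Xva, yva) {
  ytr <- as.character(ytr)
  cls <- unique(ytr)
  M <- do.call(rbind, lapply(cls, function(cl)
    colMeans(Xtr[ytr == cl, , drop = FALSE])))
  n_cl <- vapply(cls, function(cl) sum(ytr == cl), numeric(1))
  pred_va <- cls[apply(Xva, 1L, function(x)
    which.min(colSums((t(M) - x)^2)))]
  err <- sum(pred_va != as.character(yva))
  for (i in seq_len(nrow(Xtr))) {
    j <- match(ytr[i], cls)
    Mi <- M
    if (n_cl[j] > 1L)
      Mi[j, ] <- (M[j, ] * n_cl[j] - Xtr[i, ]) / (n_cl[j] - 1L)
    pred <- cls[which.min(colSums((t(Mi) - Xtr[i, ])^2))]
    err <- err + (pred != ytr[i])
  }
  err / (nrow(Xtr) + nrow(Xva))
}

# Small PLS1 validation RMSE (2 latent variables, capped by rank).
eval_pls <- function(Xtr, ytr, Xva, yva) {
  a <- min(2L, nrow(Xtr) - 1L, ncol(Xtr))
  fit <- pls1_fit(Xtr, as.numeric(ytr), a)
  sqrt(mean((as.numeric(yva) - pls1_predict(fit, Xva))^2))
}

#' Random hyperparameter search over MLP configurations
#'
#' Samples `n_trials` configurations uniformly from the stated ranges
#' (dropout rate, 1 or 2 hidden layers, neurons per layer), trains each
#' with early stopping, and tabulates the results. Classification tables
#' are ranked by test accuracy (descending) then test loss (ascending);
#' regression tables by validation loss (ascending), so model choice is
#' tuned on the validation split.
#'
#' @param X_train,y_train,X_val,y_val,X_test,y_test The three splits.
#' @param n_trials Number of sampled configurations (default 50).
#' @param seed Integer seed; trial i uses `seed + i`.
#' @param task `"classification"` or `"regression"`.
#' @param neurons Range of hidden-layer sizes (default `c(2, 250)`).
#' @param dropout_range Dropout range (default `c(0, 0.9)`; a rate of 1
#'   would drop every unit).
#' @param max_epochs,patience,lr Training-loop settings passed to
#'   [mlp_config()].
#' @return Data frame (one ranked row per trial) with columns `topology`
#'   (e.g. `"60-242-7"`), `hidden_layers`, `dropout`, `epoch`,
#'   `accuracy`/`r` and losses; the winning trained model is attached as
#'   attribute `"best_model"`.
#' @export
mlp_search <- function(X_train, y_train, X_val, y_val, X_test, y_test,
                       n_trials = 50L, seed = 1L,
                       task = c("classification", "regression"),
                       neurons = c(2L, 250L), dropout_range = c(0, 0.9),
                       max_epochs = 600L, patience = 50L, lr = 0.001) {
  task <- match.arg(task)
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  X_test <- as.matrix(X_test)
  n_in <- ncol(X_train)
  n_out <- if (task == "classification")
    length(unique(as.character(c(y_train, y_val, y_test)))) else 1L
  levels <- if (task == "classification")
    sort(unique(as.character(c(y_train, y_val, y_test))))
  rows <- vector("list", n_trials)
  models <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(seed + i)
    n_layers <- sample(1:2, 1L)
    pool <- seq.int(neurons[1], neurons[2])
    hid <- pool[sample.int(length(pool), n_layers, replace = TRUE)]
    drop <- stats::runif(1, dropout_range[1], dropout_range[2])
    cfg <- mlp_config(n_in, n_out, hidden = hid, dropout = drop,
                      task = task, lr = lr, max_epochs = max_epochs,
                      patience = patience)
    fit <- mlp_train(cfg, X_train, y_train, X_val, y_val, seed = seed + i,
                     class_levels = levels)
    topo <- paste(c(n_in, hid, n_out), collapse = "-")
    if (task == "classification") {
      pred <- mlp_predict(fit, X_test, type = "class")
      acc <- 100 * mean(pred == as.character(y_test))
      tloss <- cce_loss(mlp_predict(fit, X_test), y_test)
      rows[[i]] <- data.frame(trial = i, topology = topo,
                              hidden_layers = n_layers, dropout = drop,
                              epoch = fit$stopped_epoch, accuracy = acc,
                              test_loss = tloss,
                              val_loss = fit$best_val_loss,
                              stringsAsFactors = FALSE)
    } else {
      pred <- mlp_predict(fit, X_test)
      rmse <- sqrt(mean((as.numeric(y_test) - pred)^2))
      r <- suppressWarnings(stats::cor(as.numeric(y_test), pred))
      rows[[i]] <- data.frame(trial = i, topology = topo,
                              hidden_layers = n_layers, dropout = drop,
                              epoch = fit$stopped_epoch, r = r,
                              rmse = rmse, val_loss = fit$best_val_loss,
                              stringsAsFactors = FALSE)
    }
    models[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  ord <- if (task == "classification")
    order(-tab$accuracy, tab$test_loss) else order(tab$val_loss)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "best_model") <- models[[tab$trial[1L]]]
  tab
}
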