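toy_class_data <- function(n = 20, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * 2, -2), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  list(X = X, y = rep(c("lo", "hi"), each = n))
}

test_that("forward pass: softmax rows sum to one, zero net is uniform", {
  cfg <- mlp_config(4, 7, hidden = 5, task = "classification")
  m <- mlp_init(cfg, seed = 1)
  X <- matrix(rnorm(12), 3, 4)
  out <- mlp_forward(m, X)$output
  expect_equal(rowSums(out), rep(1, 3), tolerance = 1e-9)
  for (l in seq_along(m$weights)) {
    m$weights[[l]]$W[] <- 0; m$weights[[l]]$b[] <- 0
  }
  expect_equal(mlp_forward(m, X)$output,
               matrix(1 / 7, 3, 7), tolerance = 1e-12)
  # inference is deterministic even with a dropout config
  cfg2 <- mlp_config(4, 7, hidden = 5, dropout = 0.5)
  m2 <- mlp_init(cfg2, seed = 2)
  expect_identical(mlp_forward(m2, X)$output, mlp_forward(m2, X)$output)
  expect_error(mlp_forward(m2, matrix(0, 2, 3)), "expected 4")
})

test_that("cross-entropy matches its closed forms and a per-sample loop", {
  P <- diag(3); colnames(P) <- c("a", "b", "c")
  expect_equal(cce_loss(P, c("a", "b", "c")), 0, tolerance = 1e-9)
  U <- matrix(1 / 7, 5, 7, dimnames = list(NULL, letters[1:7]))
  expect_equal(cce_loss(U, rep("d", 5)), log(7), tolerance = 1e-12)
  set.seed(2)
  Q <- matrix(runif(6 * 4), 6, 4); Q <- Q / rowSums(Q)
  colnames(Q) <- letters[1:4]
  y <- sample(letters[1:4], 6, replace = TRUE)
  loop <- mean(vapply(1:6, function(i) -log(Q[i, y[i]]), numeric(1)))
  expect_equal(cce_loss(Q, y), loop, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  for (task in c("classification", "regression")) {
    n_out <- if (task == "classification") 3L else 1L
    cfg <- mlp_config(5, n_out, hidden = 4, dropout = 0, task = task,
                      max_epochs = 1)
    m <- mlp_init(cfg, seed = 3)
    set.seed(4)
    X <- matrix(rnorm(30), 6, 5)
    Y <- if (task == "classification")
      one_hot(sample(c("a", "b", "c"), 6, replace = TRUE), c("a", "b", "c"))
    else rnorm(6, mean = 2)
    if (task == "regression") {
      # keep the ReLU output active so the loss is differentiable here
      m$weights[[2]]$b[] <- 5
    }
    bp <- mlp_backprop(m, X, Y, training = FALSE)
    loss_at <- function(model) mlp_backprop(model, X, Y,
                                            training = FALSE)$loss
    h <- 1e-6
    for (l in seq_along(m$weights)) for (nm in c("W", "b")) {
      g <- bp$grads[[l]][[nm]]
      for (idx in seq_along(g)) {
        mp <- m; mp$weights[[l]][[nm]][idx] <- mp$weights[[l]][[nm]][idx] + h
        mm <- m; mm$weights[[l]][[nm]][idx] <- mm$weights[[l]][[nm]][idx] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        expect_equal(unname(g[idx]), fd, tolerance = 1e-5)
      }
    }
    # duplicating the batch leaves the mean gradient unchanged
    Y2 <- if (is.matrix(Y)) rbind(Y, Y) else c(Y, Y)
    bp2 <- mlp_backprop(m, rbind(X, X), Y2, training = FALSE)
    expect_equal(bp2$grads[[1]]$W, bp$grads[[1]]$W, tolerance = 1e-12)
  }
})

test_that("gradients vanish at a perfectly fitted minimum", {
  d <- toy_class_data(15, seed = 5)
  cfg <- mlp_config(2, 2, hidden = 8, task = "classification",
                    max_epochs = 3000, patience = 3000, lr = 0.01)
  fit <- mlp_train(cfg, d$X, d$y, d$X, d$y, seed = 6)
  bp <- mlp_backprop(fit, d$X, one_hot(d$y, fit$class_levels),
                     training = FALSE)
  expect_lt(max(abs(unlist(lapply(bp$grads, `[[`, "W")))), 1e-2)
})

test_that("ADAM updates follow the closed-form first step", {
  w <- list(list(W = matrix(c(1, -1), 1), b = 0.5))
  st <- adam_init(w)
  zero_g <- list(list(W = matrix(0, 1, 2), b = 0))
  expect_equal(adam_step(w, zero_g, st, 1)$weights, w)
  g <- list(list(W = matrix(c(0.3, -2), 1), b = 0.1))
  up <- adam_step(w, g, st, 1, lr = 0.001)
  # bias-corrected first step ~ -lr * sign(gradient)
  expect_equal(up$weights[[1]]$W,
               w[[1]]$W - 0.001 * sign(g[[1]]$W), tolerance = 1e-4)
  # same state and gradients give identical trajectories
  up2 <- adam_step(w, g, st, 1, lr = 0.001)
  expect_identical(up, up2)
})

test_that("inverted dropout preserves expectation and seeds reproduce", {
  expect_equal(dropout_mask(3, 4, 0), matrix(1, 3, 4))
  expect_error(dropout_mask(2, 2, 1), "every unit")
  m1 <- dropout_mask(10, 10, 0.4, seed = 7)
  m2 <- dropout_mask(10, 10, 0.4, seed = 7)
  expect_identical(m1, m2)
  big <- dropout_mask(500, 200, 0.4, seed = 8)
  expect_equal(mean(big), 1, tolerance = 0.01)
  expect_true(all(big %in% c(0, 1 / 0.6)))
})

test_that("training separates a separable toy problem and stops properly", {
  d <- toy_class_data(20, seed = 9)
  cfg <- mlp_config(2, 2, hidden = 6, task = "classification",
                    max_epochs = 800, patience = 50, lr = 0.01)
  fit <- mlp_train(cfg, d$X, d$y, d$X, d$y, seed = 10)
  expect_equal(mean(mlp_predict(fit, d$X, type = "class") == d$y), 1)
  expect_equal(nrow(fit$history), fit$stopped_epoch)
  # restored weights achieve the best recorded validation loss
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  out <- mlp_forward(fit, d$X)$output
  colnames(out) <- fit$class_levels
  expect_equal(cce_loss(out, d$y), fit$best_val_loss, tolerance = 1e-9)
  # bit-reproducible under the seed
  fit2 <- mlp_train(cfg, d$X, d$y, d$X, d$y, seed = 10)
  expect_identical(fit2$history, fit$history)
  expect_identical(fit2$weights, fit$weights)
})

test_that("patience zero stops at the first non-improving epoch", {
  d <- toy_class_data(10, seed = 11)
  # validation labels carry no signal, so validation loss soon worsens
  set.seed(99)
  Xval <- matrix(rnorm(20), 10, 2)
  yval <- sample(c("lo", "hi"), 10, replace = TRUE)
  cfg <- mlp_config(2, 2, hidden = 4, task = "classification",
                    max_epochs = 500, patience = 0, lr = 0.05)
  fit <- mlp_train(cfg, d$X, d$y, Xval, yval, seed = 12)
  expect_lt(fit$stopped_epoch, 500L)
  expect_equal(fit$stopped_epoch, fit$best_epoch + 1L)
})

test_that("regression head is nonnegative and learns a linear map", {
  set.seed(13)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- pmax(2 + X %*% c(1, -1, 0.5, 0), 0)
  cfg <- mlp_config(4, 1, hidden = 16, task = "regression",
                    max_epochs = 2000, patience = 200, lr = 0.01)
  fit <- mlp_train(cfg, X[1:40, ], y[1:40], X[41:50, ], y[41:50],
                   seed = 14)
  pred <- mlp_predict(fit, X[51:60, ])
  expect_true(all(pred >= 0))
  expect_gt(stats::cor(pred, y[51:60]), 0.95)
})

test_that("splits are exhaustive, disjoint and largest-remainder sized", {
  sp <- split_data(100, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  sp2 <- split_data(10, c(0.6, 0.2, 0.2), seed = 2)
  expect_equal(lengths(sp2), c(train = 6L, val = 2L, test = 2L))
  for (seed in 1:5) {
    lab <- sample(letters[1:3], 37, replace = TRUE)
    sp3 <- split_data(lab, c(0.6, 0.2, 0.2), seed = seed, stratify = TRUE)
    all_idx <- sort(unname(unlist(sp3)))
    expect_equal(all_idx, 1:37)
    expect_equal(anyDuplicated(unlist(sp3)), 0L)
  }
  expect_error(split_data(100, c(0.5, 0.4)), "sum to 1")
  expect_error(split_data(3, c(0.9, 0.05, 0.05), seed = 1), "empty")
})

test_that("sliding windows enumerate starts and pick the informative region", {
  expect_length(sliding_windows(512, 62, 2), 226L)
  expect_equal(sliding_windows(62, 62, 2), 1L)
  expect_error(sliding_windows(50, 62), "exceeds")
  # plant the class signal in columns 41-50 of a 120-column matrix
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(2 * n * 120), 2 * n, 120)
  lab <- rep(c("a", "b"), each = n)
  X[lab == "b", 41:50] <- X[lab == "b", 41:50] + 3
  sel <- sliding_window_selection(X[seq(1, 2 * n, 2), ],
                                  lab[seq(1, 2 * n, 2)],
                                  X[seq(2, 2 * n, 2), ],
                                  lab[seq(2, 2 * n, 2)],
                                  window = 20, step = 2,
                                  task = "classification")
  expect_true(any(41:50 %in% sel$cols))
  expect_length(sel$errors, length(sel$starts))
})

test_that("hyperparameter search tabulates, ranks and names topologies", {
  d <- toy_class_data(12, seed = 16)
  # 60 informative-ish inputs so the topology string mirrors a 60-in net
  set.seed(17)
  X60 <- cbind(d$X, matrix(rnorm(24 * 58, sd = 0.5), 24, 58))
  idx <- split_data(d$y, c(0.6, 0.2, 0.2), seed = 3, stratify = TRUE)
  tab <- mlp_search(X60[idx$train, ], d$y[idx$train],
                    X60[idx$val, ], d$y[idx$val],
                    X60[idx$test, ], d$y[idx$test],
                    n_trials = 3, seed = 18, neurons = c(242, 242),
                    max_epochs = 60, patience = 10)
  expect_equal(nrow(tab), 3L)
  expect_true(all(grepl("^60-242(-242)?-2$", tab$topology)))
  expect_setequal(tab$trial, 1:3)             # ranking is a permutation
  expect_true(all(diff(tab$accuracy) <= 0))   # ranked by accuracy desc
  one <- mlp_search(X60[idx$train, ], d$y[idx$train],
                    X60[idx$val, ], d$y[idx$val],
                    X60[idx$test, ], d$y[idx$test],
                    n_trials = 1, seed = 19, max_epochs = 30,
                    patience = 5)
  expect_equal(nrow(one), 1L)
  expect_s3_class(attr(one, "best_model"), "mlp_model")
})
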