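# NIPALS PLS1 core on centered data: returns weights W, loadings P, score
# regression coefficients q and scores T for up to `a` latent variables.
pls1_core <- function(Xc, yc, a) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Q <- numeric(a)
  T <- matrix(0, n, a)
  X <- Xc; y <- yc
  for (h in seq_len(a)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { a <- h - 1L; break }    # X exhausted
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-28) { a <- h - 1L; break }
    pv <- crossprod(X, t) / tt
    q <- sum(y * t) / tt
    X <- X - t %*% t(pv)
    y <- y - q * t
    W[, h] <- w; P[, h] <- pv; Q[h] <- q; T[, h] <- t
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = Q[seq_len(a)], T = T[, seq_len(a), drop = FALSE], a = a)
}

pls1_coef <- function(core, a) {
  W <- core$W[, seq_len(a), drop = FALSE]
  P <- core$P[, seq_len(a), drop = FALSE]
  q <- core$q[seq_len(a)]
  W %*% solve(crossprod(P, W), q)
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Extracts `a` orthogonal latent variables maximizing covariance with the
#' single response, following the NIPALS recursion (w = X'y/|X'y|, t = Xw,
#' deflation of X and y). X columns and y are centered internally; the
#' regression vector b = W(P'W)^-1 q maps centered spectra to centered
#' response.
#'
#' @param X Predictor matrix n x p (preprocessed spectra).
#' @param y Response vector, mg/100 g; must have nonzero variance.
#' @param a Number of latent variables, `1 <= a <= min(n - 1, p)`.
#' @return A `pls_model`: `b`, `W`, `P`, `q`, scores, centering state and
#'   training fitted values.
#' @export
pls1_fit <- function(X, y, a) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  a <- as.integer(a)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (a < 1L || a > min(n - 1L, p))
    stop("`a` must lie in [1, min(n - 1, p)]", call. = FALSE)
  if (stats::var(y) <= 0) stop("`y` has zero variance", call. = FALSE)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  core <- pls1_core(sweep(X, 2L, x_means, "-"), y - y_mean, a)
  if (core$a < 1L) stop("X carries no covariance with y", call. = FALSE)
  b <- pls1_coef(core, core$a)
  fitted <- as.numeric(sweep(X, 2L, x_means, "-") %*% b) + y_mean
  structure(list(b = as.numeric(b), W = core$W, P = core$P, q = core$q,
                 scores = core$T, a = core$a, x_means = x_means,
                 y_mean = y_mean, fitted = fitted),
            class = "pls_model")
}

#' Predict from a fitted PLS1 model
#'
#' @param model A `pls_model`.
#' @param X_new Matrix of new spectra, preprocessed identically to the
#'   training data.
#' @return Predicted response vector (`X_centered %*% b + y_mean`).
#' @export
pls1_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_means))
    stop("new data has the wrong number of variables", call. = FALSE)
  as.numeric(sweep(X_new, 2L, model$x_means, "-") %*% model$b) +
    model$y_mean
}

#' Leave-one-out cross-validation of PLS1
#'
#' Each sample is predicted by a model fitted on the remaining n - 1 samples
#' (centering re-estimated inside each fold, so no information leaks from
#' the held-out sample). `SECV(a) = sqrt(sum(e^2)/n)`; the returned number
#' of latent variables is the global SECV minimum, ties broken towards the
#' smaller a.
#'
#' @param X Predictor matrix (preprocessed).
#' @param y Response vector.
#' @param max_a Largest number of latent variables to evaluate.
#' @return A `pls_cv` list: data.frame `per_a` (a, secv, r_cv), `chosen_a`,
#'   and the n x max_a matrices of LOO `predictions` and `residuals`.
#' @export
pls_loo_cv <- function(X, y, max_a = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("LOO-CV needs at least 3 samples", call. = FALSE)
  max_a <- as.integer(max_a)
  if (max_a < 1L || max_a > min(n - 2L, ncol(X)))
    stop("`max_a` must lie in [1, min(n - 2, p)]", call. = FALSE)
  pred <- matrix(NA_real_, n, max_a)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    core <- pls1_core(sweep(Xi, 2L, xm, "-"), yi - ym, max_a)
    xc <- X[i, ] - xm
    for (a in seq_len(core$a))
      pred[i, a] <- sum(xc * pls1_coef(core, a)) + ym
    if (core$a < max_a)                     # rank-exhausted folds
      pred[i, (core$a + 1L):max_a] <- pred[i, core$a]
  }
  res <- pred - y
  secv <- sqrt(colMeans(res^2))
  r_cv <- apply(pred, 2L, function(p) suppressWarnings(stats::cor(y, p)))
  chosen <- which.min(secv)                 # first minimum = smaller a
  structure(list(per_a = data.frame(a = seq_len(max_a), secv = secv,
                                    r_cv = r_cv),
                 chosen_a = chosen, predictions = pred, residuals = res),
            class = "pls_cv")
}

#' Correlation and standard error of a prediction set
#'
#' @param y Reference values.
#' @param y_hat Predicted values.
#' @return Named vector `c(r = Pearson correlation, se = sqrt(mean squared
#'   residual))`. The same formula yields SECV on cross-validated and SEP on
#'   external-validation predictions.
#' @export
pls_metrics <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat) || length(y) < 2L)
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  if (stats::var(y) <= 0 || stats::var(y_hat) <= 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  c(r = stats::cor(y, y_hat), se = sqrt(mean((y - y_hat)^2)))
}

#' Flag residual outliers of a PLS1 calibration
#'
#' Standardizes the training residuals by their own standard deviation and
#' flags samples beyond `threshold_sd` (default 3).
#'
#' @param model Fitted `pls_model`.
#' @param X,y Training data.
#' @param threshold_sd Flagging threshold in residual standard deviations.
#' @return Data frame with `residual`, `standardized`, `flag`.
#' @export
pls_residual_outliers <- function(model, X, y, threshold_sd = 3) {
  e <- as.numeric(y) - pls1_predict(model, X)
  s <- stats::sd(e)
  z <- if (is.finite(s) && s > 0) e / s else rep(0, length(e))
  data.frame(residual = e, standardized = z, flag = abs(z) > threshold_sd)
}
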