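#' Fit one SIMCA class model (per-class PCA)
#'
#' Centers the class block and retains the top `k` right singular vectors as
#' loadings. The pooled residual standard deviation s0 of the training class
#' uses the degrees of freedom (n_c - k - 1)(p - k), so that the residual
#' F-statistic of a new sample is calibrated against a slightly inflated
#' within-class scale (the convention keeps honest admission rates for test
#' samples).
#'
#' @param X Numeric matrix of the class's training spectra (rows), already
#'   preprocessed.
#' @param k Number of principal components to retain (0 <= k <= n_c - 1).
#'   `NULL` selects k by leave-one-out cross-validated residual error, capped
#'   at `min(n_c - 4, 10)` so the residual scale keeps usable degrees of
#'   freedom.
#' @param label Class label to store.
#' @param cv Also estimate the class's cross-validated residual scale
#'   `s0_cv` (each training spectrum scored against a model refit without
#'   it)? Needed for calibrated class admission; default `TRUE`.
#' @return A `simca_class_model`: mean, orthonormal loadings (p x k), k,
#'   `s0`, `s0_cv` with the per-sample held-out residual variances `s2_cv`,
#'   per-PC score variances, n and the training block.
#' @export
simca_fit_class <- function(X, k = NULL, label = "class", cv = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 training samples per class",
                   call. = FALSE)
  if (is.null(k)) k <- simca_choose_k(X)
  k <- as.integer(k)
  if (k < 0L || k > min(n - 1L, p))
    stop("`k` must lie in [0, min(n_c - 1, p)]", call. = FALSE)
  model <- simca_pca(X, k, label)
  if (cv) {
    s2_cv <- vapply(seq_len(n), function(i) {
      ki <- min(k, n - 2L)
      mi <- simca_pca(X[-i, , drop = FALSE], ki, label)
      simca_sample_distance(mi, X[i, ])$s^2
    }, numeric(1))
    model$s2_cv <- s2_cv
    model$s0_cv <- sqrt(mean(s2_cv))
  }
  model
}

# Core per-class PCA fit (no cross-validation layer).
simca_pca <- function(X, k, label) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  if (k > 0L) {
    sv <- svd(Xc, nu = 0L, nv = k)
    if (sv$d[1L] < 1e-12)
      stop("degenerate (constant) class block", call. = FALSE)
    P <- sv$v
    T <- Xc %*% P
    score_var <- sv$d[seq_len(k)]^2 / (n - 1L)
    R <- Xc - T %*% t(P)
  } else {
    P <- matrix(0, p, 0L)
    T <- matrix(0, n, 0L)
    score_var <- numeric(0)
    R <- Xc
  }
  dof <- (n - k - 1L) * (p - k)
  s0 <- if (dof > 0L) sqrt(sum(R^2) / dof) else 0
  structure(
    list(label = label, mean = mu, loadings = P, k = k, s0 = s0,
         score_var = score_var, n = n, X = X, residuals = R, scores = T),
    class = "simca_class_model")
}

#' Select the number of PCs for a SIMCA class model by LOO residual error
#'
#' For each candidate k the leave-one-out squared reconstruction residual of
#' the held-out spectrum is accumulated; the k minimizing the total (PRESS)
#' is returned (ties broken towards smaller k).
#'
#' @param X Class training matrix.
#' @param k_max Upper cap, default `min(n_c - 4, 10, p - 1)`.
#' @return Integer k.
#' @export
simca_choose_k <- function(X, k_max = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(k_max)) k_max <- min(n - 4L, 10L, p - 1L)
  k_max <- max(0L, as.integer(k_max))
  press <- numeric(k_max + 1L)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    mu <- colMeans(Xi)
    xc <- X[i, ] - mu
    kk <- min(k_max, nrow(Xi) - 1L, p)
    sv <- if (kk > 0L) svd(sweep(Xi, 2L, mu, "-"), nu = 0L, nv = kk)
    press[1L] <- press[1L] + sum(xc^2)
    if (kk > 0L) {
      proj <- as.numeric(crossprod(sv$v, xc))   # scores of held-out row
      # residual with k comps = total - explained by first k
      cum <- cumsum(proj^2)
      press[1L + seq_len(kk)] <- press[1L + seq_len(kk)] +
        (sum(xc^2) - cum)
      if (kk < k_max)
        press[(kk + 2L):(k_max + 1L)] <- press[(kk + 2L):(k_max + 1L)] +
          (sum(xc^2) - cum[kk])
    }
  }
  which.min(press) - 1L
}

#' Residual distance of a spectrum to a SIMCA class model
#'
#' @param model A `simca_class_model`.
#' @param x Preprocessed spectrum of length p.
#' @return List with `s` (residual standard deviation over the p - k
#'   residual dimensions) and `F` (the ratio s^2/s0^2).
#' @export
simca_sample_distance <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != length(model$mean))
    stop("spectrum length does not match the model", call. = FALSE)
  xc <- x - model$mean
  r <- if (model$k > 0L) xc - model$loadings %*% crossprod(model$loadings, xc)
       else xc
  s2 <- sum(r^2) / (length(x) - model$k)
  Fr <- if (model$s0 > 0) s2 / model$s0^2 else if (s2 <= 1e-24) 0 else Inf
  list(s = sqrt(s2), F = Fr)
}

simca_f_crit <- function(model, p, alpha) {
  df1 <- p - model$k
  df2 <- max(model$n - model$k - 1L, 1L) * (p - model$k)
  stats::qf(1 - alpha, df1, df2)
}

#' Fit a full SIMCA model over all classes
#'
#' Fits an independent PCA model per class, the symmetric interclass
#' distance (ICD) matrix, and the aggregated discriminating power profile
#' (root mean square of the per-pair profiles).
#'
#' Class admission thresholds are calibrated from the cross-validated
#' within-class residuals: each class's held-out residual variances are
#' standardized by the class CV scale, pooled over classes, and the
#' pooled `1 - alpha` quantile sets the class's admission cutoff
#' (`admission = "cv"`, the default). With `admission = "f"` the
#' parametric F-critical value on `(p - k, (n_c - k - 1)(p - k))` degrees
#' of freedom is used instead; note that derivative-filtered spectra have
#' strongly correlated residuals, for which the parametric test is
#' anticonservative (vignette).
#'
#' @param X Preprocessed training matrix (or a `spectra_set`).
#' @param labels Class label per row (ignored when `X` is a labelled
#'   `spectra_set`).
#' @param alpha Admission test level (default 0.01, matching the 0.99
#'   level of the score-space outlier rule; see the methods vignette for
#'   the choice).
#' @param k Retained PCs: `NULL` for per-class LOO selection, a single
#'   integer, or a named vector per class.
#' @param admission `"cv"` (calibrated, default) or `"f"` (parametric).
#' @return A `simca_model` with per-class models, `icd`,
#'   `discriminating_power`, admission cutoffs `crit_s2`, `alpha` and the
#'   axis (when known).
#' @export
simca_fit <- function(X, labels = NULL, alpha = 0.01, k = NULL,
                      admission = c("cv", "f")) {
  admission <- match.arg(admission)
  axis <- NULL
  if (inherits(X, "spectra_set")) {
    if (is.null(labels)) labels <- X$labels
    axis <- X$axis
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(labels) || length(labels) != nrow(X))
    stop("`labels` must give one class per row", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)
  models <- lapply(classes, function(cl) {
    kk <- if (is.null(k)) NULL
          else if (length(k) > 1L) k[[cl]]
          else k
    simca_fit_class(X[labels == cl, , drop = FALSE], k = kk, label = cl)
  })
  names(models) <- classes
  m <- structure(list(models = models, alpha = alpha, axis = axis,
                      classes = classes, admission = admission),
                 class = "simca_model")
  s0cv2 <- vapply(models, function(cm) cm$s0_cv^2, numeric(1))
  if (admission == "cv") {
    ok <- s0cv2 > 1e-24
    z <- unlist(lapply(models[ok], function(cm) cm$s2_cv / cm$s0_cv^2))
    qz <- if (length(z)) stats::quantile(z, 1 - alpha, names = FALSE)
          else 1
    m$crit_s2 <- ifelse(ok, s0cv2 * qz, 1e-24)
  } else {
    p <- ncol(X)
    m$crit_s2 <- vapply(models, function(cm)
      cm$s0^2 * simca_f_crit(cm, p, alpha), numeric(1))
  }
  names(m$crit_s2) <- classes
  m$s0_cv2 <- s0cv2
  m$icd <- simca_icd_matrix(m)
  m$discriminating_power <- simca_dp_aggregate(m)
  m
}

# Residual matrix of block Xx under class model my.
simca_cross_residuals <- function(my, Xx) {
  Xc <- sweep(Xx, 2L, my$mean, "-")
  if (my$k > 0L) Xc - (Xc %*% my$loadings) %*% t(my$loadings) else Xc
}

# Pooled residual variance of block Xx fitted to model my.
simca_pooled_s2 <- function(my, Xx) {
  R <- simca_cross_residuals(my, Xx)
  sum(R^2) / (nrow(Xx) * (ncol(Xx) - my$k))
}

#' Interclass distance between two SIMCA class models
#'
#' `D(a, b) = sqrt((s_ab^2 + s_ba^2) / (s_aa^2 + s_bb^2)) - 1`, where
#' `s_xy` is the pooled residual standard deviation of class x's training
#' samples fitted to class y's model. The `- 1` normalization makes the
#' self-distance exactly zero; a value above 3 conventionally indicates
#' well-separated classes.
#'
#' @param ma,mb Fitted `simca_class_model`s sharing the variable axis.
#' @return Nonnegative scalar (0 for identical models on identical data).
#' @export
simca_icd <- function(ma, mb) {
  if (length(ma$mean) != length(mb$mean))
    stop("class models were fitted on different axes", call. = FALSE)
  s_aa <- simca_pooled_s2(ma, ma$X)
  s_bb <- simca_pooled_s2(mb, mb$X)
  s_ab <- simca_pooled_s2(mb, ma$X)   # class a samples on model b
  s_ba <- simca_pooled_s2(ma, mb$X)
  max(sqrt((s_ab + s_ba) / (s_aa + s_bb)) - 1, 0)
}

simca_icd_matrix <- function(model) {
  cl <- model$classes
  D <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  if (length(cl) >= 2L)
    for (i in seq_along(cl)[-length(cl)])
      for (j in (i + 1L):length(cl)) {
        d <- simca_icd(model$models[[i]], model$models[[j]])
        D[i, j] <- d; D[j, i] <- d
      }
  D
}

#' Per-variable discriminating power between two classes
#'
#' For each variable j,
#' `DP_j = sqrt((s_ab,j^2 + s_ba,j^2) / (s_aa,j^2 + s_bb,j^2))` built from
#' the residual variances at variable j alone. Peaks mark the wavenumbers
#' that drive the separation (for carotenoid profiles, the nu1 C=C stretch
#' region near 1520 cm^-1). The denominator is floored at a small epsilon
#' relative to its own scale to guard zero within-class residuals.
#'
#' @param ma,mb Fitted `simca_class_model`s.
#' @return Numeric vector of length p (~1 everywhere for identical classes).
#' @export
simca_discriminating_power <- function(ma, mb) {
  if (length(ma$mean) != length(mb$mean))
    stop("class models were fitted on different axes", call. = FALSE)
  v <- function(R) colMeans(R^2)
  s_aa <- v(simca_cross_residuals(ma, ma$X))
  s_bb <- v(simca_cross_residuals(mb, mb$X))
  s_ab <- v(simca_cross_residuals(mb, ma$X))
  s_ba <- v(simca_cross_residuals(ma, mb$X))
  den <- s_aa + s_bb
  floor_eps <- 1e-12 * max(mean(den), .Machine$double.xmin)
  sqrt((s_ab + s_ba) / pmax(den, floor_eps))
}

simca_dp_aggregate <- function(model) {
  cl <- model$classes
  if (length(cl) < 2L) return(NULL)
  acc <- NULL; np <- 0L
  for (i in seq_along(cl)[-length(cl)])
    for (j in (i + 1L):length(cl)) {
      dp <- simca_discriminating_power(model$models[[i]], model$models[[j]])
      acc <- if (is.null(acc)) dp^2 else acc + dp^2
      np <- np + 1L
    }
  sqrt(acc / np)
}

#' Classify spectra with a fitted SIMCA model
#'
#' Each spectrum's residual variance against every class model is compared
#' with the class admission cutoff (see [simca_fit()]); a sample may be
#' admitted to one class, several, or none. The reported prediction is the
#' admitted class with the smallest residual F-ratio (`NA` when admitted
#' nowhere); `nearest` is the smallest F-ratio class regardless of
#' admission. F-ratios standardize the residual variance by the class's
#' cross-validated residual scale, so classes with different intrinsic
#' noise levels are compared on an equal footing.
#'
#' @param model A fitted `simca_model`.
#' @param X Preprocessed matrix or `spectra_set` (same plan as training).
#' @return Data frame with columns `nearest`, `predicted` and one logical
#'   `admitted_<class>` column per class; the F-ratio matrix is attached as
#'   attribute `"F"`.
#' @export
simca_classify <- function(model, X) {
  if (inherits(X, "spectra_set")) X <- X$X
  X <- as.matrix(X)
  cl <- model$classes
  S2 <- matrix(NA_real_, nrow(X), length(cl), dimnames = list(NULL, cl))
  for (j in seq_along(cl))
    for (i in seq_len(nrow(X)))
      S2[i, j] <- simca_sample_distance(model$models[[j]], X[i, ])$s^2
  scale2 <- vapply(seq_along(cl), function(j) {
    cm <- model$models[[j]]
    s <- if (!is.null(cm$s0_cv) && cm$s0_cv > 0) cm$s0_cv^2 else cm$s0^2
    if (s <= 0) 1e-24 else s
  }, numeric(1))
  Fm <- sweep(S2, 2L, scale2, "/")
  admitted <- sweep(S2, 2L, model$crit_s2, "<=")
  nearest <- cl[max.col(-Fm, ties.method = "first")]
  predicted <- vapply(seq_len(nrow(X)), function(i) {
    adm <- which(admitted[i, ])
    if (!length(adm)) return(NA_character_)
    cl[adm[which.min(Fm[i, adm])]]
  }, character(1))
  out <- data.frame(nearest = nearest, predicted = predicted,
                    stringsAsFactors = FALSE)
  for (j in seq_along(cl)) out[[paste0("admitted_", cl[j])]] <- admitted[, j]
  attr(out, "F") <- Fm
  out
}

#' Classification accuracy under the nearest-admitted-class rule
#'
#' A prediction counts as correct when the true class is the admitted class
#' with the smallest F-ratio; samples admitted nowhere count as errors.
#'
#' @param model Fitted `simca_model`.
#' @param X Preprocessed test data (matrix or `spectra_set`).
#' @param labels True classes (taken from `X` when it is a labelled set).
#' @return List with `accuracy` (percent) and `confusion` (true x predicted
#'   table, "none" column for unadmitted samples).
#' @export
simca_accuracy <- function(model, X, labels = NULL) {
  if (inherits(X, "spectra_set") && is.null(labels)) labels <- X$labels
  res <- simca_classify(model, X)
  pred <- ifelse(is.na(res$predicted), "none", res$predicted)
  acc <- 100 * mean(pred == labels)
  conf <- table(true = labels, predicted = pred)
  list(accuracy = acc, confusion = conf)
}

#' Score-space Mahalanobis and residual outlier diagnostics
#'
#' Mahalanobis distance is computed in the model's score space using the
#' per-PC score variances; a training sample is flagged when its distance
#' exceeds `sqrt(qchisq(0.99, k))` or its residual F-ratio exceeds the
#' F-critical value. With k = 0 only the residual criterion applies.
#'
#' @param model A `simca_class_model`.
#' @param X Optional matrix to diagnose (default: the training block).
#' @param alpha Residual F-test level (default 0.05).
#' @return Data frame with `score_distance`, `residual_sd`, `f_ratio`,
#'   `flag`.
#' @export
simca_outliers <- function(model, X = NULL, alpha = 0.05) {
  if (is.null(X)) X <- model$X
  X <- as.matrix(X)
  p <- ncol(X)
  crit_f <- simca_f_crit(model, p, alpha)
  crit_d <- if (model$k > 0L) sqrt(stats::qchisq(0.99, model$k)) else Inf
  out <- data.frame(score_distance = numeric(nrow(X)),
                    residual_sd = numeric(nrow(X)),
                    f_ratio = numeric(nrow(X)),
                    flag = logical(nrow(X)))
  for (i in seq_len(nrow(X))) {
    xc <- X[i, ] - model$mean
    d <- 0
    if (model$k > 0L) {
      t_i <- as.numeric(crossprod(model$loadings, xc))
      d <- sqrt(sum(t_i^2 / model$score_var))
    }
    sd_i <- simca_sample_distance(model, X[i, ])
    out$score_distance[i] <- d
    out$residual_sd[i] <- sd_i$s
    out$f_ratio[i] <- sd_i$F
    out$flag[i] <- (model$k > 0L && d > crit_d) || sd_i$F > crit_f
  }
  out
}

#' First-three-PC projections per class
#'
#' Projects spectra onto the first three loadings of every class model (the
#' basis of the familiar 3D class-projection plot). Classes with fewer than
#' 3 retained PCs are zero-padded with a warning.
#'
#' @param model A fitted `simca_model`.
#' @param X Matrix or `spectra_set` to project.
#' @return Named list (per class) of n x 3 score matrices.
#' @export
simca_scores_3d <- function(model, X) {
  if (inherits(X, "spectra_set")) X <- X$X
  X <- as.matrix(X)
  lapply(model$models, function(cm) {
    if (cm$k < 3L)
      warning("class ", cm$label, " has k < 3; padding scores with zeros",
              call. = FALSE)
    Xc <- sweep(X, 2L, cm$mean, "-")
    S <- matrix(0, nrow(X), 3L)
    kk <- min(cm$k, 3L)
    if (kk > 0L)
      S[, seq_len(kk)] <- Xc %*% cm$loadings[, seq_len(kk), drop = FALSE]
    colnames(S) <- paste0("PC", 1:3)
    S
  })
}
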