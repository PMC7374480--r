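test_that("per-class PCA matches an eigen-decomposition oracle", {
  set.seed(1)
  X <- matrix(rnorm(30 * 12), 30, 12)
  m <- simca_fit_class(X, k = 3, cv = FALSE)
  ev <- eigen(stats::cov(X))$vectors[, 1:3]
  for (j in 1:3) {
    # loadings defined up to sign
    agree <- min(sum((m$loadings[, j] - ev[, j])^2),
                 sum((m$loadings[, j] + ev[, j])^2))
    expect_lt(agree, 1e-16)
  }
  expect_equal(crossprod(m$loadings), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("exact low-rank classes give zero residual scale", {
  set.seed(2)
  basis <- matrix(rnorm(10 * 2), 10, 2)
  scores <- matrix(rnorm(8 * 2), 8, 2)
  X <- scores %*% t(basis) + matrix(5, 8, 10)
  m <- simca_fit_class(X, k = 2, cv = FALSE)
  expect_equal(m$s0, 0, tolerance = 1e-10)
  # k = 0 reduces to the class mean; residuals are the centered data
  m0 <- simca_fit_class(X, k = 0, cv = FALSE)
  expect_equal(m0$residuals, sweep(X, 2, colMeans(X)), ignore_attr = TRUE)
  expect_error(simca_fit_class(X, k = 9), "must lie in")
})

test_that("sample distance obeys its closed forms", {
  set.seed(3)
  X <- matrix(rnorm(12 * 8, sd = 2), 12, 8)
  m <- simca_fit_class(X, k = 2, cv = FALSE)
  p <- 8
  expect_equal(simca_sample_distance(m, m$mean)$s, 0)
  in_span <- m$mean + 3 * m$loadings[, 1]
  expect_equal(simca_sample_distance(m, in_span)$s, 0, tolerance = 1e-10)
  # unit vector orthogonal to the loadings: s^2 = 1/(p - k)
  v <- rnorm(p)
  v <- v - m$loadings %*% crossprod(m$loadings, v)
  v <- v / sqrt(sum(v^2))
  expect_equal(simca_sample_distance(m, m$mean + v)$s^2, 1 / (p - 2),
               tolerance = 1e-10)
  expect_error(simca_sample_distance(m, 1:3), "length")
})

test_that("classification matches a brute-force oracle and ignores class order", {
  cls <- two_gaussian_classes(n = 25, p = 15, shift = 8, seed = 4)
  X <- rbind(cls$a, cls$b)
  lab <- rep(c("a", "b"), each = 25)
  m <- simca_fit(X, lab, k = 2)
  set.seed(5)
  Xnew <- rbind(cls$a[1:5, ] + rnorm(5 * 15, sd = 0.1),
                cls$b[1:5, ] + rnorm(5 * 15, sd = 0.1))
  res <- simca_classify(m, Xnew)
  # brute-force re-implementation of the residual distance per class
  for (cl in c("a", "b")) {
    cm <- m$models[[cl]]
    for (i in seq_len(nrow(Xnew))) {
      xc <- Xnew[i, ] - cm$mean
      r <- xc - cm$loadings %*% crossprod(cm$loadings, xc)
      s2 <- sum(r^2) / (15 - cm$k)
      expect_equal(unname(attr(res, "F")[i, cl]), s2 / cm$s0_cv^2,
                   tolerance = 1e-10)
    }
  }
  # order of classes must not matter
  m2 <- simca_fit(X[c(26:50, 1:25), ], lab[c(26:50, 1:25)], k = 2)
  res2 <- simca_classify(m2, Xnew)
  expect_equal(res2$nearest, res$nearest)
  expect_equal(res2$predicted, res$predicted)
  # training samples with zero residual are admitted to their class
  expect_true(all(simca_classify(m, cls$a[1:3, ])$predicted == "a"))
  # an absurdly distant spectrum is admitted nowhere
  far <- matrix(1e4, 1, 15)
  expect_true(is.na(simca_classify(m, far)$predicted))
})

test_that("interclass distances are symmetric, zero on the diagonal and scale with separation", {
  cls <- two_gaussian_classes(n = 50, p = 20, shift = 0, seed = 6)
  ma <- simca_fit_class(cls$a, k = 2, label = "a")
  mb <- simca_fit_class(cls$b, k = 2, label = "b")
  expect_equal(simca_icd(ma, ma), 0)
  # same generating distribution: distance near zero
  expect_lt(simca_icd(ma, mb), 0.5)
  # monotone in the planted mean shift
  d <- vapply(c(2, 5, 10), function(sh) {
    cc <- two_gaussian_classes(n = 50, p = 20, shift = sh, seed = 7)
    simca_icd(simca_fit_class(cc$a, k = 2), simca_fit_class(cc$b, k = 2))
  }, numeric(1))
  expect_true(all(diff(d) > 0))
  # full-model ICD matrix invariants
  X <- rbind(cls$a, cls$b); lab <- rep(c("a", "b"), each = 50)
  m <- simca_fit(X, lab, k = 2)
  expect_equal(m$icd, t(m$icd))
  expect_equal(diag(m$icd), c(a = 0, b = 0))
  expect_true(all(m$icd >= 0))
})

test_that("discriminating power finds the planted variable and is ~1 for identical classes", {
  cls <- two_gaussian_classes(n = 40, p = 25, shift = 12, shift_var = 17,
                              seed = 8)
  ma <- simca_fit_class(cls$a, k = 2)
  mb <- simca_fit_class(cls$b, k = 2)
  dp <- simca_discriminating_power(ma, mb)
  expect_equal(which.max(dp), 17L)
  same <- two_gaussian_classes(n = 60, p = 25, shift = 0, seed = 9)
  dp0 <- simca_discriminating_power(simca_fit_class(same$a, k = 2),
                                    simca_fit_class(same$b, k = 2))
  expect_true(all(abs(dp0 - 1) < 0.6))
})

test_that("the nu1 band region separates lycopene from beta-carotene profiles", {
  ds <- generate_dataset(c(lycopene_high = 25, bcarotene = 25),
                         replicates = 3, seed = 11)
  avg <- average_replicates(ds$spectra, ds$meta)
  plan <- preprocess_plan(step_snv(), step_region(1370, 1700),
                          step_mean_center())
  f <- pp_fit(plan, avg)
  m <- simca_fit(f$set)
  dp <- simca_discriminating_power(m$models[["lycopene_high"]],
                                   m$models[["bcarotene"]])
  peak <- f$set$axis[which.max(dp)]
  nearest_1523 <- default_axis()[which.min(abs(default_axis() - 1523))]
  expect_lte(abs(peak - nearest_1523), 2 * 2300 / 511)
})

test_that("outlier diagnostics flag planted outliers and are deterministic", {
  set.seed(10)
  X <- matrix(rnorm(30 * 12), 30, 12)
  m <- simca_fit_class(X, k = 3)
  d <- simca_outliers(m, rbind(m$mean, X[1, ]))
  expect_equal(d$score_distance[1], 0)
  expect_equal(d$residual_sd[1], 0)
  # a 10-sd outlier in residual space is flagged
  out <- m$mean + 10 * apply(X, 2, stats::sd)
  expect_true(simca_outliers(m, matrix(out, 1))$flag)
  # duplicated rows get identical flags
  dd <- simca_outliers(m, X[c(1, 1, 2, 2), ])
  expect_equal(dd$flag[1], dd$flag[2])
  expect_equal(dd$f_ratio[3], dd$f_ratio[4])
})

test_that("3D scores are the centered projections with diagonal covariance", {
  set.seed(12)
  X <- matrix(rnorm(25 * 10), 25, 10)
  m <- simca_fit(X, rep("a", 25), k = 4)
  sc <- simca_scores_3d(m, X)$a
  cm <- m$models$a
  expect_equal(sc, sweep(X, 2, cm$mean) %*% cm$loadings[, 1:3],
               ignore_attr = TRUE)
  expect_equal(simca_scores_3d(m, matrix(cm$mean, 1))$a,
               matrix(0, 1, 3), tolerance = 1e-10, ignore_attr = TRUE)
  cv <- stats::cov(sc)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-10, ignore_attr = TRUE)
  m2 <- simca_fit(X, rep("a", 25), k = 2)
  expect_warning(simca_scores_3d(m2, X), "k < 3")
})
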