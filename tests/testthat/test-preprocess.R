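test_that("SNV matches a two-pass oracle and is idempotent", {
  expect_equal(snv(c(-1, 0, 1)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "zero-variance")
  set.seed(4)
  x <- rnorm(512, mean = 30, sd = 7)
  # independent two-pass loop
  m <- 0; for (v in x) m <- m + v; m <- m / length(x)
  ss <- 0; for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (length(x) - 1))
  expect_equal(snv(x), (x - m) / s, tolerance = 1e-12)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  # matrix input: row-wise
  X <- rbind(x, 2 * x + 5)
  expect_equal(snv(X)[1, ], snv(x), ignore_attr = TRUE)
})

test_that("Savitzky-Golay reproduces exact polynomials", {
  n <- 30
  expect_equal(savitzky_golay(rep(3, n), 5, 2, 2), rep(0, n))
  expect_equal(savitzky_golay(seq_len(n), 5, 2, 2), rep(0, n),
               tolerance = 1e-10)
  y2 <- savitzky_golay(seq_len(n)^2, 5, 2, 2)
  expect_equal(y2[3:(n - 2)], rep(2, n - 4), tolerance = 1e-9)
  # deriv 0 reproduces any polynomial of degree <= order at interior points
  x <- seq_len(n)
  pol <- 1 + 2 * x - 0.3 * x^2
  sm <- savitzky_golay(pol, 7, 2, 0)
  expect_equal(sm[4:(n - 3)], pol[4:(n - 3)], tolerance = 1e-8)
})

test_that("Savitzky-Golay interior points match a per-window LS fit oracle", {
  set.seed(8)
  y <- rnorm(60)
  w <- 11; half <- (w - 1) / 2; ord <- 2
  for (d in 0:2) {
    got <- savitzky_golay(y, w, ord, d)
    for (i in (half + 1):(60 - half)) {
      idx <- (i - half):(i + half)
      t <- idx - i
      fit <- stats::lm.fit(outer(t, 0:ord, `^`), y[idx])
      expected <- fit$coefficients[d + 1] * factorial(d)
      expect_equal(got[i], unname(expected), tolerance = 1e-8)
    }
  }
})

test_that("Savitzky-Golay validates its window arguments", {
  expect_error(savitzky_golay(1:20, 4, 2, 2), "odd")
  expect_error(savitzky_golay(1:20, 3, 3, 2), "exceed")
  expect_error(savitzky_golay(1:4, 5, 2, 2), "number of points")
  expect_error(savitzky_golay(1:20, 5, 1, 2), "cannot exceed")
})

test_that("mean centering stores and re-applies training means", {
  one <- matrix(rnorm(6), 1, 6)
  expect_equal(mean_center(one)$X, matrix(0, 1, 6), ignore_attr = TRUE)
  set.seed(2)
  tr <- matrix(rnorm(40), 8, 5); te <- matrix(rnorm(10), 2, 5)
  mc <- mean_center(tr)
  ap <- mean_center(te, mc$means)
  for (i in 1:2) for (j in 1:5)
    expect_equal(ap$X[i, j], te[i, j] - mean(tr[, j]))
  # invertible given stored means
  expect_equal(sweep(mc$X, 2, mc$means, "+"), tr)
  # already-centered data: means ~ 0, data unchanged
  cc <- mean_center(mc$X)
  expect_equal(cc$means, rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("region selection keeps exactly the closed-interval grid points", {
  s <- spectra_set(matrix(rnorm(2 * 512), 2), default_axis())
  expect_equal(ncol(select_region(s, 200, 2500)$X), 512L)
  expect_equal(ncol(select_region(s, s$axis[1], s$axis[1])$X), 1L)
  # count by direct enumeration of grid points 200 + i*(2300/511)
  cnt <- 0L
  for (i in 0:511) {
    w <- 200 + i * (2300 / 511)
    if (w >= 1370 && w <= 1700) cnt <- cnt + 1L
  }
  expect_equal(cnt, 74L)
  expect_equal(ncol(select_region(s, 1370, 1700)$X), cnt)
  expect_error(select_region(s, 3000, 3100), "no axis points")
  expect_error(select_region(s, 10, 5), "<=")
})

test_that("preprocess plans apply in order and never refit on test data", {
  s <- random_set(n = 6, p = 40, seed = 5)
  plan <- preprocess_plan(step_snv(), step_sg(5, 2, 2),
                          step_region(500, 1500), step_mean_center())
  f <- pp_fit(plan, s)
  # manual replication in the declared order
  X <- snv(s$X)
  X <- savitzky_golay(X, 5, 2, 2)
  keep <- s$axis >= 500 & s$axis <= 1500
  X <- X[, keep, drop = FALSE]
  mc <- mean_center(X)
  expect_equal(f$set$X, mc$X, ignore_attr = TRUE)
  # stored state comes from the training set only
  test_set <- random_set(n = 3, p = 40, seed = 99)
  out <- pp_apply(f$plan, test_set)
  means <- f$plan$steps[[4]]$means
  expect_equal(means, mc$means, ignore_attr = TRUE)
  manual_test <- savitzky_golay(snv(test_set$X), 5, 2, 2)[, keep]
  expect_equal(out$X, sweep(manual_test, 2, means, "-"),
               ignore_attr = TRUE)
  # unfitted plans with fitted steps refuse to apply
  expect_error(pp_apply(plan, test_set), "not fitted")
})
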