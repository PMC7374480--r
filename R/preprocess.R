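#' Standard normal variate (SNV) transform
#'
#' Normalizes each spectrum to zero mean and unit sample standard deviation
#' across the whole spectral range, correcting multiplicative scatter.
#'
#' @param x Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return Same shape as the input.
#' @export
snv <- function(x) {
  one <- function(v) {
    if (length(v) < 2L) stop("SNV needs at least 2 points", call. = FALSE)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance spectrum: SNV undefined", call. = FALSE)
    (v - mean(v)) / s
  }
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(x)
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial filter: each output point is the
#' `deriv`-th derivative (with respect to index position) of the polynomial
#' of order `poly_order` fitted over the centered odd-length window.
#' Interior points use the symmetric window; at the edges the full window is
#' fitted asymmetrically so the output length equals the input length.
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @param window Odd window length, > `poly_order`, <= number of points.
#' @param poly_order Polynomial order (default 2, the chemometrics default).
#' @param deriv Derivative order 0, 1 or 2 (0 = smoothing only).
#' @return Same shape as the input.
#' @export
savitzky_golay <- function(x, window, poly_order = 2L, deriv = 0L) {
  window <- as.integer(window); poly_order <- as.integer(poly_order)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window <= poly_order)
    stop("`window` must exceed `poly_order`", call. = FALSE)
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2", call. = FALSE)
  if (deriv > poly_order)
    stop("`deriv` cannot exceed `poly_order`", call. = FALSE)
  p <- if (is.matrix(x)) ncol(x) else length(x)
  if (p < window) stop("`window` exceeds the number of points",
                       call. = FALSE)
  one <- function(v) signal::sgolayfilt(v, p = poly_order, n = window,
                                        m = deriv, ts = 1)
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(x)
}

#' Column mean centering with stored means
#'
#' @param X Numeric matrix (samples in rows).
#' @param means Optional previously fitted column means; when supplied they
#'   are subtracted unchanged (application to test data), otherwise the
#'   column means of `X` are estimated and returned.
#' @return List with `X` (centered matrix) and `means`.
#' @export
mean_center <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) {
    if (nrow(X) < 1L) stop("need at least one row", call. = FALSE)
    means <- colMeans(X)
  }
  if (length(means) != ncol(X))
    stop("stored means do not match the number of variables", call. = FALSE)
  list(X = sweep(X, 2L, means, "-"), means = means)
}

#' Restrict a spectra set (or matrix) to a wavenumber region
#'
#' Retains exactly the axis points w with `lo <= w <= hi` (closed interval),
#' order preserved.
#'
#' @param set A `spectra_set`, or a matrix (then `axis` must be given).
#' @param lo,hi Region bounds in cm^-1, `lo < hi` (or `lo == hi` to pick a
#'   single grid point).
#' @param axis Axis vector when `set` is a bare matrix.
#' @return Same type as `set`, restricted to the region.
#' @export
select_region <- function(set, lo, hi, axis = NULL) {
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  ax <- if (inherits(set, "spectra_set")) set$axis else axis
  if (is.null(ax)) stop("`axis` required for matrix input", call. = FALSE)
  keep <- which(ax >= lo & ax <= hi)
  if (!length(keep))
    stop("no axis points inside [", lo, ", ", hi, "]", call. = FALSE)
  if (inherits(set, "spectra_set")) {
    out <- set
    out$X <- set$X[, keep, drop = FALSE]
    out$axis <- ax[keep]
    out
  } else {
    set[, keep, drop = FALSE]
  }
}

#' Build a preprocessing plan
#'
#' A plan is an ordered list of pretreatment steps applied exactly in the
#' given order. Steps with fitted state (mean centering) estimate their
#' statistics once on the training set ([pp_fit()]) and re-apply them
#' unchanged to new data ([pp_apply()]), so no test-set information leaks
#' into the preprocessing.
#'
#' @param ... Steps created by [step_snv()], [step_sg()], [step_region()],
#'   [step_mean_center()].
#' @return A `preprocess_plan`.
#' @export
preprocess_plan <- function(...) {
  steps <- list(...)
  ok <- vapply(steps, function(s) is.list(s) && !is.null(s$type), logical(1))
  if (!all(ok)) stop("all arguments must be plan steps", call. = FALSE)
  structure(list(steps = steps, fitted = FALSE), class = "preprocess_plan")
}

#' @rdname preprocess_plan
#' @export
step_snv <- function() list(type = "snv")

#' @rdname preprocess_plan
#' @param window,poly_order,deriv Savitzky-Golay parameters, see
#'   [savitzky_golay()].
#' @export
step_sg <- function(window, poly_order = 2L, deriv = 2L)
  list(type = "sg", window = window, poly_order = poly_order, deriv = deriv)

#' @rdname preprocess_plan
#' @param lo,hi Region bounds in cm^-1.
#' @export
step_region <- function(lo, hi) list(type = "region", lo = lo, hi = hi)

#' @rdname preprocess_plan
#' @export
step_mean_center <- function() list(type = "mean_center")

pp_run <- function(plan, set, fit) {
  stopifnot(inherits(set, "spectra_set"))
  for (i in seq_along(plan$steps)) {
    st <- plan$steps[[i]]
    if (st$type == "snv") {
      set$X <- snv(set$X)
    } else if (st$type == "sg") {
      set$X <- savitzky_golay(set$X, st$window, st$poly_order, st$deriv)
    } else if (st$type == "region") {
      set <- select_region(set, st$lo, st$hi)
    } else if (st$type == "mean_center") {
      if (fit) {
        mc <- mean_center(set$X)
        plan$steps[[i]]$means <- mc$means
      } else {
        if (is.null(st$means))
          stop("plan not fitted: mean-centering state missing",
               call. = FALSE)
        mc <- mean_center(set$X, st$means)
      }
      set$X <- mc$X
    } else stop("unknown step type: ", st$type, call. = FALSE)
  }
  list(plan = plan, set = set)
}

#' Fit a preprocessing plan on training data
#'
#' @param plan A `preprocess_plan`.
#' @param set Training `spectra_set`.
#' @return List with `plan` (fitted: centering means stored) and `set`
#'   (the preprocessed training data).
#' @export
pp_fit <- function(plan, set) {
  out <- pp_run(plan, set, fit = TRUE)
  out$plan$fitted <- TRUE
  out
}

#' Apply a fitted preprocessing plan to new data
#'
#' @param plan A fitted `preprocess_plan` (from [pp_fit()]); plans without
#'   fitted steps may be applied directly.
#' @param set A `spectra_set`.
#' @return The preprocessed `spectra_set`.
#' @export
pp_apply <- function(plan, set) {
  pp_run(plan, set, fit = FALSE)$set
}
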