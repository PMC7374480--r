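#' Carotenoid profile classes
#'
#' The seven carotenoid-profile classes used throughout the package. Tomato
#' fruit cluster into these groups according to the dominant carotenoid
#' (all-trans-lycopene, tetra-cis-lycopene, beta-carotene), secondary
#' carotenoids (beta- or gamma-carotene alongside lycopene), the presence of
#' skin anthocyanins, or the near-absence of carotenoids altogether.
#'
#' @return Character vector of the seven class names.
#' @export
carotenoid_classes <- function() {
  c("lycopene_high", "lycopene_bcarotene", "lycopene_gcarotene",
    "bcarotene", "bcarotene_anthocyanin", "tetracis_lycopene",
    "low_carotenoid")
}

#' Construct a single Raman spectrum
#'
#' @param axis Numeric vector of wavenumbers in cm^-1, strictly increasing.
#' @param intensity Numeric vector of intensities (arbitrary counts), same
#'   length as `axis`.
#' @param sample_id Sample identifier (character scalar).
#' @param replicate Replicate number, integer >= 1.
#'
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(axis, intensity, sample_id, replicate = 1L) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("`axis` and `intensity` must have the same length", call. = FALSE)
  if (length(axis) < 2L || any(diff(axis) <= 0))
    stop("`axis` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(axis)) || !all(is.finite(intensity)))
    stop("spectrum values must all be finite", call. = FALSE)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("`replicate` must be an integer >= 1", call. = FALSE)
  structure(
    list(axis = axis, intensity = intensity,
         sample_id = as.character(sample_id), replicate = replicate),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (rep %d): %d points, %.1f-%.1f cm-1\n",
              x$sample_id, x$replicate, length(x$axis),
              min(x$axis), max(x$axis)))
  invisible(x)
}

#' Construct a set of spectra sharing one wavenumber axis
#'
#' The n x p intensity matrix plus shared axis, optional class labels and
#' optional reference concentrations is the unit all models in the package
#' consume.
#'
#' @param X Numeric matrix, one row per sample, one column per wavenumber.
#' @param axis Shared wavenumber axis (length `ncol(X)`), strictly increasing.
#' @param sample_id Character vector of sample ids (length `nrow(X)`).
#' @param labels Optional class label per row (character or factor).
#' @param y Optional reference concentration per row, mg/100 g, nonnegative.
#' @param analyte Optional analyte name the concentrations refer to.
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(X, axis, sample_id = NULL, labels = NULL, y = NULL,
                        analyte = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  axis <- as.numeric(axis)
  if (ncol(X) != length(axis))
    stop("`axis` length must equal ncol(X)", call. = FALSE)
  if (length(axis) >= 2L && any(diff(axis) <= 0))
    stop("`axis` must be strictly increasing", call. = FALSE)
  if (nrow(X) > 0 && !all(is.finite(X)))
    stop("intensities must all be finite", call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(rownames(X))) rownames(X)
                 else sprintf("s%03d", seq_len(nrow(X)))
  }
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(X))
    stop("`sample_id` must have one entry per row of X", call. = FALSE)
  rownames(X) <- sample_id
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(X))
      stop("`labels` must have one entry per row of X", call. = FALSE)
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X))
      stop("`y` must have one entry per row of X", call. = FALSE)
    if (any(y < 0, na.rm = TRUE))
      stop("reference concentrations must be >= 0", call. = FALSE)
  }
  structure(
    list(X = X, axis = axis, sample_id = sample_id, labels = labels, y = y,
         analyte = analyte),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%.1f-%.1f cm-1)\n",
              nrow(x$X), ncol(x$X),
              if (length(x$axis)) min(x$axis) else NA,
              if (length(x$axis)) max(x$axis) else NA))
  if (!is.null(x$labels))
    cat("  labels: ", paste(names(table(x$labels)), table(x$labels),
                            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$y))
    cat(sprintf("  y (%s): %.2f-%.2f mg/100 g\n",
                if (is.null(x$analyte)) "?" else x$analyte,
                min(x$y), max(x$y)))
  invisible(x)
}

#' Subset a spectra_set by row
#'
#' @param set A `spectra_set`.
#' @param i Row index vector.
#' @return A `spectra_set` with the selected rows; labels/y subset in step.
#' @export
subset_rows <- function(set, i) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(set$X[i, , drop = FALSE], set$axis,
              sample_id = set$sample_id[i],
              labels = if (!is.null(set$labels)) set$labels[i],
              y = if (!is.null(set$y)) set$y[i],
              analyte = set$analyte)
}

#' Write a spectra set as wide CSV plus metadata sidecar
#'
#' The spectra file holds the axis in a first column named
#' `wavenumber_cm-1` followed by one intensity column per sample, ordered by
#' sample id. A second CSV holds the metadata (sample id, class,
#' concentration, analyte).
#'
#' @param set A `spectra_set`.
#' @param path Output path for the spectra CSV.
#' @param meta_path Output path for the metadata CSV; default replaces the
#'   extension of `path` with `_meta.csv`.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_spectra <- function(set, path, meta_path = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(meta_path))
    meta_path <- paste0(sub("\\.csv$", "", path), "_meta.csv")
  ord <- order(set$sample_id)
  df <- data.frame(`wavenumber_cm-1` = set$axis, check.names = FALSE)
  for (i in ord) df[[set$sample_id[i]]] <- set$X[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  nw <- length(ord)
  meta <- data.frame(
    sample_id = set$sample_id[ord],
    class = if (!is.null(set$labels)) set$labels[ord]
            else rep(NA_character_, nw),
    concentration_mg_per_100g = if (!is.null(set$y)) set$y[ord]
                                else rep(NA_real_, nw),
    analyte = rep(if (!is.null(set$analyte)) set$analyte
                  else NA_character_, length.out = nw),
    stringsAsFactors = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a wide-CSV spectra file (with optional metadata sidecar)
#'
#' @param path Spectra CSV with first column `wavenumber_cm-1` and one
#'   intensity column per sample.
#' @param meta_path Optional metadata CSV as written by [write_spectra()];
#'   when the default sidecar file exists next to `path` it is read
#'   automatically.
#' @return A `spectra_set` with axis sorted ascending and sample order as in
#'   the file.
#' @export
read_spectra <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("ragged rows in ", path, ": not a valid wide spectra CSV",
         call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L) stop("empty spectra file", call. = FALSE)
  axis <- as.numeric(df[[1L]])
  if (anyNA(axis)) stop("non-numeric wavenumber column", call. = FALSE)
  d <- diff(axis)
  if (length(d) && all(d < 0)) {            # stored descending: flip
    axis <- rev(axis)
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    d <- diff(axis)
  }
  if (length(d) && any(d <= 0))
    stop("wavenumber axis is not strictly monotone", call. = FALSE)
  sample_id <- colnames(df)[-1L]
  X <- t(as.matrix(df[, -1L, drop = FALSE]))
  storage.mode(X) <- "double"
  if (nrow(X) > 0 && anyNA(X))
    stop("non-numeric intensity values", call. = FALSE)
  labels <- NULL; y <- NULL; analyte <- NULL
  if (is.null(meta_path)) {
    cand <- paste0(sub("\\.csv$", "", path), "_meta.csv")
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path) && file.exists(meta_path) && length(sample_id)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    m <- match(sample_id, meta$sample_id)
    if (!anyNA(m)) {
      if (!all(is.na(meta$class[m]))) labels <- meta$class[m]
      if (!all(is.na(meta$concentration_mg_per_100g[m])))
        y <- meta$concentration_mg_per_100g[m]
      a <- unique(stats::na.omit(meta$analyte[m]))
      if (length(a) == 1L) analyte <- a
    }
  }
  spectra_set(X, axis, sample_id = sample_id, labels = labels, y = y,
              analyte = analyte)
}

#' Average replicate spectra per sample
#'
#' Collapses a list of replicate spectra into one averaged spectrum per
#' sample id (arithmetic mean of replicate intensities). Averaging replicate
#' surface scans is the standard first step before modelling.
#'
#' @param spectra List of `raman_spectrum` objects; replicates of a sample
#'   must share the axis.
#' @param meta Optional metadata data.frame with columns `sample_id` and any
#'   of `class`, `concentration_mg_per_100g`, `analyte`, used to attach
#'   labels/concentrations to the averaged set.
#' @return A `spectra_set` with one row per distinct sample id (order of
#'   first appearance).
#' @export
average_replicates <- function(spectra, meta = NULL) {
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  uid <- unique(ids)
  axis <- spectra[[1L]]$axis
  X <- matrix(NA_real_, nrow = length(uid), ncol = length(axis))
  for (j in seq_along(uid)) {
    grp <- spectra[ids == uid[j]]
    for (s in grp) {
      if (length(s$axis) != length(axis) ||
          any(abs(s$axis - axis) > 1e-9))
        stop("replicates of sample ", uid[j],
             " do not share the wavenumber axis", call. = FALSE)
    }
    M <- do.call(rbind, lapply(grp, function(s) s$intensity))
    X[j, ] <- colMeans(M)
  }
  labels <- NULL; y <- NULL; analyte <- NULL
  if (!is.null(meta)) {
    m <- match(uid, meta$sample_id)
    if (!is.null(meta$class)) labels <- meta$class[m]
    if (!is.null(meta$concentration_mg_per_100g))
      y <- meta$concentration_mg_per_100g[m]
    if (!is.null(meta$analyte)) {
      a <- unique(stats::na.omit(meta$analyte[m]))
      if (length(a) == 1L) analyte <- a
    }
  }
  spectra_set(X, axis, sample_id = uid, labels = labels, y = y,
              analyte = analyte)
}
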