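#' Default per-class sample counts for the classification benchmark
#'
#' 106 samples spread over the seven profiles in roughly the proportions of
#' a breeding panel dominated by red (lycopene-type) fruit, with smaller
#' orange (beta-carotene / tetra-cis-lycopene), purple (anthocyanin) and
#' yellow-green (low carotenoid) groups.
#'
#' @return Named integer vector summing to 106.
#' @export
default_class_counts <- function() {
  c(lycopene_high = 30L, lycopene_bcarotene = 12L,
    lycopene_gcarotene = 12L, bcarotene = 16L,
    bcarotene_anthocyanin = 8L, tetracis_lycopene = 15L,
    low_carotenoid = 13L)
}

#' Configuration of the seven-class classification experiment
#'
#' @param n_per_class Samples per class (default [default_class_counts()]).
#' @param noise A [noise_config()].
#' @param replicates Replicate spectra per sample (default 3).
#' @param seed Master seed; stage seeds (simulation, splits, network
#'   training) are derived as small offsets.
#' @param alpha SIMCA admission F-test level.
#' @param sg_window Savitzky-Golay window for the SIMCA branch (default 25,
#'   2nd derivative).
#' @param region Classification region bounds in cm^-1 (default
#'   `c(1370, 1700)`).
#' @param ann_window,ann_step Sliding-window selection parameters for the
#'   network branch (default 62-point window, step 2).
#' @param n_trials Hyperparameter-search trials (default 50).
#' @param max_epochs,patience Network training-loop settings.
#' @return A `classification_config` list.
#' @export
classification_config <- function(n_per_class = default_class_counts(),
                                  noise = noise_config(), replicates = 3L,
                                  seed = 1L, alpha = 0.01,
                                  sg_window = 25L, region = c(1370, 1700),
                                  ann_window = 62L, ann_step = 2L,
                                  n_trials = 50L, max_epochs = 600L,
                                  patience = 50L) {
  stopifnot(all(names(n_per_class) %in% carotenoid_classes()))
  structure(as.list(environment()), class = "classification_config")
}

#' Run the seven-class classification experiment
#'
#' Simulates the benchmark dataset, averages the replicate spectra and runs
#' both classifiers: SIMCA on SNV + Savitzky-Golay second-derivative +
#' region-restricted + mean-centered spectra with a stratified 80/20 split,
#' and an MLP on mean-centered spectra restricted to the sliding-window-
#' selected region with a stratified 80/10/10 split and random
#' hyperparameter search. Reports both accuracies, the full-data interclass
#' distance matrix and the discriminating-power peak. Fully reproducible
#' from the config seed.
#'
#' @param config A [classification_config()].
#' @return An `evaluation_report` list: `simca_accuracy`,
#'   `simca_confusion`, `icd` (full-data), `min_icd`, `dp_argmax_cm1`,
#'   `ann_accuracy`, `ann_table`, seeds and sizes.
#' @export
run_classification <- function(config = classification_config()) {
  seed_sim <- config$seed
  seed_split <- config$seed + 1L
  seed_ann <- config$seed + 2L
  ds <- generate_dataset(config$n_per_class, config$noise,
                         replicates = config$replicates, seed = seed_sim)
  avg <- average_replicates(ds$spectra, ds$meta)
  n <- nrow(avg$X)

  ## --- SIMCA branch -------------------------------------------------
  plan <- preprocess_plan(step_snv(),
                          step_sg(config$sg_window, 2L, 2L),
                          step_region(config$region[1], config$region[2]),
                          step_mean_center())
  sp <- split_data(avg$labels, c(0.8, 0.2), seed = seed_split,
                   stratify = TRUE)
  train <- subset_rows(avg, sp$train)
  test <- subset_rows(avg, sp$test)
  fit_pp <- pp_fit(plan, train)
  train_pp <- fit_pp$set
  test_pp <- pp_apply(fit_pp$plan, test)
  sm <- simca_fit(train_pp, alpha = config$alpha)
  acc <- simca_accuracy(sm, test_pp)

  # interclass distances on the full benchmark set
  full_pp <- pp_fit(plan, avg)$set
  sm_full <- simca_fit(full_pp, alpha = config$alpha)
  offdiag <- sm_full$icd[upper.tri(sm_full$icd)]

  # discriminating power peak for the pure-lycopene vs beta-carotene pair
  dp <- simca_discriminating_power(sm_full$models[["lycopene_high"]],
                                   sm_full$models[["bcarotene"]])
  dp_argmax <- full_pp$axis[which.max(dp)]

  ## --- network branch -----------------------------------------------
  sp3 <- split_data(avg$labels, c(0.8, 0.1, 0.1), seed = seed_split,
                    stratify = TRUE)
  mc <- mean_center(avg$X[sp3$train, , drop = FALSE])
  Xtr <- mc$X
  Xva <- mean_center(avg$X[sp3$val, , drop = FALSE], mc$means)$X
  Xte <- mean_center(avg$X[sp3$test, , drop = FALSE], mc$means)$X
  sel <- sliding_window_selection(Xtr, avg$labels[sp3$train],
                                  Xva, avg$labels[sp3$val],
                                  window = config$ann_window,
                                  step = config$ann_step,
                                  task = "classification")
  tab <- mlp_search(Xtr[, sel$cols, drop = FALSE], avg$labels[sp3$train],
                    Xva[, sel$cols, drop = FALSE], avg$labels[sp3$val],
                    Xte[, sel$cols, drop = FALSE], avg$labels[sp3$test],
                    n_trials = config$n_trials, seed = seed_ann,
                    task = "classification",
                    max_epochs = config$max_epochs,
                    patience = config$patience)

  structure(list(
    simca_accuracy = acc$accuracy,
    simca_confusion = acc$confusion,
    icd = sm_full$icd,
    min_icd = min(offdiag),
    dp_argmax_cm1 = dp_argmax,
    ann_accuracy = tab$accuracy[1L],
    ann_topology = tab$topology[1L],
    ann_table = tab,
    ann_window_cm1 = range(avg$axis[sel$cols]),
    n = n,
    seeds = c(sim = seed_sim, split = seed_split, ann = seed_ann)),
    class = "evaluation_report")
}

#' Configuration of the single-analyte quantification experiment
#'
#' @param n_samples Number of analyte-dominant samples (default 58, the
#'   lycopene benchmark; beta-carotene runs at its natural n = 17 are
#'   supported but small-n).
#' @param analyte `"lycopene"` or `"bcarotene"`.
#' @param noise,replicates,seed As in [classification_config()].
#' @param sg_window Savitzky-Golay window for the PLSR branch (default 15,
#'   2nd derivative with smoothing).
#' @param max_a Largest number of PLS latent variables tried in LOO-CV.
#' @param ann_window,ann_step,n_trials,max_epochs,patience Network branch
#'   settings (regression networks train longer by default).
#' @return A `quantification_config` list.
#' @export
quantification_config <- function(n_samples = 58L,
                                  analyte = c("lycopene", "bcarotene"),
                                  noise = noise_config(), replicates = 3L,
                                  seed = 1L, sg_window = 15L, max_a = 10L,
                                  ann_window = 62L, ann_step = 2L,
                                  n_trials = 20L, max_epochs = 2000L,
                                  patience = 100L) {
  analyte <- match.arg(analyte)
  structure(as.list(environment()), class = "quantification_config")
}

#' Run the quantification experiment
#'
#' Simulates analyte-dominant samples with reference concentrations drawn
#' uniformly from the analyte range, then calibrates two regressors:
#' PLS1 on Savitzky-Golay second-derivative (15-point, smoothed) mean-
#' centered spectra with leave-one-out latent-variable selection on a
#' stratified 80/20 calibration/validation split, and an MLP regressor on
#' mean-centered spectra restricted to the sliding-window-selected region
#' with a 60/20/20 split tuned on the validation set.
#'
#' @param config A [quantification_config()].
#' @return An `evaluation_report` list with `r_cv`, `secv`, `chosen_a`,
#'   `r_pred`, `sep` (PLSR) and `ann_r`, `ann_rmse` plus predictions.
#' @export
run_quantification <- function(config = quantification_config()) {
  seed_sim <- config$seed
  seed_split <- config$seed + 1L
  seed_ann <- config$seed + 2L
  recipe <- quantification_recipe(config$analyte)
  n_per <- stats::setNames(config$n_samples, recipe$label)
  ds <- generate_dataset(n_per, config$noise,
                         replicates = config$replicates, seed = seed_sim,
                         recipes = stats::setNames(list(recipe),
                                                   recipe$label))
  avg <- average_replicates(ds$spectra, ds$meta)
  y <- avg$y

  ## --- PLSR branch --------------------------------------------------
  D <- savitzky_golay(avg$X, config$sg_window, 2L, 2L)
  quart <- cut(y, stats::quantile(y, probs = seq(0, 1, 0.25)),
               include.lowest = TRUE, labels = FALSE)
  sp <- split_data(as.character(quart), c(0.8, 0.2), seed = seed_split,
                   stratify = TRUE)
  mc <- mean_center(D[sp$train, , drop = FALSE])
  Xcal <- mc$X
  Xval <- mean_center(D[sp$test, , drop = FALSE], mc$means)$X
  ycal <- y[sp$train]; yval <- y[sp$test]
  cv <- pls_loo_cv(Xcal, ycal, max_a = config$max_a)
  a <- cv$chosen_a
  fit <- pls1_fit(Xcal, ycal, a)
  pred <- pls1_predict(fit, Xval)
  m_cv <- pls_metrics(ycal, cv$predictions[, a])
  m_pred <- pls_metrics(yval, pred)

  ## --- network branch -----------------------------------------------
  sp3 <- split_data(length(y), c(0.6, 0.2, 0.2), seed = seed_ann)
  mc2 <- mean_center(avg$X[sp3$train, , drop = FALSE])
  Xtr <- mc2$X
  Xva <- mean_center(avg$X[sp3$val, , drop = FALSE], mc2$means)$X
  Xte <- mean_center(avg$X[sp3$test, , drop = FALSE], mc2$means)$X
  sel <- sliding_window_selection(Xtr, y[sp3$train], Xva, y[sp3$val],
                                  window = config$ann_window,
                                  step = config$ann_step,
                                  task = "regression")
  tab <- mlp_search(Xtr[, sel$cols, drop = FALSE], y[sp3$train],
                    Xva[, sel$cols, drop = FALSE], y[sp3$val],
                    Xte[, sel$cols, drop = FALSE], y[sp3$test],
                    n_trials = config$n_trials, seed = seed_ann,
                    task = "regression", max_epochs = config$max_epochs,
                    patience = config$patience)

  structure(list(
    analyte = config$analyte,
    chosen_a = a,
    r_cv = unname(m_cv["r"]), secv = unname(m_cv["se"]),
    r_pred = unname(m_pred["r"]), sep = unname(m_pred["se"]),
    predictions = data.frame(sample_id = avg$sample_id[sp$test],
                             y = yval, y_hat = pred),
    ann_r = tab$r[1L], ann_rmse = tab$rmse[1L],
    ann_topology = tab$topology[1L],
    ann_table = tab,
    ann_window_cm1 = range(avg$axis[sel$cols]),
    n = length(y),
    seeds = c(sim = seed_sim, split = seed_split, ann = seed_ann)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  if (!is.null(x$simca_accuracy)) {
    cat(sprintf("  SIMCA held-out accuracy: %.1f%%\n", x$simca_accuracy))
    cat(sprintf("  ANN test accuracy: %.1f%% (topology %s)\n",
                x$ann_accuracy, x$ann_topology))
    cat(sprintf("  min interclass distance: %.2f\n", x$min_icd))
    cat(sprintf("  discriminating-power peak: %.1f cm-1\n",
                x$dp_argmax_cm1))
  }
  if (!is.null(x$r_pred)) {
    cat(sprintf("  %s PLSR: a = %d, r_cv = %.3f, SECV = %.2f, r_pred = %.3f, SEP = %.2f mg/100 g\n",
                x$analyte, x$chosen_a, x$r_cv, x$secv, x$r_pred, x$sep))
    cat(sprintf("  %s ANN:  r = %.3f, RMSE = %.2f mg/100 g (topology %s)\n",
                x$analyte, x$ann_r, x$ann_rmse, x$ann_topology))
  }
  invisible(x)
}
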