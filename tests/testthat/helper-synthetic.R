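# Shared fixture builders (everything generated in code, seeded).

# Small random spectra_set with labels and concentrations.
random_set <- function(n = 5, p = 40, seed = 1, labelled = TRUE) {
  set.seed(seed)
  axis <- seq(400, 1800, length.out = p)
  X <- matrix(rnorm(n * p, mean = 10), n, p)
  spectra_set(X, axis,
              sample_id = sprintf("s%02d", seq_len(n)),
              labels = if (labelled) sample(c("a", "b"), n, replace = TRUE),
              y = if (labelled) runif(n, 1, 20),
              analyte = if (labelled) "lycopene")
}

# Noise-free configuration (pure band signal plus nothing).
silent_noise <- function(baseline_scale = 0)
  noise_config(baseline_poly_order = 0L, baseline_scale = baseline_scale,
               multiplicative_scatter_sd = 0, additive_noise_sd = 0)

# Two Gaussian classes in p dimensions with a mean shift along one axis.
two_gaussian_classes <- function(n = 30, p = 20, shift = 0, sd = 1,
                                 shift_var = 1, seed = 1) {
  set.seed(seed)
  Xa <- matrix(rnorm(n * p, sd = sd), n, p)
  Xb <- matrix(rnorm(n * p, sd = sd), n, p)
  Xb[, shift_var] <- Xb[, shift_var] + shift
  list(a = Xa, b = Xb)
}

# Tiny trained-by-construction regression data: y = X %*% beta.
linear_data <- function(n = 12, p = 8, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  list(X = X, y = as.numeric(X %*% beta), beta = beta)
}
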