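#' Default instrument wavenumber axis
#'
#' Linear 512-point axis from 200 to 2500 cm^-1 inclusive, mimicking a
#' handheld 1064 nm Raman instrument with a 512-pixel detector. Pixel
#' spacing is 2300/511 ~ 4.5 cm^-1; we model the axis as linear in
#' wavenumber (see the methods vignette for the discussion of the nominal
#' 8 cm^-1 optical resolution).
#'
#' @return Numeric vector of 512 equally spaced wavenumbers.
#' @export
default_axis <- function() seq(200, 2500, length.out = 512L)

#' Lorentzian line shape with unit peak height
#'
#' @param axis Wavenumbers at which to evaluate.
#' @param center Band center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @return Numeric vector, 1 at the center.
#' @export
lorentzian <- function(axis, center, fwhm) {
  if (fwhm <= 0) stop("`fwhm` must be > 0", call. = FALSE)
  hw2 <- (fwhm / 2)^2
  hw2 / ((axis - center)^2 + hw2)
}

#' Band specification
#'
#' @param center Band center in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1, > 0.
#' @param rel_amp Relative amplitude >= 0 (peak height per mg/100 g of the
#'   parent component).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, fwhm, rel_amp) {
  if (fwhm <= 0) stop("`fwhm` must be > 0", call. = FALSE)
  if (rel_amp < 0) stop("`rel_amp` must be >= 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, rel_amp = rel_amp),
            class = "band_spec")
}

# Band tables per pigment. All carotenoids share the C-CH3 rocking band at
# 1007 cm-1 and the C-C stretch at 1158 cm-1; the diagnostic nu1 C=C stretch
# sits at 1519 (all-trans-lycopene), 1523 (tetra-cis-lycopene), 1528
# (beta-carotene). gamma-carotene's nu1 is placed at 1516 cm-1 and the
# anthocyanin signature as a pair of aromatic ring-stretch bands near
# 1600/1630 cm-1: neither is an established literature value here, they are
# package defaults (vignette).
component_bands <- function(name) {
  common <- list(band_spec(1007, 10, 0.35), band_spec(1158, 10, 0.60))
  nu1 <- switch(name,
    lycopene          = band_spec(1519, 12, 1.0),
    tetracis_lycopene = band_spec(1523, 12, 1.0),
    bcarotene         = band_spec(1528, 12, 1.0),
    gcarotene         = band_spec(1516, 12, 1.0),
    anthocyanin       = NULL,
    stop("unknown component: ", name, call. = FALSE))
  if (name == "anthocyanin")
    return(list(band_spec(1601, 16, 0.9), band_spec(1630, 16, 0.5)))
  c(common, list(nu1))
}

#' Class recipes for the seven carotenoid profiles
#'
#' Each recipe lists the pigment components of a class together with the
#' concentration range (mg/100 g) its samples are drawn from. The
#' `low_carotenoid` class has no components: its spectra are baseline and
#' noise only. Class ranges reflect the class semantics — the
#' `lycopene_high` class holds fruit with *high* lycopene (floored at
#' 8 mg/100 g), composite classes hold fruit where both pigments are
#' substantial, and `tetracis_lycopene` fruit have tetra-cis-lycopene as
#' their clearly dominant pigment. The full quantification reference
#' ranges (lycopene 1.8-21.5, beta-carotene 1.6-9.5 mg/100 g) are used by
#' [quantification_recipe()]; composite floors are package defaults
#' (vignette).
#'
#' @return Named list of `class_recipe` objects, one per class in
#'   [carotenoid_classes()].
#' @export
class_recipes <- function() {
  comp <- function(name, lo, hi)
    list(name = name, bands = component_bands(name), range = c(lo, hi))
  r <- list(
    lycopene_high = list(comp("lycopene", 8.0, 21.5)),
    lycopene_bcarotene = list(comp("lycopene", 6.0, 15.0),
                              comp("bcarotene", 4.0, 9.5)),
    lycopene_gcarotene = list(comp("lycopene", 6.0, 15.0),
                              comp("gcarotene", 4.0, 9.5)),
    bcarotene = list(comp("bcarotene", 3.0, 9.5)),
    bcarotene_anthocyanin = list(comp("bcarotene", 3.0, 9.5),
                                 comp("anthocyanin", 2.0, 8.0)),
    tetracis_lycopene = list(comp("tetracis_lycopene", 4.0, 21.5)),
    low_carotenoid = list())
  lapply(stats::setNames(names(r), names(r)), function(lab)
    structure(list(label = lab, components = r[[lab]]),
              class = "class_recipe"))
}

#' Single-analyte recipe over the full quantification reference range
#'
#' Calibration datasets span the whole reference range measured by UV-Vis
#' across all analyte-dominant fruit: 1.8-21.5 mg/100 g for
#' all-trans-lycopene and 1.6-9.5 mg/100 g for beta-carotene.
#'
#' @param analyte `"lycopene"` or `"bcarotene"`.
#' @return A single-component `class_recipe`.
#' @export
quantification_recipe <- function(analyte = c("lycopene", "bcarotene")) {
  analyte <- match.arg(analyte)
  rng <- if (analyte == "lycopene") c(1.8, 21.5) else c(1.6, 9.5)
  structure(list(
    label = if (analyte == "lycopene") "lycopene_high" else "bcarotene",
    components = list(list(name = analyte,
                           bands = component_bands(analyte),
                           range = rng))),
    class = "class_recipe")
}

#' Noise configuration for the spectrum simulator
#'
#' Models the nuisance structure that SNV and derivative filtering are meant
#' to remove from fruit-surface Raman spectra: a smooth random baseline
#' (fluorescence-like), a per-spectrum multiplicative scatter factor, and
#' additive detector noise.
#'
#' @param baseline_poly_order Polynomial order of the random baseline
#'   (integer >= 0, default 2).
#' @param baseline_scale Overall baseline amplitude in intensity counts
#'   (default 2).
#' @param multiplicative_scatter_sd SD of the N(1, sd) scatter factor
#'   (default 0.15).
#' @param additive_noise_sd SD of additive Gaussian noise in counts
#'   (default 0.215, i.e. 1% of the largest nu1 band amplitude 21.5).
#' @return A `noise_config` list.
#' @export
noise_config <- function(baseline_poly_order = 2L, baseline_scale = 2,
                         multiplicative_scatter_sd = 0.15,
                         additive_noise_sd = 0.215) {
  if (baseline_poly_order < 0) stop("`baseline_poly_order` must be >= 0",
                                    call. = FALSE)
  if (multiplicative_scatter_sd < 0 || additive_noise_sd < 0 ||
      baseline_scale < 0)
    stop("noise scales must be >= 0", call. = FALSE)
  structure(list(baseline_poly_order = as.integer(baseline_poly_order),
                 baseline_scale = baseline_scale,
                 multiplicative_scatter_sd = multiplicative_scatter_sd,
                 additive_noise_sd = additive_noise_sd),
            class = "noise_config")
}

# Pure band signal of a recipe at given component concentrations.
recipe_signal <- function(recipe, concentrations, axis) {
  sig <- numeric(length(axis))
  for (cmp in recipe$components) {
    conc <- concentrations[[cmp$name]]
    if (is.null(conc)) stop("missing concentration for component ",
                            cmp$name, call. = FALSE)
    if (conc < 0) stop("negative concentration for ", cmp$name,
                       call. = FALSE)
    for (b in cmp$bands)
      sig <- sig + conc * b$rel_amp * lorentzian(axis, b$center, b$fwhm)
  }
  sig
}

# Random smooth baseline, positive by construction so raw spectra stay
# nonnegative at the default noise scales.
random_baseline <- function(axis, order, scale) {
  u <- (axis - min(axis)) / (max(axis) - min(axis))
  coef <- c(stats::runif(1, 1, 2),
            if (order >= 1) stats::runif(order, -0.4, 0.4))
  v <- numeric(length(axis))
  for (d in 0:order) v <- v + coef[d + 1L] * u^d
  scale * v
}

#' Simulate one Raman spectrum
#'
#' Intensity is the sum of concentration-scaled Lorentzian bands of the
#' recipe components plus a random polynomial baseline, all multiplied by a
#' multiplicative scatter factor ~ N(1, sd), plus additive Gaussian noise.
#' Deterministic under a fixed seed.
#'
#' @param recipe A `class_recipe` from [class_recipes()].
#' @param concentrations Named list/vector of component concentrations in
#'   mg/100 g (names must cover the recipe components).
#' @param noise A [noise_config()].
#' @param axis Wavenumber axis (default [default_axis()]).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [generate_dataset()]).
#' @param sample_id,replicate Metadata for the returned spectrum.
#' @return A `raman_spectrum`.
#' @export
generate_spectrum <- function(recipe, concentrations = list(),
                              noise = noise_config(), axis = default_axis(),
                              seed = NULL, sample_id = "synthetic",
                              replicate = 1L) {
  if (!is.null(seed)) set.seed(seed)
  sig <- recipe_signal(recipe, as.list(concentrations), axis)
  base <- random_baseline(axis, noise$baseline_poly_order,
                          noise$baseline_scale)
  scatter <- stats::rnorm(1, 1, noise$multiplicative_scatter_sd)
  eps <- stats::rnorm(length(axis), 0, noise$additive_noise_sd)
  raman_spectrum(axis, scatter * (sig + base) + eps,
                 sample_id = sample_id, replicate = replicate)
}

#' Draw component concentrations for a class
#'
#' Concentrations are drawn independently and uniformly from each
#' component's recipe range.
#'
#' @param recipe A `class_recipe`.
#' @param n Number of samples.
#' @param seed Optional seed.
#' @return Data frame with one column per component, n rows (0 columns for
#'   the low-carotenoid class).
#' @export
sample_concentrations <- function(recipe, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (cmp in recipe$components)
    out[[cmp$name]] <- stats::runif(n, cmp$range[1], cmp$range[2])
  out
}

#' Simulate a labelled multi-class dataset with replicates
#'
#' Samples are drawn class by class; replicate spectra of a sample share its
#' component concentrations but receive independent baseline, scatter and
#' noise draws. Bit-reproducible under a fixed seed.
#'
#' @param n_per_class Named integer vector, names a subset of
#'   [carotenoid_classes()].
#' @param noise A [noise_config()].
#' @param replicates Replicate spectra per sample (default 3).
#' @param seed Integer seed.
#' @param axis Wavenumber axis.
#' @param recipes Recipe list, default [class_recipes()].
#' @return List with `spectra` (list of `raman_spectrum`, replicates
#'   consecutive) and `meta` (data.frame: sample_id, class, analyte,
#'   concentration_mg_per_100g of the dominant (first) component, plus one
#'   `conc_<component>` column per pigment).
#' @export
generate_dataset <- function(n_per_class, noise = noise_config(),
                             replicates = 3L, seed = 1L,
                             axis = default_axis(),
                             recipes = class_recipes()) {
  unknown <- setdiff(names(n_per_class), names(recipes))
  if (length(unknown))
    stop("unknown class key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  spectra <- list()
  meta <- list()
  idx <- 0L
  for (cls in names(n_per_class)) {
    n <- as.integer(n_per_class[[cls]])
    if (n <= 0L) next
    recipe <- recipes[[cls]]
    conc <- sample_concentrations(recipe, n)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", cls, i)
      ci <- as.list(conc[i, , drop = FALSE])
      for (r in seq_len(replicates))
        spectra[[length(spectra) + 1L]] <-
          generate_spectrum(recipe, ci, noise, axis,
                            sample_id = sid, replicate = r)
      dom <- if (length(recipe$components)) recipe$components[[1L]]$name
             else NA_character_
      row <- data.frame(sample_id = sid, class = cls, analyte = dom,
                        concentration_mg_per_100g =
                          if (is.na(dom)) 0 else ci[[dom]],
                        stringsAsFactors = FALSE)
      for (nm in names(ci)) row[[paste0("conc_", nm)]] <- ci[[nm]]
      meta[[idx]] <- row
    }
  }
  meta <- if (length(meta)) {
    all_cols <- unique(unlist(lapply(meta, names)))
    do.call(rbind, lapply(meta, function(r) {
      for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
      r[all_cols]
    }))
  } else {
    data.frame(sample_id = character(), class = character(),
               analyte = character(),
               concentration_mg_per_100g = numeric())
  }
  list(spectra = spectra, meta = meta)
}

#' Pigment concentration from UV-Vis absorbance (Beer-Lambert)
#'
#' Converts an absorbance reading on a hexane extract into a pigment
#' concentration in the original sample: `A/(epsilon * path)` gives mM in
#' the extract, scaled by extract volume, molar mass and sample mass to
#' mg per 100 g of fruit. Millimolar extinction coefficients of 172 and
#' 139 mM^-1 cm^-1 apply to all-trans-lycopene (503 nm) and beta-carotene
#' (451 nm) respectively.
#'
#' @param absorbance Absorbance (AU), >= 0.
#' @param epsilon_mM Millimolar extinction coefficient, mM^-1 cm^-1, > 0.
#' @param hexane_volume_L Extract volume in litres, > 0.
#' @param sample_mass_g Sample mass in grams, > 0.
#' @param molar_mass_g_per_mol Pigment molar mass, g/mol, > 0
#'   (536.87 for both lycopene and beta-carotene).
#' @param path_cm Optical path length in cm, > 0 (default 1).
#' @return Concentration in mg/100 g.
#' @export
reference_concentration <- function(absorbance, epsilon_mM, hexane_volume_L,
                                    sample_mass_g,
                                    molar_mass_g_per_mol = 536.87,
                                    path_cm = 1) {
  if (any(absorbance < 0)) stop("`absorbance` must be >= 0", call. = FALSE)
  if (epsilon_mM <= 0 || hexane_volume_L <= 0 || sample_mass_g <= 0 ||
      molar_mass_g_per_mol <= 0 || path_cm <= 0)
    stop("epsilon, volume, mass, molar mass and path must be > 0",
         call. = FALSE)
  mM <- absorbance / (epsilon_mM * path_cm)           # mmol/L in extract
  mg <- mM * hexane_volume_L * molar_mass_g_per_mol   # mg in extract
  mg / sample_mass_g * 100
}
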