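Package: ramanotype
Title: Chemometric Profiling and Quantification of Tomato Carotenoids from Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carotenoid phenotyping of tomato fruit from handheld
    Raman spectra. Provides a seeded simulator of surface Raman spectra with
    class-diagnostic nu1 (C=C stretch) band positions for all-trans-lycopene,
    tetra-cis-lycopene and beta-carotene; spectral pretreatments (standard
    normal variate, Savitzky-Golay smoothing and derivatives, mean centering,
    region selection); SIMCA classification with interclass distances,
    discriminating power and outlier diagnostics; PLS1 calibration with
    leave-one-out cross-validation; a from-scratch multilayer perceptron with
    dropout, ADAM and early stopping including sliding-window spectral
    variable selection; and end-to-end classification and quantification
    pipelines with evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
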