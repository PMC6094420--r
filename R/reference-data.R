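#' Published reference results for the ibuprofen-in-serum calibration
#'
#' Two small tables transcribed from the published ibuprofen serum study
#' this package's workflow emulates, shipped for arithmetic cross-checks
#' (the underlying spectra were never deposited, so the trained model itself
#' is not reproducible):
#'
#' * `reference_predictions()` — the 61 samples with nominal and predicted
#'   concentrations (x 1e-7 M), the reported per-sample REP%, and the set
#'   assignment implied by the published footnote markers (12 test, 9
#'   validation, 40 calibration).
#' * `reference_variance()` — the reported eigenvalue / percent variance
#'   table of the PCA on the unfolded 61 x 12030 matrix (first 20
#'   components).
#'
#' @return A data.frame.
#' @export
reference_predictions <- function() {
  utils::read.csv(system.file("extdata", "reported_predictions.csv",
                              package = "eemcalib"))
}

#' @rdname reference_predictions
#' @export
reference_variance <- function() {
  utils::read.csv(system.file("extdata", "reported_variance.csv",
                              package = "eemcalib"))
}
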