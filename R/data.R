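#' Published per-patient labeled-pixel counts
#'
#' The per-patient, per-class labeled-pixel counts of the 13 high-grade
#' glioma images of the intraoperative dataset (the raw images themselves
#' are private). Useful for recomputing the dataset's class-balance
#' arithmetic and for choosing realistic class-imbalance profiles for the
#' phantom generator.
#'
#' @return A data.frame with columns `patient`, `healthy`, `tumor`,
#'   `venous`, `arterial`, `dura`.
#' @export
tissue_pixel_counts <- function() {
  utils::read.csv(system.file("extdata", "tissue_pixel_counts.csv",
                              package = "hsibrain"))
}

#' Published camera-comparison table (overall accuracy vs band count)
#'
#' Overall accuracies and spectral band counts of brain-tissue
#' classification systems reported in the literature, including the
#' 25-band snapshot approaches. Input to [oacc_per_band()].
#'
#' @return A data.frame with columns `approach`, `oacc_percent`, `n_bands`.
#' @export
band_comparison <- function() {
  utils::read.csv(system.file("extdata", "band_comparison.csv",
                              package = "hsibrain"),
                  check.names = FALSE)
}
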