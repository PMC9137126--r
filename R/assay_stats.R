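#' Flow-cytometry Stain Index
#'
#' Separation measure between a stained population and its background:
#' `(mean positive - mean background) / (2 * SD background)`.
#'
#' @param mean_positive Mean fluorescence of the positive population
#'   (arbitrary units).
#' @param mean_background Mean fluorescence of the background population.
#' @param sd_background Standard deviation of the background; must be
#'   strictly positive.
#' @return Numeric stain index (vectorised).
#' @export
stain_index <- function(mean_positive, mean_background, sd_background) {
  if (any(sd_background <= 0)) stopf("sd_background must be strictly positive")
  (mean_positive - mean_background) / (2 * sd_background)
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Relative expression of a target gene in a sample versus a calibrator,
#' both normalised to a shared reference gene:
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_calibrator - Ct_ref_calibrator)` and the fold change is
#' `2^-ddCt`. Strictly decreasing in ddCt.
#'
#' @param ct_target_sample,ct_ref_sample Target / reference-gene Ct in the
#'   sample.
#' @param ct_target_calibrator,ct_ref_calibrator Target / reference-gene Ct
#'   in the calibrator.
#' @return Fold change `2^-ddCt` (vectorised).
#' @export
relative_quant <- function(ct_target_sample, ct_ref_sample,
                           ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stopf("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
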