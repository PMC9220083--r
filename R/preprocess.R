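#' Region-wise preprocessing for the multi-block path
#'
#' The preprocessing applied independently to each spectral region before
#' multi-block analysis, in order: restrict to the region, Savitzky-Golay
#' second differentiation with the region's window (per contiguous segment),
#' then EMSC with linear and quadratic terms against the mean derivative
#' spectrum of the set. The derivative removes broad baselines and sharpens
#' overlapping bands; EMSC then removes the remaining multiplicative
#' (path-length / biomass) differences between spectra.
#'
#' @param x A `spectra_set` on the acquisition grid.
#' @param region A [region_spec()] or one of `"lipid"`, `"protein"`,
#'   `"mixed"`, `"polysaccharide"` (must have `sg_deriv = 2`).
#' @return The EMSC-corrected derivative `spectra_set` (region grid), with
#'   attributes `emsc_coefficients` and `emsc_excluded` carrying the fit
#'   report.
#' @export
preprocess_for_multiblock <- function(x, region) {
  if (is.character(region)) region <- region_spec(region)
  if (region$sg_deriv != 2) {
    stop("region '", region$name,
         "' is not a derivative region; use preprocess_for_correlation()")
  }
  out <- x |>
    split_region(region) |>
    sg_second_derivative(region) |>
    emsc_correct()
  res <- out$corrected
  attr(res, "emsc_coefficients") <- out$coefficients
  attr(res, "emsc_excluded") <- out$excluded
  attr(res, "emsc_reference") <- out$reference
  res
}

#' Wide-region preprocessing for the correlation path
#'
#' The correlation analysis pools all growth conditions of a genus as rows of
#' one matrix; its spectra are restricted to the 3050-2800 and 1800-900 cm^-1
#' intervals and EMSC-normalized (linear and quadratic terms) without
#' differentiation, so peak absorbances stay directly interpretable.
#'
#' @param x A `spectra_set` whose grid covers both intervals.
#' @return The EMSC-corrected `spectra_set` on the wide region grid, with
#'   attributes `emsc_coefficients` and `emsc_excluded`.
#' @export
preprocess_for_correlation <- function(x) {
  region <- region_spec("correlation_wide")
  out <- x |>
    split_region(region) |>
    emsc_correct()
  res <- out$corrected
  attr(res, "emsc_coefficients") <- out$coefficients
  attr(res, "emsc_excluded") <- out$excluded
  attr(res, "emsc_reference") <- out$reference
  res
}
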