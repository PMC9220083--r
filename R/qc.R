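#' Quality-control configuration
#'
#' Three transparent screening criteria applied to raw absorbance spectra
#' before any preprocessing: a floor on the peak signal in a protein-band
#' window (too little biomass), a ceiling on the absorbance anywhere
#' (detector saturation), and a floor on the signal-to-noise ratio. SNR is
#' the peak height in the signal window (max minus min) divided by the
#' standard deviation of the linearly detrended absorbance in a quiet window
#' free of biological bands.
#'
#' @param min_peak_absorbance Minimum peak height in the signal window.
#' @param max_absorbance Saturation ceiling for any grid point.
#' @param min_snr Minimum signal-to-noise ratio.
#' @param noise_window_cm1 Quiet window `[lo, hi]` used for the noise estimate.
#' @param noise_exclude_cm1 Optional interval excluded from the noise window
#'   (e.g. atmospheric CO2 around 2300-2400 cm^-1); may be disjoint from it,
#'   in which case it has no effect.
#' @param signal_window_cm1 Window `[lo, hi]` holding the reference signal band
#'   (default covers the Amide I protein band).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_peak_absorbance = 0.05,
                      max_absorbance = 2.0,
                      min_snr = 20,
                      noise_window_cm1 = c(1900, 2200),
                      noise_exclude_cm1 = c(2300, 2400),
                      signal_window_cm1 = c(1600, 1700)) {
  stopifnot(min_peak_absorbance > 0, max_absorbance > 0, min_snr > 0,
            length(noise_window_cm1) == 2, length(signal_window_cm1) == 2)
  structure(list(
    min_peak_absorbance = min_peak_absorbance,
    max_absorbance = max_absorbance,
    min_snr = min_snr,
    noise_window_cm1 = sort(as.numeric(noise_window_cm1)),
    noise_exclude_cm1 = sort(as.numeric(noise_exclude_cm1)),
    signal_window_cm1 = sort(as.numeric(signal_window_cm1))
  ), class = "qc_config")
}

in_window <- function(grid, w) grid >= w[1] & grid <= w[2]

#' Screen spectra for quality
#'
#' Classifies every spectrum of a set as passing or failing the configured
#' criteria. The first criterion violated determines the reason, checked in
#' the order `low_signal` (peak height in the signal window below the floor),
#' `saturated` (any absorbance above the ceiling), `low_snr`. The check is
#' deterministic and per-spectrum, so permuting the input permutes the output
#' identically, and raising `min_snr` can only move spectra from pass to fail.
#'
#' @param x A `spectra_set` whose grid covers the configured windows.
#' @param config A [qc_config()].
#' @return A list with elements `pass` (a `spectra_set`) and `fail` (a tibble
#'   with columns `sample_id`, `reason`).
#' @export
quality_check <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "spectra_set"), inherits(config, "qc_config"))
  sig_idx <- which(in_window(x$grid, config$signal_window_cm1))
  noise_idx <- which(in_window(x$grid, config$noise_window_cm1) &
                       !in_window(x$grid, config$noise_exclude_cm1))
  if (length(sig_idx) < 2) {
    stop("signal window [", config$signal_window_cm1[1], ", ",
         config$signal_window_cm1[2], "] not covered by the grid")
  }
  if (length(noise_idx) < 4) {
    stop("noise window [", config$noise_window_cm1[1], ", ",
         config$noise_window_cm1[2], "] not covered by the grid")
  }
  nu <- x$grid[noise_idx]
  reasons <- vapply(seq_len(n_spectra(x)), function(i) {
    z <- x$values[i, ]
    peak <- max(z[sig_idx]) - min(z[sig_idx])
    if (peak < config$min_peak_absorbance) return("low_signal")
    if (max(z) > config$max_absorbance) return("saturated")
    res <- stats::lm.fit(cbind(1, nu), z[noise_idx])$residuals
    noise_sd <- stats::sd(res)
    if (noise_sd > 0 && peak / noise_sd < config$min_snr) return("low_snr")
    ""
  }, character(1))
  ok <- reasons == ""
  list(
    pass = subset_spectra(x, which(ok)),
    fail = tibble::tibble(sample_id = x$meta$sample_id[!ok],
                          reason = reasons[!ok])
  )
}
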