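#' Extended multiplicative signal correction
#'
#' Removes multiplicative gain and a polynomial baseline from each spectrum
#' by ordinary least squares against a reference spectrum. Each spectrum `z`
#' is modelled as
#'
#'   z = a + b * m + d * u + e * u^2 + residual
#'
#' where `m` is the reference (by default the pointwise mean of the set being
#' corrected), and `u` is the wavenumber axis min-max rescaled to \[-1, 1\]
#' over the set's grid, which conditions the polynomial terms numerically.
#' The corrected spectrum is `z* = (z - a - d*u - e*u^2) / b`, so correcting
#' the reference itself returns it unchanged and the correction is invariant
#' to rescaling an input by a positive constant or adding any polynomial in
#' `u` up to the chosen degree.
#'
#' Spectra whose fitted gain `b` has magnitude below `gain_floor` carry
#' essentially no reference signal and cannot be meaningfully divided by `b`;
#' they are excluded from the corrected set and reported, never silently
#' corrected.
#'
#' @param x A `spectra_set` with at least one spectrum and >= 4 grid points.
#' @param reference Optional reference spectrum (numeric vector on the grid of
#'   `x`); defaults to the pointwise mean of the set.
#' @param poly_degree Degree of the polynomial baseline terms (default 2,
#'   i.e. linear plus quadratic).
#' @param gain_floor Magnitude below which a fitted gain is degenerate.
#' @return A list of class `emsc_result` with elements `corrected` (a
#'   `spectra_set`), `reference`, `coefficients` (tibble: `sample_id`,
#'   `offset`, `gain`, `poly_1` ... `poly_<degree>`), and `excluded` (tibble:
#'   `sample_id`, `reason`).
#' @export
emsc_correct <- function(x, reference = NULL, poly_degree = 2,
                         gain_floor = 1e-8) {
  stopifnot(inherits(x, "spectra_set"), n_spectra(x) >= 1)
  if (length(x$grid) < poly_degree + 2) {
    stop("grid too short (", length(x$grid), " points) for EMSC with degree ",
         poly_degree)
  }
  if (is.null(reference)) reference <- colMeans(x$values)
  reference <- as.numeric(reference)
  if (length(reference) != length(x$grid)) {
    stop("reference length ", length(reference), " does not match grid length ",
         length(x$grid))
  }
  u <- rescale_u(x$grid)
  poly_terms <- if (poly_degree >= 1) {
    vapply(seq_len(poly_degree), function(k) u^k, numeric(length(u)))
  } else {
    matrix(numeric(0), nrow = length(u), ncol = 0)
  }
  M <- cbind(offset = 1, gain = reference, poly_terms)
  # one QR factorization serves every spectrum in the set
  coefs <- qr.coef(qr(M), t(x$values))
  coefs <- matrix(coefs, nrow = ncol(M),
                  dimnames = list(NULL, x$meta$sample_id))
  b <- coefs[2, ]
  degenerate <- !is.finite(b) | abs(b) < gain_floor
  baseline <- M[, -2, drop = FALSE] %*% coefs[-2, , drop = FALSE]
  corrected_t <- sweep(t(x$values) - baseline, 2, b, "/")
  keep <- which(!degenerate)
  corrected <- spectra_set(t(corrected_t[, keep, drop = FALSE]), x$grid,
                           x$meta[keep, , drop = FALSE])
  attr(corrected, "segments") <- attr(x, "segments")
  attr(corrected, "region") <- attr(x, "region")
  coef_tbl <- tibble::tibble(sample_id = x$meta$sample_id,
                             offset = unname(coefs[1, ]), gain = unname(b))
  if (poly_degree >= 1) {
    for (k in seq_len(poly_degree)) {
      coef_tbl[[paste0("poly_", k)]] <- unname(coefs[2 + k, ])
    }
  }
  structure(list(
    corrected = corrected,
    reference = reference,
    coefficients = coef_tbl[keep, , drop = FALSE],
    excluded = tibble::tibble(
      sample_id = x$meta$sample_id[degenerate],
      reason = rep("gain_degenerate", sum(degenerate))
    )
  ), class = "emsc_result")
}

rescale_u <- function(grid) {
  rng <- range(grid)
  if (rng[1] == rng[2]) return(rep(0, length(grid)))
  2 * (grid - rng[1]) / (rng[2] - rng[1]) - 1
}

#' @export
print.emsc_result <- function(x, ...) {
  cat("<emsc_result> ", n_spectra(x$corrected), " corrected spectra",
      if (nrow(x$excluded) > 0) paste0(", ", nrow(x$excluded), " excluded"),
      "\n", sep = "")
  invisible(x)
}

#' Per-spectrum EMSC coefficients
#' @param x An `emsc_result`.
#' @param ... Unused.
#' @return The coefficients tibble (`sample_id`, `offset`, `gain`, `poly_*`).
#' @method tidy emsc_result
#' @export
tidy.emsc_result <- function(x, ...) x$coefficients

#' One-row EMSC fit summary
#' @param x An `emsc_result`.
#' @param ... Unused.
#' @return A tibble with spectrum counts and the gain spread.
#' @method glance emsc_result
#' @export
glance.emsc_result <- function(x, ...) {
  tibble::tibble(
    n_corrected = n_spectra(x$corrected),
    n_excluded = nrow(x$excluded),
    gain_sd = stats::sd(x$coefficients$gain)
  )
}
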