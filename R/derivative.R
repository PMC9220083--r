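#' Savitzky-Golay second derivative of a spectra set
#'
#' Computes the second derivative of every spectrum by local least-squares
#' polynomial fitting over a sliding odd-length window (Savitzky-Golay),
#' independently per contiguous segment of the region grid, so that the
#' window never spans the gap of a split region such as the lipid region.
#' Boundary points are handled by evaluating the local polynomial fitted to
#' the first/last window of the segment, so the output has the same length
#' as the input. Values are scaled by 1/dnu^2, giving grid-spacing-invariant
#' units of absorbance * cm^2; for spectra that are polynomials of degree
#' <= the fit order the result is exact (a linear spectrum differentiates
#' to exactly zero).
#'
#' @param x A `spectra_set`, typically the output of [split_region()].
#' @param region A [region_spec()] or region name supplying `sg_window` and
#'   `sg_polyorder`; defaults to the region recorded on `x`.
#' @return A `spectra_set` of second-derivative spectra on the same grid.
#' @export
sg_second_derivative <- function(x, region = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.null(region)) {
    nm <- attr(x, "region")
    if (is.null(nm)) stop("no region recorded on the input; pass `region`")
    region <- region_spec(nm)
  }
  if (is.character(region)) region <- region_spec(region)
  n <- region$sg_window
  p <- region$sg_polyorder
  stopifnot(n %% 2 == 1, n > p)
  seg <- region_segments(x)
  out <- x$values
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) < n) {
      stop("segment ", s, " of region '", region$name, "' has ", length(idx),
           " points, fewer than the window size ", n)
    }
    nu <- x$grid[idx]
    d <- diff(nu)
    dx <- mean(d)
    if (max(abs(d - dx)) > 1e-6 * abs(dx)) {
      stop("non-uniform grid spacing within segment ", s, " of region '",
           region$name, "'")
    }
    D <- sg_filter_matrix(length(idx), p, n, m = 2L, dx = dx)
    # remove a per-spectrum linear trend first: a second-derivative filter
    # annihilates it exactly, and the smaller residual magnitude keeps the
    # filter output well conditioned for large absolute signal values
    Z <- x$values[, idx, drop = FALSE]
    Z <- Z - rowMeans(Z) # keeps magnitudes small before the trend fit
    basis <- cbind(1, nu - mean(nu))
    trend <- t(qr.fitted(qr(basis), t(Z)))
    out[, idx] <- (Z - trend) %*% t(D)
  }
  res <- spectra_set(out, x$grid, x$meta)
  attr(res, "segments") <- seg
  attr(res, "region") <- region$name
  res
}

# Dense L x L differentiation operator: central Savitzky-Golay filter row in
# the interior, asymmetric boundary rows (polynomial evaluated off-centre)
# at the edges, as in signal::sgolayfilt.
sg_filter_matrix <- function(L, p, n, m, dx) {
  FF <- unclass(signal::sgolay(p = p, n = n, m = m, ts = dx))
  k <- (n - 1L) / 2L
  D <- matrix(0, L, L)
  for (i in seq_len(L)) {
    if (i <= k) {
      D[i, 1:n] <- FF[i, ]
    } else if (i > L - k) {
      D[i, (L - n + 1L):L] <- FF[n - (L - i), ]
    } else {
      D[i, (i - k):(i + k)] <- FF[k + 1L, ]
    }
  }
  D
}
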