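#' Spectral region registry
#'
#' The four biochemical regions the analysis splits mid-IR spectra into,
#' with their Savitzky-Golay window sizes, plus the wide region used by the
#' correlation analysis (which is EMSC-normalized without differentiation):
#'
#' * `lipid`: 3050-2800 and 1800-1700 cm^-1, window 13
#' * `protein`: 1700-1500 cm^-1, window 21
#' * `mixed`: 1500-1200 cm^-1, window 17
#' * `polysaccharide`: 1200-700 cm^-1, window 13
#' * `correlation_wide`: 3050-2800 and 1800-900 cm^-1, no derivative
#'
#' @return `ftir_regions()` returns a tibble with one row per (region,
#'   interval); `region_spec()` returns the full specification of one region.
#' @export
ftir_regions <- function() {
  tibble::tibble(
    name = c("lipid", "lipid", "protein", "mixed", "polysaccharide",
             "correlation_wide", "correlation_wide"),
    lo_cm1 = c(2800, 1700, 1500, 1200, 700, 2800, 900),
    hi_cm1 = c(3050, 1800, 1700, 1500, 1200, 3050, 1800),
    sg_window = c(13L, 13L, 21L, 17L, 13L, 13L, 13L),
    sg_polyorder = 2L,
    sg_deriv = c(2L, 2L, 2L, 2L, 2L, 0L, 0L)
  )
}

#' @rdname ftir_regions
#' @param name One of `"lipid"`, `"protein"`, `"mixed"`, `"polysaccharide"`,
#'   `"correlation_wide"`.
#' @export
region_spec <- function(name) {
  reg <- ftir_regions()
  rows <- reg[reg$name == name, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown region '", name, "'; known regions: ",
         paste(unique(reg$name), collapse = ", "))
  }
  rows <- rows[order(rows$lo_cm1), , drop = FALSE]
  structure(list(
    name = name,
    intervals_cm1 = purrr::map2(rows$lo_cm1, rows$hi_cm1, c),
    sg_window = rows$sg_window[1],
    sg_polyorder = rows$sg_polyorder[1],
    sg_deriv = rows$sg_deriv[1]
  ), class = "region_spec")
}

#' Restrict a spectra set to a spectral region
#'
#' Keeps exactly the grid points falling inside any of the region's intervals
#' (inclusive ends), in ascending order, without reordering or interpolation.
#' The contiguous segments (one per interval) are recorded on the result so
#' that downstream differentiation never spans the gap of a split region such
#' as the lipid region.
#'
#' @param x A `spectra_set`.
#' @param region A [region_spec()] or region name.
#' @return A `spectra_set` on the restricted grid, with a `segments`
#'   attribute (integer segment id per grid point).
#' @export
split_region <- function(x, region) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.character(region)) region <- region_spec(region)
  seg_id <- rep(NA_integer_, length(x$grid))
  for (i in seq_along(region$intervals_cm1)) {
    iv <- region$intervals_cm1[[i]]
    seg_id[x$grid >= iv[1] & x$grid <= iv[2]] <- i
  }
  keep <- which(!is.na(seg_id))
  if (length(keep) == 0) {
    stop("grid has no points inside region '", region$name, "'")
  }
  out <- spectra_set(x$values[, keep, drop = FALSE], x$grid[keep], x$meta)
  attr(out, "segments") <- seg_id[keep]
  attr(out, "region") <- region$name
  out
}

region_segments <- function(x) {
  seg <- attr(x, "segments")
  if (is.null(seg)) rep(1L, length(x$grid)) else seg
}

#' Classify a wavenumber into a biochemical region
#'
#' Assigns each wavenumber to `lipid`, `protein`, `mixed` or `polysaccharide`
#' using the region registry (lipid checked first so the shared 1700 cm^-1
#' boundary goes to lipid's ester interval).
#'
#' @param wavenumber_cm1 Numeric vector of wavenumbers.
#' @return Character vector of region names (`NA` outside all regions).
#' @export
classify_wavenumber <- function(wavenumber_cm1) {
  reg <- ftir_regions()
  reg <- reg[reg$name != "correlation_wide", , drop = FALSE]
  order_names <- c("lipid", "protein", "mixed", "polysaccharide")
  out <- rep(NA_character_, length(wavenumber_cm1))
  for (nm in order_names) {
    rows <- reg[reg$name == nm, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      hit <- is.na(out) & wavenumber_cm1 >= rows$lo_cm1[j] &
        wavenumber_cm1 <= rows$hi_cm1[j]
      out[hit] <- nm
    }
  }
  out
}
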