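#' Average biological and technical replicates
#'
#' Pools all replicates of one (strain, medium, temperature) combination into
#' a single pointwise arithmetic mean spectrum, the prerequisite for
#' multi-block analysis where each row must correspond to one strain under
#' one growth condition. Replicate fields of the output metadata are set to 0
#' as an "averaged" sentinel.
#'
#' @param x A `spectra_set` (typically preprocessed).
#' @return A `spectra_set` with one spectrum per (strain_id, medium,
#'   temperature_c) group.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra_set"), n_spectra(x) >= 1)
  key <- paste(x$meta$strain_id, x$meta$medium, x$meta$temperature_c,
               sep = "\r")
  sums <- rowsum(x$values, group = key, reorder = TRUE)
  counts <- as.vector(table(key)[rownames(sums)])
  values <- sums / counts
  first <- x$meta[!duplicated(key), , drop = FALSE]
  first <- first[match(rownames(sums), key[!duplicated(key)]), , drop = FALSE]
  meta <- dplyr::mutate(
    first,
    sample_id = paste(.data$strain_id, .data$medium, .data$temperature_c,
                      "avg", sep = "__"),
    bio_rep = 0L, tech_rep = 0L
  )
  out <- spectra_set(values, x$grid, meta)
  attr(out, "segments") <- attr(x, "segments")
  attr(out, "region") <- attr(x, "region")
  out
}

#' Assemble media-aligned blocks for multi-block analysis
#'
#' Builds one matrix per medium, rows aligned on the (strain_id,
#' temperature_c) sample key. Only keys available in *every* listed medium
#' are retained (a strain-temperature combination missing from any block,
#' e.g. through poor growth or failed spectral quality, is removed
#' completely); all other keys are reported as dropped. Row order is
#' lexicographic in (strain_id, temperature_c), identical across blocks and
#' invariant to the order of the media list.
#'
#' @param x A `spectra_set` of averaged spectra (one per strain, medium,
#'   temperature).
#' @param media Ordered character vector of media forming the blocks.
#' @return A list of class `multiblock_data`: `keys` (tibble with
#'   `strain_id`, `temperature_c`, `genus`, `species`), `blocks` (named list
#'   of key-by-wavenumber matrices), `grid`, `media`, `region`, and
#'   `dropped` (tibble of removed keys).
#' @export
assemble_blocks <- function(x, media = ftir_media) {
  stopifnot(inherits(x, "spectra_set"), length(media) >= 1)
  bad <- setdiff(media, unique(x$meta$medium))
  key_tbl <- dplyr::mutate(
    x$meta,
    .key = paste(.data$strain_id, .data$temperature_c, sep = "\r"),
    .row = dplyr::row_number()
  )
  dup <- dplyr::count(key_tbl, .data$.key, .data$medium)
  if (any(dup$n > 1)) {
    first_dup <- dup[dup$n > 1, ][1, ]
    stop("duplicate sample after averaging: key '",
         gsub("\r", " / ", first_dup$.key), "' in medium ", first_dup$medium)
  }
  per_key <- key_tbl |>
    dplyr::filter(.data$medium %in% media) |>
    dplyr::summarise(n_media = dplyr::n_distinct(.data$medium),
                     .by = c(".key", "strain_id", "temperature_c",
                             "genus", "species")) |>
    dplyr::arrange(.data$strain_id, .data$temperature_c)
  all_keys <- key_tbl |>
    dplyr::distinct(.data$.key, .data$strain_id, .data$temperature_c) |>
    dplyr::arrange(.data$strain_id, .data$temperature_c)
  complete <- per_key[per_key$n_media == length(media), , drop = FALSE]
  dropped <- dplyr::anti_join(all_keys, complete[, ".key", drop = FALSE],
                              by = ".key")
  blocks <- lapply(stats::setNames(media, media), function(m) {
    rows <- key_tbl[key_tbl$medium == m, , drop = FALSE]
    idx <- rows$.row[match(complete$.key, rows$.key)]
    mat <- x$values[idx, , drop = FALSE]
    rownames(mat) <- paste(complete$strain_id, complete$temperature_c,
                           sep = "__")
    mat
  })
  structure(list(
    keys = tibble::as_tibble(
      complete[, c("strain_id", "temperature_c", "genus", "species")]),
    blocks = blocks,
    grid = x$grid,
    media = media,
    region = attr(x, "region"),
    dropped = tibble::as_tibble(
      dropped[, c("strain_id", "temperature_c")])
  ), class = "multiblock_data")
}

#' @export
print.multiblock_data <- function(x, ...) {
  cat("<multiblock_data> ", nrow(x$keys), " keys x ", length(x$blocks),
      " blocks (", paste(x$media, collapse = ", "), "), ",
      length(x$grid), " wavenumbers", sep = "")
  if (!is.null(x$region)) cat("; region: ", x$region, sep = "")
  cat("\n")
  if (nrow(x$dropped) > 0) cat("  dropped keys:", nrow(x$dropped), "\n")
  invisible(x)
}
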