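#' Media and temperature vocabularies
#'
#' The closed vocabularies of the cultivation design: one rich medium (BHI,
#' brain heart infusion) and four defined minimal media crossing the salt base
#' (M9 vs X9) with the carbon source (glucose vs glycerol), and the four
#' cultivation temperatures in degrees Celsius.
#'
#' @format Character / integer vectors.
#' @export
ftir_media <- c("BHI", "MGU", "MGY", "XGU", "XGY")

#' @rdname ftir_media
#' @export
ftir_temperatures <- c(4L, 10L, 18L, 25L)

meta_columns <- c(
  "sample_id", "strain_id", "genus", "species", "medium",
  "temperature_c", "bio_rep", "tech_rep"
)

#' Construct a spectra set
#'
#' A `spectra_set` holds a set of absorbance spectra that share one wavenumber
#' grid bit-identically: a samples-by-wavenumbers numeric matrix, the shared
#' grid (strictly increasing, cm^-1), and a per-sample metadata tibble
#' (`sample_id`, `strain_id`, `genus`, `species`, `medium`, `temperature_c`,
#' `bio_rep`, `tech_rep`). All downstream stages (quality control, region
#' splitting, differentiation, EMSC, fusion, CPCA) operate on this container.
#'
#' @param values Numeric matrix, one row per sample, one column per grid point.
#' @param grid Strictly increasing numeric vector of wavenumbers (cm^-1).
#' @param meta Tibble with one row per sample carrying the metadata columns.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(values, grid, meta) {
  values <- as.matrix(values)
  grid <- as.numeric(grid)
  meta <- tibble::as_tibble(meta)
  if (!all(meta_columns %in% names(meta))) {
    missing <- setdiff(meta_columns, names(meta))
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  meta$temperature_c <- as.integer(meta$temperature_c)
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  if (nrow(values) != nrow(meta)) {
    stop("values has ", nrow(values), " rows but metadata has ", nrow(meta))
  }
  if (ncol(values) != length(grid)) {
    stop("values has ", ncol(values), " columns but grid has ", length(grid))
  }
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("wavenumber grid must be strictly increasing")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (nrow(values) > 0 && !all(is.finite(values))) {
    bad <- meta$sample_id[!apply(is.finite(values), 1, all)]
    stop("non-finite absorbance values in sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  check_vocab(meta)
  rownames(values) <- meta$sample_id
  structure(list(values = values, grid = grid, meta = meta),
            class = "spectra_set")
}

check_vocab <- function(meta) {
  bad_med <- setdiff(unique(meta$medium), ftir_media)
  if (length(bad_med) > 0) {
    stop("unknown medium value(s): ", paste(bad_med, collapse = ", "))
  }
  bad_t <- setdiff(unique(meta$temperature_c), ftir_temperatures)
  if (length(bad_t) > 0) {
    stop("unknown temperature value(s): ", paste(bad_t, collapse = ", "))
  }
  invisible(meta)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$values), " spectra x ", length(x$grid),
      " wavenumbers", sep = "")
  if (length(x$grid) > 0) {
    cat(" [", min(x$grid), ", ", max(x$grid), " cm-1]", sep = "")
  }
  cat("\n")
  if (nrow(x$meta) > 0) {
    cat("  media: ", paste(sort(unique(x$meta$medium)), collapse = ", "),
        "; temperatures: ",
        paste(sort(unique(x$meta$temperature_c)), collapse = ", "),
        " degC\n", sep = "")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param x A `spectra_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  nrow(x$values)
}

#' Convert a spectra set to a long tibble
#'
#' One row per (sample, wavenumber) with the absorbance and the sample
#' metadata joined on, ready for dplyr/ggplot2 work.
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavenumber_cm1`, `absorbance`
#'   and the metadata columns.
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  if (nrow(x$values) == 0) {
    return(tibble::tibble(sample_id = character(), wavenumber_cm1 = numeric(),
                          absorbance = numeric()))
  }
  long <- tibble::tibble(
    sample_id = rep(x$meta$sample_id, each = length(x$grid)),
    wavenumber_cm1 = rep(x$grid, times = nrow(x$values)),
    absorbance = as.vector(t(x$values))
  )
  dplyr::left_join(long, x$meta, by = "sample_id")
}

#' @method tidy spectra_set
#' @export
tidy.spectra_set <- function(x, ...) as_tibble.spectra_set(x, ...)

#' Filter the spectra of a set by metadata
#'
#' Keeps the spectra whose metadata rows satisfy the dplyr-style conditions,
#' e.g. `filter_spectra(ss, genus == "Arthrobacter", medium == "BHI")`.
#'
#' @param x A `spectra_set`.
#' @param ... Logical conditions evaluated in the metadata tibble.
#' @return A `spectra_set` restricted to the matching samples.
#' @export
filter_spectra <- function(x, ...) {
  stopifnot(inherits(x, "spectra_set"))
  keep <- dplyr::filter(dplyr::mutate(x$meta, .row = dplyr::row_number()), ...)
  subset_spectra(x, keep$.row)
}

subset_spectra <- function(x, idx) {
  spectra_set(x$values[idx, , drop = FALSE], x$grid, x$meta[idx, , drop = FALSE])
}

#' Plot the spectra of a set
#'
#' Absorbance traces against wavenumber, one line per spectrum, with the
#' conventional reversed (descending) wavenumber axis.
#'
#' @param object A `spectra_set`.
#' @param colour_by Metadata column used for the line colour (default genus).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectra_set
#' @export
autoplot.spectra_set <- function(object, colour_by = "genus", ...) {
  long <- as_tibble.spectra_set(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavenumber_cm1, y = .data$absorbance,
    group = .data$sample_id, colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance") +
    ggplot2::theme_minimal()
}

#' Read spectra from a wide matrix CSV plus a metadata CSV
#'
#' The matrix file is a wide CSV whose first column is `wavenumber_cm1` and
#' whose remaining columns are absorbance traces keyed by `sample_id`; the
#' metadata file has one row per sample. Instrument files listing the grid in
#' descending (4000 to 500 cm^-1) order are reversed on read: the grid is
#' always stored ascending.
#'
#' @param path_matrix Path to the wide spectral matrix CSV.
#' @param path_meta Path to the sample metadata CSV.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path_matrix, path_meta) {
  # parse numbers via base R strtod (correctly rounded to the last ulp)
  mat <- readr::read_csv(path_matrix, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  meta <- readr::read_csv(path_meta, show_col_types = FALSE, progress = FALSE)
  if (names(mat)[1] != "wavenumber_cm1") {
    stop("first column of the matrix file must be 'wavenumber_cm1', got '",
         names(mat)[1], "'")
  }
  for (col in names(mat)) {
    v <- suppressWarnings(as.numeric(mat[[col]]))
    if (anyNA(v) && !all(is.na(mat[[col]]) == is.na(v))) {
      stop("non-numeric cells in matrix column '", col, "'")
    }
    mat[[col]] <- v
  }
  grid <- mat$wavenumber_cm1
  if (anyDuplicated(grid)) stop("duplicated wavenumbers in matrix file")
  if (length(grid) > 1) {
    d <- diff(grid)
    if (all(d < 0)) {
      mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
      grid <- rev(grid)
    } else if (!all(d > 0)) {
      stop("wavenumbers must be monotone (ascending or descending)")
    }
  }
  ids_matrix <- setdiff(names(mat), "wavenumber_cm1")
  missing_meta <- setdiff(ids_matrix, meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("sample(s) in matrix but not in metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  missing_mat <- setdiff(meta$sample_id, ids_matrix)
  if (length(missing_mat) > 0) {
    stop("sample(s) in metadata but not in matrix: ",
         paste(missing_mat, collapse = ", "))
  }
  meta <- meta[match(ids_matrix, meta$sample_id), , drop = FALSE]
  values <- t(as.matrix(mat[, ids_matrix, drop = FALSE]))
  spectra_set(values, grid, meta)
}

#' Write spectra to a wide matrix CSV plus a metadata CSV
#'
#' Inverse of [read_spectra()]: serializes with shortest round-trip decimal
#' representation so that read-after-write reproduces grid and values
#' bit-identically.
#'
#' @param x A `spectra_set`.
#' @param path_matrix Output path for the wide spectral matrix CSV.
#' @param path_meta Output path for the metadata CSV.
#' @return Invisibly, `x`.
#' @export
write_spectra <- function(x, path_matrix, path_meta) {
  stopifnot(inherits(x, "spectra_set"))
  wide <- tibble::as_tibble(as.data.frame(t(x$values)))
  names(wide) <- x$meta$sample_id
  wide <- dplyr::bind_cols(tibble::tibble(wavenumber_cm1 = x$grid), wide)
  # 17 significant digits guarantee an exact double round trip
  wide <- dplyr::mutate(wide, dplyr::across(dplyr::everything(),
                                            function(v) sprintf("%.17g", v)))
  readr::write_csv(wide, path_matrix, progress = FALSE)
  readr::write_csv(x$meta[, meta_columns], path_meta, progress = FALSE)
  invisible(x)
}

#' Read a single JCAMP-DX spectrum
#'
#' Minimal ingestion of a JCAMP-DX file with an `XYDATA=(X++(Y..Y))` block in
#' AFFN (plain decimal) form, as produced by common FTIR export tools. The x
#' axis is taken as wavenumber (cm^-1) and y as absorbance; descending files
#' are reversed so the grid is stored ascending.
#'
#' @param path Path to the JCAMP-DX file.
#' @param meta Optional one-row metadata tibble; defaults are filled from the
#'   file `##TITLE` with placeholder design fields (`medium = "BHI"`,
#'   `temperature_c = 18`).
#' @return A `spectra_set` holding one spectrum.
#' @export
read_jcamp <- function(path, meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  title <- sub("^##TITLE=\\s*", "", grep("^##TITLE=", lines, value = TRUE)[1])
  get_num <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(sub(paste0("^##", key, "=\\s*"), "", ln[1]))
  }
  xfactor <- get_num("XFACTOR"); if (is.na(xfactor)) xfactor <- 1
  yfactor <- get_num("YFACTOR"); if (is.na(yfactor)) yfactor <- 1
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0) stop("no ##XYDATA= block in ", path)
  end <- grep("^##END=", lines)
  end <- min(end[end > start[1]], length(lines) + 1)
  body <- lines[(start[1] + 1):(end - 1)]
  xs <- c(); ys <- c()
  for (ln in body) {
    nums <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    nums <- nums[!is.na(nums)]
    if (length(nums) < 2) next
    x0 <- nums[1] * xfactor
    yv <- nums[-1] * yfactor
    # abscissa spacing from DELTAX if given, else filled in after the loop
    xs <- c(xs, x0)
    ys <- c(ys, list(yv))
  }
  deltax <- get_num("DELTAX")
  if (is.na(deltax)) {
    npts <- length(ys[[1]])
    deltax <- if (length(xs) > 1) (xs[2] - xs[1]) / npts else 1
  }
  grid <- unlist(purrr::map2(xs, ys, function(x0, yv) {
    x0 + deltax * (seq_along(yv) - 1)
  }))
  y <- unlist(ys)
  if (length(grid) > 1 && grid[1] > grid[length(grid)]) {
    grid <- rev(grid); y <- rev(y)
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(
      sample_id = if (is.na(title) || title == "") basename(path) else title,
      strain_id = "unknown", genus = "unknown", species = "unknown",
      medium = "BHI", temperature_c = 18L, bio_rep = 1L, tech_rep = 1L
    )
  }
  spectra_set(matrix(y, nrow = 1), grid, meta)
}
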