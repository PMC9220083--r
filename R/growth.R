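#' Growth-score bands and their colour grades
#'
#' The streak-plate growth scale used for daily visual evaluation, expressed
#' as score bands with a colour grade per band: 0 and 1-2 red, 3-4 orange,
#' 5-6 yellow, 7-8 blue, 9-10 green. Bands combine which of the four streak
#' areas show growth with the single-colony diameter.
#'
#' @format `growth_bands` is the ordered vector of band labels;
#'   `growth_band_color()` maps bands to grade colours.
#' @export
growth_bands <- c("0", "1-2", "3-4", "5-6", "7-8", "9-10")

#' @rdname growth_bands
#' @param band Character vector of band labels.
#' @return Character vector of grade colours.
#' @export
growth_band_color <- function(band) {
  map <- c("0" = "red", "1-2" = "red", "3-4" = "orange", "5-6" = "yellow",
           "7-8" = "blue", "9-10" = "green")
  unknown <- setdiff(unique(band), names(map))
  if (length(unknown) > 0) {
    stop("unknown growth band(s): ", paste(unknown, collapse = ", "))
  }
  unname(map[band])
}

band_rank <- function(band) match(band, growth_bands) - 1L

#' Score streak-plate growth observations
#'
#' Maps raw streak-plate observations to the 0-10 banded growth scale:
#' no growth in any area is band 0; growth only at the inoculation/first
#' streak area without single colonies is 1-2; growth reaching the second
#' streak area with single colonies below 0.5 mm is 3-4; growth on all four
#' areas scores by colony diameter - 0.5-1.0 mm is 5-6, 1.5-2.0 mm is 7-8,
#' above 2.5 mm is 9-10. Diameters in the scale's unmapped gaps (1.0-1.5 and
#' 2.0-2.5 mm) are conservatively assigned to the lower adjacent band, as are
#' observed combinations the scale does not enumerate (e.g. colonies on all
#' areas below 0.5 mm). The mapping is monotone in colony diameter.
#'
#' @param obs Tibble of observations with columns `strain_id`, `medium`,
#'   `temperature_c`, `areas_with_growth` (either a list-column of integer
#'   vectors or strings like `"1;2;3"`; must be a prefix of 1..4),
#'   `single_colonies_present` (logical), `colony_diameter_mm` (numeric,
#'   `NA` allowed when no colonies), and optionally `days_to_growth`.
#' @return The input tibble with `band` and `grade_color` columns appended.
#' @export
score_growth <- function(obs) {
  obs <- tibble::as_tibble(obs)
  areas <- parse_areas(obs$areas_with_growth)
  n_areas <- vapply(areas, length, integer(1))
  ok_prefix <- vapply(areas, function(a) identical(a, seq_len(length(a))),
                      logical(1))
  if (any(!ok_prefix)) {
    stop("areas_with_growth must be a prefix of 1..4 (growth cannot skip an ",
         "area); offending row(s): ",
         paste(utils::head(which(!ok_prefix), 5), collapse = ", "))
  }
  colonies <- obs$single_colonies_present
  d <- obs$colony_diameter_mm
  if (any(!is.na(d) & d < 0)) stop("colony_diameter_mm must be >= 0")
  inconsistent <- n_areas == 0 & (colonies | (!is.na(d) & d > 0))
  if (any(inconsistent)) {
    stop("inconsistent observation(s): colonies reported without any growth ",
         "area; row(s): ",
         paste(utils::head(which(inconsistent), 5), collapse = ", "))
  }
  need_d <- n_areas == 4 & colonies & is.na(d)
  if (any(need_d)) {
    stop("colony_diameter_mm required when colonies are present on all ",
         "areas; row(s): ",
         paste(utils::head(which(need_d), 5), collapse = ", "))
  }
  band <- dplyr::case_when(
    n_areas == 0 ~ "0",
    !colonies ~ "1-2",
    n_areas == 1 ~ "1-2",
    n_areas < 4 ~ "3-4",
    d < 0.5 ~ "3-4",
    d < 1.5 ~ "5-6",
    d <= 2.5 ~ "7-8",
    .default = "9-10"
  )
  obs$band <- band
  obs$grade_color <- growth_band_color(band)
  obs
}

parse_areas <- function(a) {
  if (is.list(a)) {
    lapply(a, function(v) sort(as.integer(v)))
  } else {
    lapply(as.character(a), function(s) {
      if (is.na(s) || trimws(s) == "") return(integer(0))
      sort(as.integer(strsplit(s, "[;, ]+")[[1]]))
    })
  }
}

#' Summarize scored growth observations
#'
#' Aggregates a scored growth table into band counts per genus, medium and
#' temperature, and a per-strain flag for minimal-medium competence:
#' `grows_on_minimal` is true when the strain reaches band 3-4 or better on
#' any of the defined minimal media (MGU, MGY, XGU, XGY) at any temperature.
#' Counts are conserved: the band counts of each stratum sum to its row
#' count.
#'
#' @param scored Output of [score_growth()] (must carry a `band` column). A
#'   `genus` column is used if present, otherwise supply `strains`.
#' @param strains Optional tibble (`strain_id`, `genus`) used to attach
#'   genera when `scored` lacks a `genus` column.
#' @return A list of class `growth_summary`: `band_counts` (tibble: `genus`,
#'   `medium`, `temperature_c`, `band`, `n`) and `strain_growth` (tibble:
#'   `strain_id`, `genus`, `grows_on_minimal`).
#' @export
summarize_growth <- function(scored, strains = NULL) {
  scored <- tibble::as_tibble(scored)
  if (nrow(scored) == 0) stop("empty growth table")
  if (!"band" %in% names(scored)) {
    stop("no 'band' column; run score_growth() first")
  }
  if (!"genus" %in% names(scored)) {
    if (is.null(strains)) stop("no 'genus' column and no strains table given")
    scored <- dplyr::left_join(scored, strains[, c("strain_id", "genus")],
                               by = "strain_id")
  }
  minimal <- setdiff(ftir_media, "BHI")
  band_counts <- scored |>
    dplyr::count(.data$genus, .data$medium, .data$temperature_c, .data$band,
                 name = "n") |>
    dplyr::arrange(.data$genus, .data$medium, .data$temperature_c, .data$band)
  strain_growth <- scored |>
    dplyr::summarise(
      grows_on_minimal = any(.data$medium %in% minimal &
                               band_rank(.data$band) >= band_rank("3-4")),
      .by = c("strain_id", "genus")
    ) |>
    dplyr::arrange(.data$strain_id)
  structure(list(band_counts = band_counts, strain_growth = strain_growth),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat("<growth_summary> ", nrow(x$strain_growth), " strains, ",
      sum(x$strain_growth$grows_on_minimal),
      " grow on minimal media\n", sep = "")
  invisible(x)
}

#' Growth-grade grid plot
#'
#' Tile chart of scored growth observations - strains on the x axis, medium
#' by temperature on the y axis, tiles coloured by the band's grade colour -
#' mirroring the tabular colour-grade presentation of streak-plate scores.
#'
#' @param scored Output of [score_growth()].
#' @return A ggplot object.
#' @export
plot_growth_grid <- function(scored) {
  stopifnot("band" %in% names(scored))
  d <- dplyr::mutate(
    tibble::as_tibble(scored),
    condition = paste0(.data$medium, " ", .data$temperature_c, "C"),
    band = factor(.data$band, levels = growth_bands)
  )
  pal <- c("0" = "#d73027", "1-2" = "#d73027", "3-4" = "#fc8d59",
           "5-6" = "#fee08b", "7-8" = "#4575b4", "9-10" = "#1a9850")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strain_id, y = .data$condition,
                                  fill = .data$band)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Score band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
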