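#' Antarctic green-snow isolate collection
#'
#' The 45 fast-growing bacterial isolates from Antarctic green snow that
#' define the study design: nine genera of Actinobacteria and
#' Proteobacteria, identified by their culture-collection accession
#' (BIM B-XXXX).
#'
#' @return A tibble (`strain_id`, `genus`, `species`), 45 rows.
#' @export
green_snow_strains <- function() {
  tibble::tribble(
    ~strain_id,   ~genus,                 ~species,
    "BIM B-1627", "Arthrobacter",         "Arthrobacter cryoconiti",
    "BIM B-1663", "Arthrobacter",         "Arthrobacter oryzae",
    "BIM B-1624", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1625", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1626", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1628", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1664", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1666", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1656", "Arthrobacter",         "Arthrobacter sp.",
    "BIM B-1619", "Cryobacterium",        "Cryobacterium arcticum",
    "BIM B-1620", "Cryobacterium",        "Cryobacterium arcticum",
    "BIM B-1658", "Cryobacterium",        "Cryobacterium soli",
    "BIM B-1659", "Cryobacterium",        "Cryobacterium soli",
    "BIM B-1677", "Cryobacterium",        "Cryobacterium soli",
    "BIM B-1675", "Cryobacterium",        "Cryobacterium soli",
    "BIM B-1631", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1632", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1637", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1638", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1639", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1669", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1671", "Leifsonia",            "Leifsonia antarctica",
    "BIM B-1633", "Leifsonia",            "Leifsonia kafniensis",
    "BIM B-1622", "Leifsonia",            "Leifsonia rubra",
    "BIM B-1623", "Leifsonia",            "Leifsonia rubra",
    "BIM B-1634", "Leifsonia",            "Leifsonia rubra",
    "BIM B-1657", "Paeniglutamicibacter", "Paeniglutamicibacter antarcticus",
    "BIM B-1676", "Polaromonas",          "Polaromonas sp.",
    "BIM B-1672", "Pseudomonas",          "Pseudomonas extremaustralis",
    "BIM B-1668", "Pseudomonas",          "Pseudomonas fluorescens",
    "BIM B-1635", "Pseudomonas",          "Pseudomonas sp.",
    "BIM B-1667", "Pseudomonas",          "Pseudomonas sp.",
    "BIM B-1673", "Pseudomonas",          "Pseudomonas sp.",
    "BIM B-1674", "Pseudomonas",          "Pseudomonas versuta",
    "BIM B-1629", "Psychrobacter",        "Psychrobacter glacincola",
    "BIM B-1655", "Psychrobacter",        "Psychrobacter urativorans",
    "BIM B-1662", "Psychrobacter",        "Psychrobacter urativorans",
    "BIM B-1621", "Rhodococcus",          "Rhodococcus yunnanensis",
    "BIM B-1670", "Rhodococcus",          "Rhodococcus yunnanensis",
    "BIM B-1660", "Rhodococcus",          "Rhodococcus erythropolis",
    "BIM B-1661", "Rhodococcus",          "Rhodococcus erythropolis",
    "BIM B-1630", "Salinibacterium",      "Salinibacterium sp.",
    "BIM B-1636", "Salinibacterium",      "Salinibacterium sp.",
    "BIM B-1654", "Salinibacterium",      "Salinibacterium sp.",
    "BIM B-1665", "Salinibacterium",      "Salinibacterium sp."
  )
}

# Strains competent on defined minimal media: every Arthrobacter and
# Pseudomonas isolate, Rhodococcus except the one R. yunnanensis isolate
# BIM B-1621, and the single Leifsonia antarctica isolate BIM B-1671
# (19 strains in total).
minimal_growers <- function() {
  s <- green_snow_strains()
  c(
    s$strain_id[s$genus %in% c("Arthrobacter", "Pseudomonas")],
    setdiff(s$strain_id[s$genus == "Rhodococcus"], "BIM B-1621"),
    "BIM B-1671"
  )
}

#' Reconstructed streak-plate observations of the green-snow study
#'
#' A synthetic observation table consistent with the study's banded growth
#' summary: every isolate grows well on the rich BHI medium (best at 18
#' degrees C, smaller colonies towards 4 and 25 degrees C); only the 19
#' minimal-media-competent strains (all Arthrobacter and Pseudomonas
#' isolates, Rhodococcus except BIM B-1621, and Leifsonia BIM B-1671) grow
#' on the four defined minimal media, one to two bands lower than on BHI and
#' with a few strain-specific temperature limits (no minimal-media growth at
#' 25 degrees C for BIM B-1627, BIM B-1666 and BIM B-1671; none at 4 degrees
#' C for BIM B-1663). Individual streak-area and colony-diameter entries are
#' reconstructions consistent with the band, not raw measurements.
#'
#' @return A tibble of growth observations ready for [score_growth()].
#' @export
green_snow_growth_observations <- function() {
  strains <- green_snow_strains()
  growers <- minimal_growers()
  rich <- c(`4` = "7-8", `10` = "7-8", `18` = "9-10", `25` = "5-6")
  minimal <- c(`4` = "3-4", `10` = "5-6", `18` = "5-6", `25` = "3-4")
  d <- tidyr::expand_grid(strains, medium = ftir_media,
                          temperature_c = ftir_temperatures) |>
    dplyr::mutate(band = dplyr::case_when(
      medium == "BHI" & strain_id == "BIM B-1676" ~ "5-6",
      medium == "BHI" ~ rich[as.character(temperature_c)],
      !(strain_id %in% growers) ~ "0",
      strain_id %in% c("BIM B-1627", "BIM B-1666", "BIM B-1671") &
        temperature_c == 25 ~ "0",
      strain_id == "BIM B-1663" & temperature_c == 4 ~ "0",
      .default = minimal[as.character(temperature_c)]
    ))
  parts <- purrr::map(d$band, band_to_observation)
  d |>
    dplyr::mutate(
      areas_with_growth = purrr::map_chr(parts, "areas"),
      single_colonies_present = purrr::map_lgl(parts, "colonies"),
      colony_diameter_mm = purrr::map_dbl(parts, "diameter"),
      days_to_growth = ifelse(
        .data$band == "0", NA_integer_,
        pmin(12L, 3L + 3L * (.data$medium != "BHI") +
               c(`4` = 4L, `10` = 2L, `18` = 0L,
                 `25` = 1L)[as.character(.data$temperature_c)])
      )
    ) |>
    dplyr::select(-"band")
}
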