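#' Default synthetic absorption bands
#'
#' Gaussian band inventory used by the synthetic FTIR generator, with centres
#' at characteristic cellular absorptions: lipid CH3/CH2 stretches (2962,
#' 2925, 2854 cm^-1) and the ester C=O band (nominal 1743 cm^-1, centre
#' shifted per medium), the Amide I/II protein bands (1654, 1548 cm^-1),
#' CH bending / COO- / phosphodiester bands of the mixed region (1454, 1400,
#' 1240 cm^-1), and C-O / C-O-C polysaccharide ring bands (1080, 1040,
#' 980 cm^-1).
#'
#' @return A tibble (`center_cm1`, `sigma_cm1`, `class`, `base_height`,
#'   `is_ester`, `is_ch_stretch`).
#' @export
synthetic_bands <- function() {
  tibble::tribble(
    ~center_cm1, ~sigma_cm1, ~class,           ~base_height,
    2962,        9,          "lipid",          0.30,
    2925,        9,          "lipid",          0.45,
    2854,        8,          "lipid",          0.30,
    1743,        8,          "lipid",          0.25,
    1654,        16,         "protein",        0.80,
    1548,        14,         "protein",        0.55,
    1454,        12,         "mixed",          0.25,
    1400,        12,         "mixed",          0.28,
    1240,        14,         "mixed",          0.22,
    1080,        18,         "polysaccharide", 0.40,
    1040,        16,         "polysaccharide", 0.35,
    980,         14,         "polysaccharide", 0.15
  ) |>
    dplyr::mutate(is_ester = .data$center_cm1 == 1743,
                  is_ch_stretch = .data$center_cm1 > 2000)
}

# Per-genus band-height multipliers: each genus has a distinct lipid-band
# profile (non-proportional across genera so several consensus components
# separate them) and milder class-level differences elsewhere.
genus_band_multipliers <- function() {
  list(
    Arthrobacter         = c(`2962` = 1.25, `2925` = 0.85, `2854` = 1.00,
                             `1743` = 1.10, protein = 1.00, mixed = 1.05,
                             polysaccharide = 0.95),
    Pseudomonas          = c(`2962` = 0.80, `2925` = 1.00, `2854` = 1.25,
                             `1743` = 1.05, protein = 0.95, mixed = 1.00,
                             polysaccharide = 1.15),
    Rhodococcus          = c(`2962` = 1.15, `2925` = 1.20, `2854` = 1.15,
                             `1743` = 0.70, protein = 1.00, mixed = 0.90,
                             polysaccharide = 1.00),
    Leifsonia            = c(`2962` = 1.00, `2925` = 1.20, `2854` = 0.80,
                             `1743` = 0.95, protein = 1.05, mixed = 1.00,
                             polysaccharide = 1.00),
    Cryobacterium        = c(`2962` = 0.90, `2925` = 1.10, `2854` = 1.05,
                             `1743` = 1.15, protein = 1.10, mixed = 1.00,
                             polysaccharide = 1.00),
    Salinibacterium      = c(`2962` = 1.05, `2925` = 0.95, `2854` = 1.00,
                             `1743` = 1.00, protein = 1.00, mixed = 1.05,
                             polysaccharide = 0.95),
    Paeniglutamicibacter = c(`2962` = 1.10, `2925` = 1.00, `2854` = 0.90,
                             `1743` = 1.00, protein = 1.05, mixed = 1.00,
                             polysaccharide = 1.00),
    Polaromonas          = c(`2962` = 0.85, `2925` = 0.90, `2854` = 1.10,
                             `1743` = 1.20, protein = 0.95, mixed = 1.00,
                             polysaccharide = 1.20),
    Psychrobacter        = c(`2962` = 1.20, `2925` = 1.05, `2854` = 0.90,
                             `1743` = 1.30, protein = 1.00, mixed = 0.95,
                             polysaccharide = 1.05)
  )
}

# Medium effects on band classes: the rich medium is the neutral reference;
# minimal media change protein/mixed/polysaccharide levels and the ester
# band, but never the CH-stretch bands (those carry the temperature effect).
medium_class_effects <- function() {
  tibble::tribble(
    ~medium, ~protein, ~mixed, ~polysaccharide, ~ester,
    "BHI",   1.00,     1.00,   1.00,            1.00,
    "MGU",   0.92,     1.05,   1.10,            1.05,
    "MGY",   0.90,     1.08,   1.15,            0.95,
    "XGU",   0.95,     1.02,   1.08,            1.10,
    "XGY",   0.88,     1.06,   1.12,            0.90
  )
}

#' Configuration of the synthetic FTIR study
#'
#' Defines the full simulated cultivation-and-measurement design: a 2 cm^-1
#' wavenumber grid over 500-4000 cm^-1, Gaussian absorption bands with
#' genus-, medium- and temperature-dependent heights, the medium-dependent
#' ester-peak centre (1743 cm^-1 on BHI and XGU, 1741 on MGU, 1739 on MGY
#' and XGY), a per-degree-Celsius relative height change of the lipid
#' CH-stretch bands, per-replicate multiplicative gain, quadratic baseline
#' and additive noise, 3 biological x 3 technical replicates, and a growth
#' design controlling which (strain, medium, temperature) combinations
#' yield spectra at all (band below 3-4 means no measurable biomass).
#'
#' @param genera Genera simulated (defaults to the four minimal-media
#'   growers, each with a built-in band-height profile).
#' @param n_strains_per_genus Strains per genus.
#' @param media,temperatures Cultivation design vocabularies.
#' @param n_bio,n_tech Biological and technical replicates.
#' @param bands Band inventory tibble (see [synthetic_bands()]).
#' @param ester_center_by_medium Named vector of ester-band centres (cm^-1).
#' @param temp_slope_lipid Relative CH-stretch height change per degree
#'   Celsius away from `temp_ref_c`.
#' @param temp_ref_c Reference temperature for the lipid slope.
#' @param genus_effect_scale Exponent applied to the genus multipliers
#'   (1 = default effects, 0 = no genus effects).
#' @param strain_sigma Lognormal sigma of per-strain, per-band height jitter.
#' @param gain_sigma Lognormal sigma of the per-replicate multiplicative gain.
#' @param baseline_a,baseline_d,baseline_e Uniform ranges of the per-replicate
#'   baseline coefficients (offset, linear, quadratic in the rescaled
#'   wavenumber).
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (absorbance units).
#' @param growth_design Optional tibble (`genus`, `medium`, `temperature_c`,
#'   `band`) overriding the default all-growing design.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(genera = c("Arthrobacter", "Leifsonia",
                                        "Pseudomonas", "Rhodococcus"),
                             n_strains_per_genus = 5,
                             media = ftir_media,
                             temperatures = ftir_temperatures,
                             n_bio = 3, n_tech = 3,
                             bands = synthetic_bands(),
                             ester_center_by_medium = c(BHI = 1743,
                                                        XGU = 1743,
                                                        MGU = 1741,
                                                        MGY = 1739,
                                                        XGY = 1739),
                             temp_slope_lipid = 0.004,
                             temp_ref_c = 18,
                             genus_effect_scale = 1,
                             strain_sigma = 0.01,
                             gain_sigma = 0.05,
                             baseline_a = c(-0.05, 0.05),
                             baseline_d = c(-0.02, 0.02),
                             baseline_e = c(-0.01, 0.01),
                             noise_sigma = 0.001,
                             growth_design = NULL,
                             seed = 1L) {
  stopifnot(all(bands$sigma_cm1 > 0), all(bands$base_height >= 0))
  check_vocab(tibble::tibble(medium = media, temperature_c = temperatures[1]))
  bad_t <- setdiff(temperatures, ftir_temperatures)
  if (length(bad_t) > 0) {
    stop("unknown temperature(s): ", paste(bad_t, collapse = ", "))
  }
  known <- names(genus_band_multipliers())
  bad_g <- setdiff(genera, known)
  if (length(bad_g) > 0) {
    stop("no built-in band profile for genus/genera: ",
         paste(bad_g, collapse = ", "))
  }
  structure(list(
    grid = seq(500, 4000, by = 2),
    genera = genera, n_strains_per_genus = n_strains_per_genus,
    media = media, temperatures = as.integer(temperatures),
    n_bio = n_bio, n_tech = n_tech,
    bands = bands,
    ester_center_by_medium = ester_center_by_medium,
    temp_slope_lipid = temp_slope_lipid, temp_ref_c = temp_ref_c,
    genus_effect_scale = genus_effect_scale,
    strain_sigma = strain_sigma,
    gain_sigma = gain_sigma,
    baseline_a = baseline_a, baseline_d = baseline_d, baseline_e = baseline_e,
    noise_sigma = noise_sigma,
    growth_design = growth_design,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default growth design of the synthetic study
#'
#' Every simulated genus grows on every medium, best at 18 degrees C and
#' with reduced colony size towards 4 and 25 degrees C, one band lower on
#' minimal media than on the rich medium - so the default study is complete
#' (no missing blocks).
#'
#' @param genera,media,temperatures Design vocabularies.
#' @return A tibble (`genus`, `medium`, `temperature_c`, `band`).
#' @export
default_growth_design <- function(genera, media = ftir_media,
                                  temperatures = ftir_temperatures) {
  rich <- c(`4` = "7-8", `10` = "7-8", `18` = "9-10", `25` = "5-6")
  minimal <- c(`4` = "3-4", `10` = "5-6", `18` = "7-8", `25` = "3-4")
  tidyr::expand_grid(genus = genera, medium = media,
                     temperature_c = as.integer(temperatures)) |>
    dplyr::mutate(band = ifelse(
      .data$medium == "BHI",
      rich[as.character(.data$temperature_c)],
      minimal[as.character(.data$temperature_c)]
    ))
}

band_height <- function(cfg, band_row, genus, medium, temperature_c) {
  mult <- genus_band_multipliers()[[genus]]
  h <- band_row$base_height
  key <- as.character(band_row$center_cm1)
  g <- if (key %in% names(mult)) mult[[key]] else mult[[band_row$class]]
  h <- h * g^cfg$genus_effect_scale
  med <- medium_class_effects()
  med <- med[med$medium == medium, , drop = FALSE]
  if (band_row$is_ester) {
    h <- h * med$ester
  } else if (!band_row$is_ch_stretch && band_row$class %in% names(med)) {
    h <- h * med[[band_row$class]]
  }
  if (band_row$is_ch_stretch) {
    h <- h * max(1 + cfg$temp_slope_lipid * (temperature_c - cfg$temp_ref_c),
                 0.01)
  }
  h
}

band_to_observation <- function(band) {
  lut <- list(
    "0"    = list(areas = "",        colonies = FALSE, diameter = NA_real_),
    "1-2"  = list(areas = "1",       colonies = FALSE, diameter = NA_real_),
    "3-4"  = list(areas = "1;2",     colonies = TRUE,  diameter = 0.3),
    "5-6"  = list(areas = "1;2;3;4", colonies = TRUE,  diameter = 0.8),
    "7-8"  = list(areas = "1;2;3;4", colonies = TRUE,  diameter = 1.8),
    "9-10" = list(areas = "1;2;3;4", colonies = TRUE,  diameter = 2.8)
  )
  lut[[band]]
}

#' Generate a synthetic FTIR study
#'
#' Simulates the complete study defined by a [synthetic_config()]: a growth
#' table for every (strain, medium, temperature) combination, replicate
#' absorbance spectra for every combination whose growth band reaches 3-4
#' (each replicate = lognormal gain x clean Gaussian-band spectrum +
#' quadratic baseline + additive Gaussian noise), and a truth record holding
#' every planted quantity for downstream recovery checks. The output is a
#' deterministic function of the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study`: `spectra` (a `spectra_set`,
#'   replicate level), `growth` (observation tibble), `design` (the growth
#'   design used), and `truth` (list: `run_id`, `strains`, `gains` tibble
#'   with per-replicate gain and baseline coefficients, `clean` matrix of
#'   noise-free condition spectra, `clean_keys`, `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  strains <- tidyr::expand_grid(
    genus = config$genera,
    idx = seq_len(config$n_strains_per_genus)
  ) |>
    dplyr::mutate(strain_id = sprintf("SYN-%s-%02d", .data$genus, .data$idx),
                  species = paste(.data$genus, "synthetica")) |>
    dplyr::select("strain_id", "genus", "species")

  design <- config$growth_design
  if (is.null(design)) {
    design <- default_growth_design(config$genera, config$media,
                                    config$temperatures)
  }

  # per-strain, per-band lognormal height jitter (drawn first, fixed order)
  n_bands <- nrow(config$bands)
  strain_mult <- matrix(
    exp(stats::rnorm(nrow(strains) * n_bands, 0, config$strain_sigma)),
    nrow = nrow(strains),
    dimnames = list(strains$strain_id, NULL)
  )

  grid <- config$grid
  u <- rescale_u(grid)
  growth <- strains |>
    tidyr::expand_grid(medium = config$media,
                       temperature_c = config$temperatures) |>
    dplyr::left_join(design, by = c("genus", "medium", "temperature_c"))
  if (any(is.na(growth$band))) {
    stop("growth_design does not cover every (genus, medium, temperature)")
  }
  obs_parts <- purrr::map(growth$band, band_to_observation)
  growth <- growth |>
    dplyr::mutate(
      areas_with_growth = purrr::map_chr(obs_parts, "areas"),
      single_colonies_present = purrr::map_lgl(obs_parts, "colonies"),
      colony_diameter_mm = purrr::map_dbl(obs_parts, "diameter"),
      days_to_growth = ifelse(
        .data$band == "0", NA_integer_,
        pmin(12L, 3L + 3L * (.data$medium != "BHI") +
               c(`4` = 4L, `10` = 2L, `18` = 0L,
                 `25` = 1L)[as.character(.data$temperature_c)])
      ),
      planted_band = .data$band
    ) |>
    dplyr::select(-"band")

  grown <- growth[band_rank(growth$planted_band) >= band_rank("3-4"), ,
                  drop = FALSE]
  n_cond <- nrow(grown)
  n_rep <- config$n_bio * config$n_tech
  clean <- matrix(0, n_cond, length(grid))
  for (i in seq_len(n_cond)) {
    z <- numeric(length(grid))
    for (k in seq_len(n_bands)) {
      row <- config$bands[k, ]
      h <- band_height(config, row, grown$genus[i], grown$medium[i],
                       grown$temperature_c[i]) *
        strain_mult[grown$strain_id[i], k]
      mu <- if (row$is_ester) {
        config$ester_center_by_medium[[grown$medium[i]]]
      } else {
        row$center_cm1
      }
      z <- z + h * exp(-(grid - mu)^2 / (2 * row$sigma_cm1^2))
    }
    clean[i, ] <- z
  }
  rownames(clean) <- paste(grown$strain_id, grown$medium,
                           grown$temperature_c, sep = "__")

  reps <- tidyr::expand_grid(
    cond = seq_len(n_cond),
    bio_rep = seq_len(config$n_bio),
    tech_rep = seq_len(config$n_tech)
  )
  n_spec <- nrow(reps)
  gains <- exp(stats::rnorm(n_spec, 0, config$gain_sigma))
  base_a <- stats::runif(n_spec, config$baseline_a[1], config$baseline_a[2])
  base_d <- stats::runif(n_spec, config$baseline_d[1], config$baseline_d[2])
  base_e <- stats::runif(n_spec, config$baseline_e[1], config$baseline_e[2])
  values <- clean[reps$cond, , drop = FALSE] * gains +
    outer(base_a, rep(1, length(grid))) +
    outer(base_d, u) + outer(base_e, u^2)
  if (config$noise_sigma > 0) {
    values <- values + matrix(stats::rnorm(n_spec * length(grid), 0,
                                           config$noise_sigma),
                              n_spec, length(grid))
  }
  meta <- tibble::tibble(
    strain_id = grown$strain_id[reps$cond],
    genus = grown$genus[reps$cond],
    species = grown$species[reps$cond],
    medium = grown$medium[reps$cond],
    temperature_c = grown$temperature_c[reps$cond],
    bio_rep = reps$bio_rep,
    tech_rep = reps$tech_rep
  ) |>
    dplyr::mutate(sample_id = paste0(.data$strain_id, "__", .data$medium,
                                     "__", .data$temperature_c, "__b",
                                     .data$bio_rep, "t", .data$tech_rep),
                  .before = 1)
  spectra <- spectra_set(values, grid, meta)
  run_id <- paste0("syn-seed", config$seed, "-n", n_spec)
  structure(list(
    spectra = spectra,
    growth = growth,
    design = design,
    truth = list(
      run_id = run_id,
      strains = strains,
      gains = tibble::tibble(sample_id = meta$sample_id, gain = gains,
                             baseline_a = base_a, baseline_d = base_d,
                             baseline_e = base_e),
      clean = clean,
      clean_keys = tibble::as_tibble(
        grown[, c("strain_id", "genus", "medium", "temperature_c",
                  "planted_band")]),
      config = config
    ),
    run_id = run_id
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", n_spectra(x$spectra), " spectra, ",
      nrow(x$truth$strains), " strains, run ", x$run_id, "\n", sep = "")
  invisible(x)
}

#' Check pipeline outputs against the planted truth
#'
#' Compares results computed from a generated dataset with the quantities the
#' generator planted: EMSC gain recovery (fitted vs planted gains, each
#' normalized to its replicate-group mean, since a fitted gain is defined
#' relative to the reference), fusion
#' key agreement (retained keys vs the strain-temperature pairs whose genus
#' reaches band 3-4 on every block medium), leave-one-strain-out genus
#' recovery accuracy of a CPCA model, and the temperature-CH2 correlation
#' recovered by the correlation analysis (loading of the 2925 cm^-1 peak on
#' the component most correlated with temperature).
#'
#' @param truth The `truth` element of a [generate_dataset()] result.
#' @param emsc Optional `emsc_result` fitted to (a subset of) the generated
#'   replicate spectra.
#' @param multiblock Optional `multiblock_data` from the generated study.
#' @param cpca Optional `cpca_model`.
#' @param correlation Optional `correlation_loadings` with an ordinal
#'   `temperature` variable.
#' @param run_id Run identifier of the dataset the outputs came from; must
#'   match the truth record.
#' @return A tibble with one row per supplied check (`check`, `value`, `pass`
#'   where applicable as `value`s: max gain error, key agreement as 0/1,
#'   accuracy, |r|).
#' @export
truth_check <- function(truth, emsc = NULL, multiblock = NULL, cpca = NULL,
                        correlation = NULL, run_id = truth$run_id) {
  if (!identical(run_id, truth$run_id)) {
    stop("run identifier mismatch: outputs are from '", run_id,
         "' but truth is from '", truth$run_id, "'")
  }
  rows <- list()
  if (!is.null(emsc)) {
    ids <- emsc$coefficients$sample_id
    g <- truth$gains$gain[match(ids, truth$gains$sample_id)]
    if (anyNA(g)) stop("EMSC fit contains samples unknown to the truth record")
    # the fitted gain is proportional to the planted gain within each
    # condition group (replicates share one clean spectrum); compare the
    # group-mean-normalized gains
    cond <- sub("__b[0-9]+t[0-9]+$", "", ids)
    b <- emsc$coefficients$gain
    b_rel <- b / stats::ave(b, cond)
    g_rel <- g / stats::ave(g, cond)
    rows <- c(rows, list(tibble::tibble(
      check = "emsc_gain_max_error",
      value = max(abs(b_rel - g_rel))
    )))
  }
  if (!is.null(multiblock)) {
    expected <- expected_complete_keys(truth, multiblock$media)
    got <- paste(multiblock$keys$strain_id, multiblock$keys$temperature_c)
    want <- paste(expected$strain_id, expected$temperature_c)
    rows <- c(rows, list(tibble::tibble(
      check = "fusion_key_agreement",
      value = as.numeric(setequal(got, want) && length(got) == length(want))
    )))
  }
  if (!is.null(cpca)) {
    rows <- c(rows, list(tibble::tibble(
      check = "cpca_genus_accuracy",
      value = genus_recovery_accuracy(cpca)$accuracy
    )))
  }
  if (!is.null(correlation)) {
    rows <- c(rows, list(tibble::tibble(
      check = "temperature_ch2_abs_r",
      value = temperature_peak_correlation(correlation)$r_peak_abs
    )))
  }
  purrr::list_rbind(rows)
}

# Strain-temperature keys whose genus reaches band >= 3-4 on every medium.
expected_complete_keys <- function(truth, media) {
  cfg <- truth$config
  design <- if (is.null(cfg$growth_design)) {
    default_growth_design(cfg$genera, cfg$media, cfg$temperatures)
  } else {
    cfg$growth_design
  }
  ok <- design |>
    dplyr::filter(.data$medium %in% media) |>
    dplyr::summarise(
      complete = all(band_rank(.data$band) >= band_rank("3-4")) &
        dplyr::n_distinct(.data$medium) == length(media),
      .by = c("genus", "temperature_c")
    ) |>
    dplyr::filter(.data$complete)
  truth$strains |>
    dplyr::inner_join(ok, by = "genus", relationship = "many-to-many") |>
    dplyr::select("strain_id", "temperature_c")
}

#' Temperature-CH2 correlation from correlation loadings
#'
#' Finds the component most correlated with the ordinal `temperature`
#' variable and reports the absolute correlation loadings of both the
#' temperature variable and the 2925 cm^-1 CH2-stretch peak on it.
#'
#' @param cl A `correlation_loadings` object fitted with
#'   `temperature_coding = "ordinal"`.
#' @return A list: `component`, `r_temp_abs`, `r_peak_abs`.
#' @export
temperature_peak_correlation <- function(cl) {
  stopifnot(inherits(cl, "correlation_loadings"))
  temp <- cl[cl$variable == "temperature", , drop = FALSE]
  if (nrow(temp) == 0) {
    stop("no ordinal 'temperature' variable in the loadings; fit with ",
         "temperature_coding = 'ordinal'")
  }
  lead <- temp$component[which.max(abs(temp$r))]
  peak <- cl[cl$variable == "2925" & cl$component == lead, , drop = FALSE]
  if (nrow(peak) == 0) stop("no 2925 cm-1 peak variable in the loadings")
  list(component = lead,
       r_temp_abs = max(abs(temp$r)),
       r_peak_abs = abs(peak$r[1]))
}
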