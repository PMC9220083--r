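#' Default spectral peak inventory for correlation analysis
#'
#' The named mid-IR peaks tracked in the correlation-loading analysis:
#' CH3/CH2 stretching bands of lipids (2962, 2927, 2925, 2854 cm^-1) and the
#' ester C=O stretching bands (1745, 1743, 1741 cm^-1); CH2/CH3 bending and
#' deformation modes, COO- symmetric stretching and P=O phosphodiester
#' stretching bands of the mixed region; and the Amide I / Amide II protein
#' bands (1654, 1548, 1546 cm^-1). Polysaccharide-region peaks are not part
#' of the default inventory.
#'
#' @return A tibble with columns `wavenumber_cm1`, `label`, `class`.
#' @export
default_peak_set <- function() {
  tbl <- tibble::tribble(
    ~wavenumber_cm1, ~label,
    2962, "CH3 asym stretch",
    2927, "CH2 asym stretch",
    2925, "CH2 asym stretch",
    2854, "CH2 sym stretch",
    1745, "ester C=O stretch",
    1743, "ester C=O stretch",
    1741, "ester C=O stretch",
    1456, "CH2/CH3 bend",
    1454, "CH2/CH3 bend",
    1404, "COO- sym stretch",
    1402, "COO- sym stretch",
    1400, "COO- sym stretch",
    1394, "CH2/CH3 deformation",
    1380, "CH2/CH3 deformation",
    1338, "CH2/CH3 deformation",
    1336, "CH2/CH3 deformation",
    1313, "CH2/CH3 deformation",
    1311, "CH2/CH3 deformation",
    1305, "CH2/CH3 deformation",
    1243, "P=O stretch",
    1242, "P=O stretch",
    1240, "P=O stretch",
    1654, "Amide I",
    1548, "Amide II",
    1546, "Amide II"
  )
  tbl$class <- classify_wavenumber(tbl$wavenumber_cm1)
  dplyr::arrange(tbl, dplyr::desc(.data$wavenumber_cm1))
}

#' Pick peaks as second-derivative minima
#'
#' Locates absorption peaks of the mean spectrum of a set as the strict local
#' minima of its Savitzky-Golay second derivative (an absorption band has a
#' negative second-derivative well at its centre), computed per contiguous
#' segment with the region's window. Only minima whose depth below zero is at
#' least `prominence_frac` times the maximum absolute derivative are kept,
#' which suppresses noise wiggles; a flat spectrum yields an empty peak set.
#'
#' @param x A `spectra_set` (full acquisition grid or already region-split).
#' @param region A [region_spec()] or region name.
#' @param prominence_frac Minimum depth as a fraction of the maximum absolute
#'   second derivative.
#' @return A tibble (`wavenumber_cm1`, `depth`, `class`), sorted descending
#'   in wavenumber.
#' @export
pick_peaks <- function(x, region, prominence_frac = 0.01) {
  stopifnot(inherits(x, "spectra_set"), n_spectra(x) >= 1)
  if (is.character(region)) region <- region_spec(region)
  mean_set <- spectra_set(
    matrix(colMeans(x$values), nrow = 1), x$grid,
    tibble::tibble(sample_id = "mean", strain_id = "mean", genus = "mean",
                   species = "mean", medium = "BHI", temperature_c = 18L,
                   bio_rep = 1L, tech_rep = 1L)
  )
  reg <- split_region(mean_set, region)
  d <- sg_second_derivative(reg, region)
  v <- d$values[1, ]
  seg <- region_segments(d)
  floor_depth <- prominence_frac * max(abs(v))
  hits <- integer(0)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) < 3) next
    inner <- idx[-c(1, length(idx))]
    is_min <- v[inner] < v[inner - 1] & v[inner] < v[inner + 1] &
      v[inner] <= -floor_depth
    hits <- c(hits, inner[is_min])
  }
  out <- tibble::tibble(
    wavenumber_cm1 = d$grid[hits],
    depth = -v[hits]
  )
  out$class <- classify_wavenumber(out$wavenumber_cm1)
  dplyr::arrange(out, dplyr::desc(.data$wavenumber_cm1))
}

#' Genus-wise correlation-loading analysis
#'
#' Pools all growth conditions of one genus as rows, fits an ordinary
#' column-centered PCA on the EMSC-corrected wide-region spectra, and
#' computes correlation loadings: the Pearson correlation between each
#' component's score vector and each variable across samples. Variables are
#' the selected peak absorbances (read at the nearest grid point), and the
#' design of the experiment as supplementary variables - 0/1 dummies for each
#' medium and each temperature present (or a single ordinal temperature
#' variable), and 0/1 strain indicators. Supplementary variables never enter
#' the PCA fit. A genus grown only on BHI yields no medium variables, and any
#' constant variable is reported as dropped rather than given an undefined
#' correlation.
#'
#' @param x A `spectra_set` from [preprocess_for_correlation()] (replicate
#'   level, all conditions pooled).
#' @param genus Genus to analyse (must have >= 3 samples).
#' @param peaks Peak inventory tibble (`wavenumber_cm1`, optionally `label`);
#'   defaults to [default_peak_set()].
#' @param n_components Number of principal components (default 2).
#' @param temperature_coding `"dummy"` (default) for one 0/1 indicator per
#'   temperature, `"ordinal"` for a single numeric temperature variable.
#' @param include_polysaccharide Include polysaccharide-class peaks (default
#'   FALSE: they are excluded from the correlation analysis).
#' @return An object of class `correlation_loadings`: a long tibble
#'   (`variable`, `kind`, `class`, `component`, `r`) with attributes `genus`,
#'   `inner_radius` (sqrt(0.5)), `dropped` (tibble of constant variables),
#'   `n_samples`, and `scores`.
#' @export
genus_correlation_analysis <- function(x, genus,
                                       peaks = default_peak_set(),
                                       n_components = 2,
                                       temperature_coding = c("dummy",
                                                              "ordinal"),
                                       include_polysaccharide = FALSE) {
  stopifnot(inherits(x, "spectra_set"))
  temperature_coding <- match.arg(temperature_coding)
  g <- genus
  sub <- filter_spectra(x, .data$genus == g)
  if (n_spectra(sub) < 3) {
    stop("genus '", genus, "' has ", n_spectra(sub),
         " spectra; need at least 3")
  }
  pc <- stats::prcomp(sub$values, center = TRUE, scale. = FALSE)
  K <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(K), drop = FALSE]

  peaks <- peaks[peaks$wavenumber_cm1 >= min(sub$grid) &
                   peaks$wavenumber_cm1 <= max(sub$grid), , drop = FALSE]
  peaks$class <- classify_wavenumber(peaks$wavenumber_cm1)
  if (!include_polysaccharide) {
    peaks <- peaks[is.na(peaks$class) | peaks$class != "polysaccharide", ,
                   drop = FALSE]
  }
  vars <- list()
  classes <- character(0)
  kinds <- character(0)
  for (i in seq_len(nrow(peaks))) {
    j <- which.min(abs(sub$grid - peaks$wavenumber_cm1[i]))
    nm <- format(peaks$wavenumber_cm1[i])
    vars[[nm]] <- sub$values[, j]
    classes <- c(classes, peaks$class[i])
    kinds <- c(kinds, "peak")
  }
  add_design <- function(nm, v) {
    vars[[nm]] <<- v
    classes <<- c(classes, "design")
    kinds <<- c(kinds, "design")
  }
  media_present <- sort(unique(sub$meta$medium))
  if (length(media_present) > 1) {
    for (m in media_present) add_design(m, as.numeric(sub$meta$medium == m))
  }
  temps_present <- sort(unique(sub$meta$temperature_c))
  if (temperature_coding == "ordinal") {
    add_design("temperature", as.numeric(sub$meta$temperature_c))
  } else if (length(temps_present) > 1) {
    for (tc in temps_present) {
      add_design(paste0("T", tc), as.numeric(sub$meta$temperature_c == tc))
    }
  }
  strains_present <- sort(unique(sub$meta$strain_id))
  if (length(strains_present) > 1) {
    for (s in strains_present) {
      add_design(s, as.numeric(sub$meta$strain_id == s))
    }
  }
  sds <- vapply(vars, stats::sd, numeric(1))
  constant <- !is.finite(sds) | sds == 0
  dropped <- tibble::tibble(variable = names(vars)[constant],
                            reason = rep("constant", sum(constant)))
  keep <- which(!constant)
  rows <- purrr::map(keep, function(i) {
    tibble::tibble(
      variable = names(vars)[i],
      kind = kinds[i],
      class = classes[i],
      component = seq_len(K),
      r = as.vector(stats::cor(scores, vars[[i]]))
    )
  })
  out <- purrr::list_rbind(rows)
  structure(out,
            class = c("correlation_loadings", class(out)),
            genus = genus,
            inner_radius = sqrt(0.5),
            dropped = dropped,
            n_samples = n_spectra(sub),
            scores = scores)
}

#' Plot-ready correlation loadings
#'
#' Pivots the long correlation loadings to one row per variable with `r_pc1`
#' and `r_pc2` columns and the variable class (`lipid`, `mixed`, `protein`,
#' or `design`), for the conventional correlation-loading plot with circles
#' at 50% (r^2 = 0.5) and 100% explained variance.
#'
#' @param x A `correlation_loadings` object with >= 2 components.
#' @return A tibble (`variable`, `kind`, `class`, `r_pc1`, `r_pc2`), with
#'   attributes `inner_radius` and `outer_radius`.
#' @export
correlation_plot_data <- function(x) {
  stopifnot(inherits(x, "correlation_loadings"))
  if (max(x$component) < 2) stop("need at least 2 components to plot")
  wide <- tibble::as_tibble(x[x$component <= 2, ]) |>
    tidyr::pivot_wider(names_from = "component", values_from = "r",
                       names_prefix = "r_pc")
  attr(wide, "inner_radius") <- attr(x, "inner_radius")
  attr(wide, "outer_radius") <- 1
  wide
}

#' Correlation-loading plot
#'
#' @param object A `correlation_loadings` object.
#' @param ... Unused.
#' @return A ggplot object with the 50% and 100% explained-variance circles.
#' @method autoplot correlation_loadings
#' @export
autoplot.correlation_loadings <- function(object, ...) {
  d <- correlation_plot_data(object)
  theta <- seq(0, 2 * pi, length.out = 181)
  circ <- dplyr::bind_rows(
    tibble::tibble(cx = cos(theta), cy = sin(theta), radius = "100%"),
    tibble::tibble(cx = sqrt(0.5) * cos(theta), cy = sqrt(0.5) * sin(theta),
                   radius = "50%")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_pc1, y = .data$r_pc2)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$cx, y = .data$cy,
                                    group = .data$radius),
                       colour = "grey60", linetype = "dashed",
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$variable,
                                    colour = .data$class),
                       size = 2.7, vjust = -0.7, show.legend = FALSE) +
    ggplot2::coord_equal(xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1)) +
    ggplot2::labs(x = "r (PC1)", y = "r (PC2)",
                  title = paste("Correlation loadings -", attr(object, "genus"))) +
    ggplot2::theme_minimal()
}
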