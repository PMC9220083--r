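test_that("peak picking finds band centres and ignores the gaps", {
  grid <- seq(500, 4000, 2)
  one <- fun_set(list(gauss(2925, 9, 0.5)), grid)
  p1 <- pick_peaks(one, "lipid")
  expect_identical(nrow(p1), 1L)
  expect_lte(abs(p1$wavenumber_cm1 - 2925), 2)
  two <- fun_set(list(function(nu) gauss(2925, 9, 1)(nu) +
                        gauss(2854, 8, 0.7)(nu)), grid)
  p2 <- pick_peaks(two, "lipid")
  expect_identical(nrow(p2), 2L)
  expect_true(any(abs(p2$wavenumber_cm1 - 2925) <= 2))
  expect_true(any(abs(p2$wavenumber_cm1 - 2854) <= 2))
  expect_false(any(p2$wavenumber_cm1 > 2880 & p2$wavenumber_cm1 < 2900))
  flat <- fun_set(list(function(nu) rep(0.3, length(nu))), grid)
  expect_identical(nrow(pick_peaks(flat, "lipid")), 0L)
})

test_that("peak picking is translation-covariant on the grid", {
  grid <- seq(500, 4000, 2)
  base <- pick_peaks(fun_set(list(gauss(2924, 9)), grid), "lipid")
  for (k in c(2, 5)) {
    shifted <- pick_peaks(fun_set(list(gauss(2924 + 2 * k, 9)), grid), "lipid")
    expect_identical(shifted$wavenumber_cm1, base$wavenumber_cm1 + 2 * k)
  }
})

test_that("correlation loadings are exact for a variable equal to a score", {
  # rank-2 data built from two orthogonal sample patterns: the grid point
  # carried only by the dominant pattern must load 1.0 on PC1, 0 on PC2
  grid <- seq(2800, 3050, 2)
  s1 <- c(3, -1, -2, 1, -1, 0, 2, -2)
  s2 <- c(1, 1, -1, -1, 1, -1, -1, 0) * 0.3
  stopifnot(abs(sum(s1 * s2)) < 1e-12)
  v1 <- rep(0, length(grid)); v1[which.min(abs(grid - 2925))] <- 1
  v1[5] <- 0.5
  v2 <- rep(0, length(grid)); v2[20] <- 1
  vals <- outer(s1, v1) + outer(s2, v2) + 1
  ss <- spectra_set(vals, grid, make_meta(8, temperature_c = rep(c(4L, 25L), 4)))
  cl <- genus_correlation_analysis(ss, "Arthrobacter",
                                   peaks = tibble::tibble(wavenumber_cm1 = 2925))
  r1 <- cl$r[cl$variable == "2925" & cl$component == 1]
  r2 <- cl$r[cl$variable == "2925" & cl$component == 2]
  expect_equal(abs(r1), 1, tolerance = 1e-8)
  expect_equal(r2, 0, tolerance = 1e-8)
  expect_true(all(abs(cl$r) <= 1 + 1e-12))
})

test_that("design variables follow the genus's actual growth design", {
  d <- generate_dataset(bhi_only_config(seed = 31, n_strains = 3))
  prep <- preprocess_for_correlation(d$spectra)
  cl <- genus_correlation_analysis(prep, "Cryobacterium")
  # BHI-only genus: no medium variables, but temperature dummies present
  expect_false(any(cl$variable %in% ftir_media))
  expect_setequal(intersect(cl$variable, paste0("T", ftir_temperatures)),
                  paste0("T", ftir_temperatures))
  # multi-media genus carries medium variables
  d2 <- generate_dataset(small_config(seed = 32))
  cl2 <- genus_correlation_analysis(preprocess_for_correlation(d2$spectra),
                                    "Arthrobacter")
  expect_setequal(intersect(cl2$variable, ftir_media), ftir_media)
  expect_error(genus_correlation_analysis(prep, "Rhodococcus"), "at least 3")
})

test_that("constant variables are dropped with a reason, not given NaN", {
  d <- generate_dataset(bhi_only_config(seed = 33, n_strains = 3))
  prep <- preprocess_for_correlation(d$spectra)
  one_t <- filter_spectra(prep, .data$temperature_c == 18L)
  cl <- genus_correlation_analysis(one_t, "Cryobacterium",
                                   temperature_coding = "ordinal")
  dropped <- attr(cl, "dropped")
  expect_true("temperature" %in% dropped$variable)
  expect_true(all(dropped$reason == "constant"))
  expect_false(any(cl$variable == "temperature"))
  expect_true(all(is.finite(cl$r)))
})

test_that("the planted temperature effect is recovered on a BHI-only genus", {
  d <- generate_dataset(bhi_only_config(seed = 34))
  prep <- preprocess_for_correlation(d$spectra)
  cl <- genus_correlation_analysis(prep, "Cryobacterium",
                                   temperature_coding = "ordinal")
  res <- temperature_peak_correlation(cl)
  expect_gte(res$r_peak_abs, 0.7)
  expect_gte(res$r_temp_abs, 0.7)
  # doubling the planted slope does not weaken the recovered correlation
  d2 <- generate_dataset(bhi_only_config(seed = 34, temp_slope_lipid = 0.008))
  cl2 <- genus_correlation_analysis(preprocess_for_correlation(d2$spectra),
                                    "Cryobacterium",
                                    temperature_coding = "ordinal")
  expect_gte(temperature_peak_correlation(cl2)$r_peak_abs,
             res$r_peak_abs - 0.05)
})

test_that("plot data classifies peaks by region and spans the unit circle", {
  d <- generate_dataset(small_config(seed = 35))
  cl <- genus_correlation_analysis(preprocess_for_correlation(d$spectra),
                                   "Pseudomonas")
  pd <- correlation_plot_data(cl)
  expect_identical(pd$class[pd$variable == "1654"], "protein")
  expect_identical(pd$class[pd$variable == "1743"], "lipid")
  expect_identical(pd$class[pd$variable == "1400"], "mixed")
  expect_true(all(pd$class[pd$kind == "design"] == "design"))
  expect_true(all(pd$r_pc1^2 + pd$r_pc2^2 <= 2 + 1e-9))
  expect_equal(attr(pd, "inner_radius"), sqrt(0.5))
  # an all-|r|=1 toy set lies on the outer circle
  toy <- structure(
    tibble::tibble(variable = rep(c("a", "b"), each = 2),
                   kind = "peak", class = "lipid",
                   component = rep(1:2, 2),
                   r = c(1, 0, 0, -1)),
    class = c("correlation_loadings", class(tibble::tibble())),
    genus = "toy", inner_radius = sqrt(0.5))
  tp <- correlation_plot_data(toy)
  expect_equal(tp$r_pc1^2 + tp$r_pc2^2, c(1, 1), tolerance = 1e-12)
})
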