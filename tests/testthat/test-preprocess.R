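test_that("region splitting keeps exactly the in-interval grid points", {
  grid <- seq(500, 4000, by = 2)
  ss <- fun_set(list(function(nu) nu), grid)
  lip <- split_region(ss, "lipid")
  expect_true(all((lip$grid >= 2800 & lip$grid <= 3050) |
                    (lip$grid >= 1700 & lip$grid <= 1800)))
  expect_false(any(lip$grid > 1800 & lip$grid < 2800))
  expect_identical(sort(unique(attr(lip, "segments"))), c(1L, 2L))
  # protein region on a 2 cm-1 grid covers 101 points, [1500, 1700] inclusive
  prot <- split_region(ss, "protein")
  expect_length(prot$grid, 101L)
  # a region equal to the full span is the identity
  full <- structure(list(name = "full", intervals_cm1 = list(c(500, 4000)),
                         sg_window = 13L, sg_polyorder = 2L, sg_deriv = 2L),
                    class = "region_spec")
  expect_identical(split_region(ss, full)$grid, ss$grid)
  narrow <- fun_set(list(function(nu) nu), seq(2000, 2200, 2))
  expect_error(split_region(narrow, "lipid"), "no points")
})

test_that("SG second derivative is exact on low-degree polynomials for all windows", {
  grid <- seq(500, 4000, by = 2)
  ss <- fun_set(list(function(nu) 3 * nu^2 + 2 * nu + 1,
                     function(nu) 5 * nu - 7), grid)
  for (nm in c("lipid", "protein", "mixed", "polysaccharide")) {
    d <- sg_second_derivative(split_region(ss, nm), nm)
    expect_lt(max(abs(d$values[1, ] - 6)), 1e-10)
    expect_lt(max(abs(d$values[2, ])), 1e-10)
  }
})

test_that("a Gaussian band's derivative minimum sits at the band centre", {
  ss <- fun_set(list(gauss(2925, 10)), seq(500, 4000, 2))
  d <- sg_second_derivative(split_region(ss, "lipid"), "lipid")
  expect_lte(abs(d$grid[which.min(d$values[1, ])] - 2925), 2)
})

test_that("differentiation never spans the lipid-region gap", {
  # wildly different signals in the two lipid intervals; each segment's
  # derivative must equal the derivative of that interval alone
  f <- function(nu) ifelse(nu > 2000, gauss(2925, 12)(nu), 100 + 0.5 * nu)
  ss <- fun_set(list(f), seq(500, 4000, 2))
  lip <- split_region(ss, "lipid")
  d <- sg_second_derivative(lip, "lipid")
  only_hi <- structure(list(name = "hi", intervals_cm1 = list(c(2800, 3050)),
                            sg_window = 13L, sg_polyorder = 2L, sg_deriv = 2L),
                       class = "region_spec")
  d_hi <- sg_second_derivative(split_region(ss, only_hi), only_hi)
  expect_equal(d$values[1, d$grid >= 2800], d_hi$values[1, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # the low segment is linear there, so its derivative is zero
  expect_lt(max(abs(d$values[1, d$grid <= 1800])), 1e-10)
})

test_that("derivative errors on short segments and non-uniform spacing", {
  tiny <- fun_set(list(function(nu) nu), seq(1700, 1716, 2))
  reg <- structure(list(name = "t", intervals_cm1 = list(c(1700, 1716)),
                        sg_window = 13L, sg_polyorder = 2L, sg_deriv = 2L),
                   class = "region_spec")
  expect_error(sg_second_derivative(split_region(tiny, reg), reg), "fewer")
  g <- c(seq(1500, 1598, 2), 1601, seq(1604, 1700, 2))
  ss <- spectra_set(matrix(g, 1), g, make_meta(1))
  expect_error(sg_second_derivative(split_region(ss, "protein"), "protein"),
               "non-uniform")
})

test_that("EMSC recovers exact affine models and corrects back to the reference", {
  grid <- seq(900, 1800, 2)
  m <- gauss(1654, 16, 0.8)(grid) + gauss(1080, 18, 0.4)(grid)
  u <- 2 * (grid - min(grid)) / diff(range(grid)) - 1
  vals <- rbind(m, 2 * m + 0.1 + 0.3 * u, 1.5 * m - 0.2 * u^2 + 0.05)
  ss <- spectra_set(vals, grid, make_meta(3))
  res <- emsc_correct(ss, reference = m)
  cf <- tidy(res)
  expect_equal(cf$offset[1], 0, tolerance = 1e-10)
  expect_equal(cf$gain[1], 1, tolerance = 1e-10)
  expect_equal(cf$offset[2], 0.1, tolerance = 1e-10)
  expect_equal(cf$gain[2], 2, tolerance = 1e-10)
  expect_equal(cf$poly_1[2], 0.3, tolerance = 1e-10)
  expect_equal(cf$poly_2[2], 0, tolerance = 1e-10)
  for (i in 1:3) {
    expect_lt(max(abs(res$corrected$values[i, ] - m)), 1e-10)
  }
})

test_that("EMSC is idempotent and invariant to gain/baseline perturbations", {
  d <- generate_dataset(small_config(seed = 5, noise_sigma = 0))
  prep <- preprocess_for_correlation(d$spectra)
  again <- emsc_correct(prep, reference = attr(prep, "emsc_reference"))
  expect_lt(max(abs(again$corrected$values - prep$values)), 1e-10)
  # perturbing one input by a positive gain and a quadratic leaves its
  # corrected spectrum unchanged (reference held fixed)
  wide <- split_region(d$spectra, "correlation_wide")
  ref <- colMeans(wide$values)
  r1 <- emsc_correct(wide, reference = ref)
  u <- 2 * (wide$grid - min(wide$grid)) / diff(range(wide$grid)) - 1
  pert <- wide
  pert$values[1, ] <- 3.7 * pert$values[1, ] + 0.2 - 0.1 * u + 0.3 * u^2
  r2 <- emsc_correct(pert, reference = ref)
  expect_lt(max(abs(r1$corrected$values[1, ] - r2$corrected$values[1, ])),
            1e-9)
})

test_that("planted gains are recovered to 1e-6 at zero noise", {
  d <- generate_dataset(small_config(seed = 9, noise_sigma = 0))
  wide <- split_region(d$spectra, "correlation_wide")
  res <- emsc_correct(wide)
  report <- truth_check(d$truth, emsc = res, run_id = d$run_id)
  expect_lt(report$value[report$check == "emsc_gain_max_error"], 1e-6)
})

test_that("a signal-free spectrum is excluded as gain-degenerate", {
  grid <- seq(900, 1800, 2)
  m <- gauss(1654, 16, 0.8)(grid)
  vals <- rbind(m, 0.9 * m, rep(0, length(grid)))
  ss <- spectra_set(vals, grid, make_meta(3))
  res <- emsc_correct(ss, reference = m)
  expect_identical(res$excluded$sample_id, "s3")
  expect_identical(res$excluded$reason, "gain_degenerate")
  expect_identical(n_spectra(res$corrected), 2L)
})

test_that("multiblock preprocessing composes the stages and conserves samples", {
  d <- generate_dataset(small_config(seed = 2))
  prep <- preprocess_for_multiblock(d$spectra, "mixed")
  expect_identical(n_spectra(prep),
                   n_spectra(d$spectra) -
                     nrow(attr(prep, "emsc_excluded")))
  expect_true(all(prep$grid >= 1200 & prep$grid <= 1500))
  # re-running the EMSC stage (same reference) on its output changes nothing
  again <- emsc_correct(prep, reference = attr(prep, "emsc_reference"))
  expect_lt(max(abs(again$corrected$values - prep$values)), 1e-10)
  expect_error(preprocess_for_multiblock(d$spectra, "correlation_wide"),
               "not a derivative region")
})

test_that("EMSC removes planted multiplicative gain across replicates", {
  d <- generate_dataset(small_config(seed = 4, noise_sigma = 0))
  wide <- split_region(d$spectra, "correlation_wide")
  prep <- preprocess_for_correlation(d$spectra)
  cv <- function(v) stats::sd(v) / mean(v)
  total_before <- rowSums(abs(wide$values))
  total_after <- rowSums(abs(prep$values))
  key <- paste(wide$meta$strain_id, wide$meta$medium, wide$meta$temperature_c)
  key_after <- paste(prep$meta$strain_id, prep$meta$medium,
                     prep$meta$temperature_c)
  cv_before <- tapply(total_before, key, cv)
  cv_after <- tapply(total_after, key_after, cv)
  expect_lt(median(cv_after), median(cv_before))
  # grid spans exactly the two wide intervals
  expect_true(all((prep$grid >= 2800 & prep$grid <= 3050) |
                    (prep$grid >= 900 & prep$grid <= 1800)))
})
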