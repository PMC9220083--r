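test_that("wide-matrix round trip preserves grid, values and metadata", {
  set.seed(42)
  grid <- seq(500, 4000, by = 6)
  vals <- matrix(runif(3 * length(grid)), nrow = 3)
  meta <- make_meta(3, medium = c("BHI", "MGU", "XGY"),
                    temperature_c = c(4L, 18L, 25L))
  ss <- spectra_set(vals, grid, meta)
  fm <- withr::local_tempfile(fileext = ".csv")
  fmeta <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ss, fm, fmeta)
  back <- read_spectra(fm, fmeta)
  expect_identical(back$grid, ss$grid)
  expect_identical(unname(back$values), unname(ss$values))
  expect_identical(back$meta$medium, ss$meta$medium)
  expect_identical(back$meta$temperature_c, ss$meta$temperature_c)
})

test_that("descending instrument grids are reversed on read", {
  grid <- seq(500, 520, by = 2)
  vals <- matrix(seq_along(grid), nrow = 1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  # write the file in descending (instrument) order by hand
  readr::write_csv(
    tibble::tibble(wavenumber_cm1 = rev(grid), s1 = rev(as.vector(vals))), f1)
  readr::write_csv(make_meta(1), f2)
  ss <- read_spectra(f1, f2)
  expect_identical(ss$grid, as.numeric(grid))
  expect_identical(unname(ss$values[1, ]), as.numeric(seq_along(grid)))
})

test_that("read_spectra rejects unmatched ids, bad grids and non-numeric cells", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(wavenumber_cm1 = c(500, 502),
                                  ghost = c(1, 2)), f1)
  readr::write_csv(make_meta(1), f2)
  expect_error(read_spectra(f1, f2), "ghost")
  readr::write_csv(tibble::tibble(wavenumber_cm1 = c(500, 500),
                                  s1 = c(1, 2)), f1)
  expect_error(read_spectra(f1, f2), "duplicated wavenumbers")
  readr::write_csv(tibble::tibble(wavenumber_cm1 = c(500, 510, 505),
                                  s1 = c(1, 2, 3)), f1)
  expect_error(read_spectra(f1, f2), "monotone")
  writeLines(c("wavenumber_cm1,s1", "500,1.0", "502,oops"), f1)
  expect_error(read_spectra(f1, f2), "non-numeric")
})

test_that("an empty set writes header-only files", {
  ss <- spectra_set(matrix(numeric(0), 0, 0), numeric(0), make_meta(1)[0, ])
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ss, f1, f2)
  expect_length(readLines(f1), 1L)
  expect_length(readLines(f2), 1L)
})

test_that("the spectra container validates its invariants", {
  expect_error(spectra_set(matrix(1, 1, 2), c(2, 1), make_meta(1)),
               "increasing")
  expect_error(spectra_set(matrix(c(1, NA), 1, 2), c(1, 2), make_meta(1)),
               "non-finite")
  m <- make_meta(2); m$sample_id <- c("a", "a")
  expect_error(spectra_set(matrix(1, 2, 1), 1, m), "duplicated sample_id")
  m <- make_meta(1, medium = "LB")
  expect_error(spectra_set(matrix(1, 1, 1), 1, m), "unknown medium")
})

test_that("quality check flags degraded spectra with the right reasons", {
  grid <- seq(500, 4000, by = 2)
  good <- gauss(1654, 16, 0.8)
  ss <- fun_set(list(
    function(nu) rep(0, length(nu)),              # no signal at all
    function(nu) good(nu) + gauss(2925, 9, 2.2)(nu), # strong saturated band
    good                                          # clean
  ))
  res <- quality_check(ss, qc_config())
  expect_identical(res$fail$sample_id, c("s1", "s2"))
  expect_identical(res$fail$reason, c("low_signal", "saturated"))
  expect_identical(res$pass$meta$sample_id, "s3")
})

test_that("default synthetic spectra pass QC and 100x noise fails on SNR", {
  d <- generate_dataset(small_config(seed = 1))
  res <- quality_check(d$spectra)
  expect_identical(nrow(res$fail), 0L)
  noisy <- generate_dataset(small_config(seed = 1, noise_sigma = 0.1))
  res2 <- quality_check(noisy$spectra)
  expect_gt(nrow(res2$fail), 0)
  expect_true(all(res2$fail$reason == "low_snr"))
})

test_that("quality check is order-independent and monotone in min_snr", {
  d <- generate_dataset(small_config(seed = 3, noise_sigma = 0.02))
  ss <- d$spectra
  perm <- sample(n_spectra(ss))
  r1 <- quality_check(ss, qc_config(min_snr = 30))
  r2 <- quality_check(subset_ss(ss, perm), qc_config(min_snr = 30))
  expect_setequal(r1$fail$sample_id, r2$fail$sample_id)
  expect_setequal(r1$pass$meta$sample_id, r2$pass$meta$sample_id)
  for (thr in c(5, 50, 500)) {
    lo <- quality_check(ss, qc_config(min_snr = thr))
    hi <- quality_check(ss, qc_config(min_snr = thr * 2))
    expect_true(all(lo$fail$sample_id %in% hi$fail$sample_id))
  }
})

test_that("a JCAMP-DX XYDATA block maps onto the spectra container", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE= demo",
    "##JCAMP-DX= 4.24",
    "##XUNITS= 1/CM", "##YUNITS= ABSORBANCE",
    "##XFACTOR= 1", "##YFACTOR= 0.5",
    "##DELTAX= 2",
    "##XYDATA= (X++(Y..Y))",
    "1000 1 2 3 4",
    "1008 5 6",
    "##END="
  ), f)
  ss <- read_jcamp(f)
  expect_identical(ss$grid, seq(1000, 1010, by = 2))
  expect_identical(unname(ss$values[1, ]), 0.5 * (1:6))
})
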