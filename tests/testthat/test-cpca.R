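test_that("single-block CPCA degenerates to ordinary PCA", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  m <- fit_cpca(make_mb(list(X)), n_components = 3)
  Xc <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(Xc / sqrt(sum(Xc^2)), center = FALSE)
  ref <- align_signs(pc$x[, 1:3], m$global_scores)
  expect_lt(max(abs(ref - m$global_scores)), 1e-8)
})

test_that("two identical blocks share the super weight equally", {
  set.seed(22)
  X <- matrix(rnorm(10 * 4), 10, 4)
  m <- fit_cpca(make_mb(list(X, X)), n_components = 2)
  expect_lt(max(abs(abs(m$super_weights) - 1 / sqrt(2))), 1e-8)
})

test_that("global scores and variance match the concatenated-SVD oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    B <- sample(1:3, 1)
    blocks <- replicate(B, matrix(rnorm(n * sample(2:6, 1)), n), simplify = FALSE)
    K <- min(3, n - 1, sum(vapply(blocks, ncol, integer(1))))
    m <- fit_cpca(make_mb(blocks), n_components = K)
    oracle <- cpca_svd_oracle(blocks, K)
    aligned <- align_signs(oracle$scores, m$global_scores)
    expect_lt(max(abs(aligned - m$global_scores)), 1e-6)
    ev <- m$explained_variance
    got <- ev$fraction[ev$block == "global"]
    expect_lt(max(abs(got - oracle$ev[seq_len(K)])), 1e-6)
    # sign convention: largest-magnitude score entry positive
    for (k in seq_len(K)) {
      s <- m$global_scores[, k]
      expect_gt(s[which.max(abs(s))], 0)
    }
    # orthogonal global scores, unit-norm loadings and weights
    G <- crossprod(m$global_scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
    expect_lt(max(abs(colSums(m$super_weights^2) - 1)), 1e-10)
    for (b in seq_len(B)) {
      expect_lt(max(abs(colSums(m$block_loadings[[b]]^2) - 1)), 1e-10)
    }
  }
})

test_that("explained variance is complete for rank-1 blocks and drops with a noise block", {
  set.seed(24)
  t <- rnorm(9)
  blocks <- list(outer(t, runif(4)), outer(t, runif(3)))
  m <- fit_cpca(make_mb(blocks), n_components = 1)
  ev <- explained_variance_report(m)
  expect_equal(ev$global[1], 1, tolerance = 1e-10)
  d <- generate_dataset(small_config(seed = 25))
  mb <- assemble_blocks(average_replicates(
    preprocess_for_multiblock(d$spectra, "lipid")))
  m1 <- fit_cpca(mb, 2)
  noise <- mb
  noise$blocks$NOISE <- matrix(rnorm(nrow(mb$keys) * 40), nrow(mb$keys))
  noise$media <- c(noise$media, "NOISE")
  m2 <- fit_cpca(noise, 2)
  f1 <- m1$explained_variance
  f2 <- m2$explained_variance
  expect_lt(f2$fraction[f2$block == "global"][1],
            f1$fraction[f1$block == "global"][1])
})

test_that("training rows reproject onto their stored block scores", {
  d <- generate_dataset(small_config(seed = 26))
  prep <- preprocess_for_multiblock(d$spectra, "lipid")
  avg <- average_replicates(prep)
  mb <- assemble_blocks(avg)
  m <- fit_cpca(mb, 3)
  for (med in c("BHI", "MGY")) {
    rows <- filter_spectra(avg, .data$medium == med)
    ord <- match(rownames(mb$blocks[[med]]),
                 paste(rows$meta$strain_id, rows$meta$temperature_c,
                       sep = "__"))
    pr <- project_block(m, med, subset_ss(rows, ord))
    got <- as.matrix(pr[, paste0("PC", 1:3)])
    expect_lt(max(abs(got - m$block_scores[[med]])), 1e-10)
  }
  # projecting the stored column means gives the zero score
  mean_ss <- spectra_set(matrix(m$block_means$BHI, 1), m$grid, make_meta(1))
  z <- project_block(m, "BHI", mean_ss)
  expect_lt(max(abs(as.matrix(z[, paste0("PC", 1:3)]))), 1e-12)
  expect_error(project_block(m, "LB", mean_ss), "unknown medium")
  short <- spectra_set(matrix(1, 1, 3), c(1, 2, 3), make_meta(1))
  expect_error(project_block(m, "BHI", short), "grid")
})

test_that("replicate projections scatter around the averaged sample's score", {
  d <- generate_dataset(small_config(seed = 27))
  prep <- preprocess_for_multiblock(d$spectra, "lipid")
  avg <- average_replicates(prep)
  m <- fit_cpca(assemble_blocks(avg), 2)
  reps <- filter_spectra(prep, .data$medium == "BHI")
  pr <- project_block(m, "BHI", reps)
  agg <- pr |>
    dplyr::summarise(mean1 = mean(.data$PC1), se1 = stats::sd(.data$PC1) / sqrt(dplyr::n()),
                     .by = c("strain_id", "temperature_c"))
  stored <- tidy(m, "block_scores") |>
    dplyr::filter(.data$medium == "BHI")
  j <- dplyr::inner_join(agg, stored, by = c("strain_id", "temperature_c"))
  expect_true(all(abs(j$mean1 - j$PC1) <= pmax(2 * j$se1, 1e-8)))
})

test_that("n_components is validated and genus recovery works on separable data", {
  set.seed(28)
  X <- matrix(rnorm(6 * 3), 6, 3)
  expect_error(fit_cpca(make_mb(list(X)), n_components = 6), "exceeds")
  d <- generate_dataset(small_config(seed = 29))
  m <- fit_cpca(assemble_blocks(average_replicates(
    preprocess_for_multiblock(d$spectra, "lipid"))), 3)
  acc <- genus_recovery_accuracy(m, 3)
  expect_gte(acc$accuracy, 0.9)
  expect_identical(acc$n, 16L)
})
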