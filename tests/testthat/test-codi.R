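test_that("calibration sets are mean-centered per group", {
  d <- tiny_processed()
  train <- d$train

  # a spot of identical spectra gives exactly zero differences
  same <- spectra_set(train$wavenumber,
                      matrix(rep(train$intensities[1, ], 10), 10, byrow = TRUE),
                      data.frame(spectrum_id = paste0("q", 1:10),
                                 spot_id = "s", sample_id = "s", c_bsa = 1,
                                 c_al = 0.5, day = "d1"))
  set.seed(1)
  cal0 <- build_calibration_set(same, "within_sample")
  expect_true(all(cal0$diffs == 0))

  # between_concentration: one diff per sample, centered on the grand mean
  set.seed(1)
  calb <- build_calibration_set(train, "between_concentration")
  expect_equal(calb$l, length(unique(train$meta$sample_id)))
  expect_lt(max(abs(colSums(calb$diffs))), 1e-9)

  # within_sample: sample_per_group spectra per spot
  set.seed(1)
  calw <- build_calibration_set(train, "within_sample", sample_per_group = 5L)
  expect_equal(calw$l, 5L * length(unique(train$meta$spot_id)))

  # missing required metadata
  nometa <- train
  nometa$meta$day <- NA_character_
  expect_error(build_calibration_set(nometa, "instrument_calibration"),
               "requires metadata column 'day'")
})

test_that("synthetics equal their seeds when all differences are zero", {
  d <- tiny_processed()
  train <- subset_spectra(d$train, 1:8)
  zero_cal <- structure(list(source = "within_sample",
                             diffs = matrix(0, 4, n_channels(train)),
                             l = 4L, wavenumber = train$wavenumber,
                             group_descriptor = "zero"),
                        class = "codi_calibration")
  syn <- generate_synthetic(train, augmentation_config(zero_cal, 3L, rng_seed = 3L))
  expect_equal(n_spectra(syn), 24L)
  for (i in 1:8)
    for (j in 1:3)
      expect_identical(syn$intensities[(i - 1) * 3 + j, ], train$intensities[i, ])
  expect_true(all(syn$meta$synthetic))
  expect_identical(syn$meta$seed_id[1:3], rep(train$meta$spectrum_id[1], 3))
})

test_that("augmentation bookkeeping, ordering and determinism hold", {
  d <- tiny_processed()
  train <- d$train
  set.seed(2)
  cal <- build_calibration_set(train, "within_concentration")
  cfg <- augmentation_config(cal, n_per_seed = 15L, rng_seed = 3L)

  aug1 <- augment_training_set(train, cfg)
  expect_equal(n_spectra(aug1), n_spectra(train) * 16L)
  expect_equal(sum(!aug1$meta$synthetic), n_spectra(train))
  # originals first, unchanged
  expect_identical(aug1$intensities[seq_len(n_spectra(train)), ],
                   unname(train$intensities))

  aug2 <- augment_training_set(train, cfg)
  expect_identical(aug1$intensities, aug2$intensities)

  expect_error(augmentation_config(cal, n_per_seed = 0L), "n_per_seed")
  # axis mismatch is refused
  other <- crop_range(train, 500, 1700)
  expect_error(generate_synthetic(other, cfg), "axes do not match")
})

test_that("synthetic spectra are unbiased around their seed", {
  d <- tiny_processed()
  seed_spec <- subset_spectra(d$train, 1)
  set.seed(4)
  cal <- build_calibration_set(d$train, "within_sample")
  syn <- generate_synthetic(seed_spec,
                            augmentation_config(cal, 2000L, rng_seed = 9L))
  dev <- sweep(syn$intensities, 2, seed_spec$intensities[1, ])
  # E[Y] = seed: channel means within 4 standard errors of zero
  se <- apply(dev, 2, sd) / sqrt(nrow(dev))
  expect_true(all(abs(colMeans(dev)) <= 4 * se + 1e-12))
})

test_that("perturbation covariance follows the configured beta rule", {
  # oracle: Cov(Y - s) = sum_j sd_j^2 * t(diffs_j) %*% diffs_j
  set.seed(8)
  b <- 12L
  w <- seq_len(b)
  seeds <- spectra_set(w, matrix(rnorm(b), 1, b))
  diffs <- matrix(rnorm(5 * b, sd = 0.3), 5, b)
  diffs <- sweep(diffs, 2, colMeans(diffs))
  cal <- structure(list(source = "within_sample", diffs = diffs, l = 5L,
                        wavenumber = w, group_descriptor = "x"),
                   class = "codi_calibration")
  for (rule in c("one_over_l", "one_over_sqrt_l")) {
    sd_beta <- if (rule == "one_over_l") 1 / 5 else 1 / sqrt(5)
    expected <- sd_beta^2 * crossprod(diffs)
    syn <- generate_synthetic(seeds, augmentation_config(
      cal, 4000L, beta_sd_rule = rule, rng_seed = 5L))
    dev <- sweep(syn$intensities, 2, seeds$intensities[1, ])
    emp <- crossprod(dev) / nrow(dev)
    n <- nrow(dev)
    se <- sqrt((outer(diag(expected), diag(expected)) + expected^2) / n)
    expect_true(all(abs(emp - expected) <= 5 * se + 1e-12))
  }
})
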