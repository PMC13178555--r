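test_that("crop_range keeps inclusive bounds and is idempotent", {
  s <- spectra_set(350:1850, matrix(1, 2, 1501))
  cr <- crop_range(s, 400, 1800)
  expect_equal(n_channels(cr), 1401L)
  expect_equal(range(cr$wavenumber), c(400, 1800))
  expect_equal(crop_range(cr, 400, 1800), cr)   # identity once inside
  expect_error(crop_range(s, 1000, 1000), "lo must be < hi")
  expect_error(crop_range(s, 1800.2, 1800.9), "fewer than 2")
})

test_that("spike removal flags only genuine outliers", {
  set.seed(5)
  b <- 40L
  base <- matrix(rnorm(100 * b), 100, b)
  s <- spectra_set(seq_len(b), base)

  # identical spectra: SD = 0 everywhere, nothing may flag
  same <- spectra_set(seq_len(b), matrix(3, 100, b))
  expect_length(remove_spikes(same)$removed, 0L)

  # infinite threshold: identity
  expect_length(remove_spikes(s, threshold = Inf)$removed, 0L)

  # a spectrum with a channel at mean + 10 SD is always removed; at a 4 SD
  # threshold the expected false-positive count stays small
  res20 <- lapply(1:20, function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(100 * b), 100, b)
    m[7, 13] <- mean(m[, 13]) + 10 * sd(m[, 13])
    remove_spikes(spectra_set(seq_len(b), m), 4)$removed
  })
  expect_true(all(vapply(res20, function(r) 7L %in% r, logical(1))))
  expect_lt(mean(lengths(res20) - 1L), 1)   # < 1 false positive per spot

  expect_error(remove_spikes(subset_spectra(s, 1:2)), "at least 3")
})

test_that("iterative polynomial baseline removes smooth trends, keeps peaks", {
  w <- seq(400, 1800, by = 2)
  x <- (w - 1100) / 700
  poly4 <- 5 + 3 * x - 2 * x^2 + x^3 + 0.5 * x^4
  out <- correct_baseline(poly4, w, order = 4L)
  expect_lt(max(abs(out)), 1e-6 * max(abs(poly4)))

  out_const <- correct_baseline(rep(7, length(w)), w)
  expect_lt(max(abs(out_const)), 1e-9)

  # order-2 trend plus one narrow peak: peak height recovered within 5 %
  set.seed(3)
  peak <- 100 * exp(-(seq_along(w) - 350)^2 / (2 * 5^2))
  spec <- (2 + 0.004 * (w - 400) - 1e-6 * (w - 400)^2) + peak
  corr <- correct_baseline(spec, w, order = 4L)
  expect_lt(abs(max(corr) - 100) / 100, 0.05)

  expect_error(correct_baseline(1:4, 1:4, order = 4L), "more channels")
})

test_that("reference-peak normalization fixes the window max at 1", {
  w <- seq(900, 1050, by = 2)
  y <- exp(-(w - 976)^2 / 50) * 2
  n <- normalize_to_reference_peak(y, w)
  win <- abs(w - 976) <= 5
  expect_equal(max(n[win]), 1)
  expect_equal(n, y / 2)
  expect_equal(normalize_to_reference_peak(n, w), n)      # identity once normalized
  # scale invariance
  expect_equal(normalize_to_reference_peak(7.3 * y, w), n)
  expect_error(normalize_to_reference_peak(numeric(length(w)), w), "absent")
  expect_error(normalize_to_reference_peak(y, w, center = 2000, halfwidth = 5),
               "no channel")
})

test_that("clip_negatives is elementwise max(., 0) and idempotent", {
  expect_equal(clip_negatives(c(-0.1, 0.5, -2)), c(0, 0.5, 0))
  x <- c(0, 1, 2)
  expect_equal(clip_negatives(x), x)
  y <- rnorm(50)
  expect_equal(clip_negatives(clip_negatives(y)), clip_negatives(y))
})

test_that("full pipeline yields non-negative, reference-normalized spectra", {
  d <- tiny_processed()
  out <- d$train
  expect_true(all(out$intensities >= 0))
  win <- abs(out$wavenumber - 976) <= 5
  win_max <- apply(out$intensities[, win, drop = FALSE], 1, max)
  expect_true(all(abs(win_max - 1) < 1e-12))
  expect_true(all(out$wavenumber >= 400 & out$wavenumber <= 1800))
})

test_that("pipeline log lists exactly the injected cosmic spikes", {
  d <- tiny_processed()
  injected <- d$raw$train$meta$spectrum_id[d$raw$train$meta$spiked]
  logged <- unlist(d$log$removed, use.names = FALSE)
  expect_setequal(logged, injected)
  expect_equal(d$log$n_removed, length(injected))
})

test_that("pipeline propagates degenerate-group errors with context", {
  cfg <- tiny_sim_cfg(spectra_per_spot = 2L)   # too few spectra per spot
  d <- simulate_dataset(cfg)
  expect_error(preprocess_pipeline(d$train, preprocess_config()),
               "spot .*at least 3")
})
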