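test_that("spectral angle distance follows the arccos formula", {
  expect_equal(sad(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sad(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sad(c(1, 0), c(1, 1)), pi / 4)
  # scale insensitivity and symmetry
  x <- abs(rnorm(20)); y <- abs(rnorm(20))
  expect_equal(sad(x, 3.7 * y), sad(x, y))
  expect_equal(sad(x, y), sad(y, x))
  expect_error(sad(numeric(5), x[1:5]), "zero-norm")
})

test_that("total_loss combines SAD and the anchoring MSE", {
  x <- rbind(c(1, 0, 0), c(0, 1, 0))
  z <- rbind(c(0.5, 0.5), c(1, 0.4))
  perfect <- total_loss(x, 2 * x, z, z, w_c = 40)
  expect_equal(perfect$total, 0)

  targ <- rbind(c(0.4, 0.5), c(1.2, 0.5))
  no_anchor <- total_loss(x, rbind(c(1, 1, 0), c(0, 1, 1)), z, targ, w_c = 0)
  expect_equal(no_anchor$total, mean(c(pi / 4, pi / 4)))

  # two-spectrum batch against independent hand arithmetic
  xhat <- rbind(c(1, 1, 0), c(0, 2, 0))
  lo <- total_loss(x, xhat, z, targ, w_c = 40)
  sad_hand <- mean(c(acos(1 / sqrt(2)), acos(1)))
  mse_hand <- mean((z - targ)^2)
  expect_equal(lo$total, sad_hand + 40 * mse_hand, tolerance = 1e-10)

  expect_error(total_loss(x, xhat, z, rbind(c(NA, 1), c(1, 1))), "targets")
})

test_that("model building is deterministic with a non-negative decoder", {
  s <- ae_spec(rng_seed = 42L)
  w <- seq(400, 1800, by = 20)
  m1 <- build_model(s, w)
  m2 <- build_model(s, w)
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$params$Wdec >= 0))
  expect_equal(dim(m1$params$Wdec), c(length(w), 2L))

  # forward pass of a zero spectrum is finite
  fw <- ramanunmix:::.ae_forward_cpp(m1$params, matrix(0, length(w), 1))
  expect_true(all(is.finite(fw$latent)))
  expect_true(all(is.finite(fw$reconstruction)))

  em0 <- extract_endmembers(m1)
  expect_false(attr(em0, "trained"))
  expect_equal(nrow(em0$spectra), 2L)
})

test_that("the recorded epoch loss matches the R loss oracle before updates", {
  set.seed(1)
  b <- 40L; n <- 6L
  X <- matrix(abs(rnorm(b * n)), n, b)
  targ <- cbind(runif(n, 0, 2), 0.5)
  s <- ae_spec(max_epochs = 1L, batch_size = n, rng_seed = 5L)
  m0 <- build_model(s, seq_len(b))
  fw <- ramanunmix:::.ae_forward_cpp(m0$params, t(X))
  oracle <- total_loss(X, t(fw$reconstruction), t(fw$latent), targ, w_c = 40)
  fit <- ae_unmix(spectra_set(seq_len(b), X), s, targets = targ, model = m0)
  expect_equal(fit$loss_history$total[1], oracle$total, tolerance = 1e-10)
})

test_that("training reduces the loss, stays deterministic, keeps the decoder non-negative", {
  d <- tiny_processed()
  train <- subset_spectra(d$train, which(d$train$meta$spot_id %in%
                                           unique(d$train$meta$spot_id)[1:4]))
  s <- ae_spec(max_epochs = 3L, rng_seed = 3L)
  fit1 <- ae_unmix(train, s)
  fit2 <- ae_unmix(train, s)
  h <- fit1$loss_history
  expect_lt(h$total[nrow(h)], h$total[1])
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$params$Wd1, fit2$params$Wd1)
  expect_true(all(fit1$params$Wdec >= 0))
  expect_error(ae_unmix(train, s, targets = matrix(NA_real_,
                                                   n_spectra(train), 2)),
               "targets")
})

test_that("latent activations learn the concentrations on synthetic data", {
  d <- tiny_processed()
  set.seed(3)
  cal <- build_calibration_set(d$train, "within_concentration")
  aug <- augment_training_set(d$train,
                              augmentation_config(cal, 5L, rng_seed = 3L))
  fit <- ae_unmix(aug, ae_spec(rng_seed = 3L))
  pred <- predict(fit, d$train)
  expect_gt(cor(pred[, "BSA"], d$train$meta$c_bsa), 0.95)
  expect_true(all(pred >= 0))

  # zero spectrum: finite non-negative outputs
  z <- d$train
  z$intensities[1, ] <- 0
  predz <- predict(fit, subset_spectra(z, 1))
  expect_true(all(is.finite(predz)) && all(predz >= 0))

  # decoder endmembers resemble the generating references
  em <- extract_endmembers(fit, d$refs)
  dist <- match_components(em, d$refs)$distances
  expect_lt(max(dist), 0.15)
  expect_identical(rownames(em$spectra), d$refs$labels)
})
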