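test_that("nnls_solve recovers exact non-negative combinations", {
  em <- toy_basis(32L)
  y <- 0.3 * em$spectra[1, ] + 0.7 * em$spectra[2, ]
  coef <- nnls_solve(em, y)
  expect_equal(unname(coef), c(0.3, 0.7), tolerance = 1e-10)

  # negative target of one basis vector: constraint active, both coefficients 0
  w <- 1:8
  ortho <- endmember_set(w, rbind(c(1, 1, 0, 0, 0, 0, 0, 0) / sqrt(2),
                                  c(0, 0, 1, 1, 0, 0, 0, 0) / sqrt(2)),
                         c("e1", "e2"))
  expect_equal(unname(nnls_solve(ortho, -ortho$spectra[1, ])), c(0, 0))
  expect_error(nnls_solve(em, rnorm(10)), "different axes")
})

test_that("nnls objective matches the grid-search oracle", {
  set.seed(10)
  for (i in 1:10) {
    A <- matrix(abs(rnorm(16)), 2, 8)
    y <- rnorm(8)
    em <- endmember_set(1:8, A, c("a", "b"))
    coef <- nnls_solve(em, y)
    obj_lh <- sum((y - as.numeric(coef %*% A))^2)
    oracle <- nnls_grid_oracle(A, y)
    expect_lte(obj_lh, oracle$obj + 1e-9)
  }
})

test_that("the vectorized 2-component fast path equals Lawson-Hanson", {
  set.seed(20)
  A <- matrix(abs(rnorm(60)), 2, 30)
  Y <- matrix(rnorm(25 * 30), 25, 30)       # many rows force the clamped face
  fast <- ramanunmix:::nnls2_matrix(A, Y)
  for (i in seq_len(nrow(Y))) {
    lh <- pracma::lsqnonneg(t(A), Y[i, ])$x
    expect_equal(unname(fast[i, ]), unname(lh), tolerance = 1e-9)
  }
})

test_that("nnls_map returns exact ratios on noise-free mixtures", {
  cfg <- clean_sim_cfg()
  d <- simulate_dataset(cfg)
  keep <- d$references$wavenumber >= 400 & d$references$wavenumber <= 1800
  refs <- endmember_set(d$references$wavenumber[keep],
                        d$references$spectra[, keep, drop = FALSE],
                        d$references$labels)

  # on the raw (cropped) clean mixtures the decomposition is exact
  raw <- crop_range(d$train, 400, 1800)
  um_raw <- nnls_map(raw, refs, target = "BSA", reference = "AlOH3")
  expect_equal(um_raw$ratio, raw$meta$c_bsa / raw$meta$c_al, tolerance = 1e-10)

  # after the full pipeline the baseline estimate perturbs the ratio slightly
  pre <- preprocess_pipeline(d$train, preprocess_config())$set
  um <- nnls_map(pre, refs, target = "BSA", reference = "AlOH3")
  expect_equal(um$ratio, pre$meta$c_bsa / pre$meta$c_al, tolerance = 0.02)

  # zero spectrum cannot crash; its ratio is flagged absent
  z <- pre
  z$intensities[1, ] <- 0
  um2 <- nnls_map(z, refs)
  expect_true(is.na(um2$ratio[1]))
})

test_that("MCR-ALS error history is monotone and recovers bilinear data", {
  set.seed(11)
  w <- seq_len(120)
  S <- rbind(exp(-(w - 30)^2 / 60), exp(-(w - 85)^2 / 110))
  C <- cbind(runif(60, 0, 2), runif(60, 0.2, 1))
  fit <- mcr_als(C %*% S, mcr_config(rng_seed = 3L))
  expect_true(all(diff(fit$error_history) <= 1e-10))
  expect_true(all(fit$endmembers$spectra >= 0))
  expect_true(all(unclass(fit$abundances) >= 0))
  expect_equal(sqrt(rowSums(fit$endmembers$spectra^2)), c(1, 1),
               ignore_attr = TRUE, tolerance = 1e-9)
  rmse <- sqrt(mean((C %*% S - unclass(fit$abundances) %*%
                       fit$endmembers$spectra)^2))
  expect_lt(rmse, 1e-6)
  refs <- endmember_set(w, S, c("a", "b"))
  expect_lt(max(match_components(fit$endmembers, refs)$distances), 1e-4)
})

test_that("rank-deficient data yields a near-zero component plus warning", {
  w <- seq_len(50)
  s <- exp(-(w - 25)^2 / 40)
  D <- outer(runif(20, 0.5, 2), s)           # rank 1
  expect_warning(fit <- mcr_als(D, mcr_config(rng_seed = 1L)), "near-zero")
  ab <- unclass(fit$abundances)
  expect_lt(min(colSums(ab)) / max(colSums(ab)), 1e-6)
})

test_that("concentration calibration is the closed-form least-squares scale", {
  conc <- c(0.2, 0.5, 1, 1.5, 2)
  ab <- abundance_matrix(cbind(BSA = conc, AlOH3 = rep(1, 5)))
  expect_equal(fit_concentration_scale(ab, conc)$scale, 1)
  ab2 <- abundance_matrix(cbind(BSA = 2 * conc, AlOH3 = rep(1, 5)))
  expect_equal(fit_concentration_scale(ab2, conc)$scale, 0.5)
  ab0 <- abundance_matrix(cbind(BSA = rep(0, 5), AlOH3 = rep(1, 5)))
  expect_error(fit_concentration_scale(ab0, conc), "cannot calibrate")
})

test_that("calibrated MCR predictions recover noisy training concentrations", {
  d <- tiny_processed()
  fit <- mcr_als(d$train, mcr_config(rng_seed = 3L))
  m <- match_components(fit$endmembers, d$refs)
  ab <- unclass(fit$abundances)[, m$permutation, drop = FALSE]
  colnames(ab) <- d$refs$labels
  cal <- fit_concentration_scale(abundance_matrix(ab), d$train$meta$c_bsa)
  fit$endmembers <- endmember_set(fit$endmembers$wavenumber,
                                  fit$endmembers$spectra[m$permutation, ,
                                                         drop = FALSE],
                                  d$refs$labels)
  pred <- predict(fit, d$train, cal)
  means <- tapply(pred[, "BSA"], d$train$meta$c_bsa, mean, na.rm = TRUE)
  truth <- as.numeric(names(means))
  expect_true(all(abs(means - truth) / truth < 0.25))

  # zero spectrum: reference coefficient 0 -> flagged absent, no crash
  z <- d$train
  z$intensities[1, ] <- 0
  predz <- predict(fit, z, cal)
  expect_true(is.na(predz[1, "BSA"]))
})
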