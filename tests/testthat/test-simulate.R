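test_that("make_endmember evaluates sums of Gaussians", {
  w <- seq(400, 1800, by = 2)
  one <- make_endmember(list(peak_spec(976, 1, 8)), w)
  expect_equal(max(one), 1)
  expect_equal(w[which.max(one)], 976)
  expect_error(make_endmember(list(), w), "empty")

  # linearity: two far-apart peaks equal the sum of the individual spectra
  p1 <- peak_spec(500, 2, 5); p2 <- peak_spec(1500, 1, 5)
  expect_equal(make_endmember(list(p1, p2), w),
               make_endmember(list(p1), w) + make_endmember(list(p2), w))
})

test_that("adsorbed_fraction follows the configured isotherm", {
  expect_equal(adsorbed_fraction(1.5, 0.5, adsorption_model("linear")), 1.5)
  expect_equal(adsorbed_fraction(5, 0.5, adsorption_model("hard_cap", capacity = 2)), 2)
  # langmuir with q_max = 2.5, K = 2 at c = 5: 2.5 * 10 / 11
  lm <- adsorption_model("langmuir", capacity = 2.5, langmuir_K = 2)
  expect_equal(adsorbed_fraction(5, 0.5, lm), 2.5 * 10 / 11, tolerance = 1e-12)
  expect_error(adsorbed_fraction(-1, 0.5, lm), ">= 0")

  # monotone, bounded by both c and capacity
  cc <- seq(0, 8, by = 0.05)
  for (mod in list(adsorption_model("linear"), adsorption_model("hard_cap"),
                   adsorption_model())) {
    a <- adsorbed_fraction(cc, 0.5, mod)
    expect_true(all(diff(a) >= -1e-12))
    expect_true(all(a <= cc + 1e-12))
  }
  expect_true(all(adsorbed_fraction(cc, 0.5, adsorption_model()) <= 2 + 1e-12))
})

test_that("noise-free spots are exact linear mixtures of the references", {
  cfg <- clean_sim_cfg()
  refs <- reference_endmembers(cfg)
  sp <- simulate_spot(1.5, 0.5, cfg)
  expected <- 1.5 * refs$spectra["BSA", ] + 0.5 * refs$spectra["AlOH3", ]
  for (i in seq_len(n_spectra(sp)))
    expect_equal(as.numeric(sp$intensities[i, ]), expected, tolerance = 1e-12)
})

test_that("the peak-ratio vs concentration-ratio curve saturates", {
  # under the default isotherm the 1000/976 cm^-1 band ratio grows sublinearly
  cfg <- clean_sim_cfg()
  cfg$adsorption <- adsorption_model()        # langmuir default
  w <- cfg$wavenumber
  ratio_at <- function(cb) {
    sp <- simulate_spot(cb, 0.5, cfg)
    y <- sp$intensities[1, ]
    y[which.min(abs(w - 1000))] / y[which.min(abs(w - 976))]
  }
  r <- vapply(c(1, 2, 5), ratio_at, numeric(1))
  gain_low <- (r[2] - r[1]) / 1      # per mg/mL from 1 to 2
  gain_high <- (r[3] - r[2]) / 3     # per mg/mL from 2 to 5
  expect_lt(gain_high, gain_low)     # concave (saturating) response
})

test_that("simulate_dataset is deterministic and has the right shape", {
  cfg <- tiny_sim_cfg()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$train$intensities, d2$train$intensities)
  expect_identical(d1$test2$intensities, d2$test2$intensities)

  expect_equal(n_spectra(d1$train),
               length(cfg$c_bsa_grid) * cfg$replicates * cfg$spectra_per_spot)
  # test sets carry the extra saturated level
  expect_setequal(unique(d1$test1$meta$c_bsa), c(cfg$c_bsa_grid, 5))
  expect_equal(nrow(d1$references$spectra), 2L)
  expect_true(all(d1$references$spectra >= 0))

  one <- simulation_config(wavenumber = seq(380, 1820, by = 8),
                           replicates = 1L, spectra_per_spot = 1L,
                           spot = spot_model(grid_nx = 1L, grid_ny = 1L),
                           rng_seed = 1L)
  expect_equal(n_spectra(simulate_dataset(one)$train), 5L)
})

test_that("spike_rate 1 flags every simulated record", {
  cfg <- tiny_sim_cfg()
  cfg$spot$spike_rate <- 1
  sp <- simulate_spot(1, 0.5, cfg)
  expect_true(all(sp$meta$spiked))
})

test_that("NNLS concentration ratios are spatially uniform below saturation", {
  # end-to-end: simulate -> preprocess -> nonblind NNLS; the per-spectrum
  # BSA:Al ratio should track the adsorbed ratio with low spatial scatter
  d <- tiny_processed()
  um <- nnls_map(d$train, d$refs, target = "BSA", reference = "AlOH3")
  meta <- d$train$meta
  for (sp in unique(meta$spot_id)) {
    idx <- meta$spot_id == sp
    r <- um$ratio[idx]
    cb <- meta$c_bsa[idx][1]
    expected <- adsorbed_fraction(cb, 0.5, tiny_sim_cfg()$adsorption) / 0.5
    expect_lt(sd(r) / mean(r), 0.10)                   # spatial CV < 10 %
    expect_lt(abs(mean(r) - expected) / expected, 0.15)
  }
})
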