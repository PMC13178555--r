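# Shared fixtures, generated in code. Small problem sizes keep the unit suite
# fast; the acceptance tests run the benchmark-scale configuration.

# coarse, small simulation for unit tests; spectra_per_spot stays >= 24 so a
# single cosmic spike can exceed the 4 SD rule even though it inflates the SD
tiny_sim_cfg <- function(spectra_per_spot = 24L, rng_seed = 7L, ...) {
  simulation_config(wavenumber = seq(380, 1820, by = 8),
                    spectra_per_spot = spectra_per_spot,
                    spot = spot_model(grid_nx = 6L, grid_ny = 4L),
                    rng_seed = rng_seed, ...)
}

# noise-free variant: clean linear mixtures only
clean_sim_cfg <- function(spectra_per_spot = 6L, rng_seed = 1L, ...) {
  simulation_config(wavenumber = seq(380, 1820, by = 8),
                    spectra_per_spot = spectra_per_spot,
                    adsorption = adsorption_model("linear"),
                    unbound_fraction = 0,
                    spot = spot_model(grid_nx = 3L, grid_ny = 2L,
                                      ring_strength = 0, intensity_cv = 0,
                                      noise_sd = 0, spike_rate = 0,
                                      baseline_amp = 0),
                    rng_seed = rng_seed, ...)
}

# simple two-component orthogonal-ish basis on a short axis
toy_basis <- function(b = 64L) {
  w <- seq_len(b)
  e1 <- exp(-(w - b / 4)^2 / 18)
  e2 <- exp(-(w - 3 * b / 4)^2 / 30)
  endmember_set(w, rbind(e1, e2), c("BSA", "AlOH3"))
}

# random spectra_set for io round-trips
random_set <- function(n = 5L, b = 30L, seed = 1L) {
  set.seed(seed)
  spectra_set(sort(runif(b, 400, 1800)),
              matrix(rnorm(n * b), n, b),
              data.frame(spectrum_id = paste0("sp", seq_len(n)),
                         sample_id = "a", spot_id = "spot1",
                         replicate = "1", c_bsa = 1, c_al = 0.5))
}

# cached preprocessed tiny dataset + references, shared across test files
tiny_env <- new.env(parent = emptyenv())
tiny_processed <- function() {
  if (is.null(tiny_env$data)) {
    d <- simulate_dataset(tiny_sim_cfg())
    pre <- preprocess_pipeline(d$train, preprocess_config())
    keep <- d$references$wavenumber >= 400 & d$references$wavenumber <= 1800
    refs <- endmember_set(d$references$wavenumber[keep],
                          d$references$spectra[, keep, drop = FALSE],
                          d$references$labels)
    tiny_env$data <- list(raw = d, train = pre$set, log = pre$log, refs = refs)
  }
  tiny_env$data
}

# brute-force NNLS oracle: refine a non-negative grid around the best point
nnls_grid_oracle <- function(A, y, cmax = 4, levels = 3L, n_grid = 41L) {
  obj <- function(c1, c2) sum((y - c1 * A[1, ] - c2 * A[2, ])^2)
  lo <- c(0, 0); hi <- c(cmax, cmax)
  best <- c(0, 0)
  for (lev in seq_len(levels)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    vals <- outer(g1, g2, Vectorize(obj))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[ix[1]], g2[ix[2]])
    step <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- pmax(best - step, 0); hi <- best + step
  }
  list(coef = best, obj = obj(best[1], best[2]))
}
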