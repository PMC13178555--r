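# Synthetic model-vaccine spectra generator.
#
# Emulates dried-spot Raman measurements of BSA adsorbed to Al(OH)3:
# two Gaussian-band endmembers (Al(OH)3 with its dominant 976 cm^-1 band, a
# protein spectrum with 1000/1450/1660 cm^-1 bands), Langmuir-type adsorption
# saturation, coffee-ring spatial heterogeneity, lognormal per-spectrum
# intensity variation, smooth baseline drift, channel noise and cosmic spikes.

#' Gaussian peak specification
#' @param center band position (cm^-1)
#' @param height peak intensity (>= 0, arbitrary counts units)
#' @param width Gaussian sigma (cm^-1, > 0)
#' @return a `peak_spec` list
#' @export
peak_spec <- function(center, height = 1, width = 10) {
  stopifnot(height >= 0, width > 0)
  structure(list(center = center, height = height, width = width),
            class = "peak_spec")
}

default_peaks <- list(
  BSA = list(                      # protein bands: Phe ring, amide III, CH2, amide I
    peak_spec(850, 0.20, 10), peak_spec(1000, 1.00, 6),
    peak_spec(1250, 0.35, 28), peak_spec(1450, 0.55, 18),
    peak_spec(1660, 0.75, 22)),
  AlOH3 = list(                    # dominant internal-standard band + broad Al-O
    peak_spec(530, 0.25, 45), peak_spec(976, 1.00, 8)))

#' Evaluate a sum-of-Gaussians endmember on an axis
#'
#' @param peaks non-empty list of [peak_spec()]s
#' @param wavenumber axis to evaluate on
#' @return non-negative numeric vector, one value per channel
#' @export
make_endmember <- function(peaks, wavenumber) {
  if (!length(peaks)) stop("empty peak list", call. = FALSE)
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  y <- numeric(length(wavenumber))
  for (p in peaks)
    y <- y + p$height * exp(-(wavenumber - p$center)^2 / (2 * p$width^2))
  y
}

#' Adsorption model
#'
#' Relates nominal protein concentration to the amount actually bound to the
#' adjuvant. `capacity` is expressed as mg/mL of adsorbable protein per
#' 0.5 mg/mL of Al(OH)3 (the study's fixed adjuvant level), so the effective
#' maximum scales linearly with `c_al`.
#'
#' @param kind `"linear"` (no saturation), `"hard_cap"` (sharp cutoff) or
#'   `"langmuir"` (smooth isotherm)
#' @param capacity adsorbable protein (mg/mL) at 0.5 mg/mL Al(OH)3
#' @param langmuir_K Langmuir affinity constant, per (mg/mL)
#' @return an `adsorption_model` list
#' @export
adsorption_model <- function(kind = c("langmuir", "linear", "hard_cap"),
                             capacity = 2, langmuir_K = 4) {
  kind <- match.arg(kind)
  stopifnot(capacity > 0, langmuir_K > 0)
  structure(list(kind = kind, capacity = capacity, langmuir_K = langmuir_K),
            class = "adsorption_model")
}

#' Adsorbed protein fraction under an adsorption model
#'
#' Monotone non-decreasing in `c_bsa`, never exceeding `c_bsa`, and bounded by
#' the (Al-scaled) capacity for the saturating models.
#'
#' @param c_bsa nominal protein concentration(s), mg/mL (>= 0, vectorized)
#' @param c_al adjuvant concentration, mg/mL (>= 0)
#' @param model an [adsorption_model()]
#' @return adsorbed protein in mg/mL
#' @export
adsorbed_fraction <- function(c_bsa, c_al, model = adsorption_model()) {
  if (any(c_bsa < 0) || any(c_al < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  q_max <- model$capacity * c_al / 0.5
  switch(model$kind,
         linear = c_bsa,
         hard_cap = pmin(c_bsa, q_max),
         langmuir = pmin(c_bsa, q_max * model$langmuir_K * c_bsa /
                                  (1 + model$langmuir_K * c_bsa)))
}

#' Spot-level nuisance model
#'
#' @param grid_nx,grid_ny measurement grid dimensions over the dried spot
#' @param ring_strength radial intensity modulation in [-1, 1]; the effective
#'   sign follows the protein:adjuvant ratio (rim-bright coffee ring when
#'   protein dominates, centre-bright when the adjuvant gel dominates)
#' @param intensity_cv lognormal per-spectrum intensity coefficient of variation
#' @param noise_sd additive Gaussian channel noise (units of endmember height)
#' @param spike_rate probability that a spectrum carries one cosmic spike
#' @param baseline_amp amplitude of the smooth (order <= 2) baseline drift
#' @return a `spot_model` list
#' @export
spot_model <- function(grid_nx = 10L, grid_ny = 10L, ring_strength = 0.5,
                       intensity_cv = 0.25, noise_sd = 0.01,
                       spike_rate = 0.01, baseline_amp = 0.15) {
  stopifnot(grid_nx * grid_ny >= 1, abs(ring_strength) <= 1,
            intensity_cv >= 0, noise_sd >= 0,
            spike_rate >= 0, spike_rate <= 1, baseline_amp >= 0)
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 ring_strength = ring_strength, intensity_cv = intensity_cv,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 baseline_amp = baseline_amp),
            class = "spot_model")
}

#' Simulation configuration
#'
#' Defaults mirror the study design: five protein levels (0.2, 0.5, 1, 1.5,
#' 2 mg/mL) at fixed 0.5 mg/mL Al(OH)3, two replicate spots per level, 100
#' spectra per spot, plus an extra saturated 5 mg/mL level reserved for test
#' sets.
#'
#' @param wavenumber axis to simulate on (cm^-1)
#' @param peaks named list of peak lists, one entry per endmember
#' @param c_bsa_grid nominal protein training levels (mg/mL)
#' @param c_bsa_extra_test additional test-only levels (mg/mL); default 5
#' @param c_al adjuvant concentration (mg/mL)
#' @param replicates spots per concentration level
#' @param spectra_per_spot spectra recorded per spot
#' @param adsorption an [adsorption_model()]
#' @param spot a [spot_model()]
#' @param unbound_fraction fraction of non-adsorbed protein left in the dried
#'   pellet (residue signal); the washed test set uses 0
#' @param rng_seed integer seed controlling all randomness
#' @return a `simulation_config` list
#' @export
simulation_config <- function(wavenumber = seq(380, 1820, by = 2),
                              peaks = default_peaks,
                              c_bsa_grid = c(0.2, 0.5, 1, 1.5, 2),
                              c_bsa_extra_test = 5,
                              c_al = 0.5,
                              replicates = 2L,
                              spectra_per_spot = 100L,
                              adsorption = adsorption_model(),
                              spot = spot_model(),
                              unbound_fraction = 0.05,
                              rng_seed = 1L) {
  stopifnot(all(c_bsa_grid > 0), c_al > 0, replicates >= 1,
            spectra_per_spot >= 1, unbound_fraction >= 0, unbound_fraction <= 1)
  structure(list(wavenumber = as.numeric(wavenumber), peaks = peaks,
                 c_bsa_grid = c_bsa_grid, c_bsa_extra_test = c_bsa_extra_test,
                 c_al = c_al, replicates = as.integer(replicates),
                 spectra_per_spot = as.integer(spectra_per_spot),
                 adsorption = adsorption, spot = spot,
                 unbound_fraction = unbound_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Reference (noise-free) endmembers of a simulation
#' @param cfg a [simulation_config()]
#' @return an [endmember_set()] with the configured components
#' @export
reference_endmembers <- function(cfg) {
  spectra <- t(vapply(cfg$peaks, make_endmember, numeric(length(cfg$wavenumber)),
                      wavenumber = cfg$wavenumber))
  endmember_set(cfg$wavenumber, spectra, names(cfg$peaks))
}

# first n cells of an nx x ny grid, row-major, with radius from spot centre
grid_layout <- function(nx, ny, n) {
  gx <- rep(seq_len(nx), times = ny)[seq_len(n)]
  gy <- rep(seq_len(ny), each = nx)[seq_len(n)]
  rx <- if (nx > 1) (gx - (nx + 1) / 2) / ((nx - 1) / 2) else 0
  ry <- if (ny > 1) (gy - (ny + 1) / 2) / ((ny - 1) / 2) else 0
  list(gx = gx, gy = gy, r = sqrt(rx^2 + ry^2) / sqrt(2))  # r in [0, 1]
}

#' Simulate one dried-spot measurement
#'
#' Clean mixture = adsorbed(c_bsa) x E_BSA + c_al x E_Al (plus any unbound
#' residue), modulated by the radial coffee-ring weight and a lognormal
#' per-spectrum factor, with smooth random baseline, Gaussian channel noise
#' and (with probability `spike_rate`) one narrow cosmic spike per spectrum.
#' Spiked records are flagged in the metadata (`spiked` column). Uses the
#' current RNG state; seed at the call site for reproducibility.
#'
#' @param c_bsa nominal protein concentration (mg/mL)
#' @param c_al adjuvant concentration (mg/mL)
#' @param cfg a [simulation_config()]
#' @param spot_id,sample_id,replicate,day metadata for the spot
#' @return a [spectra_set()] with truth metadata (`c_bsa`, `c_al`,
#'   `c_bsa_adsorbed`, grid position, `spiked`)
#' @export
simulate_spot <- function(c_bsa, c_al, cfg,
                          spot_id = "spot1", sample_id = spot_id,
                          replicate = "1", day = "day1") {
  w <- cfg$wavenumber
  b <- length(w)
  n <- cfg$spectra_per_spot
  sm <- cfg$spot
  em <- reference_endmembers(cfg)
  ads <- adsorbed_fraction(c_bsa, c_al, cfg$adsorption)
  signal_bsa <- ads + cfg$unbound_fraction * (c_bsa - ads)
  clean <- signal_bsa * em$spectra["BSA", ] + c_al * em$spectra["AlOH3", ]

  lay <- grid_layout(sm$grid_nx, sm$grid_ny, n)
  # coffee ring: rim-bright when protein dominates (ratio > ~2), centre-bright
  # below; exp keeps the weight positive
  ratio <- signal_bsa / c_al
  s_eff <- sm$ring_strength * tanh(ratio - 2)
  wgt <- exp(s_eff * (lay$r^2 - 0.5))
  sigma_ln <- sqrt(log(1 + sm$intensity_cv^2))
  gain <- wgt * exp(stats::rnorm(n, -sigma_ln^2 / 2, sigma_ln))

  ints <- tcrossprod(gain, clean)            # n x b clean signal
  if (sm$baseline_amp > 0) {                 # smooth order-<=2 drift, >= 0
    t01 <- (w - min(w)) / diff(range(w))
    co <- matrix(stats::runif(3 * n, -1, 1), n, 3)
    bl <- co[, 1] %o% rep(1, b) + co[, 2] %o% t01 + co[, 3] %o% t01^2
    bl <- sm$baseline_amp * (bl - apply(bl, 1, min))
    ints <- ints + bl
  }
  if (sm$noise_sd > 0)
    ints <- ints + matrix(stats::rnorm(n * b, 0, sm$noise_sd), n, b)
  spiked <- stats::runif(n) < sm$spike_rate
  amp <- 50 * max(clean)
  for (i in which(spiked)) {
    ch <- sample.int(b, 1)
    ints[i, ch] <- ints[i, ch] + amp * stats::runif(1, 0.5, 1)
    if (ch < b && stats::runif(1) < 0.5)     # occasional two-channel spike
      ints[i, ch + 1] <- ints[i, ch + 1] + amp * stats::runif(1, 0.1, 0.4)
  }
  meta <- data.frame(
    spectrum_id = sprintf("%s_%03d", spot_id, seq_len(n)),
    sample_id = sample_id, spot_id = spot_id, replicate = as.character(replicate),
    grid_x = lay$gx, grid_y = lay$gy,
    c_bsa = c_bsa, c_al = c_al, day = day,
    c_bsa_adsorbed = ads, spiked = spiked,
    stringsAsFactors = FALSE)
  spectra_set(w, ints, meta)
}

simulate_split <- function(cfg, levels, tag, day) {
  spots <- list()
  for (cb in levels) for (r in seq_len(cfg$replicates)) {
    sid <- sprintf("%s_bsa%g_rep%d", tag, cb, r)
    spots[[sid]] <- simulate_spot(cb, cfg$c_al, cfg, spot_id = sid,
                                  sample_id = sid, replicate = as.character(r),
                                  day = day)
  }
  bind_spectra(spots)
}

#' Simulate a full study: training set, two test sets, reference endmembers
#'
#' The training set covers `c_bsa_grid` x `replicates` spots. Both test sets
#' are drawn with fresh seeds, include the extra saturated level(s), and use
#' slightly perturbed nuisance parameters; test set 2 emulates the washed
#' pellet variant (no unbound-protein residue, slightly lower drift).
#'
#' @param cfg a [simulation_config()]
#' @return list with `train`, `test1`, `test2` ([spectra_set()]s) and
#'   `references` (an [endmember_set()])
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(cfg$rng_seed)
  train <- simulate_split(cfg, cfg$c_bsa_grid, "train", "day1")

  test_levels <- c(cfg$c_bsa_grid, cfg$c_bsa_extra_test)
  cfg1 <- cfg
  cfg1$spot$intensity_cv <- cfg$spot$intensity_cv * 1.1
  cfg1$spot$baseline_amp <- cfg$spot$baseline_amp * 1.2
  set.seed(cfg$rng_seed + 1000L)
  test1 <- simulate_split(cfg1, test_levels, "test1", "day2")

  cfg2 <- cfg
  cfg2$unbound_fraction <- 0                  # washed pellet
  cfg2$spot$baseline_amp <- cfg$spot$baseline_amp * 0.8
  set.seed(cfg$rng_seed + 2000L)
  test2 <- simulate_split(cfg2, test_levels, "test2", "day3")

  list(train = train, test1 = test1, test2 = test2,
       references = reference_endmembers(cfg))
}
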