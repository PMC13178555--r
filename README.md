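# ramanunmix

Quantifying a protein antigen adsorbed to an aluminium-hydroxide adjuvant
from Raman spectra of dried sample spots — the situation of adjuvanted
("model vaccine") formulations, where the adsorbed antigen defeats ordinary
solution-phase protein assays.

The package is aimed at chemometrics / biopharmaceutical-QC work and
implements the complete computational workflow as a tested library plus a
command-line wrapper:

* **Preprocessing** per dried spot: crop to 400–1800 cm⁻¹, cosmic-spike
  removal (4 SD per-channel rule), iterative order-4 polynomial baseline
  correction, normalization to the Al(OH)₃ internal-standard band at
  976 cm⁻¹, negative clipping.
* **Linear unmixing**: non-negative least squares (Lawson–Hanson) against
  known reference endmembers, and blind MCR-ALS
  (`D ≈ C S`, both factors non-negative, unit-L2 endmembers, seeded random
  initialization) with a single training-set scaling factor for
  concentration calibration.
* **Concentration-anchored convolutional autoencoder**: encoder
  conv(16×3) → conv(16×5) → dense 128 → latent (one unit per endmember),
  decoder a bias-free non-negative linear map whose weight columns are the
  endmember spectra; loss `L = SAD + w_c·MSE` with the mean-squared-error
  term anchoring latent activations to known concentrations in mg/mL
  (`w_c = 40`); Adam, batch 8, ≤10 epochs with early stopping. The training
  loop is C++ (RcppArmadillo), deterministic under a seed.
* **CODI augmentation** (contextual out-of-distribution integration):
  synthetic spectra `Y = s + Σⱼ Σₖ βₖ(uₖⱼ − ūⱼ)` built from mean-centered
  calibration sets for four variability sources, `βₖ ~ N(0, (1/lⱼ)²)`.
* **Metrics and benchmark**: cosine distance with minimal-cost component
  matching, per-spot/per-level concentration MSE, recovery %, RSD %, inverse
  coefficient of variation, and `run_benchmark()` wiring the AE-vs-MCR
  comparison end to end.
* **Simulator**: a synthetic two-component model-vaccine study (BSA-like
  protein + Al(OH)₃-like adjuvant endmembers, Langmuir adsorption
  saturation, coffee-ring spatial heterogeneity, baseline drift, channel
  noise, cosmic spikes) providing training and two held-out test sets with
  full ground truth.

## Worked example

Simulate a small study, preprocess it, augment, train the anchored
autoencoder and read concentrations out of its latent space:

```r
library(ramanunmix)

cfg <- benchmark_sim_config(spectra_per_spot = 20L, rng_seed = 7L)
d   <- simulate_dataset(cfg)                  # train, test1, test2, references
pp  <- preprocess_pipeline(d$train, preprocess_config())$set

set.seed(3)
cal <- build_calibration_set(pp, "within_concentration")
aug <- augment_training_set(pp, augmentation_config(cal, 15L, rng_seed = 3L))
fit <- ae_unmix(aug, ae_spec(rng_seed = 3L))

pred <- predict(fit, pp)                      # latent activations, mg/mL
round(tapply(pred[, "BSA"], pp$meta$c_bsa, mean), 3)
#>   0.2   0.5     1   1.5     2
#> 0.199 0.496 0.979 1.483 1.969
```

The per-level means sit within a few percent of the nominal 0.2–2 mg/mL
grid. The decoder weights are the endmember estimates; matched against the
simulation references they are nearly indistinguishable from the true
spectra (cosine distance 0 = identical, 1 = orthogonal):

```r
refs <- with(d$references, {
  keep <- wavenumber >= 400 & wavenumber <= 1800
  endmember_set(wavenumber[keep], spectra[, keep], labels)
})
match_components(extract_endmembers(fit, refs), refs)$distances
#>          BSA        AlOH3
#> 0.0005004402 0.0377774302
```

The nonblind NNLS baseline on the same data gives the per-spectrum
concentration-ratio map (`nnls_map(pp, refs)`), and `mcr_als(pp)` the blind
factorization with `fit_concentration_scale()` / `predict()` for calibrated
concentrations.

The full five-seed comparison is one call (several minutes on one core):

```r
report <- run_benchmark()
report
#> benchmark_report: 493 train spectra, seeds {3, 15, 22, 34, 42}, CODI source within_concentration
#>   ae               endmember cosine distance: BSA 0.0005+/-0.0001, AlOH3 0.0296+/-0.0023 | test MSE 0.001805
#>   ae_unaugmented   endmember cosine distance: BSA 0.0001+/-0.0000, AlOH3 0.0397+/-0.0031 | test MSE 0.004423
#>   mcr              endmember cosine distance: BSA 0.0006+/-0.0000, AlOH3 0.0355+/-0.0003 | test MSE 0.005553
#>   elapsed: 483.8 s
```

Here the CODI-augmented autoencoder predicts held-out concentrations about
three times more accurately than calibrated MCR (test MSE 0.0018 vs 0.0056
mg²/mL²), beats the unaugmented autoencoder at Al(OH)₃ endmember extraction,
and both methods underestimate the saturated 5 mg/mL test level (predicting
≈2.1–2.4 mg/mL), as the adsorption capacity of the adjuvant dictates.

A thin CLI over the same functions is installed at
`system.file("cli/ramanunmix.R", package = "ramanunmix")` with subcommands
`run`, `simulate`, `preprocess`, `augment`, `unmix-nnls`, `unmix-mcr`,
`train-ae` and `benchmark`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ramanunmix.R", package="ramanunmix"))')" \
    run --outdir out/ --seed 1
```

Stage configuration is YAML; see `?run_pipeline`.

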