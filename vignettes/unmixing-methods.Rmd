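---
title: "Quantifying adsorbed protein in adjuvanted formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adsorbed protein in adjuvanted formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aluminium-hydroxide-adjuvanted vaccines carry their protein antigen adsorbed
onto the adjuvant gel, which defeats the usual solution-phase protein assays.
Raman spectroscopy of dried sample spots sees both components at once: the
adjuvant contributes a strong band near 976 cm⁻¹, the protein contributes
bands near 1000 cm⁻¹ (phenylalanine ring breathing), 1450 cm⁻¹ (CH
deformation) and 1660 cm⁻¹ (amide I). Because the adjuvant concentration is
fixed and known (0.5 mg/mL in the designs this package emulates), its band is
an internal standard: the protein concentration can be read off the
protein-to-adjuvant spectral ratio rather than from absolute intensities,
which vary strongly across a dried spot.

`ramanunmix` implements the full computational workflow around that idea:
spectral preprocessing, linear unmixing baselines (NNLS against known
references, MCR-ALS when references are unknown), a concentration-anchored
convolutional autoencoder, CODI data augmentation, and the evaluation metrics
used to compare the methods. Because no raw measurement set is distributed
with the package, a simulator generates spectra with the same structure, and
every claim the test suite makes is made on that synthetic data.

## Preprocessing

Five steps, in fixed order, applied per dried spot:

1. **Crop** to 400–1800 cm⁻¹ (inclusive), the region holding the relevant
   bands.
2. **Cosmic spike removal.** Per channel, mean and sample SD are computed
   across the spot's spectra; a spectrum holding any intensity further than 4
   SD from its channel mean is removed whole. Removing the whole spectrum
   rather than patching single values keeps the data matrix rectangular, and
   with ~100 spectra per spot the loss is cheap; channels with zero SD never
   flag, so a spot of identical spectra passes untouched.
3. **Baseline correction** by an iterative fit-and-clamp polynomial of order
   4: fit the polynomial, clamp the working curve to the fit wherever it
   exceeds it (so peaks stop pulling the fit upward), and refit until the
   baseline changes by less than `1e-6` in relative L2 norm (at most 100
   iterations). A single unconstrained order-4 fit bows into the peaks; the
   clamp loop is the standard cure. The design matrix uses orthogonal
   polynomials on a centered axis for conditioning.
4. **Normalization** to the internal standard: each spectrum is divided by
   its maximum intensity within 976 ± 5 cm⁻¹. A window rather than the exact
   channel tolerates small wavenumber-calibration shifts. A window maximum at
   or below `1e-9` means the internal standard is absent and is an error, not
   a silent division.
5. **Clipping** of negative values (a side effect of baseline subtraction)
   to zero.

After the pipeline every spectrum is non-negative with its reference-window
maximum exactly 1.

## Linear unmixing

**NNLS.** With reference endmember spectra available, each mixture spectrum
is decomposed as a non-negative linear combination by Lawson–Hanson active
sets (delegated to `pracma::lsqnonneg`; an exact closed-form fast path covers
the two-component case and is tested against the general solver). The
per-spectrum coefficient ratio BSA : Al(OH)₃ estimates the concentration
ratio on one overall scale, with no per-spot renormalization.

**MCR-ALS.** Without references, the data matrix is factorized as
`D ≈ C S` with both factors non-negative, by alternating exact NNLS solves.
Each iteration rescales the endmember rows to unit L2 norm, pushing the scale
into `C`; this fixes the scale ambiguity of the bilinear model (the rotational
ambiguity remains, bounded by the non-negativity constraints — the Al
endmember can absorb some protein signal when no protein-free mixture is in
the data, which is visible in the benchmark results). `S` is initialized
uniform(0, 1) under a stated seed; five restart seeds (3, 15, 22, 34, 42)
provide the variability estimates. The stopping rule — relative change of the
reconstruction error below `1e-8`, at most 500 iterations — was chosen so the
noiseless oracle test converges fully; exact per-step minimization makes the
error history monotone, which the tests assert on every fit. Concentrations
come from a single scaling factor `a = Σ rc / Σ r²` (least squares through
the origin) fitted between the training-set coefficient ratios `r` and the
known concentrations `c`, applied to all predictions.

## The concentration-anchored autoencoder

The encoder is two 1-D convolutional blocks (16 filters of width 3, then 16
of width 5; ReLU; zero "same" padding; stride 1) followed by dense layers of
128 and `latent_dim` units (LeakyReLU, slope 0.02). `latent_dim` equals the
number of endmembers (2 here). The decoder is a single linear map back to
the channels with **no bias** and **non-negative weights** — reconstructions
are conic combinations of the weight columns, so the columns are directly
interpretable as endmember spectra.

The loss is `L = SAD + w_c · MSE`, where SAD is the batch-mean spectral angle
`arccos(⟨x, x̂⟩/(‖x‖‖x̂‖))` between input and reconstruction — scale-blind,
so spot-to-spot intensity variation does not dominate — and the MSE term
anchors the latent activations to the known component concentrations in
mg/mL, averaged over batch and components, with `w_c = 40`. Both latent units
are anchored (protein and adjuvant; the adjuvant target is the constant 0.5
mg/mL). The anchoring is what makes the latent space read out directly as
concentrations at prediction time; activations are clamped at zero only when
reporting predictions, never inside the loss.

Training: Adam (learning rate 0.001), batch size 8, at most 10 epochs, early
stopping on the *training* loss (no validation split) with patience 3 and
min_delta 0.0005. The decoder weights are projected onto `≥ 0` after every
optimizer step. Initialization is Glorot-uniform under a fixed seed (the
decoder starts from the absolute value), and batch shuffling derives from the
same seed, so a run is bit-reproducible single-threaded. The training loop is
implemented in C++ (RcppArmadillo) with batched GEMMs; on one CPU core an
epoch over 8 000 spectra of 351 channels takes a few seconds.

Since the anchoring ties latent units to nominal concentrations while the
spectra encode *adsorbed* protein, the network absorbs the (mild) adsorption
nonlinearity into the encoder — the linear methods cannot, which is exactly
the behavioural difference the benchmark probes.

## CODI augmentation

Contextual out-of-distribution integration generates synthetic spectra
around a seed spectrum `s`:

`Y = s + Σⱼ fⱼ`, with `fⱼ = Σₖ βₖ (uₖⱼ − ūⱼ)`

where the `uₖⱼ` are the `lⱼ` spectra of calibration set `j`, centered on
their group mean, and the `βₖ` are i.i.d. Gaussian with mean 0 and SD
`1/lⱼ`. The SD convention is ambiguous in its usual typography (`1/lⱼ` vs
`1/√lⱼ`); this package defaults to the literal `1/lⱼ` and exposes
`one_over_sqrt_l`, under which the perturbation covariance equals the
calibration set's empirical scatter `Σⱼ σ²ⱼ diffsⱼᵀ diffsⱼ` exactly — the
covariance identity holds under either rule and is tested against the closed
form. Group means are computed from *all* group members even when only five
spectra per group are sampled into the calibration set: sampling reduces
`lⱼ`, centering should not add bias. Each β is redrawn per synthetic spectrum
and per difference spectrum, so `E[Y] = s`.

Four calibration-set constructions are provided: within-sample (per dried
spot, centered on the spot mean), within-concentration (per level, sampled
per spot, centered on the level mean), between-concentration (one mean
spectrum per sample, centered on the grand mean) and instrument-calibration
(per measurement day, centered on the overall mean). The default workflow
augments with within-concentration variability — the best performer in the
source comparison — at 15 synthetics per seed spectrum, which takes a
1 000-spectrum training set to 16 000, and repeats generation under the five
fixed seeds.

## The simulator

The synthetic study mirrors the measurement design: protein levels 0.2, 0.5,
1, 1.5 and 2 mg/mL at fixed 0.5 mg/mL adjuvant, two replicate spots per
level, 100 spectra per spot on a rectangular grid (one training set, two test
sets with fresh seeds, test sets additionally carrying a saturated 5 mg/mL
level). Endmembers are sums of Gaussians — the simplest shape satisfying
every property the tests need — with the band positions above.

Structure the generator emulates, and the one-time parameter choices:

* **Adsorption saturation.** A Langmuir isotherm
  `min(c, q_max K c / (1 + K c))` with capacity 2 mg/mL per 0.5 mg/mL
  adjuvant and `K = 4 (mg/mL)⁻¹`. The knee is placed so the nominal 2 mg/mL
  level sits at the saturation shoulder (~89 % adsorbed — a faint unbound
  residue) and 5 mg/mL is clearly saturated (~38 %), consistent with gel
  electrophoresis of the emulated design showing residual supernatant protein
  at 2 and 5 mg/mL. A 5 % fraction of the unbound protein remains in the
  dried pellet as residue signal; the "washed" second test set sets this
  to zero.
* **Coffee-ring heterogeneity.** A multiplicative radial weight
  `exp(s·(r² − ½))` whose sign follows the protein:adjuvant ratio
  (`s = ring_strength · tanh(ratio − 2)`): rim-bright when protein dominates,
  centre-bright when the adjuvant gel dominates. No fluid dynamics — just the
  qualitative spatial pattern, which normalization to the internal standard
  must (and does) cancel.
* **Nuisance terms.** Per-spectrum lognormal intensity factor (CV 0.25),
  additive Gaussian channel noise (SD 0.01 of unit peak height), smooth
  random baseline of order ≤ 2 (amplitude 0.15) — removable by the order-4
  correction — and cosmic spikes (probability 0.01 per spectrum, one or two
  channels, ~50× the signal), flagged in the metadata so the spike-removal
  log can be checked exactly.

What the simulator does **not** model: real Raman cross sections, instrument
response, water/quartz background, wavenumber miscalibration, day-to-day
drift beyond fresh noise seeds, or chemistry beyond the isotherm. Passing
tests therefore demonstrate the *computational* correctness and the relative
behaviour of the methods under controlled conditions, not instrument-level
performance on real formulations.

## Benchmark design and problem sizes

`run_benchmark()` wires the whole pipeline: simulate → preprocess → per seed
(3, 15, 22, 34, 42) CODI-augment and train an AE, fit an MCR restart →
match components to the references by minimal total cosine distance
(exhaustive over permutations) → predict concentrations on the training set
and both test sets → aggregate. The package's benchmark scale is 4 cm⁻¹
channel spacing (351 channels after cropping) and 50 spectra per spot —
500 training spectra, 8 000 after augmentation — sizes chosen so the full
five-seed benchmark, including the unaugmented-AE arm, completes in minutes
on a single core while keeping every qualitative feature of the full-size
design. The simulator's own defaults remain at the study size (100 per spot,
2 cm⁻¹).

Reported metrics follow the conventions: cosine distance between matched and
reference endmembers (mean ± SD over seeds); concentration MSE per spectrum,
averaged per spot, then mean ± SD across replicates per level, with the
saturated 5 mg/mL level excluded from MSE and recovery and reported in a
separate saturation panel; recovery (mean predicted / nominal, in %) and RSD
(SD / mean over replicate-level means, in %); and the inverse coefficient of
variation of the five endmember estimates per channel (mean / sample SD,
zero-SD channels excluded and counted). Sample (n−1) SDs are used everywhere.

## Numerical choices and degenerate inputs

* NNLS ties/degeneracy: a zero reference coefficient makes the
  concentration ratio undefined; it is reported `NA`, never imputed.
* MCR component death (rank-deficient data): the dead endmember row is reset
  to a uniform unit vector with zero abundance, a warning is emitted, and the
  error history stays monotone.
* SAD near collinearity: the cosine is clamped to `[-1+1e-9, 1-1e-9]` and the
  gradient denominator floored, so training cannot produce NaN from a perfect
  reconstruction; zero-norm vectors are a domain error in the metric and are
  skipped (zero gradient) inside training batches.
* Baseline fitting uses a QR of an orthogonal-polynomial design, shared
  across spectra of a set; rank deficiency is an explicit error.
* Axis mismatches between sets, bases and models are errors everywhere —
  resampling across axes is deliberately out of scope.

## Known limitations

* The AE's endmember quality depends on the augmentation source and seed;
  its variability across seeds is genuinely larger than MCR's, as the
  benchmark report's SDs show.
* The MCR rotational ambiguity means its Al(OH)₃ endmember can carry protein
  admixture when no low-ratio mixtures are present; with the default design
  the effect is small but visible in the cosine distances.
* Latent anchoring assumes every training spectrum (including synthetics,
  which inherit their seed's metadata) has known concentrations; the package
  refuses to train without them rather than guessing.
* The simulator's nuisance magnitudes are plausible but not fitted to any
  instrument; absolute MSE values on synthetic data should not be read as
  instrument performance.
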