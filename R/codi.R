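# Contextual Out-of-Distribution Integration (CODI).
#
# A calibration set encodes one source of spectral variability as mean-centered
# difference spectra (u_kj - ubar_j). A synthetic spectrum around a seed s_i is
#   Y = s_i + sum_j f_j,   f_j = sum_k beta_k (u_kj - ubar_j),
# with beta_k i.i.d. Gaussian, mean 0 and SD 1/l_j (or 1/sqrt(l_j)), where l_j
# is the number of difference spectra in calibration set j.

codi_sources <- c("within_sample", "within_concentration",
                  "between_concentration", "instrument_calibration")

#' Build a CODI calibration set for one variability source
#'
#' Grouping and centering depend on the source:
#' \describe{
#'   \item{within_sample}{per dried spot, sample `sample_per_group` spectra and
#'     center each on its spot's full mean.}
#'   \item{within_concentration}{per concentration level, sample
#'     `sample_per_group` spectra from each spot and center on the
#'     concentration mean.}
#'   \item{between_concentration}{one mean spectrum per sample (spot), centered
#'     on the grand mean of those sample means; `sample_per_group` is ignored.}
#'   \item{instrument_calibration}{per measurement day, sample
#'     `sample_per_group` spectra and center on the overall mean across days.}
#' }
#' Group means are always computed from all group members, not only the
#' sampled ones. Uses the current RNG state; seed at the call site.
#'
#' @param set a [spectra_set()] with the metadata the source requires
#'   (`spot_id`, `c_bsa`, or `day`)
#' @param source one of `"within_sample"`, `"within_concentration"`,
#'   `"between_concentration"`, `"instrument_calibration"`
#' @param sample_per_group spectra sampled per group (default 5)
#' @return a `codi_calibration` object: fields `source`, `diffs`
#'   (l_j x n_channels), `l`, `wavenumber`, `group_descriptor`
#' @export
build_calibration_set <- function(set, source = codi_sources,
                                  sample_per_group = 5L) {
  stopifnot(inherits(set, "spectra_set"))
  source <- match.arg(source)
  meta <- set$meta
  need <- switch(source,
                 within_sample = "spot_id",
                 within_concentration = c("c_bsa", "spot_id"),
                 between_concentration = "sample_id",
                 instrument_calibration = "day")
  for (col in need)
    if (all(is.na(meta[[col]])))
      stop(sprintf("source '%s' requires metadata column '%s'", source, col),
           call. = FALSE)

  sample_rows <- function(idx) {
    if (length(idx) < 2L)
      stop(sprintf("calibration group with fewer than 2 spectra (source '%s')",
                   source), call. = FALSE)
    idx[sample.int(length(idx), min(sample_per_group, length(idx)))]
  }

  diffs <- switch(source,
    within_sample = {
      parts <- lapply(split(seq_len(nrow(meta)), meta$spot_id), function(idx) {
        mu <- colMeans(set$intensities[idx, , drop = FALSE])
        sweep(set$intensities[sample_rows(idx), , drop = FALSE], 2, mu)
      })
      do.call(rbind, parts)
    },
    within_concentration = {
      parts <- lapply(split(seq_len(nrow(meta)), meta$c_bsa), function(idx) {
        mu <- colMeans(set$intensities[idx, , drop = FALSE])  # concentration mean
        sel <- unlist(lapply(split(idx, meta$spot_id[idx]), sample_rows))
        sweep(set$intensities[sel, , drop = FALSE], 2, mu)
      })
      do.call(rbind, parts)
    },
    between_concentration = {
      means <- t(vapply(split(seq_len(nrow(meta)), meta$sample_id), function(idx)
        colMeans(set$intensities[idx, , drop = FALSE]),
        numeric(n_channels(set))))
      if (nrow(means) < 2L)
        stop("between_concentration needs at least 2 samples", call. = FALSE)
      sweep(means, 2, colMeans(means))
    },
    instrument_calibration = {
      grand <- colMeans(set$intensities)       # overall calibration mean
      parts <- lapply(split(seq_len(nrow(meta)), meta$day), function(idx)
        sweep(set$intensities[sample_rows(idx), , drop = FALSE], 2, grand))
      do.call(rbind, parts)
    })

  if (nrow(diffs) < 2L)
    stop("calibration set must contain at least 2 difference spectra", call. = FALSE)
  structure(list(source = source, diffs = unname(diffs), l = nrow(diffs),
                 wavenumber = set$wavenumber,
                 group_descriptor = sprintf("%s (l = %d)", source, nrow(diffs))),
            class = "codi_calibration")
}

#' @export
print.codi_calibration <- function(x, ...) {
  cat(sprintf("codi_calibration: %s, %d difference spectra x %d channels\n",
              x$source, x$l, ncol(x$diffs)))
  invisible(x)
}

#' Augmentation configuration
#'
#' @param sources list of [build_calibration_set()] results (the f_1 ... f_m)
#' @param n_per_seed synthetic spectra generated per seed spectrum (default 15)
#' @param beta_sd_rule SD of the Gaussian scaling factors: `"one_over_l"`
#'   (literal 1/l_j) or `"one_over_sqrt_l"` (makes the perturbation covariance
#'   equal the calibration set's empirical scatter)
#' @param rng_seed integer seed (replicate runs in the study use 3, 15, 22,
#'   34, 42)
#' @return an `augmentation_config` list
#' @export
augmentation_config <- function(sources, n_per_seed = 15L,
                                beta_sd_rule = c("one_over_l", "one_over_sqrt_l"),
                                rng_seed = 3L) {
  beta_sd_rule <- match.arg(beta_sd_rule)
  if (inherits(sources, "codi_calibration")) sources <- list(sources)
  if (!length(sources) || !all(vapply(sources, inherits, TRUE, "codi_calibration")))
    stop("sources must be one or more codi_calibration objects", call. = FALSE)
  if (n_per_seed < 1L) stop("n_per_seed must be >= 1", call. = FALSE)
  structure(list(sources = sources, n_per_seed = as.integer(n_per_seed),
                 beta_sd_rule = beta_sd_rule, rng_seed = as.integer(rng_seed)),
            class = "augmentation_config")
}

beta_sd <- function(l, rule) if (rule == "one_over_l") 1 / l else 1 / sqrt(l)

#' Generate synthetic spectra around seed spectra (CODI)
#'
#' For each seed spectrum emits `n_per_seed` synthetics
#' `Y = s_i + sum_j f_j`, the `f_j` built from the configured calibration
#' sets with independently redrawn Gaussian scaling factors per synthetic
#' spectrum and per difference spectrum. Synthetic records inherit their
#' seed's metadata plus `synthetic = TRUE` and a `seed_id` reference.
#' Deterministic under `cfg$rng_seed`.
#'
#' @param seeds a [spectra_set()] of seed spectra
#' @param cfg an [augmentation_config()]
#' @return a [spectra_set()] of `n_spectra(seeds) * n_per_seed` synthetics
#' @export
generate_synthetic <- function(seeds, cfg) {
  stopifnot(inherits(seeds, "spectra_set"), inherits(cfg, "augmentation_config"))
  for (src in cfg$sources) check_axis_match(seeds$wavenumber, src$wavenumber)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$rng_seed)

  n_seed <- n_spectra(seeds)
  n_syn <- n_seed * cfg$n_per_seed
  base <- seeds$intensities[rep(seq_len(n_seed), each = cfg$n_per_seed), ,
                            drop = FALSE]
  for (src in cfg$sources) {
    sdv <- beta_sd(src$l, cfg$beta_sd_rule)
    beta <- matrix(stats::rnorm(n_syn * src$l, 0, sdv), n_syn, src$l)
    base <- base + beta %*% src$diffs
  }
  meta <- seeds$meta[rep(seq_len(n_seed), each = cfg$n_per_seed), , drop = FALSE]
  meta$seed_id <- meta$spectrum_id
  meta$spectrum_id <- sprintf("%s_syn%02d", meta$seed_id,
                              rep(seq_len(cfg$n_per_seed), times = n_seed))
  meta$synthetic <- TRUE
  meta$spiked <- FALSE
  spectra_set(seeds$wavenumber, base, meta)
}

#' Augment a training set with CODI synthetics
#'
#' Concatenates the original spectra (flagged `synthetic = FALSE`, first) with
#' the synthetics from [generate_synthetic()].
#'
#' @param train a [spectra_set()]
#' @param cfg an [augmentation_config()]
#' @return a [spectra_set()] of `n * (1 + n_per_seed)` spectra
#' @export
augment_training_set <- function(train, cfg) {
  syn <- generate_synthetic(train, cfg)
  orig <- train
  orig$meta$synthetic <- FALSE
  orig$meta$seed_id <- NA_character_
  bind_spectra(orig, syn)
}
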