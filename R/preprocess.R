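# Five-step spectral preprocessing chain applied per dried sample spot:
# crop -> cosmic spike removal -> iterative polynomial baseline correction ->
# internal-standard peak normalization -> negative clipping.

#' Preprocessing configuration
#'
#' @param crop_lo,crop_hi retained wavenumber window in cm^-1 (inclusive)
#' @param spike_sd_threshold cosmic-spike threshold in per-channel SD multiples
#' @param baseline_order polynomial order of the baseline model
#' @param baseline_max_iter,baseline_tol iteration cap and relative-change
#'   stopping tolerance of the fit-and-clamp baseline loop
#' @param ref_peak_center,ref_peak_halfwidth internal-standard reference window
#'   (cm^-1); the default 976 +/- 5 targets the Al(OH)3 band
#' @param ref_min_intensity smallest admissible reference value; below it the
#'   internal standard is considered absent and normalization fails
#' @return a list of class `preprocess_config`
#' @export
preprocess_config <- function(crop_lo = 400, crop_hi = 1800,
                              spike_sd_threshold = 4,
                              baseline_order = 4L, baseline_max_iter = 100L,
                              baseline_tol = 1e-6,
                              ref_peak_center = 976, ref_peak_halfwidth = 5,
                              ref_min_intensity = 1e-9) {
  stopifnot(crop_lo < crop_hi, spike_sd_threshold > 0, baseline_order >= 1,
            baseline_max_iter >= 1, baseline_tol > 0, ref_peak_halfwidth > 0,
            ref_min_intensity > 0)
  structure(list(crop_lo = crop_lo, crop_hi = crop_hi,
                 spike_sd_threshold = spike_sd_threshold,
                 baseline_order = as.integer(baseline_order),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 ref_peak_center = ref_peak_center,
                 ref_peak_halfwidth = ref_peak_halfwidth,
                 ref_min_intensity = ref_min_intensity),
            class = "preprocess_config")
}

#' Restrict a spectra set to a wavenumber window
#'
#' @param set a [spectra_set()]
#' @param lo,hi inclusive window bounds in cm^-1
#' @return the cropped `spectra_set`; record order and metadata are preserved
#' @export
crop_range <- function(set, lo = 400, hi = 1800) {
  stopifnot(inherits(set, "spectra_set"))
  if (lo >= hi) stop("crop window is empty: lo must be < hi", call. = FALSE)
  keep <- set$wavenumber >= lo & set$wavenumber <= hi
  if (sum(keep) < 2L)
    stop(sprintf("fewer than 2 channels fall in [%g, %g]", lo, hi), call. = FALSE)
  spectra_set(set$wavenumber[keep], set$intensities[, keep, drop = FALSE], set$meta)
}

#' Remove cosmic-spike spectra from a spot
#'
#' Per-channel mean and sample SD are computed across all records of the set;
#' any record holding at least one intensity further than `threshold` SDs from
#' the channel mean is removed whole. Channels with zero SD never flag.
#'
#' @param set a [spectra_set()] holding one spot's spectra (>= 3 records)
#' @param threshold SD multiples (default 4)
#' @return list with `set` (survivors) and `removed` (integer indices into the
#'   input record order)
#' @export
remove_spikes <- function(set, threshold = 4) {
  stopifnot(inherits(set, "spectra_set"), threshold > 0)
  n <- n_spectra(set)
  if (n < 3L)
    stop("spike removal needs at least 3 spectra per spot", call. = FALSE)
  mu <- colMeans(set$intensities)
  sdv <- apply(set$intensities, 2, stats::sd)
  dev <- abs(sweep(set$intensities, 2, mu, "-"))
  lim <- threshold * sdv
  # zero-SD channels can never exceed a positive limit; Inf threshold removes none
  flag <- dev > rep(lim, each = n) & rep(sdv > 0, each = n)
  removed <- which(rowSums(flag) > 0)
  if (length(removed) == n)
    stop("spike filter removed every spectrum in the spot", call. = FALSE)
  out <- if (length(removed)) subset_spectra(set, -removed) else set
  list(set = out, removed = removed)
}

# Design matrix for a polynomial baseline, orthogonalized for conditioning.
baseline_design <- function(w, order) {
  x <- (w - mean(w)) / (diff(range(w)) / 2)
  X <- cbind(1, stats::poly(x, degree = order, raw = FALSE))
  qr(X)
}

#' Iterative polynomial baseline correction (fit-and-clamp)
#'
#' Fits a polynomial of the given order to the spectrum, clamps the working
#' curve to the fit wherever it exceeds it (so peaks stop pulling the fit up),
#' and repeats until the fitted baseline changes by less than `tol` in
#' relative L2 norm or `max_iter` is reached. The final fit is subtracted
#' from the original intensities.
#'
#' @param intensities numeric vector (one spectrum)
#' @param wavenumber matching axis
#' @param order polynomial order (default 4)
#' @param max_iter,tol stopping rule of the clamp loop
#' @param qr_design optional precomputed QR of the design (internal fast path)
#' @return baseline-corrected intensity vector
#' @export
correct_baseline <- function(intensities, wavenumber, order = 4L,
                             max_iter = 100L, tol = 1e-6, qr_design = NULL) {
  b <- length(intensities)
  if (b <= order + 1L)
    stop("baseline fit needs more channels than polynomial coefficients",
         call. = FALSE)
  qx <- if (is.null(qr_design)) baseline_design(wavenumber, order) else qr_design
  if (qx$rank < order + 1L)
    stop("baseline design matrix is rank deficient", call. = FALSE)
  work <- intensities
  fit_prev <- NULL
  for (it in seq_len(max_iter)) {
    fit <- qr.fitted(qx, work)
    if (!is.null(fit_prev)) {
      rel <- sqrt(sum((fit - fit_prev)^2)) / max(sqrt(sum(fit_prev^2)), 1e-300)
      if (rel < tol) break
    }
    fit_prev <- fit
    work <- pmin(work, fit)
  }
  intensities - fit
}

#' Normalize a spectrum to the internal-standard reference peak
#'
#' The reference value is the maximum intensity inside
#' `center +/- halfwidth`; the whole spectrum is divided by it, so the window
#' maximum of the result is exactly 1. A window maximum at or below
#' `min_intensity` signals an absent internal standard and raises an error.
#'
#' @param intensities numeric vector (one spectrum)
#' @param wavenumber matching axis
#' @param center,halfwidth reference window in cm^-1 (default 976 +/- 5)
#' @param min_intensity smallest admissible reference value
#' @return the normalized intensity vector
#' @export
normalize_to_reference_peak <- function(intensities, wavenumber,
                                        center = 976, halfwidth = 5,
                                        min_intensity = 1e-9) {
  win <- which(abs(wavenumber - center) <= halfwidth)
  if (!length(win))
    stop(sprintf("no channel falls in the reference window %g +/- %g cm^-1",
                 center, halfwidth), call. = FALSE)
  ref <- max(intensities[win])
  if (!is.finite(ref) || ref <= min_intensity)
    stop(sprintf("reference peak at %g cm^-1 is absent (window max %.3g)",
                 center, ref), call. = FALSE)
  intensities / ref
}

#' Set negative intensities to zero
#' @param intensities numeric vector or matrix
#' @return same shape with `max(x, 0)` applied elementwise
#' @export
clip_negatives <- function(intensities) pmax(intensities, 0)

#' Full preprocessing pipeline
#'
#' Applies, in order: [crop_range()], [remove_spikes()] per spot (grouped by
#' `spot_id`; sets without spot metadata are treated as a single spot),
#' [correct_baseline()] per spectrum, [normalize_to_reference_peak()] and
#' [clip_negatives()]. The processing log records the removed spectra (by
#' `spectrum_id`) per spot and the parameters used.
#'
#' @param set a [spectra_set()]
#' @param cfg a [preprocess_config()]
#' @return list with `set` (processed) and `log` (named list; serializable to
#'   JSON)
#' @export
preprocess_pipeline <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"), inherits(cfg, "preprocess_config"))
  set <- crop_range(set, cfg$crop_lo, cfg$crop_hi)

  spot <- set$meta$spot_id
  spot[is.na(spot)] <- "(no spot)"
  removed_log <- list()
  keep_parts <- list()
  for (sp in unique(spot)) {
    idx <- which(spot == sp)
    if (!length(idx)) stop(sprintf("empty spot group '%s'", sp), call. = FALSE)
    sub <- subset_spectra(set, idx)
    res <- tryCatch(remove_spikes(sub, cfg$spike_sd_threshold),
                    error = function(e)
                      stop(sprintf("spot '%s': %s", sp, conditionMessage(e)),
                           call. = FALSE))
    if (length(res$removed))
      removed_log[[sp]] <- sub$meta$spectrum_id[res$removed]
    keep_parts[[sp]] <- res$set
  }
  set <- if (length(keep_parts) == 1L) keep_parts[[1]] else bind_spectra(keep_parts)

  qx <- baseline_design(set$wavenumber, cfg$baseline_order)
  out <- set$intensities
  for (i in seq_len(nrow(out))) {
    y <- correct_baseline(out[i, ], set$wavenumber, cfg$baseline_order,
                          cfg$baseline_max_iter, cfg$baseline_tol, qr_design = qx)
    y <- tryCatch(
      normalize_to_reference_peak(y, set$wavenumber, cfg$ref_peak_center,
                                  cfg$ref_peak_halfwidth, cfg$ref_min_intensity),
      error = function(e)
        stop(sprintf("spectrum '%s': %s", set$meta$spectrum_id[i],
                     conditionMessage(e)), call. = FALSE))
    out[i, ] <- clip_negatives(y)
  }
  log <- list(
    steps = c("crop", "spike_removal", "baseline", "normalize", "clip"),
    crop = c(lo = cfg$crop_lo, hi = cfg$crop_hi),
    spike_sd_threshold = cfg$spike_sd_threshold,
    baseline = c(order = cfg$baseline_order, max_iter = cfg$baseline_max_iter,
                 tol = cfg$baseline_tol),
    reference_peak = c(center = cfg$ref_peak_center,
                       halfwidth = cfg$ref_peak_halfwidth),
    n_in = length(spot), n_removed = length(unlist(removed_log)),
    removed = removed_log)
  list(set = spectra_set(set$wavenumber, out, set$meta), log = log)
}
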