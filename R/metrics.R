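# Evaluation metrics: cosine distance, component matching, concentration MSE,
# inverse coefficient of variation, recovery and relative standard deviation.
# Sample (n-1) standard deviations are used throughout.

#' Cosine distance between two spectra
#'
#' `1 - <m, mhat> / (||m|| ||mhat||)`; lies in `[0, 1]` for non-negative
#' spectra and is invariant to positive rescaling of either argument.
#'
#' @param m,mhat numeric vectors of equal length, neither all-zero
#' @return unitless distance
#' @export
cosine_distance <- function(m, mhat) {
  if (length(m) != length(mhat))
    stop("spectra must have equal length", call. = FALSE)
  nm <- sqrt(sum(m^2)); nmh <- sqrt(sum(mhat^2))
  if (nm < 1e-12 || nmh < 1e-12)
    stop("cosine distance undefined for a zero-norm vector", call. = FALSE)
  1 - sum(m * mhat) / (nm * nmh)
}

#' Match estimated components to reference endmembers
#'
#' Factorizations return components in arbitrary order; this finds the
#' bijection minimizing the total cosine distance (exhaustive search over
#' permutations, fine for the small component counts used here).
#'
#' @param estimated,reference [endmember_set()]s with equal component counts
#' @return list with `permutation` (index into `estimated` rows, ordered as
#'   `reference`), `distances` (per reference component) and `total`
#' @export
match_components <- function(estimated, reference) {
  stopifnot(inherits(estimated, "endmember_set"),
            inherits(reference, "endmember_set"))
  k <- nrow(reference$spectra)
  if (nrow(estimated$spectra) != k)
    stop("component counts differ", call. = FALSE)
  D <- matrix(0, k, k)                     # D[i, j] = dist(reference i, estimated j)
  for (i in seq_len(k)) for (j in seq_len(k))
    D[i, j] <- cosine_distance(reference$spectra[i, ], estimated$spectra[j, ])
  perms <- perm_all(k)
  costs <- vapply(perms, function(p) sum(D[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.min(costs)]]
  list(permutation = best,
       distances = stats::setNames(D[cbind(seq_len(k), best)], reference$labels),
       total = min(costs))
}

perm_all <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- perm_all(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Concentration mean squared error, aggregated per spot and concentration
#'
#' The squared error is computed per spectrum, averaged within each sample
#' spot, then summarized across replicate spots of the same nominal
#' concentration (mean and sample SD). Spectra at excluded concentrations
#' (default: the saturated 5 mg/mL level) are omitted.
#'
#' @param pred predicted analyte concentration per spectrum (mg/mL)
#' @param truth nominal analyte concentration per spectrum (mg/mL)
#' @param spot spot/replicate label per spectrum
#' @param exclude concentration levels to omit (default 5)
#' @return list with `per_spot` (data.frame: spot, concentration, n, mse),
#'   `per_concentration` (data.frame: concentration, mean_mse, sd_mse,
#'   n_spots) and `overall` (mean of per-spot MSEs)
#' @export
concentration_mse <- function(pred, truth, spot, exclude = 5) {
  stopifnot(length(pred) == length(truth), length(pred) == length(spot))
  keep <- !(truth %in% exclude)
  pred <- pred[keep]; truth <- truth[keep]; spot <- spot[keep]
  if (!length(pred)) stop("no spectra left after exclusion", call. = FALSE)
  if (any(is.na(truth)))
    stop("true concentrations required for all included spectra", call. = FALSE)
  se <- (truth - pred)^2
  groups <- split(seq_along(se), spot)
  per_spot <- data.frame(
    spot = names(groups),
    concentration = vapply(groups, function(i) truth[i][1], numeric(1)),
    n = lengths(groups),
    mse = vapply(groups, function(i) mean(se[i]), numeric(1)),
    row.names = NULL)
  agg <- split(per_spot, per_spot$concentration)
  per_conc <- data.frame(
    concentration = as.numeric(names(agg)),
    mean_mse = vapply(agg, function(d) mean(d$mse), numeric(1)),
    sd_mse = vapply(agg, function(d)
      if (nrow(d) > 1L) stats::sd(d$mse) else NA_real_, numeric(1)),
    n_spots = vapply(agg, nrow, integer(1)),
    row.names = NULL)
  list(per_spot = per_spot, per_concentration = per_conc,
       overall = mean(per_spot$mse))
}

#' Inverse coefficient of variation of repeated endmember estimates
#'
#' For each channel, the mean intensity across the repeated runs divided by
#' the sample SD across runs. Channels with zero SD are excluded from the mean
#' ICV and counted.
#'
#' @param runs matrix of repeated estimates of one endmember, one run per row
#'   (typically 5 seeded runs)
#' @return list with `per_channel` ICV (NA where SD = 0), `mean_icv`,
#'   `n_excluded`
#' @export
icv_profile <- function(runs) {
  runs <- as.matrix(runs)
  if (nrow(runs) < 2L)
    stop("ICV needs at least two repeated runs", call. = FALSE)
  mu <- colMeans(runs)
  sdv <- apply(runs, 2, stats::sd)
  icv <- ifelse(sdv > 0, mu / sdv, NA_real_)
  excluded <- sum(sdv == 0)
  list(per_channel = icv,
       mean_icv = if (excluded < length(icv)) mean(icv, na.rm = TRUE) else NA_real_,
       n_excluded = excluded)
}

#' Recovery and relative standard deviation per concentration level
#'
#' Computed over replicate-level mean predictions: recovery is
#' `100 * mean(replicate means) / expected`, RSD is
#' `100 * SD(replicate means) / mean(replicate means)`.
#'
#' @param pred predicted concentration per spectrum (mg/mL)
#' @param truth nominal concentration per spectrum (mg/mL)
#' @param spot replicate/spot label per spectrum
#' @return data.frame with concentration, n_replicates, mean_pred, recovery_pct,
#'   rsd_pct (NA, flagged, where the mean prediction is 0)
#' @export
recovery_and_rsd <- function(pred, truth, spot) {
  stopifnot(length(pred) == length(truth), length(pred) == length(spot))
  spots <- split(seq_along(pred), spot)
  rep_means <- data.frame(
    concentration = vapply(spots, function(i) truth[i][1], numeric(1)),
    mean_pred = vapply(spots, function(i) mean(pred[i], na.rm = TRUE), numeric(1)))
  levels <- split(rep_means, rep_means$concentration)
  if (any(vapply(levels, nrow, integer(1)) < 2L))
    stop("recovery/RSD needs at least 2 replicates per concentration level",
         call. = FALSE)
  out <- data.frame(
    concentration = as.numeric(names(levels)),
    n_replicates = vapply(levels, nrow, integer(1)),
    mean_pred = vapply(levels, function(d) mean(d$mean_pred), numeric(1)),
    row.names = NULL)
  out$recovery_pct <- 100 * out$mean_pred / out$concentration
  sdv <- vapply(levels, function(d) stats::sd(d$mean_pred), numeric(1))
  out$rsd_pct <- ifelse(out$mean_pred > 0, 100 * sdv / out$mean_pred, NA_real_)
  out
}
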