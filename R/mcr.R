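# Blind unmixing by Multivariate Curve Resolution - Alternating Least Squares.
#
# Bilinear model D ~ C S with C >= 0 (abundances) and S >= 0 (endmember rows).
# Alternating exact non-negative least-squares updates; each iteration ends by
# rescaling endmember rows to unit L2 norm, pushing the scale into C, which
# fixes the scale ambiguity of the factorization.

#' MCR-ALS configuration
#'
#' @param n_components number of endmembers to resolve (default 2)
#' @param max_iter iteration cap (default 500)
#' @param tol stop when the relative change of the reconstruction error falls
#'   below this (default 1e-8)
#' @param rng_seed seed for the random non-negative initialization of S
#' @return an `mcr_config` list
#' @export
mcr_config <- function(n_components = 2L, max_iter = 500L, tol = 1e-8,
                       rng_seed = 3L) {
  stopifnot(n_components >= 1, max_iter >= 1, tol > 0)
  structure(list(n_components = as.integer(n_components),
                 max_iter = as.integer(max_iter), tol = tol,
                 rng_seed = as.integer(rng_seed)),
            class = "mcr_config")
}

# exact NNLS update of X in min ||D - X B||_F, X >= 0, rows independent
nnls_update <- function(D, B) {
  if (nrow(B) == 2L) return(pmax(nnls2_matrix(B, D), 0))
  t(apply(D, 1, function(y) pracma::lsqnonneg(t(B), y)$x))
}

#' Fit an MCR-ALS model to a spectra set
#'
#' Alternates exact non-negative least-squares solves of the abundances `C`
#' (rows) given the endmembers `S`, and of `S` (columns) given `C`, from a
#' random non-negative uniform initialization of `S`. The reconstruction error
#' `||D - C S||_F` is recorded each iteration and is monotone non-increasing.
#' Non-convergence within `max_iter` returns a result with
#' `converged = FALSE` rather than an error.
#'
#' @param set a [spectra_set()] (or plain matrix, spectra in rows) with
#'   non-negative intensities and more records than components
#' @param cfg an [mcr_config()]
#' @param labels optional component labels; defaults to `comp1`, `comp2`, ...
#'   (use [match_components()] against references to identify them)
#' @return an object of class `mcr_als` with elements `endmembers`
#'   (an [endmember_set()], unit-L2 rows), `abundances` (an
#'   [abundance_matrix()]), `error_history`, `converged`, `n_iter`, `config`
#' @export
mcr_als <- function(set, cfg = mcr_config(), labels = NULL) {
  if (inherits(set, "spectra_set")) {
    D <- set$intensities
    w <- set$wavenumber
  } else {
    D <- as.matrix(set)
    w <- seq_len(ncol(D))
  }
  k <- cfg$n_components
  if (nrow(D) <= k)
    stop("need more spectra than components", call. = FALSE)
  if (max(D) <= 0) stop("data matrix is all zero", call. = FALSE)
  if (is.null(labels)) labels <- paste0("comp", seq_len(k))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$rng_seed)
  S <- matrix(stats::runif(k * ncol(D)), k, ncol(D))
  S <- S / sqrt(rowSums(S^2))

  err <- numeric(0)
  converged <- FALSE
  C <- NULL
  for (it in seq_len(cfg$max_iter)) {
    C <- nnls_update(D, S)                       # abundances given spectra
    St <- nnls_update(t(D), t(C))                # spectra given abundances
    S <- t(St)
    nrm <- sqrt(rowSums(S^2))
    dead <- nrm < 1e-12
    if (any(dead)) {                             # component died: keep a unit
      S[dead, ] <- 1 / sqrt(ncol(S))             # direction, abundance stays 0
      nrm[dead] <- 1
    }
    S <- S / nrm
    C <- sweep(C, 2, nrm, "*")
    e <- sqrt(sum((D - C %*% S)^2))
    err <- c(err, e)
    if (it > 1L) {
      rel <- abs(err[it - 1L] - e) / max(err[it - 1L], 1e-300)
      if (rel < cfg$tol) { converged <- TRUE; break }
    }
  }
  near_zero <- colSums(C) / max(colSums(C)) < 1e-6
  if (any(near_zero))
    warning(sprintf("%d component(s) have near-zero abundance (data rank < n_components?)",
                    sum(near_zero)), call. = FALSE)
  structure(list(
    endmembers = endmember_set(w, pmax(S, 0), labels),
    abundances = abundance_matrix(pmax(C, 0), labels, "raw_coefficient"),
    error_history = err, converged = converged, n_iter = length(err),
    config = cfg), class = "mcr_als")
}

#' @export
print.mcr_als <- function(x, ...) {
  cat(sprintf("MCR-ALS fit: %d components, %d iterations (%s)\n",
              x$config$n_components, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final reconstruction error ||D - CS||_F = %.6g\n",
              utils::tail(x$error_history, 1)))
  invisible(x)
}

#' @export
coef.mcr_als <- function(object, ...) object$abundances

#' @export
plot.mcr_als <- function(x, which = c("endmembers", "error"), ...) {
  which <- match.arg(which)
  if (which == "error") {
    graphics::plot(x$error_history, type = "l", log = "y",
                   xlab = "ALS iteration", ylab = "reconstruction error", ...)
  } else {
    S <- x$endmembers$spectra
    graphics::matplot(x$endmembers$wavenumber, t(S), type = "l", lty = 1,
                      xlab = expression(wavenumber ~ (cm^-1)),
                      ylab = "intensity (unit L2)", ...)
    graphics::legend("topright", legend = x$endmembers$labels,
                     col = seq_len(nrow(S)), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Fit the single concentration scaling factor from a training set
#'
#' The MCR (or NNLS) coefficient ratio `target / reference` is proportional to
#' the analyte concentration; the single factor
#' `scale = sum(ratio * known) / sum(ratio^2)` is the least-squares solution of
#' `known ~ scale * ratio` through the origin, computed per spectrum.
#'
#' @param abundances an [abundance_matrix()] for the training spectra
#' @param known known analyte concentrations (mg/mL), one per spectrum
#' @param target_component,reference_component column labels; the reference is
#'   the internal standard (`"AlOH3"`)
#' @return a `concentration_calibration` list with the `scale` factor
#' @export
fit_concentration_scale <- function(abundances, known,
                                    target_component = "BSA",
                                    reference_component = "AlOH3") {
  stopifnot(length(known) == nrow(abundances),
            target_component %in% colnames(abundances),
            reference_component %in% colnames(abundances))
  if (any(is.na(known)))
    stop("known concentrations required for all training spectra", call. = FALSE)
  ref <- abundances[, reference_component]
  ratio <- ifelse(ref > 0, abundances[, target_component] / ref, NA_real_)
  ok <- is.finite(ratio)
  if (!any(ok) || sum(ratio[ok]^2) == 0)
    stop("all coefficient ratios are zero; cannot calibrate", call. = FALSE)
  scale <- sum(ratio[ok] * known[ok]) / sum(ratio[ok]^2)
  if (scale <= 0) stop("calibration produced a non-positive scale", call. = FALSE)
  structure(list(scale = scale, target_component = target_component,
                 reference_component = reference_component),
            class = "concentration_calibration")
}

#' Predict analyte concentrations with calibrated MCR endmembers
#'
#' Unmixes each spectrum against the fitted endmembers by NNLS, forms the
#' `target / reference` coefficient ratio and multiplies by the calibrated
#' scale to obtain mg/mL. Records with a zero reference coefficient yield
#' `NA`.
#'
#' @param object an `mcr_als` fit
#' @param newdata a [spectra_set()] on the same axis
#' @param calibration a [fit_concentration_scale()] result
#' @param ... unused
#' @return an [abundance_matrix()] in mg/mL with one column per target
#'   component (plus the reference fixed concentration implied by the ratio is
#'   not reported)
#' @export
predict.mcr_als <- function(object, newdata, calibration, ...) {
  stopifnot(inherits(newdata, "spectra_set"),
            inherits(calibration, "concentration_calibration"))
  um <- nnls_map(newdata, object$endmembers,
                 target = calibration$target_component,
                 reference = calibration$reference_component)
  conc <- um$ratio * calibration$scale
  out <- matrix(pmax(conc, 0), ncol = 1,
                dimnames = list(NULL, calibration$target_component))
  out[is.na(conc), 1] <- NA_real_
  structure(out, units = "mg_per_mL",
            class = c("abundance_matrix", "matrix", "array"))
}
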