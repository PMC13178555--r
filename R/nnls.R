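# Nonblind linear unmixing by non-negative least squares.

#' Solve one non-negative least-squares problem against an endmember basis
#'
#' Finds the coefficients c >= 0 minimizing
#' `sum_i (y[i] - sum_k c_k * basis_k[i])^2` with the Lawson-Hanson active-set
#' method.
#'
#' @param basis an [endmember_set()] (rows are basis spectra)
#' @param y numeric spectrum on the same axis, or a `spectra_set` with one record
#' @return named numeric vector of non-negative coefficients
#' @export
nnls_solve <- function(basis, y) {
  stopifnot(inherits(basis, "endmember_set"))
  if (inherits(y, "spectra_set")) {
    check_axis_match(basis$wavenumber, y$wavenumber)
    y <- y$intensities[1, ]
  }
  if (length(y) != length(basis$wavenumber))
    stop("spectrum and basis are on different axes", call. = FALSE)
  coef <- pracma::lsqnonneg(t(basis$spectra), as.numeric(y))$x
  stats::setNames(as.numeric(coef), basis$labels)
}

# Exact vectorized NNLS for a 2-column basis: solve the unconstrained 2x2
# normal equations for every row; where a coefficient goes negative, fall back
# to the better of the two single-component fits (the KKT-optimal face).
nnls2_matrix <- function(A, Y) {
  g11 <- sum(A[1, ]^2); g22 <- sum(A[2, ]^2); g12 <- sum(A[1, ] * A[2, ])
  b1 <- Y %*% A[1, ]; b2 <- Y %*% A[2, ]
  det <- g11 * g22 - g12^2
  if (det <= 0) {                       # collinear basis: per-row Lawson-Hanson
    C <- t(apply(Y, 1, function(y) pracma::lsqnonneg(t(A), y)$x))
    return(C)
  }
  c1 <- (g22 * b1 - g12 * b2) / det
  c2 <- (g11 * b2 - g12 * b1) / det
  neg <- which(c1 < 0 | c2 < 0)
  if (length(neg)) {
    a1 <- pmax(b1[neg] / g11, 0)        # fit on component 1 only
    a2 <- pmax(b2[neg] / g22, 0)        # fit on component 2 only
    rss1 <- -2 * a1 * b1[neg] + a1^2 * g11
    rss2 <- -2 * a2 * b2[neg] + a2^2 * g22
    use1 <- rss1 <= rss2
    c1[neg] <- ifelse(use1, a1, 0)
    c2[neg] <- ifelse(use1, 0, a2)
  }
  cbind(c1, c2, deparse.level = 0)
}

#' Unmix every spectrum of a set against a known basis
#'
#' Row-wise [nnls_solve()] plus the per-record coefficient ratio
#' `target / reference` used for concentration-ratio maps. One overall scale
#' is used across all spots (no per-spot renormalization). The ratio is `NA`
#' where the reference coefficient is 0.
#'
#' @param set a [spectra_set()]
#' @param basis an [endmember_set()]
#' @param target,reference component labels for the ratio (defaults: first and
#'   second basis label)
#' @return list with `abundances` (an [abundance_matrix()]) and `ratio`
#'   (numeric vector, `NA` where undefined)
#' @export
nnls_map <- function(set, basis, target = basis$labels[1],
                     reference = basis$labels[2]) {
  stopifnot(inherits(set, "spectra_set"), inherits(basis, "endmember_set"))
  check_axis_match(set$wavenumber, basis$wavenumber)
  stopifnot(target %in% basis$labels, reference %in% basis$labels)
  if (nrow(basis$spectra) == 2L) {
    C <- nnls2_matrix(basis$spectra, set$intensities)
    colnames(C) <- basis$labels
  } else {
    C <- t(apply(set$intensities, 1, function(y)
      pracma::lsqnonneg(t(basis$spectra), y)$x))
    colnames(C) <- basis$labels
  }
  C <- pmax(C, 0)
  ref <- C[, reference]
  ratio <- ifelse(ref > 0, C[, target] / ref, NA_real_)
  list(abundances = abundance_matrix(C, basis$labels, "raw_coefficient"),
       ratio = as.numeric(ratio))
}
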