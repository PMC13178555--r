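#' Construct a set of Raman spectra on a shared wavenumber axis
#'
#' A `spectra_set` is the package's central container: a matrix of spectra
#' (rows are spectra, columns are channels) aligned to one strictly increasing
#' wavenumber axis, plus a per-spectrum metadata table. All downstream
#' operations (preprocessing, augmentation, unmixing) consume and return this
#' container, so axis consistency is checked once, at construction.
#'
#' @param wavenumber numeric vector of channel positions in cm^-1; must be
#'   strictly increasing, finite, and of length >= 2. If supplied in
#'   descending order it is reversed (and intensity columns with it).
#' @param intensities numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns. A single spectrum may be given as a vector.
#' @param meta optional `data.frame` with one row per spectrum. Recognised
#'   columns: `spectrum_id`, `sample_id`, `spot_id`, `replicate`, `grid_x`,
#'   `grid_y`, `c_bsa`, `c_al` (concentrations in mg/mL, `NA` = unknown) and
#'   `day`. Missing columns are filled with `NA`; a missing `spectrum_id` is
#'   generated. Extra columns are kept.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, intensities, meta = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  if (length(wavenumber) < 2L)
    stop("wavenumber axis must have at least 2 channels", call. = FALSE)
  if (any(!is.finite(wavenumber)))
    stop("wavenumber axis contains non-finite values", call. = FALSE)
  d <- diff(wavenumber)
  if (all(d < 0)) {              # descending file order: reverse in place
    wavenumber <- rev(wavenumber)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
    d <- diff(wavenumber)
  }
  if (any(d <= 0))
    stop("wavenumber axis must be strictly monotonically increasing", call. = FALSE)
  if (ncol(intensities) != length(wavenumber))
    stop(sprintf("intensity matrix has %d columns but axis has %d channels",
                 ncol(intensities), length(wavenumber)), call. = FALSE)
  if (nrow(intensities) < 1L)
    stop("a spectra_set must contain at least one spectrum", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities contain non-finite values", call. = FALSE)

  meta <- complete_meta(meta, nrow(intensities))
  structure(list(wavenumber = wavenumber, intensities = intensities, meta = meta),
            class = "spectra_set")
}

meta_columns <- c("spectrum_id", "sample_id", "spot_id", "replicate",
                  "grid_x", "grid_y", "c_bsa", "c_al", "day")

complete_meta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(spectrum_id = paste0("s", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop(sprintf("metadata has %d rows for %d spectra", nrow(meta), n), call. = FALSE)
  if (is.null(meta$spectrum_id)) meta$spectrum_id <- paste0("s", seq_len(n))
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id))
    stop("duplicate spectrum_id in metadata", call. = FALSE)
  for (col in c("sample_id", "spot_id", "replicate", "day"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_ else
      meta[[col]] <- as.character(meta[[col]])
  for (col in c("grid_x", "grid_y"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_integer_ else
      meta[[col]] <- as.integer(meta[[col]])
  for (col in c("c_bsa", "c_al")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_ else
      meta[[col]] <- as.numeric(meta[[col]])
    if (any(meta[[col]] < 0, na.rm = TRUE))
      stop(sprintf("negative concentration in metadata column '%s'", col),
           call. = FALSE)
  }
  rownames(meta) <- NULL
  # canonical columns first, extras after
  extra <- setdiff(names(meta), meta_columns)
  meta[, c(meta_columns, extra), drop = FALSE]
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d channels, %.1f-%.1f cm^-1\n",
              n_spectra(x), n_channels(x), min(x$wavenumber), max(x$wavenumber)))
  conc <- unique(stats::na.omit(x$meta$c_bsa))
  if (length(conc))
    cat("  BSA levels (mg/mL):", paste(sort(conc), collapse = ", "), "\n")
  spots <- unique(stats::na.omit(x$meta$spot_id))
  if (length(spots)) cat("  spots:", length(spots), "\n")
  invisible(x)
}

#' Number of spectra / channels in a set
#' @param set a `spectra_set`
#' @return integer count
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @rdname n_spectra
#' @export
n_channels <- function(set) length(set$wavenumber)

#' Subset a spectra_set by spectrum index
#' @param set a `spectra_set`
#' @param i integer or logical index over spectra
#' @return a `spectra_set` with the selected records
#' @export
subset_spectra <- function(set, i) {
  ints <- set$intensities[i, , drop = FALSE]
  if (nrow(ints) == 0L) stop("subset would leave an empty spectra_set", call. = FALSE)
  spectra_set(set$wavenumber, ints, set$meta[i, , drop = FALSE])
}

#' Concatenate spectra sets sharing one axis
#' @param ... `spectra_set` objects on identical wavenumber axes
#' @return a combined `spectra_set`
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "spectra_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ax <- sets[[1]]$wavenumber
  for (s in sets) check_axis_match(ax, s$wavenumber)
  metas <- lapply(sets, `[[`, "meta")
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (col in setdiff(cols, names(m))) m[[col]] <- NA
    m[, cols, drop = FALSE]
  })
  meta <- do.call(rbind, metas)
  if (anyDuplicated(meta$spectrum_id))
    meta$spectrum_id <- make.unique(meta$spectrum_id, sep = "_")
  spectra_set(ax, do.call(rbind, lapply(sets, `[[`, "intensities")), meta)
}

check_axis_match <- function(a, b, tol = 1e-9) {
  if (length(a) != length(b) || max(abs(a - b)) > tol)
    stop("wavenumber axes do not match; resampling across axes is not supported",
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a spectra_set without raising
#'
#' Checks the container invariants (axis monotone and finite, intensity rows
#' aligned and finite, non-negative concentrations) and returns a character
#' vector of human-readable violations, empty when the object conforms.
#' Content problems never raise an error here, so the function can be used to
#' triage objects assembled outside the constructor.
#'
#' @param set an object purporting to be a `spectra_set`
#' @return character vector of violation descriptions (zero-length if valid)
#' @export
validate_set <- function(set) {
  v <- character()
  if (!is.list(set) || is.null(set$wavenumber) || is.null(set$intensities))
    return("not a spectra_set: missing wavenumber or intensities")
  w <- set$wavenumber
  if (length(w) < 2L) v <- c(v, "axis has fewer than 2 channels")
  if (any(!is.finite(w))) v <- c(v, "axis contains non-finite values")
  if (length(w) >= 2L && any(diff(w) <= 0))
    v <- c(v, "axis not strictly increasing")
  ints <- set$intensities
  if (is.null(dim(ints)) || ncol(ints) != length(w)) {
    v <- c(v, "intensity matrix not aligned to axis length")
  } else {
    bad <- which(!is.finite(ints), arr.ind = TRUE)
    if (nrow(bad))
      v <- c(v, sprintf("non-finite intensity in record %d, channel %d",
                        bad[, 1], bad[, 2]))
    if (nrow(ints) < 1L) v <- c(v, "set contains no spectra")
  }
  if (!is.null(set$meta)) {
    if (nrow(set$meta) != nrow(ints))
      v <- c(v, "metadata row count differs from spectrum count")
    for (col in c("c_bsa", "c_al"))
      if (!is.null(set$meta[[col]]) && any(set$meta[[col]] < 0, na.rm = TRUE))
        v <- c(v, sprintf("negative concentration in metadata column '%s'", col))
  }
  v
}

#' Construct a labelled set of pure-component (endmember) spectra
#'
#' @param wavenumber shared wavenumber axis (cm^-1), strictly increasing
#' @param spectra non-negative matrix, one row per endmember
#' @param labels unique character labels, e.g. `c("BSA", "AlOH3")`
#' @return an object of class `endmember_set`
#' @export
endmember_set <- function(wavenumber, spectra, labels) {
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1L)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  if (ncol(spectra) != length(wavenumber))
    stop("endmember spectra not aligned to axis", call. = FALSE)
  if (nrow(spectra) < 1L) stop("need at least one endmember", call. = FALSE)
  if (any(!is.finite(spectra)) || any(spectra < 0))
    stop("endmember intensities must be finite and >= 0", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(spectra) || anyDuplicated(labels))
    stop("labels must be unique, one per endmember", call. = FALSE)
  rownames(spectra) <- labels
  structure(list(wavenumber = wavenumber, spectra = spectra, labels = labels),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("endmember_set: %d components [%s] on %d channels\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              length(x$wavenumber)))
  invisible(x)
}

#' Construct a non-negative abundance matrix
#'
#' Per-spectrum component coefficients, either raw regression coefficients or
#' calibrated concentrations in mg/mL.
#'
#' @param values numeric matrix, one row per spectrum, one column per component
#' @param component_labels column labels matching an `endmember_set`
#' @param units `"raw_coefficient"` or `"mg_per_mL"`
#' @return a matrix of class `abundance_matrix` with a `units` attribute
#' @export
abundance_matrix <- function(values,
                             component_labels = colnames(values),
                             units = c("raw_coefficient", "mg_per_mL")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(component_labels))
    stop("component_labels required", call. = FALSE)
  if (length(component_labels) != ncol(values))
    stop("one label per component column required", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  colnames(values) <- component_labels
  structure(values, units = units, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d spectra x %d components (%s)\n",
              nrow(x), ncol(x), attr(x, "units")))
  print(utils::head(unclass(x)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
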