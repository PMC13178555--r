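# Delimited-text readers/writers for spectra tables and metadata.
#
# On-disk dialect: a wide CSV/TSV whose first column is "wavenumber_cm-1" and
# every remaining column one spectrum (header = spectrum_id). Metadata lives in
# a sibling table keyed by spectrum_id. TSV is chosen by file extension.

io_sep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

disk_meta_names <- c(c_bsa = "c_bsa_mg_ml", c_al = "c_al_mg_ml")

#' Read a spectra table (and optional metadata table) from disk
#'
#' Expects the dialect written by [write_spectra_table()]: first column
#' `wavenumber_cm-1`, remaining columns one spectrum each. A descending
#' wavenumber axis is accepted and reordered to ascending. Metadata rows are
#' joined to spectra by `spectrum_id` = column name; metadata rows with no
#' matching spectrum column are dropped with a warning.
#'
#' @param path path to the spectra CSV/TSV
#' @param meta_path optional path to the metadata CSV/TSV
#' @return a [spectra_set()]
#' @export
read_spectra_table <- function(path, meta_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 2L)
    stop(sprintf("'%s': need a wavenumber column plus at least one spectrum", path),
         call. = FALSE)
  for (j in seq_len(ncol(tab))) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("'%s': non-numeric value '%s' at row %d, column '%s'",
                     path, col[bad[1]], bad[1], names(tab)[j]), call. = FALSE)
      tab[[j]] <- num
    }
  }
  w <- tab[[1]]
  if (anyDuplicated(w))
    stop(sprintf("'%s': duplicate wavenumber %g", path, w[anyDuplicated(w)]),
         call. = FALSE)
  if (is.unsorted(w) && is.unsorted(rev(w))) {   # arbitrary order: sort
    o <- order(w)
    tab <- tab[o, , drop = FALSE]
    w <- tab[[1]]
  }
  ints <- t(as.matrix(tab[, -1, drop = FALSE]))
  ids <- names(tab)[-1]
  meta <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta_path)) {
    mt <- utils::read.table(meta_path, header = TRUE, sep = io_sep(meta_path),
                            stringsAsFactors = FALSE)
    if (is.null(mt$spectrum_id))
      stop(sprintf("'%s': metadata table lacks a spectrum_id column", meta_path),
           call. = FALSE)
    if (anyDuplicated(mt$spectrum_id))
      stop(sprintf("'%s': metadata key collision on spectrum_id '%s'", meta_path,
                   mt$spectrum_id[anyDuplicated(mt$spectrum_id)]), call. = FALSE)
    unmatched <- setdiff(mt$spectrum_id, ids)
    if (length(unmatched)) {
      warning(sprintf("%d metadata rows have no matching spectrum column (e.g. '%s'); ignored",
                      length(unmatched), unmatched[1]), call. = FALSE)
      mt <- mt[mt$spectrum_id %in% ids, , drop = FALSE]
    }
    for (int in names(disk_meta_names))
      if (!is.null(mt[[disk_meta_names[[int]]]])) {
        mt[[int]] <- mt[[disk_meta_names[[int]]]]
        mt[[disk_meta_names[[int]]]] <- NULL
      }
    meta <- merge(meta, mt, by = "spectrum_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  }
  spectra_set(w, ints, meta)
}

#' Write a spectra table (and metadata sibling) to disk
#'
#' Emits the same dialect [read_spectra_table()] accepts. Metadata is written
#' next to the spectra file as `<stem>_meta.csv` unless `meta_path` is given;
#' pass `meta_path = NA` to suppress the metadata file.
#'
#' @param set a [spectra_set()]
#' @param path output path for the spectra table (.csv or .tsv)
#' @param meta_path output path for the metadata table, or `NA` for none
#' @return invisibly, the paths written
#' @export
write_spectra_table <- function(set, path,
                                meta_path = default_meta_path(path)) {
  stopifnot(inherits(set, "spectra_set"))
  tab <- data.frame(set$wavenumber, t(set$intensities), check.names = FALSE)
  names(tab) <- c("wavenumber_cm-1", set$meta$spectrum_id)
  ok <- try(utils::write.table(tab, path, sep = io_sep(path), row.names = FALSE,
                               quote = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write spectra table '%s': %s", path,
                 attr(ok, "condition")$message), call. = FALSE)
  paths <- path
  if (!is.na(meta_path)) {
    mt <- set$meta
    for (int in names(disk_meta_names)) {
      mt[[disk_meta_names[[int]]]] <- mt[[int]]
      mt[[int]] <- NULL
    }
    utils::write.table(mt, meta_path, sep = io_sep(meta_path),
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, meta_path)
  }
  invisible(paths)
}

default_meta_path <- function(path)
  sub("(\\.[A-Za-z]+)?$", "_meta.csv", path)

#' Write / read endmember spectra
#'
#' Stored in the same wide dialect, one column per component.
#' @param em an [endmember_set()]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_endmembers <- function(em, path) {
  stopifnot(inherits(em, "endmember_set"))
  tab <- data.frame(em$wavenumber, t(em$spectra), check.names = FALSE)
  names(tab) <- c("wavenumber_cm-1", em$labels)
  utils::write.table(tab, path, sep = io_sep(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_endmembers
#' @export
read_endmembers <- function(path) {
  s <- read_spectra_table(path)
  endmember_set(s$wavenumber, pmax(s$intensities, 0), s$meta$spectrum_id)
}
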