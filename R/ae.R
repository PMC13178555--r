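# Concentration-anchored convolutional autoencoder for blind unmixing.
#
# The encoder compresses each spectrum to a latent vector with one unit per
# endmember; a loss term anchors those activations to the known component
# concentrations (mg/mL), so the latent space reads out directly as
# concentrations. The decoder is a single non-negative linear map whose weight
# columns are the endmember spectra.

#' Spectral angle distance between two spectra
#'
#' `arccos(<x, xhat> / (||x|| ||xhat||))`, clamped into `[0, pi]`. Insensitive
#' to positive rescaling of either argument.
#'
#' @param x,xhat numeric vectors of equal length, neither all-zero
#' @return angle in radians
#' @export
sad <- function(x, xhat) {
  if (length(x) != length(xhat))
    stop("spectra must have equal length", call. = FALSE)
  nx <- sqrt(sum(x^2)); nxh <- sqrt(sum(xhat^2))
  if (nx < 1e-12 || nxh < 1e-12)
    stop("spectral angle undefined for a zero-norm vector", call. = FALSE)
  u <- sum(x * xhat) / (nx * nxh)
  acos(min(1, max(-1, u)))
}

#' Training loss of the anchored autoencoder
#'
#' `mean_i SAD(x_i, xhat_i) + w_c * mean_{i,k} (z_ik - c_ik)^2` over a batch.
#'
#' @param x,xhat matrices with one spectrum per row (input and reconstruction)
#' @param z latent activations, one row per spectrum
#' @param targets known concentrations (mg/mL), same shape as `z`
#' @param w_c anchoring weight (default 40)
#' @return list with `total`, `sad` and `mse` components
#' @export
total_loss <- function(x, xhat, z, targets, w_c = 40) {
  x <- rbind(x); xhat <- rbind(xhat); z <- rbind(z); targets <- rbind(targets)
  if (is.null(targets) || any(is.na(targets)))
    stop("concentration targets required for every batch element", call. = FALSE)
  stopifnot(nrow(x) == nrow(xhat), nrow(x) == nrow(z),
            all(dim(z) == dim(targets)))
  sad_term <- mean(vapply(seq_len(nrow(x)),
                          function(i) sad(x[i, ], xhat[i, ]), numeric(1)))
  mse_term <- mean((z - targets)^2)
  list(total = sad_term + w_c * mse_term, sad = sad_term, mse = mse_term)
}

#' Autoencoder architecture and training hyperparameters
#'
#' Defaults follow the study protocol: two convolutional blocks (16 filters of
#' size 3, then 16 of size 5; ReLU; zero "same" padding; stride 1), dense
#' layers of 128 and `latent_dim` units with LeakyReLU slope 0.02, a
#' non-negative linear decoder without bias, loss weight `w_c = 40`, Adam with
#' learning rate 0.001, batch size 8, at most 10 epochs with early stopping
#' (patience 3, min_delta 0.0005) on the training loss.
#'
#' @param latent_dim number of endmembers (latent units)
#' @param conv1_filters,conv1_kernel,conv2_filters,conv2_kernel encoder conv blocks
#' @param dense1_units width of the first dense layer
#' @param w_c anchoring loss weight
#' @param learning_rate,max_epochs,batch_size optimizer settings
#' @param early_stop_patience,early_stop_min_delta early stopping rule
#' @param rng_seed seed for initialization and batch shuffling
#' @return an `ae_spec` list
#' @export
ae_spec <- function(latent_dim = 2L, conv1_filters = 16L, conv1_kernel = 3L,
                    conv2_filters = 16L, conv2_kernel = 5L, dense1_units = 128L,
                    w_c = 40, learning_rate = 0.001, max_epochs = 10L,
                    batch_size = 8L, early_stop_patience = 3L,
                    early_stop_min_delta = 5e-4, rng_seed = 3L) {
  stopifnot(latent_dim >= 1, w_c >= 0, conv1_filters >= 1, conv2_filters >= 1,
            conv1_kernel >= 1, conv2_kernel >= 1, dense1_units >= 1,
            learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            early_stop_patience >= 1, early_stop_min_delta >= 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 dense1_units = as.integer(dense1_units),
                 w_c = w_c, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 rng_seed = as.integer(rng_seed)),
            class = "ae_spec")
}

#' Build an (untrained) autoencoder for a given axis
#'
#' Deterministic Glorot-uniform initialization under `spec$rng_seed`; the
#' decoder starts non-negative by construction.
#'
#' @param spec an [ae_spec()]
#' @param wavenumber the axis the model will consume
#' @param component_labels latent/endmember labels, anchoring order; default
#'   `c("BSA", "AlOH3")` for `latent_dim = 2`
#' @return an object of class `ae_unmix`, `trained = FALSE`
#' @export
build_model <- function(spec, wavenumber,
                        component_labels = if (spec$latent_dim == 2L)
                          c("BSA", "AlOH3") else paste0("comp", seq_len(spec$latent_dim))) {
  stopifnot(inherits(spec, "ae_spec"), length(wavenumber) >= spec$conv2_kernel)
  if (length(component_labels) != spec$latent_dim)
    stop("one label per latent unit required", call. = FALSE)
  params <- .ae_init_cpp(length(wavenumber), spec$latent_dim,
                         spec$conv1_filters, spec$conv1_kernel,
                         spec$conv2_filters, spec$conv2_kernel,
                         spec$dense1_units, spec$rng_seed)
  structure(list(params = params, spec = spec,
                 wavenumber = as.numeric(wavenumber),
                 component_labels = component_labels,
                 trained = FALSE, loss_history = NULL),
            class = "ae_unmix")
}

#' Fit the concentration-anchored autoencoder
#'
#' Trains with Adam on batches of `spec$batch_size`, minimizing the SAD
#' reconstruction term plus `w_c` times the latent anchoring MSE. Every
#' training record must carry concentration targets (`c_bsa`, `c_al` metadata;
#' CODI synthetics inherit their seed's values). Early stopping watches the
#' training loss. The decoder weights are projected onto `>= 0` after every
#' update. Deterministic under `spec$rng_seed` (single-threaded).
#'
#' @param train a [spectra_set()] of preprocessed training spectra
#' @param spec an [ae_spec()]
#' @param targets optional explicit target matrix (n x latent_dim, mg/mL);
#'   default is built from the `c_bsa`/`c_al` metadata in label order
#' @param model optional prebuilt [build_model()] result to continue from
#' @return a trained `ae_unmix` object with `loss_history` (per epoch: total,
#'   SAD term, anchoring MSE term)
#' @export
ae_unmix <- function(train, spec = ae_spec(), targets = NULL, model = NULL) {
  stopifnot(inherits(train, "spectra_set"))
  if (is.null(model)) model <- build_model(spec, train$wavenumber)
  spec <- model$spec
  check_axis_match(model$wavenumber, train$wavenumber)
  if (is.null(targets)) {
    cols <- c(BSA = "c_bsa", AlOH3 = "c_al")[model$component_labels]
    if (any(is.na(cols)))
      stop("no default targets for labels other than BSA/AlOH3; pass `targets`",
           call. = FALSE)
    targets <- as.matrix(train$meta[, cols, drop = FALSE])
  }
  targets <- as.matrix(targets)
  if (nrow(targets) != n_spectra(train) || ncol(targets) != spec$latent_dim)
    stop("targets must be n_spectra x latent_dim", call. = FALSE)
  if (any(is.na(targets)))
    stop("every training record needs concentration targets", call. = FALSE)

  fit <- .ae_train_cpp(model$params, t(train$intensities), t(targets),
                       spec$w_c, spec$learning_rate, spec$max_epochs,
                       spec$batch_size, spec$early_stop_patience,
                       spec$early_stop_min_delta, spec$rng_seed)
  model$params <- fit$params
  model$trained <- TRUE
  model$loss_history <- data.frame(epoch = seq_along(fit$loss_total),
                                   total = fit$loss_total,
                                   sad = fit$loss_sad, mse = fit$loss_mse)
  model$n_train <- n_spectra(train)
  model
}

#' @export
print.ae_unmix <- function(x, ...) {
  cat(sprintf("ae_unmix: %d-channel spectra -> latent [%s]%s\n",
              length(x$wavenumber), paste(x$component_labels, collapse = ", "),
              if (x$trained) "" else " (untrained)"))
  if (x$trained) {
    h <- x$loss_history
    cat(sprintf("  %d epochs; final loss %.5f (SAD %.5f + %g x MSE %.6f)\n",
                nrow(h), h$total[nrow(h)], h$sad[nrow(h)], x$spec$w_c,
                h$mse[nrow(h)]))
  }
  invisible(x)
}

#' Read the endmember spectra out of the decoder
#'
#' The decoder weight matrix holds one non-negative spectrum per latent unit.
#' With reference endmembers supplied, components are relabelled by
#' minimal-cosine-distance assignment (see [match_components()]); otherwise
#' labels follow the anchoring order.
#'
#' @param model an `ae_unmix` object (trained or not; untrained models return
#'   their initialization)
#' @param references optional [endmember_set()] used for label assignment
#' @return an [endmember_set()] with `latent_dim` spectra
#' @export
extract_endmembers <- function(model, references = NULL) {
  stopifnot(inherits(model, "ae_unmix"))
  S <- t(model$params$Wdec)                     # latent_dim x channels
  em <- endmember_set(model$wavenumber, pmax(S, 0), model$component_labels)
  if (!is.null(references)) {
    m <- match_components(em, references)
    em <- endmember_set(model$wavenumber,
                        em$spectra[m$permutation, , drop = FALSE],
                        references$labels)
  }
  attr(em, "trained") <- model$trained
  em
}

#' @export
coef.ae_unmix <- function(object, ...) extract_endmembers(object)

#' Predict component concentrations from spectra
#'
#' Runs the encoder and reports the latent activations, clamped at zero, as
#' mg/mL per component (the anchoring during training makes the latent units
#' physical). Input must be preprocessed identically to the training set.
#'
#' @param object a trained `ae_unmix` model
#' @param newdata a [spectra_set()] on the training axis
#' @param ... unused
#' @return an [abundance_matrix()] in mg/mL (rows follow `newdata`)
#' @export
predict.ae_unmix <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectra_set"))
  check_axis_match(object$wavenumber, newdata$wavenumber)
  z <- .ae_forward_cpp(object$params, t(newdata$intensities))$latent
  abundance_matrix(pmax(t(z), 0), object$component_labels, "mg_per_mL")
}

#' @export
plot.ae_unmix <- function(x, which = c("loss", "endmembers"), ...) {
  which <- match.arg(which)
  if (which == "loss" && !is.null(x$loss_history)) {
    h <- x$loss_history
    graphics::plot(h$epoch, h$total, type = "b", xlab = "epoch",
                   ylab = "training loss", ...)
  } else {
    em <- extract_endmembers(x)
    graphics::matplot(em$wavenumber, t(em$spectra), type = "l", lty = 1,
                      xlab = expression(wavenumber ~ (cm^-1)),
                      ylab = "decoder weight", ...)
    graphics::legend("topright", legend = em$labels,
                     col = seq_along(em$labels), lty = 1, bty = "n")
  }
  invisible(x)
}
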