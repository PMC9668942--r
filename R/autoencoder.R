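# LSTM encoder-decoder: configuration, seeded initialization, the Adam
# training loop with epoch-level early stopping, encoding to the 2-D latent
# plane, and per-case reconstruction error. All heavy numerics live in
# src/lstm_ae.cpp; randomness (weight init, mini-batch order) is drawn on the
# R side so runs are reproducible from a single seed.

#' Autoencoder configuration
#'
#' The reference architecture encodes the 5-item sequence through an LSTM
#' with 24 units, a per-step sigmoid dense layer with 12 units, and a second
#' LSTM whose 2-unit final-step output is the latent point; the decoder
#' mirrors the stack (2 -> 12 -> 24 -> 5) over the latent repeated across the
#' five steps, followed by a per-step linear readout. Training runs `sets *
#' epochs_per_set` epochs of `iters_per_epoch` mini-batch Adam updates
#' (mini-batches of `batch_size` cases, reshuffled every epoch) and stops
#' early once the relative epoch-to-epoch loss reduction falls below
#' `early_stop_rel_tol`.
#'
#' @param input_dim Items per timestep (5).
#' @param lstm1_dim First LSTM width (24).
#' @param fc_dim Dense bottleneck-side width (12).
#' @param latent_dim Latent dimension (2 for the reference analysis).
#' @param sets,epochs_per_set,iters_per_epoch,batch_size Training schedule:
#'   5 sets of 4 epochs, 1,000 updates per epoch, batch size 10.
#' @param early_stop_rel_tol Early-stopping threshold: an epoch-to-epoch
#'   relative reduction in mean training loss below this fraction counts as
#'   "no significant reduction" and halts training; in `[0, 1)`. The default
#'   0.02 (2 per cent) makes the stopping rule bind within the 20-epoch
#'   budget on cohort-sized data; training to the full budget keeps reducing
#'   reconstruction loss ~1 per cent per epoch while overfitting the latent.
#' @param learning_rate Adam step size.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param reverse_target If `TRUE` the decoder is trained to reproduce the
#'   sequence in reversed chronological order (alternative reading of a
#'   mirrored decoder); default reconstructs the original order.
#' @return An `autoencoder_config` list.
#' @export
autoencoder_config <- function(input_dim = 5L, lstm1_dim = 24L, fc_dim = 12L,
                               latent_dim = 2L, sets = 5L, epochs_per_set = 4L,
                               iters_per_epoch = 1000L, batch_size = 10L,
                               early_stop_rel_tol = 0.02,
                               learning_rate = 1e-3, seed = 1L,
                               reverse_target = FALSE) {
  cfg <- list(input_dim = as.integer(input_dim),
              lstm1_dim = as.integer(lstm1_dim),
              fc_dim = as.integer(fc_dim),
              latent_dim = as.integer(latent_dim),
              sets = as.integer(sets),
              epochs_per_set = as.integer(epochs_per_set),
              iters_per_epoch = as.integer(iters_per_epoch),
              batch_size = as.integer(batch_size),
              early_stop_rel_tol = early_stop_rel_tol,
              learning_rate = learning_rate,
              seed = as.integer(seed),
              reverse_target = isTRUE(reverse_target))
  dims <- c(cfg$input_dim, cfg$lstm1_dim, cfg$fc_dim, cfg$latent_dim,
            cfg$sets, cfg$epochs_per_set, cfg$iters_per_epoch, cfg$batch_size)
  if (any(is.na(dims)) || any(dims < 1L))
    stopf("all dimensions and schedule counts must be positive integers")
  if (!is.numeric(cfg$early_stop_rel_tol) || cfg$early_stop_rel_tol < 0 ||
      cfg$early_stop_rel_tol >= 1)
    stopf("early_stop_rel_tol must lie in [0, 1)")
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate <= 0)
    stopf("learning_rate must be positive")
  structure(cfg, class = "autoencoder_config")
}

# Parameter shapes, in the fixed order the C++ core expects.
param_shapes <- function(cfg) {
  d <- cfg$input_dim; a <- cfg$lstm1_dim; f <- cfg$fc_dim; k <- cfg$latent_dim
  list(Wx1 = c(d, 4 * a), Wh1 = c(a, 4 * a), b1 = c(1, 4 * a),
       We = c(a, f), be = c(1, f),
       Wx2 = c(f, 4 * k), Wh2 = c(k, 4 * k), b2 = c(1, 4 * k),
       Wx3 = c(k, 4 * f), Wh3 = c(f, 4 * f), b3 = c(1, 4 * f),
       Wd = c(f, a), bd = c(1, a),
       Wx4 = c(a, 4 * d), Wh4 = c(d, 4 * d), b4 = c(1, 4 * d),
       Wo = c(d, d), bo = c(1, d))
}

init_params <- function(cfg) {
  shapes <- param_shapes(cfg)
  with_seed(cfg$seed, {
    p <- lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (startsWith(nm, "b")) return(matrix(0, sh[1], sh[2]))
      r <- 1 / sqrt(sh[1])
      matrix(stats::runif(prod(sh), -r, r), sh[1], sh[2])
    })
    names(p) <- names(shapes)
    # standard LSTM forget-gate bias of 1 eases early gradient flow
    for (nm in c("b1", "b2", "b3", "b4")) {
      H <- ncol(p[[nm]]) / 4L
      p[[nm]][1, (H + 1):(2 * H)] <- 1
    }
    p
  })
}

zero_params <- function(cfg) {
  shapes <- param_shapes(cfg)
  lapply(shapes, function(sh) matrix(0, sh[1], sh[2]))
}

#' Build an (untrained) LSTM autoencoder
#'
#' Initializes all weights uniformly in `(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' under the configuration seed, with zero biases except a forget-gate bias
#' of 1.
#'
#' @param config An [autoencoder_config()].
#' @return An `ns_autoencoder` object (untrained).
#' @export
build_autoencoder <- function(config = autoencoder_config()) {
  if (!inherits(config, "autoencoder_config"))
    stopf("config must be an autoencoder_config")
  structure(list(config = config, params = init_params(config),
                 loss_history = numeric(0), trained = FALSE,
                 final_loss = NA_real_),
            class = "ns_autoencoder")
}

#' @export
print.ns_autoencoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ns_autoencoder> %d->%d->%d->%d%s; %s\n", cfg$input_dim, cfg$lstm1_dim,
    cfg$fc_dim, cfg$latent_dim,
    if (cfg$reverse_target) " (reversed target)" else "",
    if (x$trained)
      sprintf("trained, %d epochs, final loss %.4g", length(x$loss_history),
              x$final_loss)
    else "untrained"))
  invisible(x)
}

batch_cube <- function(batch) {
  if (!inherits(batch, "sequence_batch"))
    stopf("batch must be a sequence_batch")
  v <- batch$values
  if (length(dim(v)) != 3L) stopf("batch values must be a 3-d array")
  if (!all(is.finite(v))) stopf("batch contains non-finite values")
  aperm(v, c(1, 3, 2))  # (cases, items, timesteps) for the C++ core
}

#' Train the autoencoder
#'
#' Runs the mini-batch Adam schedule of the configuration: up to
#' `sets * epochs_per_set` epochs of `iters_per_epoch` updates on
#' mini-batches of `batch_size` cases drawn by replacement-free reshuffling
#' (wrapping over the cohort as needed). After every epoch the mean
#' mini-batch MSE is appended to `loss_history`; training stops early when
#' the relative improvement over the previous epoch drops below
#' `early_stop_rel_tol`. A full-batch loss is evaluated once at the end and
#' stored as `final_loss`.
#'
#' @param model An `ns_autoencoder` from [build_autoencoder()].
#' @param batch A non-empty `sequence_batch`.
#' @param config Optional configuration override (defaults to the model's).
#' @return The trained `ns_autoencoder` with `loss_history` filled in.
#' @export
train_autoencoder <- function(model, batch, config = model$config) {
  if (!inherits(model, "ns_autoencoder")) stopf("model must be an ns_autoencoder")
  X <- batch_cube(batch)
  n <- dim(X)[1]
  if (n < 1L) stopf("batch must contain at least one case")
  cfg <- config
  if (dim(X)[2] != cfg$input_dim)
    stopf("batch has %d items per step but the model expects %d",
          dim(X)[2], cfg$input_dim)
  params <- model$params
  m <- zero_params(cfg)
  v <- zero_params(cfg)
  step <- 0L
  n_epochs <- cfg$sets * cfg$epochs_per_set
  loss_history <- numeric(0)
  with_seed(derive_seed(cfg$seed, 101L), {
    for (epoch in seq_len(n_epochs)) {
      need <- cfg$iters_per_epoch * cfg$batch_size
      draws <- unlist(lapply(seq_len(ceiling(need / n)),
                             function(i) sample.int(n)), use.names = FALSE)
      idx <- matrix(draws[seq_len(need)], nrow = cfg$iters_per_epoch,
                    ncol = cfg$batch_size, byrow = TRUE)
      res <- ae_train_epoch_cpp(params, m, v, step, X, idx,
                                cfg$learning_rate, 0.9, 0.999, 1e-8,
                                cfg$reverse_target)
      if (!is.finite(res$loss))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      params <- res$params; m <- res$m; v <- res$v; step <- res$step
      loss_history <- c(loss_history, res$loss)
      if (epoch >= 2L) {
        prev <- loss_history[epoch - 1L]
        cur <- loss_history[epoch]
        rel <- if (prev > 0) (prev - cur) / prev else 0
        if (rel < cfg$early_stop_rel_tol) break
      }
    }
  })
  model$params <- params
  model$config <- cfg
  model$loss_history <- loss_history
  model$trained <- TRUE
  model$final_loss <- ae_forward_cpp(params, X, cfg$reverse_target)$loss
  model
}

#' Embed a cohort in the 2-D latent feature space
#'
#' Purely feed-forward: each case is encoded independently, so identical
#' inputs map to identical latent points and permuting rows permutes the
#' embedding identically.
#'
#' @param model An `ns_autoencoder` (trained or freshly built).
#' @param batch A `sequence_batch` with the model's input dimension.
#' @return A `latent_embedding`: list with `points` (n x latent_dim matrix)
#'   and `ids`.
#' @export
encode_cohort <- function(model, batch) {
  if (!inherits(model, "ns_autoencoder")) stopf("model must be an ns_autoencoder")
  X <- batch_cube(batch)
  if (dim(X)[2] != model$config$input_dim)
    stopf("batch has %d items per step but the model expects %d",
          dim(X)[2], model$config$input_dim)
  z <- ae_forward_cpp(model$params, X, model$config$reverse_target)$z
  rownames(z) <- batch$ids
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  structure(list(points = z, ids = batch$ids), class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("<latent_embedding> %d points in %d-d\n", nrow(x$points),
              ncol(x$points)))
  invisible(x)
}

#' Decode a batch back to trajectory space
#'
#' @param model An `ns_autoencoder`.
#' @param batch A `sequence_batch`.
#' @return An n x timesteps x items array of reconstructed (standardized)
#'   values.
#' @export
reconstruct <- function(model, batch) {
  X <- batch_cube(batch)
  Y <- ae_forward_cpp(model$params, X, model$config$reverse_target)$Y
  out <- aperm(Y, c(1, 3, 2))
  dimnames(out) <- dimnames(batch$values)
  out
}

#' Per-case mean squared reconstruction error
#'
#' For case i, the mean over all `timesteps * items` cells of the squared
#' difference between the (standardized) input and its reconstruction. The
#' mean of this vector equals the model's stored full-batch `final_loss` when
#' evaluated on the training batch.
#'
#' @inheritParams encode_cohort
#' @return Named numeric vector, one error per case.
#' @export
reconstruction_error <- function(model, batch) {
  if (!inherits(model, "ns_autoencoder")) stopf("model must be an ns_autoencoder")
  X <- batch_cube(batch)
  if (dim(X)[2] != model$config$input_dim)
    stopf("batch has %d items per step but the model expects %d",
          dim(X)[2], model$config$input_dim)
  err <- as.numeric(ae_forward_cpp(model$params, X,
                                   model$config$reverse_target)$per_case)
  stats::setNames(err, batch$ids)
}

#' Save / load an autoencoder checkpoint
#'
#' Checkpoints are plain JSON (configuration, weights, loss history, and the
#' scaler if one is supplied), portable across platforms.
#'
#' @param model An `ns_autoencoder`.
#' @param path JSON file path.
#' @param scaler Optional `scaler_params` stored alongside the weights.
#' @return `path` (save) or the restored `ns_autoencoder` (load).
#' @export
save_autoencoder <- function(model, path, scaler = NULL) {
  if (!inherits(model, "ns_autoencoder")) stopf("model must be an ns_autoencoder")
  payload <- list(config = unclass(model$config),
                  params = model$params,
                  loss_history = model$loss_history,
                  trained = model$trained,
                  final_loss = model$final_loss)
  if (!is.null(scaler))
    payload$scaler <- list(mean = as.list(scaler$mean),
                           sd = as.list(scaler$sd))  # keep item names in JSON
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(autoencoder_config, payload$config[
    setdiff(names(payload$config), character(0))])
  params <- lapply(payload$params, function(p) {
    m <- as.matrix(p)
    if (is.null(dim(p))) m <- matrix(as.numeric(p), nrow = 1)
    m
  })
  model <- structure(list(config = cfg, params = params,
                          loss_history = as.numeric(payload$loss_history),
                          trained = isTRUE(payload$trained),
                          final_loss = payload$final_loss %||% NA_real_),
                     class = "ns_autoencoder")
  if (!is.null(payload$scaler)) {
    attr(model, "scaler") <- structure(
      list(mean = unlist(payload$scaler$mean),
           sd = unlist(payload$scaler$sd)),
      class = "scaler_params")
  }
  model
}
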