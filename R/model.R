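#' Construct a spiking identification network
#'
#' A fully connected feedforward spiking network (default 784/200/10
#' input/hidden/output units) of LIF nodes.  Weights are initialised from a
#' zero-mean Gaussian scaled by `1/sqrt(fan-in)` (keeps initial spiking
#' rates stable); biases start at zero and act as a constant input current
#' per frame.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param lif a [lif_config].
#' @param recovery a [recovery_model] governing timing-dependent silencing.
#' @param seed integer seed for the weight initialisation.
#' @param init_sd weight standard deviation; default `1/sqrt(fan-in)` per
#'   layer when `NULL`.
#' @return an object of class `idnet_model` with elements `W1`
#'   (`n_in x n_hidden`), `b1`, `W2` (`n_hidden x n_out`), `b2`, `lif`,
#'   `recovery`, and (after training) `trained_order`, `trained_delta_t`
#'   and `boundary_pool`.
#' @export
idnet_model <- function(n_in = 784L, n_hidden = 200L, n_out = 10L,
                        lif = lif_config(), recovery = recovery_model(),
                        seed = 1L, init_sd = NULL) {
  sd1 <- if (is.null(init_sd)) 1 / sqrt(n_in) else init_sd
  sd2 <- if (is.null(init_sd)) 1 / sqrt(n_hidden) else init_sd
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(n_in * n_hidden, 0, sd1), n_in, n_hidden)
    W2 <- matrix(stats::rnorm(n_hidden * n_out, 0, sd2), n_hidden, n_out)
  })
  structure(list(W1 = W1, b1 = numeric(n_hidden), W2 = W2,
                 b2 = numeric(n_out), lif = lif, recovery = recovery,
                 trained_order = NULL, trained_delta_t = NULL,
                 boundary_pool = list(.zero_profiles(n_in, n_hidden))),
            class = "idnet_model")
}

# an all-active donor entry used until real profiles are banked
.zero_profiles <- function(n_in, n_hidden) {
  list(input = structure(numeric(n_in), class = "silencing_profile"),
       hidden = structure(numeric(n_hidden), class = "silencing_profile"))
}

#' @export
print.idnet_model <- function(x, ...) {
  cat("<idnet_model> ", nrow(x$W1), "/", ncol(x$W1), "/", ncol(x$W2),
      " LIF(tau=", x$lif$tau, ", thr=", x$lif$threshold, ")",
      if (!is.null(x$trained_order))
        paste0("  trained order: ", paste(x$trained_order, collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

# strip S3 classes recursively so plain jsonlite serialisation applies
.unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, .unclass_deep)
  else if (is.object(x) && !is.function(x)) unclass(x)
  else x
}

#' Save a model checkpoint as JSON
#'
#' Weights, biases and the LIF/recovery configuration are stored as plain
#' JSON so checkpoints are portable, diffable and usable as test fixtures.
#'
#' @param model an `idnet_model` or `ann_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    class = class(model)[1],
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    lif = model$lif, recovery = model$recovery,
    activation = model$activation,
    trained_order = model$trained_order,
    trained_delta_t = model$trained_delta_t,
    boundary_pool = lapply(model$boundary_pool, function(p)
      list(input = as.numeric(p$input), hidden = as.numeric(p$hidden)))
  )
  payload <- .unclass_deep(payload)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#'
#' @param path checkpoint path.
#' @return the restored model.
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_prof <- function(v) structure(as.numeric(v), class = "silencing_profile")
  model <- list(
    W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
    W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
    trained_order = if (length(p$trained_order)) as.integer(p$trained_order),
    trained_delta_t = p$trained_delta_t)
  if (!is.null(p$lif))
    model$lif <- structure(p$lif[c("tau", "threshold", "frame_dt")],
                           class = "lif_config")
  if (!is.null(p$recovery)) {
    rec <- p$recovery
    model$recovery <- recovery_model(rec$kernel, rec$fast_lookback,
                                     rec$slow_cutoff_ms, rec$fast_gap_ms,
                                     rec$tau_ms)
  }
  if (!is.null(p$activation)) model$activation <- p$activation
  if (is.data.frame(p$boundary_pool)) {
    model$boundary_pool <- lapply(seq_len(nrow(p$boundary_pool)), function(i)
      list(input = as_prof(p$boundary_pool$input[[i]]),
           hidden = as_prof(p$boundary_pool$hidden[[i]])))
  } else {
    model$boundary_pool <- lapply(p$boundary_pool, function(e)
      list(input = as_prof(e$input), hidden = as_prof(e$hidden)))
  }
  class(model) <- p$class
  model
}
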