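#' Training configuration
#'
#' @param eta learning rate.
#' @param alpha L2 regularisation coefficient (per-step weight decay).
#' @param epochs training epochs (default 10).
#' @param n_sequences training sequences per epoch (`NULL`: length of the
#'   dataset).
#' @param M examples per cost evaluation context (default 1: one
#'   backpropagation step at the end of each presented digit).
#' @param seed master seed for weight initialisation and mask draws.
#' @return a `training_config` list.
#' @export
training_config <- function(eta, alpha, epochs = 10L, n_sequences = NULL,
                            M = 1L, seed = 1L) {
  if (eta <= 0) stop("eta must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  epochs <- as.integer(epochs)
  if (epochs < 0L) stop("epochs must be >= 0")
  structure(list(eta = eta, alpha = alpha, epochs = epochs,
                 n_sequences = n_sequences, M = as.integer(M),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Rate outputs of a presented digit
#'
#' The output of unit `i` is its average firing over the last `d1` frames;
#' the target is the one-hot encoding of the digit label.
#'
#' @param record a `spike_record`.
#' @param d1 evaluation window length.
#' @param label true digit label.
#' @return list with `a` (10 rates in `[0, 1]`) and `y` (one-hot target),
#'   class `rate_outputs`.
#' @export
rate_outputs <- function(record, d1, label) {
  out <- record$output
  if (nrow(out) < d1) stop("record covers fewer than d1 frames")
  n_out <- ncol(out)
  label <- as.integer(label)
  if (label < 0L || label >= n_out) stop("invalid label: ", label)
  a <- colSums(out[seq.int(nrow(out) - d1 + 1L, nrow(out)), , drop = FALSE]) / d1
  y <- numeric(n_out); y[label + 1L] <- 1
  structure(list(a = a, y = y), class = "rate_outputs")
}

#' Cross-entropy cost with L2 penalty
#'
#' `C = -(1/M) * sum_m sum_i [y log a + (1 - y) log(1 - a)]
#'  + (alpha / (2 eta)) * sum_j W_j^2`, the regularisation summing over all
#' weights in the network (biases excluded).  Rates are clipped to
#' `[1e-12, 1 - 1e-12]` inside the logs.
#'
#' @param batch list of `rate_outputs` (length `M`).
#' @param weights numeric vector (or list of matrices) of all network
#'   weights; may be `NULL` for the unregularised cost.
#' @param alpha regularisation coefficient.
#' @param eta learning rate (enters only the penalty scale).
#' @return scalar cost.
#' @export
idnet_cost <- function(batch, weights = NULL, alpha = 0, eta = 1) {
  if (inherits(batch, "rate_outputs")) batch <- list(batch)
  M <- length(batch)
  if (M < 1L) stop("batch must contain at least one example")
  eps <- 1e-12
  ce <- vapply(batch, function(r) {
    a <- pmin(1 - eps, pmax(eps, r$a))
    -sum(r$y * log(a) + (1 - r$y) * log(1 - a))
  }, numeric(1))
  reg <- if (is.null(weights) || alpha == 0) 0 else {
    w <- if (is.list(weights)) unlist(weights, use.names = FALSE) else weights
    (alpha / (2 * eta)) * sum(w^2)
  }
  mean(ce) + reg
}

#' One per-digit backpropagation step
#'
#' Gradients are computed from rate surrogates: the hidden "activation" is
#' the firing fraction over the last `d1` frames, the output delta is
#' `a - y` (canonical cross-entropy delta), and the hidden surrogate
#' derivative is `r (1 - r)` at the hidden rate `r`.  Every gradient term
#' involving a silenced input or hidden node is exactly zero; the L2 term
#' contributes a per-step decay `alpha * W` to all weights.
#'
#' @param model an `idnet_model`.
#' @param record the digit's `spike_record`.
#' @param mask the silencing mask used for the digit.
#' @param label the digit's true label.
#' @param cfg a [training_config].
#' @param d1 evaluation window length.
#' @param eta_override optional per-digit learning-rate override (used to
#'   lift the digit with the lowest success rate).
#' @return the updated model.
#' @export
backprop_digit <- function(model, record, mask, label, cfg, d1,
                           eta_override = NULL) {
  eta <- if (is.null(eta_override)) cfg$eta else eta_override
  g <- .digit_gradients(model, record, mask, label, d1)
  if (!all(is.finite(g$gW1)) || !all(is.finite(g$gW2)))
    stop("non-finite gradients")
  model$W1 <- (1 - cfg$alpha) * model$W1 - eta * g$gW1
  model$b1 <- model$b1 - eta * g$gb1
  model$W2 <- (1 - cfg$alpha) * model$W2 - eta * g$gW2
  model$b2 <- model$b2 - eta * g$gb2
  model
}

# cross-entropy gradients on the rate surrogate; silenced terms vanish
.digit_gradients <- function(model, record, mask, label, d1) {
  n <- nrow(record$output)
  win <- seq.int(n - d1 + 1L, n)
  a <- colSums(record$output[win, , drop = FALSE]) / d1
  r <- colSums(record$hidden[win, , drop = FALSE]) / d1
  p <- colSums(record$input[win, , drop = FALSE]) / d1
  y <- numeric(length(a)); y[label + 1L] <- 1

  delta_o <- a - y
  r[!mask$hidden] <- 0
  p[!mask$input] <- 0
  gW2 <- outer(r, delta_o)
  gW2[!mask$hidden, ] <- 0
  dh <- as.numeric(model$W2 %*% delta_o) * r * (1 - r)
  dh[!mask$hidden] <- 0
  gW1 <- outer(p, dh)
  gW1[!mask$input, ] <- 0
  list(gW1 = gW1, gb1 = dh, gW2 = gW2, gb2 = delta_o,
       rates = list(a = a, y = y))
}

#' Train an identification network on one embedded sequence
#'
#' Iterates over timed training sequences that all share one digit order.
#' For each digit: a silencing mask is drawn (the first digit of a sequence
#' adopts a donor profile banked from previously trained sequences), the
#' masked forward pass is run, one backpropagation step is taken, and the
#' digit's activity over the last `d1` frames determines the next digit's
#' silencing profile.
#'
#' @param dataset list of `presentation_timeline`s (or a function
#'   `function(i)` returning the `i`-th timeline), all with the same order.
#' @param cfg a [training_config].
#' @param model optional starting `idnet_model`; built from `hidden` and
#'   `lif`/`recovery` when `NULL`.
#' @param hidden hidden-layer size used when `model` is `NULL`.
#' @param lif,recovery configurations used when `model` is `NULL`.
#' @param pool_size number of donor profile pairs banked for the
#'   first-digit boundary condition.
#' @param eta_by_position optional per-position learning-rate multipliers
#'   (length = sequence length): a slightly different eta for the digit
#'   with the lowest success rate can lift it (see
#'   [rescue_low_sr_digits]).
#' @return the trained `idnet_model`, with an attribute `log`:
#'   data frame of per-epoch mean cost.
#' @export
train_idnet <- function(dataset, cfg, model = NULL, hidden = 200L,
                        lif = lif_config(), recovery = recovery_model(),
                        pool_size = 20L, eta_by_position = NULL) {
  get_tl <- if (is.function(dataset)) dataset else function(i) dataset[[i]]
  n_seq <- if (!is.null(cfg$n_sequences)) cfg$n_sequences else length(dataset)
  if (n_seq < 1L) stop("no training sequences")
  first <- get_tl(1L)
  order0 <- timeline_order(first)
  spec <- first$spec
  if (is.null(model))
    model <- idnet_model(ncol(first$digits[[1]]$frames), hidden,
                         lif = lif, recovery = recovery,
                         seed = derive_seed(cfg$seed, 99L))
  model$trained_order <- order0
  model$trained_delta_t <- spec$delta_t

  log_cost <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ep_cost <- 0; ep_n <- 0L
    for (s in seq_len(n_seq)) {
      tl <- get_tl(s)
      if (!identical(timeline_order(tl), order0))
        stop("training timelines must share one digit order")
      seq_profiles <- vector("list", length(tl$digits))
      state <- NULL
      mask_seed <- derive_seed(cfg$seed, ep, s)
      step_fn <- function(k, mask, gap) {
        if (!is.null(state))
          state <<- list(
            V_hidden = decay_over_gap(state$V_hidden, gap, model$lif$tau),
            V_output = decay_over_gap(state$V_output, gap, model$lif$tau))
        rec <- forward_digit(model, tl$digits[[k]]$frames, mask, state)
        state <<- list(V_hidden = rec$V_hidden, V_output = rec$V_output)
        label <- tl$digits[[k]]$image$label
        ro <- rate_outputs(rec, spec$d1, label)
        ep_cost <<- ep_cost + idnet_cost(list(ro))
        ep_n <<- ep_n + 1L
        eta_k <- if (is.null(eta_by_position)) NULL
                 else cfg$eta * eta_by_position[k]
        model <<- backprop_digit(model, rec, mask, label, cfg, spec$d1,
                                 eta_override = eta_k)
        a_in <- activity_counts(rec$input, spec$d1)
        a_hid <- activity_counts(rec$hidden, spec$d1)
        seq_profiles[[k]] <<- list(input = profile_from_activity(a_in),
                                   hidden = profile_from_activity(a_hid))
        list(input = a_in, hidden = a_hid)
      }
      .run_spiking_sequence(model, tl, mask_seed, step_fn)
      # bank this sequence's profiles as boundary donors for later sequences
      model$boundary_pool <- utils::tail(
        c(model$boundary_pool, seq_profiles[-1L]), pool_size)
    }
    log_cost[ep] <- if (ep_n > 0L) ep_cost / ep_n else NA_real_
  }
  attr(model, "log") <- data.frame(epoch = seq_len(cfg$epochs),
                                   mean_cost = log_cost)
  model
}

#' Lift the digits with the lowest success rate
#'
#' Training sequences occasionally leave one digit with a much lower
#' success rate than the rest.  The remedy is to continue training with a
#' slightly different (boosted) learning rate for the weakest position:
#' this function evaluates per-digit SR on a validation set, and while the
#' minimum falls short of `target`, reruns a few epochs with
#' `eta_by_position` raised at the weakest position.
#'
#' @param model a trained `idnet_model`.
#' @param dataset the training timelines (list or generator).
#' @param cfg the [training_config] used for training; `epochs` is
#'   replaced by `epochs_per_round` during rescue rounds.
#' @param val_set validation timelines from the training distribution.
#' @param target minimal acceptable per-digit SR (default 0.7).
#' @param boost learning-rate multiplier at the weakest position.
#' @param epochs_per_round extra epochs per rescue round.
#' @param max_rounds maximum rescue rounds.
#' @param seed seed for the validation-time mask draws.
#' @return the (possibly further trained) model.
#' @export
rescue_low_sr_digits <- function(model, dataset, cfg, val_set, target = 0.7,
                                 boost = 2, epochs_per_round = 3L,
                                 max_rounds = 2L, seed = 1L) {
  n_pos <- length(model$trained_order)
  for (round in seq_len(max_rounds)) {
    srs <- per_digit_sr(model, val_set, "known_order",
                        seed = derive_seed(seed, round))
    if (min(srs) >= target) break
    mult <- rep(1, n_pos)
    mult[which.min(srs)] <- boost
    cfg_r <- cfg
    cfg_r$epochs <- as.integer(epochs_per_round)
    cfg_r$seed <- derive_seed(cfg$seed, 1000L + round)
    model <- train_idnet(dataset, cfg_r, model = model,
                         eta_by_position = mult)
  }
  model
}

#' Coarse-to-fine grid search for the learning parameters
#'
#' Evaluates `objective(eta, alpha, fold)` over the Cartesian grid, averages
#' across folds (cross-validation), then refines once around the best cell
#' with geometric midpoints to its grid neighbours.  Ties break toward
#' smaller `eta`, then smaller `alpha`.
#'
#' @param objective function `(eta, alpha, fold) -> score`; higher is
#'   better (e.g. the mean per-digit success rate).
#' @param eta_grid,alpha_grid non-empty numeric grids.
#' @param folds number of cross-validation folds.
#' @param refine run the fine-tuning pass (default `TRUE`).
#' @return list with `eta`, `alpha` and `score`.
#' @export
grid_search <- function(objective, eta_grid, alpha_grid, folds = 3L,
                        refine = TRUE) {
  if (length(eta_grid) == 0L || length(alpha_grid) == 0L)
    stop("parameter grids must be non-empty")
  eval_grid <- function(etas, alphas) {
    cells <- expand.grid(eta = sort(etas), alpha = sort(alphas))
    cells$score <- apply(cells, 1, function(cell) {
      mean(vapply(seq_len(folds),
                  function(f) objective(cell[["eta"]], cell[["alpha"]], f),
                  numeric(1)))
    })
    cells[order(-cells$score, cells$eta, cells$alpha), ][1, ]
  }
  best <- eval_grid(eta_grid, alpha_grid)
  if (refine && (length(eta_grid) > 1L || length(alpha_grid) > 1L)) {
    widen <- function(grid, centre) {
      g <- sort(unique(grid))
      i <- which.min(abs(g - centre))
      lo <- if (i > 1L) sqrt(g[i - 1L] * g[i]) else g[i] / 2
      hi <- if (i < length(g)) sqrt(g[i] * g[i + 1L]) else g[i] * 2
      unique(c(lo, g[i], hi))
    }
    fine <- eval_grid(widen(eta_grid, best$eta), widen(alpha_grid, best$alpha))
    if (fine$score > best$score) best <- fine
  }
  list(eta = best$eta, alpha = best$alpha, score = best$score)
}

#' Published hyperparameter presets
#'
#' The learning-rate / regularisation pairs used for the reference
#' experiments, bundled as a YAML registry: single embedded spiking
#' sequence, two embedded sequences, writer-dependent recognition, the
#' sigmoid fully connected variant, and the ReLU convolutional variant.
#'
#' @param name optional preset name; all presets when `NULL`.
#' @return a named list (or one preset's list of `eta`/`alpha`).
#' @export
hyperparam_presets <- function(name = NULL) {
  path <- system.file("extdata", "hyperparams.yaml", package = "idnet")
  presets <- yaml::read_yaml(path)
  if (is.null(name)) presets
  else if (!name %in% names(presets)) stop("unknown preset: ", name)
  else presets[[name]]
}
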