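# Continuous-activation generalisation: the same 784/200/10 architecture
# with sigmoid units, where a node's silencing probability for the next
# object equals its activation value for the previous one.

#' Standardise a gray image for the continuous-activation network
#'
#' Subtracts the mean pixel value and scales to unit standard deviation,
#' per example.
#'
#' @param image a [gray_image].
#' @return numeric vector of 784 standardised values.
#' @export
standardize_input <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  x <- as.numeric(image$pixels)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2)) # population sd: two-level images map to +/-1
  if (s == 0) stop("degenerate input: constant image has no scale")
  (x - m) / s
}

#' Construct a continuous-activation identification network
#'
#' Fully connected, with bias units feeding every hidden and output node;
#' all weights drawn from a zero-mean Gaussian with standard deviation
#' `init_sd` (default 1).
#'
#' @param n_in,n_hidden,n_out layer sizes (default 784/200/10).
#' @param activation hidden activation: `"sigmoid"` (default) or
#'   `"relu"` (output nodes stay sigmoid).
#' @param recovery a [recovery_model] for timing-dependent silencing.
#' @param seed integer seed for the weight initialisation.
#' @param init_sd weight standard deviation (default 1).
#' @return an object of class `ann_model`.
#' @export
ann_model <- function(n_in = 784L, n_hidden = 200L, n_out = 10L,
                      activation = c("sigmoid", "relu"),
                      recovery = recovery_model(), seed = 1L, init_sd = 1) {
  activation <- match.arg(activation)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(n_in * n_hidden, 0, init_sd), n_in, n_hidden)
    b1 <- stats::rnorm(n_hidden, 0, init_sd)
    W2 <- matrix(stats::rnorm(n_hidden * n_out, 0, init_sd), n_hidden, n_out)
    b2 <- stats::rnorm(n_out, 0, init_sd)
  })
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 activation = activation, recovery = recovery,
                 trained_order = NULL, trained_delta_t = NULL,
                 boundary_pool = list(.zero_profiles(n_in, n_hidden))),
            class = "ann_model")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of one object through the masked ANN
#'
#' Silenced input and hidden nodes contribute exactly zero downstream;
#' the output layer is never masked.
#'
#' @param model an `ann_model`.
#' @param input standardised input vector (see [standardize_input]).
#' @param mask list with logical `input` and `hidden` (`TRUE` = active).
#' @return list with `input` (masked), `hidden` and `output` activations.
#' @export
forward_ann_digit <- function(model, input, mask) {
  if (length(input) != nrow(model$W1)) stop("input length mismatch")
  if (length(mask$input) != nrow(model$W1) ||
      length(mask$hidden) != ncol(model$W1))
    stop("mask shapes do not match the model layers")
  x <- as.numeric(input)
  x[!mask$input] <- 0
  z1 <- as.numeric(crossprod(model$W1, x)) + model$b1
  h <- if (model$activation == "relu") pmax(0, z1) else .sigmoid(z1)
  h[!mask$hidden] <- 0
  a <- .sigmoid(as.numeric(crossprod(model$W2, h)) + model$b2)
  list(input = x, hidden = h, output = a)
}

# cross-entropy gradients with silenced terms removed
.ann_gradients <- function(model, act, mask, label) {
  y <- numeric(length(act$output)); y[label + 1L] <- 1
  delta_o <- act$output - y
  h <- act$hidden
  dact <- if (model$activation == "relu") as.numeric(h > 0) else h * (1 - h)
  dh <- as.numeric(model$W2 %*% delta_o) * dact
  dh[!mask$hidden] <- 0
  gW2 <- outer(h, delta_o)
  gW2[!mask$hidden, ] <- 0
  gW1 <- outer(act$input, dh)
  gW1[!mask$input, ] <- 0
  list(gW1 = gW1, gb1 = dh, gW2 = gW2, gb2 = delta_o)
}

#' One per-object backpropagation step for the ANN variant
#'
#' Standard sigmoid/cross-entropy gradients in which every term involving
#' a silenced input or hidden node vanishes; all weights additionally
#' decay by `alpha` per step.
#'
#' @param model an `ann_model`.
#' @param act activations from [forward_ann_digit].
#' @param mask the silencing mask used for the object.
#' @param label true label.
#' @param cfg a [training_config].
#' @return the updated model.
#' @export
backprop_ann_digit <- function(model, act, mask, label, cfg) {
  g <- .ann_gradients(model, act, mask, label)
  model$W1 <- (1 - cfg$alpha) * model$W1 - cfg$eta * g$gW1
  model$b1 <- model$b1 - cfg$eta * g$gb1
  model$W2 <- (1 - cfg$alpha) * model$W2 - cfg$eta * g$gW2
  model$b2 <- model$b2 - cfg$eta * g$gb2
  model
}

# activation values -> pseudo activity records so the spiking timing
# machinery (recovery kernel, lookback) applies unchanged; d1 = 1 keeps
# q/d1 equal to the activation.
.ann_activity <- function(values) {
  structure(list(q = pmin(1, as.numeric(values)), d1 = 1L),
            class = "activity_record")
}

#' @rdname present_sequence
#' @export
present_sequence.ann_model <- function(model, timeline, seed,
                                       keep_records = TRUE, ...) {
  n <- length(timeline$digits)
  labels <- integer(n)
  records <- if (keep_records) vector("list", n)
  masks <- vector("list", n)
  rule <- if (model$activation == "relu") "relu" else "sigmoid"
  step_fn <- function(k, mask, gap) {
    img <- timeline$digits[[k]]$image
    act <- forward_ann_digit(model, standardize_input(img), mask)
    labels[k] <<- which.max(act$output) - 1L
    if (keep_records) records[[k]] <<- act
    masks[[k]] <<- mask
    # input nodes expose the normalised gray level in [0, 1] when active
    in_val <- img$pixels / 255
    in_val[!mask$input] <- 0
    list(input = .ann_activity(in_val),
         hidden = .ann_activity(ann_silencing_profile(act$hidden, rule)))
  }
  .run_spiking_sequence(model, timeline, seed, step_fn)
  list(labels = labels, records = records, masks = masks)
}

#' Train the continuous-activation ID-net on one embedded sequence
#'
#' Mirrors [train_idnet]: per-object silencing masks are drawn from the
#' previous object's activation values (first object: donor profile from
#' the boundary pool), one cross-entropy backpropagation step follows each
#' object, and silenced terms vanish from the gradients.
#'
#' @param dataset list of `presentation_timeline`s (or generator function)
#'   sharing one order.
#' @param cfg a [training_config].
#' @param model optional starting `ann_model`.
#' @param hidden hidden-layer size when `model` is `NULL`.
#' @param recovery a [recovery_model] when `model` is `NULL`.
#' @param pool_size donor profile pairs banked for the boundary condition.
#' @return the trained `ann_model` with a per-epoch cost log attribute.
#' @export
train_ann_sequence <- function(dataset, cfg, model = NULL, hidden = 200L,
                               recovery = recovery_model(),
                               pool_size = 20L) {
  get_tl <- if (is.function(dataset)) dataset else function(i) dataset[[i]]
  n_seq <- if (!is.null(cfg$n_sequences)) cfg$n_sequences else length(dataset)
  if (n_seq < 1L) stop("no training sequences")
  first <- get_tl(1L)
  order0 <- timeline_order(first)
  if (is.null(model))
    model <- ann_model(length(first$digits[[1]]$image$pixels), hidden,
                       recovery = recovery,
                       seed = derive_seed(cfg$seed, 99L))
  model$trained_order <- order0
  model$trained_delta_t <- first$spec$delta_t
  rule <- if (model$activation == "relu") "relu" else "sigmoid"

  log_cost <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ep_cost <- 0; ep_n <- 0L
    for (s in seq_len(n_seq)) {
      tl <- get_tl(s)
      if (!identical(timeline_order(tl), order0))
        stop("training timelines must share one digit order")
      seq_profiles <- vector("list", length(tl$digits))
      step_fn <- function(k, mask, gap) {
        img <- tl$digits[[k]]$image
        act <- forward_ann_digit(model, standardize_input(img), mask)
        label <- img$label
        y <- numeric(length(act$output)); y[label + 1L] <- 1
        eps <- 1e-12
        ac <- pmin(1 - eps, pmax(eps, act$output))
        ep_cost <<- ep_cost - sum(y * log(ac) + (1 - y) * log(1 - ac))
        ep_n <<- ep_n + 1L
        model <<- backprop_ann_digit(model, act, mask, label, cfg)
        in_val <- img$pixels / 255
        in_val[!mask$input] <- 0
        hid_prof <- ann_silencing_profile(act$hidden, rule)
        seq_profiles[[k]] <<- list(
          input = structure(in_val, class = "silencing_profile"),
          hidden = hid_prof)
        list(input = .ann_activity(in_val), hidden = .ann_activity(hid_prof))
      }
      .run_spiking_sequence(model, tl, derive_seed(cfg$seed, ep, s), step_fn)
      model$boundary_pool <- utils::tail(
        c(model$boundary_pool, seq_profiles[-1L]), pool_size)
    }
    log_cost[ep] <- if (ep_n > 0L) ep_cost / ep_n else NA_real_
  }
  attr(model, "log") <- data.frame(epoch = seq_len(cfg$epochs),
                                   mean_cost = log_cost)
  model
}
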