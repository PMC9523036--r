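# Shared fixtures: tiny networks, frame trains and pruning oracles built in
# code at test time.

tiny_spec <- function(order = c(0L, 1L, 2L), d = 8L, d1 = 4L, delta_t = 200)
  sequence_spec(order, delta_t = delta_t, d = d, d1 = d1)

tiny_model <- function(n_in = 12L, n_hidden = 5L, n_out = 4L, seed = 1L)
  idnet_model(n_in, n_hidden, n_out, seed = seed)

random_frames <- function(n_in = 12L, d = 8L, seed = 1L, p = 0.5)
  encode_frames(rep(p, n_in), d = d, seed = seed)

random_mask <- function(n_in, n_hidden, seed, p_silence = 0.4) {
  set.seed(seed)
  list(input = stats::runif(n_in) > p_silence,
       hidden = stats::runif(n_hidden) > p_silence)
}

# independent oracle: build the explicitly pruned sub-network (silenced
# rows/columns deleted) and run a plain, loop-based LIF forward pass on it
pruned_forward_oracle <- function(model, frames, mask) {
  ai <- which(mask$input); ah <- which(mask$hidden)
  W1 <- model$W1[ai, ah, drop = FALSE]
  b1 <- model$b1[ah]
  W2 <- model$W2[ah, , drop = FALSE]
  cfg <- model$lif
  decay <- exp(-cfg$frame_dt / cfg$tau)
  d <- nrow(frames)
  Vh <- numeric(length(ah)); Vo <- numeric(ncol(W2))
  Sh <- matrix(FALSE, d, length(ah)); So <- matrix(FALSE, d, ncol(W2))
  for (k in seq_len(d)) {
    x <- as.numeric(frames[k, ai])
    Vh <- Vh * decay + as.numeric(crossprod(W1, x)) + b1
    fh <- Vh >= cfg$threshold
    Sh[k, ] <- fh; Vh[fh] <- 0
    Vo <- Vo * decay + as.numeric(crossprod(W2, as.numeric(fh))) + model$b2
    fo <- Vo >= cfg$threshold
    So[k, ] <- fo; Vo[fo] <- 0
  }
  list(hidden = Sh, output = So)
}

# independent re-derivation of the documented rate-surrogate gradients
surrogate_gradient_oracle <- function(model, record, mask, label, d1) {
  n <- nrow(record$output)
  win <- seq.int(n - d1 + 1L, n)
  rate <- function(S) colSums(S[win, , drop = FALSE]) / d1
  a <- rate(record$output)
  r <- rate(record$hidden) * mask$hidden
  p <- rate(record$input) * mask$input
  y <- numeric(length(a)); y[label + 1L] <- 1
  do <- a - y
  dh <- (as.numeric(model$W2 %*% do) * r * (1 - r)) * mask$hidden
  list(gW1 = outer(p, dh) * outer(as.numeric(mask$input),
                                  as.numeric(mask$hidden)),
       gb1 = dh,
       gW2 = outer(r, do) * as.numeric(mask$hidden),
       gb2 = do)
}

# a hand-built spike record whose last-d1 output rates are exactly one-hot
onehot_record <- function(d = 8L, d1 = 4L, n_in = 12L, n_hidden = 5L,
                          n_out = 4L, label = 2L) {
  So <- matrix(FALSE, d, n_out)
  So[seq.int(d - d1 + 1L, d), label + 1L] <- TRUE
  structure(list(input = matrix(FALSE, d, n_in),
                 hidden = matrix(FALSE, d, n_hidden),
                 output = So),
            class = "spike_record")
}

tiny_timeline_set <- function(spec, n, seed, writer = NULL)
  make_timeline_set(spec, n, seed, writer = writer)
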