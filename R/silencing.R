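# Activity-dependent node silencing: the long-term plasticity mechanism that
# turns a memoryless feedforward classifier into a sequence identifier.
# A node's probability of being silenced for a whole upcoming digit equals
# its firing fraction q/d1 in the last d1 frames of the previous digit.

#' Spike counts over the final evaluation window
#'
#' @param spikes logical matrix, frames x nodes, one digit's spike trains
#'   for one layer.
#' @param d1 window length in frames.
#' @return an `activity_record`: list with `q` (per-node counts in
#'   `[0, d1]`) and `d1`.
#' @export
activity_counts <- function(spikes, d1) {
  d1 <- as.integer(d1)
  if (nrow(spikes) < d1) stop("spike train shorter than d1")
  win <- spikes[seq.int(nrow(spikes) - d1 + 1L, nrow(spikes)), , drop = FALSE]
  structure(list(q = colSums(win), d1 = d1), class = "activity_record")
}

#' Silencing profile from recorded activity
#'
#' The per-node probability of being silenced for the next digit:
#' `q / d1`.  A node that fired in every window frame is silenced with
#' probability 1; a silent node stays active with certainty.
#'
#' @param rec an `activity_record`.
#' @return numeric vector of probabilities (class `silencing_profile`).
#' @export
profile_from_activity <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  structure(rec$q / rec$d1, class = "silencing_profile")
}

#' Draw a silencing mask from a profile
#'
#' One uniform draw per node, once per digit: the node is silenced iff
#' `u < p` (strict).  The resulting active/silenced state is held fixed for
#' all `d` frames of the digit.
#'
#' @param profile a `silencing_profile` (or numeric probability vector).
#' @param seed integer RNG seed.
#' @return logical vector, `TRUE` = active, `FALSE` = silenced
#'   (class `silencing_mask`).
#' @export
draw_mask <- function(profile, seed) {
  p <- unclass(profile)
  if (any(p < 0) || any(p > 1)) stop("profile values must lie in [0, 1]")
  u <- with_seed(seed, stats::runif(length(p)))
  structure(!(u < p), class = "silencing_mask")
}

#' Boundary mask for the first digit of a sequence
#'
#' The first digit has no predecessor, so boundary-condition effects are
#' excluded by adopting the silencing profile of a randomly selected digit
#' of another trained sequence: one donor profile is picked uniformly from
#' the pool and a mask is drawn from it.
#'
#' @param donor_profiles non-empty list of `silencing_profile`s.
#' @param seed integer RNG seed (selects the donor and draws the mask).
#' @return a `silencing_mask`.
#' @export
boundary_mask <- function(donor_profiles, seed) {
  if (length(donor_profiles) == 0L) stop("donor profile pool is empty")
  pick <- with_seed(derive_seed(seed, 1L),
                    sample.int(length(donor_profiles), 1L))
  draw_mask(donor_profiles[[pick]], derive_seed(seed, 2L))
}

#' Recovery model for timing-dependent silencing
#'
#' Concretises how presentation speed modulates silencing.  With the step
#' kernel, only the immediately preceding digit contributes at the trained
#' time-lag; at fast time-lags (gap below `fast_gap_ms`) the previous
#' `fast_lookback` digits all contribute, silencing additional nodes that
#' spiked for earlier digits; once a digit's elapsed time reaches
#' `slow_cutoff_ms` its effect has vanished and all nodes are active.
#' The exponential kernel instead weights each past digit by
#' `exp(-elapsed / tau_ms)`.
#'
#' @param kernel `"step"` (default) or `"exponential"`.
#' @param fast_lookback digits contributing under fast timing (default 2).
#' @param slow_cutoff_ms elapsed time beyond which silencing has recovered.
#' @param fast_gap_ms gap below which timing counts as fast; default is set
#'   from the trained `delta_t` (half of it) at use time when `NULL`.
#' @param tau_ms decay constant of the exponential kernel.
#' @return a `recovery_model` list.
#' @export
recovery_model <- function(kernel = c("step", "exponential"),
                           fast_lookback = 2L, slow_cutoff_ms = 1000,
                           fast_gap_ms = NULL, tau_ms = 300) {
  kernel <- match.arg(kernel)
  structure(list(kernel = kernel, fast_lookback = as.integer(fast_lookback),
                 slow_cutoff_ms = slow_cutoff_ms, fast_gap_ms = fast_gap_ms,
                 tau_ms = tau_ms),
            class = "recovery_model")
}

#' Timing-adjusted silencing profile
#'
#' Combines the activity of recent digits into the silencing profile for
#' the next one: `p = min(1, sum_j (q_j / d1) * g(elapsed_j))` with the
#' kernel `g` of the [recovery_model].  `history` is ordered most recent
#' first; `elapsed` is the time from the end of each past digit to the
#' onset of the upcoming one.
#'
#' @param history non-empty list of entries `list(record =
#'   activity_record, elapsed = ms)`, most recent first.
#' @param test_delta_t the gap (ms) preceding the upcoming digit.
#' @param trained_delta_t the trained gap (ms).
#' @param recovery a [recovery_model].
#' @return a `silencing_profile`.
#' @export
timing_adjusted_profile <- function(history, test_delta_t, trained_delta_t,
                                    recovery = recovery_model()) {
  if (length(history) == 0L) stop("history is empty")
  stopifnot(inherits(recovery, "recovery_model"))
  n_nodes <- length(history[[1]]$record$q)
  acc <- numeric(n_nodes)
  if (recovery$kernel == "step") {
    fast_gap <- if (is.null(recovery$fast_gap_ms)) trained_delta_t / 2
                else recovery$fast_gap_ms
    lookback <- if (test_delta_t < fast_gap) recovery$fast_lookback else 1L
    for (j in seq_len(min(lookback, length(history)))) {
      h <- history[[j]]
      if (h$elapsed >= recovery$slow_cutoff_ms) next
      acc <- acc + h$record$q / h$record$d1
    }
  } else {
    for (h in history) {
      if (h$elapsed >= recovery$slow_cutoff_ms) next
      acc <- acc + (h$record$q / h$record$d1) * exp(-h$elapsed / recovery$tau_ms)
    }
  }
  structure(pmin(1, acc), class = "silencing_profile")
}

#' Silencing profile from continuous activations (ANN variant)
#'
#' For sigmoid networks the silencing probability of a node equals its
#' activation value in `[0, 1]` for the previous object; for ReLU networks
#' activations above one silence with probability one (probability
#' `min(1, activation)`).
#'
#' @param prev_activations non-negative numeric vector.
#' @param rule `"sigmoid"` or `"relu"`.
#' @return a `silencing_profile`.
#' @export
ann_silencing_profile <- function(prev_activations, rule = c("sigmoid", "relu")) {
  rule <- match.arg(rule)
  a <- as.numeric(prev_activations)
  if (any(a < 0)) stop("activations must be non-negative")
  if (rule == "sigmoid") {
    if (any(a > 1)) stop("sigmoid rule requires activations in [0, 1]")
    p <- a
  } else {
    p <- pmin(1, a)
  }
  structure(p, class = "silencing_profile")
}
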