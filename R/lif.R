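#' Leaky integrate-and-fire configuration
#'
#' Discrete-time LIF with exponential voltage decay (time constant `tau`),
#' reset to zero on firing, and vanishing refractory period.  One time step
#' corresponds to one frame (`frame_dt` ms).
#'
#' @param tau membrane decay time constant in ms (default 20).
#' @param threshold firing threshold, dimensionless (default 1).
#' @param frame_dt frame spacing in ms (default 10).
#' @return a `lif_config` list.
#' @export
lif_config <- function(tau = 20, threshold = 1, frame_dt = 10) {
  if (tau <= 0) stop("tau must be positive")
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(tau = tau, threshold = threshold, frame_dt = frame_dt),
            class = "lif_config")
}

#' One LIF frame step
#'
#' `V' = V * exp(-frame_dt / tau) + I`; nodes reaching threshold fire and
#' reset to zero, with no refractory carry-over.
#'
#' @param V numeric vector of membrane voltages.
#' @param input_current numeric vector of accumulated input per node.
#' @param cfg a [lif_config].
#' @return list with `V` (post-step voltages) and `spikes` (logical).
#' @export
lif_step <- function(V, input_current, cfg = lif_config()) {
  if (!all(is.finite(V)) || !all(is.finite(input_current)))
    stop("non-finite voltage or input")
  V2 <- V * exp(-cfg$frame_dt / cfg$tau) + input_current
  spikes <- V2 >= cfg$threshold
  V2[spikes] <- 0
  list(V = V2, spikes = spikes)
}

#' Voltage decay across a silent gap
#'
#' Between consecutive digits no input arrives, so voltages decay by
#' `exp(-gap_ms / tau)`; at the trained 200 ms gap with `tau = 20` ms the
#' factor is `exp(-10)` and the voltage practically vanishes.
#'
#' @param V numeric vector of voltages.
#' @param gap_ms non-negative gap duration in ms.
#' @param tau decay constant in ms.
#' @return decayed voltages.
#' @export
decay_over_gap <- function(V, gap_ms, tau) {
  if (gap_ms < 0) stop("gap_ms must be non-negative")
  V * exp(-gap_ms / tau)
}
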