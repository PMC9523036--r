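#' Specification of a timed digit sequence
#'
#' A sequence is 10 consecutive different digits, the first fixed to 0,
#' presented as `d` Boolean frames each (`frame_spacing` ms apart) and
#' separated by a silent gap of `delta_t` ms between the last frame of one
#' digit and the first frame of the next.  The last `d1` frames of each
#' digit form the evaluation window for activity counts, output rates and
#' gradients.
#'
#' @param order integer vector of distinct labels; `order[1]` must be 0.
#' @param delta_t inter-digit time-lag in ms (trained value 200).
#' @param d frames per digit.
#' @param d1 evaluation window length in frames, `<= d`.
#' @param frame_spacing frame spacing in ms (default 10).
#' @return an object of class `sequence_spec`.
#' @export
#' @examples
#' spec <- sequence_spec(0:9, delta_t = 200, d = 30, d1 = 20)
sequence_spec <- function(order, delta_t = 200, d = 30, d1 = 20,
                          frame_spacing = 10) {
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("sequence labels must be distinct")
  if (order[1] != 0L) stop("the first digit of a sequence is fixed to 0")
  if (any(order < 0L) || any(order > 9L)) stop("labels must lie in [0, 9]")
  d <- as.integer(d); d1 <- as.integer(d1)
  if (d1 > d) stop("d1 must not exceed d")
  if (delta_t <= 0) stop("delta_t must be positive")
  structure(list(order = order, delta_t = delta_t, d = d, d1 = d1,
                 frame_spacing = frame_spacing),
            class = "sequence_spec")
}

#' Build the timed presentation of one sequence
#'
#' Encodes one example image per sequence position into frame trains and
#' records onset times.  Each digit's frame RNG stream is a sub-seed of
#' `seed` derived from its position, so trains are independently replayable.
#'
#' @param spec a [sequence_spec].
#' @param examples list of [gray_image]s whose labels match `spec$order`.
#' @param seed integer master seed for the frame encoding.
#' @return a `presentation_timeline`: list with `spec`, `test_delta_t`
#'   (initially `spec$delta_t`), and `digits`, a list of entries
#'   `(image, frames, onset)` with strictly increasing onsets.
#' @export
build_timeline <- function(spec, examples, seed) {
  stopifnot(inherits(spec, "sequence_spec"))
  labs <- vapply(examples, function(i) i$label, integer(1))
  if (!identical(labs, spec$order))
    stop("example labels do not match the sequence order")
  span <- spec$d * spec$frame_spacing
  digits <- vector("list", length(examples))
  onset <- 0
  for (k in seq_along(examples)) {
    frames <- encode_frames(normalize_to_prob(examples[[k]]), spec$d,
                            seed = derive_seed(seed, k),
                            frame_spacing = spec$frame_spacing)
    digits[[k]] <- list(image = examples[[k]], frames = frames, onset = onset)
    onset <- onset + span + spec$delta_t
  }
  structure(list(spec = spec, test_delta_t = spec$delta_t, digits = digits),
            class = "presentation_timeline")
}

#' Apply a fast/slow/wrong imperfection to a timeline
#'
#' The three test imperfections relative to the trained sequence:
#' `fast` shortens every inter-digit gap to `delta_t_s` (default
#' `delta_t / 10`), `slow` lengthens it to `delta_t_l` (default
#' `10 * delta_t`), and `wrong` exchanges the digits at two positions
#' (images and labels; timing unchanged).  The first (zero) digit is
#' excluded from swaps.
#'
#' @param timeline a `presentation_timeline`.
#' @param kind one of `"fast"`, `"slow"`, `"wrong"`.
#' @param delta_t_s,delta_t_l gap overrides for fast/slow.
#' @param swap integer pair of positions to exchange (`wrong` only), both
#'   `>= 2`.
#' @return a modified `presentation_timeline`.
#' @export
apply_imperfection <- function(timeline, kind = c("fast", "slow", "wrong"),
                               delta_t_s = NULL, delta_t_l = NULL,
                               swap = NULL) {
  stopifnot(inherits(timeline, "presentation_timeline"))
  kind <- match.arg(kind)
  dt <- timeline$spec$delta_t
  if (kind == "fast") {
    timeline$test_delta_t <- if (is.null(delta_t_s)) dt / 10 else delta_t_s
    if (timeline$test_delta_t >= dt) stop("fast gap must be shorter than delta_t")
  } else if (kind == "slow") {
    timeline$test_delta_t <- if (is.null(delta_t_l)) 10 * dt else delta_t_l
    if (timeline$test_delta_t <= dt) stop("slow gap must exceed delta_t")
  } else {
    if (is.null(swap) || length(swap) != 2L) stop("wrong needs swap = c(i, j)")
    swap <- as.integer(swap)
    if (any(swap < 2L)) stop("the first digit is excluded from swaps")
    if (any(swap > length(timeline$digits))) stop("swap position out of range")
    if (swap[1] == swap[2]) stop("swap positions must differ")
    i <- swap[1]; j <- swap[2]
    oi <- timeline$digits[[i]]$onset; oj <- timeline$digits[[j]]$onset
    tmp <- timeline$digits[[i]]
    timeline$digits[[i]] <- timeline$digits[[j]]
    timeline$digits[[j]] <- tmp
    timeline$digits[[i]]$onset <- oi
    timeline$digits[[j]]$onset <- oj
  }
  # re-time onsets at the test gap (total frame count is unchanged)
  span <- timeline$spec$d * timeline$spec$frame_spacing
  onset <- 0
  for (k in seq_along(timeline$digits)) {
    timeline$digits[[k]]$onset <- onset
    onset <- onset + span + timeline$test_delta_t
  }
  timeline
}

#' Labels actually presented by a timeline, in order
#' @param timeline a `presentation_timeline`.
#' @return integer vector of labels.
#' @export
timeline_order <- function(timeline) {
  vapply(timeline$digits, function(d) d$image$label, integer(1))
}

#' Enumerate all wrong-order variants of a sequence
#'
#' All sequences obtained by swapping one unordered pair of positions,
#' excluding the first (zero) digit: `choose(n - 1, 2)` variants, i.e. 36
#' for a 10-digit sequence.
#'
#' @param spec a [sequence_spec].
#' @return list of `sequence_spec`s, each differing from `spec` at exactly
#'   two positions; attribute `swaps` holds the position pairs.
#' @export
enumerate_wrong_swaps <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  n <- length(spec$order)
  pairs <- utils::combn(2:n, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c) {
    o <- spec$order
    o[pairs[, c]] <- o[rev(pairs[, c])]
    s <- spec
    s$order <- o
    s
  })
  attr(out, "swaps") <- pairs
  out
}
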