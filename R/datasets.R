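# Synthetic dataset plumbing: turn the glyph generator into timed training
# and test sequences.  One master seed fans out to per-sequence, per-digit
# sub-seeds; in writer mode one fixed frame seed is shared by all sequences
# so that similar images generate very similar frames.

#' Example images for one sequence
#'
#' @param order integer label order.
#' @param seed integer seed.
#' @param writer `NULL` (generic mode) or a writer id (same-writer mode).
#' @param pool optional list of [gray_image]s (e.g. from [read_idx]) to
#'   sample examples from by label instead of the synthetic generator.
#' @return list of [gray_image]s.
#' @export
synthetic_sequence_examples <- function(order, seed, writer = NULL,
                                        pool = NULL) {
  if (is.null(pool))
    return(lapply(seq_along(order), function(k)
      synthetic_digit(order[k], seed = derive_seed(seed, k, 5L),
                      writer = writer)))
  labels <- vapply(pool, function(i) i$label, integer(1))
  lapply(seq_along(order), function(k) {
    cand <- which(labels == order[k])
    if (length(cand) == 0L) stop("image pool has no example of label ",
                                 order[k])
    pick <- with_seed(derive_seed(seed, k, 5L),
                      cand[sample.int(length(cand), 1L)])
    pool[[pick]]
  })
}

#' Generate a set of timed presentation timelines
#'
#' @param spec a [sequence_spec].
#' @param n number of sequences.
#' @param seed master seed.
#' @param writer `NULL` or writer id.
#' @param frame_seed `NULL` to derive an independent frame stream per
#'   sequence (the default; trained and test sequences then use different
#'   digit seeds), or an integer shared by all sequences (writer mode).
#' @param pool optional image pool, see [synthetic_sequence_examples].
#' @return list of `presentation_timeline`s.
#' @export
make_timeline_set <- function(spec, n, seed, writer = NULL,
                              frame_seed = NULL, pool = NULL) {
  lapply(seq_len(n), function(s) {
    ex <- synthetic_sequence_examples(spec$order, derive_seed(seed, s, 1L),
                                      writer = writer, pool = pool)
    fs <- if (is.null(frame_seed)) derive_seed(seed, s, 2L) else frame_seed
    build_timeline(spec, ex, seed = fs)
  })
}

#' Random sequence order with fixed leading zero
#'
#' @param seed integer seed.
#' @param n_labels sequence length (default 10).
#' @return integer vector: 0 followed by a permutation of the remaining
#'   labels.
#' @export
random_order <- function(seed, n_labels = 10L) {
  c(0L, with_seed(seed, sample(seq_len(n_labels - 1L))))
}
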