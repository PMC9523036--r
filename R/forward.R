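#' Forward pass of one digit through the spiking network
#'
#' Runs the `d` frames of one digit through the masked sub-network: silenced
#' input nodes never feed spikes forward, silenced hidden nodes receive no
#' voltage update and never spike (so every weight touching a silenced node
#' contributes nothing), and output nodes are never silenced.  Voltages
#' persist across frames within the digit; between digits they are decayed
#' with [decay_over_gap] by the caller.
#'
#' @param model an `idnet_model`.
#' @param frames a `frame_train` (logical `d x n_in`).
#' @param mask list with logical vectors `input` and `hidden`
#'   (`TRUE` = active).
#' @param state optional list `V_hidden`, `V_output` of carried-over
#'   voltages (default zero).
#' @return a `spike_record`: list with logical matrices `input`, `hidden`,
#'   `output` (frames x nodes), the final voltages, and the `mask`.
#' @export
forward_digit <- function(model, frames, mask, state = NULL) {
  cfg <- model$lif
  d <- nrow(frames)
  n_in <- nrow(model$W1); H <- ncol(model$W1); O <- ncol(model$W2)
  if (ncol(frames) != n_in) stop("frame width does not match the input layer")
  if (length(mask$input) != n_in || length(mask$hidden) != H)
    stop("mask shapes do not match the model layers")

  x <- matrix(as.numeric(frames), d, n_in)
  x[, !mask$input] <- 0

  decay <- exp(-cfg$frame_dt / cfg$tau)
  thr <- cfg$threshold
  Vh <- if (is.null(state)) numeric(H) else state$V_hidden
  Vo <- if (is.null(state)) numeric(O) else state$V_output

  Ih <- x %*% model$W1 + matrix(model$b1, d, H, byrow = TRUE)
  Sh <- matrix(FALSE, d, H)
  act <- mask$hidden
  for (k in seq_len(d)) {
    Vh[act] <- Vh[act] * decay + Ih[k, act]
    fired <- act & Vh >= thr
    Sh[k, ] <- fired
    Vh[fired] <- 0
  }

  Io <- Sh %*% model$W2 + matrix(model$b2, d, O, byrow = TRUE)
  So <- matrix(FALSE, d, O)
  for (k in seq_len(d)) {
    Vo <- Vo * decay + Io[k, ]
    fired <- Vo >= thr
    So[k, ] <- fired
    Vo[fired] <- 0
  }

  structure(list(input = x > 0, hidden = Sh, output = So,
                 V_hidden = Vh, V_output = Vo, mask = mask),
            class = "spike_record")
}

#' Output label of a presented digit
#'
#' The label whose output node fired most during the last `d1` frames;
#' ties go to the lowest-index node.
#'
#' @param record a `spike_record` (or a list with an `output` spike
#'   matrix).
#' @param d1 evaluation window length.
#' @return integer label in `[0, n_out - 1]`.
#' @export
output_label <- function(record, d1) {
  out <- record$output
  if (nrow(out) < d1) stop("record covers fewer than d1 frames")
  counts <- colSums(out[seq.int(nrow(out) - d1 + 1L, nrow(out)), , drop = FALSE])
  which.max(counts) - 1L
}

#' Present a full timed sequence to a trained network
#'
#' Steps through the digits of a timeline, drawing a silencing mask for
#' each digit from the timing-adjusted activity profile of the preceding
#' digit(s) (the first digit uses a donor profile from the model's
#' boundary pool), running the masked forward pass, and decaying voltages
#' over the inter-digit gaps.  This is the test-time counterpart of
#' [train_idnet].
#'
#' @param model a trained `idnet_model` (or `ann_model`).
#' @param timeline a `presentation_timeline`.
#' @param seed integer seed for the silencing-mask draws.
#' @param keep_records keep the per-digit spike records (needed for
#'   [delta_min]); default `TRUE`.
#' @param ... passed to methods.
#' @return list with `labels` (predicted label per position), `records`
#'   (per-digit spike records or activations) and `masks`.
#' @export
present_sequence <- function(model, timeline, seed, keep_records = TRUE, ...) {
  UseMethod("present_sequence")
}

# pick one donor digit from the pool and draw both layer masks from it
.boundary_masks <- function(pool, seed) {
  pick <- with_seed(derive_seed(seed, 1L), sample.int(length(pool), 1L))
  donor <- pool[[pick]]
  list(input = draw_mask(donor$input, derive_seed(seed, 2L)),
       hidden = draw_mask(donor$hidden, derive_seed(seed, 3L)))
}

# shared digit-by-digit mask schedule for the spiking net; fn(k, mask,
# gap_ms) runs the digit and must return the per-layer activity records
.run_spiking_sequence <- function(model, timeline, seed, step_fn) {
  spec <- timeline$spec
  span <- spec$d * spec$frame_spacing
  n <- length(timeline$digits)
  history_in <- list(); history_hid <- list()
  for (k in seq_len(n)) {
    onset <- timeline$digits[[k]]$onset
    if (k == 1L) {
      # the boundary mask emulates silencing by fictitious predecessors one
      # test gap away; past the slow cutoff that silencing has recovered
      gap <- timeline$test_delta_t
      mask <- if (gap >= model$recovery$slow_cutoff_ms)
        list(input = structure(rep(TRUE, nrow(model$W1)),
                               class = "silencing_mask"),
             hidden = structure(rep(TRUE, ncol(model$W1)),
                                class = "silencing_mask"))
      else .boundary_masks(model$boundary_pool, derive_seed(seed, k))
    } else {
      gap <- onset - (timeline$digits[[k - 1L]]$onset + span)
      upd <- function(hist) lapply(seq_along(hist), function(j) {
        h <- hist[[j]]; h$elapsed <- onset - h$end_time; h
      })
      hin <- upd(history_in); hhid <- upd(history_hid)
      trained_dt <- if (is.null(model$trained_delta_t)) spec$delta_t
                    else model$trained_delta_t
      mask <- list(
        input = draw_mask(
          timing_adjusted_profile(hin, gap, trained_dt, model$recovery),
          derive_seed(seed, k, 11L)),
        hidden = draw_mask(
          timing_adjusted_profile(hhid, gap, trained_dt, model$recovery),
          derive_seed(seed, k, 12L)))
    }
    recs <- step_fn(k, mask, gap)
    end_time <- onset + span
    history_in <- c(list(list(record = recs$input, end_time = end_time)),
                    history_in)
    history_hid <- c(list(list(record = recs$hidden, end_time = end_time)),
                     history_hid)
  }
  invisible(NULL)
}

#' @rdname present_sequence
#' @export
present_sequence.idnet_model <- function(model, timeline, seed,
                                         keep_records = TRUE, ...) {
  spec <- timeline$spec
  n <- length(timeline$digits)
  labels <- integer(n)
  records <- if (keep_records) vector("list", n)
  masks <- vector("list", n)
  state <- NULL
  step_fn <- function(k, mask, gap) {
    if (!is.null(state))
      state <<- list(V_hidden = decay_over_gap(state$V_hidden, gap, model$lif$tau),
                     V_output = decay_over_gap(state$V_output, gap, model$lif$tau))
    rec <- forward_digit(model, timeline$digits[[k]]$frames, mask, state)
    state <<- list(V_hidden = rec$V_hidden, V_output = rec$V_output)
    labels[k] <<- output_label(rec, spec$d1)
    if (keep_records) records[[k]] <<- rec
    masks[[k]] <<- mask
    list(input = activity_counts(rec$input, spec$d1),
         hidden = activity_counts(rec$hidden, spec$d1))
  }
  .run_spiking_sequence(model, timeline, seed, step_fn)
  list(labels = labels, records = records, masks = masks)
}
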