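#' Histogram of minimal per-digit success rates
#'
#' @param values numeric vector in `[0, 1]`, one minimal SR per sample (or
#'   per imperfect variant).
#' @param kind `"blue"` (trained sequences) or `"orange"` (imperfect).
#' @return an `sr_histogram`.
#' @export
sr_histogram <- function(values, kind = c("blue", "orange")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(values < 0 | values > 1)) stop("SR values must lie in [0, 1]")
  structure(list(values = values, kind = kind), class = "sr_histogram")
}

#' Per-digit success rates over a test set
#'
#' Presents each test timeline and scores every sequence position under one
#' of two knowledge scenarios.  `known_order`: position `k` succeeds when
#' the predicted label equals the expected digit at `k` -- the digit the
#' test sequence actually presents there, even for a wrong sequence (a
#' swapped digit is processed under the silencing mask of the wrong
#' predecessor, which is what degrades its identification).
#' `unknown_order`: the SR of position `k` is the maximal prediction
#' frequency among the 10 labels, regardless of the presented digit.
#'
#' @param model a trained model (`idnet_model` or `ann_model`).
#' @param timelines non-empty list of test `presentation_timeline`s.
#' @param scenario `"known_order"` or `"unknown_order"`.
#' @param expected_order optional explicit label order to score against;
#'   by default each timeline is scored against the digits it presents.
#' @param seed base seed for the test-time mask draws.
#' @return numeric vector of per-position SRs.
#' @export
per_digit_sr <- function(model, timelines,
                         scenario = c("known_order", "unknown_order"),
                         expected_order = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(timelines) == 0L) stop("empty test set")
  n_pos <- length(timelines[[1]]$digits)
  pred <- t(vapply(seq_along(timelines), function(t) {
    present_sequence(model, timelines[[t]], seed = derive_seed(seed, t),
                     keep_records = FALSE)$labels
  }, integer(n_pos)))
  if (scenario == "known_order") {
    expected <- if (is.null(expected_order))
      t(vapply(timelines, timeline_order, integer(n_pos)))
    else matrix(expected_order, length(timelines), n_pos, byrow = TRUE)
    vapply(seq_len(n_pos),
           function(k) mean(pred[, k] == expected[, k]), numeric(1))
  } else {
    vapply(seq_len(n_pos), function(k)
      max(tabulate(pred[, k] + 1L, nbins = 10L)) / nrow(pred), numeric(1))
  }
}

#' Minimal per-digit success rate
#'
#' @param srs non-empty numeric vector of per-digit SRs.
#' @return the minimum.
#' @export
min_sr <- function(srs) {
  if (length(srs) == 0L) stop("empty SR vector")
  min(srs)
}

#' Decision threshold from the blue histogram
#'
#' The maximal value such that the whole blue histogram lies above it
#' (true positive = 1): the minimum of the blue values, with the decision
#' rule "value >= threshold is classified as trained".
#'
#' @param blue an `sr_histogram` or numeric vector of blue values.
#' @return scalar threshold.
#' @export
derive_threshold <- function(blue) {
  v <- if (inherits(blue, "sr_histogram")) blue$values else as.numeric(blue)
  if (length(v) == 0L) stop("empty blue histogram")
  min(v)
}

#' Confusion report at a threshold
#'
#' Specificity analysis of the blue/orange separation: the true negative
#' rate is the orange fraction below threshold, the true positive rate the
#' blue fraction at or above it.
#'
#' @param blue,orange `sr_histogram`s or numeric vectors.
#' @param threshold decision threshold (default [derive_threshold] of
#'   `blue`).
#' @return a `decision_report` list with `threshold`, `true_positive`,
#'   `false_negative`, `false_positive`, `true_negative`.
#' @export
confusion_report <- function(blue, orange, threshold = NULL) {
  b <- if (inherits(blue, "sr_histogram")) blue$values else as.numeric(blue)
  o <- if (inherits(orange, "sr_histogram")) orange$values else as.numeric(orange)
  if (length(b) == 0L || length(o) == 0L) stop("histograms must be non-empty")
  if (is.null(threshold)) threshold <- derive_threshold(b)
  tp <- mean(b >= threshold)
  tn <- mean(o < threshold)
  structure(list(threshold = threshold, true_positive = tp,
                 false_negative = 1 - tp, false_positive = 1 - tn,
                 true_negative = tn),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("<decision_report> threshold", format(x$threshold, digits = 4),
      "\n  TP", format(x$true_positive, digits = 4),
      " FN", format(x$false_negative, digits = 4),
      " FP", format(x$false_positive, digits = 4),
      " TN (specificity)", format(x$true_negative, digits = 4), "\n")
  invisible(x)
}

#' Writer-dependent gap score
#'
#' For each presented digit, the gap between the highest and second highest
#' firing output nodes over the last `d1` frames, normalised by `d1` to
#' `[0, 1]`; the minimum over the sequence's digits is the authentication
#' score.
#'
#' @param records list of per-digit `spike_record`s (as returned in
#'   `present_sequence()$records`).
#' @param d1 evaluation window length.
#' @return a `gap_score` list with `delta` (per digit) and `delta_min`.
#' @export
delta_min <- function(records, d1) {
  delta <- vapply(records, function(rec) {
    out <- rec$output
    counts <- colSums(out[seq.int(nrow(out) - d1 + 1L, nrow(out)), ,
                          drop = FALSE])
    if (length(counts) < 2L) stop("need at least two output units")
    top2 <- sort(counts, decreasing = TRUE)[1:2]
    (top2[1] - top2[2]) / d1
  }, numeric(1))
  structure(list(delta = delta, delta_min = min(delta)), class = "gap_score")
}

#' Build blue and orange histograms for an experiment
#'
#' Runs the full separation experiment: for each of `n_samples` independent
#' samples a fresh network is trained on its own random digit order, the
#' trained order contributes one blue point (the minimal per-digit SR over
#' the test set), the fast and slow imperfections contribute one orange
#' point each, and the wrong imperfection contributes one orange point per
#' two-digit swap variant (`choose(9, 2) = 36` per 10-digit sample, so 40
#' samples give 1440 points and 20 give 720).
#'
#' `sample_fn` and `min_sr_fn` expose the bookkeeping for testing and for
#' alternative model families: `sample_fn(i)` must return a trained model
#' for sample `i` and `min_sr_fn(model, i, kind, variant)` the minimal SR
#' for one condition (`variant` is a `sequence_spec` for `kind = "wrong"`,
#' otherwise `NULL`).
#'
#' @param experiment an [experiment_spec].
#' @param sample_fn,min_sr_fn optional overrides of the default
#'   train/evaluate pipeline.
#' @return list with `blue` (an `sr_histogram`), `orange` (named list of
#'   `sr_histogram`s per imperfection), `threshold`, and `reports` (a
#'   `decision_report` per imperfection).
#' @export
build_histograms <- function(experiment, sample_fn = NULL, min_sr_fn = NULL) {
  ex <- experiment
  if (is.null(sample_fn)) sample_fn <- function(i) .train_sample(ex, i)
  if (is.null(min_sr_fn))
    min_sr_fn <- function(model, i, kind, variant)
      .sample_min_sr(ex, model, i, kind, variant)

  blue <- numeric(ex$n_samples)
  orange <- stats::setNames(vector("list", length(ex$imperfections)),
                            ex$imperfections)
  for (i in seq_len(ex$n_samples)) {
    model <- sample_fn(i)
    blue[i] <- min_sr_fn(model, i, "trained", NULL)
    for (kind in ex$imperfections) {
      if (kind == "wrong") {
        base <- sequence_spec(if (is.null(model$trained_order))
                                c(0L, seq_len(9L)) else model$trained_order,
                              ex$seq$delta_t, ex$seq$d, ex$seq$d1,
                              ex$seq$frame_spacing)
        pts <- vapply(enumerate_wrong_swaps(base), function(v)
          min_sr_fn(model, i, "wrong", v), numeric(1))
      } else {
        pts <- min_sr_fn(model, i, kind, NULL)
      }
      orange[[kind]] <- c(orange[[kind]], pts)
    }
  }
  blue_h <- sr_histogram(blue, "blue")
  thr <- derive_threshold(blue_h)
  orange_h <- lapply(orange, sr_histogram, kind = "orange")
  reports <- lapply(orange_h, function(o) confusion_report(blue_h, o, thr))
  list(blue = blue_h, orange = orange_h, threshold = thr, reports = reports)
}

# resolve and memoise the experiment's optional IDX image pool
.experiment_pool <- function(ex) {
  if (is.null(ex$idx_images)) return(NULL)
  if (is.null(.pool_cache$pool) ||
      !identical(.pool_cache$key, ex$idx_images)) {
    .pool_cache$pool <- read_idx(ex$idx_images, ex$idx_labels)
    .pool_cache$key <- ex$idx_images
  }
  .pool_cache$pool
}
.pool_cache <- new.env(parent = emptyenv())

# default sample trainer: fresh random order, synthetic training set; the
# spiking net additionally gets the low-SR-digit rescue pass on a
# validation fold of the training distribution
.train_sample <- function(ex, i) {
  order <- random_order(derive_seed(ex$seed, i, 3L))
  spec <- sequence_spec(order, ex$seq$delta_t, ex$seq$d, ex$seq$d1,
                        ex$seq$frame_spacing)
  train_set <- make_timeline_set(spec, ex$n_train,
                                 derive_seed(ex$seed, i, 4L),
                                 pool = .experiment_pool(ex))
  cfg <- ex$training
  cfg$seed <- derive_seed(ex$seed, i, 6L)
  if (identical(ex$family, "ann")) {
    train_ann_sequence(train_set, cfg, hidden = ex$hidden,
                       recovery = ex$recovery)
  } else {
    model <- train_idnet(train_set, cfg, hidden = ex$hidden, lif = ex$lif,
                         recovery = ex$recovery)
    val <- make_timeline_set(spec, max(10L, ex$n_test %/% 2L),
                             derive_seed(ex$seed, i, 9L))
    rescue_low_sr_digits(model, train_set, cfg, val,
                         seed = derive_seed(ex$seed, i, 10L))
  }
}

# default condition evaluator: minimal per-digit SR under one condition
.sample_min_sr <- function(ex, model, i, kind, variant) {
  test_spec <- if (kind == "wrong") variant else
    sequence_spec(model$trained_order, ex$seq$delta_t, ex$seq$d, ex$seq$d1,
                  ex$seq$frame_spacing)
  n_test <- if (kind == "wrong") ex$n_wrong_test else ex$n_test
  tls <- make_timeline_set(test_spec, n_test,
                           derive_seed(ex$seed, i, 7L, match(kind,
                             c("trained", "fast", "slow", "wrong"))),
                           pool = .experiment_pool(ex))
  if (kind %in% c("fast", "slow"))
    tls <- lapply(tls, apply_imperfection, kind = kind)
  srs <- per_digit_sr(model, tls, scenario = ex$scenario,
                      seed = derive_seed(ex$seed, i, 8L))
  min_sr(srs)
}

#' Writer-dependent authentication experiment
#'
#' Trains a network on one writer's synthetic sequences (a single digit
#' order, one shared frame seed so that similar images generate very
#' similar frames) and scores test sequences by their minimal normalised
#' output gap [delta_min].  Blue: fresh same-writer sequences.  Orange:
#' the fast, slow and wrong imperfections of the writer's sequence, and
#' the same sequence in other writers' handwriting (`different`).
#'
#' @param experiment an [experiment_spec] (`mode = "writer"` fields used:
#'   `writer`, `foreign_writers`, `n_test`, `n_wrong_test`).
#' @return list with `blue`, `orange` (per condition) `sr_histogram`-like
#'   gap histograms, `threshold`, `reports`, and the trained `model`.
#' @export
writer_experiment <- function(experiment) {
  ex <- experiment
  order <- random_order(derive_seed(ex$seed, 1L))
  spec <- sequence_spec(order, ex$seq$delta_t, ex$seq$d, ex$seq$d1,
                        ex$seq$frame_spacing)
  frame_seed <- derive_seed(ex$seed, 424242L)
  train_set <- make_timeline_set(spec, ex$n_train, derive_seed(ex$seed, 2L),
                                 writer = ex$writer, frame_seed = frame_seed)
  cfg <- ex$training
  cfg$seed <- derive_seed(ex$seed, 3L)
  model <- if (identical(ex$family, "ann"))
    train_ann_sequence(train_set, cfg, hidden = ex$hidden,
                       recovery = ex$recovery)
  else
    train_idnet(train_set, cfg, hidden = ex$hidden, lif = ex$lif,
                recovery = ex$recovery)

  score_one <- function(tl, seed) {
    pres <- present_sequence(model, tl, seed = seed, keep_records = TRUE)
    delta_min(pres$records, spec$d1)$delta_min
  }
  score_set <- function(tls, tag) vapply(seq_along(tls), function(t)
    score_one(tls[[t]], derive_seed(ex$seed, tag, t)), numeric(1))

  new_writer_set <- function(n, tag)
    make_timeline_set(spec, n, derive_seed(ex$seed, tag), writer = ex$writer,
                      frame_seed = frame_seed)

  blue <- score_set(new_writer_set(ex$n_test, 10L), 20L)
  orange <- list(
    fast = score_set(lapply(new_writer_set(ex$n_test, 11L),
                            apply_imperfection, kind = "fast"), 21L),
    slow = score_set(lapply(new_writer_set(ex$n_test, 12L),
                            apply_imperfection, kind = "slow"), 22L),
    wrong = {
      variants <- enumerate_wrong_swaps(spec)
      swaps <- attr(variants, "swaps")
      base <- new_writer_set(ex$n_wrong_test, 13L)
      unlist(lapply(seq_len(ncol(swaps)), function(v)
        score_set(lapply(base, apply_imperfection, kind = "wrong",
                         swap = swaps[, v]), 30L + v)))
    },
    different = unlist(lapply(ex$foreign_writers, function(w)
      score_set(make_timeline_set(spec, max(1L, ex$n_test %/%
                                    length(ex$foreign_writers)),
                                  derive_seed(ex$seed, 14L, w), writer = w,
                                  frame_seed = frame_seed), 40L + w))))
  thr <- min(blue)
  reports <- lapply(orange, function(o) confusion_report(blue, o, thr))
  list(blue = blue, orange = orange, threshold = thr, reports = reports,
       model = model)
}

#' Probability of identifying an entire sequence digit-by-digit
#'
#' Without silencing, digits are classified independently, so the chance of
#' getting all `n` right is `sr^n` -- e.g. `0.9^10 ~ 0.35`, which is why a
#' plain feedforward classifier cannot serve as a sequence identifier.
#'
#' @param sr per-object success rate.
#' @param n sequence length.
#' @return `sr^n`.
#' @export
joint_sequence_probability <- function(sr, n) {
  if (sr < 0 || sr > 1) stop("sr must lie in [0, 1]")
  sr^n
}
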