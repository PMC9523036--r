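# a mock model whose present_sequence returns pre-seeded predictions lets
# the SR bookkeeping be checked against hand counts
local({
  mock_present <- function(model, timeline, seed, keep_records = TRUE, ...) {
    i <- model$cursor$i
    model$cursor$i <- i + 1L
    list(labels = model$predictions[[i]], records = NULL, masks = NULL)
  }
  .S3method("present_sequence", "mock_model", mock_present)
})

mock_model <- function(predictions, order = c(0L, 1L, 2L)) {
  structure(list(predictions = predictions,
                 cursor = new.env(), trained_order = order),
            class = "mock_model")
}

mock_timelines <- function(n) rep(list(structure(
  list(digits = vector("list", 3L)), class = "presentation_timeline")), n)

test_that("per-digit SR counts match hand-computed frequencies", {
  # 10 tests: position 2 predicted as 2 (the trained label) 3 times and as
  # 1 six times, position 1 and 3 always correct
  preds <- lapply(1:10, function(t)
    c(0L, if (t <= 3) 2L else if (t <= 9) 1L else 0L, 2L))
  m <- mock_model(preds, order = c(0L, 2L, 2L))
  m$trained_order <- c(0L, 2L, 2L) # scoring order, positions independent
  m$cursor$i <- 1L
  known <- per_digit_sr(m, mock_timelines(10), "known_order",
                        expected_order = c(0L, 2L, 2L))
  expect_equal(known, c(1, 0.3, 1))
  m$cursor$i <- 1L
  unknown <- per_digit_sr(m, mock_timelines(10), "unknown_order")
  expect_equal(unknown, c(1, 0.6, 1))
  expect_true(all(unknown >= known)) # max dominates any specific entry
  expect_error(per_digit_sr(m, list(), "known_order"), "empty")
})

test_that("scenario (b) dominates scenario (a) on arbitrary predictions", {
  for (case in 1:5) {
    set.seed(case)
    preds <- lapply(1:20, function(t) sample(0:9, 3, replace = TRUE))
    m <- mock_model(preds, order = c(0L, 1L, 2L))
    m$cursor$i <- 1L
    known <- per_digit_sr(m, mock_timelines(20), "known_order",
                          expected_order = c(0L, 1L, 2L))
    m$cursor$i <- 1L
    unknown <- per_digit_sr(m, mock_timelines(20), "unknown_order")
    expect_true(all(unknown >= known - 1e-12))
  }
})

test_that("min SR and the blue-histogram threshold follow their definitions", {
  expect_equal(min_sr(c(0.9, 0.8, 0.95)), 0.8)
  expect_equal(min_sr(0.7), 0.7)
  expect_error(min_sr(numeric(0)), "empty")

  blue <- sr_histogram(c(0.85, 0.88, 0.92), "blue")
  thr <- derive_threshold(blue)
  expect_equal(thr, 0.85)
  expect_equal(derive_threshold(sr_histogram(0.8, "blue")), 0.8)
  # true positive = 1 at the derived threshold, and no larger threshold
  # keeps it at 1 (exhaustive over a grid above the minimum)
  expect_equal(confusion_report(blue, blue, thr)$true_positive, 1)
  for (t2 in seq(thr + 1e-6, 1, length.out = 50))
    expect_lt(mean(blue$values >= t2), 1)
})

test_that("confusion rates count orange below and blue above threshold", {
  blue <- sr_histogram(c(0.85, 0.88, 0.92), "blue")
  orange <- sr_histogram(c(0.5, 0.86, 0.95), "orange")
  rep1 <- confusion_report(blue, orange, 0.85)
  expect_equal(rep1$true_negative, 1 / 3)
  expect_equal(rep1$false_positive, 2 / 3)
  expect_equal(rep1$true_positive, 1)
  expect_equal(rep1$false_negative, 0)
  expect_equal(rep1$true_positive + rep1$false_negative, 1)
  expect_equal(rep1$false_positive + rep1$true_negative, 1)

  low <- sr_histogram(c(0.1, 0.2), "orange")
  expect_equal(confusion_report(blue, low, 0.85)$true_negative, 1)
  # blue scored as orange against its own threshold: nothing below it
  expect_equal(confusion_report(blue, blue, 0.85)$true_negative, 0)
})

test_that("the normalised output gap and its minimum follow the counts", {
  mk <- function(counts, d1 = 20L) {
    out <- matrix(FALSE, d1, length(counts))
    for (i in seq_along(counts)) if (counts[i] > 0)
      out[seq_len(counts[i]), i] <- TRUE
    structure(list(output = out), class = "spike_record")
  }
  full <- delta_min(list(mk(c(20, 0, 0))), 20)
  expect_equal(full$delta, 1)
  gap <- delta_min(list(mk(c(15, 10, 0))), 20)
  expect_equal(gap$delta, 0.25)
  two <- delta_min(list(mk(c(20, 0, 0)), mk(c(15, 10, 0))), 20)
  expect_equal(two$delta_min, 0.25)
  expect_error(delta_min(list(mk(5L)), 20), "two output")
  # bounds: 0 <= delta <= 1 for random count patterns
  for (s in 1:20) {
    set.seed(s)
    counts <- sample(0:20, 4, replace = TRUE)
    d <- delta_min(list(mk(counts)), 20)$delta
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("histogram bookkeeping yields one wrong point per sample and swap", {
  stub_sample <- function(i) NULL
  stub_sr <- function(model, i, kind, variant) 0.9
  mk_ex <- function(n) experiment_spec(n_samples = n)
  h40 <- build_histograms(mk_ex(40), stub_sample, stub_sr)
  expect_length(h40$blue$values, 40L)
  expect_length(h40$orange$wrong$values, 40L * 36L) # 1440 points
  expect_length(h40$orange$fast$values, 40L)
  h20 <- build_histograms(mk_ex(20), stub_sample, stub_sr)
  expect_length(h20$orange$wrong$values, 20L * 36L) # 720 points
  h3 <- build_histograms(experiment_spec(n_samples = 3,
                                         imperfections = "fast"),
                         stub_sample, stub_sr)
  expect_length(h3$orange$fast$values, 3L)
  expect_null(h3$orange$wrong)
})

test_that("a plain classifier's whole-sequence success decays exponentially", {
  expect_equal(joint_sequence_probability(0.9, 10), 0.9^10, tolerance = 1e-15)
  expect_equal(joint_sequence_probability(1, 10), 1)
  expect_error(joint_sequence_probability(1.1, 10), "\\[0, 1\\]")
})
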