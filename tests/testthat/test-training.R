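test_that("rate outputs are firing fractions over the last d1 frames", {
  rec <- onehot_record(d = 8L, d1 = 4L, label = 2L)
  ro <- rate_outputs(rec, d1 = 4L, label = 2L)
  expect_equal(ro$a, c(0, 0, 1, 0))
  expect_equal(ro$y, c(0, 0, 1, 0))
  # 10 fires in a d1 = 20 window gives rate 0.5
  out <- matrix(FALSE, 20, 2)
  out[1:10, 1] <- TRUE
  rec2 <- structure(list(output = out), class = "spike_record")
  expect_equal(rate_outputs(rec2, 20, 0L)$a, c(0.5, 0))
  expect_error(rate_outputs(rec, 4L, 7L), "invalid label")
})

test_that("the cost is cross-entropy plus the (alpha/2eta) weight penalty", {
  # perfect rates and zero weights: zero cost
  perfect <- structure(list(a = c(1, 0, 0), y = c(1, 0, 0)),
                       class = "rate_outputs")
  expect_equal(idnet_cost(list(perfect), weights = 0, alpha = 1, eta = 1), 0,
               tolerance = 1e-9)
  # M = 1, y = (1,0,...), a = (0.5, tiny...): ln 2 plus small terms
  half <- structure(list(a = c(0.5, 1e-9, 1e-9), y = c(1, 0, 0)),
                    class = "rate_outputs")
  expect_equal(idnet_cost(list(half)), log(2), tolerance = 1e-6)
  # regularisation alone: (alpha / 2 eta) * sum W^2 at the reference pair
  reg <- idnet_cost(list(perfect), weights = c(1, -2),
                    alpha = 3.3e-5, eta = 2.7e-4)
  # the clipped logs leave an O(1e-12) cross-entropy residue
  expect_equal(reg, 3.3e-5 / (2 * 2.7e-4) * 5, tolerance = 1e-9)
  # rates at the boundary are clipped, not infinite
  bad <- structure(list(a = c(0, 1, 0.5), y = c(1, 0, 0)),
                   class = "rate_outputs")
  expect_true(is.finite(idnet_cost(list(bad))))
})

test_that("gradient terms with silenced nodes vanish", {
  model <- tiny_model(seed = 1)
  frames <- random_frames(seed = 2, p = 0.7)
  mask <- list(input = rep(TRUE, 12), hidden = rep(FALSE, 5))
  rec <- forward_digit(model, frames, mask)
  cfg <- training_config(eta = 0.1, alpha = 0, epochs = 1)
  upd <- backprop_digit(model, rec, mask, label = 1L, cfg, d1 = 4L)
  # all hidden silenced: only the output biases can move
  expect_identical(upd$W1, model$W1)
  expect_identical(upd$W2, model$W2)
  expect_identical(upd$b1, model$b1)
  expect_false(identical(upd$b2, model$b2))
})

test_that("a perfect one-hot output with alpha = 0 gives a zero update", {
  model <- tiny_model(seed = 3)
  rec <- onehot_record(label = 2L)
  mask <- list(input = rep(TRUE, 12), hidden = rep(TRUE, 5))
  cfg <- training_config(eta = 0.1, alpha = 0, epochs = 1)
  upd <- backprop_digit(model, rec, mask, label = 2L, cfg, d1 = 4L)
  expect_equal(upd$W1, model$W1, tolerance = 1e-15)
  expect_equal(upd$W2, model$W2, tolerance = 1e-15)
  expect_equal(upd$b2, model$b2, tolerance = 1e-15)
})

test_that("with zero cross-entropy gradient one step scales weights by 1-alpha", {
  model <- tiny_model(seed = 4)
  rec <- onehot_record(label = 0L)
  mask <- list(input = rep(TRUE, 12), hidden = rep(TRUE, 5))
  cfg <- training_config(eta = 0.1, alpha = 0.01, epochs = 1)
  upd <- backprop_digit(model, rec, mask, label = 0L, cfg, d1 = 4L)
  expect_identical(upd$W1, (1 - 0.01) * model$W1)
  expect_identical(upd$W2, (1 - 0.01) * model$W2)
})

test_that("masked gradients match an independent surrogate re-derivation", {
  for (case in 1:10) {
    model <- tiny_model(seed = 30 + case)
    frames <- random_frames(seed = 60 + case, p = 0.6)
    mask <- random_mask(12L, 5L, seed = 90 + case)
    rec <- forward_digit(model, frames, mask)
    cfg <- training_config(eta = 0.05, alpha = 0, epochs = 1)
    upd <- backprop_digit(model, rec, mask, label = 3L, cfg, d1 = 4L)
    g <- surrogate_gradient_oracle(model, rec, mask, 3L, d1 = 4L)
    expect_equal(upd$W1, model$W1 - 0.05 * g$gW1, tolerance = 1e-12)
    expect_equal(upd$b1, model$b1 - 0.05 * g$gb1, tolerance = 1e-12)
    expect_equal(upd$W2, model$W2 - 0.05 * g$gW2, tolerance = 1e-12)
    expect_equal(upd$b2, model$b2 - 0.05 * g$gb2, tolerance = 1e-12)
  }
})

test_that("training under a mask equals training the pruned network", {
  model <- tiny_model(seed = 5)
  frames <- random_frames(seed = 6, p = 0.6)
  mask <- random_mask(12L, 5L, seed = 7)
  if (!any(mask$input)) mask$input[1] <- TRUE
  if (!any(mask$hidden)) mask$hidden[1] <- TRUE
  cfg <- training_config(eta = 0.1, alpha = 0, epochs = 1)

  rec <- forward_digit(model, frames, mask)
  upd <- backprop_digit(model, rec, mask, label = 2L, cfg, d1 = 4L)

  ai <- which(mask$input); ah <- which(mask$hidden)
  pruned <- model
  pruned$W1 <- model$W1[ai, ah, drop = FALSE]
  pruned$b1 <- model$b1[ah]
  pruned$W2 <- model$W2[ah, , drop = FALSE]
  oracle <- pruned_forward_oracle(model, frames, mask)
  prec <- structure(list(input = frames[, ai, drop = FALSE],
                         hidden = oracle$hidden, output = oracle$output),
                    class = "spike_record")
  pmask <- list(input = rep(TRUE, length(ai)), hidden = rep(TRUE, length(ah)))
  pupd <- backprop_digit(pruned, prec, pmask, label = 2L, cfg, d1 = 4L)

  expect_equal(upd$W1[ai, ah, drop = FALSE], pupd$W1, tolerance = 1e-14)
  expect_equal(upd$b1[ah], pupd$b1, tolerance = 1e-14)
  expect_equal(upd$W2[ah, , drop = FALSE], pupd$W2, tolerance = 1e-14)
  expect_equal(upd$b2, pupd$b2, tolerance = 1e-14)
  # weights touching silenced nodes are untouched at alpha = 0
  expect_identical(upd$W1[!mask$input, , drop = FALSE],
                   model$W1[!mask$input, , drop = FALSE])
  expect_identical(upd$W2[!mask$hidden, , drop = FALSE],
                   model$W2[!mask$hidden, , drop = FALSE])
})

test_that("training runs are reproducible and zero epochs return the init", {
  spec <- tiny_spec(order = c(0L, 1L, 2L), d = 6L, d1 = 3L)
  train <- tiny_timeline_set(spec, 4L, seed = 8)
  cfg0 <- training_config(eta = 0.05, alpha = 1e-5, epochs = 0, seed = 9)
  m0 <- train_idnet(train, cfg0, hidden = 6L)
  init <- idnet_model(784L, 6L, 10L, seed = derive_seed(9L, 99L))
  expect_identical(m0$W1, init$W1)
  expect_identical(m0$W2, init$W2)

  cfg <- training_config(eta = 0.05, alpha = 1e-5, epochs = 2, seed = 9)
  m1 <- train_idnet(train, cfg, hidden = 6L)
  m2 <- train_idnet(train, cfg, hidden = 6L)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$trained_order, spec$order)

  # inconsistent orders across the dataset are rejected
  other <- tiny_timeline_set(tiny_spec(order = c(0L, 2L, 1L), d = 6L,
                                       d1 = 3L), 1L, seed = 10)
  expect_error(train_idnet(c(train[1], other), cfg, hidden = 6L),
               "share one digit order")
})

test_that("grid search finds a planted optimum and breaks ties to small eta", {
  mock <- function(eta, alpha, fold) -(log10(eta) + 3)^2 - (log10(alpha) + 5)^2
  best <- grid_search(mock, eta_grid = 10^c(-4, -3, -2),
                      alpha_grid = 10^c(-6, -5, -4), folds = 2)
  expect_equal(best$eta, 1e-3)
  expect_equal(best$alpha, 1e-5)
  # single cell: returned as-is
  one <- grid_search(function(...) 1, 0.1, 0.01, folds = 1, refine = FALSE)
  expect_equal(one$eta, 0.1)
  expect_equal(one$alpha, 0.01)
  # flat objective: ties broken toward the smaller eta, then alpha
  flat <- grid_search(function(...) 0.5, c(0.2, 0.1), c(0.02, 0.01),
                      folds = 1, refine = FALSE)
  expect_equal(flat$eta, 0.1)
  expect_equal(flat$alpha, 0.01)
  expect_error(grid_search(mock, numeric(0), 1), "non-empty")
})

test_that("the bundled hyperparameter registry carries the reference pairs", {
  p <- hyperparam_presets()
  expect_equal(p$spiking_one_sequence, list(alpha = 3.3e-5, eta = 2.7e-4))
  expect_equal(p$spiking_two_sequences, list(alpha = 1e-6, eta = 4.7e-4))
  expect_equal(p$writer_dependent, list(alpha = 8e-6, eta = 3.7e-4))
  expect_equal(p$ann_sigmoid, list(alpha = 5e-6, eta = 7e-2))
  expect_equal(p$ann_lenet_relu, list(eta = 1e-2))
  expect_error(hyperparam_presets("nonexistent"), "unknown preset")
})
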