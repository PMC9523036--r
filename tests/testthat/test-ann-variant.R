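test_that("input standardisation centres and scales each example", {
  img <- synthetic_digit(6, seed = 1)
  x <- standardize_input(img)
  expect_lt(abs(mean(x)), 1e-10)
  expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-10)
  # two-level image, half 0 and half 255: standardised values are +/- 1
  two <- gray_image(rep(c(0L, 255L), each = 392), 0)
  expect_equal(sort(unique(standardize_input(two))), c(-1, 1),
               tolerance = 1e-12)
  expect_error(standardize_input(gray_image(rep(7L, 784), 0)), "degenerate")
})

test_that("masked ANN forward equals the pruned network", {
  model <- ann_model(12L, 5L, 4L, seed = 2)
  img <- gray_image(c(seq(0L, 220L, length.out = 12), rep(0L, 772)), 1)
  x <- standardize_input(img)[1:12]
  # build a 12-input standardised vector directly
  mask <- random_mask(12L, 5L, seed = 3)
  if (!any(mask$input)) mask$input[1] <- TRUE
  if (!any(mask$hidden)) mask$hidden[1] <- TRUE
  act <- forward_ann_digit(model, x, mask)

  sig <- function(z) 1 / (1 + exp(-z))
  ai <- which(mask$input); ah <- which(mask$hidden)
  h_or <- sig(as.numeric(crossprod(model$W1[ai, ah, drop = FALSE], x[ai])) +
              model$b1[ah])
  a_or <- sig(as.numeric(crossprod(model$W2[ah, , drop = FALSE], h_or)) +
              model$b2)
  expect_equal(act$hidden[ah], h_or, tolerance = 1e-14)
  expect_equal(act$output, a_or, tolerance = 1e-14)
  expect_true(all(act$hidden[!mask$hidden] == 0))

  # all hidden silenced: outputs are sigmoid of the output biases
  none <- forward_ann_digit(model, x, list(input = mask$input,
                                           hidden = rep(FALSE, 5)))
  expect_equal(none$output, sig(model$b2), tolerance = 1e-14)
  # all-active mask equals the unmasked pass
  all_on <- list(input = rep(TRUE, 12), hidden = rep(TRUE, 5))
  full <- forward_ann_digit(model, x, all_on)
  expect_equal(full$hidden, sig(as.numeric(crossprod(model$W1, x)) + model$b1),
               tolerance = 1e-14)
})

test_that("ANN gradients match central finite differences on the pruned net", {
  model <- ann_model(6L, 4L, 3L, seed = 4)
  x <- c(0.5, -1.2, 0.3, 1.1, -0.4, 0.8)
  mask <- list(input = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
               hidden = c(TRUE, FALSE, TRUE, TRUE))
  label <- 1L
  cost_of <- function(m) {
    a <- forward_ann_digit(m, x, mask)$output
    y <- numeric(3); y[label + 1] <- 1
    -sum(y * log(a) + (1 - y) * log(1 - a))
  }
  g <- idnet:::.ann_gradients(model, forward_ann_digit(model, x, mask),
                              mask, label)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(5, 4))) {
    mp <- model; mp$W1[idx[1], idx[2]] <- mp$W1[idx[1], idx[2]] + eps
    mm <- model; mm$W1[idx[1], idx[2]] <- mm$W1[idx[1], idx[2]] - eps
    fd <- (cost_of(mp) - cost_of(mm)) / (2 * eps)
    an <- g$gW1[idx[1], idx[2]]
    if (abs(fd) > 1e-8) expect_lt(abs(an - fd) / max(abs(fd), 1e-8), 1e-5)
    else expect_lt(abs(an), 1e-8)
  }
  for (idx in list(c(1, 1), c(3, 2), c(4, 3))) {
    mp <- model; mp$W2[idx[1], idx[2]] <- mp$W2[idx[1], idx[2]] + eps
    mm <- model; mm$W2[idx[1], idx[2]] <- mm$W2[idx[1], idx[2]] - eps
    fd <- (cost_of(mp) - cost_of(mm)) / (2 * eps)
    expect_lt(abs(g$gW2[idx[1], idx[2]] - fd) / max(abs(fd), 1e-8), 1e-5)
  }
  # silenced-node gradient terms are identically zero
  expect_true(all(g$gW1[3, ] == 0))
  expect_true(all(g$gW1[, 2] == 0))
  expect_true(all(g$gW2[2, ] == 0))
  expect_true(all(g$gb1[2] == 0))
})

test_that("sigmoid activations always satisfy the silencing precondition", {
  model <- ann_model(12L, 5L, 4L, seed = 5)
  for (s in 1:5) {
    img <- synthetic_digit(s %% 10, seed = s)
    x <- standardize_input(img)[1:12] * 3 # exaggerate the scale
    act <- forward_ann_digit(model, x, list(input = rep(TRUE, 12),
                                            hidden = rep(TRUE, 5)))
    expect_true(all(act$hidden > 0 & act$hidden < 1))
    expect_silent(ann_silencing_profile(act$hidden, "sigmoid"))
  }
})

test_that("ReLU activations above one are silenced with probability one", {
  model <- ann_model(12L, 5L, 4L, activation = "relu", seed = 6)
  x <- rep(2, 12)
  act <- forward_ann_digit(model, x, list(input = rep(TRUE, 12),
                                          hidden = rep(TRUE, 5)))
  prof <- ann_silencing_profile(act$hidden, "relu")
  hot <- act$hidden > 1
  if (any(hot)) {
    expect_true(all(prof[hot] == 1))
    for (s in 1:10)
      expect_false(any(draw_mask(prof, seed = s)[hot]))
  }
  expect_true(all(prof[act$hidden == 0] == 0))
})

test_that("ANN sequence training is reproducible and separates wrong orders", {
  spec <- sequence_spec(c(0L, 3L, 7L, 1L, 5L, 9L, 2L, 8L, 4L, 6L),
                        delta_t = 200, d = 4L, d1 = 2L)
  train <- make_timeline_set(spec, 20L, seed = 31)
  cfg <- training_config(eta = 0.05, alpha = 1e-5, epochs = 8, seed = 32)
  m1 <- train_ann_sequence(train, cfg, hidden = 20L)
  m2 <- train_ann_sequence(train, cfg, hidden = 20L)
  expect_identical(m1$W1, m2$W1)

  m0 <- train_ann_sequence(train, training_config(eta = 0.05, alpha = 1e-5,
                                                  epochs = 0, seed = 32),
                           hidden = 20L)
  init <- ann_model(784L, 20L, 10L, seed = derive_seed(32L, 99L))
  expect_identical(m0$W1, init$W1)

  test <- make_timeline_set(spec, 15L, seed = 33)
  blue <- min_sr(per_digit_sr(m1, test, "known_order", seed = 34))
  wrong <- lapply(make_timeline_set(spec, 15L, seed = 35),
                  apply_imperfection, kind = "wrong", swap = c(2, 3))
  orange <- min_sr(per_digit_sr(m1, wrong, "known_order", seed = 36))
  expect_gt(blue, orange)
})
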