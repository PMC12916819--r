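test_that("tiny CNN input gradients match central finite differences", {
  cnn <- tiny_cnn(n_channels = 2, seed = 3)
  set.seed(1)
  xa <- array(rnorm(2 * 1000), c(10, 10, 10, 2))
  x <- as_volume(xa)
  wts <- array(0, c(10, 10, 10)); wts[5, 5, 5] <- 1; wts[6, 4, 5] <- -0.3
  g <- input_gradient(cnn, x, wts)
  f <- function(a) sum(wts * forward_logits(cnn, as_volume(a))$y)
  h <- 1e-5
  for (probe in list(c(5, 5, 5, 1), c(4, 6, 5, 2), c(8, 5, 5, 1), c(1, 1, 1, 2))) {
    ap <- xa; ap[probe[1], probe[2], probe[3], probe[4]] <- ap[probe[1], probe[2], probe[3], probe[4]] + h
    am <- xa; am[probe[1], probe[2], probe[3], probe[4]] <- am[probe[1], probe[2], probe[3], probe[4]] - h
    expect_equal(g[probe[1], probe[2], probe[3], probe[4]],
                 (f(ap) - f(am)) / (2 * h), tolerance = 1e-6)
  }
})

test_that("tiny CNN handles odd spatial extents by internal padding", {
  cnn <- tiny_cnn(n_channels = 1, seed = 2)
  set.seed(2)
  x <- as_volume(array(rnorm(9 * 7 * 5), c(9, 7, 5)))
  y <- forward_logits(cnn, x)
  expect_equal(dim(y$y), c(9L, 7L, 5L))
  w <- array(0, c(9, 7, 5)); w[5, 4, 3] <- 1
  g <- input_gradient(cnn, x, w)
  expect_equal(dim(g), c(9L, 7L, 5L, 1L))
  # FD spot check through the padding path
  h <- 1e-5
  xa <- x$data
  ap <- xa; ap[6, 4, 3, 1] <- ap[6, 4, 3, 1] + h
  am <- xa; am[6, 4, 3, 1] <- am[6, 4, 3, 1] - h
  fd <- (forward_logits(cnn, as_volume(ap[, , , 1]))$y[5, 4, 3] -
           forward_logits(cnn, as_volume(am[, , , 1]))$y[5, 4, 3]) / (2 * h)
  expect_equal(g[6, 4, 3, 1], fd, tolerance = 1e-6)
})

test_that("activation derivatives: backprop matches finite differences, higher orders vanish", {
  cnn <- tiny_cnn(n_channels = 2, seed = 5)
  set.seed(5)
  x <- as_volume(array(rnorm(2 * 8^3), c(8, 8, 8, 2)))
  wts <- array(runif(8^3), c(8, 8, 8))
  for (layer in c("enc_relu", "dec_relu")) {
    g1 <- activation_gradient(cnn, x, layer, wts, order = 1)
    for (at in list(c(4, 4, 4, 1), c(2, 6, 3, 2))) {
      fd <- fd_activation_derivative(cnn, x, layer, wts, at, order = 1)
      expect_equal(g1[at[1], at[2], at[3], at[4]], fd, tolerance = 1e-4)
    }
  }
  # logits are exactly linear in the final decoder activations: exact
  # second/third derivatives are zero, and finite differences agree
  d2 <- activation_gradient(cnn, x, "dec_relu", wts, order = 2)
  d3 <- activation_gradient(cnn, x, "dec_relu", wts, order = 3)
  expect_equal(max(abs(d2)), 0)
  expect_equal(max(abs(d3)), 0)
  fd2 <- fd_activation_derivative(cnn, x, "dec_relu", wts, c(4, 4, 4, 2), order = 2)
  expect_equal(fd2, 0, tolerance = 1e-5)
  expect_error(activation_gradient(cnn, x, "dec_relu", wts, order = 4), "order")
  expect_error(activation_gradient(cnn, x, "nope", wts, order = 1), "not exposed")
})

test_that("tiny CNN gradient support respects the analytic receptive field", {
  cnn <- tiny_cnn(n_channels = 2, seed = 9)
  set.seed(9)
  x <- as_volume(array(rnorm(2 * 16^3), c(16, 16, 16, 2)))
  w <- array(0, c(16, 16, 16)); w[8, 8, 8] <- 1
  g <- input_gradient(cnn, x, w)
  sup <- which(apply(abs(g) > 1e-12, 1:3, any), arr.ind = TRUE)
  cheb <- apply(abs(sweep(sup, 2, c(8, 8, 8))), 1, max)
  expect_true(all(cheb <= receptive_field_radius(cnn)))
})

test_that("model JSON serialization round-trips weights exactly", {
  cnn <- tiny_cnn(n_channels = 2, c1 = 4, c2 = 8, seed = 13)
  path <- tempfile(fileext = ".json")
  save_model(cnn, path)
  back <- load_model(path)
  expect_equal(back$params, cnn$params)
  x <- as_volume(array(rnorm(2 * 6^3), c(6, 6, 6, 2)))
  expect_equal(forward_logits(back, x)$y, forward_logits(cnn, x)$y)
})

test_that("training on phantoms reduces the loss and detects lesions", {
  fit <- trained_fixture()
  expect_lt(tail(fit$history, 1), fit$history[1])
  expect_gt(fit$validation$lesion_tpr, 0.8)
  expect_true(fit$model$trained)
})

test_that("zero training epochs returns the untrained model with a warning", {
  phs <- phantom_stream(20, phantom_config(dims = c(16, 16, 16), n_lesions = 1,
                                           seed = 50))
  expect_warning(out <- train_tiny_model(phs, epochs = 0, seed = 1),
                 "untrained")
  expect_false(out$model$trained)
  expect_error(train_tiny_model(phs[1:5], epochs = 1), "at least 20")
})
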