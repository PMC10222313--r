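# Hand-computed layer-shape fixture. Conv arithmetic: pad-1 3x3 conv keeps
# rows x cols; non-overlapping pooling floors; valid 3x3 conv subtracts 2.
shape_fixture <- list(
  list(arch = "time_cnn", input = c(16L, 250L),
       pool1 = c(16L, 83L), conv2 = c(14L, 81L), pool2 = c(14L, 40L),
       flatten = 35840L),
  list(arch = "time_cnn", input = c(8L, 250L),
       pool1 = c(8L, 83L), conv2 = c(6L, 81L), pool2 = c(6L, 40L),
       flatten = 15360L),
  list(arch = "spectral_cnn", input = c(32L, 129L),
       pool1 = c(16L, 64L), conv2 = c(14L, 62L), pool2 = c(7L, 31L),
       flatten = 13888L),
  list(arch = "spectral_cnn", input = c(36L, 129L),
       pool1 = c(18L, 64L), conv2 = c(16L, 62L), pool2 = c(8L, 31L),
       flatten = 15872L),
  list(arch = "spectral_cnn", input = c(64L, 129L),
       pool1 = c(32L, 64L), conv2 = c(30L, 62L), pool2 = c(15L, 31L),
       flatten = 29760L),
  list(arch = "spectral_cnn", input = c(68L, 129L),
       pool1 = c(34L, 64L), conv2 = c(32L, 62L), pool2 = c(16L, 31L),
       flatten = 31744L)
)

test_that("layer shapes match the hand-computed convolution arithmetic", {
  for (fx in shape_fixture) {
    sh <- cnn_layer_shapes(model_spec(fx$arch, fx$input))
    expect_equal(c(sh$rows[3], sh$cols[3]), fx$pool1, info = fx$arch)
    expect_equal(c(sh$rows[4], sh$cols[4]), fx$conv2)
    expect_equal(c(sh$rows[5], sh$cols[5]), fx$pool2)
    expect_equal(sh$cols[6], fx$flatten)
    expect_equal(sh$cols[8], 10L)  # class probabilities out

    # the compiled engine must agree with the R-side arithmetic
    cpp <- emgimage:::cpp_cnn_check_shapes(
      emgimage:::cpp_cfg(model_spec(fx$arch, fx$input)))
    expect_equal(unname(cpp[c("pool2_rows", "pool2_cols")]), fx$pool2)
    expect_equal(unname(cpp[["flatten"]]), 64L * prod(fx$pool2))
  }
})

test_that("unsupported input shapes are rejected with diagnostics", {
  expect_error(model_spec("time_cnn", c(4, 250)), "does not support")
  expect_error(model_spec("spectral_cnn", c(16, 129)), "does not support")
  expect_error(build_spectral_cnn(model_spec("spectral_cnn", c(32, 4))),
               "collapses")
  expect_error(model_spec("time_cnn", c(16, 250), n_classes = 1), ">= 2")
})

test_that("softmax output is a probability vector for any input", {
  m <- build_spectral_cnn(model_spec("spectral_cnn", c(32, 129)))
  imgs <- list(
    as_image(matrix(0, 32, 129)),                  # all-zero extreme
    as_image(matrix(1, 32, 129)),                  # all-one extreme
    as_image(matrix(runif(32 * 129), 32, 129))
  )
  p <- predict(m, imgs)
  probs <- as.matrix(p[, -1])
  expect_equal(ncol(probs), 10)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-6)
  # inference is frozen: repeated calls identical
  expect_identical(p, predict(m, imgs))
  # shape mismatch is caught
  expect_error(predict(m, list(as_image(matrix(0, 64, 129)))), "expects")
})

test_that("architecture parity: enhanced input only widens the first FC layer", {
  plain <- build_spectral_cnn(model_spec("spectral_cnn", c(64, 129)))
  enhanced <- build_spectral_cnn(model_spec("spectral_cnn", c(68, 129)))
  for (nm in c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2", "W4", "b4")) {
    expect_equal(dim(as.matrix(plain$weights[[nm]])),
                 dim(as.matrix(enhanced$weights[[nm]])), info = nm)
  }
  expect_equal(
    n_parameters(enhanced) - n_parameters(plain),
    (31744L - 29760L) * 128L
  )
})

test_that("the CNN overfits a tiny separable two-class set", {
  set.seed(9)
  imgs <- purrr::map(1:20, function(i) {
    cls <- (i - 1) %% 2
    base <- matrix(0.05 * runif(8 * 250), 8, 250)
    rows <- if (cls == 0) 1:3 else 6:8
    base[rows, ] <- base[rows, ] + 0.8
    as_image(base, label = cls, encoder = "time_domain")
  })
  m <- build_time_cnn(model_spec("time_cnn", c(8, 250), n_classes = 2))
  fit <- train_cnn(m, imgs, train_config(epochs = 30, seed = 4))
  expect_equal(fit$history$accuracy[30], 1)
  expect_equal(nrow(fit$history), 30)

  # determinism: identical seed and data reproduce the loss curve exactly
  fit2 <- train_cnn(m, imgs, train_config(epochs = 30, seed = 4))
  expect_identical(fit$history, fit2$history)

  # argmax prediction recovers the training labels
  p <- predict(fit, imgs)
  expect_equal(p$.pred, rep(c(0L, 1L), 10))
})

test_that("history bookkeeping and tidy/glance methods", {
  set.seed(3)
  imgs <- purrr::map(1:8, function(i) {
    as_image(matrix(runif(32 * 129), 32, 129), label = (i - 1) %% 2)
  })
  m <- build_spectral_cnn(model_spec("spectral_cnn", c(32, 129), n_classes = 2))
  fit <- train_cnn(m, imgs, train_config(epochs = 1, seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_named(tidy(fit), c("epoch", "loss", "accuracy"))
  g <- glance(fit)
  expect_equal(g$arch, "spectral_cnn")
  expect_equal(g$n_parameters, n_parameters(fit))
  expect_error(train_cnn(m, purrr::map(imgs, function(x) {
    x$label <- 12L; x
  })), "0..n_classes")
})
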