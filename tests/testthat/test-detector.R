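test_that("window builder emits causal right-aligned I||Q rows", {
  n <- 2000
  i100 <- time_series(seq_len(n), 100)        # distinguishable channels
  q100 <- time_series(-seq_len(n), 100)
  tgt <- time_series(rep(c(0, 1), n / 2), 100)
  ws <- build_windows(i100, q100, tgt, memory = 1.0)
  expect_equal(nrow(ws$inputs), n - 100 + 1)  # n - memory*rate + 1 windows
  expect_equal(ncol(ws$inputs), 200)

  # layout: I samples in positions 1-100 (oldest->newest), Q in 101-200
  expect_equal(ws$inputs[1, 1:100], as.numeric(1:100))
  expect_equal(ws$inputs[1, 101:200], as.numeric(-(1:100)))
  expect_equal(ws$inputs[5, 100], 104)        # newest I sample of row 5
  # target is the value at the newest sample; timestamps stride 1/100 s
  expect_equal(ws$targets[1], tgt$values[100])
  expect_close(diff(ws$timestamps), rep(0.01, nrow(ws$inputs) - 1), tol = 1e-9)

  # constant channels -> all rows identical
  cw <- build_windows(time_series(rep(2, 300), 100),
                      time_series(rep(3, 300), 100), NULL)
  expect_equal(nrow(unique(cw$inputs)), 1)

  # rate / length mismatches refused
  expect_error(build_windows(i100, time_series(seq_len(n), 50), tgt), "rates")
  expect_error(build_windows(i100, time_series(seq_len(n - 1), 100), tgt),
               "lengths")
})

test_that("the forward pass matches hand computation and a per-neuron oracle", {
  # all weights and biases zero -> sigmoid(0) = 0.5
  m0 <- ann_init("FF 3 1", 4, seed = 1)
  for (j in seq_along(m0$layers)) {
    m0$layers[[j]]$w[] <- 0; m0$layers[[j]]$b[] <- 0
  }
  expect_equal(ann_forward(m0, c(1, 2, 3, 4)), 0.5)

  # scalar 1-1-1 net: sigma(w2 tanh(w1 x + b1) + b2)
  m1 <- ann_init("FF 1 1", 1, seed = 2)
  m1$layers[[1]]$w[] <- 0.7; m1$layers[[1]]$b <- -0.2
  m1$layers[[2]]$w[] <- 1.3; m1$layers[[2]]$b <- 0.4
  x <- 0.9
  byhand <- 1 / (1 + exp(-(1.3 * tanh(0.7 * x - 0.2) + 0.4)))
  expect_equal(ann_forward(m1, x), byhand, tolerance = 1e-15)

  # FF 20 1 on a 200-vector: one hidden layer of 20 tanh units, sigmoid out
  m2 <- ann_init("FF 20 1", 200, seed = 3)
  expect_length(m2$layers, 2)
  expect_equal(dim(m2$layers[[1]]$w), c(20L, 200L))
  expect_equal(m2$layers[[1]]$act, "tanh")
  expect_equal(dim(m2$layers[[2]]$w), c(1L, 20L))
  expect_equal(m2$layers[[2]]$act, "sigmoid")
  y <- ann_forward(m2, stats::rnorm(200))
  expect_true(y > 0 && y < 1)

  # property: vectorized pass agrees with a naive per-neuron loop to 1e-12
  loop_forward <- function(model, x) {
    a <- x
    for (l in model$layers) {
      z <- numeric(nrow(l$w))
      for (o in seq_len(nrow(l$w))) z[o] <- sum(l$w[o, ] * a) + l$b[o]
      a <- switch(l$act, tanh = tanh(z), logsig = 1 / (1 + exp(-z)),
                  sigmoid = 1 / (1 + exp(-z)), linear = z)
    }
    a
  }
  withr::with_seed(11, {
    for (topo in c("FF 5 1", "FF 6 3 1", "FF 4 2 1")) {
      mm <- ann_init(topo, 7, seed = sample(1e6, 1), hidden_act = "tanh")
      xx <- stats::rnorm(7)
      expect_lt(abs(ann_forward(mm, xx) - loop_forward(mm, xx)), 1e-12)
    }
    ml <- ann_init("FF 5 1", 6, seed = 42, hidden_act = "logsig")
    xl <- stats::rnorm(6)
    expect_lt(abs(ann_forward(ml, xl) - loop_forward(ml, xl)), 1e-12)
  })

  expect_error(ann_forward(m2, numeric(100)), "does not match")
})

test_that("loss functions follow their definitions", {
  ws <- separable_windows(2, 3, seed = 1)
  ws$targets <- c(1, 0)
  m <- ann_init("FF 2 1", 3, seed = 4)
  # force outputs of exactly 0.5 by zeroing the net
  for (j in seq_along(m$layers)) { m$layers[[j]]$w[] <- 0; m$layers[[j]]$b[] <- 0 }
  expect_equal(ann_loss(m, ws, "mse"), 0.25)
  expect_equal(ann_loss(m, ws, "sse"), 2 * ann_loss(m, ws, "mse"))
  # msereg with all-zero weights reduces to gamma * MSE
  expect_equal(ann_loss(m, ws, "msereg", reg_ratio = 0.8), 0.8 * 0.25)
  expect_error(ann_loss(m, structure(list(inputs = matrix(0, 0, 3),
                                          targets = numeric(0)),
                                     class = "window_set")), "empty")
})

test_that("model serialization round-trips the forward pass bit-exactly", {
  dir <- withr::local_tempdir()
  m <- ann_init("FF 6 3 1", 12, seed = 9)
  p <- file.path(dir, "model.json")
  save_ann(m, p)
  m2 <- load_ann(p)
  x <- withr::with_seed(1, stats::rnorm(12))
  expect_identical(ann_forward(m2, x), ann_forward(m, x))
  expect_identical(m2$layers[[1]]$w, m$layers[[1]]$w)
  expect_equal(m2$topology, m$topology)
})

test_that("Levenberg-Marquardt converges on a separable problem", {
  ws <- separable_windows(100, 8, seed = 5)
  fit <- suppressWarnings(
    train_lm("FF 10 1", ws, train_config(max_epochs = 150, seed = 3,
                                         val_fraction = 0.3)))
  # training loss strictly non-increasing over accepted steps
  acc <- fit$log$train_loss[fit$log$accepted]
  expect_true(all(diff(acc) <= 1e-15))
  # converges below 1e-3 MSE on the training rows
  expect_lt(min(fit$log$train_loss), 1e-3)

  # determinism: identical seeds give bit-identical trajectories
  fit2 <- suppressWarnings(
    train_lm("FF 10 1", ws, train_config(max_epochs = 150, seed = 3,
                                         val_fraction = 0.3)))
  expect_identical(fit$log, fit2$log)
  expect_identical(radarbeat:::flatten_params(fit$model),
                   radarbeat:::flatten_params(fit2$model))

  expect_error(train_config(max_epochs = 0), "max_epochs")
  expect_error(train_config(val_fraction = 1.5), "val_fraction")
})

test_that("early stopping halts within patience on shifted validation data", {
  # training rows learnable; validation drawn from a different distribution so
  # validation loss stops improving early
  ws <- separable_windows(200, 6, seed = 6)
  ws$groups <- rep(c("a", "b"), each = 100)
  ws$targets[ws$groups == "b"] <- withr::with_seed(7, sample(0:1, 100, TRUE))
  cfg <- train_config(max_epochs = 400, seed = 2, patience = 6)
  fit <- suppressWarnings(train_lm("FF 8 1", ws, cfg))
  expect_lt(nrow(fit$log), 400)   # stopped well before the epoch budget
  # returned weights are the best-validation ones
  va <- fit$log$val_loss[fit$log$accepted]
  expect_lt(min(va) - 1e-12, va[length(va)])
})

test_that("large damping reduces LM to a gradient step", {
  ws <- separable_windows(60, 5, seed = 8)
  m <- ann_init("FF 4 1", 5, seed = 13)
  fj <- radarbeat:::ann_jacobian(m, ws$inputs)
  g <- crossprod(fj$J, ws$targets - fj$a)[, 1]
  mu <- 1e9
  G <- crossprod(fj$J)
  delta <- solve(G + diag(mu, length(g)), g)
  cosang <- sum(delta * g) / sqrt(sum(delta^2) * sum(g^2))
  expect_gt(cosang, 0.999)
})

test_that("NARX steps, topology and closed-loop fixed point behave", {
  m <- ann_init("NARX 10 1", 200, seed = 21, feedback = 10)
  expect_length(m$layers, 2)
  expect_equal(dim(m$layers[[1]]$w), c(10L, 210L))

  # zero net, zero feedback -> 0.5
  m0 <- m
  for (j in seq_along(m0$layers)) { m0$layers[[j]]$w[] <- 0; m0$layers[[j]]$b[] <- 0 }
  expect_equal(narx_forward(m0, numeric(200), numeric(10)), 0.5)
  expect_error(narx_forward(m, numeric(200), numeric(3)), "feedback depth")

  # closed-loop on constant input converges to the fixed point y = f(x, y*1)
  xconst <- withr::with_seed(3, stats::rnorm(200, sd = 0.1))
  step <- function(y) narx_forward(m, xconst, rep(y, 10))
  y <- 0.5
  for (k in 1:200) y <- step(y)          # iteration oracle
  ws <- structure(list(inputs = matrix(rep(xconst, each = 60), 60, 200),
                       targets = numeric(60), timestamps = seq_len(60) / 100,
                       rate = 100, memory = 2),
                  class = "window_set")
  out <- narx_predict(m, ws)
  expect_lt(abs(out[60] - y), 1e-6)

  # open-loop training windows carry target feedback columns
  tgt <- time_series(rep(c(0, 0, 0, 1), 75), 100)
  i100 <- time_series(stats::rnorm(300), 100)
  q100 <- time_series(stats::rnorm(300), 100)
  nws <- build_narx_windows(i100, q100, tgt, memory = 1, feedback = 10)
  expect_equal(ncol(nws$inputs), 210)
  k_new <- 101                            # second row's newest sample index
  expect_equal(nws$inputs[2, 201:210], tgt$values[(k_new - 10):(k_new - 1)])
})
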