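test_that("learning-rate schedules evaluate their closed forms", {
  expect_equal(lr_at(lr_schedule("fixed"), c(0, 1, 7000, 15000)), rep(0.01, 4))
  st <- lr_schedule("step")
  expect_equal(lr_at(st, 0), 0.01)
  expect_equal(lr_at(st, 499), 0.01)
  expect_equal(lr_at(st, 500), 0.01 * 0.75)
  expect_equal(lr_at(st, 1250), 0.005625) # 0.01 * 0.75^2
  expect_equal(lr_at(lr_schedule("exp"), 0), 0.01)
  expect_equal(lr_at(lr_schedule("exp"), 3), 0.01 * 0.75^3)
  po <- lr_schedule("poly")
  expect_equal(lr_at(po, 15000), 0)
  expect_equal(lr_at(po, 7500), 0.01 * 0.25)
  sg <- lr_schedule("sigmoid")
  expect_equal(lr_at(sg, 500), 0.005) # exactly base_lr / 2 at the midpoint
  expect_error(lr_at(st, -1), "outside")
  expect_error(lr_at(st, 15001), "outside")
})

test_that("step/exp/poly schedules are non-increasing and sigmoid non-decreasing", {
  i <- seq(0, 15000, by = 125)
  for (k in c("step", "exp", "poly")) {
    expect_true(all(diff(lr_at(lr_schedule(k), i)) <= 0), info = k)
  }
  expect_true(all(diff(lr_at(lr_schedule("sigmoid"), i)) >= 0))
})

test_that("MSRA draws have variance 2/fan-in and scale as 1/sqrt(fan-in)", {
  x2 <- msra_init(1e5, fan_in = 2, seed = 1)
  expect_equal(mean(x2), 0, tolerance = 0.02)
  expect_equal(var(x2), 1.0, tolerance = 0.05)
  x8 <- msra_init(1e5, fan_in = 8, seed = 2)
  expect_equal(sd(x8) / sd(x2), 0.5, tolerance = 0.03)
  expect_identical(msra_init(10, 4, seed = 9), msra_init(10, 4, seed = 9))
})

test_that("loss at zero weights is ln 3 and batch duplication changes nothing", {
  cfg <- mini_config()
  w <- cnn_zero_weights(cfg)
  set.seed(3)
  x <- array(runif(cfg$n_channels * cfg$W * 6), c(cfg$n_channels, cfg$W, 6))
  l <- c(2L, 3L, 7L, 2L, 3L, 7L)
  lg <- loss_and_gradients(w, x, l)
  expect_equal(lg$loss, log(3), tolerance = 1e-12)

  wi <- rand_weights(cfg, seed = 2)
  lg1 <- loss_and_gradients(wi, x, l)
  xdup <- array(c(x, x), c(cfg$n_channels, cfg$W, 12))
  lg2 <- loss_and_gradients(wi, xdup, c(l, l))
  expect_equal(lg2$loss, lg1$loss, tolerance = 1e-12)
  expect_equal(lg2$grads, lg1$grads, tolerance = 1e-12)
})

test_that("initial loss on a balanced batch sits near ln 3 for MSRA nets", {
  cfg <- mini_config(n_channels = 8, W = 8, pl1 = 32)
  set.seed(10)
  x <- array(runif(8 * 8 * 30, 0, 0.3), c(8, 8, 30))
  l <- rep(c(2L, 3L, 7L), 10)
  losses <- vapply(1:10, function(s) {
    loss_and_gradients(cnn_init(cfg, seed = s), x, l)$loss
  }, 0)
  # the MSRA-initialized output layer gives the class scores a spread of
  # order sqrt(2 * mean(H^2)) regardless of head width, so the balanced-batch
  # loss starts a little above ln 3 (by roughly half the score variance);
  # it cannot start materially below ln 3 because the random weights are
  # independent of the labels
  expect_true(all(losses - log(3) > -0.05))
  expect_true(all(losses - log(3) < 0.6))
  expect_lt(abs(mean(losses) - log(3)), 0.3)
})

test_that("gradients match central finite differences on every layer type", {
  cfg <- mini_config(n_channels = 3, W = 6)
  w <- rand_weights(cfg, seed = 4)
  set.seed(11)
  B <- 5
  x <- array(runif(3 * 6 * B), c(3, 6, B))
  l <- c(2L, 3L, 7L, 3L, 2L)
  lg <- loss_and_gradients(w, x, l)
  h <- 1e-5
  for (nm in names(lg$grads)) {
    n <- length(w[[nm]])
    idx <- unique(round(seq(1, n, length.out = min(15, n))))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      num <- (loss_and_gradients(wp, x, l)$loss -
                loss_and_gradients(wm, x, l)$loss) / (2 * h)
      denom <- max(1e-6, abs(num) + abs(lg$grads[[nm]][i]))
      expect_lt(abs(num - lg$grads[[nm]][i]) / denom, 1e-4)
    }
  }
})

test_that("AdaGrad follows the accumulated-history closed form", {
  cfg <- mini_config()
  w <- cnn_zero_weights(cfg)
  g <- lapply(unclass(w), function(a) { a[] <- 0.37; a })
  st <- solver_state("adagrad", w)
  lr <- 0.01
  cur <- w
  # constant gradient: t-th update magnitude is exactly lr / sqrt(t)
  for (t in 1:8) {
    up <- adagrad_step(st, cur, g, lr)
    step_t <- unique(round(abs(as.numeric(up$weights$pl1_w - cur$pl1_w)), 12))
    expect_equal(step_t, lr / sqrt(t), tolerance = 1e-6)
    cur <- up$weights
    st <- up$state
  }
  expect_equal(st$iteration, 8L)
  # history is non-decreasing and non-negative
  expect_true(all(st$history$pl1_w >= 0))
  # zero gradient leaves weights untouched
  g0 <- lapply(unclass(w), function(a) { a[] <- 0; a })
  up0 <- adagrad_step(st, cur, g0, lr)
  expect_identical(up0$weights$conv1_w, cur$conv1_w)
  # first-step direction is -sign(g)
  st1 <- solver_state("adagrad", w)
  up1 <- adagrad_step(st1, w, g, lr)
  expect_true(all(up1$weights$pl2_w < 0))
})

test_that("momentum SGD accumulates the geometric-series buffer", {
  cfg <- mini_config()
  w <- cnn_zero_weights(cfg)
  gval <- 0.2
  g <- lapply(unclass(w), function(a) { a[] <- gval; a })
  lr <- 0.01
  mu <- 0.9
  st <- solver_state("sgd", w, momentum = mu)
  cur <- w
  for (k in 1:6) {
    up <- sgd_step(st, cur, g, lr)
    cur <- up$weights
    st <- up$state
    expect_equal(unique(as.numeric(st$history$pl1_w)),
                 lr * gval * (1 - mu^k) / (1 - mu), tolerance = 1e-12)
  }
  # momentum 0 is plain gradient descent
  st0 <- solver_state("sgd", w, momentum = 0)
  up <- sgd_step(st0, w, g, lr)
  expect_equal(unique(as.numeric(up$weights$pl1_w)), -lr * gval)
  # zero gradient forever keeps weights constant
  g0 <- lapply(unclass(w), function(a) { a[] <- 0; a })
  stz <- solver_state("sgd", w)
  upz <- sgd_step(stz, w, g0, lr)
  expect_identical(upz$weights$pl1_w, w$pl1_w)
})

test_that("training runs are reproducible and recorded at checkpoints", {
  ds <- tiny_dataset()
  r1 <- cnn_train(ds$train[[1]], ds$test[[1]], max_iter = 12, batch_size = 16,
                  eval_every = 6, seed = 3)
  r2 <- cnn_train(ds$train[[1]], ds$test[[1]], max_iter = 12, batch_size = 16,
                  eval_every = 6, seed = 3)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$final_weights, r2$final_weights)
  expect_identical(r1$history$iteration, c(6L, 12L))
  expect_true(all(diff(r1$history$iteration) > 0))
  r3 <- cnn_train(ds$train[[1]], ds$test[[1]], max_iter = 12, batch_size = 16,
                  eval_every = 6, seed = 4)
  expect_false(identical(r1$final_weights, r3$final_weights))
})

test_that("repeat-and-average reports the arithmetic mean over runs", {
  ds <- tiny_dataset()
  res <- repeat_and_average(ds$train[[1]], ds$test[[1]], n_repeats = 2,
                            seeds = c(5, 6), max_iter = 8, batch_size = 16,
                            eval_every = 8)
  expect_length(res$accuracies, 2)
  expect_equal(res$mean_accuracy, mean(res$accuracies))
  single <- repeat_and_average(ds$train[[1]], ds$test[[1]], n_repeats = 1,
                               seeds = 5, max_iter = 8, batch_size = 16,
                               eval_every = 8)
  expect_equal(single$mean_accuracy, single$accuracies[1])
  expect_equal(single$accuracies[1], res$accuracies[1])
  # seed permutation leaves the mean unchanged
  resR <- repeat_and_average(ds$train[[1]], ds$test[[1]], n_repeats = 2,
                             seeds = c(6, 5), max_iter = 8, batch_size = 16,
                             eval_every = 8)
  expect_equal(sort(resR$accuracies), sort(res$accuracies))
  expect_equal(resR$mean_accuracy, res$mean_accuracy)
})
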