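# Training stack: learning-rate schedules, MSRA initialization, softmax
# cross-entropy with exact backpropagation through every layer, AdaGrad and
# momentum-SGD solvers, the minibatch loop, and repeat-and-average runs.

#' Learning-rate schedule
#'
#' The five schedules used to control the learning rate over iterations, with
#' their published default parameters (base rate 0.01, gamma 0.75, stepsize
#' 500, 15,000 iterations, power 2):
#' \describe{
#'   \item{fixed}{`base_lr`}
#'   \item{step}{`base_lr * gamma^floor(i / stepsize)`}
#'   \item{exp}{`base_lr * gamma^i` (with gamma 0.75 this underflows to a
#'     vanishing rate within ~100 iterations; retained as defined)}
#'   \item{poly}{`base_lr * (1 - i / max_iter)^power`}
#'   \item{sigmoid}{`base_lr / (1 + exp(-gamma * (i - stepsize)))` -- note
#'     this rises with i toward `base_lr`, reaching `base_lr / 2` exactly at
#'     `i = stepsize`}
#' }
#'
#' @param kind One of `"fixed"`, `"step"`, `"exp"`, `"poly"`, `"sigmoid"`.
#' @param base_lr Initial learning rate.
#' @param gamma Decay factor.
#' @param stepsize Iterations per step (step), or midpoint (sigmoid).
#' @param max_iter Total iterations (poly horizon).
#' @param power Polynomial exponent.
#' @return An `lr_schedule` list.
#' @export
lr_schedule <- function(kind = c("step", "fixed", "exp", "poly", "sigmoid"),
                        base_lr = 0.01, gamma = 0.75, stepsize = 500L,
                        max_iter = 15000L, power = 2) {
  kind <- match.arg(kind)
  if (base_lr <= 0) stop("base_lr must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (stepsize < 1 || max_iter < 1) stop("stepsize and max_iter must be >= 1")
  structure(
    list(kind = kind, base_lr = base_lr, gamma = gamma,
         stepsize = as.integer(stepsize), max_iter = as.integer(max_iter),
         power = power),
    class = "lr_schedule"
  )
}

#' Learning rate at an iteration
#'
#' Evaluates the schedule's closed form; vectorized over `i`.
#'
#' @param schedule An [lr_schedule()].
#' @param i Iteration number(s), `0 <= i <= max_iter`.
#' @return Numeric learning rate(s).
#' @export
lr_at <- function(schedule, i) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (any(i < 0 | i > schedule$max_iter)) {
    stop("iteration outside [0, max_iter]")
  }
  with(schedule, switch(kind,
    fixed = rep_len(base_lr, length(i)),
    step = base_lr * gamma^floor(i / stepsize),
    exp = base_lr * gamma^i,
    poly = base_lr * (1 - i / max_iter)^power,
    sigmoid = base_lr / (1 + exp(-gamma * (i - stepsize)))
  ))
}

#' MSRA (He) weight initialization draws
#'
#' Zero-mean Gaussian samples with variance `2 / fan_in`, the initialization
#' suited to ReLU networks.
#'
#' @param n Number of draws.
#' @param fan_in Fan-in of the layer (>= 1).
#' @param seed Optional seed for a self-contained draw.
#' @return Numeric vector of length `n`.
#' @export
msra_init <- function(n, fan_in, seed = NULL) {
  stopifnot(fan_in >= 1)
  draw <- function() rnorm(n, mean = 0, sd = sqrt(2 / fan_in))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# map class codes to softmax output positions
class_positions <- function(labels, classes = PSD_CLASSES) {
  idx <- match(labels, classes)
  if (anyNA(idx)) {
    stop("labels outside the class set {", paste(classes, collapse = ", "), "}")
  }
  idx
}

#' Loss and exact gradients for a minibatch
#'
#' Mean softmax cross-entropy over the batch, with exact analytic gradients
#' for every trainable array: sigmoid on the dense hidden layer, ReLU gating,
#' pair-max pooling routing gradient to the argmax map (ties to the lower map
#' index), and both per-channel convolutions under the configured padding.
#'
#' @param weights A `cnn_weights` object.
#' @param windows A `window_set` or `96 x W x B` array.
#' @param labels Class codes, one per window (taken from the window set when
#'   omitted).
#' @return List with `loss` (scalar) and `grads` (same structure as
#'   `weights`).
#' @export
loss_and_gradients <- function(weights, windows, labels = NULL) {
  cfg <- attr(weights, "config")
  x <- if (inherits(windows, "window_set")) windows$data else windows
  if (is.null(labels) && inherits(windows, "window_set")) labels <- windows$labels
  if (is.null(labels)) stop("labels are required")
  d <- dim(x)
  if (length(d) != 3 || d[3] == 0) stop("empty batch")
  stopifnot(length(labels) == d[3])
  idx <- class_positions(labels, PSD_CLASSES[seq_len(cfg$n_classes)])
  if (!is.double(x)) storage.mode(x) <- "double"
  out <- .cpp_loss_grad(unclass(weights), x, as.integer(idx), unclass(cfg))
  if (!is.finite(out$loss)) stop("non-finite loss in the softmax-loss layer")
  out
}

#' Create solver state
#'
#' AdaGrad keeps the per-weight accumulated squared-gradient history; SGD
#' keeps a per-weight momentum buffer.
#'
#' @param solver `"adagrad"` or `"sgd"`.
#' @param weights The `cnn_weights` the state will track.
#' @param epsilon AdaGrad numerical floor, added outside the square root.
#' @param momentum SGD momentum coefficient in [0, 1).
#' @return A `solver_state` list.
#' @export
solver_state <- function(solver = c("adagrad", "sgd"), weights,
                         epsilon = 1e-8, momentum = 0.9) {
  solver <- match.arg(solver)
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  zeros <- lapply(unclass(weights), function(a) {
    a[] <- 0
    a
  })
  structure(
    list(solver = solver, history = zeros, epsilon = epsilon,
         momentum = momentum, iteration = 0L),
    class = "solver_state"
  )
}

#' One AdaGrad update
#'
#' Adds the squared gradient to the per-weight history, then steps each
#' weight by `lr * g / (sqrt(history) + epsilon)`: the first step with any
#' non-zero gradient has magnitude exactly `lr`, and under a constant
#' gradient the t-th step has magnitude `lr / sqrt(t)`.
#'
#' @param state A `solver_state` created with `solver = "adagrad"`.
#' @param weights Current `cnn_weights`.
#' @param grads Gradients from [loss_and_gradients()].
#' @param lr Learning rate for this iteration.
#' @return List with updated `weights` and `state`.
#' @export
adagrad_step <- function(state, weights, grads, lr) {
  stopifnot(state$solver == "adagrad")
  for (nm in names(state$history)) {
    g <- grads[[nm]]
    state$history[[nm]] <- state$history[[nm]] + g * g
    weights[[nm]] <- weights[[nm]] -
      lr * g / (sqrt(state$history[[nm]]) + state$epsilon)
  }
  state$iteration <- state$iteration + 1L
  list(weights = weights, state = state)
}

#' One momentum-SGD update
#'
#' The buffer accumulates `momentum * buffer + lr * g` and the weights move
#' by the buffer, so the update converges along the summed vector of recent
#' updates ("short history"), in contrast to AdaGrad's full gradient-norm
#' history.
#'
#' @param state A `solver_state` created with `solver = "sgd"`.
#' @param weights Current `cnn_weights`.
#' @param grads Gradients from [loss_and_gradients()].
#' @param lr Learning rate for this iteration.
#' @param momentum Momentum coefficient, defaulting to the state's.
#' @return List with updated `weights` and `state`.
#' @export
sgd_step <- function(state, weights, grads, lr, momentum = state$momentum) {
  stopifnot(state$solver == "sgd")
  for (nm in names(state$history)) {
    state$history[[nm]] <- momentum * state$history[[nm]] + lr * grads[[nm]]
    weights[[nm]] <- weights[[nm]] - state$history[[nm]]
  }
  state$iteration <- state$iteration + 1L
  list(weights = weights, state = state)
}

accuracy_on <- function(weights, windows, batch_size = 512L) {
  if (n_windows(windows) == 0) return(NA_real_)
  mean(cnn_predict(weights, windows, batch_size) == windows$labels)
}

#' Train the network
#'
#' Minibatch training with MSRA initialization, the chosen learning-rate
#' schedule and solver, and periodic accuracy checkpoints. Windows are pooled
#' over all training sessions and shuffled each epoch with the run seed, so a
#' run is exactly reproducible. Reported alongside the final weights are the
#' weights of the checkpoint with the best test accuracy (training typically
#' peaks well before the final iteration).
#'
#' @param train_sessions A labelled [psd_session()] or list of them.
#' @param test_sessions Optional labelled session(s) scored at checkpoints.
#' @param config A [cnn_config()].
#' @param schedule An [lr_schedule()].
#' @param solver `"adagrad"` or `"sgd"`.
#' @param max_iter Number of minibatch updates (one update = one iteration).
#' @param batch_size Windows per minibatch.
#' @param eval_every Checkpoint interval in iterations.
#' @param seed Run seed (initialization and shuffling).
#' @param stride,label_policy Windowing options, see [window_session()].
#' @param eval_train_max Cap on the number of training windows scored at
#'   checkpoints (a fixed subsample keeps checkpoints cheap on long runs).
#' @param momentum SGD momentum coefficient.
#' @param epsilon AdaGrad denominator floor.
#' @param verbose Print checkpoint lines.
#' @return A `train_record`: `history` data frame (iteration, lr, loss,
#'   train_acc, test_acc), `final_weights`, `best_weights`, `best_iteration`,
#'   `best_test_acc`, `final_train_acc`, `final_test_acc`, `seed`, `config`,
#'   `schedule`, `solver`.
#' @export
cnn_train <- function(train_sessions, test_sessions = NULL,
                      config = cnn_config(), schedule = lr_schedule("step"),
                      solver = c("adagrad", "sgd"),
                      max_iter = 2000L, batch_size = 64L, eval_every = 250L,
                      seed = 1L, stride = 1L, label_policy = "last-frame",
                      eval_train_max = 4000L, momentum = 0.9, epsilon = 1e-8,
                      verbose = FALSE) {
  solver <- match.arg(solver)
  if (inherits(train_sessions, "psd_session")) train_sessions <- list(train_sessions)
  if (inherits(test_sessions, "psd_session")) test_sessions <- list(test_sessions)
  if (!length(train_sessions)) stop("at least one labelled training session is required")
  if (any(!vapply(train_sessions, is_labelled, TRUE))) {
    stop("all training sessions must be labelled")
  }
  train_w <- combine_window_sets(lapply(
    train_sessions, window_session, W = config$W, stride = stride,
    label_policy = label_policy
  ))
  if (n_windows(train_w) < batch_size) {
    batch_size <- max(1L, n_windows(train_w))
  }
  test_w <- if (!is.null(test_sessions)) {
    combine_window_sets(lapply(
      test_sessions, window_session, W = config$W, stride = stride,
      label_policy = label_policy
    ))
  }
  if (schedule$kind == "exp" && schedule$gamma < 1) {
    message("exp schedule: learning rate underflows to ~0 within ",
            ceiling(log(1e-12) / log(schedule$gamma)), " iterations")
  }
  max_iter <- min(max_iter, schedule$max_iter)

  with_seed(seed, {
    weights <- cnn_init(config, seed = sample.int(.Machine$integer.max, 1))
    state <- solver_state(solver, weights, epsilon = epsilon, momentum = momentum)
    n_tr <- n_windows(train_w)
    eval_idx <- if (n_tr > eval_train_max) sample.int(n_tr, eval_train_max) else seq_len(n_tr)
    eval_train <- list(
      data = train_w$data[, , eval_idx, drop = FALSE],
      labels = train_w$labels[eval_idx], W = train_w$W
    )
    class(eval_train) <- "window_set"

    order_ <- sample.int(n_tr)
    cursor <- 1L
    hist_rows <- list()
    best <- list(acc = -Inf, weights = weights, iteration = 0L)

    checkpoint <- function(i, lr, loss) {
      tr_acc <- accuracy_on(weights, eval_train)
      te_acc <- if (!is.null(test_w)) accuracy_on(weights, test_w) else NA_real_
      if (verbose) {
        cat(sprintf("iter %6d  lr %.5g  loss %.4f  train %.4f  test %s\n",
                    i, lr, loss, tr_acc,
                    if (is.na(te_acc)) "-" else sprintf("%.4f", te_acc)))
      }
      sel <- if (is.na(te_acc)) tr_acc else te_acc
      if (!is.na(sel) && sel > best$acc) {
        best <<- list(acc = sel, weights = weights, iteration = i)
      }
      data.frame(iteration = i, lr = lr, loss = loss,
                 train_acc = tr_acc, test_acc = te_acc)
    }

    loss <- NA_real_
    for (i in seq_len(max_iter)) {
      if (cursor + batch_size - 1L > n_tr) {
        order_ <- sample.int(n_tr)
        cursor <- 1L
      }
      take <- order_[cursor:(cursor + batch_size - 1L)]
      cursor <- cursor + batch_size
      lg <- loss_and_gradients(
        weights, train_w$data[, , take, drop = FALSE], train_w$labels[take]
      )
      loss <- lg$loss
      if (!is.finite(loss)) {
        stop("training diverged at iteration ", i, " (non-finite loss)")
      }
      lr <- lr_at(schedule, i)
      upd <- if (solver == "adagrad") {
        adagrad_step(state, weights, lg$grads, lr)
      } else {
        sgd_step(state, weights, lg$grads, lr)
      }
      weights <- upd$weights
      state <- upd$state
      if (i %% eval_every == 0L || i == max_iter) {
        hist_rows[[length(hist_rows) + 1L]] <- checkpoint(i, lr, loss)
      }
    }
    history <- do.call(rbind, hist_rows)
    structure(
      list(
        history = history,
        final_weights = weights,
        best_weights = best$weights,
        best_iteration = best$iteration,
        best_test_acc = if (!is.null(test_w)) best$acc else NA_real_,
        final_train_acc = history$train_acc[nrow(history)],
        final_test_acc = history$test_acc[nrow(history)],
        seed = seed, config = config, schedule = schedule, solver = solver
      ),
      class = "train_record"
    )
  })
}

#' @export
print.train_record <- function(x, ...) {
  cat(sprintf(
    "<train_record> %s solver, %s schedule, %d iterations (seed %d)\n",
    x$solver, x$schedule$kind, max(x$history$iteration), x$seed
  ))
  cat(sprintf("  final: train %.4f, test %s; best test %s at iteration %d\n",
              x$final_train_acc,
              if (is.na(x$final_test_acc)) "-" else sprintf("%.4f", x$final_test_acc),
              if (is.na(x$best_test_acc)) "-" else sprintf("%.4f", x$best_test_acc),
              x$best_iteration))
  invisible(x)
}

#' Repeat a training run and average test effectiveness
#'
#' Runs [cnn_train()] `n_repeats` times with distinct seeds and reports the
#' per-run and mean test effectiveness, the protocol used to damp
#' initialization/shuffling randomness (five repeats by convention).
#'
#' @param ... Arguments passed to [cnn_train()] (everything except `seed`).
#' @param n_repeats Number of runs.
#' @param seeds Optional explicit seeds (length `n_repeats`); defaults to
#'   seeds derived from `master_seed`.
#' @param master_seed Seed from which run seeds are derived when `seeds` is
#'   missing.
#' @return List with `runs` (train records), `accuracies` (final test
#'   accuracy per run), `mean_accuracy`, `best_accuracies`, `seeds`.
#' @export
repeat_and_average <- function(..., n_repeats = 5L, seeds = NULL,
                               master_seed = 1L) {
  stopifnot(n_repeats >= 1)
  if (is.null(seeds)) seeds <- derive_seeds(master_seed, n_repeats)
  stopifnot(length(seeds) == n_repeats)
  runs <- lapply(seeds, function(s) cnn_train(..., seed = s))
  acc <- vapply(runs, function(r) r$final_test_acc, 0)
  list(
    runs = runs,
    accuracies = acc,
    mean_accuracy = mean(acc),
    best_accuracies = vapply(runs, function(r) r$best_test_acc, 0),
    seeds = seeds
  )
}
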