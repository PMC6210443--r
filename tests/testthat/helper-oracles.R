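# Independent reference implementations (naive loops, no shared code with the
# package internals) plus small fixtures used across the test files.

# direct triple-loop 1-D convolution: kern is out_maps x in_maps x k
naive_conv <- function(x, kern, bias, padding = "same") {
  k <- dim(kern)[3]
  Tin <- ncol(x)
  pl <- if (padding == "same") (k - 1) %/% 2 else 0
  pr <- if (padding == "same") k - 1 - pl else 0
  xp <- cbind(matrix(0, nrow(x), pl), x, matrix(0, nrow(x), pr))
  Tout <- Tin + pl + pr - k + 1
  out <- matrix(0, dim(kern)[1], Tout)
  for (f in seq_len(dim(kern)[1])) {
    for (t in seq_len(Tout)) {
      s <- 0
      for (m in seq_len(dim(kern)[2])) {
        for (j in seq_len(k)) s <- s + kern[f, m, j] * xp[m, t + j - 1]
      }
      out[f, t] <- s + bias[f]
    }
  }
  out
}

# exhaustive max over adjacent map groups
naive_pool <- function(x, pool = 2) {
  out <- matrix(0, nrow(x) / pool, ncol(x))
  for (m in seq_len(nrow(out))) {
    for (t in seq_len(ncol(x))) {
      out[m, t] <- max(x[(m - 1) * pool + seq_len(pool), t])
    }
  }
  out
}

# straight-line scalar re-implementation of the whole forward pass
naive_forward <- function(win, w, cfg) {
  feat <- c()
  for (c_i in seq_len(cfg$n_channels)) {
    cw <- if (cfg$shared_filters) 1L else c_i
    x <- win[c_i, , drop = FALSE]
    k1 <- array(w$conv1_w[, , cw], c(cfg$conv1_filters, 1, cfg$conv1_size))
    F1 <- naive_conv(x, k1, w$conv1_b[, cw], cfg$padding)
    k2 <- w$conv2_w[, , , cw, drop = FALSE]
    dim(k2) <- dim(k2)[1:3]
    F2 <- naive_conv(F1, k2, w$conv2_b[, cw], cfg$padding)
    Z <- pmax(naive_pool(F2, cfg$pool_size), 0)
    feat <- c(feat, as.numeric(Z))
  }
  H <- 1 / (1 + exp(-(w$pl1_w %*% feat + w$pl1_b)))
  s <- w$pl2_w %*% H + w$pl2_b
  e <- exp(s - max(s))
  as.numeric(e / sum(e))
}

# random miniature network (small channel count so oracle loops stay fast)
mini_config <- function(n_channels = 2, W = 6, f1 = 3, k1 = 3, f2 = 2, k2 = 3,
                        pool = 2, pl1 = 4, padding = "same") {
  suppressWarnings(cnn_config(
    W = W, conv1_filters = f1, conv1_size = k1,
    conv2_filters = f2, conv2_size = k2, pool_size = pool,
    pl1_outputs = pl1, n_channels = n_channels, padding = padding
  ))
}

rand_window <- function(cfg) {
  matrix(runif(cfg$n_channels * cfg$W), cfg$n_channels, cfg$W)
}

# initialized weights with a randomized (non-zero) output layer, so oracle
# and gradient checks exercise the full head rather than the uniform softmax
rand_weights <- function(cfg, seed = 1) {
  w <- cnn_init(cfg, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1000)
  w$pl2_w[] <- rnorm(length(w$pl2_w), sd = 0.3)
  w$pl2_b[] <- rnorm(length(w$pl2_b), sd = 0.1)
  w
}

# published Subject 1 confusion matrix (predicted rows x actual columns)
subject1_cm <- function() {
  matrix(
    c(905, 213, 61,
      64, 725, 157,
      71, 86, 1222),
    nrow = 3, byrow = TRUE,
    dimnames = list(predicted = c("2", "3", "7"), actual = c("2", "3", "7"))
  )
}

# short synthetic sessions for fast training-path tests
tiny_dataset <- function(minutes = 0.25, seed = 5) {
  generate_dataset(generator_config(session_minutes = minutes, seed = seed))
}

# deterministic label permutation without disturbing the ambient RNG stream
with_perm_seed <- function(labels, seed = 77) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(labels)
}
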