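# Channel-isolated CNN over 96 PSD channels. Each channel's 1 x W stream is
# processed by its own pair of stacked 1-D convolutions (no pooling between
# them), then feature maps are max-pooled in adjacent pairs along the map
# axis (time untouched), gated by ReLU, and only then do the 96 channels meet
# in the fully connected head: dense -> sigmoid -> dense -> softmax.

#' Network configuration
#'
#' Layer hyperparameters of the channel-isolated CNN. The defaults give the
#' published final architecture: 50 conv filters of width 5, then 20 filters
#' of width 3 per channel, pair-max pooling over the feature-map axis
#' (20 -> 10 maps), a 96-unit sigmoid dense layer and a 3-class softmax.
#'
#' `padding = "same"` (zero padding, output length preserved) is the default
#' because the published layer-by-layer output dimensions keep the time length
#' at W through both convolutions; `"valid"` (no padding) is available.
#' Filters are independent per channel by default -- there is no data flow
#' between channels before the fully connected layer; `shared_filters = TRUE`
#' ties one filter bank across all channels, for ablation.
#'
#' @param W Input window width in frames (16 = 1 s, 8 = 0.5 s).
#' @param conv1_filters,conv1_size First convolution: maps and kernel width.
#' @param conv2_filters,conv2_size Second convolution: maps and kernel width.
#' @param pool_size Pair size of the feature-map max pool (must divide
#'   `conv2_filters`); stride equals the pair size.
#' @param pl1_outputs Width of the dense sigmoid layer (96 in the final
#'   architecture; 200 is the hyperparameter-scan base).
#' @param n_classes Number of output classes.
#' @param padding `"same"` or `"valid"`.
#' @param shared_filters Share one conv bank across the 96 channels.
#' @param n_channels Number of input channels (96 for the 8 x 12 PSD layout).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(W = 16L,
                       conv1_filters = 50L, conv1_size = 5L,
                       conv2_filters = 20L, conv2_size = 3L,
                       pool_size = 2L,
                       pl1_outputs = 96L,
                       n_classes = 3L,
                       padding = c("same", "valid"),
                       shared_filters = FALSE,
                       n_channels = PSD_N_CHANNELS) {
  padding <- match.arg(padding)
  cfg <- list(
    W = as.integer(W), n_channels = as.integer(n_channels),
    conv1_filters = as.integer(conv1_filters), conv1_size = as.integer(conv1_size),
    conv2_filters = as.integer(conv2_filters), conv2_size = as.integer(conv2_size),
    pool_size = as.integer(pool_size),
    pl1_outputs = as.integer(pl1_outputs), n_classes = as.integer(n_classes),
    padding = padding, shared_filters = isTRUE(shared_filters)
  )
  if (cfg$conv1_size < 1 || cfg$conv2_size < 1) stop("conv kernel sizes must be >= 1")
  if (cfg$conv1_filters < 1 || cfg$conv2_filters < 1) stop("filter counts must be >= 1")
  if (cfg$conv1_size %% 2 == 0 || cfg$conv2_size %% 2 == 0) {
    warning("even conv kernel width: same-padding becomes asymmetric ",
            "(left floor((k-1)/2), right the rest)")
  }
  if (cfg$conv2_filters %% cfg$pool_size != 0) {
    stop("pool_size must divide conv2_filters (",
         cfg$conv2_filters, " maps, pool ", cfg$pool_size, ")")
  }
  if (cfg$pl1_outputs < cfg$n_classes) stop("pl1_outputs must be >= n_classes")
  if (cfg$padding == "valid") {
    w_left <- cfg$W - (cfg$conv1_size - 1L) - (cfg$conv2_size - 1L)
    if (w_left < 1) stop("window too short for two valid convolutions")
  }
  structure(cfg, class = "cnn_config")
}

# time length after both convolutions
conv_out_width <- function(config) {
  if (config$padding == "same") config$W
  else config$W - (config$conv1_size - 1L) - (config$conv2_size - 1L)
}

# length of the concatenated per-channel feature vector fed to the dense head
feature_dim <- function(config) {
  n_pool <- config$conv2_filters %/% config$pool_size
  config$n_channels * n_pool * conv_out_width(config)
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cnn_config> %d channels x %d frames (%s padding)\n",
      "  conv1 %d x %d -> conv2 %d x %d -> pool /%d -> ReLU\n",
      "  dense %d -> sigmoid -> dense %d -> softmax; filters %s per channel\n"
    ),
    x$n_channels, x$W, x$padding,
    x$conv1_filters, x$conv1_size, x$conv2_filters, x$conv2_size, x$pool_size,
    x$pl1_outputs, x$n_classes,
    if (x$shared_filters) "shared" else "independent"
  ))
  invisible(x)
}

#' Slice a window into per-channel streams
#'
#' The slicer input stage: partitions the 96 x W window into 96 independent
#' 1 x W channel streams. Stacking the slices in order reconstructs the
#' window exactly.
#'
#' @param window A 96 x W numeric matrix (or the `data` slice of a
#'   `window_set`).
#' @return List of 96 matrices of dimension 1 x W.
#' @export
slice_window <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) != PSD_N_CHANNELS) {
    stop("expected ", PSD_N_CHANNELS, " channel rows, got ", nrow(window))
  }
  lapply(seq_len(nrow(window)), function(k) window[k, , drop = FALSE])
}

# asymmetric zero-padding amounts for a width-k kernel under same padding
pad_split <- function(k) {
  left <- (k - 1L) %/% 2L
  c(left = left, right = k - 1L - left)
}

#' 1-D convolution of feature maps
#'
#' Cross-correlation with stride 1, the layer primitive of the network: each
#' output element is the dot product of a kernel with the aligned region of
#' the input maps, plus a per-output-map bias. `"same"` padding zero-pads the
#' time axis so the output keeps the input length; `"valid"` shrinks it by
#' `kernel width - 1`.
#'
#' @param maps_in Numeric matrix, input maps x time.
#' @param kernels Array `c(out_maps, in_maps, k)` of filter weights.
#' @param bias Per-output-map bias (scalar or length `out_maps`).
#' @param padding `"same"` or `"valid"`.
#' @return Matrix out_maps x output time length.
#' @export
conv1d <- function(maps_in, kernels, bias = 0, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  maps_in <- as.matrix(maps_in)
  dk <- dim(kernels)
  if (length(dk) != 3) stop("kernels must be an out_maps x in_maps x k array")
  if (dk[2] != nrow(maps_in)) {
    stop("kernel expects ", dk[2], " input maps, got ", nrow(maps_in))
  }
  k <- dk[3]
  T_in <- ncol(maps_in)
  if (padding == "valid" && k > T_in) stop("kernel longer than the input")
  pads <- if (padding == "same") pad_split(k) else c(left = 0L, right = 0L)
  T_out <- T_in + sum(pads) - k + 1L
  x <- cbind(
    matrix(0, nrow(maps_in), pads["left"]),
    maps_in,
    matrix(0, nrow(maps_in), pads["right"])
  )
  out <- matrix(0, dk[1], T_out)
  for (j in seq_len(k)) {
    out <- out + matrix(kernels[, , j], dk[1], dk[2]) %*%
      x[, j:(j + T_out - 1L), drop = FALSE]
  }
  out + bias
}

#' Max-pool feature maps in adjacent groups
#'
#' Pools along the feature-map axis, not time: output map m at time t is the
#' maximum of input maps `{pool*(m-1)+1, ..., pool*m}` at time t, so 20 maps
#' of length 16 become 10 maps of length 16.
#'
#' @param maps_in Numeric matrix, maps x time.
#' @param pool Group size (must divide the map count); stride equals `pool`.
#' @return Matrix with `nrow(maps_in) / pool` rows.
#' @export
pool_feature_maps <- function(maps_in, pool = 2L) {
  maps_in <- as.matrix(maps_in)
  m <- nrow(maps_in)
  if (m %% pool != 0) {
    stop("map count ", m, " not divisible by pool size ", pool)
  }
  out <- maps_in[seq.int(1L, m, by = pool), , drop = FALSE]
  if (pool > 1) {
    for (j in 2:pool) {
      out <- pmax(out, maps_in[seq.int(j, m, by = pool), , drop = FALSE])
    }
  }
  out
}

#' Initialize model weights
#'
#' All weight arrays are drawn with MSRA (He) initialization -- zero-mean
#' Gaussians of variance 2 / fan-in, suited to ReLU networks -- and biases
#' start at zero. Per-channel banks are independent draws unless the config
#' shares filters. (A zero-initialized output layer would start the loss at
#' exactly ln 3, but its first adaptive-gradient updates are sign-normalized
#' outer products of a rank-one residual, which leaves the output rows nearly
#' collinear and can trap training in a constant-prediction basin; the random
#' output layer avoids that degeneracy.)
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed; the same seed reproduces the same weights.
#' @return A `cnn_weights` list: `conv1_w` (`filters x k x banks`), `conv1_b`,
#'   `conv2_w` (`filters x in_maps x k x banks`), `conv2_b`, `pl1_w`, `pl1_b`,
#'   `pl2_w`, `pl2_b`, with the config attached as an attribute.
#' @export
cnn_init <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  banks <- if (config$shared_filters) 1L else config$n_channels
  fd <- feature_dim(config)
  with_seed(seed, {
    w <- list(
      conv1_w = array(
        msra_init(config$conv1_filters * config$conv1_size * banks,
                  fan_in = config$conv1_size),
        dim = c(config$conv1_filters, config$conv1_size, banks)
      ),
      conv1_b = matrix(0, config$conv1_filters, banks),
      conv2_w = array(
        msra_init(config$conv2_filters * config$conv1_filters *
                    config$conv2_size * banks,
                  fan_in = config$conv1_filters * config$conv2_size),
        dim = c(config$conv2_filters, config$conv1_filters, config$conv2_size, banks)
      ),
      conv2_b = matrix(0, config$conv2_filters, banks),
      pl1_w = matrix(msra_init(config$pl1_outputs * fd, fan_in = fd),
                     config$pl1_outputs, fd),
      pl1_b = numeric(config$pl1_outputs),
      pl2_w = matrix(msra_init(config$n_classes * config$pl1_outputs,
                               fan_in = config$pl1_outputs),
                     config$n_classes, config$pl1_outputs),
      pl2_b = numeric(config$n_classes)
    )
    structure(w, config = config, class = "cnn_weights")
  })
}

#' Zero-valued model weights
#'
#' All weights and biases exactly zero; the forward pass then yields the
#' uniform distribution over classes for any input.
#'
#' @param config A [cnn_config()].
#' @return A `cnn_weights` object.
#' @export
cnn_zero_weights <- function(config = cnn_config()) {
  w <- cnn_init(config, seed = 1L)
  for (nm in names(w)) w[[nm]][] <- 0
  w
}

#' @export
print.cnn_weights <- function(x, ...) {
  cfg <- attr(x, "config")
  pc <- count_parameters(cfg)
  cat(sprintf("<cnn_weights> %s filters, %d trainable parameters\n",
              if (cfg$shared_filters) "shared" else "per-channel", pc$total))
  print(pc$by_layer, row.names = FALSE)
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars under this package's conventions:
#' independent per-channel conv banks (unless shared) and biases in every
#' conv and dense layer.
#'
#' @param config A [cnn_config()], or a bare list with the same fields
#'   (zero-sized layers then count zero).
#' @return List with `total` and a `by_layer` data frame (weights, biases).
#' @export
count_parameters <- function(config = cnn_config()) {
  g <- function(nm, default = 0L) if (is.null(config[[nm]])) default else config[[nm]]
  banks <- if (isTRUE(g("shared_filters", FALSE))) 1L else g("n_channels", 0L)
  conv1_w <- banks * g("conv1_filters") * g("conv1_size")
  conv1_b <- banks * g("conv1_filters")
  conv2_w <- banks * g("conv2_filters") * g("conv1_filters") * g("conv2_size")
  conv2_b <- banks * g("conv2_filters")
  fd <- if (conv2_w > 0 && inherits(config, "cnn_config")) feature_dim(config) else {
    np <- if (g("pool_size") > 0) g("conv2_filters") %/% max(1L, g("pool_size")) else 0L
    g("n_channels") * np * g("W")
  }
  pl1_w <- g("pl1_outputs") * fd
  pl1_b <- g("pl1_outputs")
  pl2_w <- g("n_classes") * g("pl1_outputs")
  pl2_b <- g("n_classes")
  by_layer <- data.frame(
    layer = c("conv1", "conv2", "pl1", "pl2"),
    weights = c(conv1_w, conv2_w, pl1_w, pl2_w),
    biases = c(conv1_b, conv2_b, pl1_b, pl2_b)
  )
  list(total = sum(by_layer$weights) + sum(by_layer$biases), by_layer = by_layer)
}

# Batched forward pass over the compiled kernel. x: n_channels x W x B array.
# Returns class probabilities (n_classes x B) and the dense intermediates.
cnn_forward_batch <- function(weights, x) {
  cfg <- attr(weights, "config")
  d <- dim(x)
  if (length(d) != 3 || d[1] != cfg$n_channels || d[2] != cfg$W) {
    stop("input must be ", cfg$n_channels, " x ", cfg$W, " x B, got ",
         paste(d, collapse = " x "))
  }
  if (!is.double(x)) storage.mode(x) <- "double"
  out <- .cpp_forward(unclass(weights), x, unclass(cfg))
  if (any(!is.finite(out$probs))) {
    stop("non-finite values in the softmax output layer")
  }
  out
}

#' Forward pass for a single window
#'
#' Runs the full network -- slicer, per-channel convolution pair, pair-max
#' pooling, ReLU, dense sigmoid layer, dense output layer, softmax -- on one
#' 96 x W window.
#'
#' @param window A `96 x W` matrix.
#' @param weights A `cnn_weights` object (see [cnn_init()]).
#' @return Named probability vector over the classes (sums to 1).
#' @export
cnn_forward <- function(window, weights) {
  cfg <- attr(weights, "config")
  window <- as.matrix(window)
  x <- array(window, dim = c(nrow(window), ncol(window), 1L))
  p <- cnn_forward_batch(weights, x)$probs[, 1]
  names(p) <- as.character(PSD_CLASSES[seq_len(cfg$n_classes)])
  p
}

#' Predict class labels for a set of windows
#'
#' Argmax of the softmax output; exact probability ties resolve to the lowest
#' class code.
#'
#' @param weights A `cnn_weights` object.
#' @param windows A `window_set` or a `96 x W x n` array.
#' @param batch_size Windows per forward batch.
#' @param classes Class codes reported (positions match softmax outputs).
#' @return Integer vector of predicted class codes.
#' @export
cnn_predict <- function(weights, windows, batch_size = 512L,
                        classes = PSD_CLASSES) {
  x <- if (inherits(windows, "window_set")) windows$data else windows
  n <- dim(x)[3]
  if (n == 0) return(integer(0))
  out <- integer(n)
  for (at in seq.int(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    p <- cnn_forward_batch(weights, x[, , idx, drop = FALSE])$probs
    out[idx] <- max.col(t(p), ties.method = "first")
  }
  classes[out]
}
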