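# Synthetic PSD sessions. The generator reproduces the structural facts the
# classifier relies on -- positive band-power values, 16 frames/s, ~4-minute
# sessions, a task switch every 15 s, class-conditional band-power effects --
# as a log-normal model with AR(1) temporal correlation on the log scale.
# It is a synthetic stand-in for testing, not a model of any recorded dataset.

#' Configuration for the synthetic PSD session generator
#'
#' Defaults emulate the acquisition protocol the classifier targets: 8
#' electrodes x 12 sub-bands sampled 16 times per second, sessions of about
#' 4 minutes, and a switch between the three mental tasks every 15 s (240
#' frames). Channel values are `exp(baseline + class_effect + AR(1) noise)`,
#' hence strictly positive.
#'
#' The default class effects imitate motor-imagery physiology purely to make
#' the classes separable: left-hand imagery attenuates mu/low-beta power over
#' right-hemisphere sensorimotor channels (C4, CP2, P4), right-hand imagery
#' mirrors this on the left (C3, CP1, P3), and word generation raises
#' parietal (P3, Pz, P4) alpha-band power.
#'
#' @param session_minutes Session length in minutes.
#' @param block_seconds Seconds between task switches.
#' @param class_effects 3 x 96 matrix of per-class mean log-power offsets,
#'   rows named by class code ("2", "3", "7").
#' @param noise_sigma Marginal standard deviation of the AR(1) log-noise.
#' @param ar_coeff AR(1) coefficient of the log-noise, in [0, 1).
#' @param baseline Length-96 vector of baseline log-powers.
#' @param seed Integer seed; identical configs generate identical sessions.
#' @return A `generator_config` list.
#' @export
generator_config <- function(session_minutes = 4,
                             block_seconds = 15,
                             class_effects = default_class_effects(),
                             noise_sigma = 0.5,
                             ar_coeff = 0.6,
                             baseline = default_baseline(),
                             seed = 1L) {
  if (session_minutes <= 0) stop("session_minutes must be positive")
  if (block_seconds <= 0) stop("block_seconds must be positive")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must lie in [0, 1)")
  class_effects <- as.matrix(class_effects)
  if (!identical(dim(class_effects), c(3L, PSD_N_CHANNELS)) &&
      !all(dim(class_effects) == c(3, PSD_N_CHANNELS))) {
    stop("class_effects must be a 3 x 96 matrix")
  }
  if (is.null(rownames(class_effects))) {
    rownames(class_effects) <- as.character(PSD_CLASSES)
  }
  stopifnot(length(baseline) == PSD_N_CHANNELS)
  structure(
    list(
      n_electrodes = PSD_N_ELECTRODES, n_subbands = PSD_N_SUBBANDS,
      frame_rate = PSD_FRAME_RATE,
      session_minutes = session_minutes, block_seconds = block_seconds,
      classes = PSD_CLASSES, class_effects = class_effects,
      noise_sigma = noise_sigma, ar_coeff = ar_coeff,
      baseline = baseline, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Default class-conditional log-power offsets
#'
#' @param magnitude Peak offset size on the log-power scale. The default 0.8
#'   against the default noise sigma of 0.5 makes single frames strongly
#'   separable, which is what the end-to-end classifier checks require.
#' @return A 3 x 96 matrix, rows named "2", "3", "7".
#' @export
default_class_effects <- function(magnitude = 0.8) {
  eff <- matrix(0, 3, PSD_N_CHANNELS,
                dimnames = list(as.character(PSD_CLASSES), NULL))
  mu <- 1:3        # 8-14 Hz sub-bands
  beta <- 7:8      # 20-24 Hz sub-bands
  right_hem <- c(3L, 5L, 8L)  # C4, CP2, P4
  left_hem <- c(1L, 4L, 6L)   # C3, CP1, P3
  parietal <- c(6L, 7L, 8L)   # P3, Pz, P4
  # class 2, left-hand imagery: desynchronization over the right hemisphere
  eff["2", channel_index(rep(right_hem, each = 3), rep(mu, 3))] <- -magnitude
  eff["2", channel_index(rep(right_hem, each = 2), rep(beta, 3))] <- -magnitude / 2
  # class 3, right-hand imagery: mirror image
  eff["3", channel_index(rep(left_hem, each = 3), rep(mu, 3))] <- -magnitude
  eff["3", channel_index(rep(left_hem, each = 2), rep(beta, 3))] <- -magnitude / 2
  # class 7, word generation: parietal alpha increase
  eff["7", channel_index(rep(parietal, each = 3), rep(mu, 3))] <- magnitude * 0.75
  eff
}

#' Default baseline log-power per channel
#'
#' Log-power declines mildly with sub-band frequency, giving the familiar
#' decreasing band-power profile without attempting a realistic 1/f spectrum.
#' Band-power units are arbitrary; the baseline is set so typical band powers
#' are about 0.1. At this scale the concatenated convolution features reach
#' the dense sigmoid layer inside its responsive range at initialization --
#' larger scales saturate the sigmoid and stall adaptive-gradient training,
#' since the network applies no input normalization.
#'
#' @return Length-96 numeric vector.
#' @export
default_baseline <- function() {
  s <- channel_layout()$subband_index
  -2 - 0.1 * (s - 1)
}

#' Generate one labelled synthetic PSD session
#'
#' Draws a block label schedule (uniform over the three tasks, no immediate
#' repetition, one block per `block_seconds`), then per-channel log-power as
#' baseline + class effect + AR(1) noise, exponentiated. The same config
#' (including seed) always yields the identical session.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @param subject_id Identifier stored on the session.
#' @return A labelled [psd_session()] of
#'   `session_minutes * 60 * 16` frames.
#' @export
generate_session <- function(config = generator_config(), seed = config$seed,
                             subject_id = "synthetic") {
  stopifnot(inherits(config, "generator_config"))
  N <- as.integer(round(config$session_minutes * 60 * config$frame_rate))
  if (N < 1L) stop("degenerate config: zero-length session")
  block_len <- as.integer(round(config$block_seconds * config$frame_rate))
  n_blocks <- ceiling(N / block_len)
  with_seed(seed, {
    block_labels <- integer(n_blocks)
    block_labels[1] <- sample(config$classes, 1)
    if (n_blocks > 1) {
      for (b in 2:n_blocks) {
        block_labels[b] <- sample(setdiff(config$classes, block_labels[b - 1]), 1)
      }
    }
    labels <- rep(block_labels, each = block_len)[seq_len(N)]
    sig <- config$noise_sigma
    innov_sd <- sig * sqrt(1 - config$ar_coeff^2)
    eps <- matrix(rnorm(N * PSD_N_CHANNELS, sd = innov_sd), N, PSD_N_CHANNELS)
    eps[1, ] <- rnorm(PSD_N_CHANNELS, sd = sig)
    if (config$ar_coeff > 0 && N > 1) {
      eps <- apply(eps, 2, function(x) {
        as.numeric(stats::filter(x, config$ar_coeff, method = "recursive"))
      })
    }
    logp <- eps +
      rep(config$baseline, each = N) +
      config$class_effects[as.character(labels), , drop = FALSE]
    psd_session(exp(logp), labels, subject_id)
  })
}

#' Generate a train/test dataset of synthetic sessions
#'
#' Mirrors the distribution format the classifier targets: several labelled
#' training sessions plus a labelled test session per subject, all drawn
#' independently from the same generative law.
#'
#' @param config A [generator_config()]; its seed determines the per-session
#'   seeds.
#' @param n_train Number of training sessions (default 3).
#' @param n_test Number of test sessions (default 1).
#' @return List with elements `train` and `test`, each a list of sessions.
#' @export
generate_dataset <- function(config = generator_config(), n_train = 3L, n_test = 1L) {
  stopifnot(n_train >= 1, n_test >= 1)
  seeds <- derive_seeds(config$seed, n_train + n_test)
  sessions <- lapply(seq_len(n_train + n_test), function(i) {
    role <- if (i <= n_train) sprintf("train_%d", i) else sprintf("test_%d", i - n_train)
    generate_session(config, seed = seeds[i], subject_id = paste0("synthetic/", role))
  })
  list(
    train = sessions[seq_len(n_train)],
    test = sessions[n_train + seq_len(n_test)]
  )
}
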