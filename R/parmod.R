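# One-factor hyperparameter scan: perturb one layer parameter at a time by
# +/-25% / +/-50% with ceiling rounding, retrain with matched seeds, and
# report the change in accuracy progress over training against the base run.

#' Ceiling-rounded parameter modification
#'
#' `ceiling(x * (1 + delta))`: the rule that derives each scan value from its
#' base, rounding up to the nearest integer. For the published bases it gives
#' first-conv sizes \{3, 4, 7, 8\} from 5, second-conv sizes \{4, 5\} from 3,
#' and dense widths \{100, 150, 250, 300\} from 200.
#'
#' @param x Base parameter value (positive integer).
#' @param delta Modification factor, with `1 + delta > 0` (the scan uses
#'   -0.50, -0.25, +0.25, +0.50).
#' @return The modified integer value (always >= 1 or an error).
#' @export
modified_param <- function(x, delta) {
  stopifnot(length(x) == 1, length(delta) == 1)
  if (x < 1 || x != round(x)) stop("base value must be a positive integer")
  if (1 + delta <= 0) stop("1 + delta must be positive")
  r <- as.integer(ceiling(x * (1 + delta)))
  if (r < 1L) stop("modified value ", r, " is not a valid layer size")
  r
}

scan_label <- function(parameter, delta, value) {
  pretty <- c(conv1_size = "CONV1 filter size", conv2_size = "CONV2 filter size",
              pl1_outputs = "PL1 outputs")
  what <- if (parameter %in% names(pretty)) pretty[[parameter]] else parameter
  unit <- if (parameter %in% c("conv1_size", "conv2_size")) {
    sprintf("(%d×1)", value)
  } else {
    sprintf("(%d)", value)
  }
  sprintf("%+d%%—%s %s", as.integer(delta * 100), what, unit)
}

#' Run the one-factor parameter scan
#'
#' For each (parameter, delta) cell: derive the modified value with
#' [modified_param()], train the network with only that parameter changed,
#' and measure the accuracy-progress change versus the base run -- the mean
#' difference (modified minus base) of test-accuracy checkpoints over matched
#' iterations, in percentage points, rounded to the nearest integer. Seeds
#' are matched between the base and every modified run so initialization
#' noise cancels. Cells whose configuration cannot train are reported as
#' failed and the scan continues.
#'
#' @param train_sessions,test_sessions Labelled sessions passed to
#'   [cnn_train()].
#' @param base_config The base [cnn_config()]. The scan's published base uses
#'   `pl1_outputs = 200`.
#' @param parameters Character vector of parameters to scan (any of
#'   `"conv1_size"`, `"conv2_size"`, `"pl1_outputs"`).
#' @param deltas Modification factors applied to each parameter.
#' @param seeds Seeds shared by the base run and every cell (one run per
#'   seed, results averaged).
#' @param ... Further arguments to [cnn_train()] (`max_iter`, `batch_size`,
#'   `eval_every`, ...).
#' @return Data frame with one row per cell: `parameter`, `delta`,
#'   `base_value`, `modified_value`, `label`, `change_pct` (rounded
#'   percentage points; `NA` for failed cells), `status`.
#' @export
run_scan <- function(train_sessions, test_sessions, base_config = cnn_config(pl1_outputs = 200L),
                     parameters = c("conv1_size", "conv2_size", "pl1_outputs"),
                     deltas = c(-0.50, -0.25, 0.25, 0.50),
                     seeds = 1L, ...) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  run_curves <- function(config) {
    lapply(seeds, function(s) {
      cnn_train(train_sessions, test_sessions, config = config, seed = s, ...)$history
    })
  }
  base_curves <- run_curves(base_config)

  cells <- expand.grid(delta = deltas, parameter = parameters,
                       stringsAsFactors = FALSE)[, c("parameter", "delta")]
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    par <- cells$parameter[r]
    delta <- cells$delta[r]
    base_value <- base_config[[par]]
    out <- data.frame(
      parameter = par, delta = delta, base_value = base_value,
      modified_value = NA_integer_, label = NA_character_,
      change_pct = NA_real_, status = "ok", stringsAsFactors = FALSE
    )
    result <- tryCatch({
      value <- modified_param(base_value, delta)
      out$modified_value <- value
      out$label <- scan_label(par, delta, value)
      if (delta == 0 || value == base_value) {
        out$change_pct <- 0
        out$status <- "ok (base value)"
        return(out)
      }
      args <- as.list(unclass(base_config))
      args[[par]] <- value
      args$padding <- base_config$padding
      config <- withCallingHandlers(
        do.call(cnn_config, args),
        warning = function(w) {
          out$status <<- paste0("flagged: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      mod_curves <- run_curves(config)
      diffs <- mapply(function(m, b) {
        k <- min(nrow(m), nrow(b))
        mean(m$test_acc[seq_len(k)] - b$test_acc[seq_len(k)])
      }, mod_curves, base_curves)
      out$change_pct <- round(mean(diffs) * 100)
      out
    }, error = function(e) {
      out$status <- paste0("failed: ", conditionMessage(e))
      out
    })
    result
  })
  do.call(rbind, rows)
}
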