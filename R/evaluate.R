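# Multi-class evaluation suite: confusion matrices (predicted rows x actual
# columns), overall success rate, one-vs-rest binarization, ROC point
# parameters, mean/sd aggregation, per-frame effectiveness, and
# generalization error.

#' Multi-class confusion matrix
#'
#' Entry (r, c) counts instances predicted as `class_order[r]` whose actual
#' class is `class_order[c]` -- predicted classes on rows, actual classes on
#' columns.
#'
#' @param predicted,actual Equal-length vectors of class codes.
#' @param class_order Class codes fixing row/column order (default 2, 3, 7).
#' @return A K x K integer matrix with dimnames `predicted` and `actual`.
#' @export
confusion_matrix <- function(predicted, actual, class_order = PSD_CLASSES) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  bad <- setdiff(unique(c(predicted, actual)), class_order)
  if (length(bad)) {
    stop("labels outside the class order: ", paste(bad, collapse = ", "))
  }
  p <- factor(predicted, levels = class_order)
  a <- factor(actual, levels = class_order)
  cm <- table(p, a)
  m <- matrix(as.integer(cm), length(class_order), length(class_order),
              dimnames = list(predicted = as.character(class_order),
                              actual = as.character(class_order)))
  m
}

#' Overall success rate
#'
#' The trace of the confusion matrix divided by the total number of
#' classified instances; multi-class, symmetrical, in [0, 1].
#'
#' @param cm A square confusion matrix (predicted rows x actual columns).
#' @return Numeric scalar in [0, 1].
#' @export
osr <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix has no instances")
  sum(diag(cm)) / n
}

#' One-vs-rest binarization of a confusion matrix
#'
#' Presents the multi-class problem as a binary class/non-class one for a
#' chosen class: TP is the diagonal cell, FP the rest of the predicted row,
#' FN the rest of the actual column, TN everything else, so
#' TP + FP + FN + TN = N.
#'
#' @param cm A square confusion matrix (predicted rows x actual columns).
#' @param class Class code (must appear in the matrix dimnames).
#' @return Named list `TP`, `FP`, `FN`, `TN`, `N`, `class`.
#' @export
binarize_one_vs_rest <- function(cm, class) {
  cm <- as.matrix(cm)
  i <- match(as.character(class), rownames(cm))
  if (is.na(i)) stop("class ", class, " not found in the confusion matrix")
  TP <- cm[i, i]
  FP <- sum(cm[i, -i])
  FN <- sum(cm[-i, i])
  TN <- sum(cm[-i, -i])
  list(TP = TP, FP = FP, FN = FN, TN = TN, N = sum(cm), class = class)
}

#' ROC point parameters of a binary confusion
#'
#' Accuracy, sensitivity, specificity and the predictive values of a
#' class/non-class split:
#' `ACC = (TP + TN) / N`, `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)`,
#' `PPV = TP / (TP + FP)`, `NPV = TN / (TN + FN)`. A parameter whose
#' denominator is zero is undefined and returned as `NA`, not 0.
#'
#' @param b A binary confusion from [binarize_one_vs_rest()] (or any list
#'   with `TP`, `FP`, `FN`, `TN`).
#' @return Named numeric vector `ACC`, `TPR`, `TNR`, `PPV`, `NPV`.
#' @export
roc_params <- function(b) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  N <- b$TP + b$FP + b$FN + b$TN
  c(
    ACC = rate(b$TP + b$TN, N),
    TPR = rate(b$TP, b$TP + b$FN),
    TNR = rate(b$TN, b$TN + b$FP),
    PPV = rate(b$TP, b$TP + b$FP),
    NPV = rate(b$TN, b$TN + b$FN)
  )
}

#' Per-class ROC table for a confusion matrix
#'
#' Convenience wrapper: one-vs-rest parameters for every class plus the
#' overall success rate, values rounded half-up to 4 decimals for reporting
#' (set `digits = NULL` for full precision).
#'
#' @param cm A square confusion matrix.
#' @param digits Decimal places for half-up rounding, or `NULL`.
#' @return Data frame with columns `class`, `OSR`, `ACC`, `TPR`, `TNR`,
#'   `PPV`, `NPV` (OSR repeated on each row).
#' @export
roc_table <- function(cm, digits = 4) {
  classes <- rownames(as.matrix(cm))
  rows <- lapply(classes, function(cl) {
    p <- roc_params(binarize_one_vs_rest(cm, cl))
    data.frame(class = cl, OSR = osr(cm), t(p))
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' Aggregate ROC parameters across subjects
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' parameter across a list of per-subject values.
#'
#' @param values A list of named numeric vectors (e.g. from [roc_params()]),
#'   or a numeric matrix with one row per subject.
#' @return Data frame with rows `mean` and `sd`.
#' @export
aggregate_roc <- function(values) {
  m <- if (is.matrix(values)) values else do.call(rbind, values)
  if (nrow(m) < 1) stop("nothing to aggregate")
  means <- colMeans(m, na.rm = TRUE)
  sds <- if (nrow(m) >= 2) apply(m, 2, sd, na.rm = TRUE) else rep(NA_real_, ncol(m))
  out <- rbind(mean = means, sd = sds)
  as.data.frame(out)
}

#' Per-frame classification effectiveness
#'
#' Percentage of frames whose prediction matches the label column of the test
#' session. With causal windows of width W and stride 1, the first `W - 1`
#' frames have no complete preceding window; they are excluded from scoring
#' and the exclusion count is reported.
#'
#' @param predicted Predicted class codes for the scored frames, in frame
#'   order (e.g. one per window from [cnn_predict()] at stride 1).
#' @param session The labelled test [psd_session()].
#' @return List with `percent` (0--100), `n_scored`, `n_excluded`,
#'   `n_correct`.
#' @export
effectiveness <- function(predicted, session) {
  stopifnot(inherits(session, "psd_session"))
  if (!is_labelled(session)) stop("effectiveness needs a labelled test session")
  N <- n_frames(session)
  n <- length(predicted)
  if (n > N) stop("more predictions (", n, ") than frames (", N, ")")
  excluded <- N - n
  actual <- session$labels[(excluded + 1L):N]
  correct <- sum(predicted == actual)
  list(
    percent = 100 * correct / n,
    n_scored = n,
    n_excluded = excluded,
    n_correct = correct
  )
}

#' Score a trained model against a labelled session
#'
#' Windows the session causally (stride 1, last-frame labels), predicts every
#' window, and reports per-frame effectiveness together with the confusion
#' matrix and per-class ROC parameters.
#'
#' @param weights A `cnn_weights` object.
#' @param session A labelled [psd_session()].
#' @param stride Frame stride between scored windows.
#' @return List with `effectiveness`, `confusion`, `roc` (see [roc_table()]),
#'   `predicted`, `actual`.
#' @export
evaluate_session <- function(weights, session, stride = 1L) {
  cfg <- attr(weights, "config")
  w <- window_session(session, W = cfg$W, stride = stride,
                      label_policy = "last-frame")
  predicted <- cnn_predict(weights, w)
  eff <- if (stride == 1L) {
    effectiveness(predicted, session)
  } else {
    list(percent = 100 * mean(predicted == w$labels),
         n_scored = length(predicted),
         n_excluded = n_frames(session) - length(predicted),
         n_correct = sum(predicted == w$labels))
  }
  cm <- confusion_matrix(predicted, w$labels)
  list(
    effectiveness = eff,
    confusion = cm,
    roc = roc_table(cm),
    predicted = predicted,
    actual = w$labels
  )
}

#' Generalization error
#'
#' Training-phase accuracy minus test accuracy, in percentage points: the
#' gap that measures how well the learned classifier transfers to unseen
#' data.
#'
#' @param train_accuracy,test_accuracy Accuracies in percent (0--100).
#' @return Numeric difference in percentage points.
#' @export
generalization_error <- function(train_accuracy, test_accuracy) {
  if (any(train_accuracy < 0 | train_accuracy > 100) ||
      any(test_accuracy < 0 | test_accuracy > 100)) {
    stop("accuracies must be percentages in [0, 100]")
  }
  train_accuracy - test_accuracy
}
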