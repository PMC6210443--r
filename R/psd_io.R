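# Feature files hold one frame per line: 96 whitespace-separated PSD values
# (8 electrodes x 12 sub-bands), labelled files carry the class code as a 97th
# column. Frames arrive every 62.5 ms (16 per second).

PSD_ELECTRODES <- c("C3", "Cz", "C4", "CP1", "CP2", "P3", "Pz", "P4")
PSD_N_ELECTRODES <- 8L
PSD_N_SUBBANDS <- 12L
PSD_N_CHANNELS <- 96L
PSD_FRAME_RATE <- 16L
PSD_CLASSES <- c(2L, 3L, 7L)

#' Electrode/sub-band layout of the 96 PSD channels
#'
#' Channels are ordered electrode-major: channel `(e - 1) * 12 + s` is
#' electrode `e` (in file column order C3, Cz, C4, CP1, CP2, P3, Pz, P4) and
#' sub-band `s` (2 Hz bands ascending, 8--10 Hz up to 28--30 Hz). This
#' convention is fixed package-wide so that feature files, window tensors and
#' model weights can never disagree about row identity.
#'
#' @return A data frame with one row per channel: `channel`, `electrode`,
#'   `electrode_index`, `subband_index`, `band_hz` (the sub-band's frequency,
#'   8 to 30 Hz in 2 Hz steps).
#' @examples
#' head(channel_layout())
#' @export
channel_layout <- function() {
  e <- rep(seq_len(PSD_N_ELECTRODES), each = PSD_N_SUBBANDS)
  s <- rep(seq_len(PSD_N_SUBBANDS), times = PSD_N_ELECTRODES)
  data.frame(
    channel = seq_len(PSD_N_CHANNELS),
    electrode = PSD_ELECTRODES[e],
    electrode_index = e,
    subband_index = s,
    band_hz = 8 + 2 * (s - 1)
  )
}

#' Map (electrode, sub-band) to a channel row index
#'
#' @param electrode_index Electrode position 1..8 (file column order).
#' @param subband_index Sub-band position 1..12 (8--10 Hz = 1).
#' @return Integer channel index in 1..96.
#' @examples
#' channel_index(1, 1)  # C3, 8-10 Hz -> 1
#' channel_index(8, 12) # P4, 28-30 Hz -> 96
#' @export
channel_index <- function(electrode_index, subband_index) {
  stopifnot(
    all(electrode_index %in% seq_len(PSD_N_ELECTRODES)),
    all(subband_index %in% seq_len(PSD_N_SUBBANDS))
  )
  as.integer((electrode_index - 1L) * PSD_N_SUBBANDS + subband_index)
}

#' Construct a PSD session
#'
#' A session is an ordered sequence of feature frames: a numeric matrix with
#' one row per 62.5 ms frame and 96 columns (see [channel_layout()]), plus an
#' optional per-frame class label in \{2, 3, 7\} (left-hand imagery, right-hand
#' imagery, word generation).
#'
#' @param values Numeric matrix, frames x 96. All values must be finite and
#'   non-negative (they are power spectral densities).
#' @param labels Optional integer vector of class codes, one per frame.
#' @param subject_id Optional identifier carried through reports.
#' @return An object of class `psd_session` with elements `values`, `labels`
#'   (possibly `NULL`) and `subject_id`.
#' @export
psd_session <- function(values, labels = NULL, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && ncol(values) != PSD_N_CHANNELS) {
    stop("a session needs exactly ", PSD_N_CHANNELS, " PSD values per frame, got ",
         ncol(values), " columns")
  }
  if (!all(is.finite(values))) {
    stop("session contains non-finite PSD values")
  }
  if (any(values < 0)) {
    stop("session contains negative PSD values")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) {
      stop("length(labels) must equal the number of frames")
    }
    bad <- setdiff(unique(labels), PSD_CLASSES)
    if (length(bad)) {
      stop("labels outside the task code set {2, 3, 7}: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(
    list(values = values, labels = labels, subject_id = subject_id),
    class = "psd_session"
  )
}

#' Number of frames in a session
#' @param session A `psd_session`.
#' @return Integer frame count.
#' @export
n_frames <- function(session) nrow(session$values)

#' Is the session labelled?
#' @param session A `psd_session`.
#' @return `TRUE` if per-frame class labels are present.
#' @export
is_labelled <- function(session) !is.null(session$labels)

#' @export
print.psd_session <- function(x, ...) {
  n <- n_frames(x)
  cat(sprintf(
    "<psd_session> %d frames (%.1f s at %d Hz), %s",
    n, n / PSD_FRAME_RATE, PSD_FRAME_RATE,
    if (is_labelled(x)) "labelled" else "unlabelled"
  ))
  if (!is.na(x$subject_id)) cat(", subject ", x$subject_id, sep = "")
  cat("\n")
  if (is_labelled(x) && n > 0) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read a PSD feature file
#'
#' Parses a whitespace-delimited ASCII feature file: one frame per line, 96
#' PSD values, and -- when `labelled = TRUE` -- the class code as a 97th
#' column. Blank lines are ignored. Errors name the offending (original)
#' line number.
#'
#' @param path Path to the feature file.
#' @param labelled Whether lines carry the 97th label column.
#' @param subject_id Optional identifier stored on the session.
#' @return A [psd_session()].
#' @export
read_feature_file <- function(path, labelled = TRUE, subject_id = NA_character_) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    return(psd_session(matrix(numeric(0), 0, PSD_N_CHANNELS), subject_id = subject_id))
  }
  tokens <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  want <- PSD_N_CHANNELS + as.integer(labelled)
  lens <- lengths(tokens)
  if (any(lens != want)) {
    bad <- which(lens != want)[1]
    stop(sprintf(
      "line %d of %s: expected %d whitespace-separated tokens, found %d",
      keep[bad], path, want, lens[bad]
    ))
  }
  flat <- suppressWarnings(as.numeric(unlist(tokens)))
  mat <- matrix(flat, nrow = length(keep), ncol = want, byrow = TRUE)
  if (anyNA(mat) || !all(is.finite(mat))) {
    bad <- which(!is.finite(mat[, seq_len(want), drop = FALSE]), arr.ind = TRUE)
    stop(sprintf(
      "line %d of %s: non-numeric or non-finite value", keep[bad[1, 1]], path
    ))
  }
  labels <- NULL
  if (labelled) {
    raw <- mat[, want]
    labels <- as.integer(round(raw))
    if (any(raw != labels)) {
      stop("non-integer class label in ", path)
    }
  }
  psd_session(mat[, seq_len(PSD_N_CHANNELS), drop = FALSE], labels, subject_id)
}

#' Write a PSD feature file
#'
#' Emits the format read by [read_feature_file()]: one line per frame, 96
#' values (10 significant digits), then the class label when the session is
#' labelled.
#'
#' @param session A non-empty [psd_session()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_file <- function(session, path) {
  stopifnot(inherits(session, "psd_session"))
  if (n_frames(session) == 0) stop("refusing to write an empty session")
  body <- apply(session$values, 1, function(row) {
    paste(sprintf("%.10g", row), collapse = " ")
  })
  if (is_labelled(session)) {
    body <- paste(body, session$labels)
  }
  ok <- tryCatch({
    writeLines(body, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write feature file ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Cut a session into fixed-width network input windows
#'
#' Extracts `96 x W` blocks of consecutive frames (the network's input unit:
#' W = 16 frames is 1 s, W = 8 is 0.5 s). With stride 1 each frame beyond the
#' first `W - 1` terminates exactly one window, so per-frame predictions align
#' with the label column of the test file.
#'
#' Label policies for labelled sessions:
#' \describe{
#'   \item{`last-frame`}{the label of the window's final frame (causal; the
#'     default, matching an online reading of the classifier).}
#'   \item{`majority`}{the most frequent label in the window; ties go to the
#'     lowest class code.}
#'   \item{`pure-only`}{windows spanning a class switch are dropped.}
#' }
#'
#' @param session A [psd_session()].
#' @param W Window width in frames, normally 8 or 16.
#' @param stride Frame step between consecutive windows.
#' @param label_policy One of `"last-frame"`, `"majority"`, `"pure-only"`.
#' @return A `window_set`: list with `data` (96 x W x n array, rows ordered as
#'   [channel_layout()]), `labels` (or `NULL`), `starts` and `ends` (frame
#'   indices), `W`, `stride`, `label_policy`, `n_dropped`.
#' @export
window_session <- function(session, W = 16L, stride = 1L,
                           label_policy = c("last-frame", "majority", "pure-only")) {
  stopifnot(inherits(session, "psd_session"))
  label_policy <- match.arg(label_policy)
  W <- as.integer(W)
  stride <- as.integer(stride)
  if (W < 1L || stride < 1L) stop("W and stride must be positive")
  if (!W %in% c(8L, 16L)) {
    warning("window width ", W, " frames differs from the standard 8 (0.5 s) or 16 (1 s)")
  }
  N <- n_frames(session)
  if (N < W) {
    warning("session of ", N, " frames is shorter than the window (", W, "); no windows")
    return(empty_window_set(W, stride, label_policy, is_labelled(session)))
  }
  starts <- seq.int(1L, N - W + 1L, by = stride)
  n <- length(starts)
  ch <- t(session$values) # 96 x N
  cols <- rep(starts, each = W) + rep.int(0:(W - 1L), n)
  data <- ch[, cols, drop = FALSE]
  dim(data) <- c(PSD_N_CHANNELS, W, n)

  labels <- NULL
  n_dropped <- 0L
  ends <- starts + W - 1L
  if (is_labelled(session)) {
    lab_mat <- matrix(session$labels[cols], nrow = W, ncol = n)
    labels <- switch(label_policy,
      "last-frame" = lab_mat[W, ],
      "majority" = apply(lab_mat, 2, function(l) {
        tab <- table(l)
        as.integer(names(tab)[which.max(tab)]) # ties -> lowest code (table is sorted)
      }),
      "pure-only" = lab_mat[1, ]
    )
    if (label_policy == "pure-only") {
      pure <- colSums(lab_mat != rep(lab_mat[1, ], each = W)) == 0L
      n_dropped <- sum(!pure)
      data <- data[, , pure, drop = FALSE]
      labels <- labels[pure]
      starts <- starts[pure]
      ends <- ends[pure]
    }
    labels <- as.integer(labels)
  }
  structure(
    list(
      data = data, labels = labels, starts = starts, ends = ends,
      W = W, stride = stride, label_policy = label_policy,
      n_dropped = n_dropped, channel_order = "electrode-major"
    ),
    class = "window_set"
  )
}

empty_window_set <- function(W, stride, label_policy, labelled) {
  structure(
    list(
      data = array(numeric(0), dim = c(PSD_N_CHANNELS, W, 0)),
      labels = if (labelled) integer(0) else NULL,
      starts = integer(0), ends = integer(0),
      W = W, stride = stride, label_policy = label_policy,
      n_dropped = 0L, channel_order = "electrode-major"
    ),
    class = "window_set"
  )
}

#' Number of windows in a window set
#' @param windows A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(windows) dim(windows$data)[3]

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows of %d x %d (stride %d, policy %s)%s\n",
    n_windows(x), PSD_N_CHANNELS, x$W, x$stride, x$label_policy,
    if (x$n_dropped > 0) sprintf(", %d dropped at class switches", x$n_dropped) else ""
  ))
  invisible(x)
}

# rbind several sessions' windows into one set (training pools all sessions)
combine_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (length(sets) == 1) return(sets[[1]])
  W <- sets[[1]]$W
  stopifnot(all(vapply(sets, function(s) s$W, 0L) == W))
  n <- vapply(sets, n_windows, 0L)
  data <- array(0, dim = c(PSD_N_CHANNELS, W, sum(n)))
  at <- 0L
  for (s in sets) {
    if (n_windows(s) > 0) data[, , at + seq_len(n_windows(s))] <- s$data
    at <- at + n_windows(s)
  }
  labels <- if (!is.null(sets[[1]]$labels)) {
    unlist(lapply(sets, `[[`, "labels"), use.names = FALSE)
  }
  structure(
    list(
      data = data, labels = labels,
      starts = unlist(lapply(sets, `[[`, "starts")),
      ends = unlist(lapply(sets, `[[`, "ends")),
      W = W, stride = sets[[1]]$stride, label_policy = sets[[1]]$label_policy,
      n_dropped = sum(vapply(sets, function(s) s$n_dropped, 0L)),
      channel_order = "electrode-major"
    ),
    class = "window_set"
  )
}
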