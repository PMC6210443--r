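# Portable weight container: a JSON header describing the config, the
# channel-order convention and every array's dimensions, next to a flat
# little-endian float64 binary holding the arrays in header order.

#' Save model weights
#'
#' Writes `<path>.json` (network config, channel-order convention, array
#' names and dimensions) and `<path>.bin` (all arrays as little-endian
#' float64, concatenated in header order).
#'
#' @param weights A `cnn_weights` object.
#' @param path Output path stem (extensions are appended).
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "cnn_weights"))
  cfg <- attr(weights, "config")
  arrays <- lapply(unclass(weights), function(a) {
    if (is.null(dim(a))) length(a) else dim(a)
  })
  header <- list(
    format = "eegcnn-weights-1",
    channel_order = "electrode-major",
    config = unclass(cfg),
    arrays = arrays
  )
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(weights)) {
    writeBin(as.numeric(weights[[nm]]), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Load model weights
#'
#' Reads a container written by [save_weights()].
#'
#' @param path Path stem used at save time.
#' @return A `cnn_weights` object.
#' @export
load_weights <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$format, "eegcnn-weights-1")) {
    stop("unrecognized weight container format at ", path)
  }
  cfg <- do.call(cnn_config, header$config[setdiff(names(header$config), character(0))])
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  w <- list()
  for (nm in names(header$arrays)) {
    d <- as.integer(header$arrays[[nm]])
    vals <- readBin(con, what = "numeric", n = prod(d), size = 8, endian = "little")
    if (length(vals) != prod(d)) stop("truncated weight binary at ", path)
    w[[nm]] <- if (length(d) > 1) array(vals, dim = d) else vals
  }
  structure(w, config = cfg, class = "cnn_weights")
}
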