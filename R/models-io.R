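# Model serialization: weights + config + seed in a single archive.

#' Save a fitted model (weights, config and seed) to one file
#'
#' @param model an `iat_model` or `position_model`.
#' @param path output path (RDS archive).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("iat_model", "position_model"))) {
    stop_invalid("model must be an iat_model or position_model")
  }
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path archive path.
#' @return The model object.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("iat_model", "position_model"))) {
    stop_invalid("file does not contain a cardiopatch model")
  }
  m
}
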