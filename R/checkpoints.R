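#' Save a model checkpoint with a JSON sidecar
#'
#' Writes the model to `path` (RDS) and a human-readable sidecar
#' `<path>.json` recording the class, architecture spec, and any metrics
#' supplied.
#'
#' @param model an `sdcnn` or `resunet` model
#' @param path destination .rds path
#' @param metrics optional named list recorded in the sidecar
#' @param seed optional seed recorded in the sidecar
#' @export
save_checkpoint <- function(model, path, metrics = NULL, seed = NULL) {
  saveRDS(model, path)
  sidecar <- list(class = class(model)[1], spec = model$spec,
                  n_parameters = n_parameters(model),
                  metrics = metrics, seed = seed,
                  saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#' @param path .rds path written by [save_checkpoint()]
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
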