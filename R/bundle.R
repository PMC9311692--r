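# Model bundles: a fitted classifier plus everything needed to reproduce
# its decoding — class list, sensor selection, training standardization
# statistics, selected features and seeds — persisted as a directory with a
# plain-text manifest.

#' Save and load model bundles
#'
#' @param model A fitted classifier accepted by [predict_scores()].
#' @param path Bundle directory (created if missing).
#' @param center,scale Training standardization statistics.
#' @param features Selected feature names, in training order.
#' @param sensors Sensor group the model was trained on.
#' @param window_size Window size (s) the model expects.
#' @param seed The seed the fit was run under (recorded for provenance).
#' @return `save_model_bundle()` returns `path` invisibly;
#'   `load_model_bundle()` returns a list with the model and its manifest
#'   fields, directly usable with [decode_stream()].
#' @export
save_model_bundle <- function(model, path, center = NULL, scale = NULL,
                              features = NULL, sensors = "both",
                              window_size = 3, seed = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(path, "model.rds"))
  manifest <- list(format = class(model)[1],
                   classes = if (!is.null(model$classes)) model$classes
                             else levels(model$y),
                   sensors = sensors, window_size = window_size,
                   features = features, seed = seed,
                   center = as.list(center), scale = as.list(scale))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  model <- readRDS(file.path(path, "model.rds"))
  list(model = model,
       sensors = manifest$sensors,
       window_size = manifest$window_size,
       features = if (length(manifest$features)) unlist(manifest$features),
       center = unlist(manifest$center),
       scale = unlist(manifest$scale),
       classes = unlist(manifest$classes),
       seed = manifest$seed)
}
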