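## Persistence: checkpoint archives (serialised named-array parameter sets
## with a JSON metadata sidecar carrying the shape manifest), prediction CSVs
## and evaluation-report JSON. All artifacts embed the seed and a hash of the
## configuration that produced them.

param_shapes <- function(params) {
  lapply(params, function(p) as.integer(dim(p) %||% length(p)))
}

#' Save / load a checkpoint archive
#'
#' The archive is a compressed serialisation of the parameter arrays plus
#' model configuration and provenance; a JSON sidecar (`<path>.json`) records
#' the shape manifest, validation accuracy and provenance for inspection
#' without deserialising. Loading verifies the stored shape manifest and
#' reports a corrupted archive as an I/O error.
#'
#' @param checkpoint A [Checkpoint-class].
#' @param path Destination `.rds` path.
#' @return The path (save) or the [Checkpoint-class] (load).
#' @export
saveCheckpoint <- function(checkpoint, path) {
  obj <- list(id = checkpoint@id, params = checkpoint@params,
              config = checkpoint@config, valAccuracy = checkpoint@valAccuracy,
              provenance = checkpoint@provenance,
              shapes = param_shapes(checkpoint@params))
  saveRDS(obj, path)
  meta <- list(id = checkpoint@id, val_accuracy = checkpoint@valAccuracy,
               provenance = checkpoint@provenance,
               shapes = param_shapes(checkpoint@params),
               config_hash = config_hash(checkpoint@config))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = 10)),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) io_error("checkpoint not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    io_error("corrupted checkpoint archive %s: %s", path, conditionMessage(e)))
  if (!all(c("id", "params", "config", "valAccuracy", "shapes") %in% names(obj)))
    io_error("corrupted checkpoint archive %s: missing fields", path)
  if (!identical(param_shapes(obj$params), obj$shapes))
    io_error("checkpoint %s failed its shape manifest", path)
  new("Checkpoint", id = obj$id, params = obj$params, config = obj$config,
      valAccuracy = obj$valAccuracy, provenance = obj$provenance)
}

#' Instantiate the model a checkpoint stores
#'
#' @param checkpoint A [Checkpoint-class].
#' @return A [ComponentModel-class].
#' @export
checkpointModel <- function(checkpoint) {
  newComponentModel(checkpoint@config, checkpoint@params)
}

#' Write / read a predictions file
#'
#' CSV with one row per evaluated sample: id, true and predicted answer, true
#' and predicted question type, and the routed model id.
#'
#' @param predictions Predictions data.frame from [evaluateModel()].
#' @param path CSV path.
#' @return The path / the data.frame.
#' @export
writePredictions <- function(predictions, path) {
  if (anyDuplicated(predictions$id))
    contract_error("predictions must have one row per sample id")
  utils::write.csv(predictions, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) io_error("predictions file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load an assembly descriptor
#'
#' JSON naming the level-1 checkpoint, the level-2 checkpoints and the routing
#' table; loading re-instantiates the bi-level model from the referenced
#' archives (paths resolve relative to the descriptor).
#'
#' @param model A [MultiLevelModel-class] whose models came from checkpoints.
#' @param checkpointPaths Named list: `level1` path and `level2` named list of
#'   paths.
#' @param path Destination JSON path.
#' @return The path / the [MultiLevelModel-class].
#' @export
saveAssembly <- function(model, checkpointPaths, path) {
  desc <- list(level1 = checkpointPaths$level1,
               level2 = checkpointPaths$level2,
               routing = as.list(routing(model)))
  writeLines(as.character(jsonlite::toJSON(desc, auto_unbox = TRUE)), path)
  invisible(path)
}

#' @rdname saveAssembly
#' @export
loadAssembly <- function(path) {
  if (!file.exists(path)) io_error("assembly descriptor not found: %s", path)
  desc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  level1 <- checkpointModel(loadCheckpoint(resolve(desc$level1)))
  level2 <- lapply(desc$level2, function(p) checkpointModel(loadCheckpoint(resolve(p))))
  buildBilevel(level1, level2, routing = unlist(desc$routing))
}
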