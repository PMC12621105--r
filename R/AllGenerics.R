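#' Accessor generics
#'
#' Small accessor surface over the package's S4 containers, in place of direct
#' slot access.
#'
#' @param x An object.
#' @param object An object.
#' @param ... Further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("manifestCounts", function(x, ...) standardGeneric("manifestCounts"))

#' @rdname accessors
#' @export
setGeneric("valAccuracy", function(x) standardGeneric("valAccuracy"))

#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("ingredients", function(x) standardGeneric("ingredients"))

#' @rdname accessors
#' @export
setGeneric("soupAudit", function(x) standardGeneric("soupAudit"))

#' @rdname accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname accessors
#' @export
setGeneric("weightedMetrics", function(x) standardGeneric("weightedMetrics"))

#' @rdname accessors
#' @export
setGeneric("perTypeAccuracies", function(x) standardGeneric("perTypeAccuracies"))

#' @rdname accessors
#' @export
setGeneric("routing", function(x) standardGeneric("routing"))

#' Predict a label for one sample with a VQA model
#'
#' Dispatches over the model class: trained component models run the full
#' tokenize/encode/fuse/classify pipeline; lookup models return planted labels
#' (used as controllable oracles in experiments and tests).
#'
#' @param model A [VQAModel-class] object.
#' @param sample A single-sample record (one row of a manifest in list form,
#'   with `image` and optional `mask` tensors attached).
#' @param ... Further arguments for methods.
#' @return A list with elements `label` (character) and `scores` (named numeric
#'   probability vector over the model's label space).
#' @export
setGeneric("predictSample", function(model, sample, ...) standardGeneric("predictSample"))

#' Evaluate a model over one split of a manifest
#'
#' @param model A [VQAModel-class] or [MultiLevelModel-class] object.
#' @param manifest A [VQAManifest-class].
#' @param ... Further arguments for methods (`split`, `router`, `misrouteProb`).
#' @return A list with `predictions` (data.frame), `report`
#'   ([EvaluationReport-class]) and `accuracy`.
#' @export
setGeneric("evaluateModel", function(model, manifest, ...) standardGeneric("evaluateModel"))
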