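#' VQAManifest: a dataset manifest
#'
#' An ordered collection of VQA sample records (paths, not pixels) plus the
#' directory its relative paths resolve against. Each record holds an id, an
#' image path, an optional region-mask path, the question text, the question
#' type, the answer label and the split assignment. Tallies are always
#' recomputed from the sample table (see [manifestCounts()]), never stored.
#'
#' @slot samples A data.frame with columns `id`, `image_path`, `mask_path`
#'   (NA when absent), `question`, `question_type`, `answer`, `split`.
#' @slot dir Directory against which relative paths resolve.
#' @export
setClass("VQAManifest", representation(samples = "data.frame", dir = "character"))

setValidity("VQAManifest", function(object) {
  df <- object@samples
  need <- c("id", "image_path", "mask_path", "question", "question_type", "answer", "split")
  if (!all(need %in% names(df)))
    return(paste("missing manifest columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  # duplicate ids and per-record rule breaches are *reported* by
  # validateManifest() rather than thrown here, so invalid manifests can be
  # loaded for diagnosis
  TRUE
})

#' VQAModel: virtual parent of answerable models
#'
#' Anything that can map a (image, question) sample to a label over a fixed
#' label space. Concrete subclasses: [ComponentModel-class] (the trainable
#' encoder-fusion-MLP reference model) and [LookupModel-class] (a planted
#' lookup oracle for controlled experiments).
#'
#' @export
setClass("VQAModel", representation("VIRTUAL"))

#' ComponentModel: text encoder + image encoder + fusion MLP
#'
#' The component VQA model: a word-level tokenizer and small self-attention
#' text encoder (leading summary-token state as the text feature), a
#' patchify/embed/attend/mean-pool image encoder, per-modality normalisation,
#' concatenation, and an MLP classification head. The parameter list is
#' partitioned into visual (`v_*`), textual (`t_*`) and head (`h_*`)
#' components; this partition is the unit of greedy-soup averaging.
#'
#' @slot config Model configuration (dimensions, patch size, vocabulary,
#'   normalisation constants, label space role).
#' @slot params Named list of parameter arrays.
#' @export
setClass("ComponentModel", contains = "VQAModel",
         representation(config = "list", params = "list"))

setValidity("ComponentModel", function(object) {
  cfg <- object@config
  if (!cfg$role %in% c("answer", "qtype")) return("role must be 'answer' or 'qtype'")
  k <- length(cfg$labels)
  if (k != if (cfg$role == "answer") 5L else 4L)
    return("head output width must equal the label-space size for the model role")
  if (!is.null(object@params$h_W2) && ncol(object@params$h_W2) != k)
    return("head output layer width does not match label space")
  TRUE
})

#' LookupModel: planted-label oracle model
#'
#' A synthetic reference model that answers by sample id from a planted table,
#' with a fallback label for unseen ids. It supports controlled experiments
#' where per-type accuracies must be known exactly (e.g. routing property
#' checks), independent of any training run.
#'
#' @slot table Named character vector: sample id -> label.
#' @slot fallback Label returned for ids absent from `table`.
#' @slot labels The model's label space.
#' @slot role "answer" or "qtype".
#' @export
setClass("LookupModel", contains = "VQAModel",
         representation(table = "character", fallback = "character",
                        labels = "character", role = "character"))

#' Checkpoint: a parameter snapshot with measured validation accuracy
#'
#' The unit of greedy-soup averaging: a full parameter set (visual, textual and
#' head components), the validation accuracy measured when it was written, and
#' training provenance (epoch, phase within the epoch, hyperparameters, seed).
#'
#' @slot id Checkpoint identifier (unique within a training run).
#' @slot params Named list of parameter arrays.
#' @slot config The model configuration the parameters instantiate.
#' @slot valAccuracy Measured validation accuracy in [0, 1].
#' @slot provenance List: `epoch`, `phase` ("half" or "end"), `hyperparameters`,
#'   `seed`.
#' @export
setClass("Checkpoint",
         representation(id = "character", params = "list", config = "list",
                        valAccuracy = "numeric", provenance = "list"))

setValidity("Checkpoint", function(object) {
  if (length(object@valAccuracy) != 1 || is.na(object@valAccuracy) ||
      object@valAccuracy < 0 || object@valAccuracy > 1)
    return("valAccuracy must be a single value in [0, 1]")
  if (!is.null(object@provenance$phase) &&
      !object@provenance$phase %in% c("half", "end"))
    return("provenance phase must be 'half' or 'end'")
  TRUE
})

#' SoupResult: outcome of greedy-soup averaging
#'
#' @slot ingredients Ordered ids of the accepted checkpoints.
#' @slot params Uniform average of the accepted ingredients' parameters.
#' @slot config Model configuration shared by the ingredients.
#' @slot valAccuracy Validation accuracy of the final soup.
#' @slot audit Per-candidate data.frame: id, valAccuracy, tried, accepted,
#'   accuracy if added, and the running soup accuracy after the decision.
#' @export
setClass("SoupResult",
         representation(ingredients = "character", params = "list", config = "list",
                        valAccuracy = "numeric", audit = "data.frame"))

#' MultiLevelModel: the assembled multi-level VQA system
#'
#' An ordered list of levels. Every level before the last holds a single
#' router model over question types plus a routing table; the last level holds
#' the answer models. The shipped instantiation is bi-level (n = 2): level 1
#' predicts the question type (intermediate only, never exposed as an answer),
#' the switch function routes to the mapped second-level model, and that
#' model's answer is final.
#'
#' @slot levels List of levels; each level is a list with `models` (named list
#'   of [VQAModel-class]) and, for non-final levels, `routing` (named character
#'   QuestionType -> next-level model id).
#' @slot nLevels Number of levels (>= 2 for the bi-level instantiation).
#' @export
setClass("MultiLevelModel", representation(levels = "list", nLevels = "integer"))

setValidity("MultiLevelModel", function(object) {
  if (object@nLevels < 2L) return("a multi-level model needs at least 2 levels")
  if (length(object@levels) != object@nLevels) return("levels length must equal nLevels")
  for (i in seq_len(object@nLevels - 1L)) {
    lv <- object@levels[[i]]
    rt <- lv$routing
    if (is.null(rt)) return(sprintf("level %d has no routing table", i))
    if (!setequal(names(rt), questionTypes()))
      return(sprintf("level %d routing must be total over the four question types", i))
    nxt <- names(object@levels[[i + 1L]]$models)
    if (!all(rt %in% nxt))
      return(sprintf("level %d routing targets missing from level %d: %s", i, i + 1L,
                     paste(setdiff(rt, nxt), collapse = ", ")))
  }
  TRUE
})

#' EvaluationReport: the full evaluation surface of one run
#'
#' Confusion matrix (rows = truth, columns = prediction), per-class one-vs-rest
#' precision/recall/F1 with supports, overall accuracy, macro (unweighted mean)
#' and weighted (support-weighted mean) aggregates, and optionally accuracy per
#' question type. Weighted recall always equals overall accuracy (single-label
#' multi-class identity); this is asserted at construction.
#'
#' @slot confusion Integer K x K matrix with label dimnames.
#' @slot perClass data.frame: label, precision, recall, f1, support.
#' @slot accuracy Overall accuracy in [0, 1].
#' @slot macro Named numeric: precision, recall, f1.
#' @slot weighted Named numeric: precision, recall, f1.
#' @slot perType Named numeric of per-question-type accuracies (may be empty).
#' @export
setClass("EvaluationReport",
         representation(confusion = "matrix", perClass = "data.frame",
                        accuracy = "numeric", macro = "numeric",
                        weighted = "numeric", perType = "numeric"))

#' SeedStudyResult: seed-stability analysis
#'
#' Per-seed test accuracies (percent), their mean and sample standard deviation
#' (n - 1 denominator), and a two-tailed one-sample t-test of the mean against
#' a fixed baseline (df = n - 1). When the accuracies have zero spread the test
#' is degenerate and no t/p is reported.
#'
#' @slot perSeed data.frame: seed, accuracy (percent).
#' @slot mean Mean accuracy (percent).
#' @slot sd Sample standard deviation (percent).
#' @slot baseline Baseline accuracy (percent).
#' @slot tStatistic t statistic (NA when degenerate).
#' @slot pValue Two-tailed p-value (NA when degenerate).
#' @slot degenerate TRUE when sd == 0.
#' @export
setClass("SeedStudyResult",
         representation(perSeed = "data.frame", mean = "numeric", sd = "numeric",
                        baseline = "numeric", tStatistic = "numeric",
                        pValue = "numeric", degenerate = "logical"))

## ------------------------------------------------------------------
## Accessors

#' @rdname accessors
#' @aliases samples,VQAManifest-method
setMethod("samples", "VQAManifest", function(x, ...) x@samples)

#' @rdname accessors
setMethod("valAccuracy", "Checkpoint", function(x) x@valAccuracy)

#' @rdname accessors
setMethod("valAccuracy", "SoupResult", function(x) x@valAccuracy)

#' @rdname accessors
setMethod("modelParameters", "ComponentModel", function(x) x@params)

#' @rdname accessors
setMethod("modelParameters", "Checkpoint", function(x) x@params)

#' @rdname accessors
setMethod("modelParameters", "SoupResult", function(x) x@params)

#' @rdname accessors
setMethod("modelConfig", "ComponentModel", function(x) x@config)

#' @rdname accessors
setMethod("modelConfig", "Checkpoint", function(x) x@config)

#' @rdname accessors
setMethod("modelConfig", "SoupResult", function(x) x@config)

#' @rdname accessors
setMethod("provenance", "Checkpoint", function(x) x@provenance)

#' @rdname accessors
setMethod("ingredients", "SoupResult", function(x) x@ingredients)

#' @rdname accessors
setMethod("soupAudit", "SoupResult", function(x) x@audit)

#' @rdname accessors
setMethod("confusion", "EvaluationReport", function(x) x@confusion)

#' @rdname accessors
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

#' @rdname accessors
setMethod("overallAccuracy", "EvaluationReport", function(x) x@accuracy)

#' @rdname accessors
setMethod("macroMetrics", "EvaluationReport", function(x) x@macro)

#' @rdname accessors
setMethod("weightedMetrics", "EvaluationReport", function(x) x@weighted)

#' @rdname accessors
setMethod("perTypeAccuracies", "EvaluationReport", function(x) x@perType)

#' @rdname accessors
setMethod("routing", "MultiLevelModel", function(x) x@levels[[1L]]$routing)

## ------------------------------------------------------------------
## show() methods

setMethod("show", "VQAManifest", function(object) {
  df <- object@samples
  cat(sprintf("VQAManifest with %d samples\n", nrow(df)))
  if (nrow(df) > 0) {
    cat("  splits: ", paste(sprintf("%s=%d", names(table(df$split)), table(df$split)),
                            collapse = ", "), "\n", sep = "")
    cat("  types:  ", paste(sprintf("%s=%d", names(table(df$question_type)),
                                    table(df$question_type)), collapse = ", "), "\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "ComponentModel", function(object) {
  cfg <- object@config
  cat(sprintf("ComponentModel (role=%s): D_t=%d, D_v=%d, patch=%d, %d+%d attention blocks\n",
              cfg$role, cfg$d_t, cfg$d_v, cfg$patch, cfg$blocks_t, cfg$blocks_v))
  cat(sprintf("  vocabulary: %d tokens; labels: %s\n",
              length(cfg$vocab), paste(cfg$labels, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "LookupModel", function(object) {
  cat(sprintf("LookupModel (role=%s) with %d planted ids (fallback: %s)\n",
              object@role, length(object@table), object@fallback))
  invisible(NULL)
})

setMethod("show", "Checkpoint", function(object) {
  pv <- object@provenance
  cat(sprintf("Checkpoint %s: valAccuracy=%.4f (epoch %s, %s, seed %s)\n",
              object@id, object@valAccuracy,
              pv$epoch %||% "?", pv$phase %||% "?", pv$seed %||% "?"))
  invisible(NULL)
})

setMethod("show", "SoupResult", function(object) {
  cat(sprintf("SoupResult: %d ingredient(s) [%s], valAccuracy=%.4f\n",
              length(object@ingredients), paste(object@ingredients, collapse = ", "),
              object@valAccuracy))
  invisible(NULL)
})

setMethod("show", "MultiLevelModel", function(object) {
  cat(sprintf("MultiLevelModel with %d levels\n", object@nLevels))
  rt <- object@levels[[1L]]$routing
  cat("  routing: ", paste(sprintf("%s->%s", names(rt), rt), collapse = ", "), "\n", sep = "")
  cat(sprintf("  final level: %d answer model(s)\n",
              length(object@levels[[object@nLevels]]$models)))
  invisible(NULL)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport over %d samples, accuracy %.4f\n",
              sum(object@confusion), object@accuracy))
  cat(sprintf("  macro    P/R/F1: %.4f/%.4f/%.4f\n",
              object@macro["precision"], object@macro["recall"], object@macro["f1"]))
  cat(sprintf("  weighted P/R/F1: %.4f/%.4f/%.4f\n",
              object@weighted["precision"], object@weighted["recall"], object@weighted["f1"]))
  if (length(object@perType) > 0)
    cat("  per-type accuracy (%): ",
        paste(sprintf("%s=%.2f", names(object@perType), 100 * object@perType),
              collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SeedStudyResult", function(object) {
  cat(sprintf("SeedStudyResult over %d seeds: mean %.2f%%, sd %.2f\n",
              nrow(object@perSeed), object@mean, object@sd))
  if (object@degenerate) {
    cat("  degenerate: zero variance across seeds, no t-test\n")
  } else {
    cat(sprintf("  vs baseline %.2f%%: t = %.2f, p = %.4f (df = %d)\n",
                object@baseline, object@tStatistic, object@pValue, nrow(object@perSeed) - 1L))
  }
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
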