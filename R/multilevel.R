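## The multi-level assembly: a question-type classifier at level 1, a switch
## function that either finalises or routes on the predicted type, and
## type-specialised answer models at the final level. The level-1 prediction
## is intermediate only — it is consumed by the switch function and never
## exposed as an answer, and misclassified types are routed per the (wrong)
## prediction, not corrected.

#' Classify the question type of a sample (level 1)
#'
#' Runs the component pipeline over the four-type label space. The prediction
#' is intermediate: it feeds the switch function only.
#'
#' @param level1 A role = "qtype" [VQAModel-class].
#' @param sample An in-memory sample record.
#' @return List with `type` and `scores` (four probabilities summing to 1).
#' @export
classifyQuestionType <- function(level1, sample) {
  role <- if (is(level1, "ComponentModel")) level1@config$role else level1@role
  if (role != "qtype")
    contract_error("level-1 model must have role 'qtype', got '%s'", role)
  out <- predictSample(level1, sample)
  list(type = asQuestionType(out$label), scores = out$scores)
}

#' Switch decision for a predicted question type
#'
#' With no further level the decision is FINAL and carries the intermediate
#' answer; otherwise it is ROUTE with the routing table's target for the
#' predicted type.
#'
#' @param predictedType A question type token.
#' @param routingTable Named character vector QuestionType -> model id (total
#'   over the four types).
#' @param hasNextLevel Logical.
#' @return List with `code` ("FINAL" or "ROUTE"), `target` (model id, ROUTE
#'   only) and `intermediate` (the carried intermediate answer).
#' @export
switchDecision <- function(predictedType, routingTable, hasNextLevel = TRUE) {
  predictedType <- asQuestionType(predictedType)
  if (!hasNextLevel)
    return(list(code = "FINAL", target = NULL, intermediate = predictedType))
  if (!predictedType %in% names(routingTable))
    contract_error("routing table has no entry for type %s", predictedType)
  list(code = "ROUTE", target = unname(routingTable[[predictedType]]),
       intermediate = predictedType)
}

#' Derive a routing table from per-type validation accuracies
#'
#' Each question type routes to the model with the highest validation accuracy
#' on that type; ties go to the lowest model index (table row order).
#'
#' @param perTypeAcc Numeric matrix, rows = model ids (rownames), columns =
#'   question types.
#' @return Named character vector QuestionType -> model id.
#' @export
deriveRouting <- function(perTypeAcc) {
  if (is.null(rownames(perTypeAcc)) || is.null(colnames(perTypeAcc)))
    contract_error("perTypeAcc needs model-id rownames and question-type colnames")
  missing_types <- setdiff(questionTypes(), colnames(perTypeAcc))
  if (length(missing_types) > 0)
    contract_error("no accuracy entries for type(s): %s",
                   paste(missing_types, collapse = ", "))
  rt <- vapply(questionTypes(), function(tp) {
    col <- perTypeAcc[, tp]
    if (all(is.na(col))) contract_error("no accuracy entries for type %s", tp)
    rownames(perTypeAcc)[which.max(col)]  # first max = lowest model index
  }, "")
  rt
}

#' Assemble a bi-level VQA model
#'
#' With `routing = "auto"` the per-type validation accuracy of every
#' second-level model is measured on the supplied manifest and the routing
#' table picks the per-type best (ties toward the earlier model). An explicit
#' routing table must be total over the four types and name existing models.
#'
#' @param level1 A role = "qtype" [VQAModel-class].
#' @param level2 Named list of role = "answer" [VQAModel-class] objects.
#' @param routing "auto" or a named character vector QuestionType -> model id.
#' @param manifest Required for "auto": manifest providing the validation
#'   split.
#' @param split Split used for "auto" routing derivation.
#' @return A [MultiLevelModel-class] (bi-level).
#' @export
buildBilevel <- function(level1, level2, routing = "auto", manifest = NULL,
                         split = "val") {
  if (is.null(names(level2)) || any(!nzchar(names(level2))))
    contract_error("level2 must be a named list of models")
  l1role <- if (is(level1, "ComponentModel")) level1@config$role else level1@role
  if (l1role != "qtype")
    contract_error("level-1 model must have role 'qtype', got '%s'", l1role)
  for (m in level2) {
    role <- if (is(m, "ComponentModel")) m@config$role else m@role
    if (role != "answer")
      contract_error("all level-2 models must have role 'answer'")
  }
  if (identical(routing, "auto")) {
    if (is.null(manifest))
      contract_error("auto routing requires a validation manifest")
    acc <- t(vapply(level2, function(m) {
      rep_ <- evaluateModel(m, manifest, split = split)$report
      pt <- perTypeAccuracies(rep_)
      out <- stats::setNames(rep(NA_real_, 4), questionTypes())
      out[names(pt)] <- pt
      out
    }, stats::setNames(numeric(4), questionTypes())))
    routing <- deriveRouting(acc)
  }
  mlm <- new("MultiLevelModel",
             levels = list(list(models = list(level1 = level1), routing = routing),
                           list(models = level2, routing = NULL)),
             nLevels = 2L)
  validObject(mlm)
  mlm
}

#' Answer a sample with a multi-level model
#'
#' Walks the levels: each non-final level predicts a question type, the switch
#' function routes on it, and the final level's routed model produces the
#' answer. The trace records each level's prediction, scores, decision and
#' routed target; intermediate predictions never leak into the answer.
#'
#' @param model A [MultiLevelModel-class].
#' @param sample An in-memory sample record (see [load_sample]).
#' @return List with `answer` (an answer label) and `trace`.
#' @export
answerSample <- function(model, sample) {
  trace <- list()
  current <- "level1"
  for (i in seq_len(model@nLevels)) {
    level <- model@levels[[i]]
    m <- level$models[[current]]
    if (is.null(m)) contract_error("routed model '%s' missing at level %d", current, i)
    if (i < model@nLevels) {
      cls <- classifyQuestionType(m, sample)
      dec <- switchDecision(cls$type, level$routing, hasNextLevel = TRUE)
      trace[[length(trace) + 1L]] <- list(level = i, model = current,
                                          predicted_type = cls$type,
                                          scores = cls$scores, decision = dec$code,
                                          target = dec$target)
      current <- dec$target
    } else {
      out <- predictSample(m, sample)
      trace[[length(trace) + 1L]] <- list(level = i, model = current,
                                          scores = out$scores, decision = "FINAL")
      return(list(answer = asAnswerLabel(out$label), trace = trace))
    }
  }
  contract_error("multi-level walk ended without a final answer")
}

#' @rdname evaluateModel
#' @param router "level1" uses the level-1 classifier; "oracle" routes on the
#'   true question type (an upper-bound diagnostic).
#' @param misrouteProb Probability of corrupting the level-1 type to a
#'   uniformly random other type before routing (robustness diagnostic).
setMethod("evaluateModel", signature("MultiLevelModel", "VQAManifest"),
          function(model, manifest, split = "test", router = c("level1", "oracle"),
                   misrouteProb = 0, ...) {
  router <- match.arg(router)
  tensors <- load_split_tensors(manifest, split)
  if (length(tensors) == 0) contract_error("empty split '%s'", split)
  routing_tab <- model@levels[[1L]]$routing
  final_models <- model@levels[[model@nLevels]]$models

  n <- length(tensors)
  pred <- character(n); ptype <- character(n); routed <- character(n)
  truth <- vapply(tensors, `[[`, "", "answer")
  types <- vapply(tensors, `[[`, "", "question_type")
  for (i in seq_len(n)) {
    s <- tensors[[i]]
    tp <- if (router == "oracle") s$question_type
          else classifyQuestionType(model@levels[[1L]]$models$level1, s)$type
    if (misrouteProb > 0 && runif(1) < misrouteProb)
      tp <- sample(setdiff(questionTypes(), tp), 1)
    dec <- switchDecision(tp, routing_tab, hasNextLevel = TRUE)
    out <- predictSample(final_models[[dec$target]], s)
    pred[i] <- asAnswerLabel(out$label)
    ptype[i] <- tp
    routed[i] <- dec$target
  }

  cm <- confusionMatrix(truth, pred, answerLabels())
  report <- evaluationReport(cm, perType = perTypeAccuracy(types, pred == truth)$per_type)
  predictions <- data.frame(id = vapply(tensors, `[[`, "", "id"),
                            true_answer = truth, predicted_answer = pred,
                            true_type = types, predicted_type = ptype,
                            routed_model = routed, stringsAsFactors = FALSE)
  list(predictions = predictions, report = report, accuracy = report@accuracy)
})
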