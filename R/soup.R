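## Greedy-soup parameter averaging. Checkpoints are sorted by descending
## validation accuracy; the soup starts from the best one, and each remaining
## candidate is tentatively averaged in (uniformly, over all accepted
## ingredients plus the candidate) and kept only if the evaluated validation
## accuracy does not drop. A top-k pre-filter restricts the candidate pool to
## the k leading checkpoints (default k = 3).

#' Check that two parameter sets are combinable
#'
#' Parameter sets are combinable iff their name sets and per-name shapes are
#' identical.
#'
#' @param a,b Named lists of arrays.
#' @return TRUE, or a contract error naming the offending entry.
#' @export
combinableParameters <- function(a, b) {
  if (!setequal(names(a), names(b))) {
    off <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    contract_error("parameter sets are not combinable: name mismatch at %s",
                   paste(off, collapse = ", "))
  }
  for (nm in names(a)) {
    da <- dim(a[[nm]]) %||% length(a[[nm]])
    db <- dim(b[[nm]]) %||% length(b[[nm]])
    if (!identical(da, db))
      contract_error("parameter sets are not combinable: shape mismatch at %s", nm)
  }
  TRUE
}

#' Entry-wise average of parameter sets
#'
#' The uniform arithmetic mean of every named array, jointly across the
#' visual, textual and head components.
#'
#' @param sets Nonempty list of combinable parameter sets.
#' @return A parameter set of the same shape.
#' @export
averageParameters <- function(sets) {
  if (length(sets) == 0) contract_error("cannot average an empty list of parameter sets")
  for (s in sets[-1]) combinableParameters(sets[[1]], s)
  out <- sets[[1]]
  for (nm in names(out)) {
    acc <- sets[[1]][[nm]]
    for (s in sets[-1]) acc <- acc + s[[nm]]
    out[[nm]] <- acc / length(sets)
  }
  out
}

#' Top-k checkpoint pool
#'
#' Checkpoints sorted by validation accuracy (descending; ties keep the
#' earlier training order) and truncated to the k leading ones.
#'
#' @param checkpoints Nonempty list of [Checkpoint-class] objects.
#' @param k Pool size (>= 1).
#' @return Ordered list of at most k checkpoints.
#' @export
topKPool <- function(checkpoints, k = 3L) {
  if (length(checkpoints) == 0) contract_error("empty checkpoint list")
  if (!is_count(k)) contract_error("k must be a positive integer")
  acc <- vapply(checkpoints, valAccuracy, 0)
  ord <- order(-acc)  # stable: equal accuracies keep original order
  head(checkpoints[ord], k)
}

#' Greedy-soup ensembling over a checkpoint pool
#'
#' Implements the ensembling recipe exactly: sort by descending validation
#' accuracy, initialise the soup with the best checkpoint, then for each
#' remaining candidate tentatively average it into the accepted set and keep
#' it iff the evaluated accuracy is greater than or equal to the current soup
#' accuracy (`rule = "alg5"`; `rule = "strict"` demands a strict improvement).
#' The final parameters equal the uniform average of the accepted ingredients,
#' re-averaged from scratch at every acceptance, and the audited soup-accuracy
#' sequence is non-decreasing, so the final soup is never worse on validation
#' than its best single ingredient.
#'
#' @param checkpoints List of [Checkpoint-class] objects (a pool, e.g. from
#'   [topKPool()]; re-sorted internally).
#' @param evaluator `function(params) -> accuracy`, e.g. from
#'   [accuracyEvaluator()]. Failures are propagated with the candidate id.
#' @param rule Acceptance rule: "alg5" (>=) or "strict" (>).
#' @return A [SoupResult-class].
#' @export
greedySoup <- function(checkpoints, evaluator, rule = c("alg5", "strict")) {
  rule <- match.arg(rule)
  if (length(checkpoints) == 0) contract_error("empty checkpoint pool")
  acc <- vapply(checkpoints, valAccuracy, 0)
  pool <- checkpoints[order(-acc)]
  for (ck in pool[-1]) combinableParameters(pool[[1]]@params, ck@params)

  eval_with <- function(params, id) {
    tryCatch(evaluator(params), error = function(e)
      stop(errorCondition(sprintf("evaluator failed on candidate %s: %s",
                                  id, conditionMessage(e)),
                          class = c("bivqa_contract_error", "error"))))
  }

  soup_sets <- list(pool[[1]]@params)
  soup_ids <- pool[[1]]@id
  soup_params <- pool[[1]]@params
  soup_acc <- eval_with(soup_params, pool[[1]]@id)
  audit <- data.frame(id = pool[[1]]@id, val_accuracy = pool[[1]]@valAccuracy,
                      tried = TRUE, accepted = TRUE, accuracy_if_added = soup_acc,
                      soup_accuracy = soup_acc, stringsAsFactors = FALSE)

  for (ck in pool[-1]) {
    cand_params <- averageParameters(c(soup_sets, list(ck@params)))
    cand_acc <- eval_with(cand_params, ck@id)
    accepted <- if (rule == "alg5") cand_acc >= soup_acc else cand_acc > soup_acc
    if (accepted) {
      soup_sets <- c(soup_sets, list(ck@params))
      soup_ids <- c(soup_ids, ck@id)
      soup_params <- cand_params
      soup_acc <- cand_acc
    }
    audit <- rbind(audit, data.frame(id = ck@id, val_accuracy = ck@valAccuracy,
                                     tried = TRUE, accepted = accepted,
                                     accuracy_if_added = cand_acc,
                                     soup_accuracy = soup_acc,
                                     stringsAsFactors = FALSE))
  }

  res <- new("SoupResult", ingredients = soup_ids, params = soup_params,
             config = pool[[1]]@config, valAccuracy = soup_acc, audit = audit)
  ## invariant: the audited accuracy sequence never decreases, hence the final
  ## soup is at least as good as the best single ingredient on validation
  stopifnot(!is.unsorted(res@audit$soup_accuracy))
  res
}

#' Soup a training run and return the souped model
#'
#' Convenience wrapper: top-k pre-filter over the emitted checkpoints, greedy
#' soup against validation accuracy, and assembly of the final model.
#'
#' @param run Result of [trainComponent()].
#' @param manifest Manifest providing the validation split.
#' @param k Top-k pool size.
#' @param rule Acceptance rule, see [greedySoup()].
#' @return List with `model` (a [ComponentModel-class] carrying the souped
#'   parameters) and `soup` (the [SoupResult-class]).
#' @export
soupTrainingRun <- function(run, manifest, k = 3L, rule = "alg5") {
  pool <- topKPool(run$checkpoints, k)
  evaluator <- accuracyEvaluator(pool[[1]]@config, manifest, split = "val")
  soup <- greedySoup(pool, evaluator, rule = rule)
  list(model = newComponentModel(soup@config, soup@params), soup = soup)
}
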