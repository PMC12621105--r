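## Evaluation surface: confusion matrix, per-class one-vs-rest precision /
## recall / F1, overall accuracy, macro (unweighted mean) and weighted
## (support-weighted mean) aggregates, per-question-type accuracy, and the
## seed-stability analysis. Conventions for empty denominators: precision with
## no predicted positives is 0, recall with no true positives is 0, F1 with
## P = R = 0 is 0. Values are kept at full precision internally; serialisation
## rounds proportions to 4 decimals and percentages to 2.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with truth `labels[i]` and
#' prediction `labels[j]`.
#'
#' @param truths,predictions Equal-length label vectors; every value must be
#'   in `labels`.
#' @param labels Ordered label list fixing the matrix layout.
#' @return Integer K x K matrix with label dimnames.
#' @export
confusionMatrix <- function(truths, predictions, labels) {
  if (length(truths) != length(predictions))
    contract_error("truths and predictions differ in length")
  bad <- setdiff(unique(c(truths, predictions)), labels)
  if (length(bad) > 0)
    contract_error("labels outside the label list: %s", paste(bad, collapse = ", "))
  tab <- table(factor(truths, levels = labels), factor(predictions, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(truth = labels, prediction = labels))
  m
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall Values in [0, 1] (vectorised).
#' @return F1 values; 0 where precision + recall is 0.
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Macro and weighted aggregates of a per-class metric
#'
#' The macro aggregate is the unweighted mean over classes; the weighted
#' aggregate is the support-weighted mean, normalised by the total sample
#' count. For recall, the weighted aggregate equals overall accuracy.
#'
#' @param x Per-class metric values.
#' @param support Per-class sample counts.
#' @return The aggregate value.
#' @export
macroAverage <- function(x) mean(x)

#' @rdname macroAverage
#' @export
weightedAverage <- function(x, support) sum(x * support) / sum(support)

#' Overall accuracy from per-class recalls and supports
#'
#' In single-label multi-class evaluation the per-class recall times support
#' counts the correctly classified samples of that class, so the
#' support-weighted mean of recalls reconstructs overall accuracy — the
#' identity that lets published per-class tables be checked against their
#' printed accuracy.
#'
#' @param recall Per-class recalls.
#' @param support Per-class supports.
#' @return Accuracy in [0, 1].
#' @export
accuracyFromRecall <- function(recall, support) weightedAverage(recall, support)

#' Full evaluation report from a confusion matrix
#'
#' @param cm Confusion matrix from [confusionMatrix()] (K >= 2, at least one
#'   count).
#' @param perType Optional named per-question-type accuracies to attach.
#' @return An [EvaluationReport-class].
#' @export
evaluationReport <- function(cm, perType = NULL) {
  if (nrow(cm) < 2) contract_error("a report needs at least two classes")
  total <- sum(cm)
  if (total < 1) contract_error("all-zero confusion matrix")
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  support <- rowSums(cm)
  precision <- ifelse(pred_pos == 0, 0, tp / pred_pos)
  recall <- ifelse(support == 0, 0, tp / support)
  f1 <- f1Score(precision, recall)
  accuracy <- sum(tp) / total
  per_class <- data.frame(label = rownames(cm), precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          support = unname(as.integer(support)),
                          stringsAsFactors = FALSE)
  macro <- c(precision = macroAverage(precision), recall = macroAverage(recall),
             f1 = macroAverage(f1))
  weighted <- c(precision = weightedAverage(precision, support),
                recall = weightedAverage(recall, support),
                f1 = weightedAverage(f1, support))
  ## single-label multi-class identity, asserted on every report
  stopifnot(abs(weighted[["recall"]] - accuracy) < 1e-12)
  new("EvaluationReport", confusion = cm, perClass = per_class,
      accuracy = accuracy, macro = macro, weighted = weighted,
      perType = if (is.null(perType)) stats::setNames(numeric(0), character(0)) else perType)
}

#' Accuracy per question type
#'
#' Accuracy restricted to the samples of each (true) question type, plus the
#' pooled overall accuracy. Types with no samples are omitted with a warning.
#'
#' @param types True question types, aligned with `correct`.
#' @param correct Logical vector: prediction correct?
#' @return List with `per_type` (named numeric) and `overall`.
#' @export
perTypeAccuracy <- function(types, correct) {
  if (length(types) != length(correct))
    contract_error("types and correct differ in length")
  asQuestionType(types)
  present <- questionTypes()[questionTypes() %in% types]
  absent <- setdiff(questionTypes(), present)
  if (length(absent) > 0)
    warning(sprintf("no samples for question type(s): %s", paste(absent, collapse = ", ")))
  per_type <- vapply(present, function(tp) mean(correct[types == tp]), 0)
  list(per_type = per_type, overall = mean(correct))
}

#' Seed-stability analysis
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-seed
#' accuracies, and a two-tailed one-sample t-test of their mean against a
#' fixed baseline: `t = (mean - baseline) / (SD / sqrt(n))` with n - 1 degrees
#' of freedom. (A paired test against a constant baseline reduces exactly to
#' this one-sample form.) Zero spread across seeds is reported as a degenerate
#' result with no t/p.
#'
#' @param accuracies Per-seed accuracies, in percent.
#' @param baseline Baseline accuracy, in percent.
#' @param seeds Optional seed labels for the per-seed table.
#' @return A [SeedStudyResult-class].
#' @export
seedStability <- function(accuracies, baseline, seeds = seq_along(accuracies)) {
  if (length(accuracies) < 2) contract_error("seed stability needs at least two accuracies")
  if (!all(is.finite(accuracies)) || !is.finite(baseline))
    contract_error("accuracies and baseline must be finite")
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  n <- length(accuracies)
  per_seed <- data.frame(seed = seeds, accuracy = accuracies)
  if (s == 0) {
    return(new("SeedStudyResult", perSeed = per_seed, mean = m, sd = s,
               baseline = baseline, tStatistic = NA_real_, pValue = NA_real_,
               degenerate = TRUE))
  }
  t_stat <- (m - baseline) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  new("SeedStudyResult", perSeed = per_seed, mean = m, sd = s, baseline = baseline,
      tStatistic = t_stat, pValue = p, degenerate = FALSE)
}

## ------------------------------------------------------------------
## Serialisation helpers (4-decimal proportions, 2-decimal percentages)

#' Serialise an evaluation report
#'
#' @param report An [EvaluationReport-class].
#' @return A list ready for JSON serialisation, with proportions rounded to 4
#'   decimals and per-type percentages to 2.
#' @export
reportAsList <- function(report) {
  pc <- perClassMetrics(report)
  list(
    labels = pc$label,
    confusion = unname(apply(confusion(report), 1, as.integer, simplify = FALSE)),
    per_class = lapply(seq_len(nrow(pc)), function(i) list(
      label = pc$label[i], precision = round(pc$precision[i], 4),
      recall = round(pc$recall[i], 4), f1 = round(pc$f1[i], 4),
      support = pc$support[i])),
    accuracy = round(overallAccuracy(report), 4),
    macro_avg = as.list(round(macroMetrics(report), 4)),
    weighted_avg = as.list(round(weightedMetrics(report), 4)),
    per_type_accuracy_pct = as.list(round(100 * perTypeAccuracies(report), 2)))
}

#' Text table mirroring the published layout
#'
#' Per-class rows (precision, recall, F1, support) followed by Accuracy,
#' Macro Avg and Weighted Avg footer rows.
#'
#' @param report An [EvaluationReport-class].
#' @return Character vector of table lines.
#' @export
reportAsTable <- function(report) {
  pc <- perClassMetrics(report)
  lines <- c(sprintf("%-12s %9s %9s %9s %9s", "", "precision", "recall", "f1-score", "support"))
  for (i in seq_len(nrow(pc))) {
    lines <- c(lines, sprintf("%-12s %9.4f %9.4f %9.4f %9d", pc$label[i],
                              pc$precision[i], pc$recall[i], pc$f1[i], pc$support[i]))
  }
  n <- sum(pc$support)
  lines <- c(lines,
             sprintf("%-12s %9s %9s %9.4f %9d", "Accuracy", "", "", overallAccuracy(report), n),
             sprintf("%-12s %9.4f %9.4f %9.4f %9d", "Macro Avg",
                     macroMetrics(report)["precision"], macroMetrics(report)["recall"],
                     macroMetrics(report)["f1"], n),
             sprintf("%-12s %9.4f %9.4f %9.4f %9d", "Weighted Avg",
                     weightedMetrics(report)["precision"], weightedMetrics(report)["recall"],
                     weightedMetrics(report)["f1"], n))
  lines
}
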