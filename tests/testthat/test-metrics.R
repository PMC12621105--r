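# Evaluation surface: confusion matrices, per-class metrics, aggregates,
# per-type accuracy and the seed-stability analysis.

test_that("confusion matrix counts truth/prediction pairs", {
  labels <- c("A", "B", "C")
  cm <- confusionMatrix(c("A", "B", "C"), c("A", "B", "C"), labels)
  expect_identical(sum(diag(cm)), 3L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)
  expect_error(confusionMatrix("A", c("A", "B"), labels),
               class = "bivqa_contract_error")
  expect_error(confusionMatrix("D", "A", labels), class = "bivqa_contract_error")

  set.seed(1)
  truths <- sample(labels, 100, replace = TRUE)
  preds <- sample(labels, 100, replace = TRUE)
  cm2 <- confusionMatrix(truths, preds, labels)
  # brute-force pairwise tally oracle
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    expect_identical(cm2[i, j],
                     sum(truths == labels[i] & preds == labels[j]))
  }
  expect_identical(unname(rowSums(cm2)),
                   unname(vapply(labels, function(l) sum(truths == l), 0)))
})

test_that("report metrics agree with a per-sample tallying oracle", {
  labels <- answerLabels()
  set.seed(2)
  truths <- sample(labels, 200, replace = TRUE, prob = c(4, 5, 1, 1, 2))
  preds <- ifelse(runif(200) < 0.7, truths, sample(labels, 200, replace = TRUE))
  rep_ <- evaluationReport(confusionMatrix(truths, preds, labels))
  pc <- perClassMetrics(rep_)
  for (k in seq_along(labels)) {
    l <- labels[k]
    tp <- sum(truths == l & preds == l)
    prec <- if (sum(preds == l) == 0) 0 else tp / sum(preds == l)
    rec <- if (sum(truths == l) == 0) 0 else tp / sum(truths == l)
    expect_equal(pc$precision[k], prec)
    expect_equal(pc$recall[k], rec)
    expect_equal(pc$f1[k], f1Score(prec, rec))
    expect_identical(pc$support[k], sum(truths == l))
  }
  expect_equal(overallAccuracy(rep_), mean(truths == preds))
  expect_equal(unname(macroMetrics(rep_)["precision"]), mean(pc$precision))
  expect_equal(unname(weightedMetrics(rep_)["f1"]),
               sum(pc$f1 * pc$support) / 200)
})

test_that("weighted recall equals accuracy; equal supports collapse the
           aggregates; F1 obeys the harmonic-mean bound", {
  set.seed(3)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 4), K, K,
                 dimnames = list(letters[1:K], letters[1:K]))
    if (sum(cm) == 0) next
    rep_ <- evaluationReport(cm)
    expect_equal(unname(weightedMetrics(rep_)["recall"]), overallAccuracy(rep_))
    pc <- perClassMetrics(rep_)
    expect_true(all(pc$f1 <= 2 * pmin(pc$precision, pc$recall) + 1e-12))
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
  }
  # equal supports: macro and weighted coincide
  cm_eq <- matrix(c(7, 3, 3, 7), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  rep_eq <- evaluationReport(cm_eq)
  expect_equal(macroMetrics(rep_eq), weightedMetrics(rep_eq))
})

test_that("degenerate confusion matrices follow the 0/0 conventions", {
  # class "b" never predicted and never true
  cm <- matrix(c(5L, 0L, 0L, 0L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  rep_ <- evaluationReport(cm)
  pc <- perClassMetrics(rep_)
  expect_identical(pc$precision[2], 0)
  expect_identical(pc$recall[2], 0)
  expect_identical(pc$f1[2], 0)
  expect_error(evaluationReport(matrix(0L, 2, 2)), class = "bivqa_contract_error")
  # perfect classifier: every metric 1
  diag_cm <- diag(c(3L, 4L, 5L))
  dimnames(diag_cm) <- list(letters[1:3], letters[1:3])
  rep_d <- evaluationReport(diag_cm)
  expect_equal(overallAccuracy(rep_d), 1)
  expect_true(all(perClassMetrics(rep_d)$f1 == 1))
  expect_equal(unname(macroMetrics(rep_d)), rep(1, 3))
})

test_that("per-type accuracy matches a brute-force filter and the pooled
           identity", {
  set.seed(4)
  types <- sample(questionTypes(), 120, replace = TRUE)
  correct <- runif(120) < 0.7
  pt <- perTypeAccuracy(types, correct)
  for (tp in names(pt$per_type))
    expect_equal(pt$per_type[[tp]], mean(correct[types == tp]))
  w <- table(types)[names(pt$per_type)]
  expect_equal(pt$overall, sum(pt$per_type * as.numeric(w)) / sum(w))
  expect_equal(pt$overall, mean(correct))
  # all-correct case and omitted types
  expect_true(all(perTypeAccuracy(types, rep(TRUE, 120))$per_type == 1))
  expect_warning(perTypeAccuracy(rep("WHOLE", 5), rep(TRUE, 5)),
                 "no samples")
})

test_that("seed stability reduces to the one-sample t-test", {
  # closed-form cross-check at n = 2 (df = 1: the t-distribution is Cauchy)
  res <- seedStability(c(80, 90), baseline = 84)
  expect_equal(res@mean, 85)
  expect_equal(res@sd, sd(c(80, 90)))
  t_hand <- (85 - 84) / (sd(c(80, 90)) / sqrt(2))
  expect_equal(res@tStatistic, t_hand)
  expect_equal(res@pValue, 2 * stats::pcauchy(-abs(t_hand)))

  # zero spread: degenerate flag, no t/p
  dg <- seedStability(c(84, 84, 84), baseline = 84)
  expect_true(dg@degenerate)
  expect_true(is.na(dg@tStatistic) && is.na(dg@pValue))
  expect_equal(dg@mean, 84)

  expect_error(seedStability(85, 84), class = "bivqa_contract_error")
  expect_error(seedStability(c(85, Inf), 84), class = "bivqa_contract_error")
})

test_that("report serialisation rounds to the published precision", {
  cm <- confusionMatrix(c("YES", "NO", "YES"), c("YES", "NO", "NO"),
                        c("YES", "NO"))
  rep_ <- evaluationReport(cm, perType = c(WHOLE = 2 / 3))
  lst <- reportAsList(rep_)
  expect_equal(lst$accuracy, round(2 / 3, 4))
  expect_equal(lst$per_type_accuracy_pct$WHOLE, 66.67)
  txt <- reportAsTable(rep_)
  expect_true(any(grepl("Weighted Avg", txt)))
  expect_true(any(grepl("Macro Avg", txt)))
})
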