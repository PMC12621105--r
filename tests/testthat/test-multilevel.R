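# Switch function, routing derivation and the assembled bi-level system.

test_that("the switch function routes on the predicted type or finalises", {
  rt <- c(WHOLE = "m2", REGION = "m3", FOVEA = "m2", GRADE = "m1")
  d <- switchDecision("GRADE", rt, hasNextLevel = TRUE)
  expect_identical(d$code, "ROUTE")
  expect_identical(d$target, "m1")
  # without a next level the decision is FINAL regardless of type
  for (tp in questionTypes()) {
    d0 <- switchDecision(tp, rt, hasNextLevel = FALSE)
    expect_identical(d0$code, "FINAL")
    expect_null(d0$target)
  }
  expect_error(switchDecision("WHOLE", rt[-1], hasNextLevel = TRUE),
               class = "bivqa_contract_error")
})

test_that("routing derivation picks the per-type argmax with low-index ties", {
  # per-type validation accuracies of the three component models, as published
  acc <- rbind(model1 = c(GRADE = 84.73, WHOLE = 90.84, FOVEA = 85.29, REGION = 83.22),
               model2 = c(GRADE = 83.21, WHOLE = 92.37, FOVEA = 90.84, REGION = 85.95),
               model3 = c(GRADE = 82.44, WHOLE = 88.55, FOVEA = 87.02, REGION = 88.02))
  rt <- deriveRouting(acc)
  expect_identical(rt[["GRADE"]], "model1")
  expect_identical(rt[["WHOLE"]], "model2")
  expect_identical(rt[["FOVEA"]], "model2")
  expect_identical(rt[["REGION"]], "model3")

  single <- acc[1, , drop = FALSE]
  expect_true(all(deriveRouting(single) == "model1"))

  tie <- rbind(a = c(GRADE = 1, WHOLE = 1, FOVEA = 1, REGION = 1),
               b = c(GRADE = 1, WHOLE = 1, FOVEA = 1, REGION = 1))
  expect_true(all(deriveRouting(tie) == "a"))

  expect_error(deriveRouting(acc[, 1:3]), class = "bivqa_contract_error")
})

test_that("assembly construction validates roles, routing totality and
           target existence", {
  fx <- tiny_dataset()
  l1 <- lookupModel(character(0), role = "qtype")
  l2 <- list(m1 = lookupModel(character(0), role = "answer"))
  expect_error(buildBilevel(l2$m1, l2, routing = c(WHOLE = "m1", REGION = "m1",
                                                   FOVEA = "m1", GRADE = "m1")),
               class = "bivqa_contract_error")  # level-1 role wrong
  expect_error(buildBilevel(l1, l2, routing = c(WHOLE = "missing", REGION = "m1",
                                                FOVEA = "m1", GRADE = "m1")))
  expect_error(buildBilevel(l1, l2, routing = c(WHOLE = "m1")))
  expect_error(buildBilevel(l1, l2, routing = "auto"),
               class = "bivqa_contract_error")  # no validation manifest
  mlm <- buildBilevel(l1, l2, routing = c(WHOLE = "m1", REGION = "m1",
                                          FOVEA = "m1", GRADE = "m1"))
  expect_s4_class(mlm, "MultiLevelModel")
  expect_identical(mlm@nLevels, 2L)
})

test_that("answers stay in the answer space and the trace carries the
           routing decision but not the intermediate answer", {
  fx <- tiny_dataset()
  df <- samples(manifestSplit(fx$manifest, "test"))
  truth <- stats::setNames(df$question_type, df$id)
  l1 <- lookupModel(truth, role = "qtype")
  ans <- stats::setNames(ifelse(df$question_type == "GRADE", "GRADE_1", "NO"), df$id)
  l2 <- list(m1 = lookupModel(ans, role = "answer"),
             m2 = lookupModel(ans, role = "answer"))
  mlm <- buildBilevel(l1, l2, routing = c(WHOLE = "m1", REGION = "m2",
                                          FOVEA = "m1", GRADE = "m2"))
  s <- bivqa:::load_sample(manifestSplit(fx$manifest, "test"), 1)
  out <- answerSample(mlm, s)
  expect_true(out$answer %in% answerLabels())
  expect_identical(out$trace[[1]]$decision, "ROUTE")
  expect_identical(out$trace[[2]]$decision, "FINAL")
  expect_false(identical(out$answer, out$trace[[1]]$predicted_type))
})

test_that("with an oracle router the assembly reproduces each routed model's
           per-type accuracy and dominates every component", {
  fx <- tiny_dataset()
  # planted specialists: each model excels on one type and is weak elsewhere
  m_grade <- planted_lookup_model(fx$manifest, "test",
                                  c(WHOLE = 0.4, REGION = 0.4, FOVEA = 0.4, GRADE = 1.0))
  m_bin <- planted_lookup_model(fx$manifest, "test",
                                c(WHOLE = 1.0, REGION = 0.5, FOVEA = 0.9, GRADE = 0.3))
  m_region <- planted_lookup_model(fx$manifest, "test",
                                   c(WHOLE = 0.5, REGION = 1.0, FOVEA = 0.4, GRADE = 0.3))
  l2 <- list(m1 = m_grade, m2 = m_bin, m3 = m_region)
  l1 <- lookupModel(character(0), role = "qtype")  # unused under oracle routing
  mlm <- buildBilevel(l1, l2, routing = "auto", manifest = fx$manifest,
                      split = "test")
  expect_identical(unname(routing(mlm)[c("GRADE", "WHOLE", "FOVEA", "REGION")]),
                   c("m1", "m2", "m2", "m3"))

  res <- evaluateModel(mlm, fx$manifest, split = "test", router = "oracle")
  comp <- lapply(l2, evaluateModel, manifest = fx$manifest, split = "test")
  for (tp in questionTypes()) {
    routed <- routing(mlm)[[tp]]
    expect_equal(perTypeAccuracies(res$report)[[tp]],
                 perTypeAccuracies(comp[[routed]]$report)[[tp]])
  }
  for (cv in comp) expect_gte(res$accuracy, cv$accuracy)
})

test_that("identical level-2 models make routing irrelevant", {
  fx <- tiny_dataset()
  m <- planted_lookup_model(fx$manifest, "test",
                            c(WHOLE = 0.8, REGION = 0.7, FOVEA = 0.6, GRADE = 0.5))
  l1 <- lookupModel(character(0), role = "qtype")
  base_acc <- evaluateModel(m, fx$manifest, split = "test")$accuracy
  for (rt in list(c(WHOLE = "a", REGION = "a", FOVEA = "b", GRADE = "b"),
                  c(WHOLE = "b", REGION = "a", FOVEA = "a", GRADE = "a"))) {
    mlm <- buildBilevel(l1, list(a = m, b = m), routing = rt)
    expect_equal(evaluateModel(mlm, fx$manifest, split = "test",
                               router = "oracle")$accuracy, base_acc)
  }
})

test_that("misrouting noise degrades assembly accuracy monotonically", {
  fx <- tiny_dataset()
  # strong specialists so misrouting is costly
  l2 <- list(
    m1 = planted_lookup_model(fx$manifest, "test",
                              c(WHOLE = 0.1, REGION = 0.1, FOVEA = 0.1, GRADE = 1.0)),
    m2 = planted_lookup_model(fx$manifest, "test",
                              c(WHOLE = 1.0, REGION = 0.1, FOVEA = 1.0, GRADE = 0.0)),
    m3 = planted_lookup_model(fx$manifest, "test",
                              c(WHOLE = 0.1, REGION = 1.0, FOVEA = 0.1, GRADE = 0.0)))
  df <- samples(manifestSplit(fx$manifest, "test"))
  l1 <- lookupModel(stats::setNames(df$question_type, df$id), role = "qtype")
  mlm <- buildBilevel(l1, l2, routing = c(WHOLE = "m2", REGION = "m3",
                                          FOVEA = "m2", GRADE = "m1"))
  accs <- vapply(c(0, 0.25, 0.5), function(eps) {
    set.seed(99)
    evaluateModel(mlm, fx$manifest, split = "test", misrouteProb = eps)$accuracy
  }, 0)
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})
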