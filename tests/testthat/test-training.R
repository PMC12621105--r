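# Training loop: checkpoint cadence, determinism, optimisation sanity, the
# question-type convergence property, and the seed study.

small_args <- list(dT = 16L, dV = 16L, blocksT = 1L, blocksV = 1L, dFF = 24L,
                   headHidden = 24L)

test_that("checkpoint cadence yields 2 * epochs checkpoints with provenance", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "answer", batchSize = 16L, lr = 1e-3, epochs = 2L,
                     seed = 5L)
  run <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  expect_length(run$checkpoints, 4L)
  ids <- vapply(run$checkpoints, function(ck) ck@id, "")
  expect_identical(ids, c("e1_half", "e1_end", "e2_half", "e2_end"))
  for (ck in run$checkpoints) {
    expect_identical(provenance(ck)$seed, 5L)
    expect_true(provenance(ck)$phase %in% c("half", "end"))
    expect_true(valAccuracy(ck) >= 0 && valAccuracy(ck) <= 1)
  }
  # end-only cadence halves the stream
  cfg2 <- trainConfig(role = "answer", batchSize = 16L, lr = 1e-3, epochs = 2L,
                      seed = 5L, cadence = c(half = FALSE, end = TRUE))
  expect_length(trainComponent(fx$manifest, cfg2, modelArgs = small_args)$checkpoints, 2L)
})

test_that("equal seed and configuration reproduce bit-identical checkpoints", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "answer", batchSize = 16L, lr = 1e-3, epochs = 1L,
                     seed = 42L)
  r1 <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  r2 <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  expect_identical(r1$model@params, r2$model@params)
  expect_identical(vapply(r1$checkpoints, valAccuracy, 0),
                   vapply(r2$checkpoints, valAccuracy, 0))
  # a different seed changes the initial parameters
  cfg2 <- trainConfig(role = "answer", batchSize = 16L, lr = 1e-3, epochs = 1L,
                      seed = 43L)
  r3 <- trainComponent(fx$manifest, cfg2, modelArgs = small_args)
  expect_false(identical(r1$model@params$h_W1, r3$model@params$h_W1))
})

test_that("stored checkpoint accuracies survive re-evaluation of the stored
           parameters", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3, epochs = 1L,
                     seed = 8L)
  run <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  val <- bivqa:::load_split_tensors(fx$manifest, "val")
  for (ck in run$checkpoints) {
    expect_equal(bivqa:::tensor_accuracy(ck@params, ck@config, val),
                 valAccuracy(ck))
  }
})

test_that("training reduces the loss on a learnable task", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3, epochs = 3L,
                     seed = 2L)
  run <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  ll <- run$lossLog
  expect_lt(mean(tail(ll, 3)), mean(head(ll, 3)))
})

test_that("a question-type model reaches 0.95 validation accuracy within one
           epoch on 500 synthetic samples", {
  dir <- file.path(tempdir(), "bivqa-qtype500")
  man <- generateDataset(synthConfig(n = c(train = 500, val = 150, test = 150),
                                     seed = 7L), dir)
  cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3, epochs = 1L,
                     seed = 42L)
  run <- trainComponent(man, cfg)
  final <- run$checkpoints[[length(run$checkpoints)]]
  expect_gte(valAccuracy(final), 0.95)
})

test_that("label/role mismatches and empty splits are contract errors", {
  fx <- tiny_dataset()
  df <- samples(fx$manifest)
  no_val <- newManifest(df[df$split != "val", ], dir = fx$dir)
  expect_error(trainComponent(no_val, trainConfig(role = "answer")),
               class = "bivqa_contract_error")
  m_answer <- tiny_model("answer")
  expect_error(trainComponent(fx$manifest, trainConfig(role = "qtype"),
                              model = m_answer),
               class = "bivqa_contract_error")
})

test_that("the seed study returns one deterministic accuracy per seed", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3, epochs = 1L)
  df <- runSeedStudy(fx$manifest, cfg, seeds = c(3L, 4L), modelArgs = small_args)
  expect_identical(nrow(df), 2L)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 100))
  df2 <- runSeedStudy(fx$manifest, cfg, seeds = c(3L, 3L), modelArgs = small_args)
  expect_identical(df2$accuracy[1], df2$accuracy[2])
  expect_error(runSeedStudy(fx$manifest, cfg, seeds = 3L),
               class = "bivqa_contract_error")
})

test_that("greedy soup over an emitted checkpoint stream never falls below
           the best single checkpoint", {
  fx <- tiny_dataset()
  cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3, epochs = 2L,
                     seed = 11L)
  run <- trainComponent(fx$manifest, cfg, modelArgs = small_args)
  souped <- soupTrainingRun(run, fx$manifest, k = 3)
  best <- max(vapply(run$checkpoints, valAccuracy, 0))
  expect_gte(valAccuracy(souped$soup) + 1e-12, best)
})
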