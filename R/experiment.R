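## The scaled-down end-to-end bi-level experiment: train a question-type
## router and three answer models with differing hyperparameters, greedy-soup
## each answer model's checkpoint stream, assemble with auto-derived routing,
## and evaluate the assembly against its components. Problem sizes and
## training lengths are chosen so the whole run completes in minutes on one
## CPU (see the methods vignette).

#' Default component training configurations of the bi-level experiment
#'
#' The three answer models differ in batch size, learning rate, training
#' epochs, seed and loss weighting, which is what drives their
#' per-question-type specialisation.
#'
#' @param seed Base seed; component seeds are derived from it.
#' @param epochs Baseline epochs; the three models train for `epochs / 2`,
#'   `epochs` and `1.5 * epochs` epochs respectively, giving a deliberately
#'   staggered pool: a short-schedule model, a class-weighted model that
#'   favours the rare grade answers, and a long-schedule large-batch model.
#' @return A list of [trainConfig()] objects (named model1..model3); a config
#'   may carry component-specific [componentConfig()] arguments as a
#'   `modelArgs` attribute.
#' @export
level2Configs <- function(seed = 42L, epochs = 8L) {
  list(
    model1 = trainConfig(role = "answer", batchSize = 16L, lr = 2e-3,
                         epochs = max(1L, epochs %/% 2L), seed = seed + 1L),
    model2 = trainConfig(role = "answer", batchSize = 16L, lr = 2e-3,
                         epochs = epochs, seed = seed + 2L, classWeighting = TRUE),
    model3 = trainConfig(role = "answer", batchSize = 32L, lr = 3e-3,
                         epochs = epochs + epochs %/% 2L, seed = seed + 3L))
}

#' Run the scaled-down bi-level experiment end to end
#'
#' Trains the level-1 question-type classifier, trains and greedy-soups three
#' level-2 answer models with differing hyperparameters, assembles the
#' bi-level model with auto-derived routing, and evaluates the assembly and
#' every component on the test split.
#'
#' @param manifest A [VQAManifest-class] with train/val/test splits.
#' @param seed Base seed for all training runs.
#' @param epochs Epochs per answer model.
#' @param level1Epochs Epochs for the question-type model.
#' @param modelArgs Extra [componentConfig()] arguments shared by all
#'   components (the experiment default downsamples inputs 2x for speed).
#' @param k Top-k soup pool size.
#' @return A list: `level1` (model), `level1ValAccuracy`, `components` (named
#'   list of souped [ComponentModel-class]), `soups` (named list of
#'   [SoupResult-class]), `assembly` ([MultiLevelModel-class]), `evaluation`
#'   (assembly test evaluation), `componentEvaluations` (named list),
#'   `componentAccuracies` (named numeric, test), `assemblyAccuracy` (test).
#' @export
runBilevelExperiment <- function(manifest, seed = 42L, epochs = 8L,
                                 level1Epochs = 2L,
                                 modelArgs = list(downsample = 2L), k = 3L) {
  l1cfg <- trainConfig(role = "qtype", batchSize = 16L, lr = 2e-3,
                       epochs = level1Epochs, seed = seed)
  l1run <- trainComponent(manifest, l1cfg, modelArgs = modelArgs)
  l1acc <- valAccuracy(l1run$checkpoints[[length(l1run$checkpoints)]])

  configs <- level2Configs(seed = seed, epochs = epochs)
  soups <- list()
  components <- list()
  for (nm in names(configs)) {
    margs <- attr(configs[[nm]], "modelArgs") %||% modelArgs
    run <- trainComponent(manifest, configs[[nm]], modelArgs = margs)
    souped <- soupTrainingRun(run, manifest, k = k)
    soups[[nm]] <- souped$soup
    components[[nm]] <- souped$model
  }

  assembly <- buildBilevel(l1run$model, components, routing = "auto",
                           manifest = manifest)
  evaluation <- evaluateModel(assembly, manifest, split = "test")
  evaluationOracle <- evaluateModel(assembly, manifest, split = "test",
                                    router = "oracle")
  componentEvaluations <- lapply(components, evaluateModel, manifest = manifest,
                                 split = "test")
  ## validation-split evaluations: the split the routing was derived from,
  ## where the routed mixture provably attains the per-type maxima
  valEvaluationOracle <- evaluateModel(assembly, manifest, split = "val",
                                       router = "oracle")
  valComponentEvaluations <- lapply(components, evaluateModel,
                                    manifest = manifest, split = "val")
  list(level1 = l1run$model, level1ValAccuracy = l1acc,
       components = components, soups = soups, assembly = assembly,
       evaluation = evaluation, evaluationOracle = evaluationOracle,
       componentEvaluations = componentEvaluations,
       componentAccuracies = vapply(componentEvaluations, `[[`, 0, "accuracy"),
       assemblyAccuracy = evaluation$accuracy,
       valEvaluationOracle = valEvaluationOracle,
       valComponentEvaluations = valComponentEvaluations,
       valComponentAccuracies = vapply(valComponentEvaluations, `[[`, 0, "accuracy"),
       valAssemblyOracleAccuracy = valEvaluationOracle$accuracy)
}
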