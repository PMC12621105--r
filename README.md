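# bivqa — bi-level visual question answering for retinal fundus images

`bivqa` implements a hierarchical (bi-level) visual question answering
system for diabetic macular edema (DME) style fundus imagery, together with
everything needed to exercise it end to end on a CPU: a synthetic fundus-VQA
dataset generator with geometry-derived ground truth, small trainable
reference encoders, greedy-soup checkpoint ensembling, and the full
evaluation and seed-stability machinery.

## The problem and the model

Medical VQA answers a natural-language question `Q` about a clinical image
`I` with a model `A = VQA(I, Q, Θ)`. DME questions come in four types —
presence of hard exudates in the **whole** image, in a masked **region**, in
the **fovea**, and the overall DME **grade** (0 = no exudates, 1 =
peripheral only, 2 = macular involvement) — and models with different
hyperparameters tend to excel on different types. The bi-level system
exploits that:

1. **Level 1** is a component VQA model fine-tuned to predict the *question
   type* (4-way) instead of the answer. Its prediction is intermediate: it
   is consumed only by the switch function.
2. A **switch function** routes the (image, question) pair through a routing
   table `question type → model id` to the type-specialised second-level
   model (`D = 0` emit the final answer, `D = 1` route onward).
3. **Level 2** holds several answer models (5-way: yes/no/grades 0–2), each
   fine-tuned on *all* data but with different hyperparameters. The routed
   model's answer is final.

Each component model is an encoder-fusion classifier: a text encoder whose
leading summary-token state is the question feature, an image encoder that
patchifies the image (`(X − μ)/σ`, zero-pad to the patch grid, non-overlapping
`P×P` patches, linear embedding + positional embeddings, attention blocks,
mean pooling `F = (1/N) Σ H_i`), per-modality L2 normalisation, concatenation,
and an MLP softmax head.

Component models are improved by **greedy-soup ensembling**: checkpoints are
written at mid-epoch and epoch end with their measured validation accuracy;
the top-k (k = 3) checkpoints are sorted by descending accuracy, the soup
starts with the best, and each remaining candidate is averaged in
(`θ′ = (1/j) Σ θ_i`, uniformly across the visual Θ1, textual Θ2 and head Θ3
components) and kept iff validation accuracy does not drop — so the soup is
never worse on validation than its best ingredient.

The routing table is derived from data: `routing[t] = argmax_m valAcc_m(t)`,
the per-type validation argmax over the level-2 pool. With a well-trained
router the assembly's per-type accuracy equals the routed model's, so the
assembly attains the per-type maxima of its component pool.

## Worked example

Generate a small synthetic dataset, fine-tune a question-type model, soup
its checkpoints, and evaluate:

```r
library(bivqa)

dir <- file.path(tempdir(), "readme-demo")
manifest <- generateDataset(tinyPreset(seed = 42), dir)
manifest
#> VQAManifest with 112 samples
#>   splits: test=24, train=64, val=24
#>   types:  FOVEA=28, GRADE=28, REGION=28, WHOLE=28

run <- trainComponent(manifest,
                      trainConfig(role = "qtype", batchSize = 16, lr = 2e-3,
                                  epochs = 2, seed = 42))
souped <- soupTrainingRun(run, manifest, k = 3)
souped$soup
#> SoupResult: 3 ingredient(s) [e1_end, e2_half, e2_end], valAccuracy=1.0000

ev <- evaluateModel(souped$model, manifest, split = "test")
ev$report
#> EvaluationReport over 24 samples, accuracy 1.0000
#>   macro    P/R/F1: 1.0000/1.0000/1.0000
#>   weighted P/R/F1: 1.0000/1.0000/1.0000
#>   per-type accuracy (%): WHOLE=100.00, REGION=100.00, FOVEA=100.00, GRADE=100.00
```

The question-type level saturates quickly because the four question
templates are almost fully revealed by the question text and the region
mask. The seed-stability analysis is a one-sample two-tailed t-test of the
per-seed accuracies against a fixed baseline:

```r
seedStability(c(86.04, 86.12, 87.41, 86.12, 85.89), baseline = 83.69,
              seeds = c(10, 23, 42, 70, 100))
#> SeedStudyResult over 5 seeds: mean 86.32%, sd 0.62
#>   vs baseline 83.69%: t = 9.49, p = 0.0007 (df = 4)
```

A full bi-level experiment — level-1 router, three level-2 answer models
with staggered hyperparameters, greedy soup, auto-derived routing — is one
call: `runBilevelExperiment(generateDataset(dmeLikePreset(seed = 42), dir))`.

There is also a thin command-line surface over the same functions
(`inst/cli/bivqa.R`) with subcommands `generate`, `train`, `soup`,
`assemble`, `evaluate` and `seed-study`.

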