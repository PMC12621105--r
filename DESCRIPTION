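Package: bivqa
Title: Bi-Level Visual Question Answering for Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-level (bi-level) visual question answering framework for
    diabetic macular edema style fundus imagery. The first level classifies the
    question type (whole image, masked region, fovea, or grade); a switch
    function routes the image-question pair to a type-specialised second-level
    answer model; second-level models are ensembled by greedy-soup parameter
    averaging of training checkpoints. Includes small trainable reference
    text/image transformer encoders with a normalise-concatenate-MLP fusion
    head, a synthetic fundus VQA dataset generator with geometry-derived ground
    truth, the full evaluation surface (confusion matrices, per-class and
    macro/weighted precision, recall and F1, per-question-type accuracy), and a
    seed-stability study with a one-sample t-test against a fixed baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'labels.R'
    'AllGenerics.R'
    'AllClasses.R'
    'manifest.R'
    'synth-scene.R'
    'synth-generate.R'
    'encoder-text.R'
    'encoder-image.R'
    'fusion.R'
    'component.R'
    'training.R'
    'soup.R'
    'multilevel.R'
    'metrics.R'
    'io.R'
    'cli.R'
    'experiment.R'
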