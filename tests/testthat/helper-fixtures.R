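# Shared fixtures. Heavy artifacts (generated datasets) are built once per
# test session and cached in the session temp directory.

.fixture_env <- new.env(parent = emptyenv())

# A small generated dataset (48x48 images, uniform type mix) used by most
# integration-level tests.
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    dir <- file.path(tempdir(), "bivqa-tiny")
    man <- generateDataset(tinyPreset(seed = 42L), dir)
    .fixture_env$tiny <- list(dir = dir, manifest = man)
  }
  .fixture_env$tiny
}

# A minimal component configuration for fast unit tests of the encoders.
tiny_cfg <- function(role = "answer", vocab = NULL, ...) {
  if (is.null(vocab))
    vocab <- buildVocabulary(vapply(questionTypes(), questionText, ""))
  componentConfig(role, vocab, imageSize = c(16, 16), mu = c(0.2, 0, 0, 0),
                  sigma = c(0.25, 1, 1, 1), dT = 8L, dV = 8L, blocksT = 1L,
                  blocksV = 1L, dFF = 12L, patch = 8L, headHidden = 10L,
                  maxLen = 12L, ...)
}

tiny_model <- function(role = "answer", seed = 1L, ...) {
  set.seed(seed)
  newComponentModel(tiny_cfg(role, ...))
}

random_sample_record <- function(cfg, seed = 1L, with_mask = FALSE) {
  set.seed(seed)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  list(id = "s1", question = questionText("WHOLE"),
       question_type = if (with_mask) "REGION" else "WHOLE",
       answer = "YES", split = "train",
       image = matrix(runif(H * W), H, W),
       mask = if (with_mask) matrix(rbinom(H * W, 1, 0.3), H, W) else NULL)
}

# A checkpoint around an arbitrary parameter list (for soup fixtures).
param_checkpoint <- function(id, params, val_accuracy, order = 1L) {
  new("Checkpoint", id = id, params = params, config = list(),
      valAccuracy = val_accuracy,
      provenance = list(epoch = order, phase = "end", hyperparameters = list(),
                        seed = 1L))
}

# Lookup answer models with planted per-type accuracies over a manifest
# split: for each question type, the first `round(rate * n_t)` samples (in
# manifest order) answer correctly, the rest get a deliberately wrong label.
planted_lookup_model <- function(manifest, split, rates) {
  df <- samples(manifestSplit(manifest, split))
  tab <- character(0)
  for (tp in names(rates)) {
    rows <- df[df$question_type == tp, ]
    if (nrow(rows) == 0) next
    n_ok <- round(rates[[tp]] * nrow(rows))
    for (i in seq_len(nrow(rows))) {
      truth <- rows$answer[i]
      lab <- if (i <= n_ok) truth else {
        wrong <- setdiff(compatibleAnswers(rows$question_type[i]), truth)
        wrong[1]
      }
      tab[rows$id[i]] <- lab
    }
  }
  lookupModel(tab, role = "answer")
}

expect_file_identical <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
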