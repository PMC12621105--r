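## The component VQA model: configuration, initialisation, the end-to-end
## forward pass (tokenize -> text encoder -> image encoder -> fuse -> MLP) and
## its backward pass, plus prediction/evaluation over manifests.
##
## Model inputs stack the grayscale fundus image, the region mask (all-zero
## when the question has no mask) and, by default, derived high-pass channels
## (see sample_input). The mask channel is what lets the model tell region
## questions apart from whole-image questions; the derived channels expose
## small bright lesions, and lesion-in-region structure, to the linear patch
## embedding.

#' Build a component-model configuration
#'
#' Defaults are deliberately small so the whole system trains in seconds on a
#' CPU: 64-dimensional text and image features, two attention blocks per
#' encoder, patch size 8, and a 128-unit MLP hidden layer. Larger pretrained
#' backbones can be plugged in through the same operation surface
#' (tokenize / text features / image features / fuse / classify) by supplying
#' a model object honouring those signatures.
#'
#' @param role "answer" (5-way answer head) or "qtype" (4-way question-type
#'   head).
#' @param vocab Vocabulary from [buildVocabulary()].
#' @param imageSize `(H, W)` the model expects.
#' @param mu,sigma Per-channel normalisation constants (typically training
#'   split statistics; stored with the model).
#' @param dT,dV Text / image feature widths.
#' @param blocksT,blocksV Attention blocks per encoder.
#' @param dFF Feed-forward width inside attention blocks.
#' @param patch Patch size.
#' @param headHidden MLP hidden width.
#' @param maxLen Maximum token-sequence length.
#' @param channels Input channels: 2 = image + mask; 3 = additionally the
#'   image-mask product; 4 = image, mask, positive high-pass response and its
#'   mask conjunction (see the methods vignette).
#' @param downsample Integer block-average downsampling factor applied to the
#'   input before patchification (a parameter-free preprocessing step of the
#'   image encoder; 1 = native resolution).
#' @param normalization Per-modality feature normalisation: "l2" or
#'   "standardize".
#' @param featureScale Fixed multiplier applied to the fused vector at the
#'   head input; the default `sqrt((dT + dV) / 2)` restores the scale
#'   per-dimension-standardised features would have, so the head trains at
#'   ordinary learning rates despite the unit-norm modality blocks.
#' @return A configuration list.
#' @export
componentConfig <- function(role = c("answer", "qtype"), vocab,
                            imageSize = c(96, 96), mu = 0, sigma = 1,
                            dT = 64L, dV = 64L, blocksT = 2L, blocksV = 2L,
                            dFF = 128L, patch = 8L, headHidden = 128L,
                            maxLen = 16L, channels = 4L, downsample = 1L,
                            normalization = c("l2", "standardize"),
                            featureScale = sqrt((dT + dV) / 2)) {
  role <- match.arg(role)
  if (!is_count(downsample)) contract_error("downsample must be a positive integer")
  labels <- if (role == "answer") answerLabels() else questionTypes()
  eff <- as.integer(ceiling(imageSize / downsample))
  list(role = role, labels = labels, vocab = vocab,
       image_size = as.integer(imageSize),
       mu = rep_len(mu, channels), sigma = rep_len(sigma, channels),
       d_t = as.integer(dT), d_v = as.integer(dV),
       blocks_t = as.integer(blocksT), blocks_v = as.integer(blocksV),
       d_ff = as.integer(dFF), patch = as.integer(patch),
       head_hidden = as.integer(headHidden), max_len = as.integer(maxLen),
       channels = as.integer(channels), downsample = as.integer(downsample),
       n_patches = as.integer(prod(ceiling(eff / patch))),
       normalization = match.arg(normalization),
       feature_scale = featureScale)
}

## Block-average downsampling of an H x W matrix by an integer factor
## (bottom/right zero padding to a multiple of the factor).
block_downsample <- function(M, f) {
  if (f == 1L) return(M)
  H <- nrow(M); W <- ncol(M)
  Hp <- as.integer(ceiling(H / f) * f); Wp <- as.integer(ceiling(W / f) * f)
  X <- matrix(0, Hp, Wp)
  X[seq_len(H), seq_len(W)] <- M
  A <- array(X, c(f, Hp %/% f, f, Wp %/% f))
  colMeans(aperm(A, c(1, 3, 2, 4)), dims = 2)
}

## Parameter initialisation, consuming the global RNG: Xavier-scaled Gaussian
## weight matrices (sd = sqrt(2 / (fan_in + fan_out))), embedding tables at
## sd = 1/sqrt(d), zero biases, unit layer-norm gains.
init_params <- function(cfg) {
  rn <- function(nr, nc) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  emb <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  p <- list(
    t_emb = emb(length(cfg$vocab), cfg$d_t),
    t_pos = emb(cfg$max_len, cfg$d_t),
    v_Wemb = rn(cfg$patch^2 * cfg$channels, cfg$d_v),
    v_bemb = numeric(cfg$d_v),
    v_pos = emb(cfg$n_patches, cfg$d_v)
  )
  block <- function(pf, d) {
    p[[paste0(pf, "ln1_g")]] <<- rep(1, d); p[[paste0(pf, "ln1_b")]] <<- numeric(d)
    p[[paste0(pf, "Wqkv")]] <<- rn(d, 3L * d); p[[paste0(pf, "Wo")]] <<- rn(d, d)
    p[[paste0(pf, "ln2_g")]] <<- rep(1, d); p[[paste0(pf, "ln2_b")]] <<- numeric(d)
    p[[paste0(pf, "W1")]] <<- rn(d, cfg$d_ff); p[[paste0(pf, "b1")]] <<- numeric(cfg$d_ff)
    p[[paste0(pf, "W2")]] <<- rn(cfg$d_ff, d); p[[paste0(pf, "b2")]] <<- numeric(d)
  }
  for (b in seq_len(cfg$blocks_t)) block(sprintf("t%d_", b), cfg$d_t)
  for (b in seq_len(cfg$blocks_v)) block(sprintf("v%d_", b), cfg$d_v)
  p$h_W1 <- rn(cfg$d_t + cfg$d_v, cfg$head_hidden)
  p$h_b1 <- numeric(cfg$head_hidden)
  p$h_W2 <- rn(cfg$head_hidden, length(cfg$labels))
  p$h_b2 <- numeric(length(cfg$labels))
  p
}

## Which parameter component (visual / textual / head) a named array belongs to.
param_component <- function(name) {
  c(v = "theta1", t = "theta2", h = "theta3")[substr(name, 1, 1)]
}

#' Create a component model
#'
#' @param config From [componentConfig()].
#' @param params Optional parameter list; freshly initialised from the current
#'   RNG state when omitted.
#' @return A [ComponentModel-class].
#' @export
newComponentModel <- function(config, params = NULL) {
  if (is.null(params)) params <- init_params(config)
  new("ComponentModel", config = config, params = params)
}

## ------------------------------------------------------------------
## Sample input preparation

## Box blur with an integer radius (window 2r+1), via separable running sums
## with edge replication in the normalisation.
box_blur <- function(M, r) {
  n <- 2L * r + 1L
  run <- function(X) {
    cs <- apply(rbind(0, X), 2, cumsum)
    H <- nrow(X)
    lo <- pmax(seq_len(H) - r - 1L, 0L)
    hi <- pmin(seq_len(H) + r, H)
    (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
  }
  t(run(t(run(M))))
}

## Model input tensor. Channels:
##   2: image, mask (zeros when absent)
##   3: + image*mask product
##   4: image, mask, positive high-pass response, high-pass*mask.
## The high-pass channel (image minus a 5x5 box blur, clipped at zero) is the
## classic small-bright-lesion detector: it responds to compact hard-exudate
## blobs while suppressing the larger smooth optic disc, and its mask
## conjunction exposes lesion-in-region structure to the linear patch
## embedding. Inputs are optionally block-average downsampled first.
sample_input <- function(sample, cfg) {
  img <- sample$image
  msk <- if (is.null(sample$mask)) matrix(0, nrow(img), ncol(img)) else sample$mask
  f <- cfg$downsample %||% 1L
  if (f > 1L) {
    img <- block_downsample(img, f)
    msk <- block_downsample(msk, f)
  }
  ch <- cfg$channels %||% 2L
  if (ch >= 4L) {
    hp <- pmax(img - box_blur(img, 2L), 0)
    array(c(img, msk, hp, hp * msk), c(dim(img), 4L))
  } else if (ch == 3L) {
    array(c(img, msk, img * msk), c(dim(img), 3L))
  } else {
    array(c(img, msk), c(dim(img), 2L))
  }
}

## The training target for a sample under the model role: role "qtype"
## replaces the answer with the question type.
target_label <- function(sample, role) {
  if (role == "answer") sample$answer else sample$question_type
}

## Tokenize all samples, memoised over the (tiny) set of distinct questions.
tokenize_all <- function(tensors, vocab) {
  qs <- vapply(tensors, `[[`, "", "question")
  uq <- unique(qs)
  idmap <- lapply(uq, tokenize, vocab = vocab)
  names(idmap) <- uq
  lapply(qs, function(q) idmap[[q]])
}

## ------------------------------------------------------------------
## Forward / loss / gradient for one sample

component_forward <- function(params, cfg, ids, input) {
  tf <- text_forward(ids, params, cfg)
  vf <- image_forward(input, params, cfg)
  fu <- fuse_forward(tf$feature, vf$feature, cfg)
  hd <- head_forward(fu$fused, params, cfg$feature_scale %||% 1)
  list(scores = hd$scores, tf = tf, vf = vf, fu = fu, hd = hd)
}

## Cross-entropy loss and parameter gradients (accumulated into gacc).
component_loss_grad <- function(params, cfg, ids, input, y_index, gacc, weight = 1) {
  fwd <- component_forward(params, cfg, ids, input)
  p <- fwd$scores
  loss <- -log(max(p[y_index], 1e-12)) * weight
  dlogits <- p * weight
  dlogits[y_index] <- dlogits[y_index] - weight
  dfused <- head_backward(dlogits, fwd$hd, params, gacc)
  dmod <- fuse_backward(dfused, fwd$fu, cfg)
  text_backward(dmod$dtext, fwd$tf, params, cfg, gacc)
  image_backward(dmod$dimage, fwd$vf, params, cfg, gacc)
  loss
}

## Cross-entropy loss and gradients for a minibatch. The question language is
## a small closed set, so the text encoder runs once per distinct question;
## backpropagation is linear in the output gradient, so the per-sample text
## gradients are summed per question and pushed through one backward pass.
batch_loss_grad <- function(params, cfg, questions, inputs, y_idx, weights, gacc) {
  uq <- unique(questions)
  tf <- lapply(uq, function(q) text_forward(tokenize(q, cfg$vocab), params, cfg))
  names(tf) <- uq
  dtext <- stats::setNames(rep(list(numeric(cfg$d_t)), length(uq)), uq)
  total <- 0
  for (i in seq_along(inputs)) {
    q <- questions[i]
    vf <- image_forward(inputs[[i]], params, cfg)
    fu <- fuse_forward(tf[[q]]$feature, vf$feature, cfg)
    hd <- head_forward(fu$fused, params, cfg$feature_scale %||% 1)
    w <- weights[i]
    total <- total - log(max(hd$scores[y_idx[i]], 1e-12)) * w
    dlogits <- hd$scores * w
    dlogits[y_idx[i]] <- dlogits[y_idx[i]] - w
    dfused <- head_backward(dlogits, hd, params, gacc)
    dmod <- fuse_backward(dfused, fu, cfg)
    dtext[[q]] <- dtext[[q]] + dmod$dtext
    image_backward(dmod$dimage, vf, params, cfg, gacc)
  }
  for (q in uq) text_backward(dtext[[q]], tf[[q]], params, cfg, gacc)
  total
}

## Predicted labels for a list of in-memory samples under (params, cfg),
## with the text features computed once per distinct question.
predict_tensors <- function(params, cfg, tensors) {
  qs <- vapply(tensors, `[[`, "", "question")
  uq <- unique(qs)
  tfeat <- lapply(uq, function(q)
    text_forward(tokenize(q, cfg$vocab), params, cfg)$feature)
  names(tfeat) <- uq
  vapply(seq_along(tensors), function(i) {
    vfeat <- image_forward(sample_input(tensors[[i]], cfg), params, cfg)$feature
    fu <- fuse_forward(tfeat[[qs[i]]], vfeat, cfg)
    cfg$labels[which.max(head_forward(fu$fused, params, cfg$feature_scale %||% 1)$scores)]
  }, "")
}

## Accuracy of (params, cfg) on in-memory samples.
tensor_accuracy <- function(params, cfg, tensors) {
  pred <- predict_tensors(params, cfg, tensors)
  truth <- vapply(tensors, target_label, "", role = cfg$role)
  mean(pred == truth)
}

#' Validation-accuracy evaluator over a manifest split
#'
#' Returns a closure mapping a parameter set to accuracy on the given split
#' under the supplied model configuration — the evaluator consumed by
#' [greedySoup()]. Every call re-runs the full validation pass; nothing is
#' cached across parameter sets.
#'
#' @param config A component-model configuration.
#' @param manifest A [VQAManifest-class].
#' @param split Manifest split to evaluate on.
#' @return `function(params) -> accuracy in [0, 1]`.
#' @export
accuracyEvaluator <- function(config, manifest, split = "val") {
  tensors <- load_split_tensors(manifest, split)
  function(params) tensor_accuracy(params, config, tensors)
}

## ------------------------------------------------------------------
## Prediction / evaluation methods

#' @rdname predictSample
setMethod("predictSample", "ComponentModel", function(model, sample, ...) {
  cfg <- model@config
  ids <- tokenize(sample$question, cfg$vocab)
  fwd <- component_forward(model@params, cfg, ids, sample_input(sample, cfg))
  scores <- fwd$scores
  names(scores) <- cfg$labels
  list(label = cfg$labels[which.max(scores)], scores = scores)
})

#' @rdname predictSample
setMethod("predictSample", "LookupModel", function(model, sample, ...) {
  lab <- model@table[sample$id]
  if (is.na(lab)) lab <- model@fallback
  scores <- stats::setNames(as.numeric(model@labels == lab), model@labels)
  list(label = unname(lab), scores = scores)
})

#' Create a lookup (planted-label) model
#'
#' @param table Named character vector mapping sample ids to labels.
#' @param role "answer" or "qtype".
#' @param fallback Label for unseen ids (defaults to the first label of the
#'   role's space).
#' @return A [LookupModel-class].
#' @export
lookupModel <- function(table, role = c("answer", "qtype"), fallback = NULL) {
  role <- match.arg(role)
  labels <- if (role == "answer") answerLabels() else questionTypes()
  if (length(table) > 0 && !all(table %in% labels))
    contract_error("lookup table contains labels outside the %s space", role)
  if (is.null(fallback)) fallback <- labels[1]
  new("LookupModel", table = table, fallback = fallback, labels = labels, role = role)
}

#' @rdname evaluateModel
#' @param split Manifest split to evaluate on.
setMethod("evaluateModel", signature("VQAModel", "VQAManifest"),
          function(model, manifest, split = "test", ...) {
  tensors <- load_split_tensors(manifest, split)
  if (length(tensors) == 0) contract_error("empty split '%s'", split)
  role <- if (is(model, "ComponentModel")) model@config$role else model@role
  labels <- if (is(model, "ComponentModel")) model@config$labels else model@labels
  pred <- vapply(tensors, function(s) predictSample(model, s)$label, "")
  truth <- vapply(tensors, target_label, "", role = role)
  types <- vapply(tensors, `[[`, "", "question_type")
  cm <- confusionMatrix(truth, pred, labels)
  report <- evaluationReport(cm, perType = perTypeAccuracy(types, pred == truth)$per_type)
  predictions <- data.frame(
    id = vapply(tensors, `[[`, "", "id"),
    true_answer = if (role == "answer") truth else NA_character_,
    predicted_answer = if (role == "answer") pred else NA_character_,
    true_type = types,
    predicted_type = if (role == "qtype") pred else NA_character_,
    routed_model = NA_character_, stringsAsFactors = FALSE)
  list(predictions = predictions, report = report, accuracy = report@accuracy)
})
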