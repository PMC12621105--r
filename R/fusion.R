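## Fusion of the two modality features and the MLP classification head.
## Each modality vector is normalised independently so the two are on a
## similar scale, then concatenated text-first and passed through a one-hidden-
## layer MLP with a softmax output over the model's label space.

norm_forward <- function(x, method, eps = 1e-8) {
  if (method == "l2") {
    n <- sqrt(sum(x * x))
    if (n < 1e-12) return(list(y = x * 0, norm = 0, method = method))
    list(y = x / n, norm = n, method = method)
  } else {  # per-vector standardisation
    m <- mean(x)
    u <- x - m
    s <- sqrt(mean(u * u) + eps)
    list(y = u / s, s = s, method = method)
  }
}

norm_backward <- function(dy, cache) {
  if (cache$method == "l2") {
    if (cache$norm == 0) return(dy * 0)
    y <- cache$y
    (dy - y * sum(y * dy)) / cache$norm
  } else {
    y <- cache$y
    h <- (dy - y * mean(dy * y)) / cache$s
    h - mean(h)
  }
}

fuse_forward <- function(tfeat, vfeat, cfg) {
  if (!all(is.finite(tfeat)) || !all(is.finite(vfeat)))
    contract_error("non-finite feature entries passed to fuse")
  tn <- norm_forward(tfeat, cfg$normalization)
  vn <- norm_forward(vfeat, cfg$normalization)
  if (cfg$normalization == "l2" && (identical(tn$norm, 0) || identical(vn$norm, 0)))
    log_event("fuse_zero_vector")
  list(fused = c(tn$y, vn$y), tcache = tn, vcache = vn)
}

fuse_backward <- function(dfused, fwd, cfg) {
  dt <- length(fwd$tcache$y)
  list(dtext = norm_backward(dfused[seq_len(dt)], fwd$tcache),
       dimage = norm_backward(dfused[-seq_len(dt)], fwd$vcache))
}

#' Fuse a text and an image feature
#'
#' Normalises each modality vector independently (per-vector L2 by default; a
#' zero vector maps to zero) and concatenates text-first. For nonzero inputs
#' under L2 normalisation the fused vector has squared norm 2, and the fusion
#' is invariant to positive rescaling of either input.
#'
#' @param model A [ComponentModel-class] (supplies the normalisation choice).
#' @param textFeature,imageFeature Finite numeric vectors.
#' @return Numeric vector of length `D_t + D_v`.
#' @export
fuseFeatures <- function(model, textFeature, imageFeature) {
  fuse_forward(textFeature, imageFeature, model@config)$fused
}

## ------------------------------------------------------------------
## MLP head
##
## The fused vector enters the head multiplied by a fixed feature scale
## (sqrt((D_t + D_v) / 2) by default), which maps the two unit-norm modality
## blocks onto the scale per-dimension-standardised features would have;
## without it the unit-norm inputs force impractically large head weights.

head_forward <- function(fused, params, scale = 1) {
  fs <- fused * scale
  z1 <- drop(fs %*% params$h_W1) + params$h_b1
  r <- relu(z1)
  z2 <- drop(r %*% params$h_W2) + params$h_b2
  list(scores = softmax_vec(z2), z1 = z1, r = r, fs = fs, scale = scale)
}

## dlogits -> gradient of head params (into gacc) and of the fused vector.
head_backward <- function(dlogits, fwd, params, gacc) {
  gadd(gacc, "h_W2", outer(fwd$r, dlogits))
  gadd(gacc, "h_b2", dlogits)
  dr <- drop(params$h_W2 %*% dlogits)
  dz1 <- dr * (fwd$z1 > 0)
  gadd(gacc, "h_W1", outer(fwd$fs, dz1))
  gadd(gacc, "h_b1", dz1)
  drop(params$h_W1 %*% dz1) * fwd$scale
}

#' Classify a fused feature vector
#'
#' Applies the MLP head and softmax. Scores sum to one; the predicted label is
#' the argmax with ties broken toward the lowest label index.
#'
#' @param model A [ComponentModel-class].
#' @param fused Fused feature vector from [fuseFeatures()].
#' @return List with `scores` (named probabilities) and `label`.
#' @export
classifyFeatures <- function(model, fused) {
  params <- model@params
  if (length(fused) != nrow(params$h_W1))
    contract_error("fused width %d does not match head input width %d",
                   length(fused), nrow(params$h_W1))
  scores <- head_forward(fused, params, model@config$feature_scale %||% 1)$scores
  names(scores) <- model@config$labels
  list(scores = scores, label = model@config$labels[which.max(scores)])
}
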