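## Reference image encoder: normalise, zero-pad to a multiple of the patch
## size, split into non-overlapping patches, linearly embed, add learned
## positional embeddings, run the shared attention blocks, and mean-pool the
## final patch states into a fixed-length feature.

#' Split an image into normalised, flattened patches
#'
#' The image is normalised as `(x - mu) / sigma` per channel, zero-padded on
#' the bottom/right to the next multiple of `P`, and split row-major into
#' `ceiling(H/P) * ceiling(W/P)` flattened patches (channel-stacked for
#' multi-channel inputs).
#'
#' @param image H x W matrix or H x W x C array.
#' @param P Patch size (>= 1).
#' @param mu,sigma Per-channel normalisation constants; `sigma` must be
#'   strictly positive.
#' @return N x (P^2 C) matrix of patch vectors.
#' @export
patchify <- function(image, P, mu = 0, sigma = 1) {
  if (!is_count(P)) contract_error("patch size must be a positive integer")
  if (any(sigma <= 0)) contract_error("sigma must be strictly positive")
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  mu <- rep_len(mu, C); sigma <- rep_len(sigma, C)
  Hp <- as.integer(ceiling(H / P) * P); Wp <- as.integer(ceiling(W / P) * P)
  nbr <- Hp %/% P; nbc <- Wp %/% P
  per_channel <- lapply(seq_len(C), function(ch) {
    X <- matrix(0, Hp, Wp)  # zero padding after normalisation
    X[seq_len(H), seq_len(W)] <- (image[, , ch] - mu[ch]) / sigma[ch]
    ## A[p, bi, q, bj] = X[(bi-1)P+p, (bj-1)P+q]; column order (bj fastest,
    ## then bi) gives row-major patch ordering over the patch grid.
    A <- array(X, c(P, nbr, P, nbc))
    t(matrix(aperm(A, c(1, 3, 4, 2)), nrow = P * P))
  })
  do.call(cbind, per_channel)
}

image_forward <- function(image, params, cfg) {
  X <- patchify(image, cfg$patch, cfg$mu, cfg$sigma)
  if (nrow(X) != nrow(params$v_pos))
    contract_error("image yields %d patches but the model was configured for %d",
                   nrow(X), nrow(params$v_pos))
  E <- add_rows(X %*% params$v_Wemb, params$v_bemb)
  H <- E + params$v_pos
  caches <- vector("list", cfg$blocks_v)
  for (b in seq_len(cfg$blocks_v)) {
    out <- attn_block_forward(H, params, sprintf("v%d_", b))
    H <- out$H
    caches[[b]] <- out$cache
  }
  list(feature = colMeans(H), H = H, X = X, caches = caches)
}

image_backward <- function(dfeature, fwd, params, cfg, gacc) {
  N <- nrow(fwd$X)
  dH <- matrix(dfeature / N, N, cfg$d_v, byrow = TRUE)  # mean pool
  for (b in rev(seq_len(cfg$blocks_v))) {
    dH <- attn_block_backward(dH, fwd$caches[[b]], params, sprintf("v%d_", b), gacc)
  }
  gadd(gacc, "v_pos", dH)
  gadd(gacc, "v_Wemb", crossprod(fwd$X, dH))
  gadd(gacc, "v_bemb", colSums(dH))
  invisible(NULL)
}

#' Extract the pooled image feature
#'
#' Patchify, embed, attend, then average the final patch states over all
#' patches: a fixed-length vector independent of image size (for the size the
#' model was configured with).
#'
#' @param model A [ComponentModel-class].
#' @param image H x W matrix or H x W x C array with values in [0, 1].
#' @return Numeric vector of length `D_v`.
#' @export
imageFeatures <- function(model, image) {
  image_forward(image, model@params, model@config)$feature
}
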