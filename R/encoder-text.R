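## Reference text encoder: word-level tokenizer, learned token + position
## embeddings, and a small stack of single-head self-attention blocks. The
## final hidden state at the leading summary-token position is the sentence
## feature. Forward and backward passes are written out explicitly (no
## autodiff backend); gradients are verified against finite differences in the
## test suite.

.RESERVED_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[UNK]")

#' Build a word vocabulary from training questions
#'
#' Lowercases, strips punctuation, splits on whitespace, and assigns ids after
#' four reserved tokens (padding, summary marker, separator, unknown). The
#' question language is a small closed template set, so the vocabulary is tiny.
#'
#' @param questions Character vector of question strings.
#' @return Named integer vector token -> id.
#' @export
buildVocabulary <- function(questions) {
  words <- sort(unique(unlist(lapply(questions, split_words))))
  stats::setNames(seq_len(length(.RESERVED_TOKENS) + length(words)),
                  c(.RESERVED_TOKENS, words))
}

split_words <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9 ]", " ", text)
  w <- strsplit(trimws(text), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Tokenize a question
#'
#' Word tokens are wrapped by the summary and separator markers, so the id
#' sequence length is always the word count plus two. Out-of-vocabulary words
#' map to the unknown id. Empty text yields just the two markers.
#'
#' @param question Question string.
#' @param vocab Vocabulary from [buildVocabulary()].
#' @return Integer id sequence.
#' @export
tokenize <- function(question, vocab) {
  if (!all(.RESERVED_TOKENS %in% names(vocab)))
    contract_error("vocabulary is missing reserved marker tokens")
  words <- split_words(question)
  ids <- unname(vocab[words])
  ids[is.na(ids)] <- vocab[["[UNK]"]]
  c(vocab[["[CLS]"]], ids, vocab[["[SEP]"]])
}

## ------------------------------------------------------------------
## Shared self-attention block (used by both encoders), pre-norm form:
##
##   H1 = H  + softmax(Q K'/sqrt(d)) V Wo   with Q,K,V from LN1(H)
##   H2 = H1 + relu(LN2(H1) W1 + b1) W2 + b2
##
## Single head; row-wise layer normalisation with learnable gain/bias keeps
## activations bounded so the from-scratch encoders train stably.

ln_forward <- function(H, g, b, eps = 1e-6) {
  m <- rowMeans(H)
  u <- H - m
  s <- sqrt(rowMeans(u * u) + eps)
  xhat <- u / s
  list(Y = xhat * rep(g, each = nrow(H)) + rep(b, each = nrow(H)),
       xhat = xhat, s = s)
}

ln_backward <- function(dY, cache, g, gacc, gname, bname) {
  xhat <- cache$xhat
  gadd(gacc, gname, colSums(dY * xhat))
  gadd(gacc, bname, colSums(dY))
  dxhat <- dY * rep(g, each = nrow(dY))
  r1 <- rowMeans(dxhat)
  r2 <- rowMeans(dxhat * xhat)
  (dxhat - r1 - xhat * r2) / cache$s
}

attn_block_forward <- function(H, params, pf) {
  p <- function(nm) params[[paste0(pf, nm)]]
  d <- ncol(H)
  n1 <- ln_forward(H, p("ln1_g"), p("ln1_b"))
  QKV <- n1$Y %*% p("Wqkv")  # fused projection: columns [Q | K | V]
  Q <- QKV[, seq_len(d), drop = FALSE]
  K <- QKV[, d + seq_len(d), drop = FALSE]
  V <- QKV[, 2 * d + seq_len(d), drop = FALSE]
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d))
  C <- A %*% V
  H1 <- H + C %*% p("Wo")
  n2 <- ln_forward(H1, p("ln2_g"), p("ln2_b"))
  Z <- add_rows(n2$Y %*% p("W1"), p("b1"))
  R <- relu(Z)
  H2 <- H1 + add_rows(R %*% p("W2"), p("b2"))
  list(H = H2, cache = list(H = H, n1 = n1, Q = Q, K = K, V = V, A = A, C = C,
                            H1 = H1, n2 = n2, Z = Z, R = R))
}

attn_block_backward <- function(dH2, cache, params, pf, gacc) {
  p <- function(nm) params[[paste0(pf, nm)]]
  d <- ncol(cache$H)

  ## feed-forward sub-layer
  dR <- tcrossprod(dH2, p("W2"))
  dZ <- dR * (cache$Z > 0)
  gadd(gacc, paste0(pf, "W2"), crossprod(cache$R, dH2))
  gadd(gacc, paste0(pf, "b2"), .colSums(dH2, nrow(dH2), d))
  gadd(gacc, paste0(pf, "W1"), crossprod(cache$n2$Y, dZ))
  gadd(gacc, paste0(pf, "b1"), .colSums(dZ, nrow(dZ), ncol(dZ)))
  dN2 <- tcrossprod(dZ, p("W1"))
  dH1 <- dH2 + ln_backward(dN2, cache$n2, p("ln2_g"), gacc,
                           paste0(pf, "ln2_g"), paste0(pf, "ln2_b"))

  ## attention sub-layer
  dO <- dH1
  gadd(gacc, paste0(pf, "Wo"), crossprod(cache$C, dO))
  dC <- tcrossprod(dO, p("Wo"))
  dA <- tcrossprod(dC, cache$V)
  dV <- crossprod(cache$A, dC)
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- crossprod(dS, cache$Q) / sqrt(d)
  dQKV <- cbind(dQ, dK, dV)
  dN1 <- tcrossprod(dQKV, p("Wqkv"))
  gadd(gacc, paste0(pf, "Wqkv"), crossprod(cache$n1$Y, dQKV))
  dH1 + ln_backward(dN1, cache$n1, p("ln1_g"), gacc,
                    paste0(pf, "ln1_g"), paste0(pf, "ln1_b"))
}

## Accumulate a gradient into an environment keyed by parameter name.
gadd <- function(gacc, name, val) {
  cur <- gacc[[name]]
  gacc[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

## ------------------------------------------------------------------
## Text encoder forward/backward

text_forward <- function(ids, params, cfg) {
  V <- nrow(params$t_emb)
  if (any(ids < 1L | ids > V))
    contract_error("token id out of vocabulary range [1, %d]", V)
  L <- length(ids)
  if (L > nrow(params$t_pos))
    contract_error("token sequence longer than the configured maximum (%d)", nrow(params$t_pos))
  H <- params$t_emb[ids, , drop = FALSE] + params$t_pos[seq_len(L), , drop = FALSE]
  caches <- vector("list", cfg$blocks_t)
  for (b in seq_len(cfg$blocks_t)) {
    out <- attn_block_forward(H, params, sprintf("t%d_", b))
    H <- out$H
    caches[[b]] <- out$cache
  }
  list(feature = H[1L, ], H = H, ids = ids, caches = caches)
}

text_backward <- function(dfeature, fwd, params, cfg, gacc) {
  L <- length(fwd$ids)
  dH <- matrix(0, L, cfg$d_t)
  dH[1L, ] <- dfeature
  for (b in rev(seq_len(cfg$blocks_t))) {
    dH <- attn_block_backward(dH, fwd$caches[[b]], params, sprintf("t%d_", b), gacc)
  }
  ## embedding rows accumulate over repeated ids
  demb_rows <- rowsum(dH, group = fwd$ids)
  demb <- matrix(0, nrow(params$t_emb), cfg$d_t)
  idx <- as.integer(rownames(demb_rows))
  demb[idx, ] <- demb_rows
  gadd(gacc, "t_emb", demb)
  dpos <- matrix(0, nrow(params$t_pos), cfg$d_t)
  dpos[seq_len(L), ] <- dH
  gadd(gacc, "t_pos", dpos)
  invisible(NULL)
}

#' Extract the text feature for a token sequence
#'
#' Runs the reference text encoder and returns the final hidden state at the
#' summary-token (first) position: a fixed-length vector independent of the
#' input length.
#'
#' @param model A [ComponentModel-class].
#' @param ids Integer token ids from [tokenize()].
#' @return Numeric vector of length `D_t`.
#' @export
textFeatures <- function(model, ids) {
  text_forward(ids, model@params, model@config)$feature
}
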