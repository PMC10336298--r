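#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Sinusoidal positional encoding
#'
#' Coordinate `i` (0-based) of the encoding at position `pos` is
#' `sin(pos / 10000^(i/e))` for even `i` and `cos(pos / 10000^((i-1)/e))`
#' for odd `i`. Note the exponent is `i/e` (not the `2i/d` of some
#' transformer variants); consecutive even/odd coordinates therefore share
#' a frequency through the `(i-1)` shift.
#'
#' @param pos Non-negative integer position, or a vector of positions.
#' @param e Encoding dimension.
#' @return An `e`-vector, or a `length(pos) x e` matrix for vector input.
#' @export
positionalEncoding <- function(pos, e) {
  stopifnot(all(pos >= 0), e >= 1)
  i <- 0:(e - 1)
  expo <- ifelse(i %% 2 == 0, i / e, (i - 1) / e)
  one <- function(p) {
    ang <- p / 10000^expo
    ifelse(i %% 2 == 0, sin(ang), cos(ang))
  }
  if (length(pos) == 1) return(one(pos))
  t(vapply(pos, one, numeric(e)))
}

#' Mask a batch of tokenised sequences
#'
#' Per sequence, `k = max(1, round(maskRate * m))` of the `m` maskable
#' positions (everything except `[CLS]` and `[PAD]`) are chosen uniformly
#' without replacement and replaced by `[MASK]`; the originals stay
#' available in `originalIds`. Sequences with zero maskable positions are
#' passed through with a warning. Ties in the rounding go up (`round`
#' half-up), matching the training engine.
#'
#' @param batch List of [TokenizedSequence-class].
#' @param maskRate Fraction in (0, 1).
#' @param vocab The [NodeVocabulary-class] (supplies the special ids).
#' @return List of [TokenizedSequence-class] with masks applied.
#' @export
applyMask <- function(batch, maskRate, vocab) {
  stopifnot(maskRate > 0, maskRate < 1)
  sp <- specialIds(vocab)
  lapply(batch, function(s) {
    maskable <- which(s@tokenIds != sp["cls"] & s@tokenIds != sp["pad"])
    maskable <- setdiff(maskable, 1L)  # position 0 is [CLS] by construction
    m <- length(maskable)
    if (m == 0) {
      warning("sequence with no maskable positions skipped")
      return(s)
    }
    k <- max(1L, roundHalfUp(maskRate * m))
    pick <- maskable[sample.int(m, k)]
    ids <- s@tokenIds
    ids[pick] <- sp[["mask"]]
    flags <- rep(FALSE, length(ids))
    flags[pick] <- TRUE
    new("TokenizedSequence", tokenIds = ids, positions = s@positions,
        maskFlags = flags, originalIds = s@originalIds)
  })
}

#' Multi-head scaled dot-product self-attention
#'
#' Per head `h`: `softmax(Q_h K_h^T / sqrt(d_k)) V_h` with
#' `Q = H Wq`, `K = H Wk`, `V = H Wv` sliced into `nHeads` column blocks of
#' width `d_k = d / nHeads`; head outputs are concatenated. This is the
#' bare attention map -- residual connection and layer normalisation are
#' applied by the encoder block around it.
#'
#' @param H `L x d` matrix of token vectors.
#' @param Wq,Wk,Wv `d x d` projection matrices.
#' @param nHeads Number of attention heads (divides `d`).
#' @param keyPad Optional logical length-`L` vector; `TRUE` keys are
#'   excluded from attention.
#' @return `L x d` matrix.
#' @export
selfAttention <- function(H, Wq, Wk, Wv, nHeads = 1L, keyPad = NULL) {
  d <- ncol(H)
  stopifnot(d %% nHeads == 0)
  dk <- d %/% nHeads
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  out <- matrix(0, nrow(H), d)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    if (!is.null(keyPad)) S[, keyPad] <- -1e30
    P <- exp(S - apply(S, 1, max))
    P <- P / rowSums(P)
    out[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  out
}

#' Position-wise feed-forward layer
#'
#' `ReLU(x W1 + b1) W2 + b2`, applied to each position separately and
#' identically. Accepts a single `d`-vector or an `L x d` matrix of
#' positions.
#'
#' @param x Input vector or matrix.
#' @param W1,b1,W2,b2 The two linear maps.
#' @return Same shape as `x`.
#' @export
feedForward <- function(x, W1, b1, W2, b2) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  Z <- sweep(x %*% W1, 2, b1, "+")
  Z[Z < 0] <- 0
  out <- sweep(Z %*% W2, 2, b2, "+")
  if (vec) drop(out) else out
}

#' Masked-token cross-entropy loss
#'
#' Cross-entropy summed over masked positions only:
#' `-sum_{(b,l) in mask} log p[b, l, target(b,l)]` with `p` the softmax of
#' the logits over the `M` node classes. `"mean_over_masked"` divides by
#' the number of masked positions (the training default, for
#' learning-rate stability); `"sum"` is the literal unnormalised sum.
#'
#' @param logits `B x L x M` array.
#' @param batch List of masked [TokenizedSequence-class] (as produced by
#'   [applyMask()]).
#' @param reduction `"sum"` or `"mean_over_masked"`.
#' @return Scalar loss.
#' @export
mlmLoss <- function(logits, batch, reduction = c("sum", "mean_over_masked")) {
  reduction <- match.arg(reduction)
  stopifnot(length(dim(logits)) == 3)
  total <- 0
  nm <- 0L
  for (b in seq_along(batch)) {
    s <- batch[[b]]
    for (l in which(s@maskFlags)) {
      z <- logits[b, l, ]
      z <- z - max(z)
      logp <- z - log(sum(exp(z)))
      total <- total - logp[s@originalIds[l]]
      nm <- nm + 1L
    }
  }
  if (nm == 0) stop("no masked positions in batch")
  if (reduction == "sum") total else total / nm
}

#' Propagate an embedding table over a network
#'
#' One random-walk-with-restart iteration, `X' = (1 - alpha) W X + alpha X`,
#' applied to the rows of nodes with degree > 0 in `network`; rows of
#' degree-0 nodes and of the special tokens (`[CLS]`, `[MASK]`, `[PAD]`)
#' are left untouched, so unused rows are not shrunk towards zero.
#' `alpha = 1` is the identity.
#'
#' @param X `(n + 3) x e` (or `n x e`) embedding matrix, node rows in
#'   vocabulary order.
#' @param network A [WalkNetwork-class].
#' @param alpha Restart probability in \[0, 1\].
#' @return The propagated matrix, same shape.
#' @export
propagateEmbeddings <- function(X, network, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- length(network@vocab@nodes)
  stopifnot(nrow(X) >= n)
  pres <- which(presentNodes(network))
  if (length(pres) == 0 || alpha == 1) return(X)
  Xn <- X[seq_len(n), , drop = FALSE]
  WX <- as.matrix(network@W %*% Xn)
  X[pres, ] <- (1 - alpha) * WX[pres, , drop = FALSE] +
    alpha * Xn[pres, , drop = FALSE]
  X
}

# --- plain-R encoder forward pass -------------------------------------------
# A literal composition of the exported operations (embedding lookup +
# positional encoding, then per block: self-attention, residual + layer
# norm, feed-forward, residual + layer norm). Used as the reference
# implementation the compiled engine is checked against; dropout-free.

layerNormRows <- function(X, eps = 1e-5) {
  t(apply(X, 1, function(r) {
    c <- r - mean(r)
    c / sqrt(mean(c^2) + eps)
  }))
}

rEncoderForward <- function(model, cfg, tokens0, PE) {
  # tokens0: B x L matrix of 0-based token ids; PE: L x e
  e <- cfg$e
  d <- if (cfg$concat) 2L * e else e
  padId <- cfg$M + 2L
  B <- nrow(tokens0); L <- ncol(tokens0)
  out <- array(0, c(B, L, d))
  for (b in seq_len(B)) {
    ids <- tokens0[b, ] + 1L
    emb <- model$X[ids, , drop = FALSE]
    H <- if (cfg$concat) cbind(emb, PE[seq_len(L), , drop = FALSE])
         else emb + PE[seq_len(L), , drop = FALSE]
    pad <- tokens0[b, ] == padId
    for (blk in model$blocks) {
      A <- selfAttention(H, blk$Wq, blk$Wk, blk$Wv, nHeads = cfg$heads,
                         keyPad = if (any(pad)) pad else NULL)
      H <- layerNormRows(H + A)
      F <- feedForward(H, blk$W1, blk$b1, blk$W2, blk$b2)
      H <- layerNormRows(H + F)
    }
    out[b, , ] <- H
  }
  out
}
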