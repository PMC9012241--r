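# Transformer encoder stack: masked multi-head self-attention and
# position-wise feed-forward sub-layers, each with residual connection and
# post-norm layer normalization. Forward passes cache the intermediates the
# hand-derived backward passes need; batches are stacked (B*l) x f matrices
# with row order (b-1)*l + j and a flat validity mask.

.LN_EPS <- 1e-5

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layer_norm_forward <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv_sd <- 1 / sqrt(v + .LN_EPS)
  xhat <- Xc * inv_sd
  out <- sweep(xhat, 2L, gamma, "*")
  out <- sweep(out, 2L, beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd)
}

layer_norm_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; identity when training = FALSE or p = 0.
dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  keep <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * keep, mask = keep)
}
dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

init_linear <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout),
       b = numeric(dout))
}

init_encoder_layer <- function(f, d_ff) {
  list(Wq = init_linear(f, f)$W, bq = numeric(f),
       Wk = init_linear(f, f)$W, bk = numeric(f),
       Wv = init_linear(f, f)$W, bv = numeric(f),
       Wo = init_linear(f, f)$W, bo = numeric(f),
       g1 = rep(1, f), b1n = numeric(f),
       W1 = init_linear(f, d_ff)$W, bf1 = numeric(d_ff),
       W2 = init_linear(d_ff, f)$W, bf2 = numeric(f),
       g2 = rep(1, f), b2n = numeric(f))
}

affine <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

# ---- multi-head self-attention --------------------------------------------

# Batched masked MHA on a stacked matrix. Attention is computed among the
# non-PAD positions of each sequence only (equivalent to -Inf logits at PAD
# keys); output rows at PAD positions are exactly zero.
mha_forward <- function(X, mask, B, l, p, h) {
  f <- ncol(X)
  d_k <- f / h
  Q <- affine(X, p$Wq, p$bq)
  K <- affine(X, p$Wk, p$bk)
  V <- affine(X, p$Wv, p$bv)
  H <- matrix(0, nrow(X), f)
  attn <- vector("list", B)
  idxs <- vector("list", B)
  for (b in seq_len(B)) {
    block <- ((b - 1L) * l + 1L):(b * l)
    idx <- block[mask[block]]
    if (length(idx) == 0L) stop("all-PAD sequence in attention", call. = FALSE)
    Pb <- vector("list", h)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * d_k + 1L):(i * d_k)
      logits <- tcrossprod(Q[idx, cols, drop = FALSE],
                           K[idx, cols, drop = FALSE]) / sqrt(d_k)
      logits <- logits - apply(logits, 1L, max)
      P <- exp(logits)
      P <- P / rowSums(P)
      Pb[[i]] <- P
      H[idx, cols] <- P %*% V[idx, cols, drop = FALSE]
    }
    attn[[b]] <- Pb
    idxs[[b]] <- idx
  }
  out <- affine(H, p$Wo, p$bo)
  out[!mask, ] <- 0
  list(out = out, Q = Q, K = K, V = V, H = H, attn = attn, idxs = idxs)
}

mha_backward <- function(dout, cache, X, mask, B, l, p, h) {
  f <- ncol(X)
  d_k <- f / h
  dout[!mask, ] <- 0
  g <- list(Wo = crossprod(cache$H, dout), bo = colSums(dout))
  dH <- tcrossprod(dout, p$Wo)
  dQ <- matrix(0, nrow(X), f); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    idx <- cache$idxs[[b]]
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * d_k + 1L):(i * d_k)
      P <- cache$attn[[b]][[i]]
      Vb <- cache$V[idx, cols, drop = FALSE]
      dHb <- dH[idx, cols, drop = FALSE]
      dP <- tcrossprod(dHb, Vb)
      dV[idx, cols] <- crossprod(P, dHb)
      dlog <- P * (dP - rowSums(dP * P))
      dlog <- dlog / sqrt(d_k)
      dQ[idx, cols] <- dlog %*% cache$K[idx, cols, drop = FALSE]
      dK[idx, cols] <- crossprod(dlog, cache$Q[idx, cols, drop = FALSE])
    }
  }
  g$Wq <- crossprod(X, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(X, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(X, dV); g$bv <- colSums(dV)
  dX <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dX = dX, grads = g)
}

#' Masked multi-head self-attention
#'
#' Scaled dot-product attention with `h` heads over a single sequence.
#' Attention logits toward `PAD` positions are masked out (equivalently set
#' to `-Inf` before the softmax), so `PAD` tokens never contribute to any
#' non-PAD output row; output rows at `PAD` positions are zero.
#'
#' @param F_in `l x f` input feature matrix.
#' @param mask logical vector of length `l`; `FALSE` marks `PAD`.
#' @param params layer parameter list with `Wq`, `bq`, `Wk`, `bk`, `Wv`,
#'   `bv`, `Wo`, `bo` (as created by the model initializer); each `W*` is
#'   `f x f` holding all `h` head projections in column blocks of width
#'   `f/h`.
#' @param h number of heads; `f` must be divisible by `h` so that
#'   `d_k = d_v = f/h`.
#' @return `l x f` output matrix.
#' @export
multi_head_self_attention <- function(F_in, mask, params, h) {
  f <- ncol(F_in)
  if (f %% h != 0) stop("feature dimension f must be divisible by h", call. = FALSE)
  if (!any(mask)) stop("degenerate input: all positions are PAD", call. = FALSE)
  mha_forward(F_in, mask, 1L, nrow(F_in), params, h)$out
}

# ---- encoder layer ---------------------------------------------------------

encoder_layer_forward <- function(X, mask, B, l, p, h, dropout, training) {
  a <- mha_forward(X, mask, B, l, p, h)
  d1 <- dropout_forward(a$out, dropout, training)
  ln1 <- layer_norm_forward(X + d1$out, p$g1, p$b1n)
  h1 <- ln1$out
  h1[!mask, ] <- 0
  z1 <- affine(h1, p$W1, p$bf1)
  ffo <- affine(gelu(z1), p$W2, p$bf2)
  d2 <- dropout_forward(ffo, dropout, training)
  ln2 <- layer_norm_forward(h1 + d2$out, p$g2, p$b2n)
  out <- ln2$out
  out[!mask, ] <- 0
  list(out = out, mha = a, d1 = d1, ln1 = ln1, h1 = h1, z1 = z1,
       d2 = d2, ln2 = ln2)
}

encoder_layer_backward <- function(dout, cache, X, mask, B, l, p, h) {
  dout[!mask, ] <- 0
  b2 <- layer_norm_backward(dout, cache$ln2, p$g2)
  g <- list(g2 = b2$dgamma, b2n = b2$dbeta)
  dffo <- dropout_backward(b2$dX, cache$d2$mask)
  gz <- gelu(cache$z1)
  g$W2 <- crossprod(gz, dffo); g$bf2 <- colSums(dffo)
  dz1 <- tcrossprod(dffo, p$W2) * gelu_grad(cache$z1)
  g$W1 <- crossprod(cache$h1, dz1); g$bf1 <- colSums(dz1)
  dh1 <- b2$dX + tcrossprod(dz1, p$W1)
  dh1[!mask, ] <- 0
  b1 <- layer_norm_backward(dh1, cache$ln1, p$g1)
  g$g1 <- b1$dgamma; g$b1n <- b1$dbeta
  da <- dropout_backward(b1$dX, cache$d1$mask)
  mb <- mha_backward(da, cache$mha, X, mask, B, l, p, h)
  g <- c(g, mb$grads)
  list(dX = b1$dX + mb$dX, grads = g)
}

#' Single transformer encoder layer
#'
#' Applies masked multi-head self-attention followed by a position-wise
#' feed-forward network (GELU activation, inner dimension `4f` by default),
#' each wrapped in a residual connection and post-norm layer normalization.
#'
#' @inheritParams multi_head_self_attention
#' @param dropout dropout probability; active only when `training = TRUE`.
#' @param training logical; enables dropout.
#' @return `l x f` output matrix (`PAD` rows zero).
#' @export
encoder_layer <- function(F_in, mask, params, h, dropout = 0, training = FALSE) {
  encoder_layer_forward(F_in, mask, 1L, nrow(F_in), params, h,
                        dropout, training)$out
}

# ---- encoder stack ---------------------------------------------------------

encode_forward <- function(X, mask, B, l, layers, h, dropout, training) {
  caches <- vector("list", length(layers))
  inputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    inputs[[i]] <- X
    caches[[i]] <- encoder_layer_forward(X, mask, B, l, layers[[i]], h,
                                         dropout, training)
    X <- caches[[i]]$out
  }
  list(out = X, caches = caches, inputs = inputs)
}

encode_backward <- function(dout, enc_cache, mask, B, l, layers, h) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bk <- encoder_layer_backward(dout, enc_cache$caches[[i]],
                                 enc_cache$inputs[[i]], mask, B, l,
                                 layers[[i]], h)
    grads[[i]] <- bk$grads
    dout <- bk$dX
  }
  list(dX = dout, grads = grads)
}

#' Encode an embedded sequence with a transformer stack
#'
#' Sequentially applies the encoder layers to an embedded sequence and
#' returns the layer-normalized global feature matrix `F_global`.
#'
#' @param S `l x f` embedded sequence (see [embed_sequence()]).
#' @param mask logical validity vector of length `l`.
#' @param layers list of encoder-layer parameter lists.
#' @param h number of attention heads.
#' @param dropout dropout probability (training only).
#' @param training logical.
#' @return `l x f` matrix of global per-position features; `PAD` rows zero.
#' @export
encode <- function(S, mask, layers, h, dropout = 0, training = FALSE) {
  encode_forward(S, mask, 1L, nrow(S), layers, h, dropout, training)$out
}
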