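# Initial sequence embedding: scaled token embedding + sinusoidal positional
# encoding, with an optional learned projection when the embedding table is
# narrower than the encoder feature dimension.

#' Sinusoidal positional encoding
#'
#' The fixed (parameter-free) cosine positional encoding: for 0-based
#' position `pos` and 0-based feature pair index `i`,
#' `PE[pos, 2i] = sin(pos / 10000^(2i/f))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/f))`.
#' Because the encoding depends only on the absolute position, two sequences
#' of different lengths share the encoding on their common prefix, which
#' keeps a trained model usable on variable-length input.
#'
#' @param l sequence length (rows), `l >= 1`.
#' @param f feature dimension (columns), must be even.
#' @return An `l x f` numeric matrix with entries in `[-1, 1]`.
#' @examples
#' pe <- positional_encoding(4, 8)
#' pe[1, ]  # position 0: sin terms are 0, cos terms are 1
#' @export
positional_encoding <- function(l, f) {
  if (f %% 2 != 0) stop("feature dimension f must be even", call. = FALSE)
  if (l < 1) stop("length l must be >= 1", call. = FALSE)
  pos <- 0:(l - 1)
  i2 <- 2 * (0:(f / 2 - 1))                # the exponent numerator 2i
  ang <- outer(pos, 10000^(i2 / f), "/")   # l x f/2
  pe <- matrix(0, l, f)
  pe[, seq(1, f, by = 2)] <- sin(ang)
  pe[, seq(2, f, by = 2)] <- cos(ang)
  pe
}

# Embedding parameters: table V x d_emb (PAD row pinned to zero) and an
# optional projection d_emb x f used when d_emb != f.
init_embedding <- function(vocab_size, d_emb, f, pad_id) {
  E <- matrix(stats::rnorm(vocab_size * d_emb, sd = 1 / sqrt(d_emb)),
              vocab_size, d_emb)
  E[pad_id, ] <- 0
  p <- list(E = E)
  if (d_emb != f) {
    p$W_proj <- matrix(stats::rnorm(d_emb * f, sd = sqrt(2 / (d_emb + f))),
                       d_emb, f)
  }
  p
}

#' Embed a token sequence
#'
#' Builds the initial `l x f` representation: the token embedding (projected
#' to dimension `f` when the table is narrower), scaled by `sqrt(f)`, plus
#' the sinusoidal positional encoding. `PAD` rows are exactly zero and the
#' positional encoding is not added there.
#'
#' @param seq a `token_sequence` (see [regularize_length()]).
#' @param params embedding parameters: a list with matrix `E`
#'   (vocabulary x d_emb) and optionally `W_proj` (d_emb x f).
#' @param f encoder feature dimension.
#' @return `l x f` numeric matrix.
#' @export
embed_sequence <- function(seq, params, f) {
  ids <- seq$ids
  if (any(ids < 1L | ids > nrow(params$E)))
    stop("token id outside the embedding table", call. = FALSE)
  S <- embed_batch(matrix(ids, nrow = 1L), matrix(seq$mask, nrow = 1L), params, f)
  S
}

# Batched embedding forward: ids and mask are B x l matrices; returns a
# stacked (B*l) x f matrix with row order (b-1)*l + j.
embed_batch <- function(ids, mask, params, f) {
  B <- nrow(ids); l <- ncol(ids)
  flat_ids <- as.vector(t(ids))            # row (b-1)*l + j  <-> (b, j)
  flat_mask <- as.vector(t(mask))
  X <- params$E[flat_ids, , drop = FALSE]
  if (!is.null(params$W_proj)) X <- X %*% params$W_proj
  X <- sqrt(f) * X
  pe <- positional_encoding(l, f)
  X <- X + pe[rep(seq_len(l), B), , drop = FALSE]
  X[!flat_mask, ] <- 0
  X
}

# Backward: accumulate gradients into the embedding table (and projection).
# dX is the (B*l) x f upstream gradient; PAD rows must already be zero.
embed_backward <- function(dX, ids, mask, params, f) {
  flat_ids <- as.vector(t(ids))
  flat_mask <- as.vector(t(mask))
  dX <- dX * flat_mask                      # no gradient into PAD rows
  dX <- sqrt(f) * dX
  g <- list()
  if (!is.null(params$W_proj)) {
    Xe <- params$E[flat_ids, , drop = FALSE]
    g$W_proj <- crossprod(Xe * flat_mask, dX)
    dEmb <- dX %*% t(params$W_proj)
  } else {
    dEmb <- dX
  }
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  # scatter-add by token id
  for (id in unique(flat_ids[flat_mask])) {
    rows <- which(flat_ids == id & flat_mask)
    dE[id, ] <- colSums(dEmb[rows, , drop = FALSE])
  }
  g$E <- dE
  g
}
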