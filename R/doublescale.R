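# Double-scale attention core: multi-scale 1-D convolutional feature
# extraction, the feature-agreement score, the joint (scale x position)
# softmax attention matrix W with positional margin v, and the mixed-scale
# feature map.
#
# Batched internals operate on stacked (B*l) x f matrices; the exported
# single-sequence operations wrap them with B = 1.

# Gather index for a convolution tap: maps stacked row (b, j) to stacked row
# (b, j + offset), or 0 when j + offset falls outside the sequence (zero
# padding). Index 0 addresses the sentinel zero row of rbind(0, X).
conv_gather_idx <- function(B, l, offset) {
  j <- seq_len(l) + offset
  base <- ifelse(j >= 1L & j <= l, j, NA_integer_)
  idx <- rep((seq_len(B) - 1L) * l, each = l) + rep(base, B)
  idx[is.na(idx)] <- 0L
  idx
}

# Window offsets for kernel size S, left-of-center for even S: position j
# summarizes window j - ceiling((S-1)/2) ... j + floor((S-1)/2).
conv_offsets <- function(S) {
  (-ceiling((S - 1) / 2)):(floor((S - 1) / 2))
}

init_scale_params <- function(f, size, channels_per_size, a_dim) {
  C <- channels_per_size * size
  K <- lapply(seq_len(size), function(s)
    matrix(stats::rnorm(f * C, sd = sqrt(2 / (f * size + C))), f, C))
  list(size = size, K = K, b = numeric(C),
       Wp = init_linear(C, a_dim)$W, bp = numeric(a_dim))
}

# Forward conv + variance rescale + GELU + linear projection for one scale.
# X: stacked (B*l) x f with PAD rows zero. Returns map (B*l) x a_dim with
# PAD-centered rows zeroed, plus backward cache.
scale_conv_forward <- function(X, mask, B, l, sp, activation = TRUE,
                               project = TRUE) {
  S <- sp$size
  offs <- conv_offsets(S)
  Xp <- rbind(0, X)
  C <- length(sp$b)
  Y <- matrix(0, nrow(X), C)
  for (s in seq_along(offs)) {
    idx <- conv_gather_idx(B, l, offs[s])
    Y <- Y + Xp[idx + 1L, , drop = FALSE] %*% sp$K[[s]]
  }
  Y <- sweep(Y, 2L, sp$b, "+") / sqrt(S)
  out <- Y
  A <- NULL
  if (activation) A <- gelu(Y)
  if (project) {
    if (is.null(A)) A <- Y
    out <- affine(A, sp$Wp, sp$bp)
  } else if (activation) out <- A
  out[!mask, ] <- 0
  list(out = out, z = Y, A = A)
}

scale_conv_backward <- function(dmap, cache, X, mask, B, l, sp) {
  S <- sp$size
  dmap[!mask, ] <- 0
  g <- list()
  dA <- dmap
  if (!is.null(sp$Wp)) {
    g$Wp <- crossprod(cache$A, dmap)
    g$bp <- colSums(dmap)
    dA <- tcrossprod(dmap, sp$Wp)
  }
  dz <- dA * gelu_grad(cache$z)
  dconv <- dz / sqrt(S)
  g$b <- colSums(dconv)
  offs <- conv_offsets(S)
  Xp <- rbind(0, X)
  dX <- matrix(0, nrow(X), ncol(X))
  g$K <- vector("list", S)
  for (s in seq_along(offs)) {
    idx <- conv_gather_idx(B, l, offs[s])
    g$K[[s]] <- crossprod(Xp[idx + 1L, , drop = FALSE], dconv)
    Tm <- tcrossprod(dconv, sp$K[[s]])
    ok <- idx > 0L
    dX[idx[ok], ] <- dX[idx[ok], , drop = FALSE] + Tm[ok, , drop = FALSE]
  }
  list(dX = dX, grads = g)
}

#' Multi-scale convolutional feature extraction
#'
#' Runs one 1-D convolution per kernel size over the encoder's global
#' feature matrix (stride 1, same-length zero padding, window centered on
#' the output position with the left-of-center convention for even sizes).
#' Raw convolution outputs are divided by `sqrt(S_k)` to compensate the
#' variance expansion of summing `S_k` taps, passed through a GELU, and
#' linearly projected into the shared agreement subspace.
#'
#' @param F_global `l x f` global feature matrix (`PAD` rows zero).
#' @param mask logical validity vector of length `l`.
#' @param params model `scales` parameter list (one element per kernel
#'   size, each with tap matrices `K`, bias `b`, projection `Wp`, `bp`).
#' @param activation,project set `FALSE` to stop after the raw scaled
#'   convolution (used for testing the convolution itself).
#' @return A list of `l x f` feature maps, one per kernel size,
#'   `PAD`-centered rows zeroed.
#' @export
extract_scale_features <- function(F_global, mask, params,
                                   activation = TRUE, project = TRUE) {
  l <- nrow(F_global)
  for (sp in params) {
    if (sp$size > l)
      stop(sprintf("kernel size %d exceeds sequence length %d", sp$size, l),
           call. = FALSE)
  }
  lapply(params, function(sp)
    scale_conv_forward(F_global, mask, 1L, l, sp, activation, project)$out)
}

#' Central vectors of the feature-agreement algorithm
#'
#' At each position `j`, the central vector is the arithmetic mean of the
#' global feature vector and the `N` scale feature vectors at `j`:
#' `F_cent_j = (F_global_j + sum_k F_Sk_j) / (N + 1)`. The global features
#' supervise the convolutions toward position-concentrated representations.
#'
#' @param F_global `l x f` matrix.
#' @param maps list of `N` scale feature maps, each `l x f`.
#' @param include_global if `FALSE`, the mean is over the `N` scale maps
#'   only (ablation switch).
#' @return `l x f` matrix of central vectors.
#' @export
central_vectors <- function(F_global, maps, include_global = TRUE) {
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != nrow(F_global)) || any(dims[2, ] != ncol(F_global)))
    stop("scale feature maps must share the shape of F_global", call. = FALSE)
  acc <- Reduce(`+`, maps)
  if (include_global) (F_global + acc) / (length(maps) + 1)
  else acc / length(maps)
}

#' Feature-agreement scores
#'
#' The agreement of scale `S_k` at position `j` is the scaled dot product
#' of the scale feature vector with the central vector,
#' `agree_Sk_j = (F_Sk_j . F_cent_j) / sqrt(f)`. High agreement marks a
#' scale whose local feature is consistent with the consensus of all scales
#' at that position. `PAD` columns are set to `-Inf` so they receive
#' exactly zero mass in the subsequent softmax.
#'
#' @param maps list of `N` scale feature maps (`l x f`).
#' @param centers `l x f` central-vector matrix from [central_vectors()].
#' @param mask logical validity vector of length `l`.
#' @param divisor `"sqrt_f"` (default, transformer-style scaling) or `"f"`.
#' @return `N x l` agreement matrix.
#' @export
agreement_scores <- function(maps, centers, mask, divisor = c("sqrt_f", "f")) {
  divisor <- match.arg(divisor)
  f <- ncol(centers)
  div <- if (divisor == "sqrt_f") sqrt(f) else f
  A <- t(vapply(maps, function(m) rowSums(m * centers) / div,
                numeric(nrow(centers))))
  if (!all(is.finite(A[, mask, drop = FALSE])))
    stop("non-finite agreement scores", call. = FALSE)
  A[, !mask] <- -Inf
  A
}

#' Double-scale attention matrix
#'
#' Flattens the `N x l` agreement matrix, applies a single softmax over all
#' `N * l` entries, and reshapes back, yielding the joint distribution `W`
#' over (spatial scale, position) pairs; `PAD` columns (agreement `-Inf`)
#' get exactly zero mass. The positional margin `v` is the column sum of
#' `W` over scales.
#'
#' @param A `N x l` agreement matrix with `-Inf` at `PAD` columns.
#' @return An object of class `dsattn_attention`: list with matrix `W`
#'   (`N x l`, entries sum to 1) and vector `v` (length `l`, sums to 1).
#' @export
attention_matrix <- function(A) {
  finite <- is.finite(A)
  if (!any(finite)) stop("degenerate input: all columns are PAD", call. = FALSE)
  m <- max(A[finite])
  W <- exp(A - m)
  W[!finite] <- 0
  W <- W / sum(W)
  structure(list(W = W, v = colSums(W)), class = "dsattn_attention")
}

#' @export
print.dsattn_attention <- function(x, ...) {
  cat("<dsattn_attention> ", nrow(x$W), " scales x ", ncol(x$W),
      " positions; margin mass ", format(sum(x$v)), "\n", sep = "")
  invisible(x)
}

#' Mixed-scale features
#'
#' Position-wise convex mixture of the scale feature maps under the
#' scale-conditional weights `W_kj / v_j`:
#' `F_mixed_j = sum_k (W_kj / v_j) F_Sk_j`. Positions dominated by one
#' scale inherit that scale's features; `PAD` rows are zero.
#'
#' @param att a `dsattn_attention` object (see [attention_matrix()]).
#' @param maps list of `N` scale feature maps (`l x f`).
#' @param mask logical validity vector of length `l`.
#' @param eps numeric guard added to the margin denominator.
#' @return `l x f` mixed feature matrix.
#' @export
mix_features <- function(att, maps, mask, eps = 1e-12) {
  W <- att$W; v <- att$v
  l <- ncol(W)
  out <- matrix(0, l, ncol(maps[[1]]))
  vs <- v + eps
  for (k in seq_along(maps)) out <- out + (W[k, ] / vs) * maps[[k]]
  out[!mask, ] <- 0
  out
}

# ---- batched pipeline ------------------------------------------------------

# Full double-scale forward on a stacked batch. G: (B*l) x f global features
# with PAD rows zero. Returns stacked mixed features, per-position margin
# weights, attention pieces, and caches for backward.
ds_forward <- function(G, mask, B, l, params, cfg) {
  N <- length(params$scales)
  convs <- lapply(params$scales, function(sp)
    scale_conv_forward(G, mask, B, l, sp))
  maps <- lapply(convs, `[[`, "out")
  denom <- if (isTRUE(cfg$include_global)) N + 1 else N
  Fc <- Reduce(`+`, maps)
  if (isTRUE(cfg$include_global)) Fc <- Fc + G
  Fc <- Fc / denom
  div <- if (identical(cfg$agree_divisor, "f")) ncol(G) else sqrt(ncol(G))
  # Ascore: (B*l) x N, scores by position row
  Ascore <- vapply(maps, function(m) rowSums(m * Fc) / div, numeric(nrow(G)))
  Ascore <- matrix(Ascore, nrow = nrow(G), ncol = N)
  # per-sequence joint softmax over the l x N block, -Inf at PAD rows
  W <- matrix(0, nrow(G), N)
  for (b in seq_len(B)) {
    block <- ((b - 1L) * l + 1L):(b * l)
    ok <- mask[block]
    Ab <- Ascore[block, , drop = FALSE][ok, , drop = FALSE]
    E <- exp(Ab - max(Ab))
    W[block[ok], ] <- E / sum(E)
  }
  v <- rowSums(W)
  vs <- v + (v == 0)            # PAD rows: 0/1 = 0
  Fm <- matrix(0, nrow(G), ncol(maps[[1]]))
  for (k in seq_len(N)) Fm <- Fm + (W[, k] / vs) * maps[[k]]
  list(Fm = Fm, W = W, v = v, vs = vs, maps = maps, Fc = Fc,
       Ascore = Ascore, convs = convs, div = div, denom = denom)
}

# Backward of ds_forward. dFm: grad wrt mixed features; dv_extra: grad wrt
# the margin v from the aggregation stage. Returns dG and parameter grads.
ds_backward <- function(dFm, dv_extra, cache, G, mask, B, l, params, cfg) {
  N <- length(params$scales)
  W <- cache$W; vs <- cache$vs; maps <- cache$maps; Fm <- cache$Fm
  dFm[!mask, ] <- 0
  dmaps <- vector("list", N)
  dW <- matrix(0, nrow(G), N)
  for (k in seq_len(N)) {
    wk <- W[, k] / vs
    dmaps[[k]] <- wk * dFm
    # d/dW_kj of sum_m W_mj F_mj / v_j  =  (F_kj - F_mixed_j) / v_j
    dW[, k] <- rowSums(dFm * (maps[[k]] - Fm)) / vs
  }
  dW <- dW + dv_extra            # margin v = rowSums(W)
  # joint softmax backward per sequence block
  dA <- matrix(0, nrow(G), N)
  for (b in seq_len(B)) {
    block <- ((b - 1L) * l + 1L):(b * l)
    Wb <- W[block, , drop = FALSE]
    s <- sum(dW[block, , drop = FALSE] * Wb)
    dA[block, ] <- Wb * (dW[block, , drop = FALSE] - s)
  }
  # agreement backward
  Fc <- cache$Fc
  dFc <- matrix(0, nrow(G), ncol(G))
  for (k in seq_len(N)) {
    dmaps[[k]] <- dmaps[[k]] + (dA[, k] / cache$div) * Fc
    dFc <- dFc + (dA[, k] / cache$div) * maps[[k]]
  }
  dG <- matrix(0, nrow(G), ncol(G))
  if (isTRUE(cfg$include_global)) dG <- dG + dFc / cache$denom
  for (k in seq_len(N)) dmaps[[k]] <- dmaps[[k]] + dFc / cache$denom
  grads <- vector("list", N)
  for (k in seq_len(N)) {
    bk <- scale_conv_backward(dmaps[[k]], cache$convs[[k]], G, mask, B, l,
                              params$scales[[k]])
    grads[[k]] <- bk$grads
    dG <- dG + bk$dX
  }
  list(dG = dG, scale_grads = grads)
}
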