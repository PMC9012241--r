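# Independent naive-loop reference implementations used to cross-check the
# vectorized model code, plus small random-instance builders.

# Multi-head scaled dot-product attention, one explicit loop per query
# position and head. X: l x f, all positions real.
oracle_mha <- function(X, p, h) {
  l <- nrow(X); f <- ncol(X); d_k <- f / h
  Q <- X %*% p$Wq + matrix(p$bq, l, f, byrow = TRUE)
  K <- X %*% p$Wk + matrix(p$bk, l, f, byrow = TRUE)
  V <- X %*% p$Wv + matrix(p$bv, l, f, byrow = TRUE)
  H <- matrix(0, l, f)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    for (q in seq_len(l)) {
      logits <- numeric(l)
      for (k in seq_len(l))
        logits[k] <- sum(Q[q, cols] * K[k, cols]) / sqrt(d_k)
      w <- exp(logits - max(logits)); w <- w / sum(w)
      for (k in seq_len(l)) H[q, cols] <- H[q, cols] + w[k] * V[k, cols]
    }
  }
  H %*% p$Wo + matrix(p$bo, l, f, byrow = TRUE)
}

# Sliding-window 1-D convolution with zero padding, left-of-center windows,
# divided by sqrt(S). taps: list of S matrices f x C.
oracle_conv <- function(X, taps, bias) {
  l <- nrow(X); S <- length(taps); C <- length(bias)
  lo <- ceiling((S - 1) / 2)
  Y <- matrix(0, l, C)
  for (j in seq_len(l)) {
    acc <- bias
    for (s in seq_len(S)) {
      src <- j + (s - 1) - lo
      if (src >= 1 && src <= l) acc <- acc + as.vector(X[src, ] %*% taps[[s]])
    }
    Y[j, ] <- acc / sqrt(S)
  }
  Y
}

oracle_central <- function(G, maps, include_global = TRUE) {
  l <- nrow(G); f <- ncol(G); N <- length(maps)
  out <- matrix(0, l, f)
  for (j in seq_len(l)) {
    acc <- if (include_global) G[j, ] else rep(0, f)
    for (k in seq_len(N)) acc <- acc + maps[[k]][j, ]
    out[j, ] <- acc / (N + include_global)
  }
  out
}

oracle_agreement <- function(maps, centers, div) {
  N <- length(maps); l <- nrow(centers)
  A <- matrix(0, N, l)
  for (k in seq_len(N))
    for (j in seq_len(l))
      A[k, j] <- sum(maps[[k]][j, ] * centers[j, ]) / div
  A
}

oracle_joint_softmax <- function(A) {
  flat <- as.vector(A)
  fin <- is.finite(flat)
  e <- rep(0, length(flat))
  e[fin] <- exp(flat[fin] - max(flat[fin]))
  W <- matrix(e / sum(e), nrow(A), ncol(A))
  v <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) v[j] <- sum(W[, j])
  list(W = W, v = v)
}

oracle_mix <- function(W, v, maps) {
  l <- ncol(W); f <- ncol(maps[[1]]); N <- nrow(W)
  out <- matrix(0, l, f)
  for (j in seq_len(l)) {
    if (v[j] <= 0) next
    for (k in seq_len(N))
      out[j, ] <- out[j, ] + (W[k, j] / v[j]) * maps[[k]][j, ]
  }
  out
}

oracle_aggregate <- function(C, v) {
  M <- ncol(C)
  p <- numeric(M)
  for (d in seq_len(M))
    for (j in seq_len(nrow(C)))
      p[d] <- p[d] + C[j, d] * v[j]
  p
}

# Random attention-layer parameters.
rand_attn_params <- function(f) {
  list(Wq = matrix(rnorm(f * f), f, f), bq = rnorm(f),
       Wk = matrix(rnorm(f * f), f, f), bk = rnorm(f),
       Wv = matrix(rnorm(f * f), f, f), bv = rnorm(f),
       Wo = matrix(rnorm(f * f), f, f), bo = rnorm(f))
}

# Random scale feature maps with zeroed PAD rows.
rand_maps <- function(N, l, f, mask = rep(TRUE, l)) {
  lapply(seq_len(N), function(k) {
    m <- matrix(rnorm(l * f), l, f)
    m[!mask, ] <- 0
    m
  })
}

# A random untrained tiny classifier model (direct object construction).
rand_tiny_model <- function(cfg) {
  params <- dsattn:::init_model(cfg)
  structure(list(params = params, config = cfg,
                 classes = paste0("class", seq_len(cfg$n_classes))),
            class = "dsattn")
}

# Uniform-background random amino-acid string.
rand_aa <- function(n) {
  paste(sample(setdiff(dsattn::aa_vocab()$residues, c("U", "O")), n,
               replace = TRUE), collapse = "")
}
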