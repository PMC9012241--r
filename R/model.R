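# Model configuration, parameter initialization, and the full forward /
# backward passes for classification and masked-LM objectives.

#' Model configuration
#'
#' Collects every architectural hyper-parameter of a double-scale attention
#' model. The default values are the desk-scale configuration (input length
#' 128, feature dimension 64, 2 encoder layers, 2 heads); the full-scale
#' configuration (length 512, dimension 512, 8 heads, 6 layers, initial
#' embedding dimension 16) ships as `inst/configs/full-6layer.yaml`.
#'
#' @param l fixed input length in tokens.
#' @param f encoder feature (hidden-state) dimension; divisible by `h`.
#' @param h number of attention heads; per-head dimensions are
#'   `d_k = d_v = f/h`.
#' @param n_layers number of encoder layers.
#' @param d_emb initial embedding dimension; when smaller than `f` a
#'   learned linear projection maps embeddings to `f` before the positional
#'   encoding is added.
#' @param d_ff feed-forward inner dimension (default `4 * f`).
#' @param scales strictly increasing convolution kernel sizes, each
#'   `<= l`; default `c(5, 10, 20)`, matching the common lengths of
#'   annotated protein motif features.
#' @param channels_per_size convolution output channels per unit of kernel
#'   size (channel count for size `S_k` is `channels_per_size * S_k`).
#' @param agree_divisor `"sqrt_f"` or `"f"`: divisor of the agreement dot
#'   product.
#' @param include_global include the global features in the central-vector
#'   mean (ablation switch; default `TRUE`).
#' @param dropout global dropout probability.
#' @param n_classes number of output classes `M` (`NULL` for an
#'   encoder-only / pre-training model).
#' @return A list of class `dsattn_config`.
#' @export
dsattn_config <- function(l = 128L, f = 64L, h = 2L, n_layers = 2L,
                          d_emb = f, d_ff = 4L * f,
                          scales = c(5L, 10L, 20L), channels_per_size = 16L,
                          agree_divisor = c("sqrt_f", "f"),
                          include_global = TRUE, dropout = 0.1,
                          n_classes = NULL) {
  agree_divisor <- match.arg(agree_divisor)
  if (f %% h != 0) stop("f must be divisible by h", call. = FALSE)
  if (f %% 2 != 0) stop("f must be even (positional encoding)", call. = FALSE)
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  scales <- as.integer(scales)
  if (any(diff(scales) <= 0) || any(scales < 1))
    stop("kernel sizes must be strictly increasing positive integers", call. = FALSE)
  if (any(scales > l)) stop("kernel sizes must not exceed l", call. = FALSE)
  if (!is.null(n_classes) && n_classes < 2)
    stop("n_classes must be >= 2", call. = FALSE)
  structure(list(l = as.integer(l), f = as.integer(f), h = as.integer(h),
                 n_layers = as.integer(n_layers), d_emb = as.integer(d_emb),
                 d_ff = as.integer(d_ff), scales = scales,
                 channels_per_size = as.integer(channels_per_size),
                 agree_divisor = agree_divisor,
                 include_global = include_global,
                 dropout = dropout,
                 n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
                 d_k = as.integer(f / h)),
            class = "dsattn_config")
}

#' @export
print.dsattn_config <- function(x, ...) {
  cat("<dsattn_config> l=", x$l, " f=", x$f, " h=", x$h,
      " layers=", x$n_layers, " scales={", paste(x$scales, collapse = ","),
      "} classes=", if (is.null(x$n_classes)) "-" else x$n_classes,
      "\n", sep = "")
  invisible(x)
}

# Initialize all model parameters (uses the current RNG state).
init_model <- function(cfg) {
  voc <- aa_vocab()
  params <- list(
    embed = init_embedding(length(voc$tokens), cfg$d_emb, cfg$f, voc$pad_id),
    encoder = lapply(seq_len(cfg$n_layers),
                     function(i) init_encoder_layer(cfg$f, cfg$d_ff)),
    scales = lapply(cfg$scales, function(S)
      init_scale_params(cfg$f, S, cfg$channels_per_size, cfg$f)),
    mlm = {
      lin <- init_linear(cfg$f, length(voc$residue_ids))
      list(Wd = lin$W, bd = lin$b)
    })
  if (!is.null(cfg$n_classes))
    params$classifier <- init_classifier(cfg$f, cfg$n_classes)
  params
}

# ---- full passes -----------------------------------------------------------

# ids, mask: B x l matrices. Returns class probabilities P (B x M) plus all
# caches needed for the backward pass.
model_forward <- function(params, cfg, ids, mask, training = FALSE) {
  B <- nrow(ids); l <- ncol(ids)
  flat_mask <- as.vector(t(mask))
  X <- embed_batch(ids, mask, params$embed, cfg$f)
  enc <- encode_forward(X, flat_mask, B, l, params$encoder, cfg$h,
                        cfg$dropout, training)
  ds <- ds_forward(enc$out, flat_mask, B, l, params, cfg)
  hd <- head_forward(ds$Fm, ds$v, B, l, params$classifier)
  list(P = hd$P, W = ds$W, v = ds$v, enc = enc, ds = ds, hd = hd,
       X = X, flat_mask = flat_mask, B = B, l = l)
}

# Cross-entropy on the aggregated distribution; labels: integer 1..M.
model_backward <- function(fw, labels, params, cfg, ids, mask) {
  B <- fw$B; l <- fw$l
  P <- fw$P
  dP <- matrix(0, B, ncol(P))
  py <- P[cbind(seq_len(B), labels)]
  dP[cbind(seq_len(B), labels)] <- -1 / (pmax(py, 1e-12) * B)
  hb <- head_backward(dP, fw$hd, fw$ds$Fm, fw$ds$v, B, l, params$classifier)
  db <- ds_backward(hb$dFm, hb$dv, fw$ds, fw$enc$out, fw$flat_mask, B, l,
                    params, cfg)
  eb <- encode_backward(db$dG, fw$enc, fw$flat_mask, B, l, params$encoder,
                        cfg$h)
  eg <- embed_backward(eb$dX, ids, mask, params$embed, cfg$f)
  list(grads = list(embed = eg, encoder = eb$grads, scales = db$scale_grads,
                    classifier = hb$grads),
       loss = mean(-log(pmax(py, 1e-12))))
}

# Masked-LM pass. tpos: stacked row indices of target positions; torig: the
# original residue ids there.
mlm_forward <- function(params, cfg, ids, mask, tpos, torig, training = FALSE) {
  B <- nrow(ids); l <- ncol(ids)
  flat_mask <- as.vector(t(mask))
  X <- embed_batch(ids, mask, params$embed, cfg$f)
  enc <- encode_forward(X, flat_mask, B, l, params$encoder, cfg$h,
                        cfg$dropout, training)
  G <- enc$out
  logits <- affine(G[tpos, , drop = FALSE], params$mlm$Wd, params$mlm$bd)
  probs <- row_softmax(logits)
  loss <- mean(-log(pmax(probs[cbind(seq_along(tpos), torig)], 1e-12)))
  list(loss = loss, probs = probs, enc = enc, X = X, flat_mask = flat_mask,
       B = B, l = l)
}

mlm_backward <- function(fw, params, cfg, ids, mask, tpos, torig) {
  n <- length(tpos)
  dlog <- fw$probs
  dlog[cbind(seq_len(n), torig)] <- dlog[cbind(seq_len(n), torig)] - 1
  dlog <- dlog / n
  G <- fw$enc$out
  g_mlm <- list(Wd = crossprod(G[tpos, , drop = FALSE], dlog),
                bd = colSums(dlog))
  dG <- matrix(0, nrow(G), ncol(G))
  dG[tpos, ] <- tcrossprod(dlog, params$mlm$Wd)
  eb <- encode_backward(dG, fw$enc, fw$flat_mask, fw$B, fw$l,
                        params$encoder, cfg$h)
  eg <- embed_backward(eb$dX, ids, mask, params$embed, cfg$f)
  list(grads = list(embed = eg, encoder = eb$grads, mlm = g_mlm))
}

# ---- optimizer -------------------------------------------------------------

# Walk the gradient tree; for every numeric leaf update the matching
# parameter leaf with AdamW (decoupled weight decay on weight matrices only).
adamw_init <- function() list(m = list(), v = list(), t = 0L)

adamw_step <- function(params, grads, state, lr, wd = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, m, v) {
    if (is.numeric(g)) {
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      upd <- (m / bc1) / (sqrt(v / bc2) + eps)
      if (is.matrix(p)) p <- p - lr * wd * p
      p <- p - lr * upd
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) m <- vector("list", length(g))
    if (is.null(v)) v <- vector("list", length(g))
    keys <- names(g)
    for (i in seq_along(g)) {
      if (is.null(g[[i]])) next
      key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
      r <- walk(p[[key]], g[[i]],
                if (length(m) >= i) m[[i]] else NULL,
                if (length(v) >= i) v[[i]] else NULL)
      p[[key]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load model checkpoints
#'
#' Serializes a fitted model, pre-trained encoder, or raw parameter list to
#' an `.rds` file so pre-trained encoder weights can be transferred into
#' fine-tuning runs.
#'
#' @param object any package model object.
#' @param path file path.
#' @return `dsattn_load` returns the deserialized object.
#' @export
dsattn_save <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname dsattn_save
#' @export
dsattn_load <- function(path) readRDS(path)
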