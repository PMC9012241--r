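# Self-supervised masked-LM pre-training, supervised fine-tuning, learning
# rate schedules, and evaluation metrics.

#' Masked-LM corruption of a token sequence
#'
#' Selects `floor(mask_fraction * n_eligible)` positions (at least 1)
#' uniformly without replacement among the eligible positions — non-`PAD`
#' positions whose token is not already `MASK` (unknown residues `X` are
#' encoded as `MASK` and are never prediction targets). Each selected token
#' is replaced by `MASK` (probability 0.8), by a uniformly random residue
#' token (0.1), or kept unchanged (0.1).
#'
#' @param seq a `token_sequence`.
#' @param mask_fraction fraction of eligible positions to target.
#' @param action_probs named numeric vector `c(mask=, random=, keep=)`
#'   summing to 1.
#' @return `NULL` (skip-record signal) when no position is eligible;
#'   otherwise a list with the corrupted `token_sequence` (`seq`), target
#'   `positions` (1-based within the window), the `original` ids there,
#'   and the `action` applied at each target.
#' @export
mlm_corrupt <- function(seq, mask_fraction = 0.15,
                        action_probs = c(mask = 0.8, random = 0.1, keep = 0.1)) {
  stopifnot(abs(sum(action_probs) - 1) < 1e-9,
            mask_fraction > 0, mask_fraction < 1)
  voc <- aa_vocab()
  eligible <- which(seq$mask & seq$ids != voc$mask_id)
  if (length(eligible) == 0L) return(NULL)
  n_t <- max(1L, floor(mask_fraction * length(eligible)))
  pos <- if (length(eligible) == 1L) eligible else sample(eligible, n_t)
  orig <- seq$ids[pos]
  u <- stats::runif(n_t)
  action <- ifelse(u < action_probs[["mask"]], "mask",
                   ifelse(u < action_probs[["mask"]] + action_probs[["random"]],
                          "random", "keep"))
  ids <- seq$ids
  ids[pos[action == "mask"]] <- voc$mask_id
  nr <- sum(action == "random")
  if (nr) ids[pos[action == "random"]] <- sample(voc$residue_ids, nr, replace = TRUE)
  out <- seq
  out$ids <- ids
  list(seq = out, positions = pos, original = orig, action = action)
}

#' Masked-LM loss
#'
#' Mean cross-entropy, over the target positions, of a position-wise linear
#' decoder's softmax over the 22 residue tokens.
#'
#' @param F_global `l x f` encoder output.
#' @param positions row indices of the prediction targets.
#' @param original original residue ids (1..22) at those positions.
#' @param params decoder parameters: `Wd` (`f x 22`), `bd`.
#' @return Scalar loss.
#' @export
mlm_loss <- function(F_global, positions, original, params) {
  if (length(positions) == 0L) stop("empty target set", call. = FALSE)
  probs <- row_softmax(affine(F_global[positions, , drop = FALSE],
                              params$Wd, params$bd))
  mean(-log(pmax(probs[cbind(seq_along(positions), original)], 1e-12)))
}

#' Learning-rate schedules
#'
#' `pretrain_lr` ramps linearly from 0 to `peak_lr` over `warmup_steps`,
#' then decays as `peak_lr * sqrt(warmup_steps / step)` (inverse square
#' root, continuous at the warm-up boundary). `finetune_lr` starts at
#' `initial_lr` and is multiplied by `decay_factor` after every
#' `decay_every` iterations.
#'
#' @param step,iteration 0-based optimizer step.
#' @param warmup_steps warm-up length (full-scale default 50,000).
#' @param peak_lr maximum learning rate (full-scale defaults: 5e-5 for the
#'   6-layer model, 1e-4 for the 3-layer model).
#' @param initial_lr fine-tuning starting rate (full-scale default 1e-5).
#' @param decay_factor multiplicative decay (default 0.95).
#' @param decay_every iterations between decays (default 100).
#' @return Learning rate (non-negative scalar).
#' @export
pretrain_lr <- function(step, warmup_steps, peak_lr) {
  stopifnot(step >= 0, warmup_steps >= 1)
  if (step <= warmup_steps) peak_lr * step / warmup_steps
  else peak_lr * sqrt(warmup_steps / step)
}

#' @rdname pretrain_lr
#' @export
finetune_lr <- function(iteration, initial_lr = 1e-5, decay_factor = 0.95,
                        decay_every = 100) {
  stopifnot(iteration >= 0, decay_factor > 0, decay_factor <= 1)
  initial_lr * decay_factor^(iteration %/% decay_every)
}

# ---- batching --------------------------------------------------------------

# Normalize + window each raw sequence; returns B x l id and mask matrices.
prepare_batch <- function(sequences, l, mode = "train") {
  B <- length(sequences)
  ids <- matrix(0L, B, l)
  msk <- matrix(FALSE, B, l)
  seqs <- vector("list", B)
  for (b in seq_len(B)) {
    ts <- encode_sequence(sequences[b], l, mode = mode)
    ids[b, ] <- ts$ids
    msk[b, ] <- ts$mask
    seqs[[b]] <- ts
  }
  list(ids = ids, mask = msk, seqs = seqs)
}

make_batches <- function(n, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# ---- pre-training ----------------------------------------------------------

#' Masked-LM pre-training of the encoder
#'
#' Self-supervised pre-training: random windows of the input sequences are
#' corrupted by [mlm_corrupt()] and the encoder plus a position-wise linear
#' decoder are trained with AdamW to recover the original residues. The
#' learning rate follows the warm-up / inverse-square-root schedule of
#' [pretrain_lr()]. The checkpoint with the best validation loss is kept.
#'
#' @param sequences character vector of raw amino-acid sequences.
#' @param config a [dsattn_config()] (`n_classes` ignored).
#' @param epochs maximum number of passes over the training split.
#' @param batch_size sequences per optimizer step.
#' @param warmup_steps,peak_lr schedule parameters (desk-scale defaults;
#'   the full-scale values 50,000 / 5e-5 ship in `inst/configs/`).
#' @param mask_fraction,action_probs corruption parameters, see
#'   [mlm_corrupt()].
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_fraction fraction of sequences held out for validation.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param verbose print per-epoch losses.
#' @return Object of class `dsattn_encoder`: parameters, config, per-epoch
#'   loss trace, and the best epoch index.
#' @export
dsattn_pretrain <- function(sequences, config = dsattn_config(),
                            epochs = 3, batch_size = 32,
                            warmup_steps = 200, peak_lr = 1e-3,
                            mask_fraction = 0.15,
                            action_probs = c(mask = 0.8, random = 0.1, keep = 0.1),
                            weight_decay = 1e-4, val_fraction = 0.05,
                            seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  params <- init_model(cfg)
  n <- length(sequences)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_seqs <- sequences[-val_idx]
  val_seqs <- sequences[val_idx]
  state <- adamw_init()
  step <- 0L
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)

  run_mlm_batch <- function(seqs_raw, mode, train) {
    bt <- prepare_batch(seqs_raw, cfg$l, mode = mode)
    tpos <- integer(0); torig <- integer(0)
    for (b in seq_along(bt$seqs)) {
      cor <- mlm_corrupt(bt$seqs[[b]], mask_fraction, action_probs)
      if (is.null(cor)) next
      bt$ids[b, ] <- cor$seq$ids
      tpos <- c(tpos, (b - 1L) * cfg$l + cor$positions)
      torig <- c(torig, cor$original)
    }
    if (length(tpos) == 0L) return(NULL)
    fw <- mlm_forward(params, cfg, bt$ids, bt$mask, tpos, torig,
                      training = train)
    list(fw = fw, bt = bt, tpos = tpos, torig = torig)
  }

  for (ep in seq_len(epochs)) {
    tr_losses <- c()
    for (bidx in make_batches(length(train_seqs), batch_size)) {
      rb <- run_mlm_batch(train_seqs[bidx], "train", TRUE)
      if (is.null(rb)) next
      if (!is.finite(rb$fw$loss))
        stop(sprintf("non-finite pre-training loss at step %d", step), call. = FALSE)
      bk <- mlm_backward(rb$fw, params, cfg, rb$bt$ids, rb$bt$mask,
                         rb$tpos, rb$torig)
      step <- step + 1L
      lr <- pretrain_lr(step, warmup_steps, peak_lr)
      upd <- adamw_step(params, bk$grads, state, lr, wd = weight_decay)
      params <- upd$params; state <- upd$state
      tr_losses <- c(tr_losses, rb$fw$loss)
    }
    vl <- c()
    for (bidx in make_batches(length(val_seqs), batch_size, shuffle = FALSE)) {
      rb <- run_mlm_batch(val_seqs[bidx], "eval", FALSE)
      if (!is.null(rb)) vl <- c(vl, rb$fw$loss)
    }
    val_loss <- mean(vl)
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                     val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f", ep,
                      mean(tr_losses), val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = params, epoch = ep)
  }
  structure(list(params = best$params, config = cfg, trace = trace,
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "dsattn_encoder")
}

#' @export
print.dsattn_encoder <- function(x, ...) {
  cat("Masked-LM pre-trained encoder\n")
  print(x$config)
  cat("best validation loss ", format(x$best_val_loss, digits = 4),
      " at epoch ", x$best_epoch, " (uniform baseline ln 22 = ",
      format(log(22), digits = 4), ")\n", sep = "")
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Multi-class evaluation metrics
#'
#' Accuracy, one-vs-rest per-class precision / recall / F1, and their
#' unweighted macro averages. A precision or recall with an empty
#' denominator is defined as 0; F1 is the harmonic mean, or 0 when both
#' components are 0. Classes absent from both predictions and truth are
#' flagged in the `absent` column.
#'
#' @param predicted,truth equal-length vectors of class labels (character
#'   or factor).
#' @param classes optional explicit class set (defaults to the union).
#' @return Object of class `dsattn_metrics`: list with `accuracy`,
#'   `per_class` data frame, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = NULL) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("predictions and labels must be non-empty and equal length", call. = FALSE)
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  tab <- table(factor(truth, classes), factor(predicted, classes))
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  absent <- rowSums(tab) == 0 & colSums(tab) == 0
  structure(list(
    accuracy = sum(tp) / length(truth),
    per_class = data.frame(class = classes, precision = unname(prec),
                           recall = unname(rec), f1 = unname(f1),
                           absent = unname(absent)),
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1)), class = "dsattn_metrics")
}

#' @export
print.dsattn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro-P %.4f  macro-R %.4f  macro-F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
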