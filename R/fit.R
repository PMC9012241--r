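# Supervised fine-tuning: the package's main model-fitting entry point.

#' Fit a double-scale attention protein classifier
#'
#' Trains the full model — token embedding, transformer encoder stack,
#' multi-scale convolutions, double-scale attention, and position-wise
#' classifier — on labeled amino-acid sequences by minimizing the
#' cross-entropy of the aggregated class distribution with AdamW. Encoder
#' and embedding weights can be transferred from a [dsattn_pretrain()] run;
#' convolutions and classifier always start fresh. The learning rate
#' follows the step-decay schedule of [finetune_lr()], and the checkpoint
#' with the best validation accuracy is kept.
#'
#' @param x character vector of raw amino-acid sequences (or a named
#'   vector; names become sequence ids).
#' @param labels class labels, one per sequence (factor or character).
#' @param config a [dsattn_config()]; `n_classes` is inferred from
#'   `labels`.
#' @param encoder optional `dsattn_encoder` object whose embedding and
#'   encoder weights initialize this model.
#' @param epochs maximum fine-tuning epochs.
#' @param batch_size sequences per optimizer step.
#' @param initial_lr,decay_factor,decay_every learning-rate schedule
#'   (desk-scale default `initial_lr = 1e-3`; the full-scale value 1e-5
#'   ships in `inst/configs/finetune-full.yaml`).
#' @param weight_decay AdamW decoupled weight decay (default 1e-4).
#' @param validation either a fraction of `x` to hold out (number in
#'   (0,1)) or a list `list(x =, labels =)` with explicit validation data.
#' @param seed integer seed; the run is deterministic given it.
#' @param verbose print per-epoch progress.
#' @return Object of class `dsattn`: list with `params`, `config`,
#'   `classes`, per-epoch `trace`, `best_epoch`, and the matched `call`.
#' @seealso [predict.dsattn()], [dsattn_explain()], [dsattn_pretrain()]
#' @examples
#' \donttest{
#' set.seed(7)
#' ds <- synth_dataset(synth_config(n_classes = 2, seqs_per_class = 30,
#'                                  length_range = c(40, 60),
#'                                  motif_lengths = c(5, 9), seed = 7))
#' cfg <- dsattn_config(l = 64, f = 16, h = 2, n_layers = 1,
#'                      scales = c(3, 5, 9), channels_per_size = 4)
#' fit <- dsattn(ds$sequences[ds$split == "train"],
#'               ds$labels[ds$split == "train"],
#'               config = cfg, epochs = 1, seed = 1)
#' predict(fit, ds$sequences[ds$split == "test"][1:3])
#' }
#' @export
dsattn <- function(x, labels, config = dsattn_config(), encoder = NULL,
                   epochs = 5, batch_size = 32,
                   initial_lr = 1e-3, decay_factor = 0.95, decay_every = 100,
                   weight_decay = 1e-4, validation = 0.1,
                   seed = NULL, verbose = FALSE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  if (length(x) != length(labels))
    stop("x and labels must have equal length", call. = FALSE)
  labels <- factor(labels)
  classes <- levels(labels)
  cfg <- config
  cfg$n_classes <- length(classes)
  if (cfg$n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  params <- init_model(cfg)
  if (!is.null(encoder)) {
    stopifnot(inherits(encoder, "dsattn_encoder"))
    ec <- encoder$config
    if (ec$f != cfg$f || ec$n_layers != cfg$n_layers || ec$h != cfg$h ||
        ec$d_emb != cfg$d_emb)
      stop("encoder architecture does not match config", call. = FALSE)
    params$embed <- encoder$params$embed
    params$encoder <- encoder$params$encoder
  }

  if (is.list(validation)) {
    val_x <- validation$x
    val_y <- factor(validation$labels, classes)
    tr_x <- x; tr_y <- labels
  } else {
    n_val <- max(1L, round(validation * length(x)))
    vi <- sample.int(length(x), n_val)
    val_x <- x[vi]; val_y <- labels[vi]
    tr_x <- x[-vi]; tr_y <- labels[-vi]
  }

  state <- adamw_init()
  iter <- 0L
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_accuracy = numeric())
  best <- list(acc = -1, params = params, epoch = 0L)

  for (ep in seq_len(epochs)) {
    losses <- c()
    for (bidx in make_batches(length(tr_x), batch_size)) {
      bt <- prepare_batch(tr_x[bidx], cfg$l, mode = "train")
      fw <- model_forward(params, cfg, bt$ids, bt$mask, training = TRUE)
      bk <- model_backward(fw, as.integer(tr_y[bidx]), params, cfg,
                           bt$ids, bt$mask)
      if (!is.finite(bk$loss))
        stop(sprintf("non-finite fine-tuning loss at iteration %d", iter),
             call. = FALSE)
      lr <- finetune_lr(iter, initial_lr, decay_factor, decay_every)
      upd <- adamw_step(params, bk$grads, state, lr, wd = weight_decay)
      params <- upd$params; state <- upd$state
      iter <- iter + 1L
      losses <- c(losses, bk$loss)
    }
    pv <- predict_probs(params, cfg, val_x, batch_size)
    acc <- mean(classes[max.col(pv)] == as.character(val_y))
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_accuracy = acc))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val acc %.3f", ep,
                      mean(losses), acc))
    if (acc > best$acc) best <- list(acc = acc, params = params, epoch = ep)
  }
  structure(list(params = best$params, config = cfg, classes = classes,
                 trace = trace, best_epoch = best$epoch,
                 best_val_accuracy = best$acc, call = cl),
            class = "dsattn")
}

# Batched evaluation-mode class probabilities for raw sequences.
predict_probs <- function(params, cfg, sequences, batch_size = 64) {
  out <- matrix(0, length(sequences), cfg$n_classes)
  for (bidx in make_batches(length(sequences), batch_size, shuffle = FALSE)) {
    bt <- prepare_batch(sequences[bidx], cfg$l, mode = "eval")
    fw <- model_forward(params, cfg, bt$ids, bt$mask, training = FALSE)
    out[bidx, ] <- fw$P
  }
  out
}

#' Predict from a fitted double-scale attention model
#'
#' @param object a fitted `dsattn` model.
#' @param newdata character vector of raw amino-acid sequences; names (or
#'   `seq1..seqn`) become row ids.
#' @param type `"class"` for hard labels, `"prob"` for the full class
#'   distribution, `"both"` for a data frame with id, predicted class and
#'   one probability column per class (the `predict` TSV layout).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.dsattn <- function(object, newdata, type = c("class", "prob", "both"),
                           ...) {
  type <- match.arg(type)
  P <- predict_probs(object$params, object$config, newdata)
  colnames(P) <- object$classes
  cls <- object$classes[max.col(P)]
  ids <- names(newdata)
  if (is.null(ids)) ids <- paste0("seq", seq_along(newdata))
  switch(type,
         class = stats::setNames(cls, ids),
         prob = { rownames(P) <- ids; P },
         both = data.frame(seq_id = ids, predicted = cls, P,
                           check.names = FALSE))
}

#' @export
print.dsattn <- function(x, ...) {
  cat("Double-scale attention protein classifier\n")
  print(x$config)
  cat("classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat(sprintf("best validation accuracy %.3f at epoch %d\n",
              x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @method summary dsattn
#' @export
summary.dsattn <- function(object, ...) {
  npar <- sum(rapply(object$params, length, how = "unlist"))
  cat("Double-scale attention protein classifier\n\n")
  print(object$config)
  cat("parameters: ", npar, "\n", sep = "")
  cat("classes:    ", paste(object$classes, collapse = ", "), "\n", sep = "")
  cat("\nTraining trace:\n")
  print(object$trace, row.names = FALSE)
  invisible(object)
}

#' @method coef dsattn
#' @export
coef.dsattn <- function(object, ...) object$params

#' Plot the training trace of a fitted model
#'
#' Training loss (left axis) and validation accuracy (right axis) per
#' epoch.
#'
#' @param x a `dsattn` object.
#' @param ... passed to [graphics::plot()].
#' @method plot dsattn
#' @export
plot.dsattn <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tr$epoch, tr$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::par(new = TRUE)
  graphics::plot(tr$epoch, tr$val_accuracy, type = "b", pch = 1, lty = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("validation accuracy", side = 4, line = 2.5)
  invisible(x)
}
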