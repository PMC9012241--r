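# Attention-based motif interpretability: matching annotated functional
# sites/regions against the double-scale attention matrix.

#' Explain a sequence with the double-scale attention matrix
#'
#' Runs a fitted model on one sequence in evaluation mode (leading window,
#' no dropout) and returns the double-scale attention matrix `W`
#' (scales x positions), its positional margin `v`, and the predicted class
#' distribution — the model's interpretability object.
#'
#' @param model a fitted `dsattn` object.
#' @param sequence a single raw amino-acid sequence.
#' @param seq_id optional identifier carried into reports.
#' @return Object of class `dsattn_explanation`: list with `W`, `v`,
#'   `mask`, `scales`, `window_start`, `probs`, `seq_id`.
#' @export
dsattn_explain <- function(model, sequence, seq_id = "seq1") {
  cfg <- model$config
  bt <- prepare_batch(sequence, cfg$l, mode = "eval")
  fw <- model_forward(model$params, cfg, bt$ids, bt$mask, training = FALSE)
  W <- t(fw$W)                       # stored (l x N) stacked; expose N x l
  p <- as.vector(fw$P)
  names(p) <- model$classes
  structure(list(W = W, v = fw$v, mask = bt$mask[1, ], scales = cfg$scales,
                 window_start = bt$seqs[[1]]$window_start,
                 raw_length = bt$seqs[[1]]$raw_length,
                 probs = p, seq_id = seq_id),
            class = "dsattn_explanation")
}

#' @export
print.dsattn_explanation <- function(x, ...) {
  cat("<dsattn_explanation> ", x$seq_id, ": ", sum(x$mask),
      " positions x scales {", paste(x$scales, collapse = ","), "}\n",
      sep = "")
  top <- order(x$v, decreasing = TRUE)[1:min(5, sum(x$mask))]
  cat(" top margin positions (0-based):",
      paste(top - 1L, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a double-scale attention explanation
#'
#' Draws the positional margin `v` as a line with one curve per spatial
#' scale of `W` underneath, optionally shading annotated regions.
#'
#' @param x a `dsattn_explanation`.
#' @param annotations optional data frame with `start`, `end` (0-based
#'   half-open) to shade.
#' @param ... passed to [graphics::matplot()].
#' @method plot dsattn_explanation
#' @export
plot.dsattn_explanation <- function(x, annotations = NULL, ...) {
  np <- sum(x$mask)
  pos <- seq_len(np) - 1L
  Y <- cbind(margin = x$v[seq_len(np)], t(x$W[, seq_len(np), drop = FALSE]))
  graphics::matplot(pos, Y, type = "l", lty = c(1, rep(2, nrow(x$W))),
                    xlab = "position (0-based)", ylab = "attention weight",
                    ...)
  if (!is.null(annotations) && nrow(annotations))
    for (i in seq_len(nrow(annotations)))
      graphics::rect(annotations$start[i], 0, annotations$end[i] - 1,
                     max(Y), col = grDevices::adjustcolor("grey", 0.3),
                     border = NA)
  graphics::legend("topright", bty = "n", lty = c(1, rep(2, nrow(x$W))),
                   col = seq_len(ncol(Y)),
                   legend = c("margin v", paste0("scale ", x$scales)))
  invisible(x)
}

# Kernel size closest to a motif length; ties broken toward the smaller
# kernel (scales are strictly increasing).
closest_kernel <- function(scales, len) scales[which.min(abs(scales - len))]

#' Match one annotation against the attention matrix
#'
#' An annotated functional site or region of length `len` is matched by
#' the double-scale attention matrix when, at its middle position `j*`
#' (left-of-center for even lengths), (1) the spatial scale with the
#' highest attention is the kernel size closest to `len` (ties toward the
#' smaller kernel), and (2) the positional margin `v[j*]` exceeds 1.5
#' times the mean margin over real (non-`PAD`) positions.
#'
#' @param explanation a `dsattn_explanation` (see [dsattn_explain()]).
#' @param start,end 0-based half-open annotation coordinates on the raw
#'   sequence.
#' @param label annotation label carried through.
#' @param scale_mode `"position"` (default): the highest-attention kernel
#'   is `argmax_k W[k, j*]`; `"sequence"`: the kernel with the largest
#'   total mass `sum_j W[k, j]`.
#' @param ratio_threshold margin-ratio threshold (default 1.5).
#' @return A list with `status` (`"match"`, `"no_match"`, or
#'   `"out_of_window"`) and, when evaluated, `matched_scale`,
#'   `closest_scale`, `center_weight_ratio`, `score`, `middle`, plus the
#'   annotation fields.
#' @export
match_annotation <- function(explanation, start, end, label = "",
                             scale_mode = c("position", "sequence"),
                             ratio_threshold = 1.5) {
  scale_mode <- match.arg(scale_mode)
  x <- explanation
  if (end <= start || start < 0)
    stop("annotation must satisfy 0 <= start < end", call. = FALSE)
  np <- sum(x$mask)
  ws <- x$window_start
  # window coordinates of the annotation under the model's chop window
  s <- start - ws; e <- end - ws
  base <- list(seq_id = x$seq_id, start = start, end = end, label = label)
  if (s < 0 || e > np)
    return(c(base, list(status = "out_of_window")))
  len <- e - s
  jmid <- (s + e - 1L) %/% 2L                 # 0-based middle position
  j <- jmid + 1L
  ck <- closest_kernel(x$scales, len)
  k_hat <- if (scale_mode == "position") which.max(x$W[, j])
           else which.max(rowSums(x$W))
  ratio <- x$v[j] / mean(x$v[x$mask])
  ok <- (x$scales[k_hat] == ck) && (ratio > ratio_threshold)
  c(base, list(status = if (ok) "match" else "no_match",
               matched_scale = x$scales[k_hat], closest_scale = ck,
               center_weight_ratio = ratio,
               score = x$W[k_hat, j], middle = jmid))
}

#' Rank matched annotations and keep the top 16
#'
#' Sorts matches by their double-scale attention score in descending
#' order (ties broken by the earlier start coordinate) and keeps the
#' first `top` of them.
#'
#' @param matches list of results from [match_annotation()]; entries whose
#'   `status` is not `"match"` are dropped.
#' @param top maximum number kept (default 16).
#' @return Data frame of the selected matches, scores non-increasing.
#' @export
rank_and_select <- function(matches, top = 16) {
  keep <- Filter(function(m) identical(m$status, "match"), matches)
  if (length(keep) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), label = character(),
                      matched_scale = integer(),
                      center_weight_ratio = numeric(), score = numeric()))
  df <- do.call(rbind, lapply(keep, function(m)
    data.frame(seq_id = m$seq_id, start = m$start, end = m$end,
               label = m$label, matched_scale = m$matched_scale,
               center_weight_ratio = m$center_weight_ratio,
               score = m$score)))
  df <- df[order(-df$score, df$start), , drop = FALSE]
  utils::head(df, top)
}

#' Attention match rate with a permutation baseline
#'
#' Computes the fraction of in-window ground-truth annotations matched by
#' the fitted model's attention matrices, and the same statistic after
#' relocating every annotation to a uniformly random valid position of its
#' sequence (length preserved), averaged over `n_perm` permutations. The
#' baseline quantifies how often the match criterion fires by chance under
#' the model's attention profile.
#'
#' @param model a fitted `dsattn` object.
#' @param sequences named character vector of raw sequences.
#' @param annotations data frame with `seq_id`, `start`, `end`, `label`
#'   (0-based half-open).
#' @param n_perm number of relocation permutations (>= 20 recommended).
#' @param scale_mode see [match_annotation()].
#' @return List with `observed`, `baseline`, `n_annotations`,
#'   `n_out_of_window`, and the per-annotation `matches` data frame.
#' @export
match_rate <- function(model, sequences, annotations, n_perm = 20,
                       scale_mode = "position") {
  ids <- unique(annotations$seq_id)
  if (is.null(names(sequences)))
    stop("sequences must be named by seq_id", call. = FALSE)
  expl <- lapply(ids, function(id)
    dsattn_explain(model, sequences[[id]], seq_id = id))
  names(expl) <- ids
  results <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    results[[i]] <- match_annotation(expl[[a$seq_id]], a$start, a$end,
                                     a$label, scale_mode = scale_mode)
  }
  status <- vapply(results, `[[`, "", "status")
  in_win <- status != "out_of_window"
  if (!any(in_win))
    stop("no annotation falls inside the model windows", call. = FALSE)
  observed <- mean(status[in_win] == "match")
  base_rates <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    hits <- 0L; tot <- 0L
    for (i in which(in_win)) {
      a <- annotations[i, ]
      ex <- expl[[a$seq_id]]
      len <- a$end - a$start
      wlen <- sum(ex$mask)
      if (wlen < len) next
      s <- sample.int(wlen - len + 1L, 1L) - 1L + ex$window_start
      r <- match_annotation(ex, s, s + len, a$label, scale_mode = scale_mode)
      tot <- tot + 1L
      hits <- hits + (r$status == "match")
    }
    base_rates[p] <- hits / max(tot, 1L)
  }
  mdf <- rank_and_select(results, top = length(results))
  list(observed = observed, baseline = mean(base_rates),
       n_annotations = sum(in_win), n_out_of_window = sum(!in_win),
       matches = mdf)
}

#' Convert 1-based closed coordinates to 0-based half-open
#'
#' Protein feature tables commonly report 1-based closed intervals
#' `[start, end]`; the package uses 0-based half-open `[start, end)`.
#'
#' @param start,end 1-based closed coordinates.
#' @return Data frame with 0-based half-open `start`, `end`.
#' @export
coords_from_1based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = start - 1L, end = end)
}
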