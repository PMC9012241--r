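# File formats: FASTA sequences, label TSV, annotation TSV, explanation
# reports.

#' Read protein sequences from FASTA
#'
#' Multi-line records are supported; sequences are coerced to uppercase.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path; lines wrapped at 60 characters.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read / write sequence class labels
#'
#' Two-column TSV `seq_id<TAB>class_label`; a header line is detected and
#' skipped when present.
#'
#' @param path TSV path.
#' @return Named character vector mapping sequence id to class label.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (nrow(df) && identical(tolower(df[1, 1]), "seq_id")) df <- df[-1, ]
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @param labels named vector of class labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(seq_id = names(labels),
                                class_label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write motif annotations
#'
#' TSV with columns `seq_id`, `start`, `end`, `label` in 0-based half-open
#' coordinates (see [coords_from_1based()] for converting 1-based closed
#' feature-table coordinates).
#'
#' @param path TSV path.
#' @return Data frame with `seq_id`, `start`, `end`, `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("seq_id", "start", "end", "label"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  if (nrow(df) && identical(tolower(df[1, 1]), "seq_id")) {
    df <- utils::read.delim(path, header = TRUE,
                            colClasses = c("character", "integer",
                                           "integer", "character"))
    names(df) <- c("seq_id", "start", "end", "label")
  }
  if (any(df$start < 0 | df$end <= df$start))
    stop("annotations must satisfy 0 <= start < end", call. = FALSE)
  df
}

#' @rdname read_annotations
#' @param annotations data frame with `seq_id`, `start`, `end`, `label`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("seq_id", "start", "end", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an attention explanation report
#'
#' Serializes one sequence's double-scale attention: a TSV with one row
#' per position (position, margin weight, one column per spatial scale)
#' and a dense array file holding the raw `N x l` matrix `W`.
#'
#' @param explanation a `dsattn_explanation`.
#' @param tsv_path per-position report path.
#' @param array_path dense matrix path (tab-separated rows of `W`);
#'   omitted when `NULL`.
#' @export
write_explanation <- function(explanation, tsv_path, array_path = NULL) {
  x <- explanation
  df <- data.frame(position = seq_along(x$v) - 1L,
                   is_pad = !x$mask,
                   margin = x$v,
                   t(x$W))
  names(df)[-(1:3)] <- paste0("scale_", x$scales)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(array_path))
    utils::write.table(x$W, array_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(tsv_path)
}

#' Load a shipped model/training configuration
#'
#' Reads one of the YAML configuration files under
#' `system.file("configs", package = "dsattn")` (or any file in the same
#' layout): a `model` section mapping onto [dsattn_config()] arguments,
#' plus optional `pretrain` and `finetune` sections with schedule and
#' optimizer settings.
#'
#' @param path YAML file path.
#' @return List with elements `model` (a `dsattn_config`), `pretrain`,
#'   `finetune`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list(model = do.call(dsattn_config, y$model),
              pretrain = y$pretrain, finetune = y$finetune)
  out
}
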