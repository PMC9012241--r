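# Amino-acid token vocabulary and sequence canonicalization.

# 22 residue letters: 20 standard amino acids plus selenocysteine (U) and
# pyrrolysine (O), in sorted order so id assignment is stable across runs.
.RESIDUES <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                    "U", "O"))
.STANDARD20 <- setdiff(.RESIDUES, c("U", "O"))

#' Amino-acid vocabulary
#'
#' The token vocabulary used throughout the package: the 22 residue letters
#' (20 standard amino acids plus selenocysteine `U` and pyrrolysine `O`, in
#' alphabetical order) followed by the `MASK` and `PAD` sentinels. Ambiguity
#' codes `B`, `Z` and `X` never receive ids; they are resolved by
#' [normalize_sequence()] before tokenization.
#'
#' @return A list with components:
#'   \describe{
#'     \item{tokens}{character vector of the 24 token names, index = id}
#'     \item{id}{named integer vector mapping token name to id}
#'     \item{residues}{the 22 residue letters}
#'     \item{residue_ids}{ids of the residue tokens}
#'     \item{mask_id,pad_id}{ids of the `MASK` and `PAD` sentinels}
#'   }
#' @examples
#' v <- aa_vocab()
#' v$id[["A"]]
#' v$mask_id
#' @export
aa_vocab <- function() {
  tokens <- c(.RESIDUES, "MASK", "PAD")
  id <- seq_along(tokens)
  names(id) <- tokens
  list(tokens = tokens,
       id = id,
       residues = .RESIDUES,
       residue_ids = unname(id[.RESIDUES]),
       mask_id = unname(id[["MASK"]]),
       pad_id = unname(id[["PAD"]]))
}

#' Canonicalize a raw amino-acid string
#'
#' Resolves the ambiguity codes of the one-letter amino-acid alphabet:
#' each `B` becomes `D` or `N` with probability 1/2 each, each `Z` becomes
#' `E` or `Q` with probability 1/2 each, and each `X` (unknown residue)
#' becomes the `MASK` token. Resolution is re-drawn independently on every
#' call, so the same raw sequence may canonicalize differently across
#' epochs. All other letters must be one of the 22 residue letters.
#'
#' @param raw a single character string of uppercase one-letter residue
#'   codes (the 22 residues plus `B`, `Z`, `X`).
#' @return Character vector of tokens, one element per input residue; every
#'   element is either a residue letter or `"MASK"`.
#' @examples
#' set.seed(1)
#' normalize_sequence("ACDB")  # last token is "D" or "N"
#' normalize_sequence("X")     # "MASK"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  allowed <- c(.RESIDUES, "B", "Z", "X")
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d (not in the amino-acid alphabet)",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  out <- chars
  ib <- which(chars == "B")
  if (length(ib)) out[ib] <- ifelse(stats::runif(length(ib)) < 0.5, "D", "N")
  iz <- which(chars == "Z")
  if (length(iz)) out[iz] <- ifelse(stats::runif(length(iz)) < 0.5, "E", "Q")
  out[chars == "X"] <- "MASK"
  out
}

#' Regularize a token sequence to a fixed length
#'
#' Chops sequences longer than `l` to a contiguous window (uniformly random
#' start in training mode, the leading window in evaluation mode) and pads
#' shorter sequences with `PAD` tokens at the end. The returned validity
#' mask is `TRUE` at real residue (or `MASK`) positions and `FALSE` at
#' `PAD` positions, which always form a contiguous suffix.
#'
#' @param tokens character vector of tokens as produced by
#'   [normalize_sequence()].
#' @param l target length (positive integer).
#' @param mode `"train"` (random chop window) or `"eval"` (window start 0).
#' @return An object of class `token_sequence`: a list with integer `ids`
#'   (length `l`), logical `mask` (length `l`), `raw_length`, and
#'   `window_start` (0-based offset of the chop window into the raw
#'   sequence; 0 when no chopping occurred).
#' @examples
#' ts <- regularize_length(normalize_sequence("ACDEF"), 8, mode = "eval")
#' ts$mask
#' @export
regularize_length <- function(tokens, l, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!is.numeric(l) || length(l) != 1L || l < 1)
    stop("target length l must be a positive integer", call. = FALSE)
  l <- as.integer(l)
  if (length(tokens) == 0L) stop("empty token sequence", call. = FALSE)
  voc <- aa_vocab()
  ids_full <- voc$id[tokens]
  if (anyNA(ids_full))
    stop(sprintf("unknown token '%s'", tokens[which(is.na(ids_full))[1L]]), call. = FALSE)
  n <- length(ids_full)
  start <- 0L
  if (n > l) {
    if (mode == "train") start <- sample.int(n - l + 1L, 1L) - 1L
    ids <- ids_full[(start + 1L):(start + l)]
    mask <- rep(TRUE, l)
  } else {
    ids <- c(ids_full, rep(voc$pad_id, l - n))
    mask <- c(rep(TRUE, n), rep(FALSE, l - n))
  }
  structure(list(ids = unname(as.integer(ids)), mask = mask,
                 raw_length = n, window_start = start),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  voc <- aa_vocab()
  cat("<token_sequence> length", length(x$ids),
      "(", sum(x$mask), "real,", sum(!x$mask), "PAD ), raw_length",
      x$raw_length, "\n")
  cat(" tokens:", paste(voc$tokens[x$ids[x$mask]], collapse = ""), "\n")
  invisible(x)
}

# Tokenize a raw string straight to a token_sequence (normalize + regularize).
encode_sequence <- function(raw, l, mode = "eval") {
  regularize_length(normalize_sequence(raw), l, mode = mode)
}
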