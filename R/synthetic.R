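# Planted-motif synthetic benchmark generator: labeled protein-like
# sequences with class-determining consensus motifs at annotated positions,
# so every pipeline stage (including the interpretability criterion) can be
# exercised without external downloads.

#' Synthetic dataset configuration
#'
#' Describes a planted-motif benchmark: background residues are drawn
#' independently from `background_freqs`; each class carries one or more
#' consensus motifs inserted at uniformly random non-overlapping positions
#' with per-position substitution noise. The default motif lengths
#' `c(5, 9, 19)` sit near / between the default convolution kernel sizes
#' `{5, 10, 20}` so the closest-kernel matching logic is exercised across
#' all scales.
#'
#' @param n_classes number of classes.
#' @param seqs_per_class sequences generated per class.
#' @param length_range integer `c(min, max)` sequence length in residues.
#' @param motif_specs optional list (one element per class) of lists with
#'   `consensus` (residue string) and `prob` (insertion probability). When
#'   `NULL`, one consensus per class is drawn from the seeded RNG with
#'   lengths recycled from `motif_lengths`.
#' @param motif_lengths consensus lengths used when `motif_specs` is
#'   `NULL`.
#' @param insertion_prob insertion probability used for auto-generated
#'   motifs.
#' @param noise per-residue substitution probability inside planted motifs
#'   (each hit becomes a residue different from the consensus letter).
#' @param background_freqs named probabilities over the 20 standard
#'   residues (default uniform); `"swissprot"` selects a natural
#'   amino-acid frequency preset.
#' @param x_rate probability of replacing a background (non-motif) residue
#'   with the unknown code `X` (codec stress-testing; default 0).
#' @param split train/validation/test proportions (default 90:5:5),
#'   applied stratified by class.
#' @param seed integer seed; generation is fully reproducible.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_classes = 3, seqs_per_class = 200,
                         length_range = c(50, 120),
                         motif_specs = NULL, motif_lengths = c(5, 9, 19),
                         insertion_prob = 1, noise = 0.05,
                         background_freqs = NULL, x_rate = 0,
                         split = c(train = 0.90, val = 0.05, test = 0.05),
                         seed = 1) {
  if (is.character(background_freqs) &&
      identical(background_freqs, "swissprot")) {
    background_freqs <- .AA_NATURAL_FREQS
  }
  if (is.null(background_freqs)) {
    background_freqs <- stats::setNames(rep(1 / 20, 20), .STANDARD20)
  }
  stopifnot(abs(sum(background_freqs) - 1) < 1e-8,
            all(names(background_freqs) %in% .STANDARD20),
            noise >= 0, noise <= 1, insertion_prob >= 0, insertion_prob <= 1,
            length(length_range) == 2, length_range[1] <= length_range[2],
            abs(sum(split) - 1) < 1e-8)
  if (is.null(motif_specs)) {
    lens <- rep_len(motif_lengths, n_classes)
    rng <- local({ set.seed(seed + 1000L); lapply(lens, function(L)
      paste(sample(.STANDARD20, L, replace = TRUE), collapse = "")) })
    motif_specs <- lapply(seq_len(n_classes), function(c)
      list(list(consensus = rng[[c]], prob = insertion_prob)))
  }
  for (ms in motif_specs) for (m in ms) {
    if (nchar(m$consensus) > length_range[1])
      stop("motif consensus longer than the minimum sequence length",
           call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 seqs_per_class = as.integer(seqs_per_class),
                 length_range = as.integer(length_range),
                 motif_specs = motif_specs, noise = noise,
                 background_freqs = background_freqs, x_rate = x_rate,
                 split = split, seed = as.integer(seed)),
            class = "synth_config")
}

# Naturally occurring amino-acid frequencies (UniProtKB/Swiss-Prot release
# statistics, renormalized over the 20 standard residues).
.AA_NATURAL_FREQS <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
})

#' Generate a planted-motif dataset
#'
#' @param config a [synth_config()].
#' @return Object of class `dsattn_synth`: list with named `sequences`,
#'   `labels` (factor), `annotations` data frame (`seq_id`, `start`,
#'   `end`, `label`; 0-based half-open ground truth), `split` (factor
#'   train/val/test, stratified by class), and `config`.
#' @export
synth_dataset <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  res <- names(cfg$background_freqs)
  n <- cfg$n_classes * cfg$seqs_per_class
  sequences <- character(n)
  ids <- character(n)
  labels <- character(n)
  ann <- vector("list", n)
  idx <- 0L
  for (cls in seq_len(cfg$n_classes)) {
    for (i in seq_len(cfg$seqs_per_class)) {
      idx <- idx + 1L
      L <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
      chars <- sample(res, L, replace = TRUE, prob = cfg$background_freqs)
      placed <- matrix(integer(0), ncol = 2)   # occupied [start, end) rows
      rows <- list()
      for (mi in seq_along(cfg$motif_specs[[cls]])) {
        m <- cfg$motif_specs[[cls]][[mi]]
        if (stats::runif(1) > m$prob) next
        mlen <- nchar(m$consensus)
        ok <- FALSE
        for (try in 1:200) {
          s <- sample.int(L - mlen + 1L, 1L) - 1L   # 0-based start
          if (!nrow(placed) ||
              all(s + mlen <= placed[, 1] | s >= placed[, 2])) { ok <- TRUE; break }
        }
        if (!ok) stop("infeasible non-overlapping motif placement", call. = FALSE)
        placed <- rbind(placed, c(s, s + mlen))
        mot <- strsplit(m$consensus, "")[[1]]
        hit <- stats::runif(mlen) < cfg$noise
        if (any(hit)) {
          mot[hit] <- vapply(mot[hit], function(ch)
            sample(setdiff(res, ch), 1L), "")
        }
        chars[(s + 1L):(s + mlen)] <- mot
        rows[[length(rows) + 1L]] <-
          data.frame(start = s, end = s + mlen,
                     label = sprintf("class%d_motif%d", cls, mi))
      }
      if (cfg$x_rate > 0) {
        bg <- setdiff(seq_len(L),
                      unlist(lapply(seq_len(nrow(placed)), function(r)
                        (placed[r, 1] + 1L):placed[r, 2])))
        xh <- bg[stats::runif(length(bg)) < cfg$x_rate]
        chars[xh] <- "X"
      }
      id <- sprintf("c%d_s%04d", cls, i)
      ids[idx] <- id
      sequences[idx] <- paste(chars, collapse = "")
      labels[idx] <- paste0("class", cls)
      if (length(rows)) {
        df <- do.call(rbind, rows)
        df <- data.frame(seq_id = id, df)
        ann[[idx]] <- df
      }
    }
  }
  names(sequences) <- ids
  annotations <- do.call(rbind, ann[!vapply(ann, is.null, TRUE)])
  if (is.null(annotations))
    annotations <- data.frame(seq_id = character(), start = integer(),
                              end = integer(), label = character())
  rownames(annotations) <- NULL
  # stratified split
  split <- character(n)
  for (cls in unique(labels)) {
    ci <- which(labels == cls)
    ci <- ci[sample.int(length(ci))]
    k <- length(ci)
    n_val <- round(cfg$split[["val"]] * k)
    n_test <- round(cfg$split[["test"]] * k)
    n_train <- k - n_val - n_test
    split[ci] <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  }
  structure(list(sequences = sequences,
                 labels = stats::setNames(factor(labels), ids),
                 annotations = annotations,
                 split = stats::setNames(
                   factor(split, levels = c("train", "val", "test")), ids),
                 config = cfg),
            class = "dsattn_synth")
}

#' @export
print.dsattn_synth <- function(x, ...) {
  cat("<dsattn_synth> ", length(x$sequences), " sequences, ",
      nlevels(x$labels), " classes, ", nrow(x$annotations),
      " planted-motif annotations\n", sep = "")
  print(table(x$labels, x$split))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `sequences.fasta` (wrapped at 60 characters), `labels.tsv`,
#' `annotations.tsv`, `split.tsv`, and `manifest.json` recording the seed
#' and full generator configuration. A write-then-read round trip through
#' [read_fasta()], [read_labels()] and [read_annotations()] reproduces the
#' records exactly.
#'
#' @param dataset a `dsattn_synth`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
synth_write <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_labels(dataset$labels, file.path(dir, "labels.tsv"))
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(data.frame(seq_id = names(dataset$split),
                                split = as.character(dataset$split)),
                     file.path(dir, "split.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfg <- dataset$config
  cfg$background_freqs <- as.list(cfg$background_freqs)
  jsonlite::write_json(list(seed = cfg$seed, config = unclass(cfg)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
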