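#' Log-odds score of a PWM at one position
#'
#' Scores the length-`width` window of `sequence` starting at `start`
#' (1-based). On the minus strand the reverse complement of that window is
#' scored. Windows containing `N` (or any non-ACGT base) score `-Inf` and can
#' never be hits.
#'
#' @param pwm A [new_pwm()] object.
#' @param sequence DNA string.
#' @param start 1-based start of the scored window.
#' @param strand `"+"` or `"-"`.
#' @param background,pseudocount Passed to [logodds_matrix()].
#' @return Scalar log-odds score.
#' @export
score_at <- function(pwm, sequence, start, strand = "+",
                     background = rep(0.25, 4), pseudocount = 1e-3) {
  stopifnot(strand %in% c("+", "-"))
  lod <- logodds_matrix(pwm, background, pseudocount)
  cpp_score_at(lod, encode_dna(sequence), as.integer(start) - 1L,
               strand == "-")
}

#' Count PWM occurrences in a sequence
#'
#' Number of (offset, strand) pairs whose log-odds score reaches the PWM's
#' `detection_threshold` (comparison is `>=`). Both strands are scanned at
#' every offset; overlapping hits all count, and a motif matching the same
#' offset on both strands (a palindrome) counts twice. Sequences shorter than
#' the motif give 0.
#'
#' @inheritParams score_at
#' @return Nonnegative integer count.
#' @export
count_occurrences <- function(pwm, sequence, background = rep(0.25, 4),
                              pseudocount = 1e-3) {
  lod <- logodds_matrix(pwm, background, pseudocount)
  cpp_count_hits(lod, pwm$detection_threshold, encode_dna(sequence))
}

#' Build the samples x motifs occurrence-count matrix
#'
#' @param sequences `data.frame` with columns `id`, `sequence`, `cell_type`
#'   (as produced by [fetch_sequences()]).
#' @param db A [motif_database()].
#' @inheritParams score_at
#' @return Object of class `MotifCountMatrix`: list with `counts` (integer
#'   matrix, samples x motifs), `sample_ids`, `motif_names`, `labels`.
#' @export
build_count_matrix <- function(sequences, db, background = rep(0.25, 4),
                               pseudocount = 1e-3) {
  stopifnot(inherits(db, "MotifDatabase"))
  if (nrow(sequences) == 0L) stop("no sequences to scan")
  if (length(db) == 0L) stop("empty motif database")
  enc <- lapply(sequences$sequence, encode_dna)
  lods <- lapply(db$motifs, logodds_matrix, background = background,
                 pseudocount = pseudocount)
  thr <- vapply(db$motifs, `[[`, numeric(1), "detection_threshold")
  counts <- cpp_count_matrix(enc, unname(lods), unname(thr))
  dimnames(counts) <- list(sequences$id, names(db))
  motif_count_matrix(counts, sequences$cell_type)
}

#' Construct a MotifCountMatrix
#'
#' @param counts Integer matrix (samples x motifs) with dimnames.
#' @param labels Cell-type label per sample.
#' @return Object of class `MotifCountMatrix`.
#' @export
motif_count_matrix <- function(counts, labels) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(labels) != nrow(counts))
    stop("labels length does not match number of samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  structure(list(counts = counts, sample_ids = rownames(counts),
                 motif_names = colnames(counts),
                 labels = as.character(labels)),
            class = "MotifCountMatrix")
}

#' @export
print.MotifCountMatrix <- function(x, ...) {
  cat(sprintf("MotifCountMatrix: %d samples x %d motifs, %d classes\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.MotifCountMatrix <- function(x) dim(x$counts)

#' Subset a MotifCountMatrix by samples and/or motifs
#'
#' @param x A `MotifCountMatrix`.
#' @param samples,motifs Index vectors (any form accepted by `[`).
#' @return A `MotifCountMatrix`.
#' @export
subset_counts <- function(x, samples = NULL, motifs = NULL) {
  stopifnot(inherits(x, "MotifCountMatrix"))
  counts <- x$counts
  labels <- x$labels
  if (!is.null(samples)) {
    counts <- counts[samples, , drop = FALSE]
    labels <- labels[samples]
  }
  if (!is.null(motifs)) counts <- counts[, motifs, drop = FALSE]
  motif_count_matrix(counts, labels)
}

#' Write a MotifCountMatrix as TSV
#'
#' Columns: `sample_id`, `cell_type`, then one column per motif. This TSV is
#' the interchange format between the scanning and modelling stages.
#'
#' @param x A `MotifCountMatrix`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, header_comment = NULL) {
  stopifnot(inherits(x, "MotifCountMatrix"))
  df <- data.frame(sample_id = x$sample_ids, cell_type = x$labels,
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MotifCountMatrix TSV written by [write_count_matrix()]
#'
#' @param path TSV path.
#' @return A `MotifCountMatrix`.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$sample_id
  motif_count_matrix(counts, df$cell_type)
}
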