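#' Read ChIP-seq peaks from narrowPeak or BED
#'
#' Accepts ENCODE narrowPeak (BED6+4, 10 columns) or plain BED (>= 3 columns).
#' Coordinates follow the BED convention: 0-based, half-open. Missing columns
#' default to `neg_log10_p = 0`, `signal = 0`, `summit_offset = -1`; a
#' narrowPeak p-value column of -1 (the ENCODE "not available" marker) is also
#' mapped to 0. Comment, `track` and `browser` lines are skipped.
#'
#' @param path Path to the peak file.
#' @param cell_type Class label attached to every peak in the file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `neg_log10_p`, `signal`, `summit_offset`, `cell_type`.
#' @export
read_narrowpeak <- function(path, cell_type) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), neg_log10_p = numeric(),
                      signal = numeric(), summit_offset = integer(),
                      cell_type = character(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  parse_line <- function(f, lineno) {
    if (length(f) < 3L)
      stop("line ", lineno, ": fewer than 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("line ", lineno, ": malformed coordinate fields '", f[2], "', '",
           f[3], "'")
    if (end <= start)
      stop("line ", lineno, ": end <= start (", start, ", ", end, ")")
    p <- if (length(f) >= 8L) suppressWarnings(as.numeric(f[8])) else 0
    if (is.na(p)) stop("line ", lineno, ": malformed p-value field '", f[8], "'")
    sig <- if (length(f) >= 7L) suppressWarnings(as.numeric(f[7])) else 0
    if (is.na(sig)) sig <- 0
    summit <- if (length(f) >= 10L) suppressWarnings(as.integer(f[10])) else -1L
    if (is.na(summit)) summit <- -1L
    if (summit >= end - start)
      stop("line ", lineno, ": summit offset ", summit,
           " outside peak of length ", end - start)
    list(chrom = f[1], start = start, end = end,
         name = if (length(f) >= 4L) f[4] else paste0(f[1], ":", start, "-", end),
         neg_log10_p = max(0, p), signal = sig,
         summit_offset = if (summit < 0L) -1L else summit)
  }
  rows <- Map(parse_line, fields, idx)
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    name = vapply(rows, `[[`, character(1), "name"),
    neg_log10_p = vapply(rows, `[[`, numeric(1), "neg_log10_p"),
    signal = vapply(rows, `[[`, numeric(1), "signal"),
    summit_offset = vapply(rows, `[[`, integer(1), "summit_offset"),
    stringsAsFactors = FALSE)
  out$cell_type <- cell_type
  out
}

#' Select the strongest unique peaks
#'
#' Collapses duplicate intervals (identical `chrom`, `start`, `end`) keeping
#' the largest `neg_log10_p`, then returns the `n` strongest peaks ordered by
#' `neg_log10_p` descending, ties broken by `signal` descending then
#' (`chrom`, `start`) ascending, so selection is deterministic.
#'
#' @param peaks Peak `data.frame` from [read_narrowpeak()].
#' @param n Number of peaks to keep (fewer are returned, with a warning, if
#'   fewer are available).
#' @return Peak `data.frame` of at most `n` rows.
#' @export
select_top_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  if (nrow(peaks) == 0L) return(peaks)
  key <- paste(peaks$chrom, peaks$start, peaks$end)
  o <- order(-peaks$neg_log10_p, -peaks$signal, peaks$chrom, peaks$start)
  peaks <- peaks[o, , drop = FALSE]
  peaks <- peaks[!duplicated(key[o]), , drop = FALSE]
  if (nrow(peaks) < n)
    warning("only ", nrow(peaks), " unique peaks available (requested ", n, ")")
  out <- head(peaks, n)
  rownames(out) <- NULL
  out
}

#' Peak centre position
#'
#' The narrowPeak summit (`start + summit_offset`) when a summit is recorded,
#' otherwise the floor of the interval midpoint.
#'
#' @param peaks Peak `data.frame`.
#' @return Integer vector of 0-based centre positions.
#' @export
peak_center <- function(peaks) {
  as.integer(ifelse(peaks$summit_offset >= 0L,
                    peaks$start + peaks$summit_offset,
                    (peaks$start + peaks$end) %/% 2L))
}

#' Build fixed-width windows around peak centres
#'
#' Each window is `[centre - flank, centre + flank)`, length `2 * flank`.
#' Windows that would extend past a contig boundary are dropped (and counted
#' in a message) rather than clipped, so every downstream sequence has equal
#' length. When `contig_lengths` is `NULL` only the left bound (position 0)
#' can be checked; right-bound violations then surface in [fetch_sequences()].
#'
#' @param peaks Peak `data.frame`.
#' @param flank Half-width in bp (>= 1).
#' @param contig_lengths Optional named integer vector of contig lengths.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `cell_type`,
#'   `source_peak_id`, `neg_log10_p`.
#' @export
make_windows <- function(peaks, flank, contig_lengths = NULL) {
  stopifnot(flank >= 1)
  centers <- peak_center(peaks)
  w <- data.frame(chrom = peaks$chrom,
                  start = centers - as.integer(flank),
                  end = centers + as.integer(flank),
                  cell_type = peaks$cell_type,
                  source_peak_id = peaks$name,
                  neg_log10_p = peaks$neg_log10_p,
                  stringsAsFactors = FALSE)
  ok <- w$start >= 0L
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(w$chrom), names(contig_lengths))
    if (length(unknown) > 0L)
      stop("contigs absent from contig-length table: ",
           paste(unknown, collapse = ", "))
    ok <- ok & w$end <= unname(contig_lengths[w$chrom])
  }
  if (any(!ok))
    message("dropped ", sum(!ok), " window(s) extending past contig bounds")
  out <- w[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract window sequences from a genome
#'
#' Sequences are returned uppercase (soft-masking is ignored) in
#' reference-strand orientation.
#'
#' @param windows Window `data.frame` from [make_windows()].
#' @param genome A named `Biostrings::DNAStringSet` or path to a FASTA file.
#'   FASTA names are truncated at the first whitespace.
#' @return `data.frame` with columns `id`, `sequence`, `cell_type`.
#' @export
fetch_sequences <- function(windows, genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("[ \t].*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  lens <- setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(windows$chrom), names(lens))
  if (length(missing) > 0L)
    stop("contig(s) absent from FASTA: ", paste(missing, collapse = ", "))
  over <- windows$end > unname(lens[windows$chrom]) | windows$start < 0L
  if (any(over))
    stop(sum(over), " window(s) exceed contig bounds; drop them with ",
         "make_windows(contig_lengths = ...)")
  seqs <- character(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    seqs[i] <- toupper(as.character(Biostrings::subseq(
      genome[[windows$chrom[i]]], start = windows$start[i] + 1L,
      end = windows$end[i])))
  }
  data.frame(id = windows$source_peak_id, sequence = seqs,
             cell_type = windows$cell_type, stringsAsFactors = FALSE)
}

#' Write windows as BED6
#'
#' Name carries the source peak id, score the rounded `neg_log10_p`, strand
#' is ".".
#'
#' @param windows Window `data.frame`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path, header_comment = NULL) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$source_peak_id, round(windows$neg_log10_p),
                    ".", stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read windows written by [write_windows_bed()]
#'
#' @param path BED6 path.
#' @param cell_type Label to attach (windows do not store labels in BED).
#' @return Window `data.frame`.
#' @export
read_windows_bed <- function(path, cell_type = NA_character_) {
  p <- read_narrowpeak(path, cell_type)
  data.frame(chrom = p$chrom, start = p$start, end = p$end,
             cell_type = p$cell_type, source_peak_id = p$name,
             neg_log10_p = p$neg_log10_p, stringsAsFactors = FALSE)
}
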