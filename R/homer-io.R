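#' Read a HOMER-format motif database
#'
#' HOMER motif files are records of a header line
#' `>CONSENSUS<TAB>NAME<TAB>LOG_ODDS_THRESHOLD` followed by one line per motif
#' position holding four whitespace-separated base probabilities (A, C, G, T).
#' Rows summing within \[0.99, 1.01\] are renormalised; anything further from 1
#' is rejected. A missing threshold defaults to 0.8 x the maximum achievable
#' log-odds score (with a warning). Duplicate names receive `_2`, `_3`, ...
#' suffixes.
#'
#' @param path Path to a HOMER motif file.
#' @return A [motif_database()] preserving file order.
#' @export
read_homer_motifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no motif records (no '>' headers) in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  motifs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[k]]), "[ \t]+")[[1]]
    consensus <- hdr[1]
    name <- if (length(hdr) >= 2L && nzchar(hdr[2])) hdr[2] else consensus
    threshold <- if (length(hdr) >= 3L) suppressWarnings(as.numeric(hdr[3])) else NA_real_
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) < 1L) stop("motif '", name, "': no probability rows")
    probs <- t(vapply(body, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
      if (length(v) != 4L || anyNA(v))
        stop("motif '", name, "': malformed probability row: ", l)
      v
    }, numeric(4), USE.NAMES = FALSE))
    rs <- rowSums(probs)
    if (any(rs < 0.99 | rs > 1.01))
      stop("motif '", name, "': probability row sums outside [0.99, 1.01]")
    probs <- probs / rs
    if (is.na(threshold)) {
      motifs[[k]] <- new_pwm(name, probs, detection_threshold = NULL,
                             consensus = consensus)
      warning("motif '", name, "': no detection threshold in header; ",
              "defaulting to 0.8 x max achievable log-odds (",
              signif(motifs[[k]]$detection_threshold, 4), ")")
    } else {
      motifs[[k]] <- new_pwm(name, probs, detection_threshold = threshold,
                             consensus = consensus)
    }
  }
  motif_database(motifs, source = path)
}

#' Write a motif database in HOMER format
#'
#' @param db A [motif_database()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homer_motifs <- function(db, path) {
  stopifnot(inherits(db, "MotifDatabase"))
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in db$motifs) {
    writeLines(sprintf(">%s\t%s\t%.12g", pwm$consensus, pwm$name,
                       pwm$detection_threshold), con)
    writeLines(apply(pwm$probs, 1, function(r)
      paste(sprintf("%.12g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Export a motif database in MEME minimal format
#'
#' Writer only, for interoperability with MEME-suite tools.
#'
#' @inheritParams write_homer_motifs
#' @param background Background base frequencies recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(db, path, background = rep(0.25, 4)) {
  stopifnot(inherits(db, "MotifDatabase"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", .base_letters, background),
                     collapse = " "), ""), con)
  for (pwm in db$motifs) {
    writeLines(c(sprintf("MOTIF %s", pwm$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         pwm$width)), con)
    writeLines(apply(pwm$probs, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
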