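#' Construct a position weight matrix (PWM) object
#'
#' A PWM is a width x 4 matrix of base probabilities (columns A, C, G, T) with
#' a name and a log-odds detection threshold. Rows must sum to 1 within 1e-3;
#' they are renormalised exactly on construction.
#'
#' @param name Motif identifier.
#' @param probs Numeric matrix, width x 4, base probabilities in A,C,G,T order.
#' @param detection_threshold Log-odds cut-off for calling a hit. If `NULL`,
#'   defaults to 0.8 x the maximum achievable log-odds score under the default
#'   background and pseudocount (a common convention when no calibrated
#'   threshold is available).
#' @param consensus Optional consensus string; derived from `probs` if missing.
#' @return An object of class `PWM` with fields `name`, `consensus`, `probs`,
#'   `detection_threshold`, `width`.
#' @examples
#' p <- new_pwm("TEST", matrix(c(0.97, 0.01, 0.01, 0.01,
#'                               0.01, 0.97, 0.01, 0.01), 2, 4, byrow = TRUE))
#' p$consensus
#' @export
new_pwm <- function(name, probs, detection_threshold = NULL, consensus = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM 'probs' must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 1L) stop("PWM must have width >= 1")
  if (any(probs < 0)) stop("PWM probabilities must be nonnegative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-3))
    stop("PWM '", name, "': row sums outside [0.999, 1.001]: ",
         paste(signif(rs[abs(rs - 1) > 1e-3], 4), collapse = ", "))
  probs <- probs / rs
  colnames(probs) <- .base_letters
  rownames(probs) <- NULL
  if (is.null(consensus))
    consensus <- paste(.base_letters[max.col(probs, ties.method = "first")],
                       collapse = "")
  pwm <- structure(
    list(name = name, consensus = consensus, probs = probs,
         detection_threshold = NA_real_, width = nrow(probs)),
    class = "PWM")
  if (is.null(detection_threshold))
    detection_threshold <- 0.8 * pwm_max_score(pwm)
  pwm$detection_threshold <- detection_threshold
  pwm
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s  width=%d  consensus=%s  threshold=%.3f\n",
              x$name, x$width, x$consensus, x$detection_threshold))
  invisible(x)
}

#' Log-odds scoring matrix of a PWM
#'
#' Entry `[i, b]` is `log(((probs[i,b] + pseudocount) / (1 + 4 * pseudocount))
#' / background[b])` (natural log). The pseudocount regularises zero
#' probabilities; with `pseudocount = 0` any zero probability is an error
#' because it would produce a -Inf score.
#'
#' @param pwm A [new_pwm()] object.
#' @param background Base frequencies (A,C,G,T), positive, summing to 1.
#' @param pseudocount Nonnegative probability added to every entry.
#' @return width x 4 numeric matrix of log-odds scores.
#' @export
logodds_matrix <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-3) {
  stopifnot(inherits(pwm, "PWM"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 positive frequencies summing to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(pwm$probs == 0))
    stop("PWM '", pwm$name,
         "' has zero probabilities; a positive pseudocount is required")
  p <- (pwm$probs + pseudocount) / (1 + 4 * pseudocount)
  log(sweep(p, 2, background, "/"))
}

#' Maximum achievable log-odds score of a PWM
#'
#' Sum over positions of the best per-base log-odds entry.
#'
#' @inheritParams logodds_matrix
#' @return Scalar score.
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-3) {
  sum(apply(logodds_matrix(pwm, background, pseudocount), 1, max))
}

#' Reverse complement of a PWM
#'
#' @param pwm A [new_pwm()] object.
#' @return A `PWM` representing binding to the opposite strand.
#' @export
pwm_reverse_complement <- function(pwm) {
  stopifnot(inherits(pwm, "PWM"))
  rc <- pwm$probs[rev(seq_len(pwm$width)), 4:1, drop = FALSE]
  colnames(rc) <- .base_letters
  new_pwm(pwm$name, rc, detection_threshold = pwm$detection_threshold)
}

#' Assemble a motif database
#'
#' @param motifs List of [new_pwm()] objects. Duplicate names are given
#'   numeric suffixes (`_2`, `_3`, ...) so feature names are unique columns.
#' @param source Free-text description of provenance.
#' @return Object of class `MotifDatabase` (fields `motifs`, `source`).
#' @export
motif_database <- function(motifs, source = "unspecified") {
  stopifnot(length(motifs) >= 1L,
            all(vapply(motifs, inherits, logical(1), "PWM")))
  nms <- vapply(motifs, `[[`, character(1), "name")
  for (i in seq_along(nms)) {
    if (i > 1L && nms[i] %in% nms[seq_len(i - 1L)]) {
      k <- 2L
      while (paste0(nms[i], "_", k) %in% nms[seq_len(i - 1L)]) k <- k + 1L
      nms[i] <- paste0(nms[i], "_", k)
      motifs[[i]]$name <- nms[i]
    }
  }
  names(motifs) <- nms
  structure(list(motifs = motifs, source = source), class = "MotifDatabase")
}

#' @export
length.MotifDatabase <- function(x) length(x$motifs)

#' @export
names.MotifDatabase <- function(x) names(x$motifs)

#' @export
print.MotifDatabase <- function(x, ...) {
  cat(sprintf("MotifDatabase: %d motifs (%s)\n", length(x), x$source))
  invisible(x)
}
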