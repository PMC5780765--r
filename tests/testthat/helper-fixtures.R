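# Shared fixtures, all built in code.

# near-deterministic PWM matching one word (e.g. "ACGT"); probability mass
# `p` on the word's base at each position
word_pwm <- function(word, name = word, p = 0.97, threshold = NULL) {
  bases <- strsplit(word, "")[[1]]
  probs <- t(vapply(bases, function(b) {
    v <- rep((1 - p) / 3, 4)
    v[match(b, c("A", "C", "G", "T"))] <- p
    v
  }, numeric(4)))
  new_pwm(name, probs, detection_threshold = threshold)
}

uniform_pwm <- function(width = 4, name = "UNIF") {
  new_pwm(name, matrix(0.25, width, 4))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent naive scanner: scores every offset on both strands by direct
# per-base summation over the log-odds matrix (no shared code with the C
# scanner beyond logodds_matrix)
naive_count <- function(pwm, sequence, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  lod <- logodds_matrix(pwm, background, pseudocount)
  w <- nrow(lod)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < w) return(0L)
  code <- match(chars, c("A", "C", "G", "T")) # NA for N etc.
  score_fwd <- function(off) {
    b <- code[off:(off + w - 1L)]
    if (anyNA(b)) return(-Inf)
    sum(lod[cbind(seq_len(w), b)])
  }
  comp <- c(4L, 3L, 2L, 1L)
  score_rev <- function(off) {
    b <- code[off:(off + w - 1L)]
    if (anyNA(b)) return(-Inf)
    rc <- rev(comp[b]) # reverse complement of the window
    sum(lod[cbind(seq_len(w), rc)])
  }
  hits <- 0L
  for (off in seq_len(n - w + 1L)) {
    if (score_fwd(off) >= pwm$detection_threshold) hits <- hits + 1L
    if (score_rev(off) >= pwm$detection_threshold) hits <- hits + 1L
  }
  hits
}

# independent brute-force rule measurement: explicit row loop
brute_rule_metrics <- function(rule, counts, labels) {
  sat <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    ok <- TRUE
    for (j in seq_along(rule$motifs)) {
      x <- counts[i, rule$motifs[j]]
      cond <- if (rule$rels[j] == "<=") x <= rule$thrs[j] else x >= rule$thrs[j]
      if (!cond) { ok <- FALSE; break }
    }
    sat[i] <- ok
  }
  if (!any(sat)) return(list(frequency = 0, error = 1, outcome = NA_character_))
  tab <- table(labels[sat])
  outcome <- sort(names(tab)[tab == max(tab)])[1]
  list(frequency = mean(sat),
       error = mean(labels[sat] != outcome),
       outcome = outcome)
}

# O(n^2) pairwise AUROC oracle (ties count 1/2)
pairwise_auroc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small planted dataset shared by forest / evaluation / rules tests:
# 3 classes x n sequences, 12 motifs, classes 1-2 marked by M01/M02 >= 3,
# class 3 by the pair M03 & M04
small_benchmark <- local({
  cache <- NULL
  function(n_per_class = 60, seed = 42) {
    if (!is.null(cache)) return(cache)
    set.seed(seed)
    db <- motif_database(
      lapply(sprintf("M%02d", 1:12), make_random_pwm,
             width = 8, concentration = 20),
      source = "test fixture")
    grammar <- grammar_spec(
      classes = c("alpha", "beta", "gamma"),
      requirements = list(
        alpha = list(list(motif = "M01", min_count = 3)),
        beta = list(list(motif = "M02", min_count = 3)),
        gamma = list(list(motif = "M03", min_count = 1),
                     list(motif = "M04", min_count = 1))),
      window_length = 240, background_rate = 0.2)
    ds <- generate_dataset(grammar, db, n_per_class = n_per_class, seed = seed)
    X <- build_count_matrix(ds$sequences, db)
    cache <<- list(db = db, grammar = grammar, ds = ds, X = X)
    cache
  }
})
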