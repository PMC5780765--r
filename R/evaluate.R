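#' One-vs-rest AUROC from vote fractions
#'
#' Computed as the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`; tied scores contribute 1/2. Equivalent to the probability
#' that a random positive sample receives a higher score than a random
#' negative one.
#'
#' @param scores Numeric scores (e.g. the fraction of trees voting for the
#'   class).
#' @param truth Logical (or 0/1) vector: `TRUE` for the class of interest.
#' @return AUROC in \[0, 1\].
#' @export
one_vs_rest_auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores) # average ranks handle ties as 1/2
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-class one-vs-rest F1 scores
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, with F1 = 0 when
#' `precision + recall == 0` (in particular for classes never predicted).
#'
#' @param predictions Hard predicted labels.
#' @param truth True labels.
#' @param classes Classes to report (default: classes present in `truth`).
#' @return Named numeric vector of F1 values.
#' @export
per_class_f1 <- function(predictions, truth, classes = sort(unique(truth))) {
  vapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so per-fold class proportions deviate from global by <= 1
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("class '", cl, "' has ", length(idx), " samples < ", folds, " folds")
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of the two-round forest
#'
#' Per repeat: a stratified fold assignment; for each fold the full two-round
#' training (round-1 feature elimination and mtry tuning) is re-run on the
#' other folds — so importance-based feature selection never leaks across the
#' held-out fold — and vote fractions for the held-out samples are collected.
#' Held-out votes are pooled within each repeat, and per-class AUROC, per-class
#' F1 and the multiclass error are computed on the pooled predictions.
#'
#' @param X A [motif_count_matrix()].
#' @param repeats,folds CV design (default 10 x 10-fold).
#' @param seed Integer master seed; repeat `r` derives its seeds from
#'   `seed + r`.
#' @param n_trees Trees per forest.
#' @return Object of class `CVResult`: list with `auroc` and `f1`
#'   (repeats x classes matrices), `error` (per-repeat multiclass error),
#'   `folds` (per-repeat assignment vectors), `classes`, `seeds`.
#' @export
cross_validate <- function(X, repeats = 10, folds = 10, seed = 1,
                           n_trees = 500) {
  stopifnot(inherits(X, "MotifCountMatrix"))
  classes <- sort(unique(X$labels))
  n <- nrow(X$counts)
  auroc <- matrix(NA_real_, repeats, length(classes),
                  dimnames = list(NULL, classes))
  f1 <- auroc
  err <- numeric(repeats)
  fold_list <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rep_seed <- seed + r
    assign <- stratified_folds(X$labels, folds, rep_seed)
    fold_list[[r]] <- assign
    votes <- matrix(NA_real_, n, length(classes),
                    dimnames = list(X$sample_ids, classes))
    for (k in seq_len(folds)) {
      test <- which(assign == k)
      fit <- two_round_train(subset_counts(X, samples = -test),
                             seed = rep_seed * 1000L + k,
                             n_trees = n_trees, final_importance = FALSE)
      v <- class_vote_scores(fit$model, subset_counts(X, samples = test))
      votes[test, colnames(v)] <- v
    }
    votes[is.na(votes)] <- 0 # classes absent from a training split get 0 votes
    pred <- classes[max.col(votes, ties.method = "first")]
    for (cl in classes)
      auroc[r, cl] <- one_vs_rest_auroc(votes[, cl], X$labels == cl)
    f1[r, ] <- per_class_f1(pred, X$labels, classes)
    err[r] <- mean(pred != X$labels)
  }
  structure(list(auroc = auroc, f1 = f1, error = err, folds = fold_list,
                 classes = classes, seeds = seed + seq_len(repeats)),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %d repeats, classes: %s\n", nrow(x$auroc),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("mean AUROC %.3f, mean F1 %.3f, mean error %.3f\n",
              mean(x$auroc), mean(x$f1), mean(x$error)))
  invisible(x)
}

#' Summarise a CVResult per class
#'
#' @param cv A [cross_validate()] result.
#' @return `data.frame` with per-class mean and sd of AUROC and F1 across
#'   repeats.
#' @export
cv_summary <- function(cv) {
  stopifnot(inherits(cv, "CVResult"))
  data.frame(class = cv$classes,
             mean_auroc = colMeans(cv$auroc),
             sd_auroc = apply(cv$auroc, 2, sd),
             mean_f1 = colMeans(cv$f1),
             sd_f1 = apply(cv$f1, 2, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a CVResult as tidy TSV plus a JSON summary
#'
#' @param cv A [cross_validate()] result.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @param header_comment Optional `#`-prefixed first line for the TSV and a
#'   `meta.note` field in the JSON.
#' @return Invisibly, the tidy `data.frame`.
#' @export
write_cv_result <- function(cv, tsv_path = NULL, json_path = NULL,
                            header_comment = NULL) {
  stopifnot(inherits(cv, "CVResult"))
  reps <- nrow(cv$auroc)
  tidy <- rbind(
    data.frame(repeat_ = rep(seq_len(reps), length(cv$classes)),
               class = rep(cv$classes, each = reps),
               metric = "auroc", value = as.vector(cv$auroc)),
    data.frame(repeat_ = rep(seq_len(reps), length(cv$classes)),
               class = rep(cv$classes, each = reps),
               metric = "f1", value = as.vector(cv$f1)),
    data.frame(repeat_ = seq_len(reps), class = "all",
               metric = "multiclass_error", value = cv$error))
  names(tidy)[1] <- "repeat"
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
    write.table(tidy, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    summ <- cv_summary(cv)
    jsonlite::write_json(
      list(meta = list(tool = "motifgrammar",
                       version = as.character(packageVersion("motifgrammar")),
                       note = header_comment),
           per_class = summ,
           mean_multiclass_error = mean(cv$error)),
      json_path, dataframe = "columns", auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(tidy)
}

#' Sweep the window half-width and recommend a flank
#'
#' For each flank the windows are rebuilt around the peak centres, sequences
#' re-extracted, re-scanned, and cross-validated; the recommended flank is the
#' one with the highest mean per-class F1 (ties go to the smaller flank).
#'
#' @param peaks Peak `data.frame` (already top-N selected).
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param db A [motif_database()].
#' @param flank_grid Nonempty vector of half-widths in bp.
#' @param repeats,folds,seed,n_trees CV configuration per flank.
#' @inheritParams score_at
#' @return List with `table` (`data.frame`: flank, mean_f1, sd_f1, mean_auroc,
#'   n_windows) and `recommended_flank`.
#' @export
window_size_sweep <- function(peaks, genome, db, flank_grid,
                              repeats = 10, folds = 10, seed = 1,
                              n_trees = 500, background = rep(0.25, 4),
                              pseudocount = 1e-3) {
  stopifnot(length(flank_grid) >= 1)
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("[ \t].*$", "", names(genome))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  rows <- lapply(flank_grid, function(flank) {
    w <- make_windows(peaks, flank, contig_lengths = lens)
    seqs <- fetch_sequences(w, genome)
    X <- build_count_matrix(seqs, db, background, pseudocount)
    cv <- cross_validate(X, repeats = repeats, folds = folds, seed = seed,
                         n_trees = n_trees)
    data.frame(flank = flank, mean_f1 = mean(cv$f1), sd_f1 = sd(cv$f1),
               mean_auroc = mean(cv$auroc), n_windows = nrow(w))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$flank), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$flank[which(tab$mean_f1 == max(tab$mean_f1))[1]]
  list(table = tab, recommended_flank = best)
}
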