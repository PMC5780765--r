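#' Train the multi-class random forest on motif counts
#'
#' Bagged classification trees with random feature subsets per split (gini
#' impurity, minimum node size 1, i.e. grown to purity), majority-vote
#' aggregation. The forest engine is \pkg{ranger}, run single-threaded with an
#' explicit seed so results are fully deterministic; per-tree in-bag counts
#' are kept so out-of-bag (OOB) bookkeeping and rule mining can interrogate
#' individual trees.
#'
#' @param X A [motif_count_matrix()].
#' @param n_trees Number of trees (default 500, which is sufficient to
#'   stabilise the OOB error at the problem sizes this package targets).
#' @param features_per_split `"auto"` (floor of sqrt(#features)) or an integer
#'   (`mtry`).
#' @param seed Integer seed; identical seed and input give an identical
#'   forest.
#' @param compute_importance If `TRUE`, per-tree OOB permutation importance
#'   (unscaled mean decrease in accuracy) is computed alongside training.
#' @return Object of class `ForestModel` with fields `engine` (the ranger
#'   fit, including `inbag.counts` per tree), `feature_names`, `class_names`,
#'   `labels`, `n_trees`, `features_per_split`, `seed`, `raw_importance`.
#' @export
train_forest <- function(X, n_trees = 500, features_per_split = "auto",
                         seed = 1, compute_importance = TRUE) {
  stopifnot(inherits(X, "MotifCountMatrix"))
  y <- factor(X$labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes to train a classifier")
  if (any(table(y) < 2L)) stop("every class needs >= 2 samples")
  p <- ncol(X$counts)
  mtry <- if (identical(features_per_split, "auto")) {
    max(1L, floor(sqrt(p)))
  } else {
    m <- as.integer(features_per_split)
    if (is.na(m) || m < 1L || m > p) stop("features_per_split must be in [1, ", p, "]")
    m
  }
  fit <- ranger::ranger(
    x = X$counts, y = y,
    num.trees = n_trees, mtry = mtry,
    min.node.size = 1, splitrule = "gini",
    importance = if (compute_importance) "permutation" else "none",
    scale.permutation.importance = FALSE,
    keep.inbag = TRUE, num.threads = 1, seed = seed)
  structure(
    list(engine = fit,
         feature_names = colnames(X$counts),
         class_names = levels(y),
         labels = as.character(y),
         n_trees = n_trees,
         features_per_split = mtry,
         seed = seed,
         raw_importance = if (compute_importance) fit$variable.importance else NULL),
    class = "ForestModel")
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees, mtry=%d, %d features, classes: %s\n",
              x$n_trees, x$features_per_split, length(x$feature_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Out-of-bag error of a trained forest
#'
#' Each training sample is predicted by majority vote of only the trees for
#' which it was out of bag; the error is the misclassified fraction among
#' samples with at least one OOB tree.
#'
#' @param model A [train_forest()] model.
#' @return Error rate in \[0, 1\].
#' @export
oob_error <- function(model) {
  stopifnot(inherits(model, "ForestModel"))
  pred <- as.character(model$engine$predictions)
  mean(pred != model$labels, na.rm = TRUE)
}

#' Scaled permutation importance (mean decrease accuracy)
#'
#' Raw MDA of a motif is the mean over trees of the drop in that tree's OOB
#' accuracy after permuting the motif's values among the tree's OOB samples.
#' The scaled MDA divides each raw value by the standard deviation of the raw
#' MDA values across all motifs, so the scaled values have unit variance; this
#' is the scaling used for reporting (e.g. a shortlist at scaled MDA > 6), not
#' the per-variable standard-error scaling some forest implementations apply.
#'
#' The raw values are computed during training (under the training seed); a
#' model trained with `compute_importance = FALSE` is retrained
#' deterministically from its stored seed and parameters.
#'
#' @param model A [train_forest()] model.
#' @param X The training [motif_count_matrix()] (only needed to retrain when
#'   importance was not computed at training time).
#' @return `data.frame` with columns `motif`, `raw_mda`, `scaled_mda`, sorted
#'   by `scaled_mda` descending.
#' @export
permutation_importance <- function(model, X = NULL) {
  stopifnot(inherits(model, "ForestModel"))
  raw <- model$raw_importance
  if (is.null(raw)) {
    if (is.null(X)) stop("model was trained without importance; supply X to retrain")
    model <- train_forest(X, n_trees = model$n_trees,
                          features_per_split = model$features_per_split,
                          seed = model$seed, compute_importance = TRUE)
    raw <- model$raw_importance
  }
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    warning("sd of raw MDA values is 0; scaled MDA undefined, reporting 0")
    scaled <- rep(0, length(raw))
  } else {
    scaled <- raw / s
  }
  out <- data.frame(motif = names(raw), raw_mda = unname(raw),
                    scaled_mda = unname(scaled), stringsAsFactors = FALSE)
  out <- out[order(-out$scaled_mda, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-round forest training with feature elimination and mtry tuning
#'
#' Round 1 trains with `features_per_split = "auto"` and computes permutation
#' importance; every motif with negative raw MDA is removed. Round 2 tunes the
#' number of features per split on the reduced matrix over the grid
#' \{floor(m/2), m, 2m\} (m = floor of sqrt of the remaining feature count,
#' clamped to \[1, p\]), picking the value with the smallest OOB error (ties
#' go to the smaller, simpler value), and returns the winning forest.
#'
#' @param X A [motif_count_matrix()].
#' @param seed Integer seed governing both rounds.
#' @param n_trees Trees per forest.
#' @param final_importance Compute permutation importance for the tuned final
#'   model (set `FALSE` inside cross-validation folds where only predictions
#'   are needed).
#' @return List with `model` (final `ForestModel`), `importance` (round-1
#'   table used for elimination), `final_importance` (tuned-model table or
#'   `NULL`), `kept_motifs`, `round1_oob`, `final_oob`, `grid` (mtry values
#'   tried and their OOB errors).
#' @export
two_round_train <- function(X, seed = 1, n_trees = 500,
                            final_importance = TRUE) {
  stopifnot(inherits(X, "MotifCountMatrix"))
  round1 <- train_forest(X, n_trees = n_trees, features_per_split = "auto",
                         seed = seed, compute_importance = TRUE)
  imp1 <- permutation_importance(round1)
  keep <- imp1$motif[imp1$raw_mda >= 0]
  if (length(keep) == 0L)
    stop("all features have negative round-1 MDA; review importance threshold")
  if (length(keep) == 1L)
    warning("only one feature survives round-1 elimination")
  keep <- model_feature_order(X, keep)
  X2 <- subset_counts(X, motifs = keep)
  p2 <- ncol(X2$counts)
  m <- max(1L, floor(sqrt(p2)))
  grid <- sort(unique(pmin(p2, pmax(1L, c(m %/% 2L, m, 2L * m)))))
  fits <- lapply(seq_along(grid), function(i)
    train_forest(X2, n_trees = n_trees, features_per_split = grid[i],
                 seed = seed + i, compute_importance = FALSE))
  errs <- vapply(fits, oob_error, numeric(1))
  best <- which(errs == min(errs))[1] # grid sorted ascending: tie -> smaller mtry
  final <- fits[[best]]
  fin_imp <- NULL
  if (final_importance) {
    final <- train_forest(X2, n_trees = n_trees, features_per_split = grid[best],
                          seed = seed + best, compute_importance = TRUE)
    fin_imp <- permutation_importance(final)
  }
  list(model = final, importance = imp1, final_importance = fin_imp,
       kept_motifs = keep, round1_oob = oob_error(round1),
       final_oob = oob_error(final),
       grid = data.frame(mtry = grid, oob_error = errs))
}

# preserve the original column order of X for a subset of motif names
model_feature_order <- function(X, motifs) {
  X$motif_names[X$motif_names %in% motifs]
}

#' Per-class vote fractions for new samples
#'
#' The fraction of trees voting for each class; rows sum to 1 and the row
#' argmax is the forest's hard prediction.
#'
#' @param model A [train_forest()] model.
#' @param X_new A [motif_count_matrix()] carrying at least the model's
#'   features (matched by name).
#' @return Numeric matrix, samples x classes.
#' @export
class_vote_scores <- function(model, X_new) {
  stopifnot(inherits(model, "ForestModel"), inherits(X_new, "MotifCountMatrix"))
  missing <- setdiff(model$feature_names, colnames(X_new$counts))
  if (length(missing) > 0L)
    stop("features missing from new data: ", paste(missing, collapse = ", "))
  counts <- X_new$counts[, model$feature_names, drop = FALSE]
  pa <- predict(model$engine, data = counts, predict.all = TRUE,
                num.threads = 1)$predictions
  k <- length(model$class_names)
  votes <- t(apply(pa, 1, tabulate, nbins = k)) / ncol(pa)
  dimnames(votes) <- list(rownames(counts), model$class_names)
  votes
}

#' Hard class predictions from vote fractions
#'
#' @inheritParams class_vote_scores
#' @return Character vector of predicted classes (row argmax of the vote
#'   matrix; ties broken by class order).
#' @export
predict_class <- function(model, X_new) {
  votes <- class_vote_scores(model, X_new)
  colnames(votes)[max.col(votes, ties.method = "first")]
}

#' Serialise a forest to a portable JSON structure
#'
#' Captures per-tree split structure (feature, threshold, children, leaf
#' prediction), feature names, class names and seed — sufficient to re-walk
#' every root-to-leaf path.
#'
#' @param model A [train_forest()] model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(model, path) {
  stopifnot(inherits(model, "ForestModel"))
  trees <- lapply(seq_len(model$n_trees), function(t)
    ranger::treeInfo(model$engine, t))
  obj <- list(tool = "motifgrammar",
              version = as.character(packageVersion("motifgrammar")),
              n_trees = model$n_trees,
              features_per_split = model$features_per_split,
              seed = model$seed,
              feature_names = model$feature_names,
              class_names = model$class_names,
              trees = trees)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write an importance table as TSV
#'
#' Sorted by scaled MDA descending.
#'
#' @param importance Table from [permutation_importance()].
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_importance_tsv <- function(importance, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(importance, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
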