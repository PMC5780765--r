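# Rule representation: a rule is a list with
#   motifs: character vector (one entry per condition, in path order)
#   rels:   "<=" or ">=" per condition (integerized bounds on motif counts)
#   thrs:   nonnegative integer thresholds
#   outcome, frequency, error, length: filled by rule_metrics()
# Conditions are conjunctive; within a rule a motif carries at most one
# lower and one upper bound (tighter bounds win when a path revisits a motif).

#' Integerize a split condition on a count feature
#'
#' Decision-tree splits on integer counts are real-valued (`x <= t` left,
#' `x > t` right); on count data they are equivalent to the integer bounds
#' `x <= floor(t)` and `x >= floor(t) + 1`.
#'
#' @param relation `"<="` for a left branch, `">"` for a right branch.
#' @param threshold Real split threshold.
#' @return List with `rel` (`"<="` or `">="`) and `thr` (integer).
#' @export
integerize_condition <- function(relation, threshold) {
  if (relation == "<=") {
    list(rel = "<=", thr = max(0L, as.integer(floor(threshold))))
  } else if (relation == ">") {
    list(rel = ">=", thr = max(0L, as.integer(floor(threshold)) + 1L))
  } else stop("relation must be '<=' or '>'")
}

# canonical signature for deduplication (alphabetical by motif, then rel/thr)
rule_signature <- function(rule) {
  o <- order(rule$motifs, rule$rels, rule$thrs)
  paste(rule$motifs[o], rule$rels[o], rule$thrs[o], sep = "", collapse = "&")
}

# merge multiple bounds on one motif to the tightest interval; an infeasible
# interval (lower > upper) marks the rule unsatisfiable (frequency 0 later)
merge_rule_bounds <- function(rule) {
  key <- paste(rule$motifs, rule$rels)
  if (!anyDuplicated(key)) return(rule)
  keep <- logical(length(key))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    best <- if (rule$rels[idx[1]] == "<=") idx[which.min(rule$thrs[idx])]
            else idx[which.max(rule$thrs[idx])]
    keep[best] <- TRUE
  }
  list(motifs = rule$motifs[keep], rels = rule$rels[keep],
       thrs = rule$thrs[keep])
}

# enumerate root-to-leaf paths of one ranger treeInfo() frame, truncating at
# max_len conditions; returns list of raw rules. treeInfo rows are ordered by
# nodeID starting at 0, so row index = nodeID + 1.
extract_paths <- function(ti, max_len = 6L) {
  left <- ti$leftChild
  right <- ti$rightChild
  var <- as.character(ti$splitvarName)
  val <- ti$splitval
  terminal <- ti$terminal
  out <- list()
  walk <- function(node, motifs, rels, thrs) {
    i <- node + 1L
    if (terminal[i] || length(motifs) >= max_len) {
      if (length(motifs) >= 1L)
        out[[length(out) + 1L]] <<- merge_rule_bounds(
          list(motifs = motifs, rels = rels, thrs = thrs))
      return(invisible())
    }
    lc <- integerize_condition("<=", val[i])
    rc <- integerize_condition(">", val[i])
    walk(left[i], c(motifs, var[i]), c(rels, lc$rel), c(thrs, lc$thr))
    walk(right[i], c(motifs, var[i]), c(rels, rc$rel), c(thrs, rc$thr))
  }
  walk(0L, character(0), character(0), integer(0))
  out
}

#' Extract candidate rules from a trained forest
#'
#' One candidate per leaf per tree: the conjunction of the integerized split
#' tests along the root-to-leaf path, truncated at `max_len` conditions (deep
#' paths beyond the cap are emitted as their first `max_len` conditions).
#' Identical condition sets are deduplicated across the forest. Outcomes are
#' not taken from the leaves; they are re-derived from covered training
#' samples by [rule_metrics()].
#'
#' @param model A [train_forest()] model.
#' @param max_len Maximum number of conditions per rule (complexity cap).
#' @return List of raw rules (fields `motifs`, `rels`, `thrs`).
#' @export
extract_rules <- function(model, max_len = 6L) {
  stopifnot(inherits(model, "ForestModel"))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rules <- list()
  for (t in seq_len(model$n_trees)) {
    ti <- ranger::treeInfo(model$engine, t)
    for (rule in extract_paths(ti, max_len)) {
      sig <- rule_signature(rule)
      if (is.null(seen[[sig]])) {
        seen[[sig]] <- TRUE
        rules[[length(rules) + 1L]] <- rule
      }
    }
  }
  rules
}

# logical cover vector of a rule over the count matrix
rule_cover <- function(rule, counts) {
  sat <- rep(TRUE, nrow(counts))
  for (i in seq_along(rule$motifs)) {
    x <- counts[, rule$motifs[i]]
    sat <- sat & if (rule$rels[i] == "<=") x <= rule$thrs[i] else x >= rule$thrs[i]
  }
  sat
}

#' Measure a rule on training data
#'
#' `frequency` is the fraction of samples satisfying all conditions; the
#' `outcome` is the majority class among satisfying samples (ties broken
#' alphabetically); `error` is the fraction of satisfying samples not of the
#' outcome class. A rule satisfied by no sample gets frequency 0, error 1 and
#' an `NA` outcome.
#'
#' @param rule A raw rule from [extract_rules()].
#' @param X A [motif_count_matrix()].
#' @return The rule with `outcome`, `frequency`, `error`, `length` filled in.
#' @export
rule_metrics <- function(rule, X) {
  stopifnot(inherits(X, "MotifCountMatrix"))
  sat <- rule_cover(rule, X$counts)
  n_sat <- sum(sat)
  rule$length <- length(rule$motifs)
  if (n_sat == 0L) {
    rule$frequency <- 0
    rule$error <- 1
    rule$outcome <- NA_character_
    return(rule)
  }
  tab <- table(X$labels[sat])
  outcome <- sort(names(tab)[tab == max(tab)])[1]
  rule$frequency <- n_sat / nrow(X$counts)
  rule$error <- (n_sat - as.integer(max(tab))) / n_sat # exact integer fraction
  rule$outcome <- outcome
  rule
}

#' Prune redundant conditions from a rule
#'
#' Conditions are visited last-to-first (deepest split first). For each, the
#' rule's error without that condition is computed (with the outcome
#' re-derived from the newly covered samples); if the relative error decay
#' `(E_without - E) / max(E, 1e-6)` is at most `max_decay` the condition is
#' permanently removed. A rule is never pruned below one condition.
#'
#' @param rule A rule with metrics (see [rule_metrics()]).
#' @param X A [motif_count_matrix()].
#' @param max_decay Maximum tolerated relative error increase (default 0.05).
#' @return The pruned rule with refreshed metrics.
#' @export
prune_rule <- function(rule, X, max_decay = 0.05) {
  if (is.null(rule$error)) rule <- rule_metrics(rule, X)
  E <- rule$error
  i <- length(rule$motifs)
  while (i >= 1L && length(rule$motifs) > 1L) {
    cand <- list(motifs = rule$motifs[-i], rels = rule$rels[-i],
                 thrs = rule$thrs[-i])
    cand <- rule_metrics(cand, X)
    decay <- (cand$error - E) / max(E, 1e-6)
    if (decay <= max_decay) {
      rule <- cand
      E <- cand$error
    }
    i <- i - 1L
  }
  rule_metrics(list(motifs = rule$motifs, rels = rule$rels, thrs = rule$thrs), X)
}

#' Select a compact, non-redundant rule set
#'
#' Deterministic greedy rule-list construction. Candidates are sorted by
#' (error ascending, length ascending, frequency descending, condition string
#' ascending) and repeatedly scanned; a candidate is appended to the ordered
#' rule list iff it strictly reduces the training misclassification of the
#' rule-list classifier (first matching rule wins; samples matching no rule
#' get the global majority class). Scanning stops after a full pass with no
#' addition. Duplicate condition sets are never co-selected.
#'
#' @param rules List of rules with metrics.
#' @param X A [motif_count_matrix()].
#' @return Object of class `RuleSet`: list with `rules` (selected, in list
#'   order), `classes`, `default_class`.
#' @export
select_rules <- function(rules, X) {
  stopifnot(inherits(X, "MotifCountMatrix"))
  classes <- sort(unique(X$labels))
  tab <- table(X$labels)
  default_class <- sort(names(tab)[tab == max(tab)])[1]
  rules <- Filter(function(r) !is.na(r$outcome), rules)
  if (length(rules) == 0L)
    return(structure(list(rules = list(), classes = classes,
                          default_class = default_class), class = "RuleSet"))
  sig <- vapply(rules, rule_signature, character(1))
  o <- order(vapply(rules, `[[`, numeric(1), "error"),
             vapply(rules, `[[`, numeric(1), "length"),
             -vapply(rules, `[[`, numeric(1), "frequency"),
             sig)
  rules <- rules[o]
  sig <- sig[o]
  covers <- lapply(rules, rule_cover, counts = X$counts)
  matched <- rep(FALSE, nrow(X$counts))
  correct_default <- X$labels == default_class
  selected <- list()
  selected_sig <- character(0)
  repeat {
    added <- FALSE
    for (i in seq_along(rules)) {
      if (sig[i] %in% selected_sig) next
      newly <- covers[[i]] & !matched
      if (!any(newly)) next
      gain <- sum(X$labels[newly] == rules[[i]]$outcome) -
        sum(correct_default[newly])
      if (gain > 0L) {
        selected[[length(selected) + 1L]] <- rules[[i]]
        selected_sig <- c(selected_sig, sig[i])
        matched <- matched | newly
        added <- TRUE
      }
    }
    if (!added) break
  }
  structure(list(rules = selected, classes = classes,
                 default_class = default_class), class = "RuleSet")
}

#' Filter rules by frequency and error
#'
#' Keeps exactly the rules with `frequency >= min_frequency` and
#' `error <= max_error` (both boundaries inclusive, i.e. "below 8%" and
#' "above 0.7" are read strictly). Classes may end up with no rule.
#'
#' @param ruleset A [select_rules()] result.
#' @param min_frequency Minimum training-cover fraction (default 0.08).
#' @param max_error Maximum misclassification among covered samples
#'   (default 0.7).
#' @return A filtered `RuleSet`.
#' @export
filter_rules <- function(ruleset, min_frequency = 0.08, max_error = 0.7) {
  stopifnot(inherits(ruleset, "RuleSet"))
  ruleset$rules <- Filter(function(r)
    r$frequency >= min_frequency && r$error <= max_error, ruleset$rules)
  ruleset
}

# display form of one rule's conditions: motifs alphabetical, "<= 0" as "= 0"
format_conditions <- function(rule) {
  o <- order(rule$motifs, rule$rels, rule$thrs)
  paste(mapply(function(m, r, t) {
    if (r == "<=" && t == 0L) paste0(m, "=0") else paste0(m, r, t)
  }, rule$motifs[o], rule$rels[o], rule$thrs[o]), collapse = " & ")
}

#' Render a rule set as a text table
#'
#' One line per rule, `conditions -> class`, grouped by predicted class;
#' classes without a surviving rule report "No rule identified".
#'
#' @param ruleset A `RuleSet`.
#' @return Character vector of lines.
#' @export
render_rules <- function(ruleset) {
  stopifnot(inherits(ruleset, "RuleSet"))
  lines <- character(0)
  for (cl in ruleset$classes) {
    cl_rules <- Filter(function(r) identical(r$outcome, cl), ruleset$rules)
    if (length(cl_rules) == 0L) {
      lines <- c(lines, paste0("No rule identified -> ", cl))
    } else {
      lines <- c(lines, vapply(cl_rules, function(r)
        paste0(format_conditions(r), " -> ", cl), character(1)))
    }
  }
  lines
}

#' Rule set as a data frame (Tables-style TSV form)
#'
#' @param ruleset A `RuleSet`.
#' @return `data.frame` with columns `rule`, `prediction`, `frequency`,
#'   `error`, `length`.
#' @export
ruleset_table <- function(ruleset) {
  stopifnot(inherits(ruleset, "RuleSet"))
  if (length(ruleset$rules) == 0L)
    return(data.frame(rule = character(), prediction = character(),
                      frequency = numeric(), error = numeric(),
                      length = integer(), stringsAsFactors = FALSE))
  df <- data.frame(
    rule = vapply(ruleset$rules, format_conditions, character(1)),
    prediction = vapply(ruleset$rules, `[[`, character(1), "outcome"),
    frequency = vapply(ruleset$rules, `[[`, numeric(1), "frequency"),
    error = vapply(ruleset$rules, `[[`, numeric(1), "error"),
    length = vapply(ruleset$rules, function(r) length(r$motifs), integer(1)),
    stringsAsFactors = FALSE)
  df[order(df$prediction, df$error, -df$frequency), , drop = FALSE]
}

#' Write a rule set as TSV and/or structured JSON
#'
#' @param ruleset A `RuleSet`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @param header_comment Optional `#`-prefixed first TSV line / JSON meta note.
#' @return Invisibly, the [ruleset_table()].
#' @export
write_rules <- function(ruleset, tsv_path = NULL, json_path = NULL,
                        header_comment = NULL) {
  tab <- ruleset_table(ruleset)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(meta = list(tool = "motifgrammar",
                       version = as.character(packageVersion("motifgrammar")),
                       note = header_comment),
           classes = ruleset$classes,
           default_class = ruleset$default_class,
           rules = lapply(ruleset$rules, function(r)
             list(conditions = data.frame(motif = r$motifs, relation = r$rels,
                                          threshold = r$thrs),
                  prediction = r$outcome, frequency = r$frequency,
                  error = r$error))),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(tab)
}

#' Full grammar-mining pipeline on a trained forest
#'
#' Extract candidate rules, measure them, prune redundant conditions,
#' deduplicate, select a non-redundant rule list, and filter by frequency and
#' error.
#'
#' @param model A [train_forest()] model.
#' @param X The training [motif_count_matrix()].
#' @param max_len Condition cap per rule.
#' @param max_decay Pruning tolerance.
#' @param min_frequency,max_error Final filter thresholds.
#' @return A filtered `RuleSet`.
#' @export
mine_rules <- function(model, X, max_len = 6L, max_decay = 0.05,
                       min_frequency = 0.08, max_error = 0.7) {
  raw <- extract_rules(model, max_len = max_len)
  measured <- lapply(raw, function(r) rule_metrics(r, X))
  pruned <- lapply(measured, function(r) prune_rule(r, X, max_decay))
  sig <- vapply(pruned, rule_signature, character(1))
  pruned <- pruned[!duplicated(sig)]
  selected <- select_rules(pruned, X)
  filter_rules(selected, min_frequency = min_frequency, max_error = max_error)
}

#' @export
print.RuleSet <- function(x, ...) {
  cat("RuleSet (", length(x$rules), " rules, default class ",
      x$default_class, ")\n", sep = "")
  writeLines(render_rules(x))
  invisible(x)
}
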