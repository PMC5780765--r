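test_that("split conditions integerize to count bounds", {
  expect_equal(integerize_condition("<=", 2.5), list(rel = "<=", thr = 2L))
  expect_equal(integerize_condition(">", 2.5), list(rel = ">=", thr = 3L))
  expect_equal(integerize_condition("<=", 0.5), list(rel = "<=", thr = 0L))
  expect_equal(integerize_condition(">", 0.5), list(rel = ">=", thr = 1L))
  expect_error(integerize_condition("<", 1), "relation")
})

test_that("path extraction enumerates leaves, truncates deep paths, merges bounds", {
  # hand-built tree: root splits M1 at 2.5; right child splits M2 at 0.5
  ti <- data.frame(
    nodeID = 0:4,
    leftChild = c(1L, NA, 3L, NA, NA),
    rightChild = c(2L, NA, 4L, NA, NA),
    splitvarName = c("M1", NA, "M2", NA, NA),
    splitval = c(2.5, NA, 0.5, NA, NA),
    terminal = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  rules <- motifgrammar:::extract_paths(ti, max_len = 6L)
  sigs <- sort(vapply(rules, motifgrammar:::rule_signature, character(1)))
  expect_equal(sigs, c("M1<=2", "M1>=3&M2<=0", "M1>=3&M2>=1"))
  # a chain deeper than the cap truncates to max_len conditions
  d <- 8L
  chain <- data.frame(
    nodeID = 0:(2 * d),
    leftChild = c(seq(2, 2 * d, by = 2), rep(NA, d + 1)),
    rightChild = c(seq(1, 2 * d - 1, by = 2), rep(NA, d + 1)),
    splitvarName = c(paste0("V", 1:d), rep(NA, d + 1)),
    splitval = c(seq_len(d) + 0.5, rep(NA, d + 1)),
    terminal = c(rep(FALSE, d), rep(TRUE, d + 1)))
  # reorder rows so children indices refer to nodeIDs, not rows
  chain <- chain[order(chain$nodeID), ]
  deep <- motifgrammar:::extract_paths(chain, max_len = 6L)
  expect_true(all(vapply(deep, function(r) length(r$motifs), integer(1)) <= 6L))
  # repeated bounds on one motif collapse to the tightest interval
  r <- motifgrammar:::merge_rule_bounds(
    list(motifs = c("A", "A", "A"), rels = c("<=", "<=", ">="),
         thrs = c(5L, 3L, 1L)))
  expect_equal(r, list(motifs = c("A", "A"), rels = c("<=", ">="),
                       thrs = c(3L, 1L)))
})

test_that("rule metrics equal brute-force recounts on random instances", {
  set.seed(14)
  classes <- c("r", "s", "t")
  for (i in 1:40) {
    n <- sample(20:80, 1)
    p <- sample(3:8, 1)
    counts <- matrix(rpois(n * p, 2), n, p,
                     dimnames = list(NULL, paste0("M", seq_len(p))))
    labels <- sample(classes, n, replace = TRUE)
    X <- motif_count_matrix(counts, labels)
    for (j in 1:5) {
      len <- sample(1:3, 1)
      rule <- list(motifs = sample(colnames(counts), len),
                   rels = sample(c("<=", ">="), len, replace = TRUE),
                   thrs = sample(0:4, len, replace = TRUE))
      got <- rule_metrics(rule, X)
      want <- brute_rule_metrics(rule, counts, labels)
      expect_identical(got$frequency, want$frequency)
      expect_identical(got$error, want$error)
      expect_identical(got$outcome, want$outcome)
    }
  }
})

test_that("rule metric conventions: full cover, empty cover, infeasible bounds", {
  X <- motif_count_matrix(matrix(2L, 5, 1, dimnames = list(NULL, "M")),
                          rep("only", 5))
  full <- rule_metrics(list(motifs = "M", rels = ">=", thrs = 0L), X)
  expect_equal(full$frequency, 1)
  expect_equal(full$error, 0)
  empty <- rule_metrics(list(motifs = "M", rels = ">=", thrs = 99L), X)
  expect_equal(empty$frequency, 0)
  expect_equal(empty$error, 1)
  expect_true(is.na(empty$outcome))
  infeasible <- rule_metrics(
    list(motifs = c("M", "M"), rels = c(">=", "<="), thrs = c(3L, 1L)), X)
  expect_equal(infeasible$frequency, 0)
})

test_that("pruning removes redundant conditions and never lengthens a rule", {
  set.seed(15)
  counts <- matrix(rpois(200 * 4, 2), 200, 4,
                   dimnames = list(NULL, paste0("M", 1:4)))
  labels <- ifelse(counts[, 1] >= 3, "hi", "lo")
  X <- motif_count_matrix(counts, labels)
  # M4 <= 100 is vacuous: removing it changes nothing (decay 0)
  rule <- rule_metrics(list(motifs = c("M1", "M4"), rels = c(">=", "<="),
                            thrs = c(3L, 100L)), X)
  pruned <- prune_rule(rule, X, max_decay = 0.05)
  expect_equal(pruned$motifs, "M1")
  expect_equal(pruned$error, 0)
  # a single-condition rule is returned unchanged
  single <- rule_metrics(list(motifs = "M1", rels = ">=", thrs = 2L), X)
  expect_equal(prune_rule(single, X)$motifs, "M1")
  # with max_decay = 0 the error never increases; length never grows
  for (i in 1:25) {
    len <- sample(2:4, 1)
    r <- rule_metrics(list(motifs = sample(colnames(counts), len),
                           rels = sample(c("<=", ">="), len, TRUE),
                           thrs = sample(0:4, len, TRUE)), X)
    pr <- prune_rule(r, X, max_decay = 0)
    expect_lte(pr$error, r$error + 1e-12)
    expect_lte(length(pr$motifs), len)
  }
})

test_that("greedy selection picks perfect rules, rejects duplicates and redundancy", {
  set.seed(16)
  n <- 60
  counts <- cbind(MA = rep(c(5L, 0L, 0L), each = n / 3),
                  MB = rep(c(0L, 5L, 0L), each = n / 3),
                  MC = rep(c(0L, 0L, 5L), each = n / 3),
                  MD = rpois(n, 1))
  labels <- rep(c("A", "B", "C"), each = n / 3)
  X <- motif_count_matrix(counts, labels)
  perfect <- lapply(c("MA", "MB", "MC"), function(m)
    rule_metrics(list(motifs = m, rels = ">=", thrs = 3L), X))
  junk <- list(
    rule_metrics(list(motifs = "MD", rels = ">=", thrs = 0L), X), # covers all
    rule_metrics(list(motifs = "MB", rels = ">=", thrs = 3L), X)) # duplicate
  rs <- select_rules(c(perfect, junk), X)
  sigs <- vapply(rs$rules, motifgrammar:::rule_signature, character(1))
  # the default class (A, the alphabetical majority tie-break) needs no rule;
  # the other perfect rules are selected exactly once and nothing redundant
  expect_equal(rs$default_class, "A")
  expect_setequal(sigs, c("MB>=3", "MC>=3"))
  # the resulting rule-list classifier is perfect on training data
  pred <- rep(rs$default_class, n)
  for (r in rev(rs$rules)) pred[counts[, r$motifs] >= r$thrs] <- r$outcome
  expect_equal(pred, labels)
})

test_that("frequency/error filtering is inclusive at the boundaries", {
  mk <- function(freq, err) list(motifs = "M", rels = ">=", thrs = 1L,
                                 outcome = "x", frequency = freq, error = err,
                                 length = 1L)
  rs <- structure(list(rules = list(mk(0.08, 0), mk(0.079, 0), mk(0.5, 0.7),
                                    mk(0.5, 0.71)),
                       classes = "x", default_class = "x"), class = "RuleSet")
  kept <- filter_rules(rs)
  metrics <- vapply(kept$rules, function(r) c(r$frequency, r$error), numeric(2))
  expect_equal(ncol(metrics), 2L)
  expect_true(all(metrics[1, ] >= 0.08))
  expect_true(all(metrics[2, ] <= 0.7))
  expect_equal(length(filter_rules(structure(
    list(rules = list(), classes = "x", default_class = "x"),
    class = "RuleSet"))$rules), 0L)
})

test_that("rendering follows the table layout with '=0' display and no-rule classes", {
  rule <- list(motifs = c("NFE2", "MAF"), rels = c(">=", "<="),
               thrs = c(3L, 0L), outcome = "HCT-116", frequency = 0.2,
               error = 0.1, length = 2L)
  rs <- structure(list(rules = list(rule),
                       classes = c("HCT-116", "PANC-1"),
                       default_class = "PANC-1"), class = "RuleSet")
  lines <- render_rules(rs)
  expect_equal(lines, c("MAF=0 & NFE2>=3 -> HCT-116",
                        "No rule identified -> PANC-1"))
  tab <- ruleset_table(rs)
  expect_equal(tab$rule, "MAF=0 & NFE2>=3")
  expect_equal(tab$prediction, "HCT-116")
  # empty rule set: every class reports no rule
  rs0 <- structure(list(rules = list(), classes = c("a", "b"),
                        default_class = "a"), class = "RuleSet")
  expect_equal(render_rules(rs0),
               c("No rule identified -> a", "No rule identified -> b"))
})

test_that("rule sets serialise to TSV and JSON", {
  rule <- list(motifs = "M1", rels = ">=", thrs = 2L, outcome = "a",
               frequency = 0.4, error = 0.05, length = 1L)
  rs <- structure(list(rules = list(rule), classes = c("a", "b"),
                       default_class = "b"), class = "RuleSet")
  tsv <- withr::local_tempfile(); js <- withr::local_tempfile()
  write_rules(rs, tsv, js, header_comment = "h")
  back <- read.table(tsv, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back$rule, "M1>=2")
  bj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(bj$rules$prediction, "a")
  expect_equal(bj$rules$conditions[[1]]$motif, "M1")
})
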