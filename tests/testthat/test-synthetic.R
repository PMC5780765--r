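test_that("random PWMs are seed-deterministic and self-detect their consensus", {
  set.seed(1); p1 <- make_random_pwm("X", width = 8, concentration = 20)
  set.seed(1); p2 <- make_random_pwm("X", width = 8, concentration = 20)
  expect_identical(p1$probs, p2$probs)
  # the consensus word must always reach the 0.8 x max threshold
  set.seed(2)
  for (i in 1:25) {
    pwm <- make_random_pwm("X", width = sample(6:10, 1), concentration = 20)
    expect_gte(count_occurrences(pwm, pwm$consensus), 1L)
  }
})

test_that("grammar validation catches unknown motifs and short windows", {
  set.seed(3)
  db <- motif_database(lapply(c("A", "B"), make_random_pwm, width = 8))
  g_bad <- grammar_spec(c("x", "y"), requirements = list(
    x = list(list(motif = "NOPE", min_count = 1))))
  expect_error(generate_dataset(g_bad, db, 2, seed = 1), "NOPE")
  g_short <- grammar_spec(c("x", "y"), window_length = 6)
  expect_error(generate_dataset(g_short, db, 2, seed = 1), "width")
  expect_error(grammar_spec(c("x", "y"), requirements = list(
    x = list(list(motif = "A", min_count = 0)))), "min_count")
})

test_that("generated datasets have correct bookkeeping and planted guarantees", {
  b <- small_benchmark()
  ds <- b$ds
  n <- nrow(ds$sequences)
  expect_equal(n, 3 * 60)
  expect_equal(as.integer(table(ds$sequences$cell_type)), rep(60L, 3))
  expect_true(all(nchar(ds$sequences$sequence) == 240L))
  expect_true(all(ds$windows$end - ds$windows$start == 240L))
  # construction validity: re-scanning recovers every planted minimum
  X <- b$X
  expect_true(all(X$counts[X$labels == "alpha", "M01"] >= 3L))
  expect_true(all(X$counts[X$labels == "beta", "M02"] >= 3L))
  expect_true(all(X$counts[X$labels == "gamma", "M03"] >= 1L))
  expect_true(all(X$counts[X$labels == "gamma", "M04"] >= 1L))
})

test_that("exclusion clauses force zero counts for the excluded motif", {
  set.seed(5)
  db <- motif_database(lapply(c("EX", "BG"), make_random_pwm, width = 8,
                              concentration = 20))
  g <- grammar_spec(c("yes", "no"),
                    requirements = list(yes = list(list(motif = "EX",
                                                        min_count = 2))),
                    exclusions = list(no = "EX"),
                    window_length = 120, background_rate = 0.3,
                    plant_halfwidth = 40)
  ds <- generate_dataset(g, db, n_per_class = 25, seed = 6)
  X <- build_count_matrix(ds$sequences, db)
  expect_true(all(X$counts[X$labels == "no", "EX"] == 0L))
  expect_true(all(X$counts[X$labels == "yes", "EX"] >= 2L))
})

test_that("decoy occurrence rates are class-balanced", {
  b <- small_benchmark()
  X <- b$X
  decoys <- paste0("M", sprintf("%02d", 7:12))
  for (m in decoys) {
    per_class <- tapply(X$counts[, m], X$labels, mean)
    pooled <- mean(X$counts[, m])
    se <- sd(X$counts[, m]) / sqrt(60)
    expect_true(all(abs(per_class - pooled) <= 4 * se),
                info = paste("decoy", m, "unbalanced"))
  }
})

test_that("null datasets are label-blind and generation is byte-deterministic", {
  set.seed(7)
  db <- motif_database(lapply(sprintf("N%d", 1:6), make_random_pwm, width = 8,
                              concentration = 20))
  g <- grammar_spec(c("p", "q"),
                    requirements = list(p = list(list(motif = "N1",
                                                      min_count = 3))),
                    window_length = 120, background_rate = 0.3,
                    plant_halfwidth = 40)
  nd <- null_dataset(g, db, n_per_class = 40, seed = 8)
  Xn <- build_count_matrix(nd$sequences, db)
  # no planted contrast: class means of every motif agree within sampling error
  for (m in names(db)) {
    diff <- abs(diff(tapply(Xn$counts[, m], Xn$labels, mean)))
    se <- sd(Xn$counts[, m]) / sqrt(40)
    expect_lte(unname(diff), 5 * max(se, 0.05))
  }
  # identical seeds give byte-identical written outputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(g, db, n_per_class = 10, seed = 9), d1)
  write_dataset(generate_dataset(g, db, n_per_class = 10, seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # and the dataset round-trips through the on-disk pipeline formats
  seqs <- Biostrings::readDNAStringSet(file.path(d1, "sequences.fa"))
  expect_equal(length(seqs), 20L)
  labels <- read.table(file.path(d1, "labels.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(labels), 20L)
})
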