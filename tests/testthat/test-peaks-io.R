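test_that("narrowPeak and BED lines parse with correct field mapping and defaults", {
  f <- withr::local_tempfile(lines = c(
    "# a comment",
    "track name=peaks",
    "chr1\t100\t340\tp1\t0\t.\t5.0\t30.0\t12.0\t120",
    "chr2\t0\t240",
    "chr3\t10\t50\tp3\t7\t+"))
  peaks <- read_narrowpeak(f, "HepG2")
  expect_equal(nrow(peaks), 3L)
  expect_equal(peaks$chrom, c("chr1", "chr2", "chr3"))
  expect_equal(peaks$start[1], 100L)
  expect_equal(peaks$end[1], 340L)
  expect_equal(peaks$neg_log10_p, c(30, 0, 0))
  expect_equal(peaks$signal, c(5, 0, 0))
  expect_equal(peaks$summit_offset, c(120L, -1L, -1L))
  expect_equal(unique(peaks$cell_type), "HepG2")

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_narrowpeak(empty, "x")), 0L)
})

test_that("malformed peak lines raise errors naming the line number", {
  bad_coord <- withr::local_tempfile(lines = c("chr1\t1\t10", "chr1\tab\t10"))
  expect_error(read_narrowpeak(bad_coord, "x"), "line 2")
  inverted <- withr::local_tempfile(lines = "chr1\t50\t50")
  expect_error(read_narrowpeak(inverted, "x"), "end <= start")
})

test_that("top-peak selection is unique, deterministic, and idempotent", {
  set.seed(1)
  n <- 1000
  peaks <- data.frame(
    chrom = sample(paste0("chr", 1:5), n, TRUE),
    start = sample.int(1e6, n), name = paste0("p", 1:n),
    neg_log10_p = round(runif(n, 1, 200), 2),
    signal = round(runif(n, 1, 50), 2),
    summit_offset = -1L, cell_type = "K562", stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 200L
  top <- select_top_peaks(peaks, 500)
  expect_equal(nrow(top), 500L)
  expect_equal(top$neg_log10_p, sort(peaks$neg_log10_p, decreasing = TRUE)[1:500],
               tolerance = 0)
  # idempotence
  expect_identical(select_top_peaks(top, 500), top)
  # duplicate interval collapses to the stronger peak
  dup <- peaks[c(1, 1), ]
  dup$neg_log10_p <- c(12, 30)
  expect_warning(kept <- select_top_peaks(dup, 10), "1 unique")
  expect_equal(kept$neg_log10_p, 30)
  # fewer than n available
  expect_warning(res <- select_top_peaks(peaks[1:7, ], 500), "7")
  expect_equal(nrow(res), 7L)
  # tie-breaking: equal p, higher signal first, then coordinate order
  ties <- peaks[1:3, ]
  ties$neg_log10_p <- 5
  ties$signal <- c(1, 9, 9)
  ties$chrom <- c("chr2", "chr3", "chr1")
  ties$start <- c(10L, 10L, 10L)
  ties$end <- ties$start + 100L
  got <- select_top_peaks(ties, 3)
  expect_equal(got$chrom, c("chr1", "chr3", "chr2"))
})

test_that("peak centre uses the summit when present, else the floored midpoint", {
  p <- data.frame(chrom = "c", start = c(100L, 100L, 100L),
                  end = c(340L, 340L, 341L),
                  summit_offset = c(120L, -1L, -1L))
  expect_equal(peak_center(p), c(220L, 220L, 220L))
})

test_that("windows are fixed-width and boundary windows are dropped, not clipped", {
  p <- data.frame(chrom = c("c1", "c1", "c1"), start = c(100L, 210L, 0L),
                  end = c(340L, 230L, 6L), name = paste0("p", 1:3),
                  neg_log10_p = c(30, 20, 10), signal = 0,
                  summit_offset = c(120L, -1L, 3L), cell_type = "A",
                  stringsAsFactors = FALSE)
  expect_message(w <- make_windows(p, 120, contig_lengths = c(c1 = 1000L)),
                 "dropped 1")
  expect_equal(nrow(w), 2L)
  expect_true(all(w$end - w$start == 240L))
  expect_equal(w$start[1], 100L)
  expect_equal(w$end[1], 340L)
  w5 <- make_windows(p[1, ], 5)
  expect_equal(c(w5$start, w5$end), c(215L, 225L))
  expect_error(make_windows(p, 120, contig_lengths = c(other = 500L)),
               "c1")
})

test_that("sequence extraction is uppercase, reference-strand, and validated", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT", c2 = tolower("ttttgggg")))
  w <- data.frame(chrom = c("c1", "c2"), start = c(0L, 2L), end = c(4L, 8L),
                  cell_type = "A", source_peak_id = c("w1", "w2"),
                  neg_log10_p = 0, stringsAsFactors = FALSE)
  seqs <- fetch_sequences(w, genome)
  expect_equal(seqs$sequence, c("ACGT", "TTGGGG"))
  w_bad <- transform(w, chrom = c("c1", "nope"))
  expect_error(fetch_sequences(w_bad, genome), "nope")
  w_over <- transform(w, end = c(4L, 99L))
  expect_error(fetch_sequences(w_over, genome), "exceed")
})

test_that("windows round-trip through BED with identical intervals", {
  w <- data.frame(chrom = c("c2", "c1"), start = c(15L, 0L), end = c(255L, 240L),
                  cell_type = "A", source_peak_id = c("a", "b"),
                  neg_log10_p = c(12.4, 3.2), stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_windows_bed(w, f)
  back <- read_windows_bed(f, "A")
  expect_identical(back[, c("chrom", "start", "end", "source_peak_id")],
                   w[, c("chrom", "start", "end", "source_peak_id")])
})
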