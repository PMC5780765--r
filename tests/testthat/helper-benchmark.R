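# Planted-grammar benchmark at full study scale (5 classes x 300 windows of
# 240 bp, 50 motifs), generated once per test file and cached; the planted
# truth used by the recovery checks is summarised alongside.
full_benchmark <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bench <- default_benchmark()
    ds <- generate_dataset(bench$grammar, bench$db, n_per_class = 300,
                           seed = 101)
    X <- build_count_matrix(ds$sequences, bench$db)
    planted <- list(
      classA = list(motifs = "M01", min_count = 3),
      classB = list(motifs = "M02", min_count = 3),
      classC = list(motifs = "M03", min_count = 3),
      classD = list(motifs = "M04", min_count = 3),
      classE = list(motifs = c("M05", "M06"), min_count = 1))
    cache <<- list(db = bench$db, grammar = bench$grammar, ds = ds, X = X,
                   planted = planted,
                   informative = c("M01", "M02", "M03", "M04", "M05", "M06"))
    cache
  }
})

# does this rule recover the class's planted signal? a condition must name a
# planted motif with direction >= and threshold within +/-1 of the planted
# minimum count
rule_recovers <- function(rule, planted_entry) {
  for (i in seq_along(rule$motifs)) {
    if (rule$motifs[i] %in% planted_entry$motifs &&
        rule$rels[i] == ">=" &&
        abs(rule$thrs[i] - planted_entry$min_count) <= 1L)
      return(TRUE)
  }
  FALSE
}
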