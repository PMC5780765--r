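---
title: "Discovering cell-type-specific motif grammars from TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cell-type-specific motif grammars from TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the method

Many transcription factors (TFs) bind the same core DNA motif yet occupy
different genomic loci in different cell types. One mechanistic hypothesis is
combinatorial: a TF's binding in a given cell type depends on co-binding
partners, so the sequence neighbourhood of its binding sites should carry a
cell-type-specific *combination* of partner motifs — a motif grammar.

`motifgrammar` operationalises this hypothesis as a supervised learning
problem with an interpretable read-out, in four stages:

1. **Windows.** For each cell type, take the strongest unique ChIP-seq peaks
   of the TF (by $-\log_{10} p$), centre a fixed-width window on each peak
   summit (or interval midpoint when no summit is recorded), and extract the
   window sequence.
2. **Annotation.** Scan every window with a large database of position
   weight matrices (PWMs) and record, per window, the occurrence count of
   each motif: both strands, all offsets, log-odds score at or above the
   motif's detection threshold. This yields a samples × motifs count matrix
   labelled by cell type.
3. **Classification.** Train a multi-class random forest (bagged,
   gini-split, grown-to-purity decision trees with a random feature subset
   per split) to predict the cell type from motif counts alone. Performance
   is estimated by repeated stratified cross-validation; per-class
   discrimination uses the fraction of trees voting for a class as the score
   of a one-vs-rest classifier and reports its AUROC, alongside per-class
   F1 ($F1 = 2PR/(P+R)$). Motif importance is the permutation-based mean
   decrease in accuracy (MDA): the average drop in a tree's out-of-bag (OOB)
   accuracy when the motif's values are permuted among that tree's OOB
   samples, scaled by the standard deviation of the MDA values across all
   motifs.
4. **Grammar.** Decompose the trained forest into conjunctive rules over
   integer motif counts (root-to-leaf paths), measure each rule's coverage
   and error on the training data, prune redundant conditions, select a
   compact non-redundant rule list, and keep only rules with frequency
   ≥ 0.08 and error ≤ 0.7. The surviving rules — e.g.
   `M02>=3 -> classB` — are the grammar.

A forest is preferred over higher-capacity black-box classifiers precisely
because stage 4 is possible: every prediction is a vote of explicit
threshold rules, so the discriminative structure can be read back out.

## Defaults and what they mean

| Parameter | Default | Why |
|---|---|---|
| flank | 120 bp (240 bp windows) | The window sweep (below) shows discriminative motif content concentrates within ~120 bp of the summit; smaller windows lose partner motifs, larger ones dilute them. |
| top peaks per cell type | 500 | Strongest-signal sites; keeps classes balanced and matrices tractable. |
| trees | 500 | OOB error stabilises well before 500 trees at these problem sizes; more trees add cost, not accuracy. |
| features per split | floor(sqrt(p)), then tuned | Classification default; round 2 tunes over {m/2, m, 2m} by OOB error (ties to the smaller, simpler value). |
| CV design | 10 × 10-fold, stratified | Stratification keeps per-fold class proportions within one sample of global, stabilising per-class metrics. |
| PWM background / pseudocount | uniform 0.25 / 0.001 | Natural-log log-odds; the pseudocount avoids -Inf for zero entries. Fixtures and synthetic thresholds are generated under the same convention. |
| default PWM threshold | 0.8 × max log-odds | Used when a motif file header carries no calibrated cut-off; logged so users can override. |
| rule cap / decay / filters | 6 conditions, 0.05 relative decay, freq ≥ 0.08, error ≤ 0.7 | Deep-path rules are low-frequency and would be filtered anyway; the decay tolerance removes conditions whose loss changes the error by ≤ 5 % relative. |
| importance shortlist | scaled MDA > 6 | Reporting threshold for calling a motif cell-type-discriminatory; meaningful when informative motifs are a small fraction of a large database. |

Training is a two-round procedure: round 1 fits with the default feature
subsampling and removes every motif with negative raw MDA (features that
*hurt* OOB accuracy), round 2 tunes the features-per-split on the reduced
matrix and refits. Cross-validation re-runs the full two-round procedure
inside every fold, so importance-based feature elimination never leaks
information from held-out samples.

## The forest engine

Trees are grown by `ranger` (single-threaded, explicitly seeded), which
exposes everything the rest of the pipeline needs from individual trees:
per-tree in-bag counts (hence OOB sample sets), full split structure via
`treeInfo()` (walked by the rule extractor), per-tree votes on new data, and
unscaled permutation importance — exactly the per-tree OOB
permute-and-measure definition of MDA used here. The paper-style scaling
(divide by the sd of MDA across motifs, *not* by a per-variable standard
error) is applied on top. Two runs with the same data and seed are
bit-identical, which the test suite asserts at file level.

## Rule mining in detail

* **Extraction.** Every root-to-leaf path of every tree yields a candidate
  rule; paths longer than 6 conditions are truncated at 6. Split tests on
  counts integerize exactly: `x <= 2.5` becomes `x <= 2`, `x > 2.5` becomes
  `x >= 3`; `x <= 0` is displayed `= 0`. Repeated bounds on a motif merge to
  the tightest interval; an infeasible interval leaves the rule uncoverable
  (frequency 0) and it is filtered later.
* **Measurement.** A rule's outcome is re-derived as the majority class of
  the training samples it covers (ties alphabetically), not taken from the
  leaf; frequency and error are exact integer fractions, which lets the test
  suite compare them bit-for-bit against a brute-force enumerator.
* **Pruning.** Conditions are revisited deepest-first; a condition is
  dropped when removing it increases the error by at most 5 % relative.
* **Selection.** A deterministic greedy rule-list: candidates sorted by
  (error, length, −frequency, condition string) are appended iff they
  strictly reduce the training misclassification of the first-match-wins
  rule list, with unmatched samples predicted as the global majority class.
  This replaces a regularised-forest rule selector with a reproducible,
  dependency-free procedure with the same stated goal (relevant and
  non-redundant rules); it is the one deliberate algorithmic substitution in
  the package. A consequence worth knowing: the majority/default class needs
  no rule of its own, so a balanced K-class problem typically yields rules
  for K−1 classes and reports "No rule identified" for the default class —
  the same phenomenon that appears in real analyses when one class is
  captured by the absence of the others' motifs.

## The synthetic benchmark: what it emulates, what it does not

`default_benchmark()` plants a known grammar so that every stage can be
validated end-to-end without downloads: 5 cell types × 300 windows of
240 bp over a 50-PWM database (width 8, sharply peaked rows). Classes A–D
each require ≥ 3 instances of their own marker motif; class E requires the
*pair* M05 ≥ 1 and M06 ≥ 1, and M05/M06 are excluded from the other
classes — a class-private co-factor pair. The exclusion matters: if the pair
motifs also occurred at background rates everywhere, ~3 % of non-E windows
would carry both by chance, and the zero-error rule "none of the other
classes' markers" would always out-rank the pair rule under the selection
order above, making conjunctive-grammar recovery impossible by construction
rather than hard. All other motifs (and, in the other classes, the
non-required informative ones) occur as Poisson background at rate 0.2 per
window, so planted minima are identifiable thresholds rather than
present/absent flags. Planted instances are sampled from the PWM itself —
not its consensus — and rejection-sampled to score above the detection
threshold, so planted counts are guaranteed but instance sequences are
noisy. A `min_count` requirement plants `min_count` plus a random surplus in
{0, 1} instances, keeping recovered thresholds testably close (± 1) to the
planted minimum. Instances are placed without overlap, uniformly within
± 100 bp of the window centre (free space distributed as random gaps), which
gives the window sweep its geometry: 10 bp windows see almost no signal,
240 bp windows see all of it, 600 bp windows only add noise.

The matched null runs the identical generative process with all
requirement/exclusion clauses ignored, so labels carry no information; it
calibrates the AUROC band (~0.5) and confirms that no motif reaches the
scaled-MDA shortlist by chance.

What passing these tests does **not** show about real data: genomic
background is not i.i.d. (repeats, CpG structure, GC heterogeneity), real
motif databases are highly redundant (correlated columns dilute per-motif
importance), class sizes are balanced here, and planted grammars have no
spatial syntax — occurrence counts deliberately ignore motif order, spacing
and orientation, which the count representation cannot express.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open (BED) throughout; peak centres use the
  floored midpoint when no summit is recorded, so they are deterministic.
* Windows crossing a contig edge are dropped (with a count), never clipped:
  the classifier assumes equal-length windows.
* Peak selection breaks ties by signal, then (chrom, start), making the
  top-N set unique and idempotent.
* Any scan window containing a non-ACGT base scores −Inf and can never be a
  hit; soft-masked lowercase bases are uppercased and scanned normally.
* A motif matching the same offset on both strands (a palindrome) counts
  twice; overlapping hits all count. Both conventions are the simplest
  well-defined ones and are what the brute-force oracle implements.
* If every raw MDA is identical (e.g. all-zero count matrices), the sd-scaled
  MDA is undefined and reported as 0 with a warning rather than NaN.
* Seeds: one master seed determines fold assignments, per-fold training
  seeds, simulation draws and permutations; derived seeds stay far below
  2^31.

## Problem sizes used by the tests and acceptance script

The validation suite runs the benchmark at its native scale (1 500 windows ×
50 motifs) for grammar recovery, the 10 × 10 CVs (signal and null), and a
window sweep at flanks {5, 120, 300} with a 2 × 5-fold CV per flank — the
sweep's F1 contrast (≈ chance at 5 bp vs ≈ 1 at 120 bp) does not need the
full CV design. The bookkeeping check runs 6 × 500 windows against a
synthetically generated 2 067-motif database (a 3 000 × 2 067 count matrix),
with the C++ scanner making that a seconds-scale operation.

## Known limitations

* Count-based features cannot represent motif spacing/ordering grammar.
* The greedy rule-list selector is order-sensitive by design (that is what
  makes it deterministic); rules it rejects as redundant may still be
  biologically interesting — inspect the pre-selection candidates if so.
* HOMER-format detection thresholds are taken at face value; databases
  calibrated under different background or log conventions should be
  re-thresholded before scanning.
* Real-data reproduction additionally depends on peak-caller behaviour
  (summit vs midpoint) and genome build; the package makes both explicit
  but cannot remove the dependence.
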