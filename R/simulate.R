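#' Sample a random PWM
#'
#' Each row is drawn from a Dirichlet distribution sharpened towards a random
#' consensus base: the consensus base gets concentration parameter
#' `concentration`, the other three get 1. High concentration gives a
#' near-consensus PWM. The detection threshold is set to 0.8 x the maximum
#' achievable log-odds score.
#'
#' @param name Motif name.
#' @param width Number of positions (>= 4).
#' @param concentration Sharpness (> 0); the default 20 gives ~87% consensus
#'   base probability per position.
#' @return A [new_pwm()] object. Uses the current RNG state; call
#'   `set.seed()` for reproducibility.
#' @export
make_random_pwm <- function(name, width = 8, concentration = 20) {
  stopifnot(width >= 4, concentration > 0)
  probs <- t(vapply(seq_len(width), function(i) {
    alpha <- rep(1, 4)
    alpha[sample.int(4, 1)] <- concentration
    g <- stats::rgamma(4, shape = alpha)
    g / sum(g)
  }, numeric(4)))
  new_pwm(name, probs)
}

#' Specify a planted motif grammar
#'
#' A grammar assigns each class a conjunction of requirement clauses
#' (motif, minimum count) and optional exclusion clauses (motif forced
#' absent). All motifs in the database additionally occur as background at
#' rate `background_rate` per window in every class (except where excluded or
#' required), emulating the chance occurrences real motifs have everywhere —
#' without them, planted minimum counts would not be identifiable from the
#' class contrast.
#'
#' @param classes Character vector of class names.
#' @param requirements Named list (by class): each element a list of
#'   `list(motif =, min_count =)` clauses. Classes may be absent (no
#'   requirement).
#' @param exclusions Named list (by class) of motif name vectors forced to
#'   count 0.
#' @param window_length Window length in bp (default 240).
#' @param background_rate Poisson rate of background plantings per motif per
#'   window (default 0.2).
#' @param base_freqs Background base frequencies (A,C,G,T).
#' @param plant_halfwidth Planted instances are confined to within this many
#'   bp of the window centre (default 100), so signal concentrates around the
#'   peak summit as in real binding sites.
#' @return Object of class `GrammarSpec`.
#' @export
grammar_spec <- function(classes, requirements = list(), exclusions = list(),
                         window_length = 240, background_rate = 0.2,
                         base_freqs = rep(0.25, 4), plant_halfwidth = 100) {
  stopifnot(length(classes) >= 2, !anyDuplicated(classes),
            abs(sum(base_freqs) - 1) < 1e-6, all(base_freqs > 0))
  for (cl in names(requirements))
    if (!cl %in% classes) stop("requirement for unknown class: ", cl)
  for (cl in names(exclusions))
    if (!cl %in% classes) stop("exclusion for unknown class: ", cl)
  for (cl in names(requirements))
    for (clause in requirements[[cl]])
      if (is.null(clause$motif) || is.null(clause$min_count) ||
          clause$min_count < 1)
        stop("each requirement clause needs a motif and min_count >= 1")
  structure(list(classes = classes, requirements = requirements,
                 exclusions = exclusions, window_length = window_length,
                 background_rate = background_rate, base_freqs = base_freqs,
                 plant_halfwidth = plant_halfwidth),
            class = "GrammarSpec")
}

# validate grammar motifs against a database; window long enough for motifs
validate_grammar <- function(grammar, db) {
  referenced <- unique(c(
    unlist(lapply(grammar$requirements, vapply, `[[`, character(1), "motif")),
    unlist(grammar$exclusions)))
  missing <- setdiff(referenced, names(db))
  if (length(missing) > 0L)
    stop("grammar references motifs absent from database: ",
         paste(missing, collapse = ", "))
  wmax <- max(vapply(db$motifs, `[[`, numeric(1), "width"))
  if (grammar$window_length < wmax + 2)
    stop("window_length must be >= max motif width + 2")
  if (grammar$plant_halfwidth + wmax > grammar$window_length / 2)
    stop("plant_halfwidth + max motif width exceeds the window half-width; ",
         "planted instances would fall outside the scanned window")
  invisible(TRUE)
}

# sample an instance from the PWM, rejecting draws that do not reach the
# detection threshold on the + strand (so planted counts are guaranteed
# detectable); falls back to the consensus after 1000 draws
sample_pwm_instance <- function(pwm, lod, max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    bases <- apply(pwm$probs, 1, function(p) sample.int(4, 1, prob = p))
    if (sum(lod[cbind(seq_len(pwm$width), bases)]) >= pwm$detection_threshold)
      return(paste(.base_letters[bases], collapse = ""))
  }
  pwm$consensus
}

# place instances of given widths without overlap within [lo, hi] (1-based,
# inclusive) by distributing the free space as random gaps between the
# instances laid left to right (the caller shuffles instance order, so the
# motif-to-position assignment is uniform). Returns starts, or NULL when the
# instances cannot fit at all.
place_instances <- function(widths, lo, hi) {
  k <- length(widths)
  if (k == 0L) return(integer(0))
  region <- hi - lo + 1L
  free <- region - sum(widths)
  if (free < 0L) return(NULL)
  slack <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
  as.integer(lo + slack + c(0L, cumsum(widths[-k])))
}

#' Generate a labelled synthetic dataset with a planted grammar
#'
#' Each sample is a contig of i.i.d. background sequence with motif instances
#' planted non-overlapping at uniform positions within `plant_halfwidth` of
#' the contig centre: every motif at Poisson(`background_rate`) background
#' occurrences, plus, for each requirement clause of the sample's class,
#' `min_count` + a random surplus in {0, 1} instances of the required motif.
#' Planted instances are rejection-sampled from the PWM so each one is
#' detectable at the motif's threshold. Excluded motifs are never planted and
#' the window is re-drawn if a spurious hit of an excluded motif arises.
#' A narrowPeak-style peak (summit at the contig centre) is recorded per
#' sample so the full peaks-to-rules pipeline can run on the output.
#'
#' @param grammar A [grammar_spec()].
#' @param db A [motif_database()]; every motif the grammar references must
#'   exist in it.
#' @param n_per_class Samples per class (default 300).
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @param contig_length Length of each sample's contig (default 660, enough
#'   for window half-widths up to 300 bp).
#' @return Object of class `SyntheticDataset`: list with `genome`
#'   (`DNAStringSet`, one contig per sample), `peaks` (narrowPeak-style
#'   `data.frame`), `windows` (at flank `window_length/2`), `sequences`
#'   (window sequences, `data.frame`), `truth` (the grammar), `db`, `seed`.
#' @export
generate_dataset <- function(grammar, db, n_per_class = 300, seed = 1,
                             contig_length = 660) {
  stopifnot(inherits(grammar, "GrammarSpec"), inherits(db, "MotifDatabase"))
  validate_grammar(grammar, db)
  if (contig_length < grammar$window_length)
    stop("contig_length must be >= window_length")
  set.seed(seed)
  centre <- contig_length %/% 2L
  flank <- grammar$window_length %/% 2L
  lods <- lapply(db$motifs, logodds_matrix)
  widths <- vapply(db$motifs, `[[`, numeric(1), "width")
  motif_names <- names(db)
  plant_lo <- centre - grammar$plant_halfwidth + 1L
  plant_hi <- centre + grammar$plant_halfwidth
  contigs <- character(0)
  contig_names <- character(0)
  peak_rows <- list()
  for (cl in grammar$classes) {
    req <- grammar$requirements[[cl]]
    excl <- grammar$exclusions[[cl]]
    req_motifs <- vapply(req, `[[`, character(1), "motif")
    for (i in seq_len(n_per_class)) {
      for (attempt in seq_len(50L)) {
        # planned instances: background for every non-excluded motif, plus
        # required counts (min + surplus) for this class's clauses
        n_bg <- rpois(length(motif_names), grammar$background_rate)
        names(n_bg) <- motif_names
        n_bg[excl] <- 0L
        n_req <- setNames(integer(length(req)), req_motifs)
        for (clause in req)
          n_req[clause$motif] <- clause$min_count + sample(0:1, 1)
        plan <- c(rep(motif_names, n_bg), rep(names(n_req), n_req))
        plan <- sample(plan) # placement order should not favour any motif
        seq_chars <- sample(.base_letters, contig_length, replace = TRUE,
                            prob = grammar$base_freqs)
        starts <- place_instances(widths[plan], plant_lo, plant_hi)
        if (is.null(starts)) { # rare Poisson tail: redraw background counts
          if (attempt == 50L)
            stop("window too crowded to place all instances; ",
                 "use longer windows or a lower background_rate")
          next
        }
        for (k in seq_along(plan)) {
          inst <- sample_pwm_instance(db$motifs[[plan[k]]], lods[[plan[k]]])
          seq_chars[starts[k]:(starts[k] + nchar(inst) - 1L)] <-
            strsplit(inst, "")[[1]]
        }
        contig <- paste(seq_chars, collapse = "")
        if (length(excl) > 0L) {
          window <- substr(contig, centre - flank + 1L, centre + flank)
          spurious <- any(vapply(excl, function(m)
            count_occurrences(db$motifs[[m]], window) > 0, logical(1)))
          if (spurious) next # redraw
        }
        break
      }
      name <- sprintf("ctg_%s_%04d", cl, i)
      contigs <- c(contigs, contig)
      contig_names <- c(contig_names, name)
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = name, start = centre - flank, end = centre + flank,
        name = paste0("peak_", name),
        neg_log10_p = round(runif(1, 10, 100), 3), signal = round(runif(1, 5, 50), 3),
        summit_offset = flank, cell_type = cl, stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(contigs, contig_names))
  peaks <- do.call(rbind, peak_rows)
  windows <- make_windows(peaks, flank,
                          contig_lengths = setNames(rep(contig_length,
                                                        length(contig_names)),
                                                    contig_names))
  sequences <- fetch_sequences(windows, genome)
  structure(list(genome = genome, peaks = peaks, windows = windows,
                 sequences = sequences, truth = grammar, db = db,
                 seed = seed),
            class = "SyntheticDataset")
}

#' Matched null dataset (labels carry no signal)
#'
#' Identical generative process to [generate_dataset()] but with all
#' requirement and exclusion clauses ignored: every class receives only the
#' uniform background plantings, so the class labels are exchangeable. Used
#' to calibrate AUROC and importance at chance level.
#'
#' @inheritParams generate_dataset
#' @return A `SyntheticDataset`.
#' @export
null_dataset <- function(grammar, db, n_per_class = 300, seed = 1,
                         contig_length = 660) {
  null_grammar <- grammar
  null_grammar$requirements <- list()
  null_grammar$exclusions <- list()
  generate_dataset(null_grammar, db, n_per_class = n_per_class, seed = seed,
                   contig_length = contig_length)
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d samples, %d classes, %d motifs, seed %d\n",
              nrow(x$sequences), length(x$truth$classes), length(x$db),
              x$seed))
  invisible(x)
}

#' The default planted benchmark: database and grammar
#'
#' 50 width-8 PWMs (high concentration) of which six are informative over
#' five classes: classes A-D each require at least 3 occurrences of their own
#' motif (M01-M04), and class E requires the conjunction M05 >= 1 and
#' M06 >= 1, exercising multi-motif rules. The pair motifs M05/M06 are
#' excluded from the other classes (a planted co-factor pair specific to one
#' cell type), so the conjunction — not the absence of the other classes'
#' motifs — is the minimal-error description of class E. The remaining 44
#' motifs are decoys occurring only as background. Windows are 240 bp with
#' instances planted within 100 bp of the centre.
#'
#' @param seed Seed for drawing the PWMs.
#' @return List with `db` (a [motif_database()]) and `grammar`
#'   (a [grammar_spec()]).
#' @export
default_benchmark <- function(seed = 20) {
  set.seed(seed)
  db <- motif_database(
    lapply(sprintf("M%02d", 1:50), make_random_pwm,
           width = 8, concentration = 20),
    source = sprintf("synthetic benchmark (seed %d)", seed))
  grammar <- grammar_spec(
    classes = paste0("class", LETTERS[1:5]),
    requirements = list(
      classA = list(list(motif = "M01", min_count = 3)),
      classB = list(list(motif = "M02", min_count = 3)),
      classC = list(list(motif = "M03", min_count = 3)),
      classD = list(list(motif = "M04", min_count = 3)),
      classE = list(list(motif = "M05", min_count = 1),
                    list(motif = "M06", min_count = 1))),
    exclusions = list(classA = c("M05", "M06"), classB = c("M05", "M06"),
                      classC = c("M05", "M06"), classD = c("M05", "M06")),
    window_length = 240, background_rate = 0.2, plant_halfwidth = 100)
  list(db = db, grammar = grammar)
}

#' Write a synthetic dataset to disk
#'
#' Emits `genome.fa` (all contigs), one `peaks_<class>.narrowPeak` per class,
#' `windows.bed`, `sequences.fa` (window sequences), `labels.tsv`
#' (sample_id, cell_type) and `truth.json` (grammar and seed). All files are
#' plain text and byte-deterministic given the dataset.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(ds$genome, file.path(dir, "genome.fa"),
                              width = 80L)
  for (cl in ds$truth$classes) {
    p <- ds$peaks[ds$peaks$cell_type == cl, , drop = FALSE]
    np <- data.frame(p$chrom, p$start, p$end, p$name, 0L, ".",
                     p$signal, p$neg_log10_p, -1, p$summit_offset)
    write.table(np, file.path(dir, paste0("peaks_", cl, ".narrowPeak")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_windows_bed(ds$windows, file.path(dir, "windows.bed"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(ds$sequences$sequence,
                                      ds$sequences$id)),
    file.path(dir, "sequences.fa"), width = 80L)
  write.table(data.frame(sample_id = ds$sequences$id,
                         cell_type = ds$sequences$cell_type),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(seed = ds$seed, classes = ds$truth$classes,
         window_length = ds$truth$window_length,
         background_rate = ds$truth$background_rate,
         plant_halfwidth = ds$truth$plant_halfwidth,
         requirements = ds$truth$requirements,
         exclusions = ds$truth$exclusions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_homer_motifs(ds$db, file.path(dir, "motifs.homer"))
  invisible(dir)
}
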