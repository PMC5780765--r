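#' Assemble and validate a pipeline configuration
#'
#' Defaults are the pipeline's standard operating point: 120 bp flanks
#' (240 bp windows), top 500 peaks per cell type, 500 trees, 10 x 10-fold
#' cross-validation, rule filters at frequency 0.08 / error 0.7, pruning
#' decay 0.05.
#'
#' @param peaks Named character vector: `cell_type = path` to a
#'   narrowPeak/BED file per cell type (ignored by [simulate_dataset()]).
#' @param genome Path to the genome FASTA.
#' @param motifs Path to the HOMER-format motif database.
#' @param out_dir Output directory.
#' @param flank Window half-width in bp.
#' @param top_n_peaks Strongest unique peaks kept per cell type.
#' @param n_trees Trees per forest.
#' @param cv_repeats,cv_folds Cross-validation design.
#' @param min_rule_frequency,max_rule_error,max_decay,rule_max_len Rule
#'   mining parameters.
#' @param background,pseudocount PWM scoring parameters.
#' @param seed Master seed; fully determines every stochastic choice.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(peaks = NULL, genome = NULL, motifs = NULL,
                            out_dir = "motifgrammar_out", flank = 120,
                            top_n_peaks = 500, n_trees = 500,
                            cv_repeats = 10, cv_folds = 10,
                            min_rule_frequency = 0.08, max_rule_error = 0.7,
                            max_decay = 0.05, rule_max_len = 6,
                            background = rep(0.25, 4), pseudocount = 1e-3,
                            seed = 1) {
  cfg <- list(peaks = peaks, genome = genome, motifs = motifs,
              out_dir = out_dir, flank = flank, top_n_peaks = top_n_peaks,
              n_trees = n_trees, cv_repeats = cv_repeats, cv_folds = cv_folds,
              min_rule_frequency = min_rule_frequency,
              max_rule_error = max_rule_error, max_decay = max_decay,
              rule_max_len = rule_max_len, background = background,
              pseudocount = pseudocount, seed = as.integer(seed))
  stopifnot(cfg$flank >= 1, cfg$top_n_peaks >= 1, cfg$n_trees >= 1,
            cfg$cv_folds >= 2)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a YAML pipeline configuration
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields
#' take the defaults. The `peaks` field is a mapping of cell type to path.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$peaks)) raw$peaks <- unlist(raw$peaks)
  do.call(pipeline_config, raw)
}

# config hash for output provenance headers: md5 of the resolved config YAML
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

# provenance line carried as a header comment by every output file
provenance <- function(cfg) {
  sprintf("motifgrammar %s config=%s seed=%d",
          as.character(packageVersion("motifgrammar")), config_hash(cfg),
          cfg$seed)
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
}

#' Simulate a planted-grammar dataset to disk
#'
#' Wraps [default_benchmark()] + [generate_dataset()] + [write_dataset()];
#' pass a custom `grammar`/`db` to override the default benchmark.
#'
#' @param out_dir Output directory.
#' @param n_per_class Samples per class.
#' @param seed Master seed.
#' @param grammar,db Optional [grammar_spec()] and [motif_database()].
#' @param null If `TRUE`, generate the matched null (no planted signal).
#' @param quiet Suppress progress messages.
#' @return The `SyntheticDataset`, invisibly.
#' @export
simulate_dataset <- function(out_dir, n_per_class = 300, seed = 1,
                             grammar = NULL, db = NULL, null = FALSE,
                             quiet = FALSE) {
  if (is.null(grammar) || is.null(db)) {
    bench <- default_benchmark()
    if (is.null(grammar)) grammar <- bench$grammar
    if (is.null(db)) db <- bench$db
  }
  gen <- if (null) null_dataset else generate_dataset
  ds <- gen(grammar, db, n_per_class = n_per_class, seed = seed)
  write_dataset(ds, out_dir)
  if (!quiet) {
    n_req <- sum(lengths(ds$truth$requirements))
    message("simulated ", nrow(ds$sequences), " windows (",
            length(ds$truth$classes), " classes x ", n_per_class, "), ",
            n_req, " requirement clause(s); wrote ", out_dir)
  }
  invisible(ds)
}

#' Run the full pipeline: peaks to grammar
#'
#' Executes the four stages in order — (1) peak selection and window-sequence
#' extraction, (2) motif annotation into the count matrix, (3) two-round
#' forest training with scaled permutation importance, (4) rule mining —
#' plus cross-validated evaluation. Every TSV/JSON output carries a header
#' with the tool version and a hash of the resolved configuration; two runs
#' with identical configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] with `peaks`, `genome`, `motifs` set.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `count_matrix`, `fit` (two-round training
#'   result), `ruleset`, `cv`, `files` (paths written).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message("[", ..., "]")
  if (is.null(config$peaks) || is.null(names(config$peaks)))
    stop("config$peaks must be a named vector of cell_type = path")
  for (p in c(config$peaks, config$genome, config$motifs))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance(config)
  write_resolved_config(config, config$out_dir)
  files <- c()

  say("stage 1/4: peaks -> windows -> sequences")
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("[ \t].*$", "", names(genome))
  lens <- setNames(Biostrings::width(genome), names(genome))
  peaks <- do.call(rbind, lapply(names(config$peaks), function(cl)
    select_top_peaks(read_narrowpeak(config$peaks[[cl]], cl),
                     config$top_n_peaks)))
  windows <- make_windows(peaks, config$flank, contig_lengths = lens)
  seqs <- fetch_sequences(windows, genome)
  files["windows"] <- file.path(config$out_dir, "windows.bed")
  write_windows_bed(windows, files["windows"], header_comment = hdr)

  say("stage 2/4: motif annotation (", nrow(seqs), " windows)")
  db <- read_homer_motifs(config$motifs)
  X <- build_count_matrix(seqs, db, config$background, config$pseudocount)
  files["counts"] <- file.path(config$out_dir, "count_matrix.tsv")
  write_count_matrix(X, files["counts"], header_comment = hdr)

  say("stage 3/4: two-round forest training")
  fit <- two_round_train(X, seed = config$seed, n_trees = config$n_trees)
  files["model"] <- file.path(config$out_dir, "forest.json")
  write_forest_json(fit$model, files["model"])
  files["importance"] <- file.path(config$out_dir, "importance.tsv")
  write_importance_tsv(fit$final_importance, files["importance"],
                       header_comment = hdr)
  say("final OOB error ", signif(fit$final_oob, 4))

  say("stage 4/4: rule mining")
  ruleset <- mine_rules(fit$model, subset_counts(X, motifs = fit$kept_motifs),
                        max_len = config$rule_max_len,
                        max_decay = config$max_decay,
                        min_frequency = config$min_rule_frequency,
                        max_error = config$max_rule_error)
  files["rules_tsv"] <- file.path(config$out_dir, "rules.tsv")
  files["rules_json"] <- file.path(config$out_dir, "rules.json")
  write_rules(ruleset, files["rules_tsv"], files["rules_json"],
              header_comment = hdr)

  say("evaluation: ", config$cv_repeats, "x", config$cv_folds, "-fold CV")
  cv <- cross_validate(X, repeats = config$cv_repeats,
                       folds = config$cv_folds, seed = config$seed,
                       n_trees = config$n_trees)
  files["cv_tsv"] <- file.path(config$out_dir, "cv_metrics.tsv")
  files["cv_json"] <- file.path(config$out_dir, "cv_summary.json")
  write_cv_result(cv, files["cv_tsv"], files["cv_json"],
                  header_comment = hdr)

  invisible(list(count_matrix = X, fit = fit, ruleset = ruleset, cv = cv,
                 files = files))
}

#' Run the window-size sweep from a configuration
#'
#' @param config A [pipeline_config()].
#' @param flank_grid Half-widths to evaluate.
#' @param quiet Suppress progress messages.
#' @return The [window_size_sweep()] result; also writes `sweep.tsv` to
#'   `config$out_dir`.
#' @export
sweep_pipeline <- function(config, flank_grid = c(5, 120, 300),
                           quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  peaks <- do.call(rbind, lapply(names(config$peaks), function(cl)
    select_top_peaks(read_narrowpeak(config$peaks[[cl]], cl),
                     config$top_n_peaks)))
  db <- read_homer_motifs(config$motifs)
  res <- window_size_sweep(peaks, config$genome, db, flank_grid,
                           repeats = config$cv_repeats,
                           folds = config$cv_folds, seed = config$seed,
                           n_trees = config$n_trees,
                           background = config$background,
                           pseudocount = config$pseudocount)
  out <- file.path(config$out_dir, "sweep.tsv")
  con <- file(out, "w")
  writeLines(paste0("# ", provenance(config)), con)
  writeLines(paste0("# recommended_flank\t", res$recommended_flank), con)
  write.table(res$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!quiet) message("recommended flank: ", res$recommended_flank, " bp")
  res
}
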