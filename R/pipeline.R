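# Pipeline commands: thin, file-oriented wrappers tying the modules into the
# train / tag / select / evaluate / audit / generate workflow. Every command
# writes the run configuration next to its outputs and is rerunnable with
# identical results for identical inputs and seed.

write_run_config <- function(dir, config, seed, extra = list()) {
  obj <- c(list(package = "humtag", seed = as.integer(seed)),
           unclass(config), extra)
  jsonlite::write_json(obj, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

read_corpus_any <- function(path) {
  if (grepl("\\.xml$", path, ignore.case = TRUE)) read_pubmed_xml(path)
  else read_citation_table(path)
}

#' Pipeline command: train a tagger
#'
#' Reads a labeled corpus, reports held-out performance from an internal
#' stratified 80/20 split (train on 80%, evaluate on 20%), then trains the
#' final tagger on all labeled records and writes the archive. Outputs:
#' `tagger.json`, `report.tsv` (the held-out evaluation), `run_config.json`.
#'
#' @param corpus_path citation table (`.jsonl`) or PubMed XML (`.xml`).
#' @param out output directory (created if needed).
#' @param classes feature classes to use.
#' @param config a [tagger_config()].
#' @param seed integer seed.
#' @return the trained `tagger`, invisibly.
#' @export
cmd_train <- function(corpus_path, out, classes = feature_classes(),
                      config = tagger_config(), seed = 1L) {
  config <- as_tagger_config(config)
  corp <- read_corpus_any(corpus_path)
  log_info(sprintf("train: read %d records (%d labeled)", length(corp),
                   sum(!is.na(corpus_labels(corp)))))
  lab <- labeled_subset(corp)
  stop_if_not(length(lab) > 0, "corpus has no labeled records")
  y <- corpus_labels(lab)
  holdout <- with_seed(derive_seed(seed, 99), stratified_sample(y, 0.2))
  fit_part <- lab[setdiff(seq_along(y), holdout)]
  tg_part <- train_tagger(fit_part, classes, config, seed = seed)
  report <- evaluate_tagger(tg_part, lab[holdout])
  log_info(sprintf("train: held-out AUC %.4f, MCC %.4f on %d records",
                   report$auc, report$mcc, report$n))
  tagger <- train_tagger(lab, classes, config, seed = seed,
                         provenance = basename(corpus_path))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  save_tagger(tagger, file.path(out, "tagger.json"))
  utils::write.table(as.data.frame(report), file.path(out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(out, config, seed,
                   list(command = "train", corpus = basename(corpus_path),
                        classes = classes))
  invisible(tagger)
}

#' Pipeline command: score a corpus
#'
#' Writes a TSV of `id` and `probability` (6 decimals) in input order.
#' Labels and MeSH fields are not required and never used.
#'
#' @param tagger_path a [save_tagger()] archive.
#' @param corpus_path corpus to score.
#' @param out_path output TSV path.
#' @return the scores, invisibly.
#' @export
cmd_tag <- function(tagger_path, corpus_path, out_path) {
  tagger <- load_tagger(tagger_path)
  corp <- read_corpus_any(corpus_path)
  log_info(sprintf("tag: scoring %d records", length(corp)))
  p <- if (length(corp) == 0) numeric(0) else predict(tagger, corp, type = "prob")
  df <- data.frame(id = corpus_ids(corp), probability = sprintf("%.6f", p))
  if (length(corp) == 0) df <- data.frame(id = character(0), probability = character(0))
  utils::write.table(df, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(p, corpus_ids(corp)))
}

#' Pipeline command: forward feature-class selection
#'
#' Runs [forward_select()] and writes the trace TSV (`stage`, `feature`,
#' `auc`, `mcc`) plus the run configuration.
#'
#' @param corpus_path labeled corpus.
#' @param out output directory.
#' @param candidates candidate feature classes.
#' @param config a [tagger_config()].
#' @param seed integer seed.
#' @return the `selection_trace`, invisibly.
#' @export
cmd_select <- function(corpus_path, out, candidates = feature_classes(),
                       config = tagger_config(), seed = 1L) {
  config <- as_tagger_config(config)
  corp <- read_corpus_any(corpus_path)
  log_info(sprintf("select: %d records, %d candidate classes", length(corp),
                   length(candidates)))
  trace <- forward_select(corp, candidates, seed = seed, config = config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_selection_trace(trace, file.path(out, "selection_trace.tsv"))
  write_run_config(out, config, seed,
                   list(command = "select", corpus = basename(corpus_path),
                        candidates = candidates))
  invisible(trace)
}

#' Pipeline command: evaluate a tagger on a labeled corpus
#'
#' Writes `report.tsv` (all binary and probabilistic metrics),
#' `calibration_curve.tsv`, `score_histogram.tsv`, and `run_config.json`.
#'
#' @param tagger_path a tagger archive.
#' @param corpus_path labeled corpus.
#' @param out output directory.
#' @param config a [tagger_config()] (threshold and bin width).
#' @return the `evaluation_report`, invisibly.
#' @export
cmd_evaluate <- function(tagger_path, corpus_path, out,
                         config = tagger_config()) {
  config <- as_tagger_config(config)
  tagger <- load_tagger(tagger_path)
  corp <- read_corpus_any(corpus_path)
  lab <- labeled_subset(corp)
  stop_if_not(length(lab) > 0, "corpus has no labeled records to evaluate on")
  log_info(sprintf("evaluate: %d labeled records", length(lab)))
  p <- predict(tagger, lab, type = "prob")
  y <- corpus_labels(lab)
  report <- evaluate_scores(p, y, config$threshold)
  curve <- calibration_curve(p, y, config$bin_width)
  hist <- score_histogram(p, y, config$bin_width)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report), file.path(out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(curve), file.path(out, "calibration_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(hist), file.path(out, "score_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_config(out, config, NA_integer_,
                   list(command = "evaluate", corpus = basename(corpus_path)))
  invisible(report)
}

#' Pipeline command: sample extreme disagreements for manual audit
#'
#' Samples up to `k` label-positive records scored below `low` (model
#' predicts NOT-HUMAN despite the Humans MeSH term) and up to `k`
#' label-negative records scored above `high` (model predicts HUMAN without
#' the term), and writes a blank review sheet with columns `id`, `stratum`,
#' `score`, `review` for a blinded reviewer to fill with `HUMAN`,
#' `NOT_HUMAN`, or `UNCERTAIN`. [score_review_sheet()] turns the filled
#' sheet into agreement statistics.
#'
#' @param scores_path a [cmd_tag()] scores TSV.
#' @param corpus_path labeled corpus joinable on `id`.
#' @param out output directory.
#' @param low,high score cutoffs defining extreme disagreement (defaults
#'   0.01 / 0.99).
#' @param k target sample size per stratum (default 100).
#' @param seed integer seed for the random sampling.
#' @return the review sheet data frame, invisibly.
#' @export
cmd_audit <- function(scores_path, corpus_path, out, low = 0.01, high = 0.99,
                      k = 100, seed = 1L) {
  sc <- utils::read.table(scores_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  corp <- read_corpus_any(corpus_path)
  y <- stats::setNames(corpus_labels(corp), corpus_ids(corp))[sc$id]
  stop_if_not(!all(is.na(y)), "no labeled records join the scores on id")
  low_pool <- sc$id[!is.na(y) & y & sc$probability < low]
  high_pool <- sc$id[!is.na(y) & !y & sc$probability > high]
  take <- function(pool, stratum) {
    if (length(pool) < k)
      warning(sprintf("only %d qualifying cases in %s stratum (requested %d)",
                      length(pool), stratum, k), call. = FALSE)
    if (length(pool) == 0) return(character(0))
    sample(pool, min(k, length(pool)))
  }
  picks <- with_seed(seed, list(low = take(low_pool, "low-score"),
                                high = take(high_pool, "high-score")))
  sheet <- data.frame(
    id = c(picks$low, picks$high),
    stratum = c(rep("low", length(picks$low)), rep("high", length(picks$high))),
    score = sprintf("%.6f", sc$probability[match(c(picks$low, picks$high), sc$id)]),
    review = rep("", length(picks$low) + length(picks$high)),
    stringsAsFactors = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sheet, file.path(out, "review_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_run_config(out, tagger_config(), seed,
                   list(command = "audit", low = low, high = high, k = k))
  log_info(sprintf("audit: sampled %d low-score and %d high-score cases",
                   length(picks$low), length(picks$high)))
  invisible(sheet)
}

#' Score a filled review sheet
#'
#' Reads a [cmd_audit()] review sheet whose `review` column has been filled
#' with `HUMAN`, `NOT_HUMAN`, or `UNCERTAIN`, tabulates the 2 x 3 review
#' table, and returns [agreement_stats()].
#'
#' @param sheet_path the filled review sheet TSV.
#' @return list with `table` (the 2 x 3 counts) and `stats` (the agreement
#'   percentages).
#' @export
score_review_sheet <- function(sheet_path) {
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  stop_if_not(all(c("stratum", "review") %in% names(sheet)),
              "review sheet needs 'stratum' and 'review' columns")
  rv <- toupper(trimws(sheet$review))
  stop_if_not(all(rv %in% c("HUMAN", "NOT_HUMAN", "UNCERTAIN")),
              "review entries must be HUMAN, NOT_HUMAN, or UNCERTAIN")
  cnt <- function(stratum, call) sum(sheet$stratum == stratum & rv == call)
  tab <- agreement_table(
    low = c(cnt("low", "HUMAN"), cnt("low", "NOT_HUMAN"), cnt("low", "UNCERTAIN")),
    high = c(cnt("high", "HUMAN"), cnt("high", "NOT_HUMAN"), cnt("high", "UNCERTAIN")))
  list(table = tab, stats = agreement_stats(tab))
}

#' Pipeline command: generate a synthetic corpus
#'
#' Writes the JSON-lines citation table, the exact-posterior sidecar, and the
#' generator parameters.
#'
#' @param out output directory.
#' @param params a [generator_params()] object.
#' @return the `generated_corpus`, invisibly.
#' @export
cmd_generate <- function(out, params = generator_params()) {
  gen <- generate_corpus(params)
  write_generated_corpus(gen, out)
  jsonlite::write_json(unclass(params), file.path(out, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_info(sprintf("generate: wrote %d records to %s", params$n_records, out))
  invisible(gen)
}
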