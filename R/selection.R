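#' Build a 5x2 cross-validation fold plan
#'
#' Five independent random 50/50 partitions of the labeled records,
#' stratified by label so each half carries the corpus prevalence to within
#' one record. Each partition yields two train/test arrangements, so a plan
#' drives ten fits. Deterministic given the seed.
#'
#' @param corpus a `corpus`; only labeled records enter the plan.
#' @param seed integer seed.
#' @return object of class `"fold_plan"`: `iterations`, a list of five
#'   `list(half1, half2)` id partitions, plus the seed.
#' @export
make_5x2_folds <- function(corpus, seed) {
  lab <- labeled_subset(corpus)
  y <- corpus_labels(lab)
  ids <- corpus_ids(lab)
  stop_if_not(sum(y) >= 2 && sum(!y) >= 2,
              "corpus too small for stratified halves: need >= 2 labeled records per class")
  iterations <- with_seed(seed, lapply(seq_len(5), function(it) {
    h1 <- character(0)
    for (cls in c(TRUE, FALSE)) {
      pool <- sample(ids[y == cls])
      h1 <- c(h1, pool[seq_len(ceiling(length(pool) / 2))])
    }
    list(half1 = sort(h1), half2 = sort(setdiff(ids, h1)))
  }))
  structure(list(iterations = iterations, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  n <- length(x$iterations[[1]]$half1) + length(x$iterations[[1]]$half2)
  cat(sprintf("<fold_plan> 5x2 cross-validation over %d labeled records (seed %d)\n",
              n, x$seed))
  invisible(x)
}

#' Cross-validated AUC and MCC for a feature-class set
#'
#' For each of the ten (iteration, half) train/test arrangements of the fold
#' plan, trains a tagger on one half (vocabulary rebuilt per fold — no test
#' leakage) and scores the other; AUC and MCC (at the configured threshold)
#' are computed per test half and averaged over the ten arrangements.
#'
#' @param corpus a labeled `corpus`.
#' @param classes non-empty set of feature classes.
#' @param plan a [make_5x2_folds()] plan over the same corpus.
#' @param config a [tagger_config()].
#' @param stopwords stop-word list.
#' @return a `"metric_pair"`: list with `auc` and `mcc`.
#' @export
cv_evaluate <- function(corpus, classes, plan, config = tagger_config(),
                        stopwords = load_stopwords()) {
  classes <- check_classes(classes)
  config <- as_tagger_config(config)
  lab <- labeled_subset(corpus)
  ids <- corpus_ids(lab)
  aucs <- numeric(0); mccs <- numeric(0)
  for (it in seq_along(plan$iterations)) {
    halves <- plan$iterations[[it]]
    for (arr in 1:2) {
      train_ids <- if (arr == 1) halves$half1 else halves$half2
      test_ids <- if (arr == 1) halves$half2 else halves$half1
      tg <- train_tagger(lab[ids %in% train_ids], classes, config, stopwords,
                         seed = derive_seed(plan$seed, it, arr))
      test <- lab[ids %in% test_ids]
      p <- predict(tg, test, type = "prob")
      y <- corpus_labels(test)
      aucs <- c(aucs, auc(p, y))
      mccs <- c(mccs, binary_metrics(binarize(p, y, config$threshold))$mcc)
    }
  }
  structure(list(auc = mean(aucs), mcc = mean(mccs)), class = "metric_pair")
}

#' The AUC-then-MCC improvement rule
#'
#' Decides which candidate feature class (if any) joins the model at a
#' forward-selection stage. A candidate is inadmissible if adding it lowers
#' either AUC or MCC below the current values (beyond the tolerance `eps`).
#' Among admissible candidates the largest AUC gain wins; when the best AUC
#' gain is within `eps` of a tie (including "no change"), the largest MCC
#' gain decides; remaining ties fall back to the canonical class order.
#' Returns `NULL` when no admissible candidate improves either metric beyond
#' `eps` — the stopping signal.
#'
#' @param current `metric_pair` of the currently included classes.
#' @param candidates named list: one `metric_pair` per candidate class (names
#'   are class names).
#' @param eps metric-comparison tolerance (>= 0).
#' @return the chosen class name, or `NULL`.
#' @export
improvement_rule <- function(current, candidates, eps = 1e-4) {
  stop_if_not(eps >= 0, "eps must be non-negative")
  if (length(candidates) == 0) return(NULL)
  # canonical enumeration order makes which.max ties deterministic
  ord <- order(match(names(candidates), feature_classes()))
  candidates <- candidates[ord]
  d_auc <- vapply(candidates, function(m) m$auc - current$auc, numeric(1))
  d_mcc <- vapply(candidates, function(m) m$mcc - current$mcc, numeric(1))
  admissible <- d_auc >= -eps & d_mcc >= -eps
  if (!any(admissible)) return(NULL)
  d_auc[!admissible] <- -Inf
  d_mcc[!admissible] <- -Inf
  best_auc <- max(d_auc)
  if (best_auc > eps) {
    tied <- admissible & d_auc >= best_auc - eps
    pick <- d_mcc
    pick[!tied] <- -Inf
    return(names(candidates)[which.max(pick)])
  }
  if (max(d_mcc) > eps) return(names(candidates)[which.max(d_mcc)])
  NULL
}

#' Forward selection over feature classes
#'
#' Greedy selection: starting from no classes (baseline AUC 0.5, MCC 0), each
#' remaining class is evaluated in combination with the already-included
#' classes under one shared 5x2 fold plan (paired comparisons across
#' candidates), and the [improvement_rule()] picks the stage winner; the
#' process stops when no candidate is both admissible and improving. The
#' resulting trace has non-decreasing AUC and MCC by construction.
#'
#' @param corpus a labeled `corpus`.
#' @param candidate_classes feature classes to consider.
#' @param seed integer seed fixing the fold plan and all fits.
#' @param config a [tagger_config()] (its `eps` is the improvement-rule
#'   tolerance).
#' @param stopwords stop-word list.
#' @return object of class `"selection_trace"`: `stages` (data frame with
#'   columns `stage`, `feature`, `auc`, `mcc`), `rejected` (classes never
#'   included), and `seed`.
#' @export
forward_select <- function(corpus, candidate_classes, seed = 1L,
                           config = tagger_config(),
                           stopwords = load_stopwords()) {
  config <- as_tagger_config(config)
  remaining <- if (length(candidate_classes)) check_classes(candidate_classes) else character(0)
  included <- character(0)
  current <- structure(list(auc = 0.5, mcc = 0), class = "metric_pair")
  stages <- data.frame(stage = integer(0), feature = character(0),
                       auc = numeric(0), mcc = numeric(0),
                       stringsAsFactors = FALSE)
  plan <- if (length(remaining)) make_5x2_folds(corpus, seed) else NULL
  while (length(remaining) > 0) {
    cand <- lapply(remaining, function(cl)
      cv_evaluate(corpus, c(included, cl), plan, config, stopwords))
    names(cand) <- remaining
    chosen <- improvement_rule(current, cand, eps = config$eps)
    if (is.null(chosen)) break
    current <- cand[[chosen]]
    included <- c(included, chosen)
    remaining <- setdiff(remaining, chosen)
    stages <- rbind(stages, data.frame(stage = nrow(stages) + 1L,
                                       feature = chosen, auc = current$auc,
                                       mcc = current$mcc,
                                       stringsAsFactors = FALSE))
    log_info(sprintf("selection stage %d: + %s (AUC %.4f, MCC %.4f)",
                     nrow(stages), chosen, current$auc, current$mcc))
  }
  structure(list(stages = stages, rejected = remaining,
                 seed = as.integer(seed)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d stages (seed %d)\n", nrow(x$stages), x$seed))
  if (nrow(x$stages)) {
    print(x$stages, row.names = FALSE)
  }
  if (length(x$rejected)) {
    cat("  never included: ", paste(x$rejected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.selection_trace <- function(x, ...) x$stages

#' Write a selection trace as TSV
#'
#' Columns `stage`, `feature`, `auc`, `mcc` — the per-stage metrics after
#' each inclusion.
#'
#' @param trace a [forward_select()] result.
#' @param path output path.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.table(trace$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
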