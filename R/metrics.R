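#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' record outscores a uniformly chosen negative one, with ties counted one
#' half. Computed from average ranks, equivalent to brute-force pairwise
#' counting.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  stop_if_not(length(scores) == length(y), "scores and labels differ in length")
  stop_if_not(any(y) && any(!y), "both classes must be present to compute AUC")
  r <- rank(scores)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binarize probabilistic scores into a confusion table
#'
#' A record is predicted positive when its score is greater than or equal to
#' the threshold (the boundary score 0.5 is positive at the default
#' threshold).
#'
#' @param scores probabilities in \[0, 1\].
#' @param labels logical (or 0/1) labels.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `"confusion_table"` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
binarize <- function(scores, labels, threshold = 0.5) {
  y <- as.logical(labels)
  stop_if_not(length(scores) == length(y), "scores and labels differ in length")
  pred <- scores >= threshold
  structure(list(tp = sum(pred & y), fp = sum(pred & !y),
                 tn = sum(!pred & !y), fn = sum(!pred & y),
                 threshold = threshold),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> tp=%d fp=%d tn=%d fn=%d (threshold %.3g)\n",
              x$tp, x$fp, x$tn, x$fn, x$threshold))
  invisible(x)
}

#' Binary metrics from a confusion table
#'
#' Standard definitions. Conventions for degenerate margins: MCC is 0 when
#' any marginal total is 0; precision/recall are 0 when their denominator is
#' 0; F1 is 0 when precision + recall is 0.
#'
#' @param ct a [binarize()] result (or a list with `tp`, `fp`, `tn`, `fn`).
#' @return named list: `mcc`, `f1`, `precision`, `recall`, `error_rate`.
#' @export
binary_metrics <- function(ct) {
  tp <- as.numeric(ct$tp); fp <- as.numeric(ct$fp)
  tn <- as.numeric(ct$tn); fn <- as.numeric(ct$fn)
  total <- tp + fp + tn + fn
  stop_if_not(total > 0, "empty confusion table")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(mcc = mcc, f1 = f1, precision = precision, recall = recall,
       error_rate = (fp + fn) / total)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability and the 0/1
#' outcome; lower is better, 0 is perfect.
#'
#' @inheritParams binarize
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(scores, labels) {
  y <- as.numeric(as.logical(labels))
  stop_if_not(length(scores) > 0, "empty input")
  stop_if_not(length(scores) == length(y), "scores and labels differ in length")
  mean((scores - y)^2)
}

#' Full evaluation report
#'
#' Binary metrics (at the given threshold) plus the probabilistic metrics AUC
#' and Brier score, the same set reported for the tagger's cross-validation
#' and test evaluations.
#'
#' @inheritParams binarize
#' @return object of class `"evaluation_report"`: `auc`, `mcc`, `f1`,
#'   `recall`, `precision`, `brier`, `error_rate`, `n`, `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  bm <- binary_metrics(binarize(scores, labels, threshold))
  structure(c(list(auc = auc(scores, labels)), bm,
              list(brier = brier(scores, labels),
                   n = length(scores), threshold = threshold)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d, threshold=%.2f\n", x$n, x$threshold))
  cat(sprintf("  AUC %.4f | MCC %.4f | F1 %.4f | P %.4f | R %.4f | Brier %.4f | error %.4f\n",
              x$auc, x$mcc, x$f1, x$precision, x$recall, x$brier, x$error_rate))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(auc = x$auc, mcc = x$mcc, f1 = x$f1, recall = x$recall,
             precision = x$precision, brier = x$brier,
             error_rate = x$error_rate, n = x$n, threshold = x$threshold)
}

#' Evaluate a tagger on a labeled corpus
#'
#' @param tagger a trained `tagger`.
#' @param corpus a `corpus`; unlabeled records are skipped.
#' @param threshold decision threshold (default: the tagger's configured
#'   threshold).
#' @return an `evaluation_report`.
#' @export
evaluate_tagger <- function(tagger, corpus, threshold = NULL) {
  lab <- labeled_subset(corpus)
  stop_if_not(length(lab) > 0, "corpus has no labeled records to evaluate on")
  p <- predict(tagger, lab, type = "prob")
  evaluate_scores(p, corpus_labels(lab),
                  threshold %||% tagger$config$threshold)
}

#' Calibration curve
#'
#' Partitions \[0, 1\] into fixed-width score bins and, per bin, reports the
#' record count, the mean predicted score, and the observed proportion of
#' positive labels — the data behind a reliability diagram. Empty bins are
#' retained with `n = 0` and `NA` proportions. Scores of exactly 1 fall in
#' the top bin.
#'
#' @inheritParams binarize
#' @param bin_width bin width; must divide 1 exactly (default 0.05).
#' @return object of class `"calibration_curve"`: a data frame with columns
#'   `lower`, `upper`, `n`, `mean_score`, `prop_positive`.
#' @export
calibration_curve <- function(scores, labels, bin_width = 0.05) {
  y <- as.logical(labels)
  stop_if_not(length(scores) == length(y), "scores and labels differ in length")
  stop_if_not(all(scores >= 0 & scores <= 1), "scores must be in [0,1]")
  nb <- 1 / bin_width
  stop_if_not(abs(nb - round(nb)) < 1e-8, "bin_width must divide 1 exactly")
  nb <- as.integer(round(nb))
  bin <- pmin(floor(scores / bin_width), nb - 1L) + 1L
  n_in <- tabulate(bin, nbins = nb)
  mean_score <- rep(NA_real_, nb)
  prop <- rep(NA_real_, nb)
  pop <- which(n_in > 0)
  mean_score[pop] <- vapply(pop, function(b) mean(scores[bin == b]), numeric(1))
  prop[pop] <- vapply(pop, function(b) mean(y[bin == b]), numeric(1))
  structure(data.frame(lower = (seq_len(nb) - 1) * bin_width,
                       upper = seq_len(nb) * bin_width,
                       n = n_in, mean_score = mean_score,
                       prop_positive = prop),
            class = c("calibration_curve", "data.frame"))
}

#' Mean absolute calibration error
#'
#' Bins the predicted scores into fixed-width bins and compares the mean
#' predicted score per bin with the mean of the reference per bin (observed
#' 0/1 labels, or exact generative posteriors when available), averaging the
#' absolute differences weighted by bin occupancy. This is the reliability-
#' diagram notion of calibration error: it isolates systematic score bias
#' from per-record estimation noise.
#'
#' @param scores predicted probabilities in \[0, 1\].
#' @param reference reference values per record: 0/1 labels or true
#'   posteriors in \[0, 1\].
#' @param bin_width bin width; must divide 1 exactly (default 0.05).
#' @return weighted mean absolute per-bin difference, in \[0, 1\].
#' @export
calibration_error <- function(scores, reference, bin_width = 0.05) {
  reference <- as.numeric(reference)
  stop_if_not(length(scores) == length(reference) && length(scores) > 0,
              "scores and reference must be equal-length and non-empty")
  stop_if_not(all(scores >= 0 & scores <= 1), "scores must be in [0,1]")
  nb <- 1 / bin_width
  stop_if_not(abs(nb - round(nb)) < 1e-8, "bin_width must divide 1 exactly")
  nb <- as.integer(round(nb))
  bin <- pmin(floor(scores / bin_width), nb - 1L) + 1L
  n_in <- tabulate(bin, nbins = nb)
  pop <- which(n_in > 0)
  diffs <- vapply(pop, function(b)
    abs(mean(scores[bin == b]) - mean(reference[bin == b])), numeric(1))
  stats::weighted.mean(diffs, n_in[pop])
}

#' Adjusted R-squared of a calibration curve
#'
#' Simple linear regression of the observed positive proportions on the mean
#' predicted scores over the populated bins; returns the adjusted R-squared
#' (1 when the proportions track the scores exactly).
#'
#' @param curve a [calibration_curve()].
#' @return adjusted R-squared (can be negative for uninformative curves).
#' @export
calibration_adjusted_r2 <- function(curve) {
  pop <- curve[curve$n > 0, , drop = FALSE]
  stop_if_not(nrow(pop) >= 3, "need at least 3 populated bins (got ", nrow(pop), ")")
  n <- nrow(pop)
  r2 <- if (stats::var(pop$prop_positive) == 0) 0 else
    summary(stats::lm(prop_positive ~ mean_score, data = pop))$r.squared
  1 - (1 - r2) * (n - 1) / (n - 2)
}

#' Per-class score histograms
#'
#' The distribution of predicted scores within the positive-label and
#' negative-label record sets, as percentages per fixed-width bin (each
#' histogram sums to 100 when its class is non-empty).
#'
#' @inheritParams calibration_curve
#' @return data frame of class `"score_histogram"` with columns `lower`,
#'   `upper`, `pct_positive`, `pct_negative`.
#' @export
score_histogram <- function(scores, labels, bin_width = 0.05) {
  y <- as.logical(labels)
  stop_if_not(all(scores >= 0 & scores <= 1), "scores must be in [0,1]")
  nb <- 1 / bin_width
  stop_if_not(abs(nb - round(nb)) < 1e-8, "bin_width must divide 1 exactly")
  nb <- as.integer(round(nb))
  bin <- pmin(floor(scores / bin_width), nb - 1L) + 1L
  pct <- function(cls) {
    cnt <- tabulate(bin[y == cls], nbins = nb)
    if (sum(cnt) == 0) rep(NA_real_, nb) else 100 * cnt / sum(cnt)
  }
  structure(data.frame(lower = (seq_len(nb) - 1) * bin_width,
                       upper = seq_len(nb) * bin_width,
                       pct_positive = pct(TRUE), pct_negative = pct(FALSE)),
            class = c("score_histogram", "data.frame"))
}

#' Agreement statistics for the extreme-disagreement review
#'
#' Summarizes a blinded manual review of the two extreme-disagreement strata:
#' records carrying the Humans MeSH term but scored below the low cutoff
#' (where the model predicts NOT-HUMAN), and records lacking the term but
#' scored above the high cutoff (model predicts HUMAN). Per stratum the
#' reviewer marked each record HUMAN, NOT_HUMAN, or UNCERTAIN; agreement is
#' the fraction of review calls matching the model's side, with UNCERTAIN
#' counted as a non-match. Overall agreement pools both strata.
#'
#' @param table a 2 x 3 matrix or data frame: rows `low` (score < low cutoff,
#'   MeSH-positive) and `high` (score > high cutoff, MeSH-negative); columns
#'   `humans`, `not_humans`, `uncertain` review counts.
#' @return named list of percentages: `low_agreement_pct`,
#'   `high_agreement_pct`, `overall_agreement_pct`.
#' @seealso [agreement_table()], [cmd_audit()]
#' @export
agreement_stats <- function(table) {
  m <- as.matrix(table)
  stop_if_not(nrow(m) == 2 && ncol(m) == 3,
              "expected a 2x3 review table (rows low/high, columns humans/not_humans/uncertain)")
  stop_if_not(all(m >= 0) && all(m == floor(m)), "review counts must be non-negative integers")
  low <- m[1, ]; high <- m[2, ]
  stop_if_not(sum(low) > 0 && sum(high) > 0, "each stratum must contain reviewed records")
  low_agree <- low[2] / sum(low)    # model says NOT-HUMAN; reviewer said not_humans
  high_agree <- high[1] / sum(high) # model says HUMAN; reviewer said humans
  overall <- (low[2] + high[1]) / (sum(low) + sum(high))
  list(low_agreement_pct = unname(100 * low_agree),
       high_agreement_pct = unname(100 * high_agree),
       overall_agreement_pct = unname(100 * overall))
}

#' Build the 2 x 3 extreme-disagreement review table
#'
#' @param low,high integer vectors of review counts
#'   `c(humans, not_humans, uncertain)` for the low-score and high-score
#'   strata.
#' @return matrix accepted by [agreement_stats()].
#' @export
agreement_table <- function(low, high) {
  m <- rbind(low = low, high = high)
  colnames(m) <- c("humans", "not_humans", "uncertain")
  m
}
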