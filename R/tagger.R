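#' Tagger configuration
#'
#' Bundles the tunable parameters shared by training, selection, and
#' evaluation. Defaults: unweighted hinge loss with `c_param = 1`; token
#' features kept at document frequency >= 2; isotonic calibration fitted on a
#' 20% internal held-out split; decision threshold 0.5; calibration-curve
#' bin width 0.05; metric-comparison tolerance `eps = 1e-4` for the forward
#' selection improvement rule.
#'
#' @param c_param SVM regularization constant (> 0).
#' @param min_df minimum document frequency for token features.
#' @param eps metric-comparison tolerance used by [improvement_rule()].
#' @param threshold probability threshold for binarizing predictions.
#' @param bin_width calibration-curve / histogram bin width.
#' @param calibrator `"isotonic"` or `"sigmoid"` (see [fit_calibration()]).
#' @param calibration_split fraction of labeled training data held out to fit
#'   the calibration map.
#' @param svm_tol,svm_max_epochs solver controls for [train_linear_svm()].
#' @return a list of class `"tagger_config"`.
#' @export
tagger_config <- function(c_param = 1, min_df = 2, eps = 1e-4, threshold = 0.5,
                          bin_width = 0.05, calibrator = c("isotonic", "sigmoid"),
                          calibration_split = 0.2, svm_tol = 0.05,
                          svm_max_epochs = 300) {
  calibrator <- match.arg(calibrator)
  stop_if_not(c_param > 0, "c_param must be positive")
  stop_if_not(is_count(min_df) && min_df >= 1, "min_df must be a positive integer")
  stop_if_not(eps >= 0, "eps must be non-negative")
  stop_if_not(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
  stop_if_not(calibration_split > 0 && calibration_split < 1,
              "calibration_split must be in (0,1)")
  structure(list(c_param = c_param, min_df = min_df, eps = eps,
                 threshold = threshold, bin_width = bin_width,
                 calibrator = calibrator, calibration_split = calibration_split,
                 svm_tol = svm_tol, svm_max_epochs = svm_max_epochs),
            class = "tagger_config")
}

as_tagger_config <- function(config) {
  if (inherits(config, "tagger_config")) return(config)
  do.call(tagger_config, config)
}

#' Train a probabilistic Humans tagger
#'
#' The end-to-end fit on a labeled corpus: build the vocabulary over the
#' requested feature classes, vectorize, z-score the numeric columns with
#' training-set statistics, hold out a stratified `calibration_split`
#' fraction, fit the linear SVM on the remainder, fit the margin-to-
#' probability calibration on the held-out margins (never on margins from
#' data the SVM saw), then refit the SVM on all labeled records and keep the
#' calibration map. Unlabeled records are ignored. MeSH descriptors are never
#' used as predictors — only title, abstract, authors, journal, and
#' pagination reach the design matrix — so the tagger applies to unindexed
#' and non-MEDLINE citations.
#'
#' @param corpus a `corpus` with at least two labeled records per class.
#' @param classes feature classes to use (default: all twelve).
#' @param config a [tagger_config()].
#' @param stopwords stop-word list for tokenization.
#' @param seed integer seed; fixes the internal split and the solver order,
#'   making training fully deterministic.
#' @param provenance free-text training-data descriptor stored in metadata.
#' @return an object of class `"tagger"`.
#' @seealso [predict.tagger()], [tag()], [save_tagger()]
#' @export
train_tagger <- function(corpus, classes = feature_classes(),
                         config = tagger_config(),
                         stopwords = load_stopwords(), seed = 1L,
                         provenance = NULL) {
  config <- as_tagger_config(config)
  classes <- check_classes(classes)
  lab <- labeled_subset(corpus)
  y <- corpus_labels(lab)
  stop_if_not(length(lab) > 0, "corpus has no labeled records")
  stop_if_not(sum(y) >= 2 && sum(!y) >= 2,
              "need at least 2 labeled records per class (got ",
              sum(y), " positive, ", sum(!y), " negative)")
  vocab <- build_vocabulary(lab, classes, min_df = config$min_df,
                            stopwords = stopwords)
  stop_if_not(length(vocab) > 0, "vocabulary is empty; lower min_df or add classes")
  X <- vectorize(lab, vocab, stopwords)
  std <- fit_standardization(X, vocab)
  X <- apply_standardization(X, std)

  n <- nrow(X)
  cal_idx <- with_seed(derive_seed(seed, 1), stratified_sample(y, config$calibration_split))
  fit_idx <- setdiff(seq_len(n), cal_idx)
  svm_part <- train_linear_svm(X[fit_idx, , drop = FALSE], y[fit_idx],
                               c_param = config$c_param, tol = config$svm_tol,
                               max_epochs = config$svm_max_epochs,
                               seed = derive_seed(seed, 2))
  cal_margins <- margin_scores(svm_part, X[cal_idx, , drop = FALSE])
  calibration <- fit_calibration(cal_margins, y[cal_idx],
                                 method = config$calibrator)
  model <- train_linear_svm(X, y, c_param = config$c_param,
                            tol = config$svm_tol,
                            max_epochs = config$svm_max_epochs,
                            seed = derive_seed(seed, 3))
  structure(list(classes = classes, vocabulary = vocab, model = model,
                 calibration = calibration, standardization = std,
                 stopwords = as.character(stopwords), config = config,
                 metadata = list(seed = as.integer(seed), n_train = n,
                                 prevalence = mean(y),
                                 provenance = provenance %||% corpus$provenance)),
            class = "tagger")
}

# indices of a stratified fraction of each label stratum (at least one record
# per class on both sides of the split)
stratified_sample <- function(y, frac) {
  idx <- integer(0)
  for (cls in c(TRUE, FALSE)) {
    pool <- which(y == cls)
    k <- min(length(pool) - 1L, max(1L, round(frac * length(pool))))
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}

fit_standardization <- function(X, vocab) {
  num_cols <- vocab$tokens[sub(":.*$", "", vocab$tokens) %in% NUMERIC_CLASSES]
  if (length(num_cols) == 0) {
    return(list(cols = character(0), mean = numeric(0), sd = numeric(0)))
  }
  sub <- as.matrix(X[, num_cols, drop = FALSE])
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(cols = num_cols, mean = unname(mu), sd = unname(sdv))
}

apply_standardization <- function(X, std) {
  if (length(std$cols) == 0) return(X)
  j <- match(std$cols, colnames(X))
  for (k in seq_along(j)) {
    X[, j[k]] <- (X[, j[k]] - std$mean[k]) / std$sd[k]
  }
  X
}

#' @export
print.tagger <- function(x, ...) {
  cat(sprintf("<tagger> %d feature classes, %d columns, trained on %d records (prevalence %.3f)\n",
              length(x$classes), length(x$vocabulary), x$metadata$n_train,
              x$metadata$prevalence))
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat(sprintf("  calibration: %s; C=%g; seed=%d\n",
              x$calibration$method, x$model$c_param, x$metadata$seed))
  invisible(x)
}

#' @export
summary.tagger <- function(object, ...) {
  w <- object$model$weights
  top <- sort(w, decreasing = TRUE)
  cat(sprintf("Probabilistic Humans tagger\n"))
  print(object)
  cat("  strongest positive features:\n")
  for (nm in names(utils::head(top, 5))) cat(sprintf("    %+8.4f  %s\n", w[nm], nm))
  cat("  strongest negative features:\n")
  for (nm in names(utils::tail(top, 5))) cat(sprintf("    %+8.4f  %s\n", w[nm], nm))
  invisible(object)
}

#' @export
coef.tagger <- function(object, ...) {
  c(object$model$weights, `(bias)` = object$model$bias)
}

#' Score citations with a trained tagger
#'
#' @param object a [train_tagger()] fit.
#' @param corpus a `corpus` of records to score (labels and MeSH optional and
#'   never used).
#' @param type `"prob"` for calibrated probabilities in \[0, 1\] (default),
#'   `"margin"` for raw signed margins, `"class"` for the thresholded
#'   logical prediction.
#' @param threshold threshold for `type = "class"` (default: the training
#'   configuration's threshold; a prediction is positive when score >=
#'   threshold).
#' @param ... unused.
#' @return numeric (or logical) vector named by record id, in corpus order.
#' @export
predict.tagger <- function(object, corpus, type = c("prob", "margin", "class"),
                           threshold = NULL, ...) {
  type <- match.arg(type)
  X <- vectorize(corpus, object$vocabulary,
                 structure(object$stopwords, class = "stopwords"))
  X <- apply_standardization(X, object$standardization)
  m <- margin_scores(object$model, X)
  names(m) <- corpus_ids(corpus)
  if (type == "margin") return(m)
  p <- calibrate(object$calibration, m)
  names(p) <- corpus_ids(corpus)
  if (type == "prob") return(p)
  p >= (threshold %||% object$config$threshold)
}

#' @rdname predict.tagger
#' @param tagger a trained tagger.
#' @export
tag <- function(tagger, corpus) predict(tagger, corpus, type = "prob")

TAGGER_FORMAT_VERSION <- "1"

#' Save / load a tagger
#'
#' Serializes the complete tagger (feature classes, vocabulary, weights,
#' calibration map, standardization statistics, stop words, configuration,
#' metadata) to a single JSON file. Floating-point values are stored with 17
#' significant digits so a round trip reproduces bit-identical predictions.
#'
#' @param tagger a trained `tagger`.
#' @param path file path of the tagger archive (JSON).
#' @return `load_tagger()` returns the reconstructed `tagger`;
#'   `save_tagger()` returns `path` invisibly.
#' @export
save_tagger <- function(tagger, path) {
  cal <- tagger$calibration
  cal_out <- if (cal$method == "isotonic") {
    list(method = "isotonic", eps = fmt_num(cal$eps),
         knots_x = fmt_num(cal$knots_x), knots_y = fmt_num(cal$knots_y))
  } else {
    list(method = "sigmoid", eps = fmt_num(cal$eps),
         A = fmt_num(cal$A), B = fmt_num(cal$B))
  }
  obj <- list(
    format_version = TAGGER_FORMAT_VERSION,
    package = "humtag",
    classes = tagger$classes,
    vocabulary = list(tokens = tagger$vocabulary$tokens,
                      min_df = tagger$vocabulary$min_df),
    model = list(weights = fmt_num(unname(tagger$model$weights)),
                 bias = fmt_num(tagger$model$bias),
                 c_param = fmt_num(tagger$model$c_param)),
    calibration = cal_out,
    standardization = list(cols = tagger$standardization$cols,
                           mean = fmt_num(tagger$standardization$mean),
                           sd = fmt_num(tagger$standardization$sd)),
    stopwords = tagger$stopwords,
    config = unclass(tagger$config),
    metadata = tagger$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot read tagger archive: ",
                                           conditionMessage(e), call. = FALSE))
  ver <- obj$format_version %||% "<missing>"
  stop_if_not(identical(ver, TAGGER_FORMAT_VERSION),
              "tagger archive format version ", ver,
              " not supported (expected ", TAGGER_FORMAT_VERSION, ")")
  toks <- as.character(obj$vocabulary$tokens %||% character(0))
  vocab <- structure(list(tokens = toks,
                          index = stats::setNames(seq_along(toks), toks),
                          classes = as.character(obj$classes),
                          min_df = as.integer(obj$vocabulary$min_df)),
                     class = "vocabulary")
  model <- structure(list(weights = stats::setNames(as.numeric(obj$model$weights), toks),
                          bias = as.numeric(obj$model$bias),
                          c_param = as.numeric(obj$model$c_param),
                          epochs = NA_integer_, converged = NA),
                     class = "linear_model")
  cal <- obj$calibration
  calibration <- if (identical(cal$method, "isotonic")) {
    structure(list(method = "isotonic", eps = as.numeric(cal$eps),
                   knots_x = as.numeric(cal$knots_x),
                   knots_y = as.numeric(cal$knots_y)),
              class = "calibration_map")
  } else {
    structure(list(method = "sigmoid", eps = as.numeric(cal$eps),
                   A = as.numeric(cal$A), B = as.numeric(cal$B)),
              class = "calibration_map")
  }
  std <- list(cols = as.character(obj$standardization$cols %||% character(0)),
              mean = as.numeric(obj$standardization$mean %||% numeric(0)),
              sd = as.numeric(obj$standardization$sd %||% numeric(0)))
  cfg <- obj$config
  config <- tagger_config(c_param = cfg$c_param, min_df = cfg$min_df,
                          eps = cfg$eps, threshold = cfg$threshold,
                          bin_width = cfg$bin_width, calibrator = cfg$calibrator,
                          calibration_split = cfg$calibration_split,
                          svm_tol = cfg$svm_tol, svm_max_epochs = cfg$svm_max_epochs)
  structure(list(classes = as.character(obj$classes), vocabulary = vocab,
                 model = model, calibration = calibration,
                 standardization = std,
                 stopwords = as.character(obj$stopwords %||% character(0)),
                 config = config,
                 metadata = list(seed = as.integer(obj$metadata$seed),
                                 n_train = as.integer(obj$metadata$n_train),
                                 prevalence = as.numeric(obj$metadata$prevalence),
                                 provenance = obj$metadata$provenance)),
            class = "tagger")
}
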