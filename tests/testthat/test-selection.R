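small_labeled <- function(n = 120, seed = 2) {
  generate_corpus(generator_params(n_records = n, separation = 1.5,
                                   vocab_abstract = 100, seed = seed))$corpus
}

test_that("5x2 fold plans are stratified partitions, reproducible from seed", {
  corp <- small_labeled(100)
  p1 <- make_5x2_folds(corp, seed = 7)
  p2 <- make_5x2_folds(corp, seed = 7)
  expect_identical(p1, p2)
  expect_length(p1$iterations, 5)
  ids <- corpus_ids(corp)
  y <- setNames(corpus_labels(corp), ids)
  prev <- mean(y)
  for (it in p1$iterations) {
    expect_setequal(c(it$half1, it$half2), ids)
    expect_length(intersect(it$half1, it$half2), 0)
    for (half in list(it$half1, it$half2)) {
      # stratification: positive count within 1 record of proportionality
      expect_lte(abs(sum(y[half]) - prev * length(half)), 1)
    }
  }
  # different seeds give different plans
  expect_false(identical(p1, make_5x2_folds(corp, seed = 8)))
})

test_that("fold plans require both classes to be splittable", {
  tiny <- corpus(id = c("a", "b", "c"), title = c("x", "y", "z"),
                 label = c(TRUE, TRUE, FALSE))
  expect_error(make_5x2_folds(tiny, 1), "too small")
})

test_that("the improvement rule follows AUC first, MCC on ties, never a decrease", {
  mp <- function(a, m) structure(list(auc = a, mcc = m), class = "metric_pair")
  current <- mp(0.955, 0.771)
  # a clear AUC gain is chosen (the first stage-2 style decision)
  expect_identical(improvement_rule(current, list(ABSTRACT_UNIGRAM = mp(0.967, 0.813))),
                   "ABSTRACT_UNIGRAM")
  # equal AUC gains: the larger MCC gain decides
  cands <- list(TITLE_UNIGRAM = mp(0.960, 0.781), JOURNAL_NAME = mp(0.960, 0.791))
  expect_identical(improvement_rule(current, cands), "JOURNAL_NAME")
  # an AUC gain is inadmissible if MCC decreases
  expect_null(improvement_rule(current, list(TITLE_BIGRAM = mp(0.965, 0.721))))
  # no admissible improvement at all
  expect_null(improvement_rule(current, list(TITLE_BIGRAM = mp(0.955, 0.771))))
  expect_null(improvement_rule(current, list()))
  # pure MCC improvement with unchanged AUC is accepted
  expect_identical(improvement_rule(current, list(AUTHOR_NAMES = mp(0.955, 0.801))),
                   "AUTHOR_NAMES")
  # exact ties on both metrics fall back to canonical class order
  tie <- list(ABSTRACT_UNIGRAM = mp(0.97, 0.80), TITLE_UNIGRAM = mp(0.97, 0.80))
  expect_identical(improvement_rule(current, tie), "TITLE_UNIGRAM")
})

test_that("cross-validation is deterministic and detects planted signal", {
  corp <- small_labeled(400, seed = 5)
  plan <- make_5x2_folds(corp, seed = 5)
  m1 <- cv_evaluate(corp, "TITLE_UNIGRAM", plan)
  m2 <- cv_evaluate(corp, "TITLE_UNIGRAM", plan)
  expect_identical(m1, m2)
  expect_gt(m1$auc, 0.6)  # titles carry the planted signal
})

test_that("a label-independent feature class scores chance-level AUC", {
  gen <- generate_corpus(generator_params(n_records = 2000, separation = 0,
                                          vocab_title = 150, seed = 9))
  plan <- make_5x2_folds(gen$corpus, seed = 9)
  m <- cv_evaluate(gen$corpus, "TITLE_UNIGRAM", plan)
  expect_lt(abs(m$auc - 0.5), 0.05)
})

test_that("forward selection returns an empty trace for no candidates", {
  corp <- small_labeled(100)
  tr <- forward_select(corp, character(0), seed = 1)
  expect_identical(nrow(tr$stages), 0L)
})

test_that("forward selection is deterministic and its trace is monotone", {
  corp <- small_labeled(300, seed = 4)
  t1 <- suppressMessages(forward_select(corp, c("TITLE_UNIGRAM", "JOURNAL_NAME"),
                                        seed = 4))
  t2 <- suppressMessages(forward_select(corp, c("TITLE_UNIGRAM", "JOURNAL_NAME"),
                                        seed = 4))
  expect_identical(t1$stages, t2$stages)
  if (nrow(t1$stages) > 1) {
    expect_true(all(diff(t1$stages$auc) >= -1e-12))
    expect_true(all(diff(t1$stages$mcc) >= -1e-12))
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_trace(t1, path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("stage", "feature", "auc", "mcc"))
})
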