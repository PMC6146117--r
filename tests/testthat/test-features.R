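test_that("tokenization splits on whitespace and punctuation, lower-cases, keeps order", {
  expect_identical(tokenize("Human T-cell responses.", no_stopwords()),
                   c("human", "t", "cell", "responses"))
  expect_identical(tokenize("", no_stopwords()), character(0))
  expect_identical(tokenize(NA_character_, no_stopwords()), character(0))
  sw <- structure(c("the", "of", "and"), class = "stopwords")
  expect_identical(tokenize("The of and", sw), character(0))
  expect_identical(tokenize("THE cell OF line", sw), c("cell", "line"))
})

test_that("tokenize is idempotent on its own space-joined output", {
  set.seed(7)
  sw <- load_stopwords()
  texts <- c("Randomized, placebo-controlled trial (n=200): outcomes.",
             "A study of IL-6/TNF-alpha signalling in T-cells",
             replicate(20, paste(sample(c("Cell", "p53", "human", "the", "of",
                                          "mice;", "(2020)", "trial."),
                                        12, replace = TRUE), collapse = " ")))
  for (tx in texts) {
    once <- tokenize(tx, sw)
    expect_identical(tokenize(paste(once, collapse = " "), sw), once)
  }
})

test_that("n-grams are contiguous windows joined with underscores", {
  expect_identical(sort(ngrams(c("a", "b", "c"), 2)), c("a_b", "b_c"))
  expect_identical(ngrams(c("a", "b", "c"), 1), c("a", "b", "c"))
  expect_identical(ngrams("a", 3), character(0))
  expect_identical(ngrams(character(0), 1), character(0))
  # multiplicities retained
  expect_identical(table(ngrams(c("x", "y", "x", "y"), 2)),
                   table(c("x_y", "y_x", "x_y")))
})

test_that("count features follow the stated definitions", {
  cf <- count_features("5 patients; 3 controls.")
  expect_identical(cf$word_count, 4L)
  expect_identical(cf$punct_count, 2L)
  expect_identical(cf$numeric_count, 2L)
  expect_identical(unlist(count_features("")), c(word_count = 0L,
                                                 punct_count = 0L,
                                                 numeric_count = 0L))
  cf2 <- count_features("p53")
  expect_identical(cf2$word_count, 1L)
  expect_identical(cf2$numeric_count, 1L)
  expect_identical(count_features(NA_character_)$word_count, 0L)
})

test_that("page counts expand MEDLINE pagination shorthand", {
  expect_identical(page_count("334-41"), 8L)
  expect_identical(page_count("334-341"), 8L)
  expect_identical(page_count("12"), 1L)
  expect_identical(page_count("e0123456"), 0L)
  expect_identical(page_count(NA_character_), 0L)
  expect_identical(page_count("100-5, 110"), 6L)
  expect_warning(pc <- page_count("ix-xii"), "unparseable")
  expect_identical(pc, 0L)
})

test_that("bibliographic features tokenize authors and journals", {
  rec <- corpus(id = "x", title = "t", authors = list(
    data.frame(last = "Smith", initials = "JA")),
    journal = "The  Lancet", pagination = "334-41")
  f <- bibliographic_features(rec)
  expect_identical(f[["AUTHOR_NAMES:smith_ja"]], 1)
  expect_identical(f[["AUTHOR_COUNT:"]], 1)
  expect_identical(f[["JOURNAL_NAME:the lancet"]], 1)
  expect_identical(f[["PAGE_COUNT:"]], 8)
  # multi-word last names collapse whitespace
  rec2 <- corpus(id = "y", title = "t", authors = list(
    data.frame(last = "van der Berg", initials = "C")))
  expect_true("AUTHOR_NAMES:van_der_berg_c" %in% names(bibliographic_features(rec2)))
})

test_that("vocabulary respects min_df, fixed numeric columns, and class order", {
  corp <- toy_corpus()
  v1 <- build_vocabulary(corp, "TITLE_UNIGRAM", min_df = 1, stopwords = no_stopwords())
  expect_true(all(startsWith(v1$tokens, "TITLE_UNIGRAM:")))
  # 'liver' appears in one record only; min_df = 2 prunes it
  expect_true("TITLE_UNIGRAM:liver" %in% v1$tokens)
  v2 <- build_vocabulary(corp, "TITLE_UNIGRAM", min_df = 2, stopwords = no_stopwords())
  expect_false("TITLE_UNIGRAM:liver" %in% v2$tokens)
  expect_true("TITLE_UNIGRAM:human" %in% v2$tokens)
  # numeric classes contribute fixed columns regardless of min_df
  v3 <- build_vocabulary(corp, c("TITLE_COUNTS", "PAGE_COUNT"), min_df = 100,
                         stopwords = no_stopwords())
  expect_identical(v3$tokens, c("TITLE_COUNTS:word_count", "TITLE_COUNTS:punct_count",
                                "TITLE_COUNTS:numeric_count", "PAGE_COUNT:"))
  # dense 1..n index, deterministic across runs, canonical class order
  v4a <- build_vocabulary(corp, c("ABSTRACT_UNIGRAM", "TITLE_UNIGRAM"),
                          min_df = 1, stopwords = no_stopwords())
  v4b <- build_vocabulary(corp, c("TITLE_UNIGRAM", "ABSTRACT_UNIGRAM"),
                          min_df = 1, stopwords = no_stopwords())
  expect_identical(v4a$tokens, v4b$tokens)
  expect_identical(unname(v4a$index), seq_along(v4a$tokens))
  expect_true(which(v4a$tokens == "TITLE_UNIGRAM:human") <
                which(v4a$tokens == "ABSTRACT_UNIGRAM:patients"))
  expect_error(build_vocabulary(corp, character(0)), "at least one")
})

test_that("vectorization produces aligned raw counts in a closed vocabulary", {
  corp <- toy_corpus()
  vocab <- build_vocabulary(corp, c("TITLE_UNIGRAM", "ABSTRACT_UNIGRAM"),
                            min_df = 1, stopwords = no_stopwords())
  X <- vectorize(corp, vocab, no_stopwords())
  expect_identical(dim(X), c(6L, length(vocab)))
  expect_identical(rownames(X), corpus_ids(corp))
  # absent abstract -> all-zero ABSTRACT_* columns
  acols <- grep("^ABSTRACT_", colnames(X))
  expect_true(all(X[3, acols] == 0))
  # duplicate title token counts with multiplicity
  dup <- corpus(id = "d", title = "cell cell line")
  Xd <- vectorize(dup, build_vocabulary(dup, "TITLE_UNIGRAM", 1, no_stopwords()),
                  no_stopwords())
  expect_identical(as.numeric(Xd[1, "TITLE_UNIGRAM:cell"]), 2)
  # unseen test-time tokens have no effect
  unseen <- corpus(id = "u", title = "zebrafish embryo")
  Xu <- vectorize(unseen, vocab, no_stopwords())
  expect_identical(sum(Xu), 0)
  # permuting records permutes rows identically
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  Xp <- vectorize(corp[perm], vocab, no_stopwords())
  expect_identical(as.matrix(Xp), as.matrix(X)[perm, ])
})

test_that("no token meeting min_df is lost between vocabulary and matrix", {
  corp <- toy_corpus()
  sw <- no_stopwords()
  vocab <- build_vocabulary(corp, "TITLE_UNIGRAM", min_df = 2, stopwords = sw)
  X <- vectorize(corp, vocab, sw)
  for (tok in vocab$tokens) {
    word <- sub("^TITLE_UNIGRAM:", "", tok)
    manual <- vapply(corp$records$title,
                     function(t) sum(tokenize(t, sw) == word), numeric(1))
    expect_identical(as.numeric(X[, tok]), unname(manual))
  }
})

test_that("title word count bounds the unigram token count", {
  gen <- generate_corpus(generator_params(n_records = 200, seed = 3))
  sw <- load_stopwords()
  wc <- count_features(gen$corpus$records$title)$word_count
  ntok <- lengths(tokenize(gen$corpus$records$title, sw))
  expect_true(all(wc >= ntok))
})
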