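test_that("PubMed XML articles map field-by-field onto citation records", {
  corp <- read_pubmed_xml(pubmed_xml_fixture())
  expect_s3_class(corp, "corpus")
  expect_length(corp, 2)
  rec <- corp$records
  expect_identical(rec$id, c("101", "102"))
  expect_identical(rec$title[1], "Human T-cell responses.")
  expect_identical(rec$abstract[1], "First part. Second part.")
  expect_identical(rec$authors[[1]]$last, c("Smith", "Doe"))
  expect_identical(rec$authors[[1]]$initials, c("JA", "B"))
  expect_identical(rec$journal[1], "Journal of Testing")
  expect_identical(rec$pagination[1], "334-41")
  expect_identical(rec$year[1], 2001L)
  expect_identical(rec$mesh_terms[[1]], c("Humans", "Female"))
  expect_true(rec$label[1])
  # second article: no abstract element -> absent, Mice-only MeSH -> negative
  expect_true(is.na(rec$abstract[2]))
  expect_true(is.na(rec$pagination[2]))
  expect_false(rec$label[2])
})

test_that("articles without a title are skipped with a warning", {
  xml <- sub("<ArticleTitle>Knockout mice protocols</ArticleTitle>", "",
             pubmed_xml_fixture(), fixed = TRUE)
  expect_warning(corp <- read_pubmed_xml(xml), "no title")
  expect_length(corp, 1)
  expect_identical(corpus_ids(corp), "101")
})

test_that("truncated XML fails closed with no partial corpus", {
  broken <- substr(pubmed_xml_fixture(), 1, 400)
  expect_error(read_pubmed_xml(broken), "malformed")
})

test_that("citation table round-trips a corpus field-for-field", {
  corp <- read_pubmed_xml(pubmed_xml_fixture())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_citation_table(corp, path)
  back <- read_citation_table(path)
  expect_identical(back$records$id, corp$records$id)
  expect_identical(back$records$title, corp$records$title)
  expect_identical(back$records$abstract, corp$records$abstract)
  expect_identical(back$records$authors, corp$records$authors)
  expect_identical(back$records$journal, corp$records$journal)
  expect_identical(back$records$pagination, corp$records$pagination)
  expect_identical(back$records$year, corp$records$year)
  expect_identical(back$records$mesh_terms, corp$records$mesh_terms)
  expect_identical(back$records$label, corp$records$label)
  # deterministic ingestion: a second write of the re-read corpus is
  # byte-identical
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_citation_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("citation table validates ids and accepts direct labels", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"title":"no id here"}'), path)
  expect_error(read_citation_table(path), "missing 'id'")
  writeLines(c('{"id":"a","title":"x"}', '{"id":"a","title":"y"}'), path)
  expect_error(read_citation_table(path), "duplicate ids.*a")
  # label without mesh_terms is legitimate (synthetic corpora)
  writeLines('{"id":"s1","title":"x","label":true}', path)
  corp <- read_citation_table(path)
  expect_true(corp$records$label[1])
  expect_null(corp$records$mesh_terms[[1]])
})

test_that("reference label keys on the Humans descriptor only", {
  expect_true(reference_label(list(c("Humans", "Female")))[1])
  expect_false(reference_label(list("Mice"))[1])
  expect_true(is.na(reference_label(list(NULL))[1]))
  # whitespace around the descriptor is tolerated; case is not
  expect_true(reference_label(list(" Humans "))[1])
  expect_false(reference_label(list("humans"))[1])
  expect_true(reference_label(list("D006801"))[1])
})

test_that("corpus construction enforces unique non-empty ids", {
  expect_error(corpus(id = c("a", "a"), title = c("x", "y")), "duplicate")
  expect_error(corpus(id = c("", "b"), title = c("x", "y")), "non-empty")
})

test_that("stop-word lists are lower-cased, deduplicated, comment-aware", {
  path <- withr::local_tempfile()
  writeLines(c("The", "of", "of", "", "# a comment", "AND"), path)
  sw <- load_stopwords(path)
  expect_setequal(as.character(sw), c("the", "of", "and"))
  writeLines(character(0), path)
  expect_warning(empty <- load_stopwords(path), "empty")
  expect_length(empty, 0)
})

test_that("the bundled stop-word list loads with one entry per distinct token", {
  sw <- load_stopwords()
  raw <- readLines(system.file("extdata", "stopwords_english.txt",
                               package = "humtag"))
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  expect_length(sw, length(unique(tolower(raw))))
  expect_true("the" %in% sw)
  expect_false(any(grepl("\\s", sw)))
})

test_that("label prevalence matches the generator's setting within binomial error", {
  gen <- generate_corpus(generator_params(n_records = 10000, seed = 42))
  y <- corpus_labels(gen$corpus)
  se <- sqrt(0.65 * 0.35 / 10000)
  expect_lt(abs(mean(y) - 0.65), 3 * se)
})
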