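#' Feature classes
#'
#' Features are organised into classes, each produced by one extractor: the
#' class (not the individual token) is the unit of forward selection. The
#' twelve classes are uni/bi/trigrams over the tokenized title and abstract,
#' the per-field count triplets (word count, punctuation-symbol count,
#' digit-containing-token count), author name tokens, author count, journal
#' name, and page count. The order returned here is the canonical enumeration
#' order and is the deterministic tie-break order during selection.
#'
#' @return character vector of the twelve class names in canonical order.
#' @export
feature_classes <- function() {
  c("TITLE_UNIGRAM", "TITLE_BIGRAM", "TITLE_TRIGRAM",
    "ABSTRACT_UNIGRAM", "ABSTRACT_BIGRAM", "ABSTRACT_TRIGRAM",
    "TITLE_COUNTS", "ABSTRACT_COUNTS",
    "AUTHOR_NAMES", "AUTHOR_COUNT", "JOURNAL_NAME", "PAGE_COUNT")
}

# classes whose columns hold raw numeric values (z-scored at training time)
# rather than token counts
NUMERIC_CLASSES <- c("TITLE_COUNTS", "ABSTRACT_COUNTS", "AUTHOR_COUNT", "PAGE_COUNT")

numeric_class_columns <- function(class) {
  switch(class,
    TITLE_COUNTS = paste0("TITLE_COUNTS:", c("word_count", "punct_count", "numeric_count")),
    ABSTRACT_COUNTS = paste0("ABSTRACT_COUNTS:", c("word_count", "punct_count", "numeric_count")),
    AUTHOR_COUNT = "AUTHOR_COUNT:",
    PAGE_COUNT = "PAGE_COUNT:",
    stop("not a numeric feature class: ", class, call. = FALSE))
}

check_classes <- function(classes) {
  stop_if_not(length(classes) > 0, "at least one feature class is required")
  bad <- setdiff(classes, feature_classes())
  stop_if_not(length(bad) == 0, "unknown feature class: ", paste(bad, collapse = ", "))
  # canonical enumeration order, duplicates dropped
  intersect(feature_classes(), classes)
}

# ASCII punctuation: the splitting alphabet for tokenization and the
# characters counted by punct_count.
ASCII_PUNCT <- "!\"#$%&'()*+,-./:;<=>?@[\\]^_`{|}~"
SPLIT_REGEX <- "[\\s!\"#$%&'()*+,./:;<=>?@\\[\\\\\\]^_`{|}~-]+"
PUNCT_REGEX <- "[!\"#$%&'()*+,./:;<=>?@\\[\\\\\\]^_`{|}~-]"

#' Tokenize citation text
#'
#' Splits on any whitespace or ASCII punctuation character, lower-cases,
#' removes stop words, and drops empty tokens. No stemming is applied and
#' token order is preserved.
#'
#' @param text character vector; `NA` is treated as empty text.
#' @param stopwords a [load_stopwords()] list, or `NULL` for none.
#' @return a list with one character vector of tokens per input element (a
#'   bare character vector if `text` has length one).
#' @export
tokenize <- function(text, stopwords = NULL) {
  one <- length(text) == 1
  text <- as.character(text)
  text[is.na(text)] <- ""
  parts <- strsplit(tolower(text), SPLIT_REGEX, perl = TRUE)
  out <- lapply(parts, function(tok) {
    tok <- tok[nzchar(tok)]
    if (!is.null(stopwords) && length(stopwords)) tok <- tok[!(tok %in% stopwords)]
    tok
  })
  if (one) out[[1]] else out
}

#' Contiguous n-grams over a token sequence
#'
#' Windows of `n` consecutive post-stop-word tokens joined with `"_"`.
#' Multiplicities are retained: the returned vector has one entry per window.
#'
#' @param tokens character vector of tokens.
#' @param n window length (1, 2, or 3 in this package's feature classes).
#' @return character vector of n-grams (empty when the sequence is shorter
#'   than `n`).
#' @export
ngrams <- function(tokens, n) {
  stop_if_not(is_count(n) && n >= 1, "n must be a positive integer")
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1) return(tokens)
  m <- L - n + 1
  parts <- lapply(seq_len(n), function(k) tokens[k:(k + m - 1)])
  do.call(paste, c(parts, sep = "_"))
}

#' Count features of a text field
#'
#' `word_count` counts whitespace-delimited tokens (before punctuation
#' splitting); `punct_count` counts ASCII punctuation characters;
#' `numeric_count` counts whitespace-delimited tokens containing at least one
#' digit. All three are zero for absent text.
#'
#' @param text character vector.
#' @return data frame with columns `word_count`, `punct_count`,
#'   `numeric_count`, one row per input element.
#' @export
count_features <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  words <- strsplit(text, "\\s+", perl = TRUE)
  words <- lapply(words, function(w) w[nzchar(w)])
  data.frame(
    word_count = lengths(words),
    punct_count = vapply(text, function(s)
      nchar(gsub(PUNCT_REGEX, "", s, perl = TRUE)) * -1L + nchar(s), integer(1),
      USE.NAMES = FALSE),
    numeric_count = vapply(words, function(w) sum(grepl("[0-9]", w)), integer(1))
  )
}

#' Page count from a MEDLINE pagination string
#'
#' Expands MEDLINE shorthand: `"334-41"` means pages 334 to 341, hence 8
#' pages; a single page (`"12"`) counts 1; electronic pagination
#' (`"e0123456"`) and unparseable strings count 0 (the latter with a
#' warning). Only the first comma/semicolon-separated segment is used.
#'
#' @param pagination character vector of raw pagination strings.
#' @return integer vector of page counts.
#' @export
page_count <- function(pagination) {
  vapply(as.character(pagination), function(p) {
    if (is.na(p) || !nzchar(trimws(p))) return(0L)
    seg <- trimws(strsplit(p, "[,;]")[[1]][1])
    if (grepl("^[Ee]\\S*\\d", seg)) return(0L)  # electronic article id
    m <- regmatches(seg, regexec("^(\\d+)\\s*-\\s*(\\d+)$", seg))[[1]]
    if (length(m) == 3) {
      a <- m[2]; b <- m[3]
      if (nchar(b) < nchar(a)) b <- paste0(substr(a, 1, nchar(a) - nchar(b)), b)
      d <- as.numeric(b) - as.numeric(a) + 1
      return(if (d >= 1) as.integer(d) else 0L)
    }
    if (grepl("^\\d+$", seg)) return(1L)
    warning("unparseable pagination '", p, "'; page count set to 0", call. = FALSE)
    0L
  }, integer(1), USE.NAMES = FALSE)
}

author_tokens <- function(author_table) {
  if (nrow(author_table) == 0) return(character(0))
  last <- gsub("\\s+", "_", trimws(tolower(author_table$last)))
  ini <- gsub("\\s+", "_", trimws(tolower(author_table$initials)))
  ifelse(nzchar(ini), paste(last, ini, sep = "_"), last)
}

#' Bibliographic features of one record
#'
#' One token per author (`"lastname_initials"`, lower-cased, whitespace
#' collapsed), the author count, the journal name as a single categorical
#' token, and the page count from the pagination string.
#'
#' @param record a one-record `corpus` (or a `corpus`; only the first record
#'   is used).
#' @return named numeric vector of class-qualified features.
#' @export
bibliographic_features <- function(record) {
  rec <- record$records[1, , drop = FALSE]
  au <- author_tokens(rec$authors[[1]])
  out <- numeric(0)
  if (length(au)) {
    tab <- table(au)
    out <- stats::setNames(as.numeric(tab), paste0("AUTHOR_NAMES:", names(tab)))
  }
  out <- c(out, stats::setNames(nrow(rec$authors[[1]]), "AUTHOR_COUNT:"))
  if (!is.na(rec$journal)) {
    jt <- journal_token(rec$journal)
    out <- c(out, stats::setNames(1, paste0("JOURNAL_NAME:", jt)))
  }
  c(out, stats::setNames(page_count(rec$pagination), "PAGE_COUNT:"))
}

journal_token <- function(journal) gsub("\\s+", " ", trimws(tolower(journal)))

# (row, token) pairs for one token-valued feature class over a whole corpus
class_token_pairs <- function(corpus, class, stopwords) {
  rec <- corpus$records
  n <- nrow(rec)
  grams_of <- function(text, k) {
    toks <- tokenize(text, stopwords)
    if (n == 1) toks <- list(toks)
    lapply(toks, ngrams, n = k)
  }
  toklist <- switch(class,
    TITLE_UNIGRAM = grams_of(rec$title, 1),
    TITLE_BIGRAM = grams_of(rec$title, 2),
    TITLE_TRIGRAM = grams_of(rec$title, 3),
    ABSTRACT_UNIGRAM = grams_of(rec$abstract, 1),
    ABSTRACT_BIGRAM = grams_of(rec$abstract, 2),
    ABSTRACT_TRIGRAM = grams_of(rec$abstract, 3),
    AUTHOR_NAMES = lapply(rec$authors, author_tokens),
    JOURNAL_NAME = lapply(rec$journal, function(j)
      if (is.na(j)) character(0) else journal_token(j)),
    stop("not a token feature class: ", class, call. = FALSE))
  data.frame(row = rep.int(seq_len(n), lengths(toklist)),
             token = unlist(toklist, use.names = FALSE) %||% character(0),
             stringsAsFactors = FALSE)
}

# per-record values for one numeric feature class, columns as in
# numeric_class_columns()
class_numeric_values <- function(corpus, class) {
  rec <- corpus$records
  m <- switch(class,
    TITLE_COUNTS = as.matrix(count_features(rec$title)),
    ABSTRACT_COUNTS = as.matrix(count_features(rec$abstract)),
    AUTHOR_COUNT = matrix(vapply(rec$authors, nrow, integer(1)), ncol = 1),
    PAGE_COUNT = matrix(page_count(rec$pagination), ncol = 1),
    stop("not a numeric feature class: ", class, call. = FALSE))
  colnames(m) <- numeric_class_columns(class)
  m
}

#' Build a vocabulary over feature classes
#'
#' Collects every class-qualified token (e.g. `"ABSTRACT_BIGRAM:cell_line"`)
#' from the requested classes that occurs in at least `min_df` distinct
#' records. Numeric classes contribute their fixed columns regardless of
#' `min_df`. Column order is deterministic: canonical class order, then
#' lexicographic (C locale) within class.
#'
#' @param corpus a non-empty `corpus`.
#' @param classes feature class names (see [feature_classes()]).
#' @param min_df minimum document frequency for token features (default 2).
#' @param stopwords stop-word list applied during tokenization.
#' @return an object of class `"vocabulary"`: the class-qualified tokens in
#'   column order plus the class set and `min_df` used.
#' @export
build_vocabulary <- function(corpus, classes, min_df = 2, stopwords = load_stopwords()) {
  stop_if_not(length(corpus) > 0, "corpus is empty")
  stop_if_not(is_count(min_df) && min_df >= 1, "min_df must be a positive integer")
  classes <- check_classes(classes)
  cols <- character(0)
  for (cl in classes) {
    if (cl %in% NUMERIC_CLASSES) {
      cols <- c(cols, numeric_class_columns(cl))
    } else {
      pairs <- class_token_pairs(corpus, cl, stopwords)
      if (nrow(pairs) == 0) next
      df <- table(unique(pairs)$token)
      keep <- names(df)[df >= min_df]
      if (length(keep)) {
        cols <- c(cols, paste0(cl, ":", sort(keep, method = "radix")))
      }
    }
  }
  structure(list(tokens = cols,
                 index = stats::setNames(seq_along(cols), cols),
                 classes = classes, min_df = min_df),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d columns over %d feature classes (min_df=%d)\n",
              length(x$tokens), length(x$classes), x$min_df))
  invisible(x)
}

#' @export
length.vocabulary <- function(x) length(x$tokens)

#' Write / read a vocabulary as TSV
#'
#' Two tab-separated columns: class-qualified token and 0-based column index.
#'
#' @param vocabulary a `vocabulary`.
#' @param path output path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  utils::write.table(
    data.frame(token = vocabulary$tokens, index = seq_along(vocabulary$tokens) - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Vectorize a corpus against a vocabulary
#'
#' Produces the sparse design matrix: n-gram, author-name, and journal
#' features as raw counts; numeric classes as their raw values (z-scoring
#' happens inside the tagger with training-set statistics). Tokens outside
#' the vocabulary are ignored, so unseen test-time tokens have no effect.
#' Row order follows corpus order.
#'
#' @param corpus a `corpus`.
#' @param vocabulary a [build_vocabulary()] result.
#' @param stopwords stop-word list (must match the one used to build the
#'   vocabulary).
#' @return a `dgCMatrix` with one row per record (rownames = ids) and one
#'   column per vocabulary entry.
#' @export
vectorize <- function(corpus, vocabulary, stopwords = load_stopwords()) {
  n <- length(corpus)
  p <- length(vocabulary$tokens)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cl in vocabulary$classes) {
    if (cl %in% NUMERIC_CLASSES) {
      vals <- class_numeric_values(corpus, cl)
      for (col in colnames(vals)) {
        j <- vocabulary$index[[col]]
        v <- vals[, col]
        nz <- which(v != 0)
        ii <- c(ii, nz); jj <- c(jj, rep.int(j, length(nz))); xx <- c(xx, v[nz])
      }
    } else {
      pairs <- class_token_pairs(corpus, cl, stopwords)
      if (nrow(pairs) == 0) next
      j <- vocabulary$index[paste0(cl, ":", pairs$token)]
      keep <- !is.na(j)
      ii <- c(ii, pairs$row[keep]); jj <- c(jj, unname(j[keep]))
      xx <- c(xx, rep.int(1, sum(keep)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p),
                       dimnames = list(corpus_ids(corpus), vocabulary$tokens))
}

#' Export a design matrix as MatrixMarket
#'
#' Writes the sparse matrix in MatrixMarket coordinate format plus a sidecar
#' text file of row ids (one per line).
#'
#' @param X a design matrix from [vectorize()].
#' @param path output `.mtx` path; row ids go to `paste0(path, ".rows")`.
#' @export
write_design_matrix <- function(X, path) {
  Matrix::writeMM(methods::as(X, "CsparseMatrix"), path)
  writeLines(rownames(X) %||% as.character(seq_len(nrow(X))), paste0(path, ".rows"))
  invisible(path)
}
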