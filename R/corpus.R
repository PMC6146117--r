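#' Construct a citation corpus
#'
#' A corpus is an ordered collection of citation records. Each record carries
#' the bibliographic fields the tagger may use as predictors (title, abstract,
#' authors, journal, pagination, year) plus, optionally, the MeSH descriptor
#' list and a reference label derived from it. A missing abstract, pagination,
#' or MeSH list is represented as absent (`NA` / `NULL`), never as an empty
#' string: absence of MeSH means "unlabeled", not "negative".
#'
#' @param id character vector of non-empty, unique record identifiers
#'   (PMIDs or synthetic ids).
#' @param title character vector of article titles.
#' @param abstract character vector; `NA` for records without an abstract.
#' @param authors list, one element per record, each a data frame with
#'   columns `last` and `initials` (zero rows for no authors).
#' @param journal character vector of journal names (`NA` allowed).
#' @param pagination character vector of raw MEDLINE pagination strings
#'   (`NA` allowed).
#' @param year integer vector of publication years (`NA` allowed).
#' @param mesh_terms list, one element per record, each a character vector of
#'   MeSH descriptor names, or `NULL` when the record has no MeSH indexing.
#' @param label logical vector: the reference label (`TRUE` = Humans). If
#'   `NULL` (default) labels are derived from `mesh_terms` via
#'   [reference_label()]. Records without MeSH stay `NA` (unlabeled).
#' @param provenance free-text description of where the records came from.
#' @return An object of class `"corpus"`.
#' @seealso [read_pubmed_xml()], [read_citation_table()], [reference_label()]
#' @export
corpus <- function(id, title, abstract = NA_character_, authors = NULL,
                   journal = NA_character_, pagination = NA_character_,
                   year = NA_integer_, mesh_terms = NULL, label = NULL,
                   provenance = "in-memory") {
  n <- length(id)
  id <- as.character(id)
  stop_if_not(n == 0 || all(nzchar(id) & !is.na(id)), "record ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  stop_if_not(length(dup) == 0,
              "duplicate record ids: ", paste(utils::head(dup, 10), collapse = ", "))
  rep_n <- function(x) {
    if (length(x) == 1 && n != 1) rep(x, n) else x
  }
  title <- nfc(rep_n(as.character(title)))
  abstract <- nfc(rep_n(as.character(abstract)))
  journal <- nfc(rep_n(as.character(journal)))
  pagination <- rep_n(as.character(pagination))
  year <- rep_n(as.integer(year))
  if (is.null(authors)) authors <- rep(list(empty_authors()), n)
  if (is.null(mesh_terms)) mesh_terms <- rep(list(NULL), n)
  stop_if_not(length(title) == n && length(abstract) == n &&
                length(journal) == n && length(pagination) == n &&
                length(year) == n && length(authors) == n &&
                length(mesh_terms) == n,
              "all fields must have one entry per record")
  authors <- lapply(authors, as_author_table)
  mesh_terms <- lapply(mesh_terms, function(m) {
    if (is.null(m) || (length(m) == 1 && is.na(m))) NULL else nfc(as.character(m))
  })
  if (is.null(label)) {
    label <- vapply(mesh_terms, mesh_label, logical(1))
  } else {
    label <- rep_n(as.logical(label))
    stop_if_not(length(label) == n, "label must have one entry per record")
  }
  records <- data.frame(id = id, title = title, abstract = abstract,
                        journal = journal, pagination = pagination,
                        year = year, label = label,
                        stringsAsFactors = FALSE)
  records$authors <- authors
  records$mesh_terms <- mesh_terms
  structure(list(records = records, provenance = provenance), class = "corpus")
}

empty_authors <- function() {
  data.frame(last = character(0), initials = character(0), stringsAsFactors = FALSE)
}

as_author_table <- function(a) {
  if (is.null(a) || (is.atomic(a) && length(a) == 1 && is.na(a))) return(empty_authors())
  if (is.data.frame(a)) {
    stop_if_not(all(c("last", "initials") %in% names(a)),
                "author tables need columns 'last' and 'initials'")
    return(data.frame(last = nfc(as.character(a$last)),
                      initials = nfc(as.character(a$initials)),
                      stringsAsFactors = FALSE))
  }
  if (is.matrix(a)) {
    return(data.frame(last = nfc(as.character(a[, 1])),
                      initials = nfc(as.character(a[, 2])),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret author entry of class ", class(a)[1], call. = FALSE)
}

# The Humans reference standard keyed on the curated descriptor string (or its
# MeSH unique id when descriptors are given as ids). Qualifiers are ignored.
HUMANS_DESCRIPTOR <- "Humans"
HUMANS_MESH_UI <- "D006801"

mesh_label <- function(mesh) {
  if (is.null(mesh)) return(NA)
  any(trimws(mesh) %in% c(HUMANS_DESCRIPTOR, HUMANS_MESH_UI))
}

#' Derive the Humans reference label from MeSH descriptors
#'
#' The reference standard is the presence of the curator-assigned MeSH
#' `"Humans"` descriptor (matched case-sensitively after whitespace trimming;
#' the MeSH unique id `D006801` is also accepted). Records without any MeSH
#' indexing get `NA`: they are unlabeled, not negative, and are skipped by
#' training and evaluation.
#'
#' @param x a `corpus`, or a list of per-record MeSH descriptor vectors.
#' @return logical vector: `TRUE`, `FALSE`, or `NA` per record.
#' @export
reference_label <- function(x) {
  mesh <- if (inherits(x, "corpus")) x$records$mesh_terms else x
  vapply(mesh, mesh_label, logical(1))
}

#' @export
length.corpus <- function(x) nrow(x$records)

#' @export
print.corpus <- function(x, ...) {
  lab <- x$records$label
  cat(sprintf("<corpus> %d records (%s)\n", nrow(x$records), x$provenance))
  cat(sprintf("  labeled: %d (prevalence %.3f), unlabeled: %d\n",
              sum(!is.na(lab)),
              if (any(!is.na(lab))) mean(lab[!is.na(lab)]) else NA_real_,
              sum(is.na(lab))))
  invisible(x)
}

#' @export
`[.corpus` <- function(x, i, ...) {
  rec <- x$records[i, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, provenance = x$provenance), class = "corpus")
}

#' @export
as.data.frame.corpus <- function(x, ...) x$records

#' Corpus record ids and labels
#' @param corpus a `corpus`.
#' @return `corpus_ids()`: character vector; `corpus_labels()`: logical vector
#'   (`NA` = unlabeled).
#' @export
corpus_ids <- function(corpus) corpus$records$id

#' @rdname corpus_ids
#' @export
corpus_labels <- function(corpus) corpus$records$label

labeled_subset <- function(corpus) corpus[!is.na(corpus$records$label)]

#' Read citation records from PubMed/MEDLINE XML
#'
#' Parses a `PubmedArticleSet` document into a [corpus()]. Per article the
#' reader takes `ArticleTitle`, the concatenation of all `AbstractText`
#' sections (joined with a single space; section labels such as "METHODS" are
#' not included), `AuthorList` (`LastName`, `Initials`), `Journal/Title`,
#' `MedlinePgn`, `PubDate/Year`, and `MeshHeadingList/DescriptorName`. Missing
#' abstract, pagination, or MeSH list yield absent fields. Articles without a
#' title are skipped with a warning. The Humans reference label is derived
#' from the MeSH descriptors when present.
#'
#' @param source path, URL-free connection, or literal XML string.
#' @return a `corpus`.
#' @export
read_pubmed_xml <- function(source) {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) stop("malformed PubMed XML: ",
                                           conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  recs <- vector("list", length(arts))
  kept <- logical(length(arts))
  for (k in seq_along(arts)) {
    a <- arts[[k]]
    title <- xml_text1(a, ".//ArticleTitle")
    if (is.na(title) || !nzchar(trimws(title))) {
      warning(sprintf("article %d has no title; record skipped", k), call. = FALSE)
      next
    }
    pmid <- xml_text1(a, ".//MedlineCitation/PMID | ./PMID")
    if (is.na(pmid)) pmid <- sprintf("record-%d", k)
    abst <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    abstract <- if (length(abst) == 0) NA_character_ else
      paste(trimws(xml2::xml_text(abst)), collapse = " ")
    au_nodes <- xml2::xml_find_all(a, ".//AuthorList/Author[LastName]")
    authors <- data.frame(
      last = vapply(au_nodes, function(n) xml_text1(n, "./LastName"), character(1)),
      initials = vapply(au_nodes, function(n) {
        ini <- xml_text1(n, "./Initials")
        if (is.na(ini)) "" else ini
      }, character(1)),
      stringsAsFactors = FALSE)
    journal <- xml_text1(a, ".//Journal/Title")
    pagination <- xml_text1(a, ".//Pagination/MedlinePgn | .//MedlinePgn")
    year <- suppressWarnings(as.integer(xml_text1(a, ".//JournalIssue/PubDate/Year")))
    if (is.na(year)) {
      md <- xml_text1(a, ".//JournalIssue/PubDate/MedlineDate")
      if (!is.na(md)) year <- suppressWarnings(as.integer(sub(".*?(\\d{4}).*", "\\1", md)))
    }
    mh_list <- xml2::xml_find_first(a, ".//MeshHeadingList")
    mesh <- if (inherits(mh_list, "xml_missing")) NULL else
      xml2::xml_text(xml2::xml_find_all(mh_list, ".//DescriptorName"))
    recs[[k]] <- list(id = pmid, title = title, abstract = abstract,
                      authors = authors, journal = journal,
                      pagination = pagination, year = year, mesh_terms = mesh)
    kept[k] <- TRUE
  }
  recs <- recs[kept]
  corpus(id = vapply(recs, `[[`, character(1), "id"),
         title = vapply(recs, `[[`, character(1), "title"),
         abstract = vapply(recs, `[[`, character(1), "abstract"),
         authors = lapply(recs, `[[`, "authors"),
         journal = vapply(recs, `[[`, character(1), "journal"),
         pagination = vapply(recs, `[[`, character(1), "pagination"),
         year = vapply(recs, `[[`, integer(1), "year"),
         mesh_terms = lapply(recs, `[[`, "mesh_terms"),
         provenance = if (is.character(source) && file.exists(source))
           paste0("pubmed-xml:", basename(source)) else "pubmed-xml")
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

#' Read and write the JSON-lines citation table
#'
#' The citation table is one JSON object per line with keys `id`, `title`,
#' `abstract`, `authors` (array of `{"last":..., "initials":...}`), `journal`,
#' `pagination`, `year`, `mesh_terms`, `label`. Absent fields are `null` or
#' omitted. `write_citation_table()` followed by `read_citation_table()`
#' reproduces the corpus field-for-field. A `label` may be supplied without
#' `mesh_terms` (synthetic corpora carry labels directly).
#'
#' @param path file path of the `.jsonl` table.
#' @return `read_citation_table()` returns a `corpus`;
#'   `write_citation_table()` returns `path` invisibly.
#' @export
read_citation_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(k) {
    tryCatch(jsonlite::fromJSON(lines[[k]], simplifyVector = FALSE),
             error = function(e) stop("citation table line ", k, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  has_id <- vapply(recs, function(r) !is.null(r$id), logical(1))
  stop_if_not(all(has_id), "citation table rows missing 'id': lines ",
              paste(utils::head(which(!has_id), 10), collapse = ", "))
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  dup <- unique(ids[duplicated(ids)])
  stop_if_not(length(dup) == 0, "duplicate ids in citation table: ",
              paste(utils::head(dup, 10), collapse = ", "))
  sc <- function(r, key) {
    v <- r[[key]]
    if (is.null(v) || length(v) == 0 || (length(v) == 1 && is.na(v[[1]]))) NA_character_
    else as.character(v[[1]])
  }
  corpus(
    id = ids,
    title = vapply(recs, sc, character(1), "title"),
    abstract = vapply(recs, sc, character(1), "abstract"),
    authors = lapply(recs, function(r) {
      a <- r$authors
      if (is.null(a) || length(a) == 0) return(empty_authors())
      data.frame(last = vapply(a, function(p) as.character(p$last %||% p[[1]]), character(1)),
                 initials = vapply(a, function(p) as.character(p$initials %||% p[[2]] %||% ""), character(1)),
                 stringsAsFactors = FALSE)
    }),
    journal = vapply(recs, sc, character(1), "journal"),
    pagination = vapply(recs, sc, character(1), "pagination"),
    year = vapply(recs, function(r) {
      v <- r$year
      if (is.null(v) || (length(v) == 1 && is.na(v[[1]]))) NA_integer_ else as.integer(v[[1]])
    }, integer(1)),
    mesh_terms = lapply(recs, function(r) {
      m <- r$mesh_terms
      if (is.null(m) || length(m) == 0) NULL else vapply(m, as.character, character(1))
    }),
    label = vapply(recs, function(r) {
      v <- r$label
      if (is.null(v) || (length(v) == 1 && is.na(v[[1]]))) NA else as.logical(v[[1]])
    }, logical(1)),
    provenance = paste0("citation-table:", basename(path)))
}

#' @rdname read_citation_table
#' @param corpus a `corpus` to serialize.
#' @export
write_citation_table <- function(corpus, path) {
  rec <- corpus$records
  lines <- vapply(seq_len(nrow(rec)), function(k) {
    au <- rec$authors[[k]]
    obj <- list(
      id = rec$id[k],
      title = rec$title[k],
      abstract = rec$abstract[k],
      authors = if (nrow(au) == 0) list() else
        lapply(seq_len(nrow(au)), function(j) list(last = au$last[j], initials = au$initials[j])),
      journal = rec$journal[k],
      pagination = rec$pagination[k],
      year = rec$year[k],
      mesh_terms = rec$mesh_terms[[k]],
      label = rec$label[k])
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load a stop-word list
#'
#' Reads a plain-text stop-word list: one token per line, `#` comment lines
#' and blank lines ignored. Tokens are lower-cased and deduplicated. With no
#' arguments, returns the bundled default English list (a snapshot of the
#' classic SMART-family list used in bag-of-words text retrieval).
#'
#' @param source path to a stop-word file, or `NULL` for the bundled list.
#' @return character vector of class `"stopwords"`.
#' @export
load_stopwords <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "stopwords_english.txt", package = "humtag")
  }
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- unique(tolower(lines))
  stop_if_not(!any(grepl("\\s", toks)), "stop-word entries must not contain whitespace")
  if (length(toks) == 0) warning("stop-word list is empty", call. = FALSE)
  structure(toks, class = "stopwords")
}
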