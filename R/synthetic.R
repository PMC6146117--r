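#' Parameters for the synthetic citation generator
#'
#' The generator emulates a labeled citation corpus with class-conditional
#' token distributions and a known generative posterior per record, so the
#' whole pipeline can be validated without bulk MEDLINE data. Labels are
#' Bernoulli with the given prevalence; title and abstract tokens are drawn
#' from class-conditional multinomials in which an `informative_fraction` of
#' the field vocabulary has its per-token log-odds shifted by
#' `+/- separation` (symmetrically, so the shift is exact); journals come
#' from a class-skewed categorical with per-journal log-odds
#' `+/- journal_skew`. Author names, counts, pagination, and year are drawn
#' independently of the class and carry no signal. The defaults mirror a
#' MEDLINE-like setting: prevalence 0.65, a 200-journal pool, 10% of records
#' without an abstract, and moderately separated classes (many weakly
#' informative tokens rather than a few decisive ones), which yields
#' posteriors spread over the whole unit interval.
#'
#' @param n_records number of records to generate.
#' @param prevalence P(label = Humans), in (0, 1).
#' @param vocab_title,vocab_abstract per-field vocabulary sizes.
#' @param separation log-odds shift of informative tokens (>= 0).
#' @param informative_fraction fraction of each field vocabulary that is
#'   informative, in \[0, 1\].
#' @param separation_title,separation_abstract optional per-field overrides
#'   of `separation` (used e.g. to plant signal in a single feature class).
#' @param journal_skew per-journal log-odds shift; defaults to `separation`.
#' @param title_length,abstract_length length distributions as
#'   `c(mean, dispersion)` of a negative binomial.
#' @param n_journals,n_authors_pool categorical pool sizes.
#' @param missing_abstract_rate fraction of records without an abstract.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a list of class `"generator_params"`.
#' @export
generator_params <- function(n_records = 20000, prevalence = 0.65,
                             vocab_title = 250, vocab_abstract = 1000,
                             separation = 1.0, informative_fraction = 0.1,
                             separation_title = NULL, separation_abstract = NULL,
                             journal_skew = NULL,
                             title_length = c(mean = 8, dispersion = 10),
                             abstract_length = c(mean = 60, dispersion = 5),
                             n_journals = 200, n_authors_pool = 500,
                             missing_abstract_rate = 0.1, seed = 1L) {
  chk <- function(ok, field, what) stop_if_not(ok, "invalid ", field, ": ", what)
  chk(is_count(n_records) && n_records >= 1, "n_records", "positive integer required")
  chk(is.numeric(prevalence) && prevalence > 0 && prevalence < 1,
      "prevalence", "must be in (0,1)")
  chk(is_count(vocab_title) && vocab_title >= 2, "vocab_title", "integer >= 2 required")
  chk(is_count(vocab_abstract) && vocab_abstract >= 2, "vocab_abstract",
      "integer >= 2 required")
  chk(is.numeric(separation) && is.finite(separation) && separation >= 0,
      "separation", "finite non-negative number required")
  chk(is.numeric(informative_fraction) && informative_fraction >= 0 &&
        informative_fraction <= 1, "informative_fraction", "must be in [0,1]")
  chk(is.numeric(missing_abstract_rate) && missing_abstract_rate >= 0 &&
        missing_abstract_rate <= 1, "missing_abstract_rate", "must be in [0,1]")
  chk(is_count(n_journals) && n_journals >= 2, "n_journals", "integer >= 2 required")
  chk(is_count(n_authors_pool) && n_authors_pool >= 1, "n_authors_pool",
      "positive integer required")
  chk(length(title_length) == 2 && all(title_length > 0), "title_length",
      "c(mean, dispersion) > 0 required")
  chk(length(abstract_length) == 2 && all(abstract_length > 0), "abstract_length",
      "c(mean, dispersion) > 0 required")
  sep_t <- separation_title %||% separation
  sep_a <- separation_abstract %||% separation
  skew <- journal_skew %||% separation
  chk(is.numeric(sep_t) && sep_t >= 0, "separation_title", "non-negative number required")
  chk(is.numeric(sep_a) && sep_a >= 0, "separation_abstract", "non-negative number required")
  chk(is.numeric(skew) && skew >= 0, "journal_skew", "non-negative number required")
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 vocab_title = as.integer(vocab_title),
                 vocab_abstract = as.integer(vocab_abstract),
                 separation = separation,
                 informative_fraction = informative_fraction,
                 separation_title = sep_t, separation_abstract = sep_a,
                 journal_skew = skew,
                 title_length = unname(title_length),
                 abstract_length = unname(abstract_length),
                 n_journals = as.integer(n_journals),
                 n_authors_pool = as.integer(n_authors_pool),
                 missing_abstract_rate = missing_abstract_rate,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# Class-conditional multinomial over `tokens`: an even number of informative
# tokens get equal base mass and a symmetric +/- sep/2 log-shift (half up,
# half down), so both class distributions share the same normalizer and the
# per-token log-odds are exactly +sep / -sep / 0. The non-informative base
# measure is Dirichlet-drawn.
make_token_model <- function(tokens, sep, frac) {
  v <- length(tokens)
  k <- 2L * floor(v * frac / 2)
  if (sep == 0) k <- 0L
  p0 <- 1 / v
  n_flat <- v - k
  base <- if (n_flat > 0) {
    g <- stats::rgamma(n_flat, shape = 1)
    g / sum(g) * (1 - k * p0)
  } else numeric(0)
  theta1 <- c(p0 * exp(rep(c(sep / 2, -sep / 2), each = k / 2)), base)
  theta0 <- c(p0 * exp(rep(c(-sep / 2, sep / 2), each = k / 2)), base)
  z <- sum(theta1)
  logodds <- c(rep(sep, k / 2), rep(-sep, k / 2), rep(0, n_flat))
  list(tokens = tokens, theta1 = theta1 / z, theta0 = theta0 / z,
       logodds = stats::setNames(logodds, tokens))
}

draw_class_tokens <- function(y, lens, model) {
  n <- length(y)
  out <- rep(list(character(0)), n)
  for (cls in c(TRUE, FALSE)) {
    rows <- which(y == cls & lens > 0)
    if (length(rows) == 0) next
    theta <- if (cls) model$theta1 else model$theta0
    draws <- sample(model$tokens, sum(lens[rows]), replace = TRUE, prob = theta)
    sp <- split(draws, rep(rows, lens[rows]))
    out[as.integer(names(sp))] <- sp
  }
  out
}

medline_page_string <- function(start, end) {
  s <- as.character(start); e <- as.character(end)
  mapply(function(a, b) {
    if (a == b) return(a)
    if (nchar(a) == nchar(b)) {
      k <- 0
      while (k < nchar(a) - 1 && substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1
      b <- substr(b, k + 1, nchar(b))
    }
    paste0(a, "-", b)
  }, s, e, USE.NAMES = FALSE)
}

MESH_FILLER_TERMS <- c("Animals", "Mice", "Rats", "Female", "Male", "Adult",
                       "Cell Line", "Models, Molecular", "Escherichia coli",
                       "Plant Proteins")

#' Generate a synthetic labeled citation corpus
#'
#' Draws a corpus under the generative model described in
#' [generator_params()] and returns it together with the exact per-record
#' Bayes posterior P(label = Humans | generated fields), computable in closed
#' form from the per-token log-odds, the journal log-odds, and the
#' prevalence. The posterior is the ceiling any classifier can reach on this
#' corpus and the reference for calibration checks. MeSH descriptors are
#' attached consistently with the label (Humans present iff the label is
#' positive) so label-derivation and MeSH-independence behavior can be
#' exercised.
#'
#' @param params a [generator_params()] object.
#' @return object of class `"generated_corpus"`: `corpus` (a [corpus()]),
#'   `params`, `posterior` (numeric vector), and `model` (the per-field
#'   log-odds tables).
#' @export
generate_corpus <- function(params = generator_params()) {
  stop_if_not(inherits(params, "generator_params"),
              "params must come from generator_params()")
  with_seed(params$seed, {
    n <- params$n_records
    title_model <- make_token_model(sprintf("t%04d", seq_len(params$vocab_title)),
                                    params$separation_title,
                                    params$informative_fraction)
    abstract_model <- make_token_model(sprintf("a%04d", seq_len(params$vocab_abstract)),
                                       params$separation_abstract,
                                       params$informative_fraction)
    journal_model <- make_token_model(sprintf("Journal of Synthetic Citations %03d",
                                              seq_len(params$n_journals)),
                                      params$journal_skew, 1)
    y <- stats::rbinom(n, 1, params$prevalence) == 1
    len_t <- pmax(1, stats::rnbinom(n, size = params$title_length[2],
                                    mu = params$title_length[1]))
    has_abstract <- stats::runif(n) >= params$missing_abstract_rate
    len_a <- ifelse(has_abstract,
                    pmax(3, stats::rnbinom(n, size = params$abstract_length[2],
                                           mu = params$abstract_length[1])), 0L)
    title_tokens <- draw_class_tokens(y, len_t, title_model)
    abstract_tokens <- draw_class_tokens(y, len_a, abstract_model)
    journal_idx <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      rows <- which(y == cls)
      theta <- if (cls) journal_model$theta1 else journal_model$theta0
      journal_idx[rows] <- sample.int(params$n_journals, length(rows),
                                      replace = TRUE, prob = theta)
    }
    journals <- journal_model$tokens[journal_idx]

    pool_last <- sprintf("Au%04d", seq_len(params$n_authors_pool))
    pool_ini <- paste0(sample(LETTERS, params$n_authors_pool, replace = TRUE),
                       sample(LETTERS, params$n_authors_pool, replace = TRUE))
    n_auth <- 1 + stats::rpois(n, 3)
    authors <- lapply(n_auth, function(k) {
      ix <- sample.int(params$n_authors_pool, min(k, params$n_authors_pool))
      data.frame(last = pool_last[ix], initials = pool_ini[ix],
                 stringsAsFactors = FALSE)
    })
    start <- sample.int(1999, n, replace = TRUE)
    pagination <- medline_page_string(start, start + stats::rpois(n, 5))
    year <- sample(1987:2016, n, replace = TRUE)
    mesh <- lapply(seq_len(n), function(k) {
      extra <- sample(MESH_FILLER_TERMS, 2)
      if (y[k]) c(HUMANS_DESCRIPTOR, extra) else extra
    })

    logit <- stats::qlogis(params$prevalence) +
      vapply(title_tokens, function(tk) sum(title_model$logodds[tk]), numeric(1)) +
      vapply(abstract_tokens, function(tk)
        if (length(tk)) sum(abstract_model$logodds[tk]) else 0, numeric(1)) +
      unname(journal_model$logodds[journals])
    posterior <- stats::plogis(logit)

    corp <- corpus(
      id = sprintf("syn%07d", seq_len(n)),
      title = vapply(title_tokens, paste, character(1), collapse = " "),
      abstract = ifelse(has_abstract,
                        vapply(abstract_tokens, paste, character(1), collapse = " "),
                        NA_character_),
      authors = authors, journal = journals, pagination = pagination,
      year = year, mesh_terms = mesh, label = y,
      provenance = sprintf("synthetic(seed=%d,n=%d,prevalence=%g)",
                           params$seed, n, params$prevalence))
    structure(list(corpus = corp, params = params, posterior = posterior,
                   model = list(logodds_title = title_model$logodds,
                                logodds_abstract = abstract_model$logodds,
                                logodds_journal = journal_model$logodds,
                                prevalence = params$prevalence)),
              class = "generated_corpus")
  })
}

#' @export
print.generated_corpus <- function(x, ...) {
  cat(sprintf("<generated_corpus> %d records, prevalence %.3f (observed %.3f), seed %d\n",
              x$params$n_records, x$params$prevalence,
              mean(corpus_labels(x$corpus)), x$params$seed))
  invisible(x)
}

#' Exact Bayes posterior of generated records
#'
#' Recomputes P(label = Humans | fields) for records generated by
#' [generate_corpus()] from the stored per-token log-odds: logit(prevalence)
#' plus the sum of the title-token, abstract-token, and journal log-odds.
#' Errors on records not produced by this generator (unknown tokens or
#' journal).
#'
#' @param gen a `generated_corpus`.
#' @param corpus records to score; defaults to the generated corpus itself.
#' @return numeric vector of posteriors in \[0, 1\].
#' @export
true_posterior <- function(gen, corpus = gen$corpus) {
  stop_if_not(inherits(gen, "generated_corpus"), "gen must be a generated_corpus")
  rec <- corpus$records
  lo_t <- gen$model$logodds_title
  lo_a <- gen$model$logodds_abstract
  lo_j <- gen$model$logodds_journal
  sum_lo <- function(text, lo, field) {
    if (is.na(text) || !nzchar(text)) return(0)
    tk <- strsplit(text, " ", fixed = TRUE)[[1]]
    v <- lo[tk]
    stop_if_not(!anyNA(v), "record not generated by this model: unknown ",
                field, " token '", tk[which(is.na(v))[1]], "'")
    sum(v)
  }
  logit <- vapply(seq_len(nrow(rec)), function(k) {
    jl <- lo_j[rec$journal[k]]
    stop_if_not(!is.na(jl), "record not generated by this model: unknown journal '",
                rec$journal[k], "'")
    stats::qlogis(gen$model$prevalence) +
      sum_lo(rec$title[k], lo_t, "title") +
      sum_lo(rec$abstract[k], lo_a, "abstract") + unname(jl)
  }, numeric(1))
  stats::plogis(logit)
}

#' Bayes-optimal AUC of a generated corpus
#'
#' The AUC obtained by scoring records with their exact generative posterior
#' — the ceiling any trained tagger can reach on this corpus (up to sampling
#' noise).
#'
#' @param gen a `generated_corpus` with at least 1000 records.
#' @return AUC in \[0, 1\].
#' @export
bayes_auc_estimate <- function(gen) {
  stop_if_not(inherits(gen, "generated_corpus"), "gen must be a generated_corpus")
  stop_if_not(gen$params$n_records >= 1000,
              "Bayes AUC estimate needs at least 1000 records")
  auc(gen$posterior, corpus_labels(gen$corpus))
}

#' Write a generated corpus to disk
#'
#' Writes the JSON-lines citation table plus a sidecar TSV of exact
#' posteriors (`id`, `posterior`).
#'
#' @param gen a `generated_corpus`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_generated_corpus <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_citation_table(gen$corpus, file.path(dir, "corpus.jsonl"))
  utils::write.table(
    data.frame(id = corpus_ids(gen$corpus), posterior = fmt_num(gen$posterior)),
    file.path(dir, "posteriors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
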