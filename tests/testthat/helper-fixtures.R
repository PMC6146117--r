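# Fixtures built in code: a small PubMed XML document and corpus builders
# shared across test files.

pubmed_xml_fixture <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<PubmedArticleSet>\n",
    " <PubmedArticle>\n",
    "  <MedlineCitation>\n",
    "   <PMID>101</PMID>\n",
    "   <Article>\n",
    "    <Journal><Title>Journal of Testing</Title>\n",
    "     <JournalIssue><PubDate><Year>2001</Year></PubDate></JournalIssue></Journal>\n",
    "    <ArticleTitle>Human T-cell responses.</ArticleTitle>\n",
    "    <Pagination><MedlinePgn>334-41</MedlinePgn></Pagination>\n",
    "    <Abstract>\n",
    "     <AbstractText Label=\"BACKGROUND\">First part.</AbstractText>\n",
    "     <AbstractText Label=\"METHODS\">Second part.</AbstractText>\n",
    "    </Abstract>\n",
    "    <AuthorList>\n",
    "     <Author><LastName>Smith</LastName><Initials>JA</Initials></Author>\n",
    "     <Author><LastName>Doe</LastName><Initials>B</Initials></Author>\n",
    "    </AuthorList>\n",
    "   </Article>\n",
    "   <MeshHeadingList>\n",
    "    <MeshHeading><DescriptorName UI=\"D006801\">Humans</DescriptorName></MeshHeading>\n",
    "    <MeshHeading><DescriptorName UI=\"D005260\">Female</DescriptorName></MeshHeading>\n",
    "   </MeshHeadingList>\n",
    "  </MedlineCitation>\n",
    " </PubmedArticle>\n",
    " <PubmedArticle>\n",
    "  <MedlineCitation>\n",
    "   <PMID>102</PMID>\n",
    "   <Article>\n",
    "    <Journal><Title>Murine Methods</Title>\n",
    "     <JournalIssue><PubDate><Year>1999</Year></PubDate></JournalIssue></Journal>\n",
    "    <ArticleTitle>Knockout mice protocols</ArticleTitle>\n",
    "   </Article>\n",
    "   <MeshHeadingList>\n",
    "    <MeshHeading><DescriptorName UI=\"D051379\">Mice</DescriptorName></MeshHeading>\n",
    "   </MeshHeadingList>\n",
    "  </MedlineCitation>\n",
    " </PubmedArticle>\n",
    "</PubmedArticleSet>\n")
}

# a tiny labeled corpus whose token content is fully known
toy_corpus <- function() {
  corpus(
    id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    title = c("human cohort study", "human trial cohort",
              "human cohort results", "mouse model study",
              "mouse liver model", "mouse model results"),
    abstract = c("patients enrolled", "patients recruited", NA,
                 "animals housed", "animals fed", NA),
    journal = c("Clinical Journal", "Clinical Journal", "Clinical Journal",
                "Animal Journal", "Animal Journal", "Animal Journal"),
    label = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    provenance = "toy")
}

no_stopwords <- function() structure(character(0), class = "stopwords")

# planted-signal design: informative title tokens, pure-noise abstract and
# journal fields sized so that irrelevant classes measurably hurt CV AUC
planted_params <- function(seed) {
  generator_params(n_records = 1600, separation = 0, separation_title = 1.5,
                   vocab_abstract = 800, n_journals = 150, journal_skew = 0,
                   seed = seed)
}

# brute-force AUC oracle: pairwise counting with half-credit ties
auc_pairwise <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
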