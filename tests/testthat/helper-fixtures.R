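# Shared fixtures: a small gazetteer backend mirroring the worked examples,
# and a JATS document builder for corpus tests.

fixture_backend <- function() {
  nlp_backend(
    persons = c("Y. Nishiyama", "K. Mackie", "Keith Gull", "Doris Thelian",
                "Peter Merrifield", "Stefano Schiaffino", "Charles Rice",
                "A. B."),
    organizations = c("Indiana University", "University of Oxford",
                      "Oxford University", "Rockefeller University",
                      "University of Vermont"),
    locations = c("Pittsburgh"))
}

jats_doc <- function(ack_body, article_id = "PMC0001", journal = "PLoS One",
                     year = 2010, extra_front = "") {
  paste0(
    "<article><front><journal-meta><journal-title>", journal,
    "</journal-title></journal-meta><article-meta>",
    "<article-id pub-id-type=\"pmc\">", article_id, "</article-id>",
    "<pub-date><year>", year, "</year></pub-date>", extra_front,
    "</article-meta></front><body><sec><title>Results</title>",
    "<p>Body text mentioning antibody staining.</p></sec></body>",
    if (!is.null(ack_body)) paste0("<back><ack>", ack_body, "</ack></back>")
    else "<back></back>",
    "</article>")
}

# Deterministic synthetic corpus reused by several heavier tests.
cached_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_corpus(synth_config(n_documents = 200,
                                             donation_rate = 1,
                                             distractor_rate = 0,
                                             rng_seed = 42))
    cache
  }
})
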