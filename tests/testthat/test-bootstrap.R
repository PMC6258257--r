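test_that("patterns are induced from the immediate parent noun phrase", {
  be <- nlp_backend()
  expect_identical(induce_patterns("We used the mouse TAG1 antibody", "TAG1", be),
                   "the mouse TARGET antibody")
  expect_identical(induce_patterns("rabbit TAG2 antibodies were a gift", "TAG2", be),
                   "rabbit TARGET antibodies")
  expect_identical(induce_patterns("no seeded name in this sentence", "TAG1", be),
                   character(0))
  # TARGET-plus-stopwords-only patterns are pruned
  expect_identical(induce_patterns("we examined the TAG9", "TAG9", be),
                   character(0))
})

test_that("pattern matching aligns TARGET with candidate tokens, case-insensitively", {
  be <- nlp_backend()
  expect_identical(
    match_patterns("is thanked for the antibody to UL7", "antibody to TARGET", be),
    "UL7")
  expect_identical(
    match_patterns("the anti-actin antibody", "TARGET antibody", be),
    "anti-actin")
  expect_identical(
    match_patterns("nothing matches here", c("antibody to TARGET"), be),
    character(0))
  # stop-words and attribute tags never fill a TARGET slot
  expect_identical(
    match_patterns("the monoclonal antibody", "the TARGET antibody", be),
    character(0))
  expect_error(match_patterns("x", "no wildcard here", be), "TARGET")
})

test_that("bootstrapping discovers names that share a context with a seed", {
  be <- nlp_backend()
  sents <- c("We used the TAG1 antibody",
             "She is thanked for the antibody to TAG1",
             "She is thanked for the antibody to TAG2",
             "This work was supported by grants")
  st <- run_bootstrap(sents, "TAG1", be, n_iterations = 1)
  expect_true("tag2" %in% st$names)
  expect_true(all(c("the TARGET antibody", "the antibody to TARGET") %in% st$patterns))

  st2 <- run_bootstrap(sents, "TAG1", be, n_iterations = 2)
  expect_true(all(st$names %in% st2$names))
  expect_true(all(st$patterns %in% st2$patterns))

  # a seed absent from the corpus persists
  st3 <- run_bootstrap(sents, c("TAG1", "GHOST9"), be, 1)
  expect_true("ghost9" %in% st3$names)

  # empty corpus: names stay the seeds, no patterns
  st4 <- run_bootstrap(character(0), c("TAG1"), be, 2)
  expect_identical(st4$names, "tag1")
  expect_identical(st4$patterns, character(0))
})

test_that("names and patterns grow monotonically to a fixed point", {
  corp <- cached_corpus()
  sents <- corpus_sentences(corp$acks)[1:60]
  seeds <- head(corp$antibody_names, 5)
  prev <- NULL
  for (it in 1:3) {
    st <- run_bootstrap(sents, seeds, corp$backend, n_iterations = it)
    if (!is.null(prev)) {
      expect_true(all(prev$names %in% st$names))
      expect_true(all(prev$patterns %in% st$patterns))
    }
    prev <- st
  }
  # every learned pattern, TARGET re-substituted with some known name,
  # reproduces a token window of some corpus sentence
  low_sents <- lapply(sents, function(s) tolower(tokenize(s)$text))
  for (p in prev$patterns) {
    pt <- strsplit(p, " ", fixed = TRUE)[[1]]
    reproduced <- any(vapply(prev$names, function(nm) {
      filled <- pt
      filled[filled == "TARGET"] <- nm
      any(vapply(low_sents, function(lt) {
        k <- length(filled)
        length(lt) >= k &&
          any(vapply(seq_len(length(lt) - k + 1L), function(s0)
            all(lt[s0:(s0 + k - 1L)] == filled), TRUE))
      }, TRUE))
    }, TRUE))
    expect_true(reproduced, info = p)
  }
})

test_that("bootstrap agrees with the exhaustive fixed-point oracle on small corpora", {
  corp <- cached_corpus()
  sents <- corpus_sentences(corp$acks)[1:50]
  seeds <- head(corp$antibody_names, 5)
  for (iters in 1:2) {
    st <- run_bootstrap(sents, seeds, corp$backend, n_iterations = iters)
    or <- oracle_bootstrap(sents, seeds, corp$backend, n_iterations = iters)
    expect_identical(sort(st$names), or$names)
    expect_identical(sort(st$patterns), or$patterns)
  }
})

test_that("bootstrap records complete donor and affiliation via the context rules", {
  be <- fixture_backend()
  ack <- acknowledgement(
    "Dr. Y. Nishiyama is thanked for the antibody to UL7.", "PMC1")
  st <- structure(list(names = "ul7", patterns = "antibody to TARGET",
                       iteration = 1L), class = "bootstrap_state")
  recs <- extract_donations_bootstrap(ack, st, be)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$donor, "Y. Nishiyama")
  expect_identical(recs$antibody, "UL7")
  expect_identical(recs$method, "bootstrap")

  two <- acknowledgement(paste(
    "Dr. Y. Nishiyama is thanked for the antibody to UL7.",
    "K. Mackie ( Indiana University ) is thanked for the antibody to CB1."),
    "PMC2")
  recs2 <- extract_donations_bootstrap(two, st, be)
  expect_identical(nrow(recs2), 2L)
  expect_identical(recs2$antibody, c("UL7", "CB1"))
  expect_identical(recs2$affiliation, c(NA_character_, "Indiana University"))
})

test_that("pattern files round-trip and reject malformed patterns", {
  path <- withr::local_tempfile(fileext = ".txt")
  pats <- c("the mouse TARGET antibody", "antibody to TARGET")
  write_pattern_file(pats, path)
  expect_identical(read_pattern_file(path), pats)
  expect_error(write_pattern_file("no wildcard", path), "TARGET")
  expect_error(write_pattern_file("TARGET TARGET antibody", path), "TARGET")
})
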