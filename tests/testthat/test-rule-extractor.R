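test_that("anchors are found per keyword occurrence with clipped windows", {
  toks <- tokenize("for providing antibodies .")
  anchors <- find_anchors(toks)
  expect_length(anchors, 1L)
  expect_identical(anchors[[1]]$anchor_index, 3L)
  expect_identical(anchors[[1]]$left, c(2L, 1L))
  expect_identical(anchors[[1]]$right, integer(0))  # clipped at the period

  toks2 <- tokenize("antibody cocktails and advice on antibody usage")
  expect_length(find_anchors(toks2), 2L)
  expect_length(find_anchors(tokenize("no keyword here")), 0L)

  # windows never cross a sentence boundary
  toks3 <- tokenize("We thank A. Gull. The TAT1 antibody was used.")
  a <- find_anchors(toks3)[[1]]
  expect_false(any(toks3$text[a$left] %in% c(".", "Gull")))
})

test_that("antibody names come from the left window, or the right after of/to", {
  be <- fixture_backend()
  toks <- tokenize("the antibody to UL7")
  nm <- extract_antibody_name(toks, find_anchors(toks)[[1]], be)
  expect_identical(nm$name, "UL7")
  expect_identical(nm$side, "right")

  toks <- tokenize("the anti-GFP antibody was provided")
  nm <- extract_antibody_name(toks, find_anchors(toks)[[1]], be)
  expect_identical(nm$name, "anti-GFP")
  expect_identical(nm$side, "left")

  # all left-window tokens are dictionary words or entity-covered: absent
  toks <- tokenize("We thank Peter Merrifield and Stefano Schiaffino for providing antibodies .")
  anchor <- find_anchors(toks)[[1]]
  expect_null(extract_antibody_name(toks, anchor, be))

  # the right window is not scanned without an intervening of/to
  toks <- tokenize("providing antibodies UL7 something")
  expect_null(extract_antibody_name(toks, find_anchors(toks)[[1]], be))
})

test_that("attribute tags are read off the left window", {
  grab <- function(tx) {
    toks <- tokenize(tx)
    extract_attributes(toks, find_anchors(toks)[[1]])
  }
  expect_identical(grab("a monoclonal anti-actin antibody"), "monoclonal")
  expect_identical(grab("primary and secondary antibodies"),
                   c("primary", "secondary"))
  expect_identical(grab("the antibody to UL7"), character(0))
})

test_that("the donor is the nearest person left of the antibody name, unbounded", {
  be <- fixture_backend()
  toks <- tokenize("Dr. Y. Nishiyama is thanked for the antibody to UL7")
  ents <- tag_entities(toks, be)
  nm_idx <- which(toks$text == "UL7")
  donor <- extract_donor(toks, nm_idx, ents)
  expect_identical(donor$text, "Y. Nishiyama")

  expect_null(extract_donor(tokenize("nobody here"), 2L,
                            tag_entities(tokenize("nobody here"), be)))

  toks2 <- tokenize("Keith Gull and K. Mackie donated the TAT1 antibody")
  ents2 <- tag_entities(toks2, be)
  donor2 <- extract_donor(toks2, which(toks2$text == "TAT1"), ents2)
  expect_identical(donor2$text, "K. Mackie")
  # brute force over all person mentions confirms nearest-wins
  pers <- ents2[ents2$label == "person", ]
  expect_identical(donor2$end, max(pers$end[pers$end < which(toks2$text == "TAT1")]))
})

test_that("the affiliation is the organization closest to the donor, before the anchor", {
  be <- fixture_backend()
  toks <- tokenize("K. Mackie ( Indiana University ) for the CB1 antibody")
  ents <- tag_entities(toks, be)
  donor <- extract_donor(toks, which(toks$text == "CB1"), ents)
  anchor_idx <- which(tolower(toks$text) == "antibody")
  affil <- extract_affiliation(toks, donor, anchor_idx, ents)
  expect_identical(affil$text, "Indiana University")

  # organization only right of the anchor: no affiliation
  toks2 <- tokenize("K. Mackie gave the CB1 antibody from Indiana University")
  ents2 <- tag_entities(toks2, be)
  donor2 <- extract_donor(toks2, which(toks2$text == "CB1"), ents2)
  expect_null(extract_affiliation(toks2, donor2,
                                  which(tolower(toks2$text) == "antibody"), ents2))

  # two organizations in between: the one closest to the donor wins
  toks3 <- tokenize("K. Mackie ( Indiana University ) at Rockefeller University sent the CB1 antibody")
  ents3 <- tag_entities(toks3, be)
  donor3 <- extract_donor(toks3, which(toks3$text == "CB1"), ents3)
  affil3 <- extract_affiliation(toks3, donor3,
                                which(tolower(toks3$text) == "antibody"), ents3)
  orgs <- ents3[ents3$label == "organization" & ents3$start > donor3$end, ]
  expect_identical(affil3$start, min(orgs$start))
  expect_identical(affil3$text, "Indiana University")
})

test_that("records are assembled per anchor, deduplicated and ordered", {
  be <- fixture_backend()
  ack <- acknowledgement(paste(
    "Dr. Y. Nishiyama is thanked for the antibody to UL7.",
    "K. Mackie ( Indiana University ) provided the CB1 antibody."), "PMC1")
  recs <- extract_donations(ack, be)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$donor, c("Y. Nishiyama", "K. Mackie"))
  expect_identical(recs$antibody, c("UL7", "CB1"))
  expect_identical(recs$affiliation, c(NA_character_, "Indiana University"))
  expect_true(all(diff(recs$anchor_index) > 0))

  # keyword hit without a donation still yields a donor-only record
  # (a known false positive of the context rules)
  thelian <- acknowledgement(paste(
    "We thank Doris Thelian for her expert advice on antibody cocktails",
    "and flow cytometry data analysis."), "PMC2")
  recs2 <- extract_donations(thelian, be)
  expect_identical(nrow(recs2), 1L)
  expect_identical(recs2$donor, "Doris Thelian")
  expect_true(is.na(recs2$antibody))

  # singular + plural keyword over the same (donor, antibody) pair collapses
  dup <- acknowledgement(
    "Keith Gull provided the TAT1 antibody and more TAT1 antibodies.", "PMC3")
  expect_identical(nrow(extract_donations(dup, be)), 1L)
})

test_that("window discipline and substring provenance hold on generated text", {
  corp <- cached_corpus()
  recs <- extract_donations_corpus(corp$acks[1:80], corp$backend)
  texts <- stats::setNames(vapply(corp$acks[1:80], `[[`, "", "text"),
                           vapply(corp$acks[1:80], `[[`, "", "article_id"))
  for (i in seq_len(nrow(recs))) {
    tx <- texts[[recs$article_id[i]]]
    for (f in c("donor", "affiliation", "antibody")) {
      v <- recs[[f]][i]
      if (!is.na(v)) expect_true(grepl(v, tx, fixed = TRUE))
    }
    toks <- tokenize(tx)
    if (!is.na(recs$antibody[i])) {
      d <- abs(which(toks$text == recs$antibody[i]) - recs$anchor_index[i])
      expect_lte(min(d), 4L)
    }
  }
  # determinism
  expect_identical(recs, extract_donations_corpus(corp$acks[1:80], corp$backend))
})
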