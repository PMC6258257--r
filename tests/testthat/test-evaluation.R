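test_that("field matching honours the normalization policy", {
  pol <- match_policy()
  expect_true(match_field("Keith Gull", "Keith Gull", pol))
  expect_true(match_field("Dr. Charles Rice", "Charles Rice", pol))
  # word-order variants do not match exactly (a known failure mode)
  expect_false(match_field("Oxford University", "University of Oxford", pol))
  expect_true(match_field("Gull", "Keith Gull",
                          match_policy(mode = "containment")))
  # any-annotator semantics and the absent-prediction rule
  expect_true(match_field("K. Gull", c("Keith Gull", "K. Gull"), pol))
  expect_true(match_field(NA_character_, character(0), pol))
  expect_false(match_field(NA_character_, "Keith Gull", pol))
})

eval_fixture <- function(n = 10, donor_hit = n, affil_hit = n, ab_hit = n) {
  gold <- list()
  recs <- ackminer:::empty_records()
  for (i in seq_len(n)) {
    id <- sprintf("D%02d", i)
    text <- sprintf("We thank P%d (O%d) for the AB%d antibody.", i, i, i)
    gold[[i]] <- gold_document(id, text, "gold", donations = list(
      gold_donation(donor = sprintf("P%d", i),
                    affiliation = sprintf("O%d", i),
                    resource_name = sprintf("AB%d", i))))
    recs <- rbind(recs, tibble::tibble(
      article_id = id, journal = NA_character_, year = NA_integer_,
      donor = if (i <= donor_hit) sprintf("P%d", i) else "Wrong Person",
      affiliation = if (i <= affil_hit) sprintf("O%d", i) else "Wrong Org",
      antibody = if (i <= ab_hit) sprintf("AB%d", i) else "WRONG1",
      attributes = list(character()), anchor_index = 1L, method = "rule"))
  }
  list(gold = gold, recs = recs)
}

test_that("perfect predictions score 1.0 on every field", {
  fx <- eval_fixture(5)
  rep <- evaluate_documents(fx$recs, fx$gold)
  expect_equal(unname(rep$accuracy), c(1, 1, 1))
  expect_equal(rep$mean, 1)
})

test_that("accuracies are ratios and the mean is their arithmetic average", {
  fx <- eval_fixture(10, donor_hit = 5, affil_hit = 7, ab_hit = 5)
  rep <- evaluate_documents(fx$recs, fx$gold)
  expect_equal(unname(rep$accuracy), c(0.5, 0.7, 0.5))
  expect_equal(unname(rep$numerator / rep$denominator), unname(rep$accuracy))
  expect_equal(rep$mean, (0.5 + 0.7 + 0.5) / 3, tolerance = 1e-12)
  # integer-rounded percentage presentation: mean prints as 57%
  expect_identical(round(100 * rep$mean), 57)
  out <- capture.output(print(rep))
  expect_true(any(grepl("mean\\s+57%", out)))
})

test_that("accuracy is invariant under document reordering and never improves under shuffling", {
  fx <- eval_fixture(8, donor_hit = 6, affil_hit = 6, ab_hit = 6)
  rep1 <- evaluate_documents(fx$recs, fx$gold)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  rep2 <- evaluate_documents(fx$recs[perm, ], fx$gold[perm])
  expect_equal(rep1$accuracy, rep2$accuracy)

  shuffled <- fx$recs
  shuffled$article_id <- fx$recs$article_id[c(2:8, 1)]
  rep3 <- evaluate_documents(shuffled, fx$gold)
  expect_true(all(rep3$accuracy <= rep1$accuracy))
})

test_that("looser normalization never lowers accuracy", {
  gold <- list(gold_document("D1", "We thank Dr. Charles Rice for the CB1 antibody.",
                             "gold", donations = list(
    gold_donation(donor = "Charles Rice", resource_name = "CB1"))))
  recs <- tibble::tibble(
    article_id = "D1", journal = NA_character_, year = NA_integer_,
    donor = "Dr. Charles Rice", affiliation = NA_character_,
    antibody = "cb1.", attributes = list(character()),
    anchor_index = 1L, method = "rule")
  strict <- evaluate_documents(recs, gold,
    match_policy(case_fold = FALSE, strip_punctuation = FALSE,
                 strip_honorifics = FALSE))
  loose <- evaluate_documents(recs, gold, match_policy())
  comparable <- c("donor", "antibody")  # no gold affiliation in this fixture
  expect_true(all(strict$accuracy[comparable] <= loose$accuracy[comparable]))
  expect_equal(unname(loose$accuracy[comparable]), c(1, 1))
})

test_that("misaligned document ids are an error", {
  fx <- eval_fixture(3)
  recs <- fx$recs
  recs$article_id[1] <- "UNKNOWN"
  expect_error(evaluate_documents(recs, fx$gold), "UNKNOWN")
})

test_that("inter-annotator agreement matches hand-countable fixtures", {
  text <- "We thank P1 (O1) for the monoclonal AB1 antibody."
  d1 <- gold_donation(donor = "P1", affiliation = "O1", resource_name = "AB1",
                      attributes = "monoclonal")
  same <- list(gold_document("D1", text, "A1", donations = list(d1)),
               gold_document("D1", text, "A2", donations = list(d1)))
  expect_equal(inter_annotator_agreement(same), 1.0)

  d2 <- gold_donation(donor = "P1 (O1", affiliation = "the", resource_name = "antibody",
                      attributes = "AB1")
  disjoint <- list(gold_document("D1", text, "A1", donations = list(d1)),
                   gold_document("D1", text, "A2", donations = list(d2)))
  expect_equal(inter_annotator_agreement(disjoint), 0.0)

  d3 <- gold_donation(donor = "P1", affiliation = "O1", resource_name = "AB1",
                      attributes = "the")
  three_of_four <- list(gold_document("D1", text, "A1", donations = list(d1)),
                        gold_document("D1", text, "A2", donations = list(d3)))
  expect_equal(inter_annotator_agreement(three_of_four), 0.75)

  expect_error(inter_annotator_agreement(
    list(gold_document("D1", text, "A1", donations = list(d1)))), "undefined")
})
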