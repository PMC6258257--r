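# Synthetic acknowledgement corpus with known ground truth.
#
# A template engine, not a language model: donation sentences in active
# ("... the TAG1 antibody") and passive ("... the antibody to TAG1") voice,
# optional bracketed affiliations and attribute tags, plus distractor
# sentences (funding, manuscript reading, advice-with-keyword). Every
# generated gold string is a substring of its document text, gazetteers
# contain exactly the planted persons and organizations (so the fixture
# entity tagger is perfect), and antibody names are guaranteed absent from
# the dictionary word list. Identical configurations generate byte-identical
# corpora.

.synth_first_names <- c(
  "John", "Mary", "Keith", "Peter", "Hugo", "Gary", "Erich", "Harold",
  "Doris", "Stefano", "Laura", "Maria", "Kenji", "Wei", "Anna", "Paulo",
  "Ingrid", "Tomas", "Elena", "Ravi", "Sofia", "Marc", "Nadia", "Oliver")

.synth_surnames <- c(
  "Gull", "Davies", "Bellen", "Ward", "Buchner", "Rice", "Gainer", "Mackie",
  "Funae", "Thelian", "Merrifield", "Schiaffino", "Nishiyama", "Okada",
  "Lindqvist", "Moreau", "Kovacs", "Petrov", "Tanaka", "Silva", "Weber",
  "Rossi", "Novak", "Larsen", "Dubois", "Fischer", "Marino", "Haug",
  "Svensson", "Kostov", "Ahmed", "Mendes", "Keller", "Brandt", "Sato",
  "Vargas", "Olsen", "Meyer", "Fontaine", "Berg")

.synth_places <- c(
  "Oxford", "Vermont", "Indiana", "Pittsburgh", "Osaka", "Uppsala",
  "Geneva", "Toronto", "Leiden", "Kyoto", "Heidelberg", "Bologna",
  "Aarhus", "Valencia", "Bergen", "Ghent", "Tartu", "Basel", "Dunedin",
  "Nagoya", "Turku", "Graz", "Cork", "Szeged", "Brno")

.synth_journals <- c("PLoS One", "PLoS Genetics", "PLoS Biology",
                     "BMC Biology", "eLife", "PLoS Pathogens")

.synth_templates <- c("active", "active_plural", "passive", "plain_thanks",
                      "funding", "reading", "advice")

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic corpus generator
#'
#' All rates are fractions in `[0, 1]`. The defaults describe a corpus of
#' keyword-filtered acknowledgements: most documents report a donation,
#' passive-voice donation sentences are the minority, affiliations are
#' usually bracketed right after the donor, and extraneous sentences
#' (funding, manuscript reading) are common.
#'
#' @param n_documents Number of documents.
#' @param donation_rate Fraction of documents with at least one donation.
#' @param passive_voice_rate Fraction of donation sentences in passive voice
#'   ("the antibody to TARGET").
#' @param bracket_affiliation_rate Fraction of donors followed by a
#'   bracketed affiliation.
#' @param attribute_rate Fraction of donation sentences carrying an
#'   attribute tag.
#' @param distractor_rate Fraction of documents with distractor sentences.
#' @param multi_donation_rate Fraction of donation documents with a second
#'   donation.
#' @param plain_thanks_rate Fraction of donation sentences thanking for
#'   antibodies without naming one.
#' @param honorific_rate Fraction of donor mentions prefixed with "Dr.".
#' @param n_antibody_names,n_persons,n_organizations Vocabulary sizes.
#' @param rng_seed Integer seed; identical configurations generate identical
#'   corpora.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_documents = 50L, donation_rate = 0.9,
                         passive_voice_rate = 0.2,
                         bracket_affiliation_rate = 0.6,
                         attribute_rate = 0.3, distractor_rate = 0.7,
                         multi_donation_rate = 0.1, plain_thanks_rate = 0.1,
                         honorific_rate = 0.2, n_antibody_names = 60L,
                         n_persons = 40L, n_organizations = 25L,
                         rng_seed = 1L) {
  cfg <- list(n_documents = as.integer(n_documents),
              donation_rate = donation_rate,
              passive_voice_rate = passive_voice_rate,
              bracket_affiliation_rate = bracket_affiliation_rate,
              attribute_rate = attribute_rate,
              distractor_rate = distractor_rate,
              multi_donation_rate = multi_donation_rate,
              plain_thanks_rate = plain_thanks_rate,
              honorific_rate = honorific_rate,
              n_antibody_names = as.integer(n_antibody_names),
              n_persons = as.integer(n_persons),
              n_organizations = as.integer(n_organizations),
              rng_seed = as.integer(rng_seed))
  rates <- cfg[grepl("_rate$", names(cfg))]
  stopifnot(cfg$n_documents >= 0L,
            all(unlist(rates) >= 0), all(unlist(rates) <= 1),
            cfg$n_antibody_names >= 1L, cfg$n_persons >= 4L,
            cfg$n_organizations >= 4L)
  structure(cfg, class = "synth_config")
}

synth_person_vocab <- function(n) {
  combos <- expand.grid(first = .synth_first_names, last = .synth_surnames,
                        stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), ]
  full <- paste(combos$first, combos$last)
  short <- paste0(substr(combos$first, 1, 1), ". ", combos$last)
  style <- runif(nrow(combos)) < 0.3
  out <- unique(ifelse(style, short, full))
  out[seq_len(min(n, length(out)))]
}

synth_org_vocab <- function(n) {
  forms <- c("University of %s", "%s University", "%s Institute",
             "%s Medical School")
  grid <- expand.grid(place = .synth_places, form = forms,
                      stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), ]
  out <- unique(sprintf(grid$form, grid$place))
  out[seq_len(min(n, length(out)))]
}

synth_antibody_vocab <- function(n, dictionary = ackminer_dictionary()) {
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    code <- paste0(
      vapply(seq_len(k), function(i)
        paste(sample(LETTERS, sample(2:3, 1), replace = TRUE), collapse = ""),
        ""),
      sample(1:99, k, replace = TRUE))
    anti <- paste0("anti-", vapply(seq_len(k), function(i)
      paste(sample(LETTERS, sample(3:4, 1), replace = TRUE), collapse = ""), ""))
    cand <- ifelse(runif(k) < 0.5, code, anti)
    cand <- cand[!(tolower(cand) %in% dictionary)]
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Realize one sentence template
#'
#' @param template_id One of `"active"`, `"active_plural"`, `"passive"`,
#'   `"plain_thanks"` (donation templates) or `"funding"`, `"reading"`,
#'   `"advice"` (distractors); anything else is an error.
#' @param person,organization,antibody,attribute Filler strings; `NA` where
#'   the template slot is unused or the optional slot is empty.
#' @param honorific Prefix the person with "Dr." in the text (the gold donor
#'   stays the bare name).
#' @return `list(text, donations, entities)`: the sentence, a list of
#'   [gold_donation()] (empty for distractors), and a data frame of
#'   non-donation entities the sentence introduces.
#' @export
generate_document <- function(template_id, person = NA_character_,
                              organization = NA_character_,
                              antibody = NA_character_,
                              attribute = NA_character_,
                              honorific = FALSE) {
  if (!template_id %in% .synth_templates)
    stop("unknown template: ", template_id)
  hp <- function() paste0(if (honorific) "Dr. " else "", person)
  orgpart <- if (!is.na(organization)) paste0(" (", organization, ")") else ""
  attrpart <- if (!is.na(attribute)) paste0(attribute, " ") else ""
  no_ent <- data.frame(label = character(), text = character(),
                       stringsAsFactors = FALSE)
  don <- function(name) list(gold_donation(
    donor = person,
    affiliation = if (nzchar(orgpart)) organization else NA_character_,
    resource_label = "antibody", resource_name = name,
    attributes = if (!is.na(attribute)) attribute else character()))
  switch(template_id,
    active = list(
      text = paste0("We thank ", hp(), orgpart, " for providing the ",
                    attrpart, antibody, " antibody."),
      donations = don(antibody), entities = no_ent),
    active_plural = list(
      text = paste0("We thank ", hp(), orgpart, " for providing ",
                    attrpart, antibody, " antibodies."),
      donations = don(antibody), entities = no_ent),
    passive = list(
      text = paste0(hp(), orgpart, " is thanked for the ", attrpart,
                    "antibody to ", antibody, "."),
      donations = don(antibody), entities = no_ent),
    plain_thanks = list(
      text = paste0("We thank ", hp(), orgpart,
                    " for generously providing antibodies."),
      donations = don(NA_character_), entities = no_ent),
    funding = list(
      text = paste0("This work was supported by grants from the ",
                    organization, "."),
      donations = list(),
      entities = data.frame(label = "organization", text = organization,
                            stringsAsFactors = FALSE)),
    reading = list(
      text = paste0("We are grateful to ", hp(),
                    " for critical reading of the manuscript."),
      donations = list(),
      entities = data.frame(label = "person", text = person,
                            stringsAsFactors = FALSE)),
    advice = list(
      text = paste0("We also thank ", hp(),
                    " for expert advice on antibody cocktails and flow cytometry."),
      donations = list(),
      entities = data.frame(label = "person", text = person,
                            stringsAsFactors = FALSE)))
}

#' Generate a synthetic acknowledgement corpus with gold annotations
#'
#' @param config A [synth_config()].
#' @return A list with elements `acks` (list of [acknowledgement()]),
#'   `gold` (list of [gold_document()], annotator `"gold"`), `backend`
#'   (an [nlp_backend()] whose gazetteers hold exactly the planted persons
#'   and organizations), and `antibody_names` (character vector of planted
#'   antibody names, lowercased, in first-appearance order).
#' @examples
#' corp <- generate_corpus(synth_config(n_documents = 5, rng_seed = 7))
#' corp$acks[[1]]
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_rng_seed(config$rng_seed, {
    persons <- synth_person_vocab(config$n_persons)
    orgs <- synth_org_vocab(config$n_organizations)
    antibodies <- synth_antibody_vocab(config$n_antibody_names)
    acks <- vector("list", config$n_documents)
    gold <- vector("list", config$n_documents)
    used_persons <- character(0)
    used_orgs <- character(0)
    planted <- character(0)

    for (i in seq_len(config$n_documents)) {
      sentences <- character(0)
      donations <- list()
      entities <- data.frame(label = character(), text = character(),
                             stringsAsFactors = FALSE)
      doc_persons <- sample(persons, 4)
      doc_orgs <- sample(orgs, 4)
      doc_abs <- sample(antibodies, 3)
      p_i <- o_i <- a_i <- 1L

      if (runif(1) < config$donation_rate) {
        n_don <- 1L + (runif(1) < config$multi_donation_rate)
        for (d in seq_len(n_don)) {
          u <- runif(1)
          template <- if (u < config$plain_thanks_rate) "plain_thanks"
            else if (u < config$plain_thanks_rate + config$passive_voice_rate)
              "passive"
            else if (runif(1) < 0.3) "active_plural" else "active"
          person <- doc_persons[p_i]; p_i <- p_i + 1L
          org <- if (runif(1) < config$bracket_affiliation_rate) {
            o <- doc_orgs[o_i]; o_i <- o_i + 1L; o
          } else NA_character_
          ab <- if (template == "plain_thanks") NA_character_ else {
            a <- doc_abs[a_i]; a_i <- a_i + 1L; a
          }
          attr_tag <- if (template != "plain_thanks" &&
                          runif(1) < config$attribute_rate)
            sample(.attribute_tags, 1) else NA_character_
          sent <- generate_document(template, person = person,
                                    organization = org, antibody = ab,
                                    attribute = attr_tag,
                                    honorific = runif(1) < config$honorific_rate)
          sentences <- c(sentences, sent$text)
          donations <- c(donations, sent$donations)
          used_persons <- c(used_persons, person)
          if (!is.na(org)) used_orgs <- c(used_orgs, org)
          if (!is.na(ab)) planted <- c(planted, ab)
        }
      }

      if (runif(1) < config$distractor_rate) {
        kinds <- sample(c("funding", "reading", "advice"),
                        size = 1L + (runif(1) < 0.4), replace = FALSE)
        kinds <- sort(kinds)  # advice < funding < reading: keyworded first
        for (kind in kinds) {
          person <- doc_persons[p_i]; p_i <- p_i + 1L
          org <- doc_orgs[o_i]; o_i <- o_i + 1L
          sent <- generate_document(kind, person = person, organization = org,
                                    honorific = runif(1) < config$honorific_rate)
          sentences <- c(sentences, sent$text)
          entities <- rbind(entities, sent$entities)
          used_persons <- c(used_persons,
                            sent$entities$text[sent$entities$label == "person"])
          used_orgs <- c(used_orgs,
                         sent$entities$text[sent$entities$label == "organization"])
        }
      }

      if (!length(sentences))
        sentences <- "The authors declare no competing interests."
      doc_id <- sprintf("SYN%05d", i)
      text <- paste(sentences, collapse = " ")
      acks[[i]] <- acknowledgement(text = text, article_id = doc_id,
                                   journal = sample(.synth_journals, 1),
                                   year = sample(2000:2014, 1))
      gold[[i]] <- gold_document(doc_id = doc_id, text = text,
                                 annotator_id = "gold",
                                 donations = donations,
                                 non_donation_entities = entities)
    }

    backend <- nlp_backend(persons = unique(used_persons),
                           organizations = unique(used_orgs))
    list(acks = acks, gold = gold, backend = backend,
         antibody_names = unique(tolower(planted)))
  })
}

#' Write the gazetteers of a backend to a directory
#'
#' One entry per line, UTF-8: `persons.txt`, `organizations.txt`,
#' `locations.txt` (see [read_gazetteers()]).
#'
#' @param backend An [nlp_backend()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gazetteers <- function(backend, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(backend$persons, file.path(dir, "persons.txt"), useBytes = TRUE)
  writeLines(backend$organizations, file.path(dir, "organizations.txt"),
             useBytes = TRUE)
  writeLines(backend$locations, file.path(dir, "locations.txt"),
             useBytes = TRUE)
  invisible(dir)
}
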