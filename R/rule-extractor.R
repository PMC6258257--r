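# Rule-based extraction of antibody donations from acknowledgement text.
#
# Every extraction is anchored on an occurrence of "antibody"/"antibodies".
# The antibody name is the first word in the 4-token left context window that
# is neither an English dictionary word nor inside a named entity; when the
# left window yields nothing and the anchor is followed by "of"/"to"
# ("antibody to UL7"), the right window is scanned the same way. Attribute
# tags (primary, secondary, monoclonal, polyclonal) are read off the left
# window. The donor is the nearest person entity left of the antibody name,
# searched without a window bound; the affiliation is the organization entity
# closest to the donor that still lies left of the anchor (affiliations are
# typically bracketed right after the name).

#' Find antibody keyword anchors with their context windows
#'
#' One anchor per case-insensitive whole-token match of "antibody" or
#' "antibodies", each carrying left and right context windows of `window`
#' tokens clipped at sentence boundaries.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param window Context window width in tokens (default 4).
#' @return List of anchor contexts: `list(anchor_index, left, right)` where
#'   `left`/`right` are integer token indices ordered nearest-first.
#' @export
find_anchors <- function(tokens, window = 4L) {
  stopifnot(window >= 1L)
  n <- nrow(tokens)
  if (n == 0L) return(list())
  sid <- sentence_ids(tokens)
  hits <- which(tolower(tokens$text) %in% .anchor_words)
  lapply(hits, function(i) {
    left <- integer(0)
    j <- i - 1L
    while (j >= 1L && length(left) < window && sid[j] == sid[i] &&
           !(tokens$text[j] %in% .sentence_end)) {
      left <- c(left, j)
      j <- j - 1L
    }
    right <- integer(0)
    j <- i + 1L
    while (j <= n && length(right) < window && sid[j] == sid[i] &&
           !(tokens$text[j] %in% .sentence_end)) {
      right <- c(right, j)
      j <- j + 1L
    }
    list(anchor_index = i, left = left, right = right)
  })
}

# A token can be an antibody-name candidate only if it carries an
# alphanumeric character (pure punctuation never names an antibody).
candidate_token <- function(txt) grepl("[[:alnum:]]", txt)

in_entity <- function(index, entities) {
  nrow(entities) > 0L && any(entities$start <= index & index <= entities$end)
}

#' Extract the antibody name for one anchor
#'
#' Scans the left window nearest-to-farthest for the first token failing the
#' dictionary test and lying inside no entity mention; if none is found and
#' the anchor is followed by "of" or "to" within the right window, the right
#' window is scanned identically.
#'
#' @param tokens Token data frame.
#' @param anchor One element of [find_anchors()].
#' @param backend An [nlp_backend()].
#' @param entities Entity data frame from [tag_entities()]; computed on the
#'   fly when missing.
#' @return `list(name, side, index)` with `side` `"left"` or `"right"`, or
#'   `NULL` when neither window yields a name.
#' @export
extract_antibody_name <- function(tokens, anchor, backend,
                                  entities = tag_entities(tokens, backend)) {
  scan <- function(indices) {
    for (i in indices) {
      txt <- tokens$text[i]
      if (!candidate_token(txt)) next
      if (tolower(txt) %in% .anchor_words) next
      if (is_dictionary_word(txt, backend)) next
      if (in_entity(i, entities)) next
      return(i)
    }
    NULL
  }
  i <- scan(anchor$left)
  if (!is.null(i))
    return(list(name = tokens$text[i], side = "left", index = i))
  if (any(tolower(tokens$text[anchor$right]) %in% c("of", "to"))) {
    i <- scan(anchor$right)
    if (!is.null(i))
      return(list(name = tokens$text[i], side = "right", index = i))
  }
  NULL
}

#' Extract attribute tags for one anchor
#'
#' @inheritParams extract_antibody_name
#' @return Character vector, a subset of
#'   `c("primary", "secondary", "monoclonal", "polyclonal")`.
#' @export
extract_attributes <- function(tokens, anchor) {
  found <- tolower(tokens$text[anchor$left])
  .attribute_tags[.attribute_tags %in% found]
}

#' Extract the donor for one anchor
#'
#' The nearest person entity lying entirely left of `from_index` (the
#' antibody-name token when one was found, otherwise the anchor itself). The
#' search window is unbounded: donor names often sit far from the antibody
#' mention. Optionally restricted to the anchor's sentence.
#'
#' @param tokens Token data frame.
#' @param from_index Token index the leftward search starts from.
#' @param entities Entity data frame from [tag_entities()].
#' @param scope `"paragraph"` (default) or `"sentence"`.
#' @return One row of `entities`, or `NULL`.
#' @export
extract_donor <- function(tokens, from_index, entities,
                          scope = c("paragraph", "sentence")) {
  scope <- match.arg(scope)
  cand <- entities[entities$label == "person" & entities$end < from_index, ,
                   drop = FALSE]
  if (scope == "sentence" && nrow(cand) > 0L) {
    sid <- sentence_ids(tokens)
    cand <- cand[sid[cand$start] == sid[from_index], , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(NULL)
  cand[which.max(cand$end), , drop = FALSE]
}

#' Extract the donor's affiliation for one anchor
#'
#' The organization entity nearest to the donor's right edge whose span lies
#' strictly between the donor and the anchor. Ties at equal distance break
#' toward the leftmost mention.
#'
#' @param tokens Token data frame.
#' @param donor One entity row (from [extract_donor()]).
#' @param anchor_index Token index of the anchor keyword.
#' @param entities Entity data frame from [tag_entities()].
#' @return One row of `entities`, or `NULL`.
#' @export
extract_affiliation <- function(tokens, donor, anchor_index, entities) {
  if (is.null(donor)) return(NULL)
  cand <- entities[entities$label == "organization" &
                     entities$start > donor$end &
                     entities$end < anchor_index, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand[which.min(cand$start), , drop = FALSE]
}

empty_records <- function() {
  tibble::tibble(article_id = character(), journal = character(),
                 year = integer(), donor = character(),
                 affiliation = character(), antibody = character(),
                 attributes = list(), anchor_index = integer(),
                 method = character())
}

#' Extract antibody donations from one acknowledgement (rule-based)
#'
#' Assembles one donation record per keyword anchor from
#' [extract_antibody_name()], [extract_attributes()], [extract_donor()] and
#' [extract_affiliation()]. Records with neither a donor nor an antibody name
#' are suppressed, and anchors yielding an identical (donor, antibody) pair
#' within the paragraph are deduplicated (a singular and a plural keyword in
#' one sentence would otherwise double-count a donation).
#'
#' @param ack An [acknowledgement()].
#' @param backend An [nlp_backend()].
#' @param window Context window width (default 4 tokens).
#' @param donor_scope `"paragraph"` (default) or `"sentence"`; see
#'   [extract_donor()].
#' @return A tibble with columns `article_id`, `journal`, `year`, `donor`,
#'   `affiliation`, `antibody`, `attributes` (list column), `anchor_index`,
#'   `method` (`"rule"`), ordered by anchor position.
#' @examples
#' be <- nlp_backend(persons = "Y. Nishiyama")
#' ack <- acknowledgement(
#'   "Dr. Y. Nishiyama is thanked for the antibody to UL7.", "PMC1")
#' extract_donations(ack, be)
#' @export
extract_donations <- function(ack, backend, window = 4L,
                              donor_scope = c("paragraph", "sentence")) {
  donor_scope <- match.arg(donor_scope)
  stopifnot(inherits(ack, "acknowledgement"))
  tokens <- tokenize(ack$text)
  entities <- tag_entities(tokens, backend)
  anchors <- find_anchors(tokens, window = window)
  rows <- list()
  for (anchor in anchors) {
    nm <- extract_antibody_name(tokens, anchor, backend, entities)
    from_index <- if (!is.null(nm)) nm$index else anchor$anchor_index
    donor <- extract_donor(tokens, from_index, entities, scope = donor_scope)
    if (is.null(nm) && is.null(donor)) next
    affil <- extract_affiliation(tokens, donor, anchor$anchor_index, entities)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      article_id = ack$article_id,
      journal = ack$journal,
      year = ack$year,
      donor = if (!is.null(donor)) donor$text else NA_character_,
      affiliation = if (!is.null(affil)) affil$text else NA_character_,
      antibody = if (!is.null(nm)) nm$name else NA_character_,
      attributes = list(extract_attributes(tokens, anchor)),
      anchor_index = anchor$anchor_index,
      method = "rule")
  }
  if (!length(rows)) return(empty_records())
  out <- do.call(rbind, rows)
  key <- paste(ifelse(is.na(out$donor), "", out$donor),
               ifelse(is.na(out$antibody), "", out$antibody), sep = "\r")
  out[!duplicated(key), , drop = FALSE]
}

#' Run the rule-based extractor over a corpus
#'
#' @param acks List of [acknowledgement()] objects.
#' @inheritParams extract_donations
#' @return One tibble of donation records (see [extract_donations()]).
#' @export
extract_donations_corpus <- function(acks, backend, window = 4L,
                                     donor_scope = c("paragraph", "sentence")) {
  donor_scope <- match.arg(donor_scope)
  rows <- lapply(acks, extract_donations, backend = backend, window = window,
                 donor_scope = donor_scope)
  out <- do.call(rbind, c(list(empty_records()), rows))
  tibble::as_tibble(out)
}

#' Write / read donation records as newline-delimited JSON
#'
#' One JSON object per record with keys `article_id`, `journal`, `year`,
#' `donor`, `affiliation`, `antibody`, `attributes` (array), `anchor_index`,
#' `method`.
#'
#' @param records Donation-record tibble.
#' @param path File path.
#' @return `read_records_jsonl` returns a tibble; `write_records_jsonl`
#'   returns `path` invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    jsonlite::toJSON(list(article_id = r$article_id, journal = r$journal,
                          year = r$year, donor = r$donor,
                          affiliation = r$affiliation, antibody = r$antibody,
                          attributes = r$attributes[[1]],
                          anchor_index = r$anchor_index, method = r$method),
                     auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_records())
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    tibble::tibble(article_id = o$article_id %||% NA_character_,
                   journal = o$journal %||% NA_character_,
                   year = as.integer(o$year %||% NA_integer_),
                   donor = o$donor %||% NA_character_,
                   affiliation = o$affiliation %||% NA_character_,
                   antibody = o$antibody %||% NA_character_,
                   attributes = list(as.character(o$attributes %||% character())),
                   anchor_index = as.integer(o$anchor_index %||% NA_integer_),
                   method = o$method %||% NA_character_)
  })
  do.call(rbind, rows)
}
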