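# Bootstrapped pattern learning for antibody names.
#
# Starting from seed antibody names, every sentence occurrence of a known
# name is constituency-parsed; the leaves of the name's immediate parent noun
# phrase, with the name replaced by a TARGET wildcard, become a learned
# pattern ("the mouse TARGET antibody"). Patterns are then matched against
# every sentence to harvest new names, and the two steps alternate. Names and
# patterns grow monotonically; two iterations are the default (more rounds
# amplify noisy rules). Donors and affiliations of bootstrap records are
# completed with the same context rules as the rule-based extractor.

pattern_tokens <- function(pattern) strsplit(pattern, " ", fixed = TRUE)[[1]]

validate_pattern <- function(pattern) {
  toks <- pattern_tokens(pattern)
  n_target <- sum(toks == "TARGET")
  if (n_target != 1L)
    stop("pattern must contain exactly one TARGET slot: ", pattern)
  if (length(toks) < 2L)
    stop("pattern must contain at least one literal token besides TARGET: ",
         pattern)
  invisible(pattern)
}

# Patterns made of TARGET plus only stop-words (e.g. "the TARGET") amplify
# noise across iterations and are discarded at induction time.
pattern_informative <- function(pattern) {
  toks <- pattern_tokens(pattern)
  lits <- toks[toks != "TARGET"]
  any(!(tolower(lits) %in% .stopword_set))
}

# Find whole-token, case-insensitive occurrences of a (possibly multi-token)
# name; returns start indices.
name_occurrences <- function(token_texts, name_tokens) {
  n <- length(token_texts)
  L <- length(name_tokens)
  if (L == 0L || n < L) return(integer(0))
  low <- tolower(token_texts)
  nm <- tolower(name_tokens)
  starts <- which(low == nm[1L])
  starts[vapply(starts, function(s) {
    s + L - 1L <= n && all(low[s:(s + L - 1L)] == nm)
  }, TRUE)]
}

#' Induce extraction patterns from known antibody names
#'
#' For every sentence occurrence of a known name, takes the leaves of the
#' name token's immediate parent noun phrase and replaces the name with the
#' `TARGET` wildcard. Literals are stored lowercased; duplicates collapse;
#' occurrences without an NP ancestor, patterns without a literal, and
#' patterns whose literals are all stop-words are dropped.
#'
#' @param sentences Character vector of sentences.
#' @param names Character vector of known antibody names (may be
#'   multi-token).
#' @param backend An [nlp_backend()].
#' @return Character vector of patterns, each a space-joined token sequence
#'   containing exactly one `TARGET`, sorted and unique.
#' @examples
#' be <- nlp_backend()
#' induce_patterns("We used the mouse TAG1 antibody", "TAG1", be)
#' @export
induce_patterns <- function(sentences, names, backend) {
  stopifnot(length(names) > 0L)
  name_toks <- lapply(names, function(nm) tokenize(nm)$text)
  out <- character(0)
  for (sent in sentences) {
    toks <- tokenize(sent)
    if (nrow(toks) == 0L) next
    low <- tolower(toks$text)
    tree <- NULL
    for (nt in name_toks) {
      starts <- name_occurrences(toks$text, nt)
      if (!length(starts)) next
      if (is.null(tree)) tree <- constituency_parse(toks, backend)
      for (s in starts) {
        run <- s:(s + length(nt) - 1L)
        np <- immediate_parent_np(tree, s)
        if (is.null(np) || !all(run %in% np)) next
        pat <- character(0)
        for (i in np) {
          if (i %in% run) {
            if (i == s) pat <- c(pat, "TARGET")
          } else {
            pat <- c(pat, low[i])
          }
        }
        if (sum(pat == "TARGET") != 1L || length(pat) < 2L) next
        pattern <- paste(pat, collapse = " ")
        if (!pattern_informative(pattern)) next
        out <- c(out, pattern)
      }
    }
  }
  sort(unique(out))
}

# Tokens a TARGET slot may absorb: must carry an alphanumeric character and
# must not be a stop-word, an anchor keyword or an attribute tag. Spans
# longer than one token must additionally consist of non-dictionary tokens,
# which keeps "mouse TAG1" from matching where "TAG1" alone is meant.
target_token_ok <- function(txt, backend, multi) {
  if (!grepl("[[:alnum:]]", txt)) return(FALSE)
  lw <- tolower(txt)
  if (lw %in% .stopword_set || lw %in% .anchor_words ||
      lw %in% .attribute_tags) return(FALSE)
  if (multi && is_dictionary_word(txt, backend)) return(FALSE)
  TRUE
}

# Internal matcher returning one row per matched TARGET span.
match_pattern_spans <- function(tokens, patterns, backend,
                                max_target_len = 3L) {
  n <- nrow(tokens)
  st <- integer(0); en <- integer(0); nm <- character(0); pt <- character(0)
  if (n == 0L || !length(patterns)) {
    return(data.frame(start = st, end = en, name = nm, pattern = pt,
                      stringsAsFactors = FALSE))
  }
  low <- tolower(tokens$text)
  src <- attr(tokens, "source")
  for (pattern in patterns) {
    validate_pattern(pattern)
    ptoks <- pattern_tokens(pattern)
    tpos <- which(ptoks == "TARGET")
    pre <- if (tpos > 1L) tolower(ptoks[seq_len(tpos - 1L)]) else character(0)
    post <- if (tpos < length(ptoks))
      tolower(ptoks[(tpos + 1L):length(ptoks)]) else character(0)
    for (L in seq_len(max_target_len)) {
      maxstart <- n - length(pre) - length(post) - L + 1L
      if (maxstart < 1L) next
      for (s in seq_len(maxstart)) {
        tstart <- s + length(pre)
        tend <- tstart + L - 1L
        if (length(pre) && !all(low[s:(tstart - 1L)] == pre)) next
        if (length(post) &&
            !all(low[(tend + 1L):(tend + length(post))] == post)) next
        span_ok <- all(vapply(tokens$text[tstart:tend], target_token_ok,
                              TRUE, backend = backend, multi = L > 1L))
        if (!span_ok) next
        surface <- if (!is.null(src))
          substr(src, tokens$start[tstart], tokens$end[tend])
        else paste(tokens$text[tstart:tend], collapse = " ")
        st <- c(st, tstart); en <- c(en, tend)
        nm <- c(nm, surface); pt <- c(pt, pattern)
      }
    }
  }
  keep <- !duplicated(paste(st, en))
  data.frame(start = st[keep], end = en[keep], name = nm[keep],
             pattern = pt[keep], stringsAsFactors = FALSE)
}

#' Match learned patterns against a sentence
#'
#' Every contiguous token window whose literals match the pattern
#' (case-insensitively) contributes the token(s) aligned with `TARGET`; the
#' result is the union over patterns. `TARGET` may absorb up to
#' `max_target_len` tokens (multi-token antibody names), but never stop-words,
#' attribute tags, the anchor keywords, or punctuation.
#'
#' @param sentence Character scalar or token data frame.
#' @param patterns Character vector of patterns (see [induce_patterns()]).
#' @param backend An [nlp_backend()].
#' @param max_target_len Maximum tokens a TARGET slot may span (default 3).
#' @return Character vector of matched name surface strings (unique).
#' @examples
#' be <- nlp_backend()
#' match_patterns("is thanked for the antibody to UL7", "antibody to TARGET", be)
#' @export
match_patterns <- function(sentence, patterns, backend, max_target_len = 3L) {
  tokens <- if (is.data.frame(sentence)) sentence else tokenize(sentence)
  unique(match_pattern_spans(tokens, patterns, backend,
                             max_target_len = max_target_len)$name)
}

#' Run the bootstrapping loop
#'
#' Alternates pattern induction (over the current name set) and pattern
#' matching (over the current pattern set) for `n_iterations` rounds starting
#' from the seed names. Both sets grow monotonically; names are tracked
#' lowercased (surface forms are recovered at record-extraction time).
#'
#' @param sentences Character vector of corpus sentences (see
#'   [corpus_sentences()] to derive them from acknowledgements).
#' @param seeds Character vector of seed antibody names (non-empty).
#' @param backend An [nlp_backend()].
#' @param n_iterations Number of rounds (default 2; more rounds tend to admit
#'   noisy rules).
#' @return An object of class `bootstrap_state`: list with `names`
#'   (lowercased, includes seeds), `patterns`, `iteration`, and per-item
#'   origin iterations (`name_origin`, `pattern_origin`; 0 = seed).
#' @export
run_bootstrap <- function(sentences, seeds, backend, n_iterations = 2L) {
  stopifnot(length(seeds) > 0L, n_iterations >= 1L)
  names_set <- unique(tolower(seeds))
  name_origin <- stats::setNames(rep(0L, length(names_set)), names_set)
  patterns <- character(0)
  pattern_origin <- integer(0)
  token_cache <- lapply(sentences, tokenize)
  for (it in seq_len(n_iterations)) {
    new_pats <- induce_patterns(sentences, names_set, backend)
    add_p <- setdiff(new_pats, patterns)
    patterns <- c(patterns, add_p)
    pattern_origin <- c(pattern_origin,
                        stats::setNames(rep(it, length(add_p)), add_p))
    if (length(patterns)) {
      found <- unique(tolower(unlist(
        lapply(token_cache, function(tk)
          match_pattern_spans(tk, patterns, backend)$name))))
      add_n <- setdiff(found, names_set)
      names_set <- c(names_set, add_n)
      name_origin <- c(name_origin,
                       stats::setNames(rep(it, length(add_n)), add_n))
    }
  }
  structure(list(names = names_set, patterns = patterns, iteration = n_iterations,
                 name_origin = name_origin, pattern_origin = pattern_origin),
            class = "bootstrap_state")
}

#' @export
print.bootstrap_state <- function(x, ...) {
  cat(sprintf("<bootstrap_state: %d names (%d seeded), %d patterns, %d iteration(s)>\n",
              length(x$names), sum(x$name_origin == 0L), length(x$patterns),
              x$iteration))
  if (length(x$patterns)) {
    cat("patterns:\n")
    cat(paste0("  ", x$patterns), sep = "\n")
  }
  invisible(x)
}

#' Sentences of an acknowledgement corpus
#'
#' @param acks List of [acknowledgement()] objects.
#' @return Character vector of sentence strings.
#' @export
corpus_sentences <- function(acks) {
  unlist(lapply(acks, function(a) split_sentence_strings(a$text)),
         use.names = FALSE) %||% character(0)
}

#' Extract antibody donations using a bootstrap state
#'
#' Antibody names are found by matching the learned patterns; the donor and
#' affiliation of each match are completed with the rule-based context
#' procedures ([extract_donor()], [extract_affiliation()]) anchored on the
#' matched name's position, and attribute tags are read off the name's left
#' context window.
#'
#' @param ack An [acknowledgement()].
#' @param state A [run_bootstrap()] result.
#' @param backend An [nlp_backend()].
#' @param window Attribute context window width (default 4 tokens).
#' @param donor_scope `"paragraph"` (default) or `"sentence"`.
#' @return Donation-record tibble as in [extract_donations()], with
#'   `method = "bootstrap"` and `anchor_index` at the matched name's first
#'   token.
#' @export
extract_donations_bootstrap <- function(ack, state, backend, window = 4L,
                                        donor_scope = c("paragraph", "sentence")) {
  donor_scope <- match.arg(donor_scope)
  stopifnot(inherits(ack, "acknowledgement"),
            inherits(state, "bootstrap_state"))
  tokens <- tokenize(ack$text)
  entities <- tag_entities(tokens, backend)
  spans <- match_pattern_spans(tokens, state$patterns, backend)
  rows <- list()
  if (nrow(spans)) spans <- spans[order(spans$start), , drop = FALSE]
  sid <- sentence_ids(tokens)
  for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]
    donor <- extract_donor(tokens, s, entities, scope = donor_scope)
    affil <- extract_affiliation(tokens, donor, s, entities)
    left <- integer(0)
    j <- s - 1L
    while (j >= 1L && length(left) < window && sid[j] == sid[s] &&
           !(tokens$text[j] %in% .sentence_end)) {
      left <- c(left, j)
      j <- j - 1L
    }
    pseudo_anchor <- list(anchor_index = s, left = left, right = integer(0))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      article_id = ack$article_id,
      journal = ack$journal,
      year = ack$year,
      donor = if (!is.null(donor)) donor$text else NA_character_,
      affiliation = if (!is.null(affil)) affil$text else NA_character_,
      antibody = spans$name[r],
      attributes = list(extract_attributes(tokens, pseudo_anchor)),
      anchor_index = s,
      method = "bootstrap")
  }
  if (!length(rows)) return(empty_records())
  out <- do.call(rbind, rows)
  key <- paste(ifelse(is.na(out$donor), "", out$donor), out$antibody,
               sep = "\r")
  out[!duplicated(key), , drop = FALSE]
}

#' Run the bootstrap extractor over a corpus
#'
#' @param acks List of [acknowledgement()] objects.
#' @inheritParams extract_donations_bootstrap
#' @return One donation-record tibble.
#' @export
extract_donations_bootstrap_corpus <- function(acks, state, backend,
                                               window = 4L,
                                               donor_scope = c("paragraph", "sentence")) {
  donor_scope <- match.arg(donor_scope)
  rows <- lapply(acks, extract_donations_bootstrap, state = state,
                 backend = backend, window = window, donor_scope = donor_scope)
  tibble::as_tibble(do.call(rbind, c(list(empty_records()), rows)))
}

#' Read / write seed and pattern files
#'
#' Seed files carry one antibody name per line; pattern files one
#' space-joined pattern per line with a literal `TARGET`.
#'
#' @param path File path.
#' @param x Character vector to write.
#' @return Character vector (readers) or `path` invisibly (writers).
#' @export
read_seed_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @rdname read_seed_file
#' @export
write_pattern_file <- function(x, path) {
  for (p in x) validate_pattern(p)
  writeLines(x, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname read_seed_file
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (p in lines) validate_pattern(p)
  lines
}
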