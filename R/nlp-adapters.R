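# Tokenization, dictionary, named-entity and constituency-parse contracts.
# The shipped backend is a deterministic gazetteer/grammar fixture: entities
# come from word lists, the parse from a small chunking grammar. Any
# production tagger/parser can be plugged in behind the same contract.

.open_punct <- c("(", "[", "{", "\"", "'", "“", "‘")
.close_punct <- c(")", "]", "}", "\"", "'", "”", "’",
                  ",", ";", ":", ".", "!", "?")
.abbrev_tokens <- c("dr.", "prof.", "mr.", "mrs.", "ms.", "jr.", "sr.",
                    "st.", "vs.", "al.", "no.", "fig.", "e.g.", "i.e.")
.sentence_end <- c(".", "!", "?")
.anchor_words <- c("antibody", "antibodies")
.attribute_tags <- c("primary", "secondary", "monoclonal", "polyclonal")

# Closed-class lexicon for the fixture grammar; everything else with an
# alphanumeric character is treated as nominal.
.pos_lexicon <- list(
  DET  = c("the", "a", "an", "this", "that", "these", "those", "each",
           "every", "his", "her", "its", "their", "our", "my", "your"),
  PRON = c("we", "i", "you", "he", "she", "it", "they", "who", "us", "them"),
  PREP = c("of", "to", "for", "from", "by", "in", "on", "with", "at", "into",
           "during", "without", "against", "among", "between", "through"),
  VERB = c("is", "are", "was", "were", "be", "been", "being", "am",
           "has", "have", "had", "do", "does", "did",
           "thank", "thanks", "thanked", "thanking",
           "provide", "provides", "provided", "providing",
           "give", "gives", "gave", "given", "giving",
           "donate", "donated", "donates", "donating",
           "supply", "supplied", "supplies", "supplying",
           "use", "used", "uses", "using", "share", "shared", "sharing",
           "support", "supported", "supports", "supporting",
           "read", "reading", "acknowledge", "acknowledged",
           "wish", "like", "would", "will", "can", "may", "must"),
  ADV  = c("generously", "kindly", "gratefully", "also", "very", "so", "not"),
  CC   = c("and", "or", "but", "nor")
)

.stopword_set <- unique(c(.pos_lexicon$DET, .pos_lexicon$PRON,
                          .pos_lexicon$PREP, .pos_lexicon$CC,
                          .pos_lexicon$ADV,
                          c("is", "are", "was", "were", "be", "been", "being",
                            "has", "have", "had", "will", "would", "can",
                            "may", "must")))

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct an NLP fixture backend
#'
#' Bundles the resources the extractors depend on: person / organization /
#' location gazetteers (used for longest-match named-entity tagging) and an
#' English word list (used for the dictionary membership test that separates
#' antibody names from ordinary words). The backend is fully deterministic:
#' repeated calls on the same input always give identical results.
#'
#' @param persons,organizations,locations Character vectors of gazetteer
#'   entries, one surface form per element (e.g. `"Y. Nishiyama"`,
#'   `"Indiana University"`).
#' @param dictionary Character vector of English words (lowercased
#'   internally). Defaults to the compact word list shipped with the package.
#' @return An object of class `nlp_backend`.
#' @examples
#' be <- nlp_backend(persons = "Y. Nishiyama")
#' tag_entities(tokenize("Dr. Y. Nishiyama is thanked"), be)
#' @export
nlp_backend <- function(persons = character(), organizations = character(),
                        locations = character(),
                        dictionary = ackminer_dictionary()) {
  stopifnot(is.character(persons), is.character(organizations),
            is.character(locations), is.character(dictionary))
  be <- list(
    persons = unique(persons[nzchar(persons)]),
    organizations = unique(organizations[nzchar(organizations)]),
    locations = unique(locations[nzchar(locations)]),
    dictionary = unique(tolower(dictionary[nzchar(dictionary)]))
  )
  # Pre-tokenize gazetteer entries and index them by first token so entity
  # tagging is a hash lookup per position rather than a scan of all entries.
  be$gazetteer_index <- lapply(
    be[c("persons", "organizations", "locations")],
    function(entries) {
      toks <- lapply(entries, function(e) tokenize(e)$text)
      keep <- lengths(toks) > 0L
      toks <- toks[keep]
      split(toks, vapply(toks, `[`, "", 1L))
    }
  )
  names(be$gazetteer_index) <- c("person", "organization", "location")
  structure(be, class = "nlp_backend")
}

#' @export
print.nlp_backend <- function(x, ...) {
  cat("<nlp_backend (gazetteer fixture)>\n")
  cat(sprintf("  persons: %d  organizations: %d  locations: %d  dictionary: %d words\n",
              length(x$persons), length(x$organizations), length(x$locations),
              length(x$dictionary)))
  invisible(x)
}

#' The word list shipped with the package
#'
#' @return Character vector of lowercase English words.
#' @export
ackminer_dictionary <- function() {
  path <- system.file("extdata", "english-words.txt", package = "ackminer")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines
}

#' Read gazetteer and word-list files from a directory
#'
#' Expects `persons.txt`, `organizations.txt`, `locations.txt` and optionally
#' `words.txt`, each UTF-8 with one entry per line. Missing files yield empty
#' gazetteers.
#'
#' @param dir Directory path.
#' @return An `nlp_backend`.
#' @export
read_gazetteers <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readLines(p, encoding = "UTF-8") else character()
  }
  words <- rd("words.txt")
  nlp_backend(persons = rd("persons.txt"),
              organizations = rd("organizations.txt"),
              locations = rd("locations.txt"),
              dictionary = if (length(words)) words else ackminer_dictionary())
}

# Split one whitespace-delimited chunk into tokens: leading brackets/quotes
# and trailing punctuation become their own tokens; a trailing period stays
# attached to initials ("Y.") and known abbreviations ("Dr.").
split_raw_token <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  n <- length(chars)
  lead <- 0L
  while (lead < n && chars[lead + 1L] %in% .open_punct) lead <- lead + 1L
  trail <- 0L
  repeat {
    core_len <- n - lead - trail
    if (core_len <= 1L) break
    last <- chars[n - trail]
    if (!(last %in% .close_punct)) break
    if (last == ".") {
      core <- paste(chars[(lead + 1L):(n - trail)], collapse = "")
      if (grepl("^[A-Za-z]\\.$", core) || tolower(core) %in% .abbrev_tokens)
        break
    }
    trail <- trail + 1L
  }
  texts <- character(0)
  offs <- integer(0)
  if (lead > 0L) {
    texts <- chars[seq_len(lead)]
    offs <- seq_len(lead)
  }
  core_len <- n - lead - trail
  if (core_len > 0L) {
    texts <- c(texts, paste(chars[(lead + 1L):(n - trail)], collapse = ""))
    offs <- c(offs, lead + 1L)
  }
  if (trail > 0L) {
    texts <- c(texts, chars[(n - trail + 1L):n])
    offs <- c(offs, (n - trail + 1L):n)
  }
  list(texts = texts, offsets = offs)
}

#' Tokenize text
#'
#' Whitespace tokenization with punctuation splitting: brackets, quotes and
#' sentence punctuation become their own tokens (the affiliation heuristic
#' needs `(` and `)` as tokens), while abbreviation periods ("Dr.", initials
#' like "Y.") stay attached. Concatenating token texts with the skipped
#' whitespace restores the input exactly.
#'
#' @param text Character scalar (NFC-normalized internally).
#' @return A data frame with columns `text`, `index` (1-based token
#'   position), `start`, `end` (1-based inclusive character span such that
#'   `substr(text, start, end) == text`), carrying the source string as
#'   attribute `"source"`.
#' @examples
#' tokenize("K. Mackie (Indiana University)")$text
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringi::stri_trans_nfc(text)
  empty <- data.frame(text = character(), index = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  attr(empty, "source") <- text
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  lens <- attr(m, "match.length")
  texts <- character(0)
  starts <- integer(0)
  for (k in seq_along(m)) {
    raw <- substr(text, m[k], m[k] + lens[k] - 1L)
    sp <- split_raw_token(raw)
    texts <- c(texts, sp$texts)
    starts <- c(starts, m[k] + sp$offsets - 1L)
  }
  out <- data.frame(text = texts, index = seq_along(texts), start = starts,
                    end = starts + nchar(texts) - 1L, stringsAsFactors = FALSE)
  attr(out, "source") <- text
  out
}

#' Dictionary membership test
#'
#' A token counts as an English word when its lowercased form (trailing
#' periods stripped, so "Dr." resolves to "dr") appears in the backend's word
#' list. Hyphenated tokens are dictionary words only when the whole hyphenated
#' form is listed, so "anti-tubulin" fails the test and is eligible as an
#' antibody name.
#'
#' @param token_text Character vector of token texts.
#' @param backend An [nlp_backend()].
#' @return Logical vector.
#' @export
is_dictionary_word <- function(token_text, backend) {
  stopifnot(inherits(backend, "nlp_backend"))
  w <- sub("\\.+$", "", tolower(token_text))
  w %in% backend$dictionary
}

#' Tag named entities by gazetteer lookup
#'
#' Longest-match, left-to-right, non-overlapping lookup of the backend's
#' person / organization / location gazetteers against the token sequence
#' (exact, case-sensitive token match). On equal length, person beats
#' organization beats location.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param backend An [nlp_backend()].
#' @return Data frame with columns `label`, `start`, `end` (inclusive token
#'   indices), `text` (surface string).
#' @export
tag_entities <- function(tokens, backend) {
  stopifnot(inherits(backend, "nlp_backend"))
  n <- nrow(tokens)
  src <- attr(tokens, "source")
  labs <- character(0); st <- integer(0); en <- integer(0); tx <- character(0)
  i <- 1L
  while (i <= n) {
    best_len <- 0L
    best_lab <- NA_character_
    for (lab in c("person", "organization", "location")) {
      cand <- backend$gazetteer_index[[lab]][[tokens$text[i]]]
      if (is.null(cand)) next
      for (entry in cand) {
        L <- length(entry)
        if (L > best_len && i + L - 1L <= n &&
            all(tokens$text[i:(i + L - 1L)] == entry)) {
          best_len <- L
          best_lab <- lab
        }
      }
    }
    if (best_len > 0L) {
      j <- i + best_len - 1L
      labs <- c(labs, best_lab); st <- c(st, i); en <- c(en, j)
      tx <- c(tx, if (!is.null(src))
        substr(src, tokens$start[i], tokens$end[j])
      else paste(tokens$text[i:j], collapse = " "))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(label = labs, start = st, end = en, text = tx,
             stringsAsFactors = FALSE)
}

classify_token <- function(txt) {
  if (!grepl("[[:alnum:]]", txt)) return("PUNCT")
  lw <- sub("\\.+$", "", tolower(txt))
  for (cls in names(.pos_lexicon)) {
    if (lw %in% .pos_lexicon[[cls]]) return(cls)
  }
  "N"
}

np_node <- function(children) list(label = "NP", children = children)
leaf_node <- function(index, text) list(label = "TOK", index = index, text = text)
is_leaf <- function(node) identical(node$label, "TOK")

#' Constituency parse (fixture grammar)
#'
#' A deterministic chunking grammar sufficient for donation sentences: noun
#' phrases are built from optional-determiner + nominal runs, and an NP
#' followed by "of"/"to" and a bare nominal run is merged into one larger NP
#' (so the lowest NP over "UL7" in "antibody to UL7" spans all three tokens).
#' Tokens outside any NP hang directly off the sentence root; an input the
#' grammar cannot chunk degrades to a flat tree rather than failing.
#'
#' @param tokens Token data frame from [tokenize()] covering one sentence.
#' @param backend Unused by the fixture grammar; kept so alternative parser
#'   backends can share the signature.
#' @return Nested list tree: nodes are `list(label, children)`, leaves
#'   `list(label = "TOK", index, text)`. Leaves read left to right reproduce
#'   the token sequence.
#' @export
constituency_parse <- function(tokens, backend = NULL) {
  n <- nrow(tokens)
  if (n == 0L) return(list(label = "S", children = list()))
  pos <- vapply(tokens$text, classify_token, "", USE.NAMES = FALSE)
  items <- list()
  i <- 1L
  while (i <= n) {
    if (pos[i] %in% c("DET", "N")) {
      nstart <- if (pos[i] == "DET") i + 1L else i
      j <- nstart
      while (j <= n && pos[j] == "N") j <- j + 1L
      if (j > nstart) {
        kids <- lapply(i:(j - 1L), function(k) leaf_node(k, tokens$text[k]))
        items[[length(items) + 1L]] <- np_node(kids)
        i <- j
        next
      }
    }
    items[[length(items) + 1L]] <- leaf_node(i, tokens$text[i])
    i <- i + 1L
  }
  # Merge NP + of/to + determinerless NP into one NP whose direct leaves are
  # the preposition and the right-hand run (the left NP stays a sub-tree).
  k <- 1L
  while (k + 2L <= length(items)) {
    a <- items[[k]]; b <- items[[k + 1L]]; d <- items[[k + 2L]]
    if (identical(a$label, "NP") && is_leaf(b) &&
        tolower(b$text) %in% c("of", "to") &&
        identical(d$label, "NP") &&
        classify_token(d$children[[1L]]$text) != "DET") {
      items[[k]] <- np_node(c(list(a), list(b), d$children))
      items <- items[-c(k + 1L, k + 2L)]
    } else {
      k <- k + 1L
    }
  }
  list(label = "S", children = items)
}

#' Leaves of a parse tree
#'
#' @param tree Tree from [constituency_parse()].
#' @return Integer vector of token indices in left-to-right order.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$index)
  unlist(lapply(tree$children, tree_leaves)) %||% integer(0)
}

find_node_path <- function(node, index) {
  if (is_leaf(node)) {
    if (node$index == index) return(list(node)) else return(NULL)
  }
  for (child in node$children) {
    p <- find_node_path(child, index)
    if (!is.null(p)) return(c(list(node), p))
  }
  NULL
}

#' Leaves of the immediate parent noun phrase
#'
#' Finds the lowest NP ancestor of the target token and returns the token
#' indices of its leaves; `NULL` when the token has no NP ancestor (e.g. in a
#' degraded flat tree).
#'
#' @param tree Tree from [constituency_parse()].
#' @param target_token_index Token index of the target leaf.
#' @return Integer vector of token indices, or `NULL`.
#' @export
immediate_parent_np <- function(tree, target_token_index) {
  path <- find_node_path(tree, target_token_index)
  if (is.null(path)) stop("token index ", target_token_index,
                          " not found among parse-tree leaves")
  nps <- Filter(function(nd) identical(nd$label, "NP"), path)
  if (!length(nps)) return(NULL)
  sort(tree_leaves(nps[[length(nps)]]))
}

# Sentence id per token: increments after ".", "!" or "?".
sentence_ids <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0L) return(integer(0))
  ends <- tokens$text %in% .sentence_end
  c(1L, 1L + cumsum(ends))[seq_len(n)]
}

# Split a paragraph into sentence strings using token offsets, so each
# sentence is an exact substring of the source.
split_sentence_strings <- function(text) {
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(character(0))
  sid <- sentence_ids(toks)
  src <- attr(toks, "source")
  vapply(split(seq_len(nrow(toks)), sid), function(idx) {
    substr(src, toks$start[idx[1L]], toks$end[idx[length(idx)]])
  }, "", USE.NAMES = FALSE)
}
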