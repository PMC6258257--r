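# Independent reference implementations used as oracles: a full-DOM
# acknowledgement extractor, a brute-force rule extractor, and a brute-force
# fixed-point bootstrapper. They share only the adapter contracts (tokenize,
# tag_entities, dictionary, parse) with the implementations under test.

dom_ack_text <- function(xml_string) {
  doc <- xml2::read_xml(xml_string, options = "")  # keep blank text nodes
  node <- xml2::xml_find_first(doc, "//ack")
  if (inherits(node, "xml_missing")) return(NULL)
  txt <- xml2::xml_text(node)
  txt <- gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", txt))
  if (nzchar(txt)) txt else NULL
}

oracle_sentence_id <- function(texts) {
  ids <- integer(length(texts))
  cur <- 1L
  for (i in seq_along(texts)) {
    ids[i] <- cur
    if (texts[i] %in% c(".", "!", "?")) cur <- cur + 1L
  }
  ids
}

oracle_window <- function(texts, i, dir, width) {
  sid <- oracle_sentence_id(texts)
  out <- integer(0)
  j <- i + dir
  while (j >= 1 && j <= length(texts) && length(out) < width) {
    if (sid[j] != sid[i] || texts[j] %in% c(".", "!", "?")) break
    out <- c(out, j)
    j <- j + dir
  }
  out
}

oracle_extract_donations <- function(ack, backend, window = 4) {
  toks <- tokenize(ack$text)
  texts <- toks$text
  ents <- tag_entities(toks, backend)
  covered <- rep(FALSE, length(texts))
  for (r in seq_len(nrow(ents)))
    covered[ents$start[r]:ents$end[r]] <- TRUE
  rows <- NULL
  seen <- character(0)
  for (i in seq_along(texts)) {
    if (!(tolower(texts[i]) %in% c("antibody", "antibodies"))) next
    left <- oracle_window(texts, i, -1L, window)
    right <- oracle_window(texts, i, +1L, window)
    pick <- function(idx) {
      for (j in idx) {
        if (!grepl("[[:alnum:]]", texts[j])) next
        if (tolower(texts[j]) %in% c("antibody", "antibodies")) next
        if (is_dictionary_word(texts[j], backend)) next
        if (covered[j]) next
        return(j)
      }
      NA_integer_
    }
    nm_idx <- pick(left)
    if (is.na(nm_idx) && any(tolower(texts[right]) %in% c("of", "to")))
      nm_idx <- pick(right)
    attrs <- c("primary", "secondary", "monoclonal", "polyclonal")
    attrs <- attrs[attrs %in% tolower(texts[left])]
    from <- if (!is.na(nm_idx)) nm_idx else i
    donor_row <- NA_integer_
    for (r in seq_len(nrow(ents))) {
      if (ents$label[r] != "person" || ents$end[r] >= from) next
      if (is.na(donor_row) || ents$end[r] > ents$end[donor_row]) donor_row <- r
    }
    if (is.na(nm_idx) && is.na(donor_row)) next
    affil_row <- NA_integer_
    if (!is.na(donor_row)) {
      for (r in seq_len(nrow(ents))) {
        if (ents$label[r] != "organization") next
        if (ents$start[r] <= ents$end[donor_row] || ents$end[r] >= i) next
        if (is.na(affil_row) || ents$start[r] < ents$start[affil_row])
          affil_row <- r
      }
    }
    donor <- if (!is.na(donor_row)) ents$text[donor_row] else NA_character_
    affil <- if (!is.na(affil_row)) ents$text[affil_row] else NA_character_
    antibody <- if (!is.na(nm_idx)) texts[nm_idx] else NA_character_
    key <- paste(ifelse(is.na(donor), "", donor),
                 ifelse(is.na(antibody), "", antibody), sep = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    rows <- rbind(rows, data.frame(
      donor = donor, affiliation = affil, antibody = antibody,
      attributes = paste(attrs, collapse = ","), anchor_index = i,
      stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(donor = character(), affiliation = character(),
                       antibody = character(), attributes = character(),
                       anchor_index = integer(), stringsAsFactors = FALSE)
  rows
}

# Exhaustive re-scan bootstrapper: every round recomputes all patterns from
# all current names and all names from all current patterns, from scratch.
oracle_bootstrap <- function(sentences, seeds, backend, n_iterations = 2) {
  stopords <- ackminer:::.stopword_set
  attrs <- c("primary", "secondary", "monoclonal", "polyclonal")
  toks_list <- lapply(sentences, tokenize)
  names_set <- unique(tolower(seeds))
  patterns <- character(0)
  induce_all <- function(nms) {
    pats <- character(0)
    for (toks in toks_list) {
      if (nrow(toks) == 0) next
      tree <- constituency_parse(toks)
      low <- tolower(toks$text)
      for (nm in nms) {
        nt <- tolower(tokenize(nm)$text)
        L <- length(nt)
        if (L == 0) next
        for (s in seq_len(max(0, nrow(toks) - L + 1))) {
          if (!all(low[s:(s + L - 1)] == nt)) next
          np <- immediate_parent_np(tree, s)
          if (is.null(np) || !all(s:(s + L - 1) %in% np)) next
          pat <- character(0)
          for (j in np) {
            if (j >= s && j <= s + L - 1) {
              if (j == s) pat <- c(pat, "TARGET")
            } else pat <- c(pat, low[j])
          }
          if (length(pat) < 2 || sum(pat == "TARGET") != 1) next
          lits <- pat[pat != "TARGET"]
          if (all(lits %in% stopords)) next
          pats <- c(pats, paste(pat, collapse = " "))
        }
      }
    }
    sort(unique(pats))
  }
  match_all <- function(pats) {
    found <- character(0)
    for (toks in toks_list) {
      low <- tolower(toks$text)
      n <- nrow(toks)
      for (p in pats) {
        pt <- strsplit(p, " ", fixed = TRUE)[[1]]
        tpos <- which(pt == "TARGET")
        for (L in 1:3) {
          for (s in seq_len(max(0, n - length(pt) - L + 2))) {
            ok <- TRUE
            ti <- s
            for (q in seq_along(pt)) {
              if (q == tpos) {
                span <- ti:(ti + L - 1)
                for (j in span) {
                  tx <- toks$text[j]
                  if (!grepl("[[:alnum:]]", tx) || tolower(tx) %in% stopords ||
                      tolower(tx) %in% c("antibody", "antibodies") ||
                      tolower(tx) %in% attrs ||
                      (L > 1 && is_dictionary_word(tx, backend))) {
                    ok <- FALSE
                    break
                  }
                }
                ti <- ti + L
              } else {
                if (low[ti] != tolower(pt[q])) {
                  ok <- FALSE
                  break
                }
                ti <- ti + 1
              }
            }
            if (ok) {
              span <- (s + tpos - 1):(s + tpos - 1 + L - 1)
              found <- c(found, tolower(paste(toks$text[span], collapse = " ")))
            }
          }
        }
      }
    }
    unique(found)
  }
  for (it in seq_len(n_iterations)) {
    patterns <- sort(unique(c(patterns, induce_all(names_set))))
    if (length(patterns))
      names_set <- unique(c(names_set, match_all(patterns)))
  }
  list(names = sort(names_set), patterns = patterns)
}

# Naive bootstrap record extraction given a fixed pattern set: exhaustive
# window matching plus brute-force donor/affiliation search.
oracle_extract_bootstrap <- function(ack, patterns, backend) {
  stopords <- ackminer:::.stopword_set
  attrs <- c("primary", "secondary", "monoclonal", "polyclonal")
  toks <- tokenize(ack$text)
  low <- tolower(toks$text)
  n <- nrow(toks)
  ents <- tag_entities(toks, backend)
  spans <- NULL
  for (p in patterns) {
    pt <- strsplit(p, " ", fixed = TRUE)[[1]]
    tpos <- which(pt == "TARGET")
    for (L in 1:3) {
      for (s in seq_len(max(0, n - length(pt) - L + 2))) {
        ok <- TRUE
        ti <- s
        for (q in seq_along(pt)) {
          if (q == tpos) {
            for (j in ti:(ti + L - 1)) {
              tx <- toks$text[j]
              if (!grepl("[[:alnum:]]", tx) || tolower(tx) %in% stopords ||
                  tolower(tx) %in% c("antibody", "antibodies") ||
                  tolower(tx) %in% attrs ||
                  (L > 1 && is_dictionary_word(tx, backend))) {
                ok <- FALSE
                break
              }
            }
            ti <- ti + L
          } else {
            if (low[ti] != tolower(pt[q])) {
              ok <- FALSE
              break
            }
            ti <- ti + 1
          }
        }
        if (ok) {
          st <- as.integer(s + tpos - 1L)
          spans <- rbind(spans,
                         data.frame(start = st, end = as.integer(st + L - 1L)))
        }
      }
    }
  }
  rows <- NULL
  seen <- character(0)
  if (!is.null(spans)) {
    spans <- unique(spans)
    spans <- spans[order(spans$start), , drop = FALSE]
    src <- attr(toks, "source")
    for (r in seq_len(nrow(spans))) {
      st <- spans$start[r]
      donor_row <- NA_integer_
      for (e in seq_len(nrow(ents))) {
        if (ents$label[e] != "person" || ents$end[e] >= st) next
        if (is.na(donor_row) || ents$end[e] > ents$end[donor_row])
          donor_row <- e
      }
      affil_row <- NA_integer_
      if (!is.na(donor_row)) {
        for (e in seq_len(nrow(ents))) {
          if (ents$label[e] != "organization") next
          if (ents$start[e] <= ents$end[donor_row] || ents$end[e] >= st) next
          if (is.na(affil_row) || ents$start[e] < ents$start[affil_row])
            affil_row <- e
        }
      }
      name <- substr(src, toks$start[st], toks$end[spans$end[r]])
      donor <- if (!is.na(donor_row)) ents$text[donor_row] else NA_character_
      key <- paste(ifelse(is.na(donor), "", donor), name, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows <- rbind(rows, data.frame(
        donor = donor,
        affiliation = if (!is.na(affil_row)) ents$text[affil_row]
                      else NA_character_,
        antibody = name, anchor_index = st, stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows))
    rows <- data.frame(donor = character(), affiliation = character(),
                       antibody = character(), anchor_index = integer(),
                       stringsAsFactors = FALSE)
  rows
}
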