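# Harvest acknowledgement sections from JATS/PMC XML. The section is located
# by a shallow linear regex scan rather than a full DOM parse: building the
# complete parse tree of every full-text article is needlessly expensive when
# only one section is wanted.

#' Construct an acknowledgement record
#'
#' @param text Plain-text acknowledgement paragraph (non-empty after
#'   whitespace normalization).
#' @param article_id Article identifier (PMC accession style); must be
#'   non-empty.
#' @param journal,year Optional article metadata; `year`, when present, must
#'   be a 4-digit positive integer.
#' @param char_offsets Optional `c(start, end)` character span of the section
#'   body inside the raw XML the record was cut from.
#' @return An object of class `acknowledgement`.
#' @export
acknowledgement <- function(text, article_id, journal = NA_character_,
                            year = NA_integer_, char_offsets = NULL) {
  text <- squeeze_ws(text)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text),
            is.character(article_id), length(article_id) == 1L,
            nzchar(article_id))
  journal <- as.character(journal %||% NA_character_)
  if (length(journal) == 0L) journal <- NA_character_
  year <- suppressWarnings(as.integer(year %||% NA_integer_))
  if (length(year) == 0L) year <- NA_integer_
  if (!is.na(year) && (year < 1000L || year > 9999L))
    stop("year must be a 4-digit positive integer, got ", year)
  structure(list(article_id = article_id,
                 journal = as.character(journal),
                 year = year,
                 text = text,
                 char_offsets = char_offsets),
            class = "acknowledgement")
}

#' @export
print.acknowledgement <- function(x, ...) {
  cat(sprintf("<acknowledgement %s%s%s>\n", x$article_id,
              if (!is.na(x$journal)) paste0(", ", x$journal) else "",
              if (!is.na(x$year)) paste0(", ", x$year) else ""))
  cat(strwrap(x$text, width = 76), sep = "\n")
  invisible(x)
}

squeeze_ws <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x, perl = TRUE), perl = TRUE)
}

strip_tags <- function(x) {
  x <- gsub("<[^>]*>", " ", x, perl = TRUE)
  # minimal XML entity decoding; numeric references are rare in PMC ack text
  ents <- c("&lt;" = "<", "&gt;" = ">", "&quot;" = "\"",
            "&apos;" = "'", "&#39;" = "'", "&amp;" = "&")
  for (e in names(ents)) x <- gsub(e, ents[[e]], x, fixed = TRUE)
  squeeze_ws(x)
}

first_capture <- function(x, pattern) {
  m <- regmatches(x, regexec(pattern, x, perl = TRUE))[[1]]
  if (length(m) >= 2L) m[2] else NA_character_
}

#' Extract the acknowledgement section from a JATS/PMC XML document
#'
#' Two-tier shallow scan: the JATS `<ack>` element is matched first; when no
#' `<ack>` exists, a heading matching `Acknowledg(e)?ments?` is tried, taking
#' the text up to the next section heading. Inline tags are stripped and
#' whitespace collapsed. Article id, journal and year are picked up from the
#' usual JATS front-matter elements when present.
#'
#' @param document JATS XML as a single string.
#' @param article_id Fallback identifier used when the XML carries no
#'   `<article-id>`.
#' @return An [acknowledgement()], or `NULL` when the document has no
#'   acknowledgement section. An `<ack>` element that opens but never closes
#'   raises an error of class `ackminer_malformed`.
#' @examples
#' parse_acknowledgement(
#'   "<article><ack><p>We thank A. B. for the anti-GFP antibody.</p></ack></article>",
#'   article_id = "PMC1")
#' @export
parse_acknowledgement <- function(document, article_id = "unknown") {
  stopifnot(is.character(document), length(document) == 1L)
  x <- stringi::stri_trans_nfc(document)

  body <- NULL
  offsets <- NULL
  open <- regexpr("<ack[\\s>]", x, perl = TRUE)
  if (open != -1L) {
    tail_from_open <- substr(x, open, nchar(x))
    gtpos <- regexpr(">", tail_from_open, fixed = TRUE)
    close <- regexpr("</ack>", x, fixed = TRUE)
    if (gtpos == -1L || close == -1L || close < open)
      stop(errorCondition(
        "acknowledgement section opens but never closes (<ack> without </ack>)",
        class = c("ackminer_malformed", "error", "condition")))
    start <- open + gtpos
    body <- substr(x, start, close - 1L)
    offsets <- c(start = start, end = close - 1L)
  } else {
    head_m <- regexpr("(?i)(^|>)\\s*Acknowledge?ments?\\s*:?(?=<|$|\\s)", x,
                      perl = TRUE)
    if (head_m != -1L) {
      start <- head_m + attr(head_m, "match.length")
      rest <- substr(x, start, nchar(x))
      stop_m <- regexpr("<title[\\s>]|<sec[\\s>]|</body>|</sec>", rest,
                        perl = TRUE)
      end <- if (stop_m == -1L) nchar(x) else start + stop_m - 2L
      body <- substr(x, start, end)
      offsets <- c(start = start, end = end)
    }
  }
  if (is.null(body)) return(NULL)
  text <- strip_tags(body)
  if (!nzchar(text)) return(NULL)

  front <- substr(x, 1L, if (open != -1L) open else nchar(x))
  id <- first_capture(front, "<article-id[^>]*>\\s*([^<]+?)\\s*</article-id>")
  journal <- first_capture(front, "<journal-title[^>]*>\\s*([^<]+?)\\s*</journal-title>")
  year <- first_capture(front, "<year[^>]*>\\s*(\\d{4})\\s*</year>")
  acknowledgement(text = text,
                  article_id = if (!is.na(id)) id else article_id,
                  journal = squeeze_ws(journal %||% NA_character_),
                  year = year,
                  char_offsets = offsets)
}

#' Does an acknowledgement mention an antibody?
#'
#' Case-insensitive whole-word search for "antibody" or "antibodies".
#' Hyphens count as word boundaries, so "antibody-producing" matches while
#' "antibodylike" does not.
#'
#' @param ack An [acknowledgement()] or a character scalar.
#' @return `TRUE` or `FALSE`.
#' @examples
#' keyword_filter("We thank P. Merrifield for providing antibodies.")
#' keyword_filter("This work was supported by NIH grants.")
#' @export
keyword_filter <- function(ack) {
  text <- if (inherits(ack, "acknowledgement")) ack$text else ack
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  grepl("(?i)(?<![[:alnum:]])antibod(?:y|ies)(?![[:alnum:]])",
        stringi::stri_trans_nfc(text), perl = TRUE)
}

#' Stream acknowledgements from a directory or archive of JATS files
#'
#' Reads `.xml`/`.nxml` files (optionally inside `.tar.gz` archives as
#' distributed by the PMC OA service) in lexicographic file-name order and
#' returns every acknowledgement section that passes [keyword_filter()].
#' Unreadable or malformed files are skipped with a message.
#'
#' @param source Directory containing JATS files, or a `.tar.gz` archive.
#' @return List of [acknowledgement()] objects, with attributes
#'   `n_documents` (files seen) and `n_skipped` (files skipped on error).
#' @export
stream_corpus <- function(source) {
  if (length(source) == 1L && grepl("\\.tar\\.gz$|\\.tgz$", source)) {
    exdir <- tempfile("ackminer_corpus_")
    dir.create(exdir)
    utils::untar(source, exdir = exdir)
    source <- exdir
  }
  stopifnot(dir.exists(source))
  files <- list.files(source, pattern = "\\.(xml|nxml)$", recursive = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files), files)]
  out <- list()
  skipped <- 0L
  for (f in files) {
    ack <- tryCatch({
      doc <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                   collapse = "\n")
      parse_acknowledgement(doc, article_id = sub("\\.(xml|nxml)$", "",
                                                  basename(f)))
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      structure(list(), class = "ackminer_skip")
    })
    if (inherits(ack, "ackminer_skip")) {
      skipped <- skipped + 1L
      next
    }
    if (!is.null(ack) && keyword_filter(ack)) out[[length(out) + 1L]] <- ack
  }
  if (skipped > 0L) message(skipped, " file(s) skipped")
  attr(out, "n_documents") <- length(files)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write / read acknowledgements as newline-delimited JSON
#'
#' One JSON object per acknowledgement with keys `article_id`, `journal`,
#' `year`, `text`.
#'
#' @param acks List of [acknowledgement()] objects.
#' @param path File path.
#' @return `read_ack_jsonl` returns a list of [acknowledgement()] objects;
#'   `write_ack_jsonl` returns `path` invisibly.
#' @export
write_ack_jsonl <- function(acks, path) {
  lines <- vapply(acks, function(a) {
    jsonlite::toJSON(list(article_id = a$article_id, journal = a$journal,
                          year = a$year, text = a$text),
                     auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ack_jsonl
#' @export
read_ack_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(l) {
    o <- jsonlite::fromJSON(l)
    acknowledgement(text = o$text, article_id = o$article_id,
                    journal = o$journal %||% NA_character_,
                    year = o$year %||% NA_integer_)
  })
}
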