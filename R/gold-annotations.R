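# Gold-standard annotation format for acknowledgement sections.
#
# Schema (UTF-8 XML):
#   <documents>
#     <document id="...">
#       <text>...</text>
#       <annotation annotator="...">
#         <donation>
#           <donor>...</donor>              (optional)
#           <affiliation>...</affiliation>  (optional)
#           <resource label="antibody" name="CB1"/>  (name optional)
#           <attribute>monoclonal</attribute>        (zero or more)
#         </donation>
#         <entity label="person">...</entity>  (non-donation entities)
#       </annotation>
#     </document>
#   </documents>
#
# One in-memory GoldDocument corresponds to one (document, annotator) pair;
# character offsets are deliberately optional (annotated strings are
# validated as substrings of the text instead). Converters from other
# annotation dialects can be plugged in by mapping into gold_document().

#' Construct a gold donation annotation
#'
#' @param donor,affiliation,resource_name Optional annotated strings
#'   (`NA` when absent).
#' @param resource_label Bio-resource type, e.g. `"antibody"`,
#'   `"cell-line"`, `"fly stock"`; must be non-empty.
#' @param attributes Character vector of free-form attribute strings (gold
#'   may exceed the rule extractor's four tags).
#' @return A list of class `gold_donation`.
#' @export
gold_donation <- function(donor = NA_character_, affiliation = NA_character_,
                          resource_label = "antibody",
                          resource_name = NA_character_,
                          attributes = character()) {
  stopifnot(is.character(resource_label), length(resource_label) == 1L,
            nzchar(resource_label))
  chr1 <- function(x) {
    x <- as.character(x %||% NA_character_)
    if (length(x) == 0L) NA_character_ else x[1L]
  }
  structure(list(donor = chr1(donor),
                 affiliation = chr1(affiliation),
                 resource_label = resource_label,
                 resource_name = chr1(resource_name),
                 attributes = as.character(attributes)),
            class = "gold_donation")
}

#' Construct a gold document (one annotator's view of one acknowledgement)
#'
#' @param doc_id Document identifier.
#' @param text The acknowledgement paragraph.
#' @param annotator_id Annotator identifier.
#' @param donations List of [gold_donation()] objects.
#' @param non_donation_entities Data frame with columns `label`, `text`:
#'   people/organizations in the acknowledgement not part of a donation.
#' @return A list of class `gold_document`.
#' @export
gold_document <- function(doc_id, text, annotator_id = "A1",
                          donations = list(),
                          non_donation_entities = data.frame(
                            label = character(), text = character(),
                            stringsAsFactors = FALSE)) {
  stopifnot(is.character(doc_id), nzchar(doc_id),
            is.character(text), nzchar(text),
            is.character(annotator_id), nzchar(annotator_id))
  structure(list(doc_id = doc_id, text = text, annotator_id = annotator_id,
                 donations = donations,
                 non_donation_entities = non_donation_entities),
            class = "gold_document")
}

gold_strings <- function(doc) {
  unlist(c(lapply(doc$donations, function(d)
    c(d$donor, d$affiliation, d$resource_name)),
    doc$non_donation_entities$text))
}

validate_gold_document <- function(doc, action = c("warn", "stop")) {
  action <- match.arg(action)
  vals <- gold_strings(doc)
  vals <- vals[!is.na(vals)]
  bad <- vals[!vapply(vals, function(v) grepl(v, doc$text, fixed = TRUE), TRUE)]
  if (length(bad)) {
    msg <- sprintf("document %s (annotator %s): annotated string(s) not found in text: %s",
                   doc$doc_id, doc$annotator_id,
                   paste(sQuote(bad), collapse = ", "))
    if (action == "stop") stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(doc)
}

#' Write gold annotations to XML
#'
#' Documents sharing a `doc_id` (multiple annotators) are grouped under one
#' `<document>` element with one `<annotation>` each. Substring invariants
#' are validated before anything is written.
#'
#' @param docs List of [gold_document()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gold_xml <- function(docs, file) {
  for (doc in docs) validate_gold_document(doc, action = "stop")
  ids <- vapply(docs, function(d) paste(d$doc_id, d$annotator_id, sep = "\r"), "")
  if (anyDuplicated(ids))
    stop("duplicate (doc_id, annotator_id) pairs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  root <- xml2::xml_new_root("documents")
  by_id <- split(docs, factor(vapply(docs, `[[`, "", "doc_id"),
                              levels = unique(vapply(docs, `[[`, "", "doc_id"))))
  for (group in by_id) {
    dnode <- xml2::xml_add_child(root, "document", id = group[[1]]$doc_id)
    tnode <- xml2::xml_add_child(dnode, "text")
    xml2::xml_set_text(tnode, group[[1]]$text)
    for (doc in group) {
      ann <- xml2::xml_add_child(dnode, "annotation",
                                 annotator = doc$annotator_id)
      for (don in doc$donations) {
        dn <- xml2::xml_add_child(ann, "donation")
        if (!is.na(don$donor))
          xml2::xml_set_text(xml2::xml_add_child(dn, "donor"), don$donor)
        if (!is.na(don$affiliation))
          xml2::xml_set_text(xml2::xml_add_child(dn, "affiliation"),
                             don$affiliation)
        rn <- xml2::xml_add_child(dn, "resource", label = don$resource_label)
        if (!is.na(don$resource_name))
          xml2::xml_set_attr(rn, "name", don$resource_name)
        for (a in don$attributes)
          xml2::xml_set_text(xml2::xml_add_child(dn, "attribute"), a)
      }
      ents <- doc$non_donation_entities
      for (i in seq_len(nrow(ents))) {
        en <- xml2::xml_add_child(ann, "entity", label = ents$label[i])
        xml2::xml_set_text(en, ents$text[i])
      }
    }
  }
  xml2::write_xml(root, file)
  invisible(file)
}

#' Read gold annotations from XML
#'
#' Malformed XML raises an error naming the offending input; annotated
#' strings that are not substrings of their document text raise a warning
#' (with document id) but are kept.
#'
#' @param file Path to a gold XML file (see [write_gold_xml()] for the
#'   schema).
#' @return List of [gold_document()] objects, one per (document, annotator)
#'   pair, in file order.
#' @export
read_gold_xml <- function(file) {
  root <- tryCatch(xml2::read_xml(file),
                   error = function(e) stop("malformed gold XML in ", file,
                                            ": ", conditionMessage(e)))
  docs <- list()
  for (dnode in xml2::xml_find_all(root, "./document")) {
    doc_id <- xml2::xml_attr(dnode, "id")
    text <- xml2::xml_text(xml2::xml_find_first(dnode, "./text"))
    for (ann in xml2::xml_find_all(dnode, "./annotation")) {
      annotator <- xml2::xml_attr(ann, "annotator")
      donations <- lapply(xml2::xml_find_all(ann, "./donation"), function(dn) {
        get1 <- function(xp) {
          nd <- xml2::xml_find_first(dn, xp)
          if (inherits(nd, "xml_missing")) NA_character_ else xml2::xml_text(nd)
        }
        rn <- xml2::xml_find_first(dn, "./resource")
        gold_donation(
          donor = get1("./donor"),
          affiliation = get1("./affiliation"),
          resource_label = if (inherits(rn, "xml_missing")) "antibody"
                           else xml2::xml_attr(rn, "label"),
          resource_name = if (inherits(rn, "xml_missing")) NA_character_
                          else xml2::xml_attr(rn, "name"),
          attributes = xml2::xml_text(xml2::xml_find_all(dn, "./attribute")))
      })
      ents <- xml2::xml_find_all(ann, "./entity")
      doc <- gold_document(
        doc_id = doc_id, text = text, annotator_id = annotator,
        donations = donations,
        non_donation_entities = data.frame(
          label = xml2::xml_attr(ents, "label"),
          text = xml2::xml_text(ents), stringsAsFactors = FALSE))
      validate_gold_document(doc, action = "warn")
      docs[[length(docs) + 1L]] <- doc
    }
  }
  docs
}

#' Group gold documents by document id
#'
#' @param docs List of [gold_document()] objects.
#' @return Named list mapping `doc_id` to the list of that document's
#'   [gold_document()] objects (one per annotator), preserving annotator
#'   separation.
#' @export
merge_annotators <- function(docs) {
  ids <- vapply(docs, `[[`, "", "doc_id")
  split(docs, factor(ids, levels = unique(ids)))
}

#' Export gold annotations as JSON
#'
#' A JSON mirror of the XML schema for downstream tooling.
#'
#' @param docs List of [gold_document()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gold_json <- function(docs, file) {
  payload <- lapply(docs, function(d) {
    list(doc_id = d$doc_id, annotator_id = d$annotator_id, text = d$text,
         donations = lapply(d$donations, unclass),
         non_donation_entities = d$non_donation_entities)
  })
  jsonlite::write_json(payload, file, auto_unbox = TRUE, na = "null")
  invisible(file)
}
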