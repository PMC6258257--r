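# Scoring extracted donation records against gold annotations.
#
# The matching criterion is made explicit and travels with every report: a
# predicted field value counts as correct when it matches the value of ANY
# annotator under the report's normalization policy. Per-field accuracy is
# the fraction of gold field values (for antibody-labelled donations, pooled
# across annotators and deduplicated after normalization) recovered by at
# least one prediction in the same document; documents without a gold
# donation contribute nothing to the denominators. The headline number is
# the arithmetic mean of the donor, affiliation and antibody accuracies.

.honorifics_re <- "^(dr|prof|professor|mr|mrs|ms)\\.?\\s+"

#' Construct a field-matching policy
#'
#' @param case_fold Lowercase both sides before comparison.
#' @param strip_punctuation Remove punctuation characters before comparison.
#' @param strip_honorifics Remove a leading honorific ("Dr.", "Prof.", ...)
#'   before comparison.
#' @param mode `"exact"`: equality after normalization; `"containment"`: the
#'   shorter normalized string contained in the longer.
#' @return A list of class `match_policy`.
#' @export
match_policy <- function(case_fold = TRUE, strip_punctuation = TRUE,
                         strip_honorifics = TRUE,
                         mode = c("exact", "containment")) {
  structure(list(case_fold = isTRUE(case_fold),
                 strip_punctuation = isTRUE(strip_punctuation),
                 strip_honorifics = isTRUE(strip_honorifics),
                 mode = match.arg(mode)),
            class = "match_policy")
}

#' @export
print.match_policy <- function(x, ...) {
  cat(sprintf("<match_policy: %s%s%s%s>\n", x$mode,
              if (x$case_fold) " +case-fold" else "",
              if (x$strip_punctuation) " +strip-punctuation" else "",
              if (x$strip_honorifics) " +strip-honorifics" else ""))
  invisible(x)
}

#' Normalize a field value under a policy
#'
#' @param x Character vector.
#' @param policy A [match_policy()].
#' @return Normalized character vector (`NA` stays `NA`).
#' @export
normalize_value <- function(x, policy = match_policy()) {
  out <- stringi::stri_trans_nfc(as.character(x))
  if (policy$strip_honorifics)
    out <- sub(.honorifics_re, "", out, ignore.case = TRUE)
  if (policy$case_fold) out <- tolower(out)
  if (policy$strip_punctuation) out <- gsub("[[:punct:]]", "", out)
  out <- squeeze_ws(out)
  out
}

#' Match one predicted field value against gold values
#'
#' @param predicted Predicted value (`NA` for absent).
#' @param gold_values Character vector of values from any annotator (may be
#'   empty or all-`NA`).
#' @param policy A [match_policy()].
#' @return `TRUE` iff the prediction matches any annotator's value under the
#'   policy; an absent prediction matches only an all-absent gold.
#' @examples
#' match_field("Dr. Charles Rice", "Charles Rice", match_policy())
#' match_field("Oxford University", "University of Oxford", match_policy())
#' @export
match_field <- function(predicted, gold_values, policy = match_policy()) {
  gold_values <- gold_values[!is.na(gold_values)]
  if (is.na(predicted) || !nzchar(predicted)) return(length(gold_values) == 0L)
  if (!length(gold_values)) return(FALSE)
  p <- normalize_value(predicted, policy)
  g <- normalize_value(gold_values, policy)
  if (policy$mode == "exact") return(any(p == g))
  any(vapply(g, function(gv) {
    grepl(p, gv, fixed = TRUE) || grepl(gv, p, fixed = TRUE)
  }, TRUE))
}

gold_field_values <- function(group, field, resource_label = "antibody") {
  vals <- unlist(lapply(group, function(doc) {
    vapply(doc$donations, function(d) {
      if (!identical(d$resource_label, resource_label)) return(NA_character_)
      switch(field, donor = d$donor, affiliation = d$affiliation,
             antibody = d$resource_name)
    }, NA_character_)
  }))
  vals[!is.na(vals)]
}

#' Evaluate donation records against gold annotations
#'
#' @param records Donation-record tibble ([extract_donations()] /
#'   [extract_donations_bootstrap()] output) whose `article_id` values align
#'   with gold `doc_id`s; predicted records for unknown documents are an
#'   error.
#' @param gold_docs List of [gold_document()] objects (multiple annotators
#'   per document allowed).
#' @param policy A [match_policy()].
#' @param resource_label Gold donations scored (default `"antibody"`, the
#'   label the extractors target).
#' @return An object of class `evaluation_report`: per-field accuracy,
#'   numerator and denominator for donor / affiliation / antibody, their
#'   arithmetic `mean`, and the `policy` used.
#' @export
evaluate_documents <- function(records, gold_docs, policy = match_policy(),
                               resource_label = "antibody") {
  groups <- merge_annotators(gold_docs)
  unknown <- setdiff(unique(records$article_id), names(groups))
  if (length(unknown))
    stop("predicted records for document(s) absent from gold: ",
         paste(unknown, collapse = ", "))
  fields <- c("donor", "affiliation", "antibody")
  num <- den <- stats::setNames(numeric(3), fields)
  for (doc_id in names(groups)) {
    group <- groups[[doc_id]]
    preds <- records[records$article_id == doc_id, , drop = FALSE]
    for (field in fields) {
      gold_vals <- gold_field_values(group, field, resource_label)
      if (!length(gold_vals)) next
      gold_norm <- unique(normalize_value(gold_vals, policy))
      pred_vals <- preds[[field]]
      pred_norm <- unique(normalize_value(pred_vals[!is.na(pred_vals)], policy))
      matched <- vapply(gold_norm, function(g) {
        if (policy$mode == "exact") g %in% pred_norm
        else any(vapply(pred_norm, function(p)
          grepl(p, g, fixed = TRUE) || grepl(g, p, fixed = TRUE), TRUE))
      }, TRUE)
      den[field] <- den[field] + length(gold_norm)
      num[field] <- num[field] + sum(matched)
    }
  }
  acc <- ifelse(den > 0, num / den, NA_real_)
  structure(list(accuracy = acc, numerator = num, denominator = den,
                 mean = mean(acc), policy = policy,
                 resource_label = resource_label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Extraction accuracy (match any annotator)\n")
  for (f in names(x$accuracy)) {
    cat(sprintf("  %-12s %3.0f%%  (%d/%d)\n", f, round(100 * x$accuracy[f]),
                x$numerator[f], x$denominator[f]))
  }
  cat(sprintf("  %-12s %3.0f%%\n", "mean", round(100 * x$mean)))
  print(x$policy)
  invisible(x)
}

agreement_fields <- function(d) {
  list(donor = d$donor, affiliation = d$affiliation,
       resource_name = d$resource_name,
       attributes = if (length(d$attributes)) sort(d$attributes) else NULL)
}

#' Inter-annotator agreement
#'
#' Over documents annotated by at least two people, the fraction of
#' annotation fields on which annotator pairs agree under the policy.
#' Donations are aligned by position within each annotator's list; a field
#' slot is considered when either annotator filled it, and agreement requires
#' both to have filled it with matching (normalized) values. Donations
#' without a counterpart count their filled fields as disagreements.
#'
#' @param gold_docs List of [gold_document()] objects.
#' @param policy A [match_policy()].
#' @return Fraction in `[0, 1]`. Errors when no document has two or more
#'   annotators (the quantity is undefined).
#' @export
inter_annotator_agreement <- function(gold_docs, policy = match_policy()) {
  groups <- Filter(function(g) length(g) >= 2L, merge_annotators(gold_docs))
  if (!length(groups))
    stop("inter-annotator agreement is undefined: no document has >= 2 annotators")
  agree <- considered <- 0L
  for (group in groups) {
    pairs <- utils::combn(length(group), 2L, simplify = FALSE)
    for (pr in pairs) {
      a <- group[[pr[1]]]$donations
      b <- group[[pr[2]]]$donations
      for (i in seq_len(max(length(a), length(b)))) {
        fa <- if (i <= length(a)) agreement_fields(a[[i]]) else NULL
        fb <- if (i <= length(b)) agreement_fields(b[[i]]) else NULL
        for (field in c("donor", "affiliation", "resource_name", "attributes")) {
          va <- fa[[field]]
          vb <- fb[[field]]
          va_filled <- !is.null(va) && !all(is.na(va))
          vb_filled <- !is.null(vb) && !all(is.na(vb))
          if (!va_filled && !vb_filled) next
          considered <- considered + 1L
          if (va_filled && vb_filled &&
              length(va) == length(vb) &&
              all(normalize_value(va, policy) == normalize_value(vb, policy)))
            agree <- agree + 1L
        }
      }
    }
  }
  agree / considered
}
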