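# Corpus-level aggregation of extracted donation records: frequency tables
# (top donors, donor-affiliation pairs, organizations, antibodies, journals)
# and the yearly donation trend normalized per 1000 articles.

#' Top-k frequency table over donation records
#'
#' Counts exact key values (optionally case-folded) in descending order,
#' ties broken lexicographically. Records missing the key are dropped. By
#' default no name normalization is applied, so "Keith Gull" and "K. Gull"
#' count separately.
#'
#' @param records Donation-record tibble.
#' @param key One of `"donor"`, `"donor_affiliation"`, `"organization"`,
#'   `"antibody"`, `"journal"`.
#' @param k Number of rows to keep (`Inf` for all).
#' @param normalize Case-fold values before counting (the presentation used
#'   for antibody-name tables).
#' @return Tibble with columns `value`, `count`, at most `k` rows.
#' @export
top_k <- function(records, key = c("donor", "donor_affiliation",
                                   "organization", "antibody", "journal"),
                  k = 5L, normalize = FALSE) {
  key <- tryCatch(match.arg(key),
                  error = function(e) stop("unknown key: ", key[1]))
  vals <- switch(key,
    donor = records$donor,
    donor_affiliation = ifelse(
      is.na(records$donor) | is.na(records$affiliation), NA_character_,
      paste(records$donor, records$affiliation, sep = " — ")),
    organization = records$affiliation,
    antibody = records$antibody,
    journal = records$journal)
  vals <- vals[!is.na(vals)]
  if (normalize) vals <- tolower(vals)
  if (!length(vals))
    return(tibble::tibble(value = character(), count = integer()))
  tab <- table(vals)
  out <- tibble::tibble(value = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$value), ]
  utils::head(out, k)
}

#' Yearly donation trend, normalized per 1000 articles
#'
#' One point per year occurring in the records or covered by
#' `corpus_counts`, ascending. `normalized` is
#' `donations / corpus_size * 1000`; years missing from `corpus_counts` get
#' `NA` with a warning.
#'
#' @param records Donation-record tibble with a `year` column.
#' @param corpus_counts Named numeric vector mapping year to the number of
#'   articles published that year (names coercible to integer years).
#' @return Tibble with columns `year`, `donations`, `corpus_size`,
#'   `normalized`.
#' @export
yearly_trend <- function(records, corpus_counts) {
  stopifnot(!is.null(names(corpus_counts)))
  rec_years <- records$year[!is.na(records$year)]
  cov_years <- as.integer(names(corpus_counts))
  years <- sort(unique(c(rec_years, cov_years)))
  donations <- vapply(years, function(y) sum(rec_years == y), 0L)
  size <- unname(corpus_counts[as.character(years)])
  missing <- years[is.na(size)]
  if (length(missing))
    warning("no corpus size for year(s): ", paste(missing, collapse = ", "),
            "; normalized rate left NA", call. = FALSE)
  tibble::tibble(
    year = years,
    donations = donations,
    corpus_size = as.numeric(size),
    normalized = ifelse(!is.na(size) & size > 0, donations / size * 1000,
                        NA_real_))
}
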