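#' Load the drug-name standardization dictionary
#'
#' A CSV mapping raw drug names (as reporters wrote them) to the generic name,
#' ATC code, and antipsychotic class. Lookups are case- and
#' whitespace-insensitive. Every drug in the `N05A` ATC group must be classed
#' `typical` or `atypical`; everything else must be `non_apd`.
#'
#' @param path CSV with columns `raw_name, generic_name, atc_code, apd_class`.
#' @return a `drug_dictionary` object.
#' @export
load_drug_dictionary <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("raw_name", "generic_name", "atc_code", "apd_class")
  stopifnot(all(need %in% names(d)))
  d$key <- normalize_key(d$raw_name)
  d$generic_name <- trimws(d$generic_name)
  d$atc_code <- trimws(d$atc_code)
  d$apd_class <- tolower(trimws(d$apd_class))
  d <- unique(d[, c("key", "generic_name", "atc_code", "apd_class")])
  dup <- d$key[duplicated(d$key)]
  if (length(dup))
    stop_srs("conflicting duplicate drug mapping for raw name(s): ",
             paste(unique(dup), collapse = ", "), class = "srs_dictionary")
  if (!all(d$apd_class %in% c("typical", "atypical", "non_apd")))
    stop_srs("apd_class must be typical, atypical or non_apd",
             class = "srs_dictionary")
  n05a <- startsWith(d$atc_code, "N05A")
  bad <- n05a & !(d$apd_class %in% c("typical", "atypical"))
  if (any(bad))
    stop_srs("N05A drugs must be typical or atypical: ",
             paste(unique(d$generic_name[bad]), collapse = ", "),
             class = "srs_dictionary")
  if (any(!n05a & d$apd_class != "non_apd"))
    stop_srs("non-N05A drugs must have apd_class non_apd",
             class = "srs_dictionary")
  structure(d, class = c("drug_dictionary", "data.frame"))
}

#' Load the reaction-term standardization dictionary
#'
#' Maps raw reaction descriptions to a MedDRA-style preferred term (PT) and its
#' single primary system organ class (SOC).
#'
#' @param path CSV with columns `raw_term, pt, soc`.
#' @return a `term_dictionary` object.
#' @export
load_term_dictionary <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("raw_term", "pt", "soc") %in% names(d)))
  d$key <- normalize_key(d$raw_term)
  d$pt <- trimws(d$pt); d$soc <- trimws(d$soc)
  d <- unique(d[, c("key", "pt", "soc")])
  dup <- d$key[duplicated(d$key)]
  if (length(dup))
    stop_srs("conflicting duplicate term mapping for raw term(s): ",
             paste(unique(dup), collapse = ", "), class = "srs_dictionary")
  pt_soc <- unique(d[, c("pt", "soc")])
  multi <- pt_soc$pt[duplicated(pt_soc$pt)]
  if (length(multi))
    stop_srs("PT mapped to more than one primary SOC: ",
             paste(unique(multi), collapse = ", "), class = "srs_dictionary")
  structure(d, class = c("term_dictionary", "data.frame"))
}

#' Load drug-label knowledge (labeled preferred terms per drug)
#'
#' Long-format CSV: one row per (generic drug, labeled PT). Used by
#' [flag_offlabel()] to call a detected signal expected (on the label) or
#' off-label. Membership is exact-string on standardized PTs.
#'
#' @param path CSV with columns `generic_name, pt`.
#' @return a `label_knowledge` object (named list of PT character sets).
#' @export
load_label_knowledge <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("generic_name", "pt") %in% names(d)))
  d$generic_name <- trimws(d$generic_name); d$pt <- trimws(d$pt)
  sets <- lapply(split(d$pt, d$generic_name), unique)
  structure(sets, class = "label_knowledge")
}

#' Load all three dictionaries at once
#'
#' @param drug_path,term_path,label_path CSV paths; defaults are the fixtures
#'   bundled with the package (the 15 antipsychotics of the source SRS study,
#'   a 44-PT reaction vocabulary, and a synthetic label-knowledge file).
#' @return list with elements `drugs`, `terms`, `labels`.
#' @export
load_dictionaries <- function(
    drug_path  = system.file("extdata", "drug_dictionary.csv", package = "srsmine"),
    term_path  = system.file("extdata", "term_dictionary.csv", package = "srsmine"),
    label_path = system.file("extdata", "label_knowledge_synthetic.csv", package = "srsmine")) {
  list(drugs = load_drug_dictionary(drug_path),
       terms = load_term_dictionary(term_path),
       labels = load_label_knowledge(label_path))
}

#' Standardize raw drug names
#'
#' Unmapped names are a value, not an error: `generic_name` is `NA` and
#' `apd_class` is `"unmapped"`, so callers can tally dictionary misses.
#'
#' @param raw_name character vector of raw drug names.
#' @param dict a `drug_dictionary`.
#' @return data.frame `generic_name, atc_code, apd_class` aligned with input.
#' @export
standardize_drug <- function(raw_name, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  i <- match(normalize_key(raw_name), dict$key)
  data.frame(generic_name = dict$generic_name[i],
             atc_code = dict$atc_code[i],
             apd_class = ifelse(is.na(i), "unmapped", dict$apd_class[i]))
}

#' Standardize raw reaction terms to PT and primary SOC
#'
#' @param raw_term character vector of raw reaction descriptions.
#' @param dict a `term_dictionary`.
#' @return data.frame `pt, soc` aligned with input (`NA` where unmapped).
#' @export
standardize_term <- function(raw_term, dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  i <- match(normalize_key(raw_term), dict$key)
  data.frame(pt = dict$pt[i], soc = dict$soc[i])
}
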