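#' Apply the study's inclusion/exclusion criteria
#'
#' A report is retained iff (1) its report year falls inside `year_window`,
#' (2) at least one *suspected* drug standardizes to an antipsychotic
#' (ATC N05A; concomitant antipsychotics do not qualify), and (3) its
#' causality rating is in `accepted_causality`. Excluded reports are logged
#' with a single reason code — the first failing rule in the fixed order
#' `year`, `not_suspected`, `causality` — so the exclusion log is
#' deterministic.
#'
#' @param x an `srs_reports` object (validated).
#' @param drug_dict a `drug_dictionary` (needed to recognize antipsychotics).
#' @param year_window inclusive `c(start, end)` calendar years; default the
#'   study window 2016-2020.
#' @param accepted_causality causality levels that qualify; default
#'   certain/probable/possible.
#' @return list: `included` (`srs_reports` subset, order preserved) and
#'   `exclusions` (data.frame `report_id, reason`).
#' @export
apply_inclusion_exclusion <- function(x, drug_dict,
                                      year_window = c(2016L, 2020L),
                                      accepted_causality = c("certain", "probable", "possible")) {
  stopifnot(inherits(x, "srs_reports"))
  if (length(accepted_causality) == 0)
    stop_srs("accepted_causality must not be empty", class = "srs_config")
  accepted_causality <- match.arg(tolower(accepted_causality), CAUSALITY_LEVELS,
                                  several.ok = TRUE)
  yr <- as.integer(format(x$reports$report_date, "%Y"))
  in_year <- !is.na(yr) & yr >= year_window[1] & yr <= year_window[2]

  std <- standardize_drug(x$drugs$raw_name, drug_dict)
  is_apd_susp <- x$drugs$role == "suspected" &
    std$apd_class %in% c("typical", "atypical")
  apd_ids <- unique(x$drugs$report_id[is_apd_susp])
  has_apd <- x$reports$report_id %in% apd_ids
  caus_ok <- x$reports$causality %in% accepted_causality

  reason <- rep(NA_character_, nrow(x$reports))
  reason[!in_year] <- "year"
  reason[is.na(reason) & !has_apd] <- "not_suspected"
  reason[is.na(reason) & !caus_ok] <- "causality"
  keep <- is.na(reason)

  inc <- x$reports[keep, , drop = FALSE]
  included <- srs_reports(
    inc,
    x$drugs[x$drugs$report_id %in% inc$report_id, , drop = FALSE],
    x$reactions[x$reactions$report_id %in% inc$report_id, , drop = FALSE])
  attr(included, "errors") <- attr(x, "errors")
  list(included = included,
       exclusions = data.frame(report_id = x$reports$report_id[!keep],
                               reason = reason[!keep]))
}

month_to_season <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

bin_age <- function(age) {
  cut(as.numeric(age), breaks = c(-Inf, 18, 35, 65, Inf), right = FALSE,
      labels = c("<18", "18-35", "35-65", ">=65"))
}

#' Derive the per-report covariates used by descriptive and regression stages
#'
#' Age is binned into `<18, [18,35), [35,65), >=65` (half-open on the right);
#' season follows the meteorological convention (spring = Mar-May, summer =
#' Jun-Aug, autumn = Sep-Nov, winter = Dec-Feb); polypharmacy means three or
#' more medications in total (suspected plus concomitant); multiple-disease
#' means two or more recorded diagnoses. A report whose suspected
#' antipsychotics span both classes is coded `atypical` if any suspected
#' atypical is present.
#'
#' @param x an `srs_reports` object (normally the included set).
#' @param drug_dict a `drug_dictionary`.
#' @return data.frame, one row per report: `report_id, sex, age, age_bin,
#'   year, season, hospital_level, hospital_type, apd_class, polypharmacy,
#'   multiple_disease, serious, outcome`.
#' @export
derive_covariates <- function(x, drug_dict) {
  stopifnot(inherits(x, "srs_reports"))
  r <- x$reports
  std <- standardize_drug(x$drugs$raw_name, drug_dict)
  dd <- data.table(report_id = x$drugs$report_id, role = x$drugs$role,
                   apd_class = std$apd_class)
  n_drugs <- dd[, .N, by = "report_id"]
  cls <- dd[role == "suspected" & apd_class %in% c("typical", "atypical"),
            .(apd_class = if (any(apd_class == "atypical")) "atypical" else "typical"),
            by = "report_id"]
  n_dx <- vapply(strsplit(r$diagnoses, ";", fixed = TRUE),
                 function(d) sum(nzchar(trimws(d))), integer(1))
  mo <- as.integer(format(r$report_date, "%m"))
  data.frame(
    report_id = r$report_id,
    sex = r$sex,
    age = r$age,
    age_bin = bin_age(r$age),
    year = as.integer(format(r$report_date, "%Y")),
    season = month_to_season(mo),
    hospital_level = r$hospital_level,
    hospital_type = r$hospital_type,
    apd_class = cls$apd_class[match(r$report_id, cls$report_id)],
    polypharmacy = n_drugs$N[match(r$report_id, n_drugs$report_id)] >= 3,
    multiple_disease = n_dx >= 2,
    serious = r$serious,
    outcome = r$outcome)
}

#' Expand included reports into drug-event combinations
#'
#' The counting unit of disproportionality analysis. Each report is split
#' into one combination per (suspected antipsychotic x standardized reaction
#' PT) pair — the full cross-product when a report carries several suspected
#' antipsychotics — with duplicates within a report collapsed to one, so
#' `(report_id, generic_drug, pt)` is unique. Suspected non-antipsychotic
#' drugs and unmapped drug names generate no combinations; reports whose
#' reaction terms all fail to standardize contribute nothing and are logged.
#'
#' @param x included `srs_reports`.
#' @param drug_dict a `drug_dictionary`.
#' @param term_dict a `term_dictionary`.
#' @return data.frame of combinations: `report_id, generic_drug, apd_class,
#'   pt, soc, serious` plus the parent covariates of [derive_covariates()].
#'   Attributes: `unmapped_drugs`, `unmapped_terms` (character vectors of
#'   distinct misses), `empty_reports` (ids contributing no combination).
#' @export
expand_combinations <- function(x, drug_dict, term_dict) {
  stopifnot(inherits(x, "srs_reports"))
  std_d <- standardize_drug(x$drugs$raw_name, drug_dict)
  std_t <- standardize_term(x$reactions$raw_term, term_dict)

  drugs <- data.table(report_id = x$drugs$report_id,
                      generic_drug = std_d$generic_name,
                      apd_class = std_d$apd_class,
                      role = x$drugs$role)
  drugs <- unique(drugs[role == "suspected" &
                          apd_class %in% c("typical", "atypical"),
                        c("report_id", "generic_drug", "apd_class")])
  rxn <- data.table(report_id = x$reactions$report_id,
                    pt = std_t$pt, soc = std_t$soc)
  rxn <- unique(rxn[!is.na(pt)])

  combos <- merge(drugs, rxn, by = "report_id", allow.cartesian = TRUE)
  cov <- derive_covariates(x, drug_dict)
  out <- merge(combos,
               setDT(cov)[, c("report_id", "sex", "age", "age_bin", "year",
                              "season", "hospital_level", "hospital_type",
                              "polypharmacy", "multiple_disease", "serious",
                              "outcome")],
               by = "report_id", sort = FALSE)
  data.table::setorder(out, report_id, generic_drug, pt)
  out <- setDF(as.data.frame(out))
  attr(out, "unmapped_drugs") <- sort(unique(
    x$drugs$raw_name[std_d$apd_class == "unmapped"]))
  attr(out, "unmapped_terms") <- sort(unique(
    x$reactions$raw_term[is.na(std_t$pt)]))
  attr(out, "empty_reports") <- setdiff(x$reports$report_id, out$report_id)
  out
}
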