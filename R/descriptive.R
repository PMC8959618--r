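#' Frequency table with printed-style percentages
#'
#' The common currency of descriptive ADR tables: labels, counts, and
#' percentages of a stated denominator, rounded half-up to 2 decimals exactly
#' as published tables print them. Top-k views keep the full denominator, not
#' the shown subtotal.
#'
#' @param labels character labels.
#' @param counts non-negative counts aligned with `labels`.
#' @param denominator the percentage base (defaults to `sum(counts)`).
#' @param basis `"reports"` or `"combinations"` — what the denominator counts.
#' @return data.frame `label, frequency, percentage` with attributes
#'   `denominator` and `basis`.
#' @export
frequency_table <- function(labels, counts,
                            denominator = sum(counts),
                            basis = c("reports", "combinations")) {
  basis <- match.arg(basis)
  stopifnot(length(labels) == length(counts), all(counts >= 0))
  out <- data.frame(label = as.character(labels), frequency = as.integer(counts),
                    percentage = if (denominator > 0)
                      pct_of(counts, denominator) else rep(NA_real_, length(counts)))
  attr(out, "denominator") <- as.integer(denominator)
  attr(out, "basis") <- basis
  out
}

#' Yearly report counts and serious proportions
#'
#' One row per calendar year of the window, zero-filled for empty years —
#' the data behind the classic "reports per year with % serious" trend plot.
#'
#' @param x included `srs_reports`.
#' @param year_window inclusive `c(start, end)`; defaults to the observed range.
#' @return data.frame `year, n_reports, n_serious, serious_pct`.
#' @export
yearly_trend <- function(x, year_window = NULL) {
  stopifnot(inherits(x, "srs_reports"))
  yr <- as.integer(format(x$reports$report_date, "%Y"))
  if (is.null(year_window)) year_window <- range(yr)
  years <- seq(year_window[1], year_window[2])
  n <- vapply(years, function(y) sum(yr == y), integer(1))
  s <- vapply(years, function(y) sum(yr == y & x$reports$serious), integer(1))
  data.frame(year = years, n_reports = n, n_serious = s,
             serious_pct = ifelse(n > 0, pct_of(s, pmax(n, 1)), 0))
}

DEFAULT_ONSET_BINS <- c(0, 1, 8, 31, 91, Inf)
DEFAULT_ONSET_LABELS <- c("same day", "1-7 d", "8-30 d", "31-90 d", ">90 d")

#' Distribution of reaction onset delay after starting the suspected drug
#'
#' Delay = reaction onset date minus the earliest suspected-antipsychotic
#' start date, in days. Default bins: same day, 1-7, 8-30, 31-90, and >90
#' days (half-open on the right: day 90 falls in 31-90, day 91 in >90).
#' Reactions with a missing onset or start date are excluded and counted, as
#' are negative delays (flagged data-entry inconsistencies).
#'
#' @param x included `srs_reports`.
#' @param drug_dict a `drug_dictionary` (to find suspected antipsychotics).
#' @param breaks ascending break points in days (first must be 0, last `Inf`);
#'   a delay `t` falls in bin `i` when `breaks[i] <= t < breaks[i+1]`.
#' @param labels bin labels.
#' @return [frequency_table()] over the bins (denominator = reactions with a
#'   computable non-negative delay) with attributes `n_missing` and
#'   `n_negative`.
#' @export
onset_distribution <- function(x, drug_dict,
                               breaks = DEFAULT_ONSET_BINS,
                               labels = DEFAULT_ONSET_LABELS) {
  stopifnot(inherits(x, "srs_reports"), length(labels) == length(breaks) - 1)
  std <- standardize_drug(x$drugs$raw_name, drug_dict)
  susp <- x$drugs[x$drugs$role == "suspected" &
                    std$apd_class %in% c("typical", "atypical") &
                    !is.na(x$drugs$start_date), , drop = FALSE]
  first_start <- tapply(as.numeric(susp$start_date), susp$report_id, min)
  delay <- as.numeric(x$reactions$onset_date) -
    as.numeric(first_start[x$reactions$report_id])
  n_missing <- sum(is.na(delay))
  n_negative <- sum(!is.na(delay) & delay < 0)
  delay <- delay[!is.na(delay) & delay >= 0]
  bin <- cut(delay, breaks = breaks, labels = labels, right = FALSE,
             include.lowest = FALSE)
  out <- frequency_table(labels, as.integer(table(bin)[labels]),
                         basis = "reports")
  attr(out, "n_missing") <- n_missing
  attr(out, "n_negative") <- n_negative
  out
}

#' Per-drug and per-class seriousness table
#'
#' One row per suspected antipsychotic and one aggregate row per class
#' (typical/atypical), each with non-serious, serious and total report counts
#' and the percentage serious. A report with several suspected
#' antipsychotics contributes once to each drug's row; class rows aggregate
#' their member drugs' rows.
#'
#' @param x included `srs_reports`.
#' @param drug_dict a `drug_dictionary`.
#' @return data.frame `apd_class, generic_drug, non_serious, serious, total,
#'   serious_pct`; class rows carry `generic_drug = NA`, drug rows sorted by
#'   total descending within class.
#' @export
drug_seriousness_table <- function(x, drug_dict) {
  stopifnot(inherits(x, "srs_reports"))
  std <- standardize_drug(x$drugs$raw_name, drug_dict)
  dd <- unique(data.table(report_id = x$drugs$report_id,
                          generic_drug = std$generic_name,
                          apd_class = std$apd_class,
                          role = x$drugs$role)[
    role == "suspected" & apd_class %in% c("typical", "atypical"),
    c("report_id", "generic_drug", "apd_class")])
  dd <- merge(dd, data.table(report_id = x$reports$report_id,
                             serious = x$reports$serious), by = "report_id")
  per_drug <- dd[, .(serious = sum(serious), total = .N),
                 by = c("apd_class", "generic_drug")]
  per_class <- dd[, .(serious = sum(serious), total = .N), by = "apd_class"]
  per_class$generic_drug <- NA_character_
  tab <- rbindlist(list(per_class, per_drug), use.names = TRUE)
  tab$non_serious <- tab$total - tab$serious
  tab$serious_pct <- pct_of(tab$serious, tab$total)
  data.table::setorder(tab, apd_class, -total)
  data.table::setcolorder(tab, c("apd_class", "generic_drug", "non_serious",
                                 "serious", "total", "serious_pct"))
  setDF(as.data.frame(tab))
}

#' System-organ-class frequency table over drug-event combinations
#'
#' @param combos combinations from [expand_combinations()].
#' @param top optional number of top rows to keep (denominator stays total).
#' @return [frequency_table()] keyed by primary SOC, frequency descending.
#' @export
soc_table <- function(combos, top = NULL) {
  tab <- sort(table(combos$soc), decreasing = TRUE)
  out <- frequency_table(names(tab), as.integer(tab),
                         denominator = nrow(combos), basis = "combinations")
  if (!is.null(top)) {
    att <- attributes(out)
    out <- head(out, top)
    attr(out, "denominator") <- att$denominator
    attr(out, "basis") <- att$basis
  }
  out
}

#' Preferred-term frequency table, optionally per antipsychotic class
#'
#' @param combos combinations from [expand_combinations()].
#' @param apd_class `NULL` for all combinations, or `"typical"`/`"atypical"`
#'   to restrict scope; the percentage denominator is the combination count
#'   in scope (per-class denominators are computed from data, never assumed).
#' @param top optional number of top rows to keep.
#' @return [frequency_table()] keyed by PT, frequency descending.
#' @export
pt_table <- function(combos, apd_class = NULL, top = NULL) {
  if (!is.null(apd_class)) {
    apd_class <- match.arg(apd_class, c("typical", "atypical"))
    combos <- combos[combos$apd_class == apd_class, , drop = FALSE]
  }
  tab <- sort(table(combos$pt), decreasing = TRUE)
  out <- frequency_table(names(tab), as.integer(tab),
                         denominator = nrow(combos), basis = "combinations")
  if (!is.null(top)) {
    att <- attributes(out)
    out <- head(out, top)
    attr(out, "denominator") <- att$denominator
    attr(out, "basis") <- att$basis
  }
  out
}

OUTCOME_PRINT <- c(relieved = "Relieved", cured = "Cured",
                   not_relieved = "Not relieved", sequelae = "Left with sequelae",
                   death = "Death", missing = "Missing")

#' Outcome tallies of included reports
#'
#' Missing outcome is its own category and the denominator includes it (all
#' included reports), so the table is exhaustive.
#'
#' @param x included `srs_reports`.
#' @return [frequency_table()] over outcome categories (categories with zero
#'   frequency retained).
#' @export
outcome_table <- function(x) {
  stopifnot(inherits(x, "srs_reports"))
  counts <- vapply(names(OUTCOME_PRINT),
                   function(o) sum(x$reports$outcome == o), integer(1))
  frequency_table(unname(OUTCOME_PRINT), counts,
                  denominator = nrow(x$reports), basis = "reports")
}
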