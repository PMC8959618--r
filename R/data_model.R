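#' @importFrom data.table data.table setDT setDF := .N .SD fread fwrite rbindlist
#' @importFrom stats rlnorm rnorm runif rbinom plogis qlogis uniroot setNames
#'   glm binomial coef vcov pchisq quantile
#' @importFrom utils head
NULL

# enumerated levels of the report schema
SEX_LEVELS       <- c("male", "female", "unknown")
CAUSALITY_LEVELS <- c("certain", "probable", "possible", "unlikely", "impossible")
OUTCOME_LEVELS   <- c("cured", "relieved", "not_relieved", "sequelae", "death", "missing")
ROLE_LEVELS      <- c("suspected", "concomitant")
HOSPITAL_TYPES   <- c("psychiatric", "general")

REPORT_COLS   <- c("report_id", "sex", "age", "report_date", "hospital_level",
                   "hospital_type", "diagnoses", "causality", "serious", "outcome")
DRUG_COLS     <- c("report_id", "raw_name", "role", "start_date")
REACTION_COLS <- c("report_id", "raw_term", "onset_date")

#' Parse ISO-8601 dates, accepting year-only values
#'
#' A bare year (e.g. `"2018"`) is accepted and imputed to July 1 of that year;
#' the `imputed` flag records this so onset-delay computations can discount it.
#'
#' @param x character vector of `YYYY-MM-DD` or `YYYY` values ("" / NA allowed).
#' @return data.frame with columns `date` (Date), `imputed`, `ok` (FALSE only
#'   for non-empty values that parse to neither form).
#' @export
parse_report_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  out <- data.frame(date = as.Date(rep(NA_character_, length(x)),
                                   format = "%Y-%m-%d"),
                    imputed = rep(FALSE, length(x)),
                    ok = rep(TRUE, length(x)))
  year_only <- !is.na(x) & grepl("^\\d{4}$", x)
  out$date[year_only] <- as.Date(paste0(x[year_only], "-07-01"),
                                 format = "%Y-%m-%d")
  out$imputed[year_only] <- TRUE
  full <- !is.na(x) & !year_only
  parsed <- as.Date(x[full], format = "%Y-%m-%d", optional = TRUE)
  # reject lexically malformed strings that as.Date would coerce loosely
  parsed[!grepl("^\\d{4}-\\d{2}-\\d{2}$", x[full])] <- as.Date(NA)
  out$date[full] <- parsed
  out$ok[full] <- !is.na(parsed)
  out
}

parse_logical <- function(x) {
  key <- tolower(trimws(as.character(x)))
  ifelse(key %in% c("true", "t", "1", "yes"), TRUE,
         ifelse(key %in% c("false", "f", "0", "no"), FALSE, NA))
}

#' Construct a validated SRS report set
#'
#' The container for spontaneous reports in long format: one parent row per
#' report plus child tables of drug uses and reaction records keyed by
#' `report_id`. Most users will obtain one from [read_reports()] or
#' [generate_reports()] rather than calling this directly.
#'
#' @param reports data.frame with columns `report_id, sex, age, report_date,
#'   hospital_level, hospital_type, diagnoses` (";"-separated), `causality,
#'   serious, outcome` (plus optional `date_imputed`).
#' @param drugs data.frame `report_id, raw_name, role, start_date`.
#' @param reactions data.frame `report_id, raw_term, onset_date`.
#' @return an object of class `srs_reports`.
#' @export
srs_reports <- function(reports, drugs, reactions) {
  reports <- as.data.frame(reports); drugs <- as.data.frame(drugs)
  reactions <- as.data.frame(reactions)
  stopifnot(all(REPORT_COLS %in% names(reports)),
            all(DRUG_COLS %in% names(drugs)),
            all(REACTION_COLS %in% names(reactions)))
  if (anyDuplicated(reports$report_id))
    stop_srs("duplicate report_id in reports table", class = "srs_invalid")
  structure(list(reports = reports, drugs = drugs, reactions = reactions),
            class = "srs_reports")
}

#' @export
print.srs_reports <- function(x, ...) {
  cat(sprintf("<srs_reports> %d reports, %d drug uses, %d reaction records\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

#' Number of reports in an `srs_reports` set
#' @param x an `srs_reports` object.
#' @export
n_reports <- function(x) nrow(x$reports)

#' Read SRS reports from the long-format CSV file set
#'
#' Reads `reports.csv`, `drugs.csv` and `reactions.csv` from `dir` (or the
#' explicit paths), validates every row, and returns the clean reports.
#' Validation never silently drops a record: every input report row either
#' becomes an `ADRReport` or is logged with a row-level error retrievable via
#' [validation_errors()], so `parsed + logged == input rows`.
#'
#' A report is dropped (and logged once, with its first failing field) when:
#' its id duplicates an earlier row, a mandatory field is missing or
#' unparseable (report date, causality, serious flag, hospital level/type),
#' an enum value is unrecognized, age is negative, or it lacks at least one
#' drug or one reaction row. Missing sex becomes `"unknown"` and missing
#' outcome becomes `"missing"`; both are explicit categories, never sentinels.
#' A reaction onset date earlier than the earliest suspected-drug start date
#' is flagged (`onset_before_start`), not dropped.
#'
#' @param dir directory containing the three CSVs.
#' @param reports_file,drugs_file,reactions_file override individual paths.
#' @return `srs_reports` with attribute `"errors"` (data.frame: report_id,
#'   field, message), input order preserved.
#' @export
read_reports <- function(dir,
                         reports_file   = file.path(dir, "reports.csv"),
                         drugs_file     = file.path(dir, "drugs.csv"),
                         reactions_file = file.path(dir, "reactions.csv")) {
  for (f in c(reports_file, drugs_file, reactions_file))
    if (!file.exists(f)) stop_srs("missing input file: ", f, class = "srs_io")
  rep_raw <- utils::read.csv(reports_file, colClasses = "character")
  drg_raw <- utils::read.csv(drugs_file, colClasses = "character")
  rxn_raw <- utils::read.csv(reactions_file, colClasses = "character")
  miss <- setdiff(REPORT_COLS, names(rep_raw))
  if (length(miss))
    stop_srs("reports.csv is missing mandatory column(s): ",
             paste(miss, collapse = ", "), class = "srs_io")
  for (m in setdiff(DRUG_COLS, names(drg_raw)))
    stop_srs("drugs.csv is missing mandatory column: ", m, class = "srs_io")
  for (m in setdiff(REACTION_COLS, names(rxn_raw)))
    stop_srs("reactions.csv is missing mandatory column: ", m, class = "srs_io")

  errors <- list()
  bad <- function(id, field, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(report_id = id, field = field,
                                                 message = msg)
  }

  n <- nrow(rep_raw)
  keep <- rep(TRUE, n)
  id <- trimws(rep_raw$report_id)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (!nzchar(id[i])) { bad(id[i], "report_id", "empty report_id"); keep[i] <- FALSE; next }
    if (i > 1 && id[i] %in% id[seq_len(i - 1)][keep[seq_len(i - 1)]]) {
      bad(id[i], "report_id", "duplicate report_id"); keep[i] <- FALSE
    }
  }

  sex <- tolower(trimws(rep_raw$sex)); sex[!nzchar(sex) | is.na(sex)] <- "unknown"
  age <- suppressWarnings(as.numeric(rep_raw$age))
  rdate <- parse_report_date(rep_raw$report_date)
  lvl <- suppressWarnings(as.integer(rep_raw$hospital_level))
  htype <- tolower(trimws(rep_raw$hospital_type))
  caus <- tolower(trimws(rep_raw$causality))
  serious <- parse_logical(rep_raw$serious)
  outcome <- tolower(trimws(rep_raw$outcome))
  outcome[!nzchar(outcome) | is.na(outcome)] <- "missing"

  drg_ids <- unique(drg_raw$report_id)
  rxn_ids <- unique(rxn_raw$report_id)
  d_start <- parse_report_date(drg_raw$start_date)
  r_onset <- parse_report_date(rxn_raw$onset_date)
  drole <- tolower(trimws(drg_raw$role))
  bad_drug_ids <- unique(drg_raw$report_id[!(drole %in% ROLE_LEVELS) | !d_start$ok |
                                             !nzchar(trimws(drg_raw$raw_name))])
  bad_rxn_ids <- unique(rxn_raw$report_id[!r_onset$ok |
                                            !nzchar(trimws(rxn_raw$raw_term))])

  for (i in seq_len(n)) {
    if (!keep[i]) next
    fail <- function(field, msg) { bad(id[i], field, msg); keep[i] <<- FALSE }
    if (!(sex[i] %in% SEX_LEVELS)) { fail("sex", paste0("unrecognized sex '", sex[i], "'")); next }
    if (!is.na(age[i]) && age[i] < 0) { fail("age", "negative age"); next }
    if (!rdate$ok[i] || is.na(rdate$date[i])) { fail("report_date", "unparseable or missing report_date"); next }
    if (is.na(lvl[i]) || !(lvl[i] %in% 1:3)) { fail("hospital_level", "hospital_level must be 1, 2 or 3"); next }
    if (!(htype[i] %in% HOSPITAL_TYPES)) { fail("hospital_type", "unrecognized hospital_type"); next }
    if (!(caus[i] %in% CAUSALITY_LEVELS)) { fail("causality", "unrecognized causality"); next }
    if (is.na(serious[i])) { fail("serious", "serious flag missing or unparseable"); next }
    if (!(outcome[i] %in% OUTCOME_LEVELS)) { fail("outcome", "unrecognized outcome"); next }
    if (!(id[i] %in% drg_ids)) { fail("drugs", "report has no drug rows"); next }
    if (!(id[i] %in% rxn_ids)) { fail("reactions", "report has no reaction rows"); next }
    if (id[i] %in% bad_drug_ids) { fail("drugs", "invalid drug row (role/date/name)"); next }
    if (id[i] %in% bad_rxn_ids) { fail("reactions", "invalid reaction row (date/term)"); next }
  }

  reports <- data.frame(report_id = id, sex = sex, age = age,
                        report_date = rdate$date,
                        hospital_level = lvl, hospital_type = htype,
                        diagnoses = trimws(rep_raw$diagnoses),
                        causality = caus, serious = serious, outcome = outcome,
                        date_imputed = rdate$imputed)[keep, , drop = FALSE]
  rownames(reports) <- NULL
  drugs <- data.frame(report_id = drg_raw$report_id,
                      raw_name = trimws(drg_raw$raw_name),
                      role = drole, start_date = d_start$date,
                      start_imputed = d_start$imputed)
  drugs <- drugs[drugs$report_id %in% reports$report_id, , drop = FALSE]
  reactions <- data.frame(report_id = rxn_raw$report_id,
                          raw_term = trimws(rxn_raw$raw_term),
                          onset_date = r_onset$date,
                          onset_imputed = r_onset$imputed)
  reactions <- reactions[reactions$report_id %in% reports$report_id, , drop = FALSE]

  # flag (never drop) reactions dated before the earliest suspected drug start
  susp <- drugs[drugs$role == "suspected" & !is.na(drugs$start_date), ]
  if (nrow(susp)) {
    first_start <- tapply(as.numeric(susp$start_date), susp$report_id, min)
    fs <- first_start[reactions$report_id]
    reactions$onset_before_start <- !is.na(fs) & !is.na(reactions$onset_date) &
      as.numeric(reactions$onset_date) < fs
  } else reactions$onset_before_start <- rep(FALSE, nrow(reactions))
  rownames(drugs) <- rownames(reactions) <- NULL

  out <- srs_reports(reports, drugs, reactions)
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(report_id = character(), field = character(), message = character())
  out
}

#' Row-level validation errors recorded by [read_reports()]
#' @param x an `srs_reports` object.
#' @return data.frame with columns report_id, field, message.
#' @export
validation_errors <- function(x) {
  attr(x, "errors") %||%
    data.frame(report_id = character(), field = character(), message = character())
}

#' Write an SRS report set to the long-format CSV file set
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(x, d))` round-trips
#' field-identically for any valid report set.
#'
#' @param x an `srs_reports` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(x, dir) {
  stopifnot(inherits(x, "srs_reports"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_out <- x$reports[, REPORT_COLS]
  rep_out$report_date <- format(rep_out$report_date, "%Y-%m-%d")
  drg_out <- x$drugs[, DRUG_COLS]
  drg_out$start_date <- ifelse(is.na(x$drugs$start_date), "",
                               format(x$drugs$start_date, "%Y-%m-%d"))
  rxn_out <- x$reactions[, REACTION_COLS]
  rxn_out$onset_date <- ifelse(is.na(x$reactions$onset_date), "",
                               format(x$reactions$onset_date, "%Y-%m-%d"))
  utils::write.csv(rep_out, file.path(dir, "reports.csv"), row.names = FALSE, na = "")
  utils::write.csv(drg_out, file.path(dir, "drugs.csv"), row.names = FALSE, na = "")
  utils::write.csv(rxn_out, file.path(dir, "reactions.csv"), row.names = FALSE, na = "")
  invisible(dir)
}
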