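# in-code fixtures shared across test files

fixture_dicts <- function() {
  load_dictionaries()  # the bundled extdata fixtures
}

# minimal valid srs_reports built in code
# drugs: list of data.frames (raw_name, role[, start_date]) per report
# reactions: list of character vectors of raw terms per report
make_reports <- function(ids, dates, causality = "probable",
                         drugs = NULL, reactions = NULL,
                         serious = FALSE, sex = "male", age = 30,
                         hospital_level = 3L, hospital_type = "psychiatric",
                         diagnoses = "schizophrenia", outcome = "cured") {
  n <- length(ids)
  rec <- function(x) rep_len(x, n)
  if (is.null(drugs))
    drugs <- rep(list(data.frame(raw_name = "risperidone", role = "suspected")), n)
  if (is.null(reactions)) reactions <- rep(list("Tremor"), n)
  reports <- data.frame(report_id = ids, sex = rec(sex), age = rec(age),
                        report_date = as.Date(dates),
                        hospital_level = rec(hospital_level),
                        hospital_type = rec(hospital_type),
                        diagnoses = rec(diagnoses),
                        causality = rec(causality), serious = rec(serious),
                        outcome = rec(outcome), date_imputed = FALSE)
  dl <- lapply(seq_len(n), function(i) {
    d <- drugs[[i]]
    if (is.null(d$start_date)) d$start_date <- as.Date(dates[i])
    d$report_id <- ids[i]
    d$start_imputed <- FALSE
    d
  })
  rl <- lapply(seq_len(n), function(i)
    data.frame(report_id = ids[i], raw_term = reactions[[i]],
               onset_date = as.Date(dates[i]), onset_imputed = FALSE,
               onset_before_start = FALSE))
  srs_reports(reports, do.call(rbind, dl)[, c("report_id", "raw_name", "role",
                                              "start_date", "start_imputed")],
              do.call(rbind, rl))
}

# the hand-enumerable toy combination set:
# {(r1,D,X),(r1,D,Y),(r2,D,X),(r3,E,X),(r4,E,Z),(r5,F,Y)}
toy_combos <- function() {
  data.frame(report_id = c("r1", "r1", "r2", "r3", "r4", "r5"),
             generic_drug = c("D", "D", "D", "E", "E", "F"),
             pt = c("X", "Y", "X", "X", "Z", "Y"))
}

# write a 3-report long-format CSV set; optionally corrupt one date
write_report_fixture <- function(dir, bad_date = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep3 <- data.frame(
    report_id = c("A1", "A2", "A3"), sex = c("male", "female", "male"),
    age = c(25, 40, 61),
    report_date = c("2018-05-01", if (bad_date) "2018-13-99" else "2019-02-10",
                    "2020-11-30"),
    hospital_level = c(3, 2, 3),
    hospital_type = c("psychiatric", "general", "psychiatric"),
    diagnoses = "schizophrenia", causality = "probable",
    serious = c("FALSE", "TRUE", "FALSE"), outcome = c("cured", "relieved", "cured"))
  drugs <- data.frame(report_id = c("A1", "A2", "A3"),
                      raw_name = c("risperidone", "clozapine", "haloperidol"),
                      role = "suspected",
                      start_date = c("2018-04-20", "2019-01-31", "2020-11-01"))
  rxn <- data.frame(report_id = c("A1", "A2", "A3"),
                    raw_term = c("Tremor", "Constipation", "Dystonia"),
                    onset_date = c("2018-04-29", "2019-02-08", "2020-11-20"))
  write.csv(rep3, file.path(dir, "reports.csv"), row.names = FALSE)
  write.csv(drugs, file.path(dir, "drugs.csv"), row.names = FALSE)
  write.csv(rxn, file.path(dir, "reactions.csv"), row.names = FALSE)
  dir
}

# independent plain-arithmetic oracle for all four methods (test-side route)
oracle_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  ror <- (a / c) / (b / d)
  se_r <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_p <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  eic <- log2((a + 1) * (n + 2)^2 / ((n + 4) * (a + b + 1) * (a + c + 1)))
  vic <- (1 / log(2)^2) * ((n - a + 3) / ((a + 1) * (n + 5)) +
                           (n - (a + b) + 1) / ((a + b + 1) * (n + 3)) +
                           (n - (a + c) + 1) / ((a + c + 1) * (n + 3)))
  list(ror = ror, ror_li = exp(log(ror) - 1.96 * se_r),
       prr = prr, prr_li = exp(log(prr) - 1.96 * se_p),
       chi2_pearson = n * (a * d - b * c)^2 / den,
       chi2_yates = n * max(0, abs(a * d - b * c) - n / 2)^2 / den,
       eic = eic, vic = vic, ic_li = eic - 2 * sqrt(vic))
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed, max_cell = 500L) {
  set.seed(seed)
  data.frame(a = sample(max_cell, n, TRUE), b = sample(max_cell, n, TRUE),
             c = sample(max_cell, n, TRUE), d = sample(max_cell, n, TRUE))
}
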