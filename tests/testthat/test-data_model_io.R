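test_that("row-level validation drops and logs bad records without losing count", {
  dir <- write_report_fixture(withr::local_tempdir(), bad_date = TRUE)
  x <- read_reports(dir)
  err <- validation_errors(x)
  expect_equal(n_reports(x), 2L)
  expect_equal(nrow(err), 1L)
  expect_equal(err$report_id, "A2")
  expect_equal(err$field, "report_date")
  # conservation: input rows = parsed + logged
  expect_equal(3L, n_reports(x) + nrow(err))
  # input order preserved
  expect_equal(x$reports$report_id, c("A1", "A3"))
})

test_that("a header-only file yields an empty collection and no errors", {
  dir <- write_report_fixture(withr::local_tempdir())
  for (f in c("reports.csv", "drugs.csv", "reactions.csv")) {
    lines <- readLines(file.path(dir, f))
    writeLines(lines[1], file.path(dir, f))
  }
  x <- read_reports(dir)
  expect_equal(n_reports(x), 0L)
  expect_equal(nrow(validation_errors(x)), 0L)
})

test_that("missing mandatory columns fail hard, naming the column", {
  dir <- write_report_fixture(withr::local_tempdir())
  r <- read.csv(file.path(dir, "reports.csv"))
  r$causality <- NULL
  write.csv(r, file.path(dir, "reports.csv"), row.names = FALSE)
  expect_error(read_reports(dir), "causality", class = "srs_io")
})

test_that("structural report defects are logged per report", {
  dir <- write_report_fixture(withr::local_tempdir())
  # A3 loses its reaction rows; a duplicate of A1 is appended
  rxn <- read.csv(file.path(dir, "reactions.csv"))
  write.csv(rxn[rxn$report_id != "A3", ], file.path(dir, "reactions.csv"),
            row.names = FALSE)
  rep3 <- read.csv(file.path(dir, "reports.csv"))
  write.csv(rbind(rep3, rep3[1, ]), file.path(dir, "reports.csv"),
            row.names = FALSE)
  x <- read_reports(dir)
  err <- validation_errors(x)
  expect_equal(n_reports(x), 2L)
  expect_setequal(err$field, c("reactions", "report_id"))
  expect_equal(4L, n_reports(x) + nrow(err))
})

test_that("year-only dates are accepted, imputed to July 1 and flagged", {
  parsed <- parse_report_date(c("2018", "2018-03-04", "", "2018-3-4"))
  expect_equal(parsed$date[1], as.Date("2018-07-01"))
  expect_true(parsed$imputed[1])
  expect_equal(parsed$date[2], as.Date("2018-03-04"))
  expect_false(parsed$imputed[2])
  expect_true(is.na(parsed$date[3]) && parsed$ok[3])   # empty = missing, not error
  expect_false(parsed$ok[4])                           # malformed
})

test_that("write_reports / read_reports round-trips a generated dataset", {
  gen <- generate_reports(synthetic_config(n_reports = 200), seed = 11)
  dir <- withr::local_tempdir()
  write_reports(gen$reports, dir)
  back <- read_reports(dir)
  expect_equal(nrow(validation_errors(back)), 0L)
  for (col in c("report_id", "sex", "age", "report_date", "hospital_level",
                "hospital_type", "diagnoses", "causality", "serious", "outcome"))
    expect_equal(back$reports[[col]], gen$reports$reports[[col]], label = col)
  expect_equal(back$drugs[, c("report_id", "raw_name", "role", "start_date")],
               gen$reports$drugs[, c("report_id", "raw_name", "role", "start_date")])
  expect_equal(back$reactions[, c("report_id", "raw_term", "onset_date")],
               gen$reports$reactions[, c("report_id", "raw_term", "onset_date")])
})

test_that("dictionaries load, normalize lookups and enforce invariants", {
  dicts <- fixture_dicts()
  # case/whitespace-insensitive lookup of a trade-name synonym
  hit <- standardize_drug("  RispeRDAL ", dicts$drugs)
  expect_equal(hit$generic_name, "risperidone")
  expect_equal(hit$apd_class, "atypical")
  # the bundled roster: 7 typical and 8 atypical antipsychotics
  roster <- unique(data.frame(g = dicts$drugs$generic_name,
                              cls = dicts$drugs$apd_class))
  expect_equal(sum(roster$cls == "typical"), 7L)
  expect_equal(sum(roster$cls == "atypical"), 8L)

  # conflicting duplicate raw term -> hard failure listing the key
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(raw_term = c("xx", "xx"), pt = c("Tremor", "Dystonia"),
                       soc = "Nervous system disorders"), bad, row.names = FALSE)
  expect_error(load_term_dictionary(bad), "xx", class = "srs_dictionary")
  # PT with two primary SOCs -> hard failure
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(raw_term = c("p", "q"), pt = "Tremor",
                       soc = c("Nervous system disorders", "Cardiac disorders")),
            bad2, row.names = FALSE)
  expect_error(load_term_dictionary(bad2), class = "srs_dictionary")
  # N05A drug classed non_apd -> hard failure
  bad3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(raw_name = "x", generic_name = "x",
                       atc_code = "N05AX99", apd_class = "non_apd"),
            bad3, row.names = FALSE)
  expect_error(load_drug_dictionary(bad3), class = "srs_dictionary")
})
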