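dicts <- fixture_dicts()

test_that("exclusion reasons follow the fixed year -> suspected -> causality order", {
  x <- make_reports(
    ids = c("E1", "E2", "E3", "K1"),
    dates = c("2015-06-01", "2018-06-01", "2018-06-01", "2018-06-01"),
    causality = c("probable", "probable", "unlikely", "possible"),
    drugs = list(
      data.frame(raw_name = "risperidone", role = "suspected"),
      data.frame(raw_name = c("aspirin", "risperidone"),
                 role = c("suspected", "concomitant")),
      data.frame(raw_name = "clozapine", role = "suspected"),
      data.frame(raw_name = "clozapine", role = "suspected")))
  res <- apply_inclusion_exclusion(x, dicts$drugs)
  expect_equal(res$included$reports$report_id, "K1")
  expect_equal(res$exclusions$reason[match(c("E1", "E2", "E3"),
                                           res$exclusions$report_id)],
               c("year", "not_suspected", "causality"))
  # a 2015 report with unaccepted causality is still logged as 'year' (first rule)
  x2 <- make_reports("E4", "2015-06-01", causality = "impossible")
  expect_equal(apply_inclusion_exclusion(x2, dicts$drugs)$exclusions$reason, "year")
  # filtering is idempotent
  res2 <- apply_inclusion_exclusion(res$included, dicts$drugs)
  expect_equal(res2$included$reports, res$included$reports)
  expect_equal(nrow(res2$exclusions), 0L)
  expect_error(apply_inclusion_exclusion(x, dicts$drugs,
                                         accepted_causality = character()),
               class = "srs_config")
})

test_that("drug and term standardization map hits and surface misses", {
  d <- standardize_drug(c("氯氮平/clozapine tablet 25mg", "haloperidol",
                          "aspirin", "no-such-drug"), dicts$drugs)
  expect_equal(d$generic_name, c("clozapine", "haloperidol", "aspirin", NA))
  expect_equal(d$apd_class, c("atypical", "typical", "non_apd", "unmapped"))
  t <- standardize_term(c("EPS symptoms", "liver enzymes raised", "??"),
                        dicts$terms)
  expect_equal(t$pt, c("Extrapyramidal disorder", "Hepatic function abnormal", NA))
  expect_equal(t$soc, c("Nervous system disorders", "Hepatobiliary disorders", NA))
})

test_that("combination expansion is the deduplicated suspected-APD x PT cross-product", {
  x <- make_reports(
    ids = c("C1", "C2", "C3", "C4"),
    dates = "2018-06-01",
    drugs = list(
      data.frame(raw_name = "risperidone", role = "suspected"),
      data.frame(raw_name = c("risperidone", "clozapine"), role = "suspected"),
      data.frame(raw_name = c("risperidone", "RISPERDAL", "aspirin"),
                 role = c("suspected", "suspected", "suspected")),
      data.frame(raw_name = "risperidone", role = "suspected")),
    reactions = list(c("Tremor", "Dystonia", "Akathisia"),
                     c("Tremor", "Dystonia"),
                     c("Tremor", "EPS symptoms", "Extrapyramidal disorder"),
                     "totally unknown term"))
  combos <- expand_combinations(x, dicts$drugs, dicts$terms)
  expect_equal(sum(combos$report_id == "C1"), 3L)         # 1 drug x 3 PTs
  expect_equal(sum(combos$report_id == "C2"), 4L)         # 2 drugs x 2 PTs
  # C3: synonyms collapse to one drug, one raw term duplicates a PT -> 2 combos
  expect_equal(sum(combos$report_id == "C3"), 2L)
  expect_false(any(combos$generic_drug == "aspirin"))
  expect_false("C4" %in% combos$report_id)                # no standardized PT
  expect_true("C4" %in% attr(combos, "empty_reports"))
  expect_true("totally unknown term" %in% attr(combos, "unmapped_terms"))
  # uniqueness of (report, drug, pt) and covariate carry-over
  expect_false(any(duplicated(combos[, c("report_id", "generic_drug", "pt")])))
  expect_true(all(c("sex", "age_bin", "season", "serious") %in% names(combos)))
  expect_gte(nrow(combos), 3L)  # >= number of contributing reports
})

test_that("covariates bin, season and flag per the documented conventions", {
  x <- make_reports(
    ids = c("V1", "V2", "V3", "V4"),
    dates = c("2018-12-15", "2018-04-01", "2018-07-01", "2018-10-01"),
    age = c(17.9, 18, 64.9, 65),
    drugs = list(
      data.frame(raw_name = c("risperidone", "haloperidol", "aspirin"),
                 role = c("suspected", "concomitant", "concomitant")),
      data.frame(raw_name = "haloperidol", role = "suspected"),
      data.frame(raw_name = c("haloperidol", "clozapine"), role = "suspected"),
      data.frame(raw_name = "risperidone", role = "suspected")),
    diagnoses = c("schizophrenia", "schizophrenia;hypertension",
                  "schizophrenia", "schizophrenia"))
  cov <- derive_covariates(x, dicts$drugs)
  expect_equal(as.character(cov$age_bin), c("<18", "18-35", "35-65", ">=65"))
  expect_equal(cov$season, c("winter", "spring", "summer", "autumn"))
  expect_equal(cov$polypharmacy, c(TRUE, FALSE, FALSE, FALSE))  # 3 drugs total
  expect_equal(cov$multiple_disease, c(FALSE, TRUE, FALSE, FALSE))
  # suspected drugs spanning both classes code as atypical
  expect_equal(cov$apd_class, c("atypical", "typical", "atypical", "atypical"))
  # missing age propagates as missing bin
  x2 <- make_reports("V9", "2018-06-01", age = NA)
  expect_true(is.na(derive_covariates(x2, dicts$drugs)$age_bin))
})
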