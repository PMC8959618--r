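dicts <- fixture_dicts()

test_that("frequency tables re-derive printed-style percentages exactly", {
  ft <- frequency_table(c("x", "y"), c(1875, 2078), denominator = 3953,
                        basis = "combinations")
  expect_equal(ft$percentage[1], 47.43)
  expect_equal(ft$percentage,
               round_half_up(100 * ft$frequency / attr(ft, "denominator"), 2))
  expect_equal(sum(ft$frequency), attr(ft, "denominator"))
  # half-up at the boundary: 0.125% -> 0.13, where round() would give 0.12
  expect_equal(frequency_table("z", 1, denominator = 800)$percentage, 0.13)
})

test_that("yearly trend zero-fills and handles degenerate inputs", {
  x <- make_reports(c("Y1", "Y2", "Y3"),
                    c("2016-02-01", "2016-09-30", "2019-05-05"),
                    serious = c(FALSE, TRUE, FALSE))
  tr <- yearly_trend(x, c(2016, 2020))
  expect_equal(tr$year, 2016:2020)
  expect_equal(tr$n_reports, c(2L, 0L, 0L, 1L, 0L))
  expect_equal(tr$serious_pct[1], 50)
  # all non-serious -> proportions all 0
  x0 <- make_reports(c("Z1", "Z2"), c("2018-01-01", "2018-06-01"))
  expect_true(all(yearly_trend(x0)$serious_pct == 0))
  expect_equal(nrow(yearly_trend(x0)), 1L)  # single-year dataset -> one row
})

test_that("onset bins are half-open on the right and exceptions are counted", {
  delays <- c(0, 1, 7, 8, 30, 31, 90, 91, 400, -3, NA)
  dates <- as.Date("2018-06-01")
  drugs <- lapply(seq_along(delays), function(i)
    data.frame(raw_name = "risperidone", role = "suspected",
               start_date = dates))
  x <- make_reports(sprintf("O%02d", seq_along(delays)),
                    rep("2018-06-01", length(delays)), drugs = drugs)
  x$reactions$onset_date <- dates + delays
  tab <- onset_distribution(x, dicts$drugs)
  expect_equal(tab$frequency,
               c(1L, 2L, 2L, 2L, 2L))  # same day | 1-7 | 8-30 | 31-90 | >90
  expect_equal(attr(tab, "n_negative"), 1L)
  expect_equal(attr(tab, "n_missing"), 1L)
  expect_equal(attr(tab, "denominator"), 9L)
})

test_that("most synthetic onsets fall within 90 days under the default delay model", {
  gen <- generate_reports(synthetic_config(n_reports = 3000), seed = 5)
  tab <- onset_distribution(gen$reports, roster_drug_dictionary(synthetic_config()))
  within_90 <- sum(tab$frequency[tab$label != ">90 d"]) / sum(tab$frequency)
  expect_gte(within_90, 0.5)
})

test_that("drug seriousness table counts per drug and aggregates per class", {
  x <- make_reports(
    ids = c("S1", "S2", "S3", "S4"),
    dates = "2018-06-01",
    serious = c(TRUE, FALSE, FALSE, TRUE),
    drugs = list(
      data.frame(raw_name = "chlorpromazine", role = "suspected"),
      data.frame(raw_name = "chlorpromazine", role = "suspected"),
      data.frame(raw_name = c("haloperidol", "risperidone"), role = "suspected"),
      data.frame(raw_name = "risperidone", role = "suspected")))
  tab <- drug_seriousness_table(x, dicts$drugs)
  cpz <- tab[!is.na(tab$generic_drug) & tab$generic_drug == "chlorpromazine", ]
  expect_equal(cpz$total, 2L)
  expect_equal(cpz$serious_pct, 50)
  # the multi-APD report S3 contributes to both drugs' rows
  expect_equal(tab$total[!is.na(tab$generic_drug) &
                           tab$generic_drug == "haloperidol"], 1L)
  expect_equal(tab$total[!is.na(tab$generic_drug) &
                           tab$generic_drug == "risperidone"], 2L)
  # class rows aggregate member drugs
  typ <- tab[is.na(tab$generic_drug) & tab$apd_class == "typical", ]
  expect_equal(typ$total, 3L)      # 2 chlorpromazine + 1 haloperidol
  expect_equal(typ$serious, 1L)
  # zero-serious drug prints 0 and 0.00%
  hal <- tab[!is.na(tab$generic_drug) & tab$generic_drug == "haloperidol", ]
  expect_equal(hal$serious, 0L)
  expect_equal(hal$serious_pct, 0)
})

test_that("SOC and PT tables use the in-scope combination denominator", {
  cfg <- synthetic_config(n_reports = 1500)
  gen <- generate_reports(cfg, seed = 9)
  dd <- roster_drug_dictionary(cfg); td <- roster_term_dictionary(cfg)
  combos <- expand_combinations(
    apply_inclusion_exclusion(gen$reports, dd)$included, dd, td)
  soc <- soc_table(combos, top = 5)
  expect_equal(nrow(soc), 5L)
  expect_equal(attr(soc, "denominator"), nrow(combos))  # full, not subtotal
  full <- soc_table(combos)
  expect_equal(sum(full$frequency), nrow(combos))       # exhaustive
  typ <- pt_table(combos, apd_class = "typical")
  expect_equal(attr(typ, "denominator"),
               sum(combos$apd_class == "typical"))      # per-class denominator
  expect_equal(nrow(pt_table(combos[0, ], top = 1)), 0L)
})

test_that("outcome table keeps Missing as a category inside the denominator", {
  x <- make_reports(c("U1", "U2", "U3"), "2018-06-01",
                    outcome = c("cured", "cured", "missing"))
  tab <- outcome_table(x)
  expect_equal(attr(tab, "denominator"), 3L)
  expect_equal(tab$frequency[tab$label == "Cured"], 2L)
  expect_equal(tab$percentage[tab$label == "Missing"], 33.33)
  x2 <- make_reports("U9", "2018-06-01", outcome = "missing")
  t2 <- outcome_table(x2)
  expect_equal(t2$percentage[t2$label == "Missing"], 100)
})
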