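test_that("build_table classifies every combination into exactly one cell", {
  tc <- toy_combos()
  tab <- build_table(tc, "D", "X")
  expect_equal(unlist(tab[c("a", "b", "c", "d", "n")]),
               c(a = 2, b = 1, c = 1, d = 2, n = 6))
  # absent drug: a = 0 with valid marginals
  tab0 <- build_table(tc, "ZZZ", "X")
  expect_equal(tab0$a, 0)
  expect_equal(tab0$a + tab0$c, 3)  # PT margin intact
  expect_equal(tab0$n, 6)
  # partition property: sum of a over all pairs = n
  sig <- mine_signals(tc)
  expect_equal(sum(sig$a), nrow(tc))
  # per-drug margin
  expect_equal(sum(sig$a[sig$generic_drug == "D"]), 3L)
  expect_error(contingency_table(-1, 0, 0, 0), class = "srs_table")
})

test_that("the worked table reproduces the frozen statistics", {
  tab <- contingency_table(5, 15, 20, 160)
  r <- ror_stats(tab)
  expect_equal(r$est, 2.666667, tolerance = 1e-3)
  expect_equal(r$li, 0.875504, tolerance = 1e-3)
  p <- prr_stats(tab)
  expect_equal(p$est, 2.25, tolerance = 1e-9)
  expect_equal(p$li, 0.948049, tolerance = 1e-3)
  expect_equal(chi2_stat(tab, corrected = FALSE), 3.174603, tolerance = 1e-3)
  expect_equal(chi2_stat(tab, corrected = TRUE), 2.031746, tolerance = 1e-3)
  ic <- bcpnn_stats(tab)
  expect_equal(ic$eic, 1.136203, tolerance = 1e-3)
  expect_equal(ic$vic, 0.492826, tolerance = 1e-3)
  expect_equal(ic$li, -0.267829, tolerance = 1e-3)
})

test_that("independence tables score ROR = PRR = 1 and chi2 = 0 exactly", {
  tab <- contingency_table(10, 90, 90, 810)  # ad = bc
  expect_identical(ror_stats(tab)$est, 1)
  expect_identical(prr_stats(tab)$est, 1)
  expect_identical(chi2_stat(tab, corrected = FALSE), 0)
  expect_identical(chi2_stat(tab, corrected = TRUE), 0)  # Yates clamped at 0
})

test_that("scale and monotonicity properties hold", {
  tab <- contingency_table(5, 15, 20, 160)
  tab10 <- contingency_table(50, 150, 200, 1600)
  expect_equal(ror_stats(tab10)$est, ror_stats(tab)$est)
  expect_gt(ror_stats(tab10)$li, ror_stats(tab)$li)  # CI narrows
  # ROR and PRR strictly increasing in a with b, c, d fixed
  for (a in c(2, 5, 9, 40)) {
    t1 <- contingency_table(a, 15, 20, 160)
    t2 <- contingency_table(a + 1, 15, 20, 160)
    expect_gt(ror_stats(t2)$est, ror_stats(t1)$est)
    expect_gt(prr_stats(t2)$est, prr_stats(t1)$est)
  }
  # E(IC) increases in a only while a is small against the margins (the
  # shrinkage estimate tends back to 0 once the pair dominates its margins)
  for (a in c(2, 5, 9)) {
    t1 <- contingency_table(a, 150, 200, 1600)
    t2 <- contingency_table(a + 1, 150, 200, 1600)
    expect_gt(bcpnn_stats(t2)$eic, bcpnn_stats(t1)$eic)
  }
})

test_that("degenerate cells yield typed non-computable results, never infinities", {
  tab <- contingency_table(0, 10, 10, 100)
  r <- ror_stats(tab)
  expect_true(is.na(r$est) && is.na(r$li))
  expect_match(r$reason, "zero cell")
  expect_true(is.na(prr_stats(tab)$est))
  # BCPNN shrinkage keeps a = 0 tables finite
  ic <- bcpnn_stats(tab)
  expect_true(is.finite(ic$eic) && is.finite(ic$li))
  # zero margin: chi2 non-computable
  expect_true(is.na(chi2_stat(contingency_table(0, 0, 10, 100))))
})

test_that("E(IC) tends to 0 under independence as n grows", {
  # margins held at n/10 each, a at independence value n/100
  n <- 1e6
  a <- n / 100; m <- n / 10
  tab <- contingency_table(a, m - a, m - a, n - 2 * m + a)
  expect_equal(bcpnn_stats(tab)$eic, 0, tolerance = 0.01)
  # the plain variant behaves likewise
  expect_equal(bcpnn_stats(tab, variant = "plain")$eic, 0, tolerance = 0.01)
})

test_that("uncorrected chi2 agrees with the Pearson oracle on random tables", {
  tabs <- random_tables(1000, seed = 404)
  ours <- mapply(function(a, b, c, d)
    chi2_stat(contingency_table(a, b, c, d), corrected = FALSE),
    tabs$a, tabs$b, tabs$c, tabs$d)
  oracle <- mapply(function(a, b, c, d)
    suppressWarnings(unname(chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                       correct = FALSE)$statistic)),
    tabs$a, tabs$b, tabs$c, tabs$d)
  expect_lt(max(abs(ours - oracle) / pmax(oracle, 1e-12)), 1e-9)
})

test_that("flags reproduce bit-identically from serialized results", {
  sig <- mine_signals(toy_combos())
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(sig, f, row.names = FALSE)
  back <- read.csv(f)
  re <- evaluate_criteria(back)
  for (nm in names(re)) expect_identical(re[[nm]], sig[[nm]], label = nm)
})

test_that("rank_signals orders by PRR with deterministic tie-breaks", {
  sig <- data.frame(generic_drug = c("d1", "d2", "d3", "d4"),
                    pt = c("p1", "p2", "p3", "p4"),
                    a = c(5, 8, 6, 6), prr = c(13.29, 15.51, 11.81, 11.81),
                    flag_consensus = c(TRUE, TRUE, TRUE, TRUE))
  r <- rank_signals(sig)
  expect_equal(r$prr, c(15.51, 13.29, 11.81, 11.81))
  expect_equal(r$generic_drug, c("d2", "d1", "d3", "d4"))
  expect_equal(nrow(rank_signals(sig[0, ])), 0L)
  # equal PRR and a: name order decides, stable across permutation
  perm <- sig[c(4, 2, 1, 3), ]
  expect_equal(rank_signals(perm)$generic_drug, r$generic_drug)
})

test_that("the consistency probe recovers a known table from rounded statistics", {
  truth <- c(a = 8, b = 120, c = 60, d = 3765)
  s <- oracle_stats(truth[1], truth[2], truth[3], truth[4])
  hits <- probe_consistent_tables(
    n = sum(truth), prr = round(s$prr, 2), ror_li = round(s$ror_li, 2),
    prr_li = round(s$prr_li, 2), chi2 = round(s$chi2_yates, 2),
    ic_li = round(s$ic_li, 2), a_range = 3:15, margin_max = 300L)
  expect_true(any(hits$a == 8 & hits$b == 120 & hits$c == 60))
})
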