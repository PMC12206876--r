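# Contingency construction and the ROR / PRR / IC statistics.

test_that("pair-level contingency tables match a hand count", {
  rep <- four_report_corpus()
  co <- select_index_cohort(rep, "INDEXDRUG")
  tab <- build_contingency_tables(co$index, co$background, level = "pt")
  e1 <- tab[tab$term == "E1", ]
  expect_equal(unlist(e1[c("a", "b", "c", "d", "n")]),
               c(a = 2, b = 1, c = 1, d = 2, n = 6))
  # conservation: sum of a equals the index pair total; a+b constant
  expect_equal(sum(tab$a), 3)
  expect_equal(unique(tab$a + tab$b), 3)
})

test_that("a single index report against an empty background is a boundary table", {
  demo <- demo_row("1")
  drug <- data.frame(primaryid = "1", drug_seq = "1", role_cod = "PS",
                     drugname = "X", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = "1", pt = "E1", stringsAsFactors = FALSE)
  rep <- assemble_reports(make_raw(demo, drug, reac))
  co <- list(index = rep, background = subset_reports(rep, character(0)))
  tab <- build_contingency_tables(co$index, co$background, "pt")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 0, c = 0, d = 0))
})

test_that("SOC-level tables count one pair per report per organ class", {
  # two PTs of one report in the same SOC must collapse to a single pair
  demo <- rbind(demo_row("1"), demo_row("2"))
  drug <- data.frame(primaryid = c("1", "2"), drug_seq = "1",
                     role_cod = "PS", drugname = c("X", "Y"),
                     stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = c("1", "1", "2"),
                     pt = c("E1", "E2", "E1"), stringsAsFactors = FALSE)
  hier <- event_hierarchy(c("E1", "E2"), c("S1", "S1"))
  rep <- assemble_reports(make_raw(demo, drug, reac), hierarchy = hier)
  co <- select_index_cohort(rep, "X")
  tab <- build_contingency_tables(co$index, co$background, "soc")
  expect_equal(tab$a[tab$term == "S1"], 1)
  expect_equal(sum(tab$a), 1)
})

test_that("ROR and its Wald interval follow the closed form", {
  # symmetric table: no association
  s <- ror_stat(5, 5, 5, 5)
  expect_equal(s$ror, 1)
  expect_lt(s$ror_low, 1); expect_gt(s$ror_high, 1)

  s <- ror_stat(10, 20, 30, 40)
  expect_equal(s$ror, 2 / 3, tolerance = 1e-12)
  expect_equal(s$ror_low, 0.272515, tolerance = 1e-5)
  expect_equal(s$ror_high, 1.630900, tolerance = 1e-5)
  expect_false(s$corrected)

  # a zero cell triggers the Haldane-Anscombe correction, flagged
  z <- ror_stat(3, 0, 7, 11)
  expect_true(z$corrected)
  expect_equal(z$ror, (3.5 * 11.5) / (0.5 * 7.5), tolerance = 1e-12)
})

test_that("PRR and the Pearson chi-square follow the closed form", {
  s <- prr_stat(5, 5, 5, 5)
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)

  s <- prr_stat(10, 20, 30, 40)
  expect_equal(s$prr, (10 / 30) / (30 / 70), tolerance = 1e-12)
  expect_equal(s$chi2, 100 * (10 * 40 - 20 * 30)^2 / (30 * 70 * 40 * 60),
               tolerance = 1e-12)

  # c = 0: infinite ratio, flagged, chi-square still computed
  s0 <- prr_stat(4, 10, 0, 20)
  expect_true(is.infinite(s0$prr))
  expect_true(s0$prr_undefined)
  expect_true(is.finite(s0$chi2) && s0$chi2 > 0)

  expect_error(prr_stat(0, 0, 1, 1), "a\\+b")
})

test_that("information component and IC025 follow the shrinkage formulas", {
  # observed equals expected -> IC = 0 (E = (a+b)(a+c)/N = a)
  s <- ic_stat(10, 10, 10, 10)
  expect_equal(s$expected, 10)
  expect_equal(s$ic, 0)

  s <- ic_stat(10, 20, 30, 40)
  expect_equal(s$expected, 12)
  expect_equal(s$ic, log2(10.5 / 12.5), tolerance = 1e-12)
  expect_equal(s$ic025,
               s$ic - 3.3 * 10.5^-0.5 - 2.0 * 10.5^-1.5, tolerance = 1e-12)
})

test_that("ROR-PRR ordering identity and chi2 symmetry hold on random tables", {
  tabs <- random_tables(300, seed = 11)
  r <- ror_stat(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  p <- prr_stat(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  # exact algebraic identity: ROR > PRR iff ROR > 1 (iff ad > bc)
  expect_equal(r > p, r > 1)
  expect_equal(abs(r - p) < 1e-12, abs(r - 1) < 1e-12)

  # chi2 invariant under swapping index<->background and term<->other
  c1 <- prr_stat(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  c2 <- prr_stat(tabs$d, tabs$c, tabs$b, tabs$a)$chi2
  expect_equal(c1, c2, tolerance = 1e-9)

  # IC025 < IC everywhere (the correction terms are strictly positive)
  ics <- ic_stat(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(ics$ic025 < ics$ic))
})

test_that("ROR and PRR increase strictly with a, holding b, c, d fixed", {
  a <- 1:50
  r <- ror_stat(a, 100, 50, 1000)$ror
  p <- prr_stat(a, 100, 50, 1000)$prr
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
})

test_that("signal gating applies the support floor and the disjunctive rule", {
  rows <- data.frame(
    term = c("LOW_SUPPORT", "STRONG", "NULL_ROW"),
    a = c(2, 367, 50),
    ror = c(9, 2.41, 1.0), ror_low = c(3, 2.15, 0.9), ror_high = c(27, 2.69, 1.1),
    prr = c(8, 2.37, 1.1), chi2 = c(30, 256.96, 0.5),
    ic = c(2, 1.14, 0.1), ic025 = c(1, 0.97, -0.2),
    ebgm = c(6, 2.2, 1.0), ebgm05 = c(3, 2.0, 1.0))
  g <- gate_signals(rows, threshold_policy())
  g <- g[match(rows$term, g$term), ]
  expect_equal(g$positive, c(FALSE, TRUE, FALSE))
  # the strong row fires on the ROR bound, as in a published-table row
  expect_true(g$flag_ror[g$term == "STRONG"])
  # rows come back sorted by a descending for top-N reporting
  g2 <- gate_signals(rows, threshold_policy())
  expect_equal(g2$a, sort(rows$a, decreasing = TRUE))
  # conjunctive combination demands every method positive
  g3 <- gate_signals(rows, threshold_policy(combination = "all"))
  expect_false(any(g3$positive[g3$term == "STRONG"]))
})

test_that("signal_table composes statistics, EBGM and gate on a corpus", {
  rep <- four_report_corpus()
  co <- select_index_cohort(rep, "INDEXDRUG")
  st <- signal_table(co$index, co$background, level = "pt",
                     ebgm_method = "ic")
  expect_setequal(st$term, c("E1", "E2", "E3"))
  expect_true(all(st$ror_low <= st$ror & st$ror <= st$ror_high))
  expect_equal(st$ebgm, 2^st$ic)
  expect_equal(st$ebgm05, 2^st$ic025)
  fm <- format_signal_table(st)
  expect_match(fm$ror[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
})
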