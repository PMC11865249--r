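test_that("ROR, RRR and safety signal match direct-arithmetic examples", {
  t1 <- contingency_table(10, 10, 10, 10)
  r1 <- compute_ror(t1)
  expect_equal(r1$ror, 1)
  expect_lt(r1$ci_low, 1)
  expect_gt(r1$ci_high, 1)
  expect_false(r1$corrected)

  t2 <- contingency_table(2, 5, 10, 500)
  r2 <- compute_ror(t2)
  expect_equal(r2$ror, 20)
  o2 <- oracle_ror(2, 5, 10, 500)
  expect_equal(r2$ci_low, unname(o2["lo"]), tolerance = 1e-12)
  expect_equal(r2$ci_high, unname(o2["hi"]), tolerance = 1e-12)
  # se on the log scale is sqrt(0.802)
  expect_equal(log(r2$ci_high / r2$ror), 1.96 * sqrt(0.802), tolerance = 1e-12)

  # independence rows: observed equals expected
  expect_equal(compute_rrr(contingency_table(2, 8, 20, 80)), 1)
  t3 <- contingency_table(2, 5, 10, 495)
  expect_equal(compute_rrr(t3), 2 / (7 * 12 / 512), tolerance = 1e-12)
  expect_equal(compute_rrr(t3), 12.19, tolerance = 1e-3)
  expect_equal(compute_safety_signal(t3), log2(2.5 / (7 * 12 / 512 + 0.5)),
               tolerance = 1e-12)
  expect_equal(compute_safety_signal(t3), 1.91, tolerance = 1e-2)

  # degenerate a = 0: rrr 0, signal negative, ror corrected
  t4 <- contingency_table(0, 10, 50, 1000)
  expect_equal(compute_rrr(t4), 0)
  expect_lt(compute_safety_signal(t4), 0)
  expect_true(compute_ror(t4)$corrected)
  # a = E gives a zero signal
  expect_equal(compute_safety_signal(contingency_table(2, 8, 18, 72)), 0)
})

test_that("metric kernels agree with oracles across random tables", {
  set.seed(99)
  for (i in 1:200) {
    tab <- rand_table()
    with(tab, {
      o <- oracle_ror(a, b, c, d)
      r <- compute_ror(tab)
      expect_equal(r$ror, unname(o["ror"]), tolerance = 1e-9)
      expect_equal(r$ci_low, unname(o["lo"]), tolerance = 1e-9)
      expect_equal(compute_rrr(tab), oracle_rrr(a, b, c, d), tolerance = 1e-9)
      expect_equal(compute_safety_signal(tab), oracle_signal(a, b, c, d),
                   tolerance = 1e-9)
      # Wald log-symmetry: the point estimate is the geometric mean of the CI
      expect_equal(exp((log(r$ci_low) + log(r$ci_high)) / 2), r$ror,
                   tolerance = 1e-9)
      # transposition leaves the ROR unchanged; swapping event columns inverts
      expect_equal(compute_ror(contingency_table(a, c, b, d))$ror, r$ror,
                   tolerance = 1e-9)
      expect_equal(compute_ror(contingency_table(b, a, d, c))$ror, 1 / r$ror,
                   tolerance = 1e-9)
    })
  }
})

test_that("metrics increase strictly in a on sparse-signal tables", {
  # observed/expected ratios are monotone in a whenever a <= min(b, c) (the
  # derivative of log RRR is 1/a + 1/N - 1/(a+b) - 1/(a+c), positive there);
  # the ROR is monotone unconditionally
  set.seed(7)
  for (i in 1:25) {
    tab <- rand_table()
    up <- contingency_table(tab$a + 1, tab$b, tab$c, tab$d)
    expect_gt(compute_ror(up)$ror, compute_ror(tab)$ror)
    a <- min(tab$a, tab$b, tab$c)
    sparse <- contingency_table(a, tab$b, tab$c, tab$d)
    up <- contingency_table(a + 1, sparse$b, sparse$c, sparse$d)
    if (a + 1 <= min(sparse$b, sparse$c)) {
      expect_gt(compute_rrr(up), compute_rrr(sparse))
      expect_gt(compute_safety_signal(up), compute_safety_signal(sparse))
      expect_gt(compute_ic(up)$ic, compute_ic(sparse)$ic)
    }
  }
  # outside that regime the ratio can fall: a saturated margin counterexample
  lo <- contingency_table(300, 2, 2, 300)
  hi <- contingency_table(301, 2, 2, 300)
  expect_lt(compute_rrr(hi), compute_rrr(lo))
})

test_that("information component behaves across methods", {
  # large-N independence: IC within 0.01 of zero
  big <- contingency_table(1000, 1000, 1000, 1000)
  expect_lt(abs(compute_ic(big)$ic), 0.01)
  expect_lt(abs(compute_ic(big, "bate1998")$ic), 0.01)

  # the default IC shares the safety-signal shrinkage kernel exactly
  set.seed(31)
  for (i in 1:20) {
    tab <- rand_table()
    ic <- compute_ic(tab)
    expect_equal(ic$ic, compute_safety_signal(tab), tolerance = 1e-12)
    expect_lte(ic$ci_low, ic$ic)
    expect_gte(ic$ci_high, ic$ic)
    icb <- compute_ic(tab, "bate1998")
    expect_lte(icb$ci_low, icb$ic)
    # the two variants agree on the sign of clear signals
    if (abs(ic$ic) > 0.5) expect_equal(sign(ic$ic), sign(icb$ic))
  }
  expect_error(compute_ic(big, "nonsense"), "gamma-shrinkage.*bate1998")
})

test_that("credible bounds match a Monte-Carlo gamma oracle", {
  # (a = 8, E = 2): margins chosen so (10 * 20) / 100 = 2
  tab <- contingency_table(8, 2, 12, 78)
  expect_equal(tab$expected, 2)
  ic <- compute_ic(tab)
  mc <- oracle_ic_mc(8, 2, 12, 78, ndraw = 2e5, seed = 4)
  expect_lt(abs(ic$ci_low - mc[1]), 0.02)
  expect_lt(abs(ic$ci_high - mc[2]), 0.02)
})

test_that("decision rule sets apply the printed strict inequalities", {
  row <- function(a, signal, rrr, ror_lo, ic_lo) {
    tibble::tibble(a = a, safety_signal = signal, rrr = rrr,
                   ror_ci_low = ror_lo, ic_ci_low = ic_lo)
  }
  # count threshold: a >= 2 for the count/signal/rrr rule
  expect_false(apply_criteria(row(1, 5, 50, 10, 2))$flag_aersmine)
  expect_true(apply_criteria(row(2, 0.1, 2.1, 0.5, -1))$flag_aersmine)
  # boundaries are strict: signal = 0, rrr = 2 fail
  expect_false(apply_criteria(row(5, 0, 10, 0.5, 0))$flag_aersmine)
  expect_false(apply_criteria(row(5, 1, 2, 0.5, 0))$flag_aersmine)
  # ROR rule: lower limit exactly 1 fails
  expect_false(apply_criteria(row(5, 1, 3, 1, 0))$flag_ror)
  expect_true(apply_criteria(row(5, 1, 3, 1.0001, 0))$flag_ror)
  # BCPNN rule: count >= 3 and IC lower limit > 0, as printed for the
  # ketamine-like (0.23) versus hydrocodone-like (-0.10) cases
  expect_true(apply_criteria(row(3, 1, 3, 2, 0.23))$flag_bcpnn)
  expect_false(apply_criteria(row(3, 1, 3, 2, -0.10))$flag_bcpnn)
  expect_false(apply_criteria(row(3, 1, 3, 2, 0))$flag_bcpnn)
  expect_false(apply_criteria(row(2, 1, 3, 2, 0.5))$flag_bcpnn)
})

test_that("contingency construction partitions the background", {
  r <- make_reports(
    drugs = list("X", "X", "Y", "Y"),
    events = list("E", "F", "E", "F")
  )
  tab <- build_contingency(r, "X", "E")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))

  # event present in every report: b = 0 and d = 0
  all_ev <- make_reports(drugs = list("X", "Y"), events = list("E", "E"))
  tab2 <- build_contingency(all_ev, "X", "E")
  expect_equal(c(tab2$b, tab2$d), c(0, 0))

  # role-qualified margin
  roled <- make_reports(
    drugs = list("X", "X"), events = list("E", "E"),
    roles = list("primary_suspect", "concomitant")
  )
  expect_equal(build_contingency(roled, "X", "E", role = "primary_suspect")$a, 1)
  expect_error(build_contingency(roled[0, ], "X", "E"), "empty")
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("screening matches per-table computation and orders by ROR", {
  cfg <- generator_config(n_reports = 3000, seed = 17,
                          planted_signals = list(
                            planted_signal("KETAMINE", "DIZZINESS", 6)))
  r <- generate_reports(cfg)
  scr <- tidy(screen_signals(r, "DIZZINESS"))
  expect_equal(scr$ror, sort(scr$ror, decreasing = TRUE))
  expect_equal(scr$drug[1], "KETAMINE")

  # screen rows agree with the single-pair route
  for (dg in scr$drug[c(1, 5, 10)]) {
    tab <- build_contingency(r, dg, "DIZZINESS")
    row <- scr[scr$drug == dg, ]
    expect_equal(c(row$a, row$b, row$c, row$d),
                 c(tab$a, tab$b, tab$c, tab$d))
    expect_equal(row$ror, compute_ror(tab)$ror, tolerance = 1e-12)
    expect_equal(row$rrr, compute_rrr(tab), tolerance = 1e-12)
    expect_equal(row$ic_ci_low, compute_ic(tab)$ci_low, tolerance = 1e-12)
  }

  one <- tidy(screen_signals(r, "DIZZINESS", drugs = "MORPHINE"))
  expect_equal(nrow(one), 1)

  g <- glance(screen_signals(r, "DIZZINESS"))
  expect_equal(g$n_background, nrow(r))
  expect_true(g$n_flag_ror >= 1)

  # optional BH adjustment is off by default
  expect_false("ror_p_adj" %in% names(scr))
  adj <- tidy(screen_signals(r, "DIZZINESS", adjust = TRUE))
  expect_true(all(adj$ror_p_adj >= adj$ror_p - 1e-12))
})

test_that("an external background changes the table denominator", {
  cohort <- make_reports(drugs = list("X", "X"), events = list("E", "E"))
  extra <- make_reports(drugs = list("Y", "Y", "X"),
                        events = list("F", "F", "F"),
                        case_id = c("B1", "B2", "B3"))
  bg <- dplyr::bind_rows(cohort, extra)
  scr <- tidy(screen_signals(cohort, "E", drugs = "X", background = bg))
  expect_equal(scr$a + scr$b + scr$c + scr$d, nrow(bg))
  expect_equal(scr$a, 2)
  expect_equal(scr$b, 1)
})
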