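write_fixture <- function(dir, quarter = "2015Q1",
                          demo = character(), drug = character(),
                          reac = character(), outc = character()) {
  writeLines(c("primaryid$caseid$caseversion$event_year$age$age_cod$sex$occp_cod",
               demo), file.path(dir, paste0("DEMO", quarter, ".txt")))
  writeLines(c("primaryid$drug_seq$role_cod$drugname$indication", drug),
             file.path(dir, paste0("DRUG", quarter, ".txt")))
  writeLines(c("primaryid$pt", reac), file.path(dir, paste0("REAC", quarter, ".txt")))
  writeLines(c("primaryid$outc_cod", outc), file.path(dir, paste0("OUTC", quarter, ".txt")))
}

test_that("malformed rows go to the reject list, never silently dropped", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    demo = c("11$1$1$2015$40$YR$F$CN", "bad$row$with$wrong$count"),
    drug = "11$1$PS$KETAMINE$",
    reac = "11$DIZZINESS")
  raw <- read_quarterly_files(dir)
  expect_equal(nrow(raw$rejects), 1)
  expect_equal(raw$rejects$reason, "column count")
  expect_equal(nrow(raw$demo), 1)
})

test_that("a missing mandatory table is a hard error", {
  dir <- withr::local_tempdir()
  write_fixture(dir)
  file.remove(file.path(dir, "REAC2015Q1.txt"))
  expect_error(read_quarterly_files(dir), "REAC")
})

test_that("assembly joins complete cases and counts incomplete ones", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    demo = c("11$1$1$2015$40$YR$F$CN",   # complete
             "21$2$1$2016$$$M$MD",       # no reaction rows -> incomplete
             "31$3$1$2017$70$YR$$"),     # no drug rows -> incomplete
    drug = c("11$1$PS$KETAMINE$POSTOPERATIVE ANALGESIA",
             "11$2$C$MORPHINE$",
             "21$1$PS$PROPOFOL$"),
    reac = c("11$DIZZINESS", "11$NAUSEA", "11$DIZZINESS", "31$HEADACHE"),
    outc = "11$HO")
  asm <- assemble_reports(read_quarterly_files(dir))
  expect_equal(nrow(asm), 1)
  expect_equal(attr(asm, "n_incomplete"), 2)
  expect_equal(asm$case_id, "1")
  expect_equal(asm$age, 40)
  expect_equal(asm$age_band, "18-64 Years")
  expect_equal(asm$sex, "female")
  expect_equal(asm$reporter, "consumer")
  expect_equal(asm$outcome, "hospitalization")
  expect_equal(asm$quarter, 1L)
  expect_equal(asm$drug_verbatim[[1]], c("KETAMINE", "MORPHINE"))
  expect_equal(asm$drug_role[[1]], c("primary_suspect", "concomitant"))
  expect_equal(asm$drug_indication[[1]], c("POSTOPERATIVE ANALGESIA", NA))
  # duplicated reaction term collapsed: events carry no duplicates
  expect_equal(asm$events[[1]], c("DIZZINESS", "NAUSEA"))
})

test_that("conflicting demographics for one primaryid are rejected", {
  dir <- withr::local_tempdir()
  write_fixture(dir,
    demo = c("11$1$1$2015$40$YR$F$CN",
             "11$1$1$2015$55$YR$M$CN",   # same primaryid, different person
             "21$2$1$2015$30$YR$F$CN",
             "21$2$1$2015$30$YR$F$CN"),  # bit-identical copy collapses
    drug = c("11$1$PS$KETAMINE$", "21$1$PS$MORPHINE$"),
    reac = c("11$DIZZINESS", "21$NAUSEA"))
  asm <- assemble_reports(read_quarterly_files(dir))
  expect_equal(asm$case_id, "2")
  rej <- attr(asm, "rejects")
  expect_equal(rej$primaryid, "11")
  expect_match(rej$reason, "conflicting")
})

test_that("deduplication keeps the latest version with documented tie-breaks", {
  r <- make_reports(
    drugs = list("A", "A", "A", "B"),
    events = list("E", "E", "E", "E"),
    case_id = c("X", "X", "X", "Y"),
    version = c(1L, 3L, 2L, 1L),
    year = c(2010L, 2011L, 2012L, 2015L)
  )
  out <- deduplicate_reports(r)
  expect_equal(out$case_id, c("X", "Y"))
  expect_equal(out$version[1], 3L)
  expect_equal(attr(out, "n_removed"), 2L)

  # tie on version: latest year wins
  tie <- make_reports(drugs = list("A", "A"), events = list("E", "E"),
                      case_id = c("Z", "Z"), version = 2L,
                      year = c(2010L, 2019L))
  expect_equal(deduplicate_reports(tie)$year, 2019L)
  # tie on version and year: later provenance (row position) wins
  tie2 <- make_reports(drugs = list("A", "B"), events = list("E", "E"),
                       case_id = c("W", "W"), version = 1L, year = 2015L)
  expect_equal(deduplicate_reports(tie2)$drug_generic[[1]], "B")

  # duplicate-free input is unchanged, order included; idempotent
  clean <- make_reports(drugs = list("A", "B", "C"),
                        events = list("E", "E", "E"),
                        case_id = c("N3", "N1", "N2"))
  expect_equal(deduplicate_reports(clean), clean, ignore_attr = TRUE)
  expect_equal(deduplicate_reports(out), out, ignore_attr = TRUE)
})

test_that("drug-name standardization normalizes, maps, and reports coverage", {
  r <- make_reports(
    drugs = list(c("  amitriptyline ", "APAP/HYDROCODONE"), "XYZZY"),
    events = list("E", "E")
  )
  # identity standardization: normalized verbatim becomes the generic
  ident <- standardize_drug_names(r)
  expect_equal(ident$drug_generic[[1]][1], "AMITRIPTYLINE")

  mapping <- tibble::tibble(
    verbatim = c("AMITRIPTYLINE", "APAP/HYDROCODONE"),
    generic = c("AMITRIPTYLINE", "ACETAMINOPHEN\\HYDROCODONE BITARTRATE")
  )
  out <- standardize_drug_names(r, mapping)
  expect_equal(out$drug_generic[[1]],
               c("AMITRIPTYLINE", "ACETAMINOPHEN\\HYDROCODONE BITARTRATE"))
  expect_equal(out$drug_generic[[2]], "UNRESOLVED:XYZZY")
  cov <- attr(out, "coverage")
  expect_equal(sum(cov$verbatim == "XYZZY"), 1)
  expect_equal(cov$n_mentions[cov$verbatim == "XYZZY"], 1)
  expect_false(cov$resolved[cov$verbatim == "XYZZY"])
})

test_that("cohort filtering applies the adult age rule and conserves counts", {
  r <- make_reports(
    drugs = list("A", "A", "A", "A"),
    events = list("DIZZINESS", "DIZZINESS", "HEADACHE", "DIZZINESS"),
    age = c(17, 45, 50, NA)
  )
  out <- apply_cohort_filter(r, cohort_filter(min_age = 18))
  excl <- attr(out, "exclusions")
  expect_equal(nrow(out), 2)  # the 17-year-old and the missing age drop
  expect_equal(excl$n[excl$criterion == "age"], 2L)
  expect_equal(sum(excl$n) + nrow(out), nrow(r))

  # missing age can be kept when requested
  keep <- apply_cohort_filter(r, cohort_filter(min_age = 18,
                                               keep_missing_age = TRUE))
  expect_equal(nrow(keep), 3)

  # an all-unset filter is the identity
  ident <- apply_cohort_filter(r, cohort_filter(min_age = NULL))
  expect_equal(nrow(ident), nrow(r))

  # event + role criteria, with conservation
  f <- cohort_filter(min_age = 18, required_event = "DIZZINESS",
                     required_role = "primary_suspect")
  out2 <- apply_cohort_filter(r, f)
  excl2 <- attr(out2, "exclusions")
  expect_equal(sum(excl2$n) + nrow(out2), nrow(r))
  expect_equal(nrow(out2), 1)
})

test_that("indication-marked cohorts are recovered exactly", {
  cfg <- generator_config(n_reports = 2000, seed = 13,
                          indication_probability = 0.25)
  r <- generate_reports(cfg)
  planted <- sum(vapply(r$drug_indication,
                        function(x) any(!is.na(x)), TRUE))
  out <- apply_cohort_filter(
    r, cohort_filter(min_age = NULL,
                     required_indication = "POSTOPERATIVE ANALGESIA"))
  expect_equal(nrow(out), planted)
  # indication sits on the primary-suspect mention
  both <- apply_cohort_filter(
    r, cohort_filter(min_age = NULL, required_role = "primary_suspect",
                     required_indication = "POSTOPERATIVE ANALGESIA"))
  expect_equal(nrow(both), planted)
})
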