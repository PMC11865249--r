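# Shared synthetic worlds and a small hand-rolled report constructor.

# build a tiny report tibble by hand; list arguments are recycled
make_reports <- function(drugs, events, roles = NULL, sex = "female",
                         age = 40, year = 2015L, quarter = 1L,
                         reporter = "consumer", outcome = "non_serious",
                         case_id = NULL, version = 1L, indication = NULL) {
  n <- max(length(drugs), length(events))
  drugs <- rep(drugs, length.out = n)
  events <- rep(events, length.out = n)
  if (is.null(roles)) {
    roles <- lapply(drugs, function(d) {
      c("primary_suspect", rep("concomitant", max(0, length(d) - 1)))
    })
  } else {
    roles <- rep(roles, length.out = n)
  }
  if (is.null(indication)) {
    indication <- lapply(drugs, function(d) rep(NA_character_, length(d)))
  } else {
    indication <- rep(indication, length.out = n)
  }
  age <- rep(age, length.out = n)
  tibble::tibble(
    case_id = case_id %||% sprintf("C%04d", seq_len(n)),
    version = rep(as.integer(version), length.out = n),
    year = rep(as.integer(year), length.out = n),
    quarter = rep(as.integer(quarter), length.out = n),
    age = age,
    age_band = age_to_band(age),
    sex = rep(sex, length.out = n),
    reporter = rep(reporter, length.out = n),
    outcome = rep(outcome, length.out = n),
    drug_verbatim = drugs,
    drug_generic = drugs,
    drug_role = roles,
    drug_indication = indication,
    events = events
  )
}

`%||%` <- rlang::`%||%`

# the parameter-recovery world: 77-drug formulary, per-term baselines of 1%,
# three planted odds effects on separate event terms
recovery_config <- function(seed, n_reports = 50000) {
  filler <- sprintf("FILLER%02d", 1:74)
  w_res <- (1 - 0.05 - 0.015 - 0.006) / 74
  vocab <- tibble::tibble(
    generic_name = c("KETAMINE", "CLONAZEPAM", "AMITRIPTYLINE", filler),
    marginal_probability = c(0.05, 0.015, 0.006, rep(w_res, 74))
  )
  ev <- tibble::tibble(
    preferred_term = c("DIZZINESS", "NAUSEA", "HEADACHE"),
    baseline_probability = c(0.01, 0.01, 0.01)
  )
  generator_config(
    n_reports = n_reports, drug_vocabulary = vocab, event_vocabulary = ev,
    drugs_per_report = c(1, 3),
    planted_signals = list(
      planted_signal("KETAMINE", "HEADACHE", 2),
      planted_signal("CLONAZEPAM", "NAUSEA", 5),
      planted_signal("AMITRIPTYLINE", "DIZZINESS", 10)
    ),
    seed = seed
  )
}

# null world for calibration: 50 equal-weight drugs x 20 events, no planted
# effects, margins all comfortably above 20 at n = 20,000
null_config <- function(seed, n_reports = 20000) {
  vocab <- tibble::tibble(
    generic_name = sprintf("NULLDRUG%02d", 1:50),
    marginal_probability = rep(1 / 50, 50)
  )
  ev <- tibble::tibble(
    preferred_term = sprintf("EVENT%02d", 1:20),
    baseline_probability = rep(0.02, 20)
  )
  generator_config(n_reports = n_reports, drug_vocabulary = vocab,
                   event_vocabulary = ev, drugs_per_report = c(1, 3),
                   seed = seed)
}
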