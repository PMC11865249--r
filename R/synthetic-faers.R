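#' Describe a planted drug-event association
#'
#' A planted signal multiplies the odds of one event term whenever the named
#' drug is present on a report (and, optionally, only for reports inside one
#' demographic stratum). `effect = 1` plants nothing and is the null.
#'
#' @param drug Generic drug name (must appear in the generator's vocabulary).
#' @param event Preferred term (must appear in the event vocabulary).
#' @param effect Multiplicative odds factor, > 0.
#' @param sex Optional restriction: `"female"` or `"male"`.
#' @param age_min,age_max Optional closed age interval restriction in years.
#' @return A list of class `faers_planted_signal`.
#' @export
#' @examples
#' planted_signal("KETAMINE", "DIZZINESS", effect = 10)
planted_signal <- function(drug, event, effect, sex = NULL,
                           age_min = NULL, age_max = NULL) {
  if (!is.numeric(effect) || length(effect) != 1 || effect <= 0) {
    stopf("`effect` must be a single positive number")
  }
  if (!is.null(sex) && !sex %in% c("female", "male")) {
    stopf("`sex` restriction must be \"female\" or \"male\"")
  }
  structure(
    list(drug = drug, event = event, effect = effect, sex = sex,
         age_min = age_min %||% -Inf, age_max = age_max %||% Inf),
    class = "faers_planted_signal"
  )
}

# Table-derived default marginals: exact published counts over their own
# total (498,876), so each map sums to 1 exactly.
.default_age_counts <- c(
  "0-1 Month" = 98, "2 Months-2 Years" = 279, "3-11 Years" = 2545,
  "12-17 Years" = 6286, "18-64 Years" = 213999, "65-85 Years" = 118117,
  "More than 85 Years" = 10276, "Not Specified" = 147276
)
.default_sex_counts <- c(female = 308892, male = 156002, unspecified = 33982)
.default_reporter_counts <- c(
  healthcare_professional = 177851, consumer = 292090, other = 2,
  unspecified = 28933
)

.default_drug_vocabulary <- function() {
  tibble(
    generic_name = c(
      "BUPIVACAINE", "MORPHINE", "LIDOCAINE",
      "ACETAMINOPHEN\\HYDROCODONE BITARTRATE", "ADALIMUMAB", "KETAMINE",
      "AMITRIPTYLINE", "CLONAZEPAM", "HYDROCODONE", "GABAPENTIN",
      "ROPIVACAINE", "ROCURONIUM BROMIDE", "MIDAZOLAM", "PROPOFOL",
      "REMIFENTANIL", "PARACETAMOL", "TRAMADOL", "ONDANSETRON",
      "PREGABALIN", "FENTANYL"
    ),
    marginal_probability = c(
      0.08, 0.08, 0.07, 0.05, 0.05, 0.05, 0.04, 0.04, 0.04, 0.05,
      0.06, 0.04, 0.05, 0.06, 0.04, 0.05, 0.05, 0.04, 0.04, 0.02
    )
  )
}

.default_event_vocabulary <- function() {
  tibble(
    preferred_term = c(
      "DIZZINESS", "NAUSEA", "HEADACHE", "VOMITING", "PRURITUS",
      "SOMNOLENCE", "FATIGUE", "DRUG INEFFECTIVE"
    ),
    baseline_probability = c(0.05, 0.08, 0.06, 0.05, 0.03, 0.03, 0.04, 0.10)
  )
}

# yearly reporting volume: ramps up from 2004, peaks in 2015, then remains
# at a high (but clearly sub-peak) plateau
.default_year_weights <- function() {
  years <- 2004:2023
  w <- c(seq(1, 10, length.out = 12), rep(7, 8))
  names(w) <- years
  w / sum(w)
}

.default_outcome_proportions <- c(
  death = 0.05, life_threatening = 0.04, hospitalization = 0.18,
  disability = 0.04, other_serious = 0.20, non_serious = 0.42,
  unspecified = 0.07
)

#' Configure the synthetic spontaneous-report generator
#'
#' Defaults encode the published baseline-characteristics marginals of a
#' large dizziness cohort (age-band, sex and reporter-type proportions taken
#' as exact published counts over their own total of 498,876), a yearly
#' reporting volume that rises to a 2015 peak and then plateaus, and a
#' mostly non-serious outcome mix. Drug and event vocabularies default to a
#' small postoperative-analgesia formulary with per-term baseline event
#' probabilities.
#'
#' @param n_reports Number of reports to draw (before duplicate injection).
#' @param drug_vocabulary Tibble with columns `generic_name`,
#'   `marginal_probability` (sampling weights for drug mentions).
#' @param event_vocabulary Tibble with columns `preferred_term`,
#'   `baseline_probability` (independent per-term Bernoulli baselines).
#' @param planted_signals List of [planted_signal()] objects.
#' @param sex_proportions,age_band_proportions,reporter_proportions,outcome_proportions
#'   Named probability vectors over the package's category enumerations;
#'   each must sum to 1 within 1e-9.
#' @param year_range Inclusive integer year interval `c(first, last)`.
#' @param year_weights Named per-year probability vector over `year_range`.
#' @param duplicate_rate Fraction of near-duplicate records injected by
#'   [inject_duplicates()], in `[0, 1]`.
#' @param drugs_per_report Integer interval `c(min, max)` of distinct drugs
#'   per report.
#' @param indication_term Free-text indication marker attached to
#'   primary-suspect mentions (models the postoperative-analgesia context).
#' @param indication_probability Probability that a report's primary-suspect
#'   mention carries `indication_term`.
#' @param seed Integer seed; the whole generator is deterministic given the
#'   configuration and this seed.
#' @return A validated list of class `faers_config`.
#' @export
generator_config <- function(n_reports = 10000,
                             drug_vocabulary = .default_drug_vocabulary(),
                             event_vocabulary = .default_event_vocabulary(),
                             planted_signals = list(),
                             sex_proportions = .default_sex_counts / sum(.default_sex_counts),
                             age_band_proportions = .default_age_counts / sum(.default_age_counts),
                             reporter_proportions = .default_reporter_counts / sum(.default_reporter_counts),
                             year_range = c(2004, 2023),
                             year_weights = .default_year_weights(),
                             outcome_proportions = .default_outcome_proportions,
                             duplicate_rate = 0.05,
                             drugs_per_report = c(1, 3),
                             indication_term = "POSTOPERATIVE ANALGESIA",
                             indication_probability = 0,
                             seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1 ||
      n_reports != round(n_reports)) {
    stopf("`n_reports` must be a single positive integer")
  }
  drug_vocabulary <- as_tibble(drug_vocabulary)
  event_vocabulary <- as_tibble(event_vocabulary)
  if (!all(c("generic_name", "marginal_probability") %in% names(drug_vocabulary)) ||
      nrow(drug_vocabulary) == 0 || any(drug_vocabulary$marginal_probability <= 0) ||
      anyDuplicated(drug_vocabulary$generic_name)) {
    stopf("`drug_vocabulary` needs unique generic_name rows with positive marginal_probability")
  }
  if (!all(c("preferred_term", "baseline_probability") %in% names(event_vocabulary)) ||
      nrow(event_vocabulary) == 0 ||
      any(event_vocabulary$baseline_probability <= 0 |
            event_vocabulary$baseline_probability >= 1) ||
      anyDuplicated(event_vocabulary$preferred_term)) {
    stopf("`event_vocabulary` needs unique preferred_term rows with baseline_probability in (0, 1)")
  }
  for (s in planted_signals) {
    if (!inherits(s, "faers_planted_signal")) {
      stopf("`planted_signals` must be a list of planted_signal() objects")
    }
    if (!s$drug %in% drug_vocabulary$generic_name) {
      stopf("`planted_signals`: drug %s is not in the drug vocabulary", s$drug)
    }
    if (!s$event %in% event_vocabulary$preferred_term) {
      stopf("`planted_signals`: event %s is not in the event vocabulary", s$event)
    }
  }
  sex_proportions <- check_prob_map(sex_proportions, SEX_LEVELS, "sex_proportions")
  age_band_proportions <- check_prob_map(age_band_proportions, AGE_BANDS,
                                         "age_band_proportions")
  reporter_proportions <- check_prob_map(reporter_proportions, REPORTER_LEVELS,
                                         "reporter_proportions")
  outcome_proportions <- check_prob_map(outcome_proportions, OUTCOME_LEVELS,
                                        "outcome_proportions")
  if (length(year_range) != 2 || year_range[1] > year_range[2]) {
    stopf("`year_range` must be an inclusive interval c(first, last)")
  }
  years <- as.character(year_range[1]:year_range[2])
  year_weights <- check_prob_map(year_weights, years, "year_weights")
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate > 1) {
    stopf("`duplicate_rate` must lie in [0, 1]")
  }
  if (length(drugs_per_report) != 2 || drugs_per_report[1] < 1 ||
      drugs_per_report[1] > drugs_per_report[2] ||
      drugs_per_report[2] > nrow(drug_vocabulary)) {
    stopf("`drugs_per_report` must be c(min, max) with 1 <= min <= max <= vocabulary size")
  }
  if (!is.numeric(indication_probability) || indication_probability < 0 ||
      indication_probability > 1) {
    stopf("`indication_probability` must lie in [0, 1]")
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      drug_vocabulary = drug_vocabulary,
      event_vocabulary = event_vocabulary,
      planted_signals = planted_signals,
      sex_proportions = sex_proportions,
      age_band_proportions = age_band_proportions,
      reporter_proportions = reporter_proportions,
      year_range = as.integer(year_range),
      year_weights = year_weights,
      outcome_proportions = outcome_proportions,
      duplicate_rate = duplicate_rate,
      drugs_per_report = as.integer(drugs_per_report),
      indication_term = indication_term,
      indication_probability = indication_probability,
      seed = as.integer(seed)
    ),
    class = "faers_config"
  )
}

# uniform age within a band; "Not Specified" -> NA
.draw_age <- function(band) {
  lo <- c(0, 2 / 12, 3, 12, 18, 65, 86)[match(band, AGE_BANDS[1:7])]
  hi <- c(2 / 12, 3, 12, 18, 65, 86, 100)[match(band, AGE_BANDS[1:7])]
  age <- lo + runif(length(band)) * (hi - lo)
  age[band == "Not Specified"] <- NA_real_
  age
}

# does each report fall inside a planted signal's demographic restriction?
.signal_applies <- function(sig, sex, age) {
  ok <- rep(TRUE, length(sex))
  if (!is.null(sig$sex)) ok <- ok & sex == sig$sex
  if (is.finite(sig$age_min) || is.finite(sig$age_max)) {
    ok <- ok & !is.na(age) & age >= sig$age_min & age <= sig$age_max
  }
  ok
}

#' Generate synthetic FAERS-like case reports
#'
#' Draws `n_reports` reports with independent demographic marginals, 1 to
#' `drugs_per_report[2]` distinct drugs per report (weighted sampling
#' without replacement by an exponential race on the vocabulary weights,
#' one uniformly chosen primary suspect), and per-term independent Bernoulli
#' events whose odds are multiplied by every applicable planted signal.
#' Deterministic given the configuration (which carries the seed).
#'
#' @param config A [generator_config()] object.
#' @return A tibble with one row per report: `case_id`, `version`, `year`,
#'   `quarter`, `age`, `age_band`, `sex`, `reporter`, `outcome`, and
#'   parallel list-columns `drug_verbatim`, `drug_generic`, `drug_role`,
#'   `drug_indication`, `events`.
#' @export
#' @examples
#' cfg <- generator_config(n_reports = 50, seed = 7)
#' generate_reports(cfg)
generate_reports <- function(config) {
  if (!inherits(config, "faers_config")) {
    stopf("`config` must come from generator_config()")
  }
  n <- config$n_reports
  with_seed(config$seed, {
    sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_proportions)
    band <- sample(AGE_BANDS, n, replace = TRUE, prob = config$age_band_proportions)
    age <- .draw_age(band)
    reporter <- sample(REPORTER_LEVELS, n, replace = TRUE,
                       prob = config$reporter_proportions)
    years <- config$year_range[1]:config$year_range[2]
    year <- sample(years, n, replace = TRUE, prob = config$year_weights)
    quarter <- sample(1:4, n, replace = TRUE)
    outcome <- sample(OUTCOME_LEVELS, n, replace = TRUE,
                      prob = config$outcome_proportions)

    # distinct drugs per report: exponential race == successive weighted
    # sampling without replacement
    vocab <- config$drug_vocabulary$generic_name
    w <- config$drug_vocabulary$marginal_probability
    w <- w / sum(w)
    m <- length(vocab)
    kmin <- config$drugs_per_report[1]
    kmax <- config$drugs_per_report[2]
    k <- if (kmin == kmax) rep(kmin, n) else sample(kmin:kmax, n, replace = TRUE)
    keys <- matrix(rexp(n * m), n, m) / matrix(w, n, m, byrow = TRUE)
    picks <- matrix(NA_integer_, n, kmax)
    for (j in seq_len(kmax)) {
      sel <- max.col(-keys, ties.method = "first")
      picks[, j] <- sel
      keys[cbind(seq_len(n), sel)] <- Inf
    }
    present <- matrix(FALSE, n, m)
    for (j in seq_len(kmax)) {
      rows <- which(k >= j)
      present[cbind(rows, picks[rows, j])] <- TRUE
    }

    ps_slot <- 1L + floor(runif(n) * k)
    role_mat <- matrix(
      sample(c("secondary_suspect", "concomitant", "interacting"),
             n * kmax, replace = TRUE, prob = c(0.30, 0.55, 0.15)),
      n, kmax
    )
    role_mat[cbind(seq_len(n), ps_slot)] <- "primary_suspect"
    has_ind <- runif(n) < config$indication_probability
    ind_mat <- matrix(NA_character_, n, kmax)
    ind_mat[cbind(which(has_ind), ps_slot[has_ind])] <- config$indication_term

    # per-term event odds: baseline odds times each applicable planted effect
    ev_terms <- config$event_vocabulary$preferred_term
    ev_p0 <- config$event_vocabulary$baseline_probability
    ev_mat <- matrix(FALSE, n, length(ev_terms))
    for (t in seq_along(ev_terms)) {
      eta <- rep(qlogis(ev_p0[t]), n)
      for (sig in config$planted_signals) {
        if (sig$event != ev_terms[t] || sig$effect == 1) next
        di <- match(sig$drug, vocab)
        hit <- present[, di] & .signal_applies(sig, sex, age)
        eta[hit] <- eta[hit] + log(sig$effect)
      }
      ev_mat[, t] <- runif(n) < plogis(eta)
    }

    # flatten per-report drug slots (pick order) into list-columns
    keep <- t(col(picks) <= matrix(k, n, kmax))
    rep_f <- factor(rep(seq_len(n), times = k), levels = seq_len(n))
    drug_names <- vocab[t(picks)[keep]]
    drugs <- unname(split(drug_names, rep_f))
    roles <- unname(split(t(role_mat)[keep], rep_f))
    inds <- unname(split(t(ind_mat)[keep], rep_f))
    ev_idx <- which(ev_mat, arr.ind = TRUE)
    events <- unname(split(ev_terms[ev_idx[, 2]],
                           factor(ev_idx[, 1], levels = seq_len(n))))

    tibble(
      case_id = as.character(10000000 + seq_len(n)),
      version = 1L,
      year = year,
      quarter = quarter,
      age = age,
      age_band = band,
      sex = sex,
      reporter = reporter,
      outcome = outcome,
      drug_verbatim = drugs,
      drug_generic = drugs,
      drug_role = roles,
      drug_indication = inds,
      events = events
    )
  })
}

#' Inject near-duplicate records
#'
#' Appends `round(duplicate_rate * n)` near-copies of randomly chosen
#' reports, alternating between two flavours seen in spontaneous-report
#' databases: the same case resubmitted with an incremented version, and a
#' bit-identical copy. The original rows keep their order; duplicates are
#' appended.
#'
#' @param reports A report tibble from [generate_reports()].
#' @param duplicate_rate Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The report tibble with duplicates appended.
#' @export
inject_duplicates <- function(reports, duplicate_rate, seed = 1L) {
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate > 1) {
    stopf("`duplicate_rate` must lie in [0, 1]")
  }
  n <- nrow(reports)
  n_dup <- round(duplicate_rate * n)
  if (n_dup == 0) return(reports)
  with_seed(seed, {
    idx <- sample(n, n_dup)
    dup <- reports[idx, ]
    bump <- rep(c(TRUE, FALSE), length.out = n_dup)
    dup$version[bump] <- dup$version[bump] + 1L
    bind_rows(reports, dup)
  })
}

# ---- quarterly-file dialect -------------------------------------------------

.demo_cols <- c("primaryid", "caseid", "caseversion", "event_year", "age",
                "age_cod", "sex", "occp_cod")
.drug_cols <- c("primaryid", "drug_seq", "role_cod", "drugname", "indication")
.reac_cols <- c("primaryid", "pt")
.outc_cols <- c("primaryid", "outc_cod")

.sex_codes <- c(female = "F", male = "M", unspecified = "")
.occp_codes <- c(healthcare_professional = "MD", consumer = "CN", other = "OT",
                 unspecified = "")
.role_codes <- c(primary_suspect = "PS", secondary_suspect = "SS",
                 concomitant = "C", interacting = "I")
.outc_codes <- c(death = "DE", life_threatening = "LT", hospitalization = "HO",
                 disability = "DS", other_serious = "OT", non_serious = "NS")

.decode <- function(x, codes, default) {
  out <- names(codes)[match(x, codes)]
  out[is.na(out) | x == ""] <- default
  out
}

#' Write reports as quarterly delimited files
#'
#' Emits the four-table dollar-delimited dialect (`DEMO<q>.txt`,
#' `DRUG<q>.txt`, `REAC<q>.txt`, `OUTC<q>.txt`, `<q>` like `2015Q1`), one
#' set per year-quarter present in the data. Backslashes in combination
#' drug names are written verbatim. A read-back through
#' [read_quarterly_files()] and [assemble_reports()] reconstructs an equal
#' report set.
#'
#' @param reports Report tibble.
#' @param directory Output directory (created if needed).
#' @param quarters Optional character vector of quarter labels to emit even
#'   when no report falls in them (header-only files).
#' @return A tibble manifest: `file`, `table`, `quarter`, `n_rows`.
#' @export
write_quarterly_files <- function(reports, directory, quarters = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ql <- if (nrow(reports)) sprintf("%dQ%d", reports$year, reports$quarter) else character()
  all_q <- sort(unique(c(ql, quarters)))
  manifest <- list()
  for (q in all_q) {
    sel <- which(ql == q)
    r <- reports[sel, ]
    primaryid <- paste0(r$case_id, r$version)
    demo <- tibble(
      primaryid = primaryid, caseid = r$case_id, caseversion = r$version,
      event_year = r$year,
      age = ifelse(is.na(r$age), "", sprintf("%.10g", r$age)),
      age_cod = ifelse(is.na(r$age), "", "YR"),
      sex = .sex_codes[r$sex], occp_cod = .occp_codes[r$reporter]
    )
    nd <- lengths(r$drug_verbatim)
    drug <- tibble(
      primaryid = rep(primaryid, nd),
      drug_seq = as.integer(unlist(lapply(nd, seq_len), use.names = FALSE)),
      role_cod = as.character(.role_codes[as.character(unlist(r$drug_role, use.names = FALSE))]),
      drugname = as.character(unlist(r$drug_verbatim, use.names = FALSE)),
      indication = dplyr::coalesce(as.character(unlist(r$drug_indication, use.names = FALSE)), "")
    )
    ne <- lengths(r$events)
    reac <- tibble(primaryid = rep(primaryid, ne),
                   pt = as.character(unlist(r$events, use.names = FALSE)))
    has_out <- r$outcome != "unspecified"
    outc <- tibble(primaryid = primaryid[has_out],
                   outc_cod = .outc_codes[r$outcome[has_out]])
    tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc)
    for (tn in names(tabs)) {
      path <- file.path(directory, paste0(tn, q, ".txt"))
      df <- tabs[[tn]]
      lines <- c(paste(names(df), collapse = "$"),
                 if (nrow(df)) do.call(paste, c(df, sep = "$")))
      tryCatch(
        readr::write_lines(lines, path),
        error = function(e) stopf("failed writing %s: %s", path, conditionMessage(e))
      )
      manifest[[paste0(tn, q)]] <- tibble(
        file = path, table = tn, quarter = q, n_rows = nrow(df)
      )
    }
  }
  bind_rows(manifest)
}
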