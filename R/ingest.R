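# split a dollar-delimited line without losing trailing empty fields
split_dollar <- function(x) {
  out <- strsplit(paste0(x, "\x01"), "$", fixed = TRUE)
  lapply(out, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
}

.read_table_files <- function(files, cols, quarters) {
  rows <- list()
  rejects <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    lines <- readr::read_lines(f)
    if (length(lines) == 0 || !identical(split_dollar(lines[1])[[1]], cols)) {
      stopf("%s: header does not match expected columns (%s)", f,
            paste(cols, collapse = ", "))
    }
    body <- lines[-1]
    if (!length(body)) next
    fields <- split_dollar(body)
    nf <- lengths(fields)
    bad <- nf != length(cols)
    if (any(bad)) {
      rejects[[f]] <- tibble(
        source_file = basename(f), line = which(bad) + 1L,
        reason = "column count", content = body[bad]
      )
    }
    good <- fields[!bad]
    if (length(good)) {
      mat <- matrix(unlist(good, use.names = FALSE), ncol = length(cols),
                    byrow = TRUE)
      df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                      .name_repair = "minimal")
      names(df) <- cols
      df$source_file <- basename(f)
      df$quarter_label <- quarters[i]
      df$source_line <- which(!bad) + 1L
      rows[[f]] <- df
    }
  }
  list(table = bind_rows(rows), rejects = bind_rows(rejects))
}

#' Read a directory of quarterly report files
#'
#' Expects the four-table dollar-delimited dialect written by
#' [write_quarterly_files()]: `DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt`,
#' `OUTC<q>.txt`. Rows with the wrong number of columns are never silently
#' dropped: they are collected into a reject table with the file, line and
#' reason.
#'
#' @param directory Directory containing at least one quarter of all four
#'   tables.
#' @return A list with tibbles `demo`, `drug`, `reac`, `outc` (each with
#'   `source_file`, `quarter_label`, `source_line` provenance columns) and
#'   `rejects`.
#' @export
read_quarterly_files <- function(directory) {
  if (!dir.exists(directory)) stopf("directory %s does not exist", directory)
  specs <- list(DEMO = .demo_cols, DRUG = .drug_cols, REAC = .reac_cols,
                OUTC = .outc_cols)
  out <- list()
  rejects <- list()
  for (tn in names(specs)) {
    files <- sort(list.files(directory, pattern = paste0("^", tn, ".+\\.txt$"),
                             full.names = TRUE))
    if (!length(files)) stopf("mandatory table %s has no files in %s", tn, directory)
    quarters <- sub(paste0("^", tn, "(.+)\\.txt$"), "\\1", basename(files))
    got <- .read_table_files(files, specs[[tn]], quarters)
    out[[tolower(tn)]] <- got$table
    rejects[[tn]] <- got$rejects
  }
  out$rejects <- bind_rows(rejects)
  out
}

#' Assemble case reports from the four raw tables
#'
#' Joins demographics, drugs, reactions and outcomes by `primaryid` into one
#' report per row. Reports lacking any drug mention or any reaction term are
#' excluded as incomplete and counted. Identical repeated demographic rows
#' (bit-identical duplicates) collapse to one; repeated `primaryid`s with
#' conflicting demographics are rejected with a reason.
#'
#' @param raw List from [read_quarterly_files()].
#' @return A report tibble (same schema as [generate_reports()]) with
#'   attributes `n_incomplete` (count of reports dropped for missing drugs
#'   or events) and `rejects` (conflicting-demographics reject tibble).
#' @export
assemble_reports <- function(raw) {
  demo <- raw$demo
  if (is.null(demo) || nrow(demo) == 0) {
    out <- empty_reports()
    attr(out, "n_incomplete") <- 0L
    attr(out, "rejects") <- tibble(primaryid = character(), reason = character())
    return(out)
  }
  demo <- demo |> arrange(.data$quarter_label, .data$source_file, .data$source_line)

  key_cols <- setdiff(names(demo), c("source_file", "quarter_label", "source_line"))
  dup <- duplicated(demo$primaryid)
  rejects <- tibble(primaryid = character(), reason = character())
  if (any(dup)) {
    first <- demo[match(unique(demo$primaryid), demo$primaryid), ]
    conflicting <- character()
    for (pid in unique(demo$primaryid[dup])) {
      rows <- demo[demo$primaryid == pid, key_cols]
      if (nrow(distinct(rows)) > 1) conflicting <- c(conflicting, pid)
    }
    if (length(conflicting)) {
      rejects <- tibble(primaryid = conflicting,
                        reason = "conflicting demographics")
      first <- first[!first$primaryid %in% conflicting, ]
    }
    demo <- first
  }

  group_list <- function(df, value_col) {
    if (is.null(df) || nrow(df) == 0) {
      return(list(keys = character(), values = list()))
    }
    df <- df |> arrange(.data$quarter_label, .data$source_file, .data$source_line)
    sp <- split(df[[value_col]], factor(df$primaryid, levels = unique(df$primaryid)))
    list(keys = names(sp), values = unname(sp))
  }

  drug <- raw$drug
  if (!is.null(drug) && nrow(drug)) {
    drug <- drug |>
      arrange(.data$quarter_label, .data$source_file, .data$source_line) |>
      distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)
    dsp <- split(seq_len(nrow(drug)),
                 factor(drug$primaryid, levels = unique(drug$primaryid)))
    drug_keys <- names(dsp)
    drug_rows <- unname(dsp)
  } else {
    drug_keys <- character(); drug_rows <- list()
  }
  reac <- raw$reac
  if (!is.null(reac) && nrow(reac)) {
    reac <- reac |>
      arrange(.data$quarter_label, .data$source_file, .data$source_line) |>
      distinct(.data$primaryid, .data$pt)
  }
  rl <- if (!is.null(reac) && nrow(reac)) {
    sp <- split(reac$pt, factor(reac$primaryid, levels = unique(reac$primaryid)))
    sp
  } else list()
  outc <- raw$outc
  outcome_map <- if (!is.null(outc) && nrow(outc)) {
    o <- outc[!duplicated(outc$primaryid), ]
    stats::setNames(.decode(o$outc_cod, .outc_codes, "unspecified"), o$primaryid)
  } else character()

  pid <- demo$primaryid
  di <- match(pid, drug_keys)
  ei <- match(pid, names(rl))
  has_drug <- !is.na(di)
  has_event <- !is.na(ei)
  keep <- has_drug & has_event
  n_incomplete <- sum(!keep)
  demo_k <- demo[keep, ]
  di <- di[keep]; ei <- ei[keep]

  age <- suppressWarnings(as.numeric(demo_k$age))
  age[demo_k$age == ""] <- NA_real_
  qlab <- demo_k$quarter_label
  quarter <- suppressWarnings(as.integer(sub("^\\d{4}Q", "", qlab)))

  drugs_of <- lapply(di, function(i) drug[drug_rows[[i]], ])
  out <- tibble(
    case_id = demo_k$caseid,
    version = as.integer(demo_k$caseversion),
    year = as.integer(demo_k$event_year),
    quarter = quarter,
    age = age,
    age_band = age_to_band(age),
    sex = .decode(demo_k$sex, .sex_codes, "unspecified"),
    reporter = .decode(demo_k$occp_cod, .occp_codes, "unspecified"),
    outcome = unname(
      ifelse(demo_k$primaryid %in% names(outcome_map),
             outcome_map[demo_k$primaryid], "unspecified")
    ),
    drug_verbatim = lapply(drugs_of, function(d) d$drugname),
    drug_generic = lapply(drugs_of, function(d) rep(NA_character_, nrow(d))),
    drug_role = lapply(drugs_of, function(d) .decode(d$role_cod, .role_codes, "concomitant")),
    drug_indication = lapply(drugs_of, function(d) {
      ind <- d$indication; ind[ind == ""] <- NA_character_; ind
    }),
    events = unname(rl[ei])
  )
  attr(out, "n_incomplete") <- n_incomplete
  attr(out, "rejects") <- rejects
  out
}

# an empty report tibble with the full schema
empty_reports <- function() {
  tibble(
    case_id = character(), version = integer(), year = integer(),
    quarter = integer(), age = double(), age_band = character(),
    sex = character(), reporter = character(), outcome = character(),
    drug_verbatim = list(), drug_generic = list(), drug_role = list(),
    drug_indication = list(), events = list()
  )
}

#' Collapse duplicate case reports to their latest version
#'
#' Keeps exactly one report per `case_id`: the highest `version`, ties broken
#' by the latest `year`, then by the latest position in the input (row
#' provenance). The result preserves the input order of first appearance of
#' each case, so duplicate-free input passes through unchanged, and the
#' operation is idempotent.
#'
#' @param reports Report tibble.
#' @return Deduplicated report tibble with attribute `n_removed`.
#' @export
deduplicate_reports <- function(reports) {
  if (nrow(reports) == 0) {
    attr(reports, "n_removed") <- 0L
    return(reports)
  }
  o <- order(match(reports$case_id, unique(reports$case_id)),
             -reports$version, -reports$year, -seq_len(nrow(reports)))
  first <- !duplicated(reports$case_id[o])
  out <- reports[o[first], ]
  attr(out, "n_removed") <- nrow(reports) - nrow(out)
  out
}

# uppercase, collapse internal whitespace, trim
normalize_drug_name <- function(x) {
  stringr::str_squish(toupper(x))
}

#' Standardize verbatim drug names to generic names
#'
#' Normalizes each verbatim name (uppercase, whitespace collapsed) and looks
#' it up in an exact mapping table. Unmapped verbatims keep their normalized
#' form prefixed with `"UNRESOLVED:"` so they remain identifiable; nothing
#' is dropped. With `mapping = NULL` the normalized verbatim itself is the
#' generic (identity standardization, appropriate for synthetic data whose
#' verbatims are already generic names). Combination products use the
#' backslash-joined convention (e.g. `"ACETAMINOPHEN\\HYDROCODONE
#' BITARTRATE"`).
#'
#' @param reports Report tibble.
#' @param mapping Optional tibble with columns `verbatim`, `generic`.
#' @return The report tibble with `drug_generic` filled, plus attribute
#'   `coverage`: a tibble (`verbatim`, `n_mentions`, `resolved`).
#' @export
standardize_drug_names <- function(reports, mapping = NULL) {
  if (!is.null(mapping)) {
    mapping <- as_tibble(mapping)
    if (!all(c("verbatim", "generic") %in% names(mapping))) {
      stopf("`mapping` must have columns verbatim, generic")
    }
    key <- normalize_drug_name(mapping$verbatim)
    val <- mapping$generic
  }
  verb <- unlist(reports$drug_verbatim, use.names = FALSE)
  norm <- normalize_drug_name(verb)
  if (is.null(mapping)) {
    generic <- norm
    resolved <- rep(TRUE, length(norm))
  } else {
    hit <- match(norm, key)
    resolved <- !is.na(hit)
    generic <- ifelse(resolved, val[hit], paste0("UNRESOLVED:", norm))
  }
  nd <- lengths(reports$drug_verbatim)
  rep_f <- factor(rep(seq_len(nrow(reports)), times = nd),
                  levels = seq_len(nrow(reports)))
  reports$drug_generic <- unname(split(generic, rep_f))
  cov <- tibble(verbatim = verb, resolved = resolved) |>
    count(.data$verbatim, .data$resolved, name = "n_mentions") |>
    select("verbatim", "n_mentions", "resolved") |>
    arrange(dplyr::desc(.data$n_mentions), .data$verbatim)
  attr(reports, "coverage") <- cov
  reports
}

#' Define a cohort filter
#'
#' @param min_age Minimum age in years (default 18, the adult cohort);
#'   `NULL` disables the age criterion.
#' @param required_role Drug role at least one mention must carry (e.g.
#'   `"primary_suspect"`); `NULL` disables.
#' @param required_event Preferred term the report must contain; `NULL`
#'   disables.
#' @param required_indication Indication marker at least one mention (of the
#'   required role, when both are set) must carry; `NULL` disables.
#' @param keep_missing_age Keep reports with missing age even when `min_age`
#'   is set (default `FALSE`: an unverifiable age fails an age criterion).
#' @return A list of class `faers_cohort_filter`.
#' @export
cohort_filter <- function(min_age = 18, required_role = NULL,
                          required_event = NULL, required_indication = NULL,
                          keep_missing_age = FALSE) {
  if (!is.null(min_age) && (!is.numeric(min_age) || min_age < 0)) {
    stopf("`min_age` must be a non-negative number or NULL")
  }
  if (!is.null(required_role) && !required_role %in% DRUG_ROLES) {
    stopf("`required_role` must be one of: %s", paste(DRUG_ROLES, collapse = ", "))
  }
  structure(
    list(min_age = min_age, required_role = required_role,
         required_event = required_event,
         required_indication = required_indication,
         keep_missing_age = keep_missing_age),
    class = "faers_cohort_filter"
  )
}

#' Apply a cohort filter to case reports
#'
#' Criteria are applied in a fixed order (age, then event, then drug
#' role/indication) and each exclusion is attributed to the first criterion
#' that fails, so the exclusion tally plus the kept count always equals the
#' input count.
#'
#' @param reports Report tibble.
#' @param filter A [cohort_filter()].
#' @return Kept report tibble with attribute `exclusions`: a tibble
#'   (`criterion`, `n`).
#' @export
apply_cohort_filter <- function(reports, filter = cohort_filter()) {
  if (!inherits(filter, "faers_cohort_filter")) {
    stopf("`filter` must come from cohort_filter()")
  }
  n <- nrow(reports)
  alive <- rep(TRUE, n)
  tally <- c(age = 0L, event = 0L, drug = 0L)
  if (!is.null(filter$min_age)) {
    ok <- !is.na(reports$age) & reports$age >= filter$min_age
    if (filter$keep_missing_age) ok <- ok | is.na(reports$age)
    tally["age"] <- sum(alive & !ok)
    alive <- alive & ok
  }
  if (!is.null(filter$required_event)) {
    ok <- purrr::map_lgl(reports$events, ~ filter$required_event %in% .x)
    tally["event"] <- sum(alive & !ok)
    alive <- alive & ok
  }
  if (!is.null(filter$required_role) || !is.null(filter$required_indication)) {
    ok <- purrr::map2_lgl(reports$drug_role, reports$drug_indication, function(role, ind) {
      sel <- rep(TRUE, length(role))
      if (!is.null(filter$required_role)) sel <- sel & role == filter$required_role
      if (!is.null(filter$required_indication)) {
        sel <- sel & !is.na(ind) & ind == filter$required_indication
      }
      any(sel)
    })
    tally["drug"] <- sum(alive & !ok)
    alive <- alive & ok
  }
  out <- reports[alive, ]
  attr(out, "exclusions") <- tibble(criterion = names(tally), n = unname(tally))
  out
}
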