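# count/percentage table over a fixed category enumeration, zero-filled
.cat_table <- function(x, levels, total) {
  n <- as.integer(table(factor(x, levels = levels)))
  tibble(
    category = levels,
    count = n,
    percentage = if (total > 0) round_half_up(100 * n / total, 2) else rep(0, length(n))
  )
}

#' Summarize baseline characteristics of a report cohort
#'
#' Produces the classic baseline table: counts and percentages by age band,
#' sex, reporter type and outcome (each map covers every category including
#' the unspecified one, so counts sum to the total), yearly report counts,
#' and a top-N drug ranking. Percentages are `100 * count / total` rounded
#' half-up to two decimals.
#'
#' @param reports Report tibble. The drug ranking is skipped when the drug
#'   list-columns are absent.
#' @param top_n Number of drugs to rank (default 5).
#' @param drug_denominator Denominator mode passed to [top_drugs()].
#' @return An object of class `cohort_summary`: a list with `total_reports`
#'   and tibbles `by_age_band`, `by_sex`, `by_reporter`, `by_outcome`,
#'   `by_year`, `top_drugs`.
#' @export
summarize_demographics <- function(reports, top_n = 5,
                                   drug_denominator = c("reports", "mentions")) {
  total <- nrow(reports)
  out <- list(
    total_reports = total,
    by_age_band = .cat_table(reports$age_band, AGE_BANDS, total),
    by_sex = .cat_table(reports$sex, SEX_LEVELS, total),
    by_reporter = .cat_table(reports$reporter, REPORTER_LEVELS, total),
    by_outcome = .cat_table(reports$outcome, OUTCOME_LEVELS, total),
    by_year = if (total > 0) {
      yearly_counts(reports)
    } else {
      tibble(year = integer(), count = integer())
    },
    top_drugs = if ("drug_generic" %in% names(reports) && total > 0) {
      top_drugs(reports, n = top_n, denominator = drug_denominator)
    } else {
      NULL
    }
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d reports\n", x$total_reports))
  for (nm in c("by_sex", "by_age_band", "by_reporter", "by_outcome")) {
    cat("\n", sub("^by_", "", nm), ":\n", sep = "")
    print(as.data.frame(x[[nm]]), row.names = FALSE)
  }
  if (!is.null(x$top_drugs)) {
    cat("\ntop drugs:\n")
    print(as.data.frame(x$top_drugs), row.names = FALSE)
  }
  invisible(x)
}

#' Yearly report counts, optionally restricted to one event term
#'
#' @param reports Report tibble.
#' @param event Optional preferred term; when given, only reports whose
#'   event set contains it are counted.
#' @param year_range Optional inclusive interval `c(first, last)`; defaults
#'   to the observed range. Every year in the range appears, zero-filled.
#' @return A tibble (`year`, `count`).
#' @export
yearly_counts <- function(reports, event = NULL, year_range = NULL) {
  if (!is.null(event)) {
    reports <- reports[purrr::map_lgl(reports$events, ~ event %in% .x), ]
  }
  if (is.null(year_range)) {
    if (nrow(reports) == 0) return(tibble(year = integer(), count = integer()))
    year_range <- range(reports$year)
  }
  years <- year_range[1]:year_range[2]
  tibble(
    year = years,
    count = as.integer(table(factor(reports$year, levels = years)))
  )
}

#' Outcome distribution, overall or by year
#'
#' Absolute counts and percentages share the same count basis; with
#' `by_year = TRUE` percentages are within-year (each year sums to 100
#' within rounding).
#'
#' @param reports Report tibble.
#' @param by_year Split by receipt year?
#' @return A tibble (`[year,] outcome, count, percentage`).
#' @export
outcome_distribution <- function(reports, by_year = FALSE) {
  if (!by_year) {
    out <- .cat_table(reports$outcome, OUTCOME_LEVELS, nrow(reports))
    return(rename(out, outcome = "category"))
  }
  years <- sort(unique(reports$year))
  purrr::map_dfr(years, function(y) {
    sel <- reports[reports$year == y, ]
    .cat_table(sel$outcome, OUTCOME_LEVELS, nrow(sel)) |>
      rename(outcome = "category") |>
      mutate(year = y, .before = 1)
  })
}

#' Rank the most commonly reported drugs
#'
#' A drug counts once per report (a report naming the same generic twice is
#' one occurrence). Ranks by report count descending, ties broken
#' alphabetically. The percentage denominator is either the number of
#' reports or the number of (distinct-per-report) drug mentions; the mode
#' used is recorded in the output.
#'
#' @param reports Report tibble with `drug_generic` filled.
#' @param n Number of drugs to return.
#' @param denominator `"reports"` or `"mentions"`.
#' @return A tibble (`rank`, `generic_name`, `count`, `percentage`,
#'   `denominator`, `denominator_n`).
#' @export
top_drugs <- function(reports, n = 5, denominator = c("reports", "mentions")) {
  denominator <- match.arg(denominator)
  if (n < 1) stopf("`n` must be >= 1")
  nd <- lengths(reports$drug_generic)
  long <- tibble(
    report = rep(seq_len(nrow(reports)), times = nd),
    generic_name = unlist(reports$drug_generic, use.names = FALSE)
  ) |> distinct()
  denom <- if (denominator == "reports") nrow(reports) else nrow(long)
  long |>
    count(.data$generic_name, name = "count") |>
    arrange(dplyr::desc(.data$count), .data$generic_name) |>
    head(n) |>
    mutate(
      rank = row_number(),
      percentage = round_half_up(100 * .data$count / denom, 2),
      denominator = denominator,
      denominator_n = denom
    ) |>
    select("rank", "generic_name", "count", "percentage", "denominator",
           "denominator_n")
}

#' Tidy a cohort summary into one long table
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A tibble (`variable`, `category`, `count`, `percentage`).
#' @export
tidy.cohort_summary <- function(x, ...) {
  purrr::map_dfr(
    c("by_age_band", "by_sex", "by_reporter", "by_outcome"),
    function(nm) mutate(x[[nm]], variable = sub("^by_", "", nm), .before = 1)
  )
}

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    total_reports = x$total_reports,
    n_years = nrow(x$by_year),
    peak_year = if (nrow(x$by_year)) x$by_year$year[which.max(x$by_year$count)] else NA_integer_
  )
}
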