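#' The four default sex-by-age strata
#'
#' Adults are cases aged 25 to 65 inclusive; elderly are cases aged above
#' 65. Ages 18-24 deliberately fall in no stratum (the published subgroup
#' definition starts at 25), and reports with unspecified age belong to no
#' stratum.
#'
#' @return A tibble (`label`, `sex`, `age_min`, `age_max`, `min_inclusive`,
#'   `max_inclusive`).
#' @export
default_strata <- function() {
  tibble(
    label = c("adult_male", "elderly_male", "adult_female", "elderly_female"),
    sex = c("male", "male", "female", "female"),
    age_min = c(25, 65, 25, 65),
    age_max = c(65, Inf, 65, Inf),
    min_inclusive = c(TRUE, FALSE, TRUE, FALSE),
    max_inclusive = c(TRUE, TRUE, TRUE, TRUE)
  )
}

# logical membership of each report in one stratum row
in_stratum <- function(reports, stratum) {
  ok <- reports$sex == stratum$sex & !is.na(reports$age)
  lo <- if (stratum$min_inclusive) reports$age >= stratum$age_min
        else reports$age > stratum$age_min
  hi <- if (stratum$max_inclusive) reports$age <= stratum$age_max
        else reports$age < stratum$age_max
  ok & lo & hi
}

#' Assign each report to a stratum
#'
#' @param reports Report tibble.
#' @param strata Stratum tibble as from [default_strata()]; rows must be
#'   pairwise disjoint.
#' @return Character vector of stratum labels (NA for reports in no
#'   stratum).
#' @export
assign_strata <- function(reports, strata = default_strata()) {
  out <- rep(NA_character_, nrow(reports))
  for (i in seq_len(nrow(strata))) {
    hit <- in_stratum(reports, strata[i, ])
    clash <- hit & !is.na(out)
    if (any(clash)) stopf("strata are not pairwise disjoint")
    out[hit] <- strata$label[i]
  }
  out
}

#' Per-stratum disproportionality metrics for a drug list
#'
#' For each stratum, rebuilds every drug-event 2x2 table within that
#' stratum's own background (the stratum's reports) and computes the
#' absolute count, the safety signal and the relative reporting ratio. A
#' stratum with no reports yields missing values, not zeros, and a warning.
#'
#' @param reports Deduplicated report tibble.
#' @param event Preferred term.
#' @param drugs Character vector of generic names; default all observed.
#' @param strata Stratum tibble ([default_strata()]).
#' @param role Optional qualifying drug role.
#' @return A long tibble (`drug`, `stratum`, `n_stratum`, `count`,
#'   `safety_signal`, `rrr`) — heatmap-ready.
#' @export
stratified_metrics <- function(reports, event, drugs = NULL,
                               strata = default_strata(), role = NULL) {
  member <- assign_strata(reports, strata)
  if (is.null(drugs)) {
    drugs <- sort(unique(unlist(reports$drug_generic, use.names = FALSE)))
  }
  purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    lab <- strata$label[i]
    sub <- reports[!is.na(member) & member == lab, ]
    if (nrow(sub) == 0) {
      warn(sprintf("stratum %s has no reports; metrics are missing", lab))
      return(tibble(drug = drugs, stratum = lab, n_stratum = 0L,
                    count = NA_integer_, safety_signal = NA_real_,
                    rrr = NA_real_))
    }
    scr <- tidy(screen_signals(sub, event, drugs = drugs, role = role,
                               stratum = lab))
    scr <- scr[match(drugs, scr$drug), ]
    tibble(drug = drugs, stratum = lab, n_stratum = nrow(sub),
           count = as.integer(scr$a), safety_signal = scr$safety_signal,
           rrr = scr$rrr)
  })
}

#' Pivot stratified metrics to a drugs-by-strata matrix
#'
#' @param metrics Long tibble from [stratified_metrics()].
#' @param metric One of `"count"`, `"safety_signal"`, `"rrr"`.
#' @return A wide tibble, one row per drug, one column per stratum.
#' @export
stratified_matrix <- function(metrics, metric = c("count", "safety_signal", "rrr")) {
  metric <- match.arg(metric)
  metrics |>
    select("drug", "stratum", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "stratum", values_from = dplyr::all_of(metric))
}

#' Top-k drugs per stratum by one metric
#'
#' Ranks descending; ties broken alphabetically by drug name; missing cells
#' never rank. The ranking is a total order, so it is invariant to the
#' input row order.
#'
#' @param metrics Long tibble from [stratified_metrics()].
#' @param metric Metric column to rank on.
#' @param k Number of drugs per stratum.
#' @return A tibble (`stratum`, `rank`, `drug`, `value`).
#' @export
top_k_per_stratum <- function(metrics, metric = "rrr", k = 5) {
  if (k < 1) stopf("`k` must be >= 1")
  if (!metric %in% names(metrics)) stopf("metric column %s not found", metric)
  metrics |>
    rename(value = dplyr::all_of(metric)) |>
    filter(!is.na(.data$value)) |>
    arrange(.data$stratum, dplyr::desc(.data$value), .data$drug) |>
    group_by(.data$stratum) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= k) |>
    ungroup() |>
    select("stratum", "rank", "drug", "value")
}

#' Pairwise Pearson correlation of drug metric profiles
#'
#' Correlates every unordered pair of drugs over the cell axis (by default
#' the strata), using only cells non-missing in both profiles. Pairs with
#' fewer than `min_cells` shared cells or zero variance in either profile
#' are excluded with a reason, never silently. With the default four-strata
#' axis the profiles have at most 4 points, so |r| is noisy; a warning says
#' so. To correlate over years instead, pass a long table of per-year
#' values with `cell_col = "year"`.
#'
#' @param metrics Long tibble with one value per drug and cell.
#' @param metric Value column to correlate.
#' @param cell_col Column defining the profile axis (default `"stratum"`).
#' @param min_cells Minimum shared non-missing cells (default 3).
#' @return A tibble (`drug_i`, `drug_j`, `n_cells`, `r`) with `drug_i <
#'   drug_j`; attribute `excluded` lists skipped pairs with reasons.
#' @export
pairwise_drug_correlation <- function(metrics, metric = "count",
                                      cell_col = "stratum", min_cells = 3) {
  if (!metric %in% names(metrics)) stopf("metric column %s not found", metric)
  wide <- metrics |>
    select("drug", dplyr::all_of(c(cell_col, metric))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(cell_col),
                       values_from = dplyr::all_of(metric))
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$drug
  drugs <- sort(wide$drug)
  if (length(drugs) < 2) stopf("need at least two drugs to correlate")
  if (ncol(mat) < 5) {
    warn(sprintf(
      "correlation profiles have only %d cells; correlations are noisy",
      ncol(mat)
    ))
  }
  pairs <- utils::combn(drugs, 2)
  res <- list(); excl <- list()
  for (p in seq_len(ncol(pairs))) {
    di <- pairs[1, p]; dj <- pairs[2, p]
    xi <- mat[di, ]; xj <- mat[dj, ]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < min_cells) {
      excl[[p]] <- tibble(drug_i = di, drug_j = dj,
                          reason = sprintf("only %d shared cells", sum(ok)))
      next
    }
    if (sd(xi[ok]) == 0 || sd(xj[ok]) == 0) {
      excl[[p]] <- tibble(drug_i = di, drug_j = dj, reason = "zero variance")
      next
    }
    res[[p]] <- tibble(drug_i = di, drug_j = dj, n_cells = sum(ok),
                       r = cor(xi[ok], xj[ok]))
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(drug_i = character(), drug_j = character(),
                  n_cells = integer(), r = double())
  }
  attr(out, "excluded") <- bind_rows(excl)
  out
}

#' Rank the most negatively correlated drug pairs
#'
#' @param correlations Tibble from [pairwise_drug_correlation()].
#' @param n Number of pairs.
#' @return The `n` most negative pairs, ascending by `r`; ties broken by
#'   the (drug_i, drug_j) name pair.
#' @export
rank_negative_pairs <- function(correlations, n = 10) {
  if (n < 1) stopf("`n` must be >= 1")
  correlations |>
    arrange(.data$r, .data$drug_i, .data$drug_j) |>
    head(n)
}
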