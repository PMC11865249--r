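#' Build a 2x2 drug-event contingency table object
#'
#' Cells follow the standard disproportionality layout: `a` reports with
#' both drug and event, `b` drug without event, `c` event without drug, `d`
#' neither. Derived quantities are the table total `N`, the drug margin
#' `a + b`, the event margin `a + c`, and the expected co-reporting count
#' under independence `E = (a + b)(a + c) / N`.
#'
#' @param a,b,c,d Non-negative integer cell counts; `N` must be >= 1.
#' @return An object of class `faers_contingency`.
#' @export
#' @examples
#' contingency_table(2, 5, 10, 500)
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stopf("all cells must be non-negative")
  }
  n <- a + b + c + d
  if (n < 1) stopf("table total N must be >= 1")
  structure(
    list(a = a, b = b, c = c, d = d, n = n,
         n_drug = a + b, n_event = a + c,
         expected = (a + b) * (a + c) / n),
    class = "faers_contingency"
  )
}

#' @export
print.faers_contingency <- function(x, ...) {
  cat(sprintf("2x2 table: a=%g b=%g c=%g d=%g (N=%g, E=%.4g)\n",
              x$a, x$b, x$c, x$d, x$n, x$expected))
  invisible(x)
}

# logical helpers over the report tibble
has_event_vec <- function(reports, event) {
  purrr::map_lgl(reports$events, ~ event %in% .x)
}

has_drug_vec <- function(reports, drug, role = NULL) {
  if (is.null(role)) {
    purrr::map_lgl(reports$drug_generic, ~ drug %in% .x)
  } else {
    purrr::map2_lgl(reports$drug_generic, reports$drug_role,
                    ~ any(.x == drug & .y == role))
  }
}

#' Build the 2x2 table for one drug-event pair
#'
#' The table is computed within the report set passed in, which acts as the
#' background population: pass the full deduplicated dataset for an
#' all-reports background or a filtered cohort for a cohort-only background.
#'
#' @param reports Deduplicated report tibble (the background).
#' @param drug Generic drug name.
#' @param event Preferred term.
#' @param role Optional qualifying drug role (e.g. `"primary_suspect"`);
#'   `NULL` counts any mention.
#' @return A [contingency_table()] object.
#' @export
build_contingency <- function(reports, drug, event, role = NULL) {
  if (nrow(reports) == 0) stopf("background report set is empty")
  if (!nzchar(drug) || !nzchar(event)) stopf("`drug` and `event` must be non-empty")
  de <- has_drug_vec(reports, drug, role)
  ev <- has_event_vec(reports, event)
  contingency_table(sum(de & ev), sum(de & !ev), sum(!de & ev), sum(!de & !ev))
}

# ---- vectorized metric kernels ---------------------------------------------

# reporting odds ratio with Wald 95% CI; Haldane-Anscombe 0.5 continuity
# correction applied to all four cells only when some cell is zero
.ror_cells <- function(a, b, c, d) {
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  off <- ifelse(corrected, 0.5, 0)
  aa <- a + off; bb <- b + off; cc <- c + off; dd <- d + off
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  list(
    ror = ror,
    ci_low = exp(log(ror) - 1.96 * se),
    ci_high = exp(log(ror) + 1.96 * se),
    corrected = corrected
  )
}

.rrr_cells <- function(a, b, c, d) {
  e <- (a + b) * (a + c) / (a + b + c + d)
  ifelse(a == 0, 0, ifelse(e == 0, Inf, a / e))
}

.signal_cells <- function(a, b, c, d) {
  e <- (a + b) * (a + c) / (a + b + c + d)
  log2((a + 0.5) / (e + 0.5))
}

.ic_gamma_cells <- function(a, b, c, d) {
  e <- (a + b) * (a + c) / (a + b + c + d)
  list(
    ic = log2((a + 0.5) / (e + 0.5)),
    ci_low = log2(qgamma(0.025, shape = a + 0.5, rate = 1) / (e + 0.5)),
    ci_high = log2(qgamma(0.975, shape = a + 0.5, rate = 1) / (e + 0.5))
  )
}

# closed-form posterior moments with uniform-marginal priors (the classical
# BCPNN normal approximation); CI = E[IC] +/- 1.96 sd[IC]
.ic_bate_cells <- function(a, b, c, d) {
  n <- a + b + c + d
  n1 <- a + b
  n2 <- a + c
  a1 <- 1; a0 <- 2
  g11 <- 1
  g <- g11 * (n + a0) * (n + a0) / ((n1 + a1) * (n2 + a1))
  eic <- log2((a + g11) * (n + a0)^2 / ((n + g) * (n1 + a1) * (n2 + a1)))
  vic <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
            (n - n1 + a0 - a1) / ((n1 + a1) * (1 + n + a0)) +
            (n - n2 + a0 - a1) / ((n2 + a1) * (1 + n + a0))) / log(2)^2
  sdic <- sqrt(vic)
  list(ic = eic, ci_low = eic - 1.96 * sdic, ci_high = eic + 1.96 * sdic)
}

.fisher_p <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    stats::fisher.test(matrix(c(a[i], c[i], b[i], d[i]), 2))$p.value
  }, numeric(1))
}

#' Reporting odds ratio with Wald interval and Fisher p-value
#'
#' `ROR = (a d)/(b c)`, with a 95% Wald interval
#' `exp(log ROR +/- 1.96 * se)` where `se = sqrt(1/a + 1/b + 1/c + 1/d)` on
#' the log scale. When any cell is zero, 0.5 is added to all four cells
#' first (Haldane-Anscombe) and the result is flagged `corrected`. The
#' p-value is a two-sided Fisher exact test on the uncorrected integer
#' table.
#'
#' @param table A [contingency_table()].
#' @return A one-row tibble: `ror`, `ci_low`, `ci_high`, `p`, `corrected`.
#' @export
#' @examples
#' compute_ror(contingency_table(2, 5, 10, 500))
compute_ror <- function(table) {
  r <- .ror_cells(table$a, table$b, table$c, table$d)
  tibble(ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
         p = .fisher_p(table$a, table$b, table$c, table$d),
         corrected = r$corrected)
}

#' Relative reporting ratio (observed over expected)
#'
#' `RRR = a N / ((a + b)(a + c)) = a / E`. Returns 0 when `a = 0` and `Inf`
#' when `E = 0` with `a > 0`. This is the observed/expected "relative risk"
#' reported by spontaneous-report mining tools.
#'
#' @param table A [contingency_table()].
#' @return A single number.
#' @export
compute_rrr <- function(table) {
  .rrr_cells(table$a, table$b, table$c, table$d)
}

#' Shrunk log2 safety signal
#'
#' `signal = log2((a + 0.5) / (E + 0.5))`: a signed observed-vs-expected
#' measure, positive when the pair is over-reported, strictly increasing in
#' `a` at fixed margins, zero exactly when `a = E`, and finite at `a = 0`.
#'
#' @param table A [contingency_table()].
#' @return A single number.
#' @export
compute_safety_signal <- function(table) {
  .signal_cells(table$a, table$b, table$c, table$d)
}

IC_METHODS <- c("gamma-shrinkage", "bate1998")

#' BCPNN information component with 95% credible bounds
#'
#' The default `"gamma-shrinkage"` method takes the observed count as
#' Gamma-distributed a posteriori, `a | data ~ Gamma(a + 0.5, 1)`, giving
#' `IC = log2((a + 0.5)/(E + 0.5))` with exact credible bounds
#' `log2(q_Gamma(alpha; a + 0.5, 1)/(E + 0.5))` at `alpha = 0.025, 0.975`.
#' The `"bate1998"` method is the classical closed-form posterior-moment
#' approximation with uniform-marginal priors and a normal interval
#' `E[IC] +/- 1.96 sd[IC]`.
#'
#' @param table A [contingency_table()].
#' @param method `"gamma-shrinkage"` (default) or `"bate1998"`.
#' @return A one-row tibble: `ic`, `ci_low`, `ci_high`, `method`.
#' @export
compute_ic <- function(table, method = "gamma-shrinkage") {
  if (!method %in% IC_METHODS) {
    stopf("unknown IC method \"%s\"; supported methods: %s", method,
          paste(IC_METHODS, collapse = ", "))
  }
  r <- if (method == "gamma-shrinkage") {
    .ic_gamma_cells(table$a, table$b, table$c, table$d)
  } else {
    .ic_bate_cells(table$a, table$b, table$c, table$d)
  }
  tibble(ic = r$ic, ci_low = r$ci_low, ci_high = r$ci_high, method = method)
}

#' Apply the three published signal-criteria rule sets
#'
#' Adds three logical flag columns to a screen results table, with the
#' strict inequalities of the published criteria:
#' * `flag_aersmine`: absolute count `a >= 2` AND safety signal `> 0` AND
#'   relative reporting ratio `> 2`;
#' * `flag_ror`: lower 95% Wald limit of the ROR `> 1`;
#' * `flag_bcpnn`: report count `a >= 3` AND lower 95% credible limit of the
#'   IC `> 0`.
#'
#' @param results A tibble with columns `a`, `safety_signal`, `rrr`,
#'   `ror_ci_low`, `ic_ci_low` (as produced by [screen_signals()]).
#' @return `results` with `flag_aersmine`, `flag_ror`, `flag_bcpnn` columns.
#' @export
apply_criteria <- function(results) {
  mutate(
    results,
    flag_aersmine = .data$a >= 2 & .data$safety_signal > 0 & .data$rrr > 2,
    flag_ror = .data$ror_ci_low > 1,
    flag_bcpnn = .data$a >= 3 & .data$ic_ci_low > 0
  )
}

#' Screen a drug list against one event
#'
#' Builds the 2x2 table for every drug against the given event within the
#' chosen background, computes all four disproportionality statistics
#' (ROR with Wald CI and Fisher p, relative reporting ratio, safety signal,
#' IC with credible bounds), applies the three rule sets, and returns the
#' results sorted by ROR descending — a forest-plot-ready table. No
#' multiple-testing adjustment is applied unless `adjust = TRUE`
#' (Benjamini-Hochberg on the Fisher p-values, reported in `p_adj`).
#'
#' @param reports Deduplicated report tibble (the cohort of interest).
#' @param event Preferred term screened against.
#' @param drugs Character vector of generic names; default all generics
#'   observed in the background.
#' @param background Optional larger report tibble to use as the background
#'   population; default the cohort itself.
#' @param role Optional qualifying drug role for the drug margin.
#' @param ic_method Passed to [compute_ic()].
#' @param stratum Label recorded on every row (default `"all"`).
#' @param adjust Add Benjamini-Hochberg adjusted p-values? Default `FALSE`.
#' @return An object of class `signal_screen`; see [tidy.signal_screen()].
#' @export
screen_signals <- function(reports, event, drugs = NULL, background = NULL,
                           role = NULL, ic_method = "gamma-shrinkage",
                           stratum = "all", adjust = FALSE) {
  bg <- background %||% reports
  if (nrow(bg) == 0) stopf("background report set is empty")
  if (!ic_method %in% IC_METHODS) {
    stopf("unknown IC method \"%s\"; supported methods: %s", ic_method,
          paste(IC_METHODS, collapse = ", "))
  }
  nd <- lengths(bg$drug_generic)
  long <- tibble(
    report = rep(seq_len(nrow(bg)), times = nd),
    generic_name = unlist(bg$drug_generic, use.names = FALSE),
    role_code = unlist(bg$drug_role, use.names = FALSE)
  )
  if (!is.null(role)) long <- long[long$role_code == role, ]
  long <- distinct(long, .data$report, .data$generic_name)
  if (is.null(drugs)) drugs <- sort(unique(long$generic_name))
  if (!length(drugs)) stopf("drug list is empty")
  ev <- has_event_vec(bg, event)
  long$with_event <- ev[long$report]
  counts <- long |>
    filter(.data$generic_name %in% drugs) |>
    group_by(.data$generic_name) |>
    summarise(n_drug = n(), a = sum(.data$with_event), .groups = "drop")
  counts <- left_join(tibble(drug = drugs), counts,
                      by = c(drug = "generic_name")) |>
    mutate(n_drug = dplyr::coalesce(.data$n_drug, 0L),
           a = dplyr::coalesce(.data$a, 0L))
  n_bg <- nrow(bg)
  n_event <- sum(ev)
  a <- counts$a
  b <- counts$n_drug - a
  cc <- n_event - a
  d <- n_bg - counts$n_drug - cc
  wald <- .ror_cells(a, b, cc, d)
  icr <- if (ic_method == "gamma-shrinkage") .ic_gamma_cells(a, b, cc, d)
         else .ic_bate_cells(a, b, cc, d)
  results <- tibble(
    drug = counts$drug, event = event, stratum = stratum,
    a = a, b = b, c = cc, d = d,
    expected = (a + b) * (a + cc) / (a + b + cc + d),
    ror = wald$ror, ror_ci_low = wald$ci_low, ror_ci_high = wald$ci_high,
    ror_p = .fisher_p(a, b, cc, d), ror_corrected = wald$corrected,
    rrr = .rrr_cells(a, b, cc, d),
    safety_signal = .signal_cells(a, b, cc, d),
    ic = icr$ic, ic_ci_low = icr$ci_low, ic_ci_high = icr$ci_high
  ) |>
    apply_criteria() |>
    arrange(dplyr::desc(.data$ror), .data$drug)
  if (adjust) results$ror_p_adj <- stats::p.adjust(results$ror_p, "BH")
  structure(
    list(results = results, event = event, n_background = n_bg,
         n_event = n_event, ic_method = ic_method, role = role,
         background_mode = if (is.null(background)) "cohort" else "external"),
    class = "signal_screen"
  )
}

#' Tidy a signal screen into its forest table
#'
#' @param x A `signal_screen` from [screen_signals()].
#' @param ... Unused.
#' @return The per-drug results tibble (one row per drug, sorted by ROR
#'   descending).
#' @export
tidy.signal_screen <- function(x, ...) x$results

#' One-row summary of a signal screen
#'
#' @param x A `signal_screen`.
#' @param ... Unused.
#' @return A one-row tibble with the event, background size and the number
#'   of drugs flagged by each rule set.
#' @export
glance.signal_screen <- function(x, ...) {
  tibble(
    event = x$event,
    n_drugs = nrow(x$results),
    n_background = x$n_background,
    n_event = x$n_event,
    ic_method = x$ic_method,
    n_flag_aersmine = sum(x$results$flag_aersmine),
    n_flag_ror = sum(x$results$flag_ror),
    n_flag_bcpnn = sum(x$results$flag_bcpnn)
  )
}

#' @export
print.signal_screen <- function(x, ...) {
  cat(sprintf(
    "Signal screen: %d drugs vs %s (background %d reports, %d with event)\n",
    nrow(x$results), x$event, x$n_background, x$n_event
  ))
  print(select(
    x$results, "drug", "a", "ror", "ror_ci_low", "ror_ci_high",
    "rrr", "safety_signal", "ic", "ic_ci_low",
    "flag_aersmine", "flag_ror", "flag_bcpnn"
  ), ...)
  invisible(x)
}
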