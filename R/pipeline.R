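#' Configure an end-to-end pipeline run
#'
#' @param input_mode `"synthetic"` (generate reports) or `"directory"`
#'   (read quarterly files).
#' @param generator A [generator_config()] for synthetic mode.
#' @param data_dir Input directory for directory mode.
#' @param mapping Optional drug-name mapping tibble (see
#'   [standardize_drug_names()]).
#' @param filter A [cohort_filter()] defining the analysis cohort.
#' @param event Target preferred term (default `"DIZZINESS"`).
#' @param drugs Drug list to screen; `NULL` screens every generic observed
#'   in the cohort.
#' @param background_mode `"cohort"` (2x2 tables within the cohort) or
#'   `"all"` (within the full deduplicated dataset).
#' @param strata Stratum tibble (default [default_strata()]).
#' @param ic_method Passed to [screen_signals()].
#' @param correlation_metric `"count"` or `"rrr"`.
#' @param correlation_axis `"strata"` or `"year"`.
#' @param top_k Ranking depth for per-stratum lists (default 5).
#' @param output_dir Output directory for TSVs and the manifest.
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @return A list of class `faers_run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "directory"),
                       generator = generator_config(),
                       data_dir = NULL, mapping = NULL,
                       filter = cohort_filter(), event = "DIZZINESS",
                       drugs = NULL,
                       background_mode = c("cohort", "all"),
                       strata = default_strata(),
                       ic_method = "gamma-shrinkage",
                       correlation_metric = c("count", "rrr"),
                       correlation_axis = c("strata", "year"),
                       top_k = 5, output_dir, seed = 1L) {
  input_mode <- match.arg(input_mode)
  background_mode <- match.arg(background_mode)
  correlation_metric <- match.arg(correlation_metric)
  correlation_axis <- match.arg(correlation_axis)
  if (correlation_axis == "year" && correlation_metric != "count") {
    stopf("the yearly correlation axis supports only the \"count\" metric")
  }
  if (input_mode == "directory") {
    if (is.null(data_dir)) stopf("`data_dir` is required in directory mode")
    if (!is.null(output_dir) && normalizePath(data_dir, mustWork = FALSE) ==
        normalizePath(output_dir, mustWork = FALSE)) {
      stopf("`output_dir` must be distinct from `data_dir`")
    }
  }
  structure(
    list(input_mode = input_mode, generator = generator, data_dir = data_dir,
         mapping = mapping, filter = filter, event = event, drugs = drugs,
         background_mode = background_mode, strata = strata,
         ic_method = ic_method, correlation_metric = correlation_metric,
         correlation_axis = correlation_axis, top_k = top_k,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "faers_run_config"
  )
}

#' Read a flat key-value run configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Generator keys are
#' prefixed `generator.` (`generator.n_reports`,
#' `generator.duplicate_rate`, `generator.indication_probability`), cohort
#' keys `filter.` (`filter.min_age`, `filter.required_role`,
#' `filter.required_event`, `filter.required_indication`); top-level keys
#' are `input_mode`, `data_dir`, `event`, `background_mode`, `ic_method`,
#' `correlation_metric`, `correlation_axis`, `top_k`. Unset keys keep the
#' package defaults (the published-marginal synthetic world and the adult
#' primary-suspect dizziness cohort).
#'
#' @param path Config file path.
#' @param output_dir,seed Supplied at run time, not in the file.
#' @return A `faers_run_config`.
#' @export
read_run_config <- function(path, output_dir, seed = 1L) {
  if (!file.exists(path)) stopf("config file %s does not exist", path)
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stopf("config line not of the form key = value: %s",
                      lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  num <- function(k, default) {
    v <- get(k); if (is.null(v)) default else as.numeric(v)
  }
  gen <- generator_config(
    n_reports = num("generator.n_reports", 10000),
    duplicate_rate = num("generator.duplicate_rate", 0.05),
    indication_probability = num("generator.indication_probability", 0),
    seed = seed
  )
  filt <- cohort_filter(
    min_age = num("filter.min_age", 18),
    required_role = get("filter.required_role"),
    required_event = get("filter.required_event"),
    required_indication = get("filter.required_indication")
  )
  run_config(
    input_mode = get("input_mode", "synthetic"),
    generator = gen,
    data_dir = get("data_dir"),
    filter = filt,
    event = get("event", "DIZZINESS"),
    background_mode = get("background_mode", "cohort"),
    ic_method = get("ic_method", "gamma-shrinkage"),
    correlation_metric = get("correlation_metric", "count"),
    correlation_axis = get("correlation_axis", "strata"),
    top_k = num("top_k", 5),
    output_dir = output_dir, seed = seed
  )
}

.write_tsv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path)
  path
}

#' Run the full screening pipeline
#'
#' Executes generate/read, assemble, standardize, deduplicate, cohort
#' filter, descriptive summaries, the disproportionality screen, the
#' stratified matrices with top-k rankings, and the pairwise correlations,
#' writing every stage's TSV plus a JSON manifest (config echo, seed, stage
#' row counts, exclusion tallies, package version, and an md5 checksum for
#' every output file). Identical config and seed produce byte-identical
#' outputs. A stage failure aborts with the stage name after writing the
#' partial manifest.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "faers_run_config")) {
    stopf("`config` must come from run_config()")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config = list(
      input_mode = config$input_mode, event = config$event,
      background_mode = config$background_mode,
      ic_method = config$ic_method,
      correlation_metric = config$correlation_metric,
      correlation_axis = config$correlation_axis,
      min_age = config$filter$min_age %||% NA,
      required_role = config$filter$required_role %||% NA,
      required_indication = config$filter$required_indication %||% NA,
      n_reports = if (config$input_mode == "synthetic") config$generator$n_reports else NA,
      duplicate_rate = if (config$input_mode == "synthetic") config$generator$duplicate_rate else NA
    ),
    stages = list(), files = character()
  )
  fail <- function(stage, e) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest_partial.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stopf("pipeline stage \"%s\" failed: %s", stage, conditionMessage(e))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  # -- input ------------------------------------------------------------
  reports <- stage("input", {
    if (config$input_mode == "synthetic") {
      gen <- config$generator
      gen$seed <- derive_seed(config$seed, "generate")
      r <- generate_reports(gen)
      r <- inject_duplicates(r, gen$duplicate_rate,
                             seed = derive_seed(config$seed, "duplicates"))
      # completeness rule applied on the direct path too: a report with no
      # recorded reaction would never survive assembly from files
      complete <- lengths(r$events) > 0 & lengths(r$drug_generic) > 0
      out <- r[complete, ]
      attr(out, "n_incomplete") <- sum(!complete)
      out
    } else {
      raw <- read_quarterly_files(config$data_dir)
      assemble_reports(raw)
    }
  })
  manifest$stages$input <- list(
    n_records = nrow(reports),
    n_incomplete = attr(reports, "n_incomplete") %||% 0L
  )

  reports <- stage("standardize", standardize_drug_names(reports, config$mapping))
  cov <- attr(reports, "coverage")
  manifest$stages$standardize <- list(
    n_verbatim = nrow(cov), n_unresolved = sum(!cov$resolved)
  )

  deduped <- stage("deduplicate", deduplicate_reports(reports))
  manifest$stages$deduplicate <- list(
    n_reports = nrow(deduped), n_removed = attr(deduped, "n_removed")
  )

  cohort <- stage("cohort_filter", apply_cohort_filter(deduped, config$filter))
  excl <- attr(cohort, "exclusions")
  manifest$stages$cohort_filter <- list(
    n_cohort = nrow(cohort),
    exclusions = stats::setNames(as.list(excl$n), excl$criterion)
  )

  files <- character()
  stage("describe", {
    summ <- summarize_demographics(cohort)
    files["demographics"] <- .write_tsv_out(tidy(summ), config$output_dir,
                                             "demographics.tsv")
    files["yearly_counts"] <- .write_tsv_out(
      yearly_counts(cohort, config$event), config$output_dir,
      "yearly_counts.tsv")
    files["outcomes"] <- .write_tsv_out(
      outcome_distribution(cohort, by_year = TRUE), config$output_dir,
      "outcomes_by_year.tsv")
    if (!is.null(summ$top_drugs)) {
      files["top_drugs"] <- .write_tsv_out(summ$top_drugs, config$output_dir,
                                            "top_drugs.tsv")
    }
  })
  manifest$stages$describe <- list(n_cohort = nrow(cohort))

  screen <- stage("screen", {
    bg <- if (config$background_mode == "all") deduped else NULL
    drugs <- config$drugs
    if (is.null(drugs)) {
      drugs <- sort(unique(unlist(cohort$drug_generic, use.names = FALSE)))
    }
    if (!length(drugs)) stopf("no drugs observed in the cohort")
    screen_signals(cohort, config$event, drugs = drugs, background = bg,
                   ic_method = config$ic_method)
  })
  files["forest"] <- .write_tsv_out(tidy(screen), config$output_dir, "forest.tsv")
  manifest$stages$screen <- as.list(glance(screen))

  strat <- stage("subgroups", {
    sm <- stratified_metrics(cohort, config$event,
                             drugs = tidy(screen)$drug, strata = config$strata)
    files["stratified_metrics"] <- .write_tsv_out(sm, config$output_dir,
                                                   "stratified_metrics.tsv")
    files["top_per_stratum"] <- .write_tsv_out(
      top_k_per_stratum(sm, "rrr", config$top_k), config$output_dir,
      "top_per_stratum.tsv")
    sm
  })
  manifest$stages$subgroups <- list(
    n_strata = nrow(config$strata),
    n_stratified_reports = sum(!is.na(assign_strata(cohort, config$strata)))
  )

  stage("correlate", {
    long <- if (config$correlation_axis == "strata") {
      strat
    } else {
      drugs <- unique(strat$drug)
      purrr::map_dfr(drugs, function(dg) {
        sel <- cohort[purrr::map_lgl(cohort$drug_generic, ~ dg %in% .x), ]
        yearly_counts(sel, config$event,
                      year_range = range(cohort$year)) |>
          mutate(drug = dg, .before = 1)
      })
    }
    cell <- if (config$correlation_axis == "strata") "stratum" else "year"
    cors <- suppressWarnings(pairwise_drug_correlation(
      long, metric = config$correlation_metric, cell_col = cell))
    files["correlations"] <- .write_tsv_out(cors, config$output_dir,
                                             "correlations.tsv")
    files["negative_pairs"] <- .write_tsv_out(
      rank_negative_pairs(cors, 10), config$output_dir, "negative_pairs.tsv")
    manifest$stages$correlate <- list(
      n_pairs = nrow(cors),
      n_excluded = nrow(attr(cors, "excluded") %||% tibble())
    )
  })

  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
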