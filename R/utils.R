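#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   count left_join bind_rows rename row_number n distinct across
#' @importFrom stats qgamma qlogis plogis rexp runif fisher.test sd cor
#' @importFrom utils head
NULL

# Category enumerations shared across the package. Band labels follow the
# FAERS age_grp convention used in baseline tables.
AGE_BANDS <- c(
  "0-1 Month", "2 Months-2 Years", "3-11 Years", "12-17 Years",
  "18-64 Years", "65-85 Years", "More than 85 Years", "Not Specified"
)
SEX_LEVELS <- c("female", "male", "unspecified")
REPORTER_LEVELS <- c("healthcare_professional", "consumer", "other", "unspecified")
OUTCOME_LEVELS <- c(
  "death", "life_threatening", "hospitalization", "disability",
  "other_serious", "non_serious", "unspecified"
)
DRUG_ROLES <- c("primary_suspect", "secondary_suspect", "concomitant", "interacting")

# band edges in years; "Not Specified" means missing age
.band_breaks <- c(0, 2 / 12, 3, 12, 18, 65, 86, Inf)

#' Map an age in years to its reporting age band
#'
#' Band edges: under 2 months; 2 months to under 3 years; 3 to under 12;
#' 12 to under 18; 18 to under 65; 65 to under 86; 86 and above. A missing
#' age maps to `"Not Specified"`.
#'
#' @param age Numeric vector of ages in years (NA allowed).
#' @return Character vector of band labels.
#' @export
age_to_band <- function(age) {
  idx <- findInterval(age, .band_breaks, rightmost.closed = FALSE)
  band <- AGE_BANDS[pmin(idx, 7L)]
  band[is.na(age)] <- "Not Specified"
  band
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; published percentage tables round
#' half up, so 0.125 at 2 decimals prints 0.13.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a stage sub-seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(
    generate = 11L, duplicates = 29L, ingest = 47L, screen = 83L,
    strata = 131L, correlate = 197L
  )
  off <- offsets[[stage]] %||% 257L
  as.integer((as.numeric(seed) * 1103L + off * 12289L) %% 2147483629)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

# validate that a named probability vector covers `levels` and sums to 1
check_prob_map <- function(p, levels, field) {
  if (!is.numeric(p) || is.null(names(p))) {
    stopf("`%s` must be a named numeric vector over: %s", field,
          paste(levels, collapse = ", "))
  }
  missing <- setdiff(levels, names(p))
  extra <- setdiff(names(p), levels)
  if (length(missing) || length(extra)) {
    stopf("`%s` must name exactly the categories %s (missing: %s; extra: %s)",
          field, paste(levels, collapse = ", "),
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  if (any(p < 0)) stopf("`%s` has negative probabilities", field)
  if (abs(sum(p) - 1) > 1e-9) {
    stopf("`%s` must sum to 1 (got %.12f)", field, sum(p))
  }
  p[levels]
}
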