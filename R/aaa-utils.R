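#' @keywords internal
"_PACKAGE"

## Closed enumerations used across the package ------------------------------

FIELD_KINDS <- c(
  "MEDICATION", "MEDICATION_LIST", "DISEASE_STATUS",
  "GERMLINE_VARIANT_STATUS", "TUMOR_PATHOGEN_GENOTYPE",
  "DEMOGRAPHIC", "LAB_VALUE", "DERIVED_PHENOTYPE_CLASS"
)

FIELD_SOURCES <- c(
  "INPATIENT_OUTPATIENT_DB", "LABORATORY_DB", "SUPPORTING_KNOWLEDGE"
)

PREDICATES <- c(
  "MEDICATION_ACTIVE", "MEDICATION_CONSIDERED", "TAKING_DRUG_IN_CLASS",
  "HAS_DISEASE", "HAS_VARIANT", "HAS_PHENOTYPE_CLASS",
  "TUMOR_HAS_MUTATION", "AGE_COMPARE", "LAB_COMPARE"
)

COMPARATORS <- c("<", "<=", "=", ">=", ">")

SUPPORT_CATEGORIES <- c(
  "DOSE_ADJUSTMENT", "PATIENT_MONITORING", "PRE_TREATMENT_CONSIDERATION",
  "BENEFIT_PREDICTION", "TESTING_GUIDANCE", "COADMINISTRATION",
  "PATIENT_COMMUNICATION"
)

#' Presentation types in increasing severity order
#'
#' Alert presentation types characterise how actionable a consequent
#' statement is: `INFORMATION` (no direct action), `RECOMMENDATION`
#' (clear action, confident language), `WARNING` (potential consequences
#' stated). Severity ranks WARNING > RECOMMENDATION > INFORMATION.
#'
#' @format Character vector of the three types, least severe first.
#' @export
PRESENTATION_TYPES <- c("INFORMATION", "RECOMMENDATION", "WARNING")

ACTION_SPECIFICITIES <- c("NONE", "VAGUE", "CLEAR")

#' EMR availability statuses for clinical-data fields
#'
#' Statuses a field can carry in an EMR capability profile: captured as
#' discrete data, derivable from supporting knowledge, one of the four
#' feasible-expansion categories (disease-status definitions, pathology
#' fields, microbiology fields, parseable free text), requiring full NLP,
#' or absent entirely.
#'
#' @format Character vector of the eight statuses.
#' @export
AVAILABILITY_STATUSES <- c(
  "DISCRETE", "REQUIRES_SUPPORTING_KNOWLEDGE",
  "EXPANSION_DISEASE_STATUS_DEFINITION", "EXPANSION_PATHOLOGY_FIELD",
  "EXPANSION_MICROBIOLOGY_FIELD", "EXPANSION_PARSEABLE_FREE_TEXT",
  "REQUIRES_FULL_NLP", "ABSENT"
)

SCENARIOS <- c("EMR_ALONE", "EMR_PLUS_KNOWLEDGE", "EMR_PLUS_EXPANSION")

EVIDENCE_CATEGORIES <- c("CO", "PD", "PK", "FA", "GN")

KNOWLEDGE_FORMS <- c(
  "PATHWAY_EVIDENCE", "VARIANT_EVIDENCE", "GENOTYPE_DATA",
  "PHENOTYPE_DATA", "CLINICAL_PGX_SECTION"
)

## Errors --------------------------------------------------------------------

# All package errors carry a machine-readable code as a condition class so
# callers can branch on tryCatch(..., <CODE> = ...) without parsing messages.
pgx_error <- function(code, msg, ...) {
  stop(errorCondition(msg, ..., class = c(code, "pgxcds_error", "error")))
}

#' Severity rank of a presentation type
#'
#' @param type Character vector of presentation types.
#' @return Integer rank: INFORMATION = 1, RECOMMENDATION = 2, WARNING = 3.
#' @export
severity_rank <- function(type) {
  r <- match(type, PRESENTATION_TYPES)
  if (anyNA(r)) {
    pgx_error("INVALID_PRESENTATION_TYPE",
              paste0("unknown presentation type: ",
                     paste(type[is.na(r)], collapse = ", ")))
  }
  r
}

## Shared rounding convention -----------------------------------------------

#' Round half away from zero
#'
#' The rounding convention shared by every percentage this package reports
#' (base R's `round()` rounds half to even, which does not reproduce the
#' conventional half-up behaviour of reported clinical percentages).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5)) # 1, 2, -1
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percentage of num/den under the shared convention; 0 when den == 0
pct_of <- function(num, den) {
  if (den == 0) return(0)
  round_half_away(100 * num / den)
}

## Misc helpers --------------------------------------------------------------

# canonical drug-name form: lowercase, squeezed whitespace, trimmed
canonical_drug <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Load a drug synonym table
#'
#' Reads a two-column TSV (alias, canonical) and returns a named character
#' vector mapping canonical alias forms to canonical generic names. The
#' packaged default maps the brand names appearing in the transcribed rule
#' fixtures (e.g. Plavix, Gleevec, Prozac) to generic names.
#'
#' @param path Path to a TSV with columns `alias` and `canonical`; default
#'   the table shipped with the package.
#' @return Named character vector (names = aliases, values = canonical).
#' @export
load_drug_synonyms <- function(path = system.file("extdata", "drug_synonyms.tsv",
                                                  package = "pgxcds")) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(canonical_drug(tab$canonical), canonical_drug(tab$alias))
}

# resolve a drug name through a synonym map to its canonical generic form
resolve_drug <- function(x, synonyms = NULL) {
  x <- canonical_drug(x)
  if (is.null(synonyms)) return(x)
  hit <- synonyms[x]
  ifelse(is.na(hit), x, unname(hit))
}

# run code under a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed so generators never perturb global randomness
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# deterministic integer apportionment of n across weights by largest
# remainder, so planted categorical mixes are exact, not sampled
apportion <- function(n, weights) {
  if (any(weights < 0) || sum(weights) <= 0) {
    pgx_error("INVALID_WEIGHTS", "mix weights must be non-negative and sum > 0")
  }
  p <- weights / sum(weights)
  exact <- n * p
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(exact - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}
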