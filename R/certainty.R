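## Certainty-lexicon scan and presentation-type classification.
##
## Labels quantify how actionable a consequent statement is. The decision
## procedure mirrors manual drug-label curation practice: consequences
## always warrant a warning; a clear action stated with confident language
## warrants a recommendation; everything else is information only. Hedged
## language ("might", "may", "could") downgrades actionability even when a
## confident verb co-occurs.

#' Construct a certainty lexicon
#'
#' Word lists used to scan consequent statements for the degree of
#' certainty of their language. Defaults are the low-certainty hedges
#' (might, may, could) and the medium/high-certainty verbs (should, will,
#' are, is, must, was, do). The optional consequence lexicon only
#' *suggests* a consequence annotation to curators; it never overrides
#' the explicit flag.
#'
#' @param low_terms,high_terms Character vectors of lowercase single
#'   tokens; must be disjoint.
#' @param consequence_terms Advisory lexicon for consequence language.
#' @return An object of class `pgx_lexicon`.
#' @export
certainty_lexicon <- function(
    low_terms = c("might", "may", "could"),
    high_terms = c("should", "will", "are", "is", "must", "was", "do"),
    consequence_terms = c("risk", "caution", "adverse", "toxicity",
                          "bleeding", "fatal")) {
  low_terms <- tolower(low_terms)
  high_terms <- tolower(high_terms)
  if (length(intersect(low_terms, high_terms)) > 0) {
    pgx_error("LEXICON_OVERLAP",
              "low_terms and high_terms must be disjoint")
  }
  bad <- grepl("[[:space:]]", c(low_terms, high_terms))
  if (any(bad)) {
    pgx_error("LEXICON_MULTIWORD", "lexicon entries must be single tokens")
  }
  structure(list(low_terms = low_terms, high_terms = high_terms,
                 consequence_terms = tolower(consequence_terms)),
            class = "pgx_lexicon")
}

#' Load a certainty lexicon from YAML
#'
#' @param path YAML file with keys `low_terms`, `high_terms`, and
#'   optionally `consequence_terms`.
#' @return A [certainty_lexicon()].
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    pgx_error("MISSING_FILE", paste0("no such lexicon file: ", path))
  }
  x <- yaml::read_yaml(path)
  certainty_lexicon(
    low_terms = unlist(x$low_terms),
    high_terms = unlist(x$high_terms),
    consequence_terms = if (is.null(x$consequence_terms)) character()
                        else unlist(x$consequence_terms)
  )
}

# case-insensitive whole-word matches of `terms` in `text`; returns a data
# frame of (token, offset). Word boundaries, so "may" never matches inside
# "Maybe".
match_terms <- function(text, terms) {
  hits <- data.frame(token = character(), offset = integer(),
                     stringsAsFactors = FALSE)
  if (length(terms) == 0) return(hits)
  for (term in terms) {
    pat <- paste0("\\b", term, "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] != -1) {
      hits <- rbind(hits, data.frame(token = rep(term, length(m)),
                                     offset = as.integer(m),
                                     stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$offset), , drop = FALSE]
}

#' Scan a statement for certainty language
#'
#' Case-insensitive whole-word matching against the low- and
#' high-certainty lexicons. Any low-certainty hedge forces `LOW`
#' regardless of co-occurring confident verbs; otherwise any
#' medium/high-certainty verb yields `MEDIUM_HIGH`; otherwise `NONE`.
#'
#' @param text Statement text (non-empty).
#' @param lexicon A [certainty_lexicon()].
#' @return List with `level` (`"LOW"`, `"MEDIUM_HIGH"`, or `"NONE"`) and
#'   `matched_tokens` (data frame of token + character offset; empty iff
#'   level is `NONE`).
#' @export
#' @examples
#' extract_certainty("coadministration should be approached with caution")$level
extract_certainty <- function(text, lexicon = certainty_lexicon()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    pgx_error("EMPTY_STATEMENT", "statement text must be a non-empty string")
  }
  low_hits <- match_terms(text, lexicon$low_terms)
  high_hits <- match_terms(text, lexicon$high_terms)
  if (nrow(low_hits) > 0) {
    list(level = "LOW", matched_tokens = low_hits)
  } else if (nrow(high_hits) > 0) {
    list(level = "MEDIUM_HIGH", matched_tokens = high_hits)
  } else {
    list(level = "NONE",
         matched_tokens = data.frame(token = character(), offset = integer(),
                                     stringsAsFactors = FALSE))
  }
}

#' Classify one consequent statement into a presentation type
#'
#' Decision procedure: (1) if the statement specifies potential
#' consequences it is a `WARNING`, whatever its language; (2) otherwise,
#' if it specifies a clear action in medium/high-certainty language it is
#' a `RECOMMENDATION`; (3) otherwise it is `INFORMATION`. Step ordering
#' realizes the tie-breaks warning > recommendation > information.
#'
#' @param stmt A [then_statement()].
#' @param lexicon A [certainty_lexicon()].
#' @return One of `"INFORMATION"`, `"RECOMMENDATION"`, `"WARNING"`.
#' @export
#' @examples
#' s <- then_statement("the dose of Celecoxib should be reduced by 50%",
#'                     action_specificity = "CLEAR")
#' classify_statement(s) # "RECOMMENDATION"
classify_statement <- function(stmt, lexicon = certainty_lexicon()) {
  stopifnot(inherits(stmt, "pgx_statement"))
  if (isTRUE(stmt$consequence_flag)) return("WARNING")
  cert <- extract_certainty(stmt$text, lexicon)
  if (identical(stmt$action_specificity, "CLEAR") &&
      identical(cert$level, "MEDIUM_HIGH")) {
    return("RECOMMENDATION")
  }
  "INFORMATION"
}

#' Classify a whole rule (maximum severity across its statements)
#'
#' Multi-consequent rules take the maximum-severity classification across
#' their statements so an alert never understates risk.
#'
#' @param rule A [pgx_rule()].
#' @param lexicon A [certainty_lexicon()].
#' @return One presentation type.
#' @export
classify_rule <- function(rule, lexicon = certainty_lexicon()) {
  types <- vapply(rule$consequents, classify_statement, character(1),
                  lexicon = lexicon)
  PRESENTATION_TYPES[max(severity_rank(types))]
}

#' Classify every rule in a catalog and report the distribution
#'
#' @param catalog A non-empty [rule_catalog()].
#' @param lexicon A [certainty_lexicon()].
#' @return List with `assignments` (named character vector rule_id ->
#'   type) and `distribution` (data frame with columns `type`, `count`,
#'   `percent`; percentages rounded half away from zero; counts sum to
#'   the catalog size).
#' @export
classify_catalog <- function(catalog, lexicon = certainty_lexicon()) {
  if (length(catalog$rules) == 0) {
    pgx_error("EMPTY_CATALOG", "cannot classify an empty catalog")
  }
  types <- vapply(catalog$rules, classify_rule, character(1),
                  lexicon = lexicon)
  ids <- vapply(catalog$rules, function(r) r$rule_id, character(1))
  counts <- vapply(PRESENTATION_TYPES,
                   function(t) sum(types == t), integer(1))
  list(
    assignments = stats::setNames(types, ids),
    distribution = data.frame(
      type = PRESENTATION_TYPES,
      count = as.integer(counts),
      percent = vapply(counts, pct_of, numeric(1), den = length(types)),
      stringsAsFactors = FALSE
    )
  )
}

#' Write a presentation-type distribution report
#'
#' Emits the distribution both as JSON and as a two-column TSV
#' (`type`, `count`, `percent`).
#'
#' @param dist The `distribution` data frame from [classify_catalog()].
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `dist`.
#' @export
write_distribution_report <- function(dist, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(dist, json_path, dataframe = "rows", digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(dist, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dist)
}
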