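## EMR data-availability analysis: which rules are executable against a
## capability profile under three nested scenarios — the EMR's discrete
## data alone, plus supporting knowledge, plus feasible expansion of the
## EMR (disease-status definitions, pathology/microbiology fields,
## parseable free text). Fields requiring full NLP, or absent outright,
## are never satisfiable, which bounds maximum coverage below 100%.

SCENARIO_STATUSES <- list(
  EMR_ALONE = "DISCRETE",
  EMR_PLUS_KNOWLEDGE = c("DISCRETE", "REQUIRES_SUPPORTING_KNOWLEDGE"),
  EMR_PLUS_EXPANSION = c("DISCRETE", "REQUIRES_SUPPORTING_KNOWLEDGE",
                         "EXPANSION_DISEASE_STATUS_DEFINITION",
                         "EXPANSION_PATHOLOGY_FIELD",
                         "EXPANSION_MICROBIOLOGY_FIELD",
                         "EXPANSION_PARSEABLE_FREE_TEXT")
)

# statuses that block execution even under feasible expansion, plus the
# expansion statuses themselves: the attribution categories
BLOCKING_STATUSES <- setdiff(AVAILABILITY_STATUSES,
                             c("DISCRETE", "REQUIRES_SUPPORTING_KNOWLEDGE"))

#' Statuses satisfied under a coverage scenario
#'
#' The three scenarios are strictly nested: `EMR_ALONE` accepts only
#' `DISCRETE` fields; `EMR_PLUS_KNOWLEDGE` additionally accepts
#' `REQUIRES_SUPPORTING_KNOWLEDGE`; `EMR_PLUS_EXPANSION` additionally
#' accepts the four feasible-expansion statuses.
#'
#' @param scenario One of `"EMR_ALONE"`, `"EMR_PLUS_KNOWLEDGE"`,
#'   `"EMR_PLUS_EXPANSION"`.
#' @return Character vector of satisfied statuses.
#' @export
scenario_statuses <- function(scenario) {
  scenario <- match.arg(scenario, SCENARIOS)
  SCENARIO_STATUSES[[scenario]]
}

#' Construct an EMR capability profile
#'
#' Maps clinical-data fields to availability statuses. Entries match a
#' field either exactly by `field_id` or by a `(kind, detail-glob)`
#' pattern; exact entries always beat patterns, and two patterns that
#' both match one field with different statuses raise `PROFILE_CONFLICT`.
#' Unmatched fields take `default_status`.
#'
#' @param entries List of entries, each
#'   `list(match = list(field_id =) | list(kind =, detail =), status =)`.
#' @param default_status Status for unmatched fields (default `ABSENT`).
#' @return An object of class `pgx_profile`.
#' @export
capability_profile <- function(entries, default_status = "ABSENT") {
  default_status <- match.arg(default_status, AVAILABILITY_STATUSES)
  keys <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$match) || is.null(e$status) ||
        !e$status %in% AVAILABILITY_STATUSES) {
      pgx_error("SCHEMA_VIOLATION",
                paste0("profile entry ", i, " needs match + valid status"))
    }
    m <- e$match
    if (!is.null(m$field_id)) {
      keys[i] <- paste0("id:", m$field_id)
    } else if (!is.null(m$kind)) {
      if (!m$kind %in% FIELD_KINDS) {
        pgx_error("SCHEMA_VIOLATION",
                  paste0("profile entry ", i, ": unknown kind ", m$kind))
      }
      keys[i] <- paste0("pat:", m$kind, ":",
                        if (is.null(m$detail)) "*" else m$detail)
    } else {
      pgx_error("SCHEMA_VIOLATION",
                paste0("profile entry ", i, ": match needs field_id or kind"))
    }
  }
  if (anyDuplicated(keys)) {
    pgx_error("PROFILE_CONFLICT",
              paste0("duplicate profile matcher(s): ",
                     paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  structure(list(entries = entries, default_status = default_status),
            class = "pgx_profile")
}

#' Look up a field's availability status in a profile
#'
#' @param profile A [capability_profile()].
#' @param field A [clinical_data_field()].
#' @return One availability status.
#' @export
field_status <- function(profile, field) {
  hits <- character()
  pattern_hits <- character()
  for (e in profile$entries) {
    m <- e$match
    if (!is.null(m$field_id)) {
      if (identical(m$field_id, field$field_id)) hits <- c(hits, e$status)
    } else if (identical(m$kind, field$kind)) {
      pat <- if (is.null(m$detail)) "*" else m$detail
      if (grepl(utils::glob2rx(pat), field$detail, ignore.case = TRUE)) {
        pattern_hits <- c(pattern_hits, e$status)
      }
    }
  }
  if (length(hits) > 0) return(hits[[1]])  # exact beats pattern
  if (length(unique(pattern_hits)) > 1) {
    pgx_error("PROFILE_CONFLICT",
              paste0("field ", field$field_id,
                     " matched by conflicting patterns: ",
                     paste(unique(pattern_hits), collapse = " vs ")))
  }
  if (length(pattern_hits) > 0) return(pattern_hits[[1]])
  profile$default_status
}

#' Is a rule executable against a profile under a scenario?
#'
#' `TRUE` iff every clinical-data field the rule's antecedent reads
#' (including supporting-knowledge requirements) maps to a status the
#' scenario satisfies.
#'
#' @param rule A valid [pgx_rule()].
#' @param profile A [capability_profile()].
#' @param scenario One of the three scenarios.
#' @return Logical scalar.
#' @export
rule_executable <- function(rule, profile, scenario) {
  ok <- scenario_statuses(scenario)
  fields <- all_rule_fields(rule)
  all(vapply(fields, function(f) field_status(profile, f) %in% ok,
             logical(1)))
}

#' Coverage of a rule catalog under an EMR capability profile
#'
#' Computes, for each of the three nested scenarios, how many rules have
#' all their clinical-data needs satisfied, and attributes the
#' still-blocked rules to blocking categories. A rule counts toward
#' blocking category C iff it requires at least one field with status C
#' and is not executable under `EMR_PLUS_KNOWLEDGE`; under
#' `attribution = "any"` a rule may count toward several categories,
#' under `"sole"` only rules blocked by exactly one category are counted.
#'
#' @param catalog Non-empty [rule_catalog()].
#' @param profile A [capability_profile()].
#' @param attribution `"any"` (default) or `"sole"`.
#' @return An object of class `pgx_coverage`: list with `scenarios`
#'   (data frame scenario/executable/total/percent), `attribution`
#'   (data frame blocking_category/count/percent, percent of the full
#'   catalog), and `per_rule` (logical matrix rules x scenarios).
#' @export
coverage <- function(catalog, profile, attribution = c("any", "sole")) {
  attribution <- match.arg(attribution)
  n <- length(catalog$rules)
  if (n == 0) pgx_error("EMPTY_CATALOG", "cannot analyse an empty catalog")
  ids <- vapply(catalog$rules, function(r) r$rule_id, character(1))

  # one status lookup per rule-field, reused across scenarios
  rule_statuses <- lapply(catalog$rules, function(r) {
    vapply(all_rule_fields(r), function(f) field_status(profile, f),
           character(1))
  })
  per_rule <- vapply(SCENARIOS, function(sc) {
    ok <- scenario_statuses(sc)
    vapply(rule_statuses, function(st) all(st %in% ok), logical(1))
  }, logical(n))
  per_rule <- matrix(per_rule, nrow = n,
                     dimnames = list(ids, SCENARIOS))

  exec <- colSums(per_rule)
  scen_df <- data.frame(
    scenario = SCENARIOS,
    executable = as.integer(exec),
    total = n,
    percent = vapply(exec, pct_of, numeric(1), den = n),
    row.names = NULL, stringsAsFactors = FALSE
  )

  blocked <- !per_rule[, "EMR_PLUS_KNOWLEDGE"]
  attr_counts <- stats::setNames(integer(length(BLOCKING_STATUSES)),
                                 BLOCKING_STATUSES)
  for (i in seq_len(n)) {
    if (!blocked[i]) next
    cats <- intersect(unique(rule_statuses[[i]]), BLOCKING_STATUSES)
    if (attribution == "sole" && length(cats) != 1) next
    attr_counts[cats] <- attr_counts[cats] + 1L
  }
  attr_df <- data.frame(
    blocking_category = names(attr_counts),
    count = as.integer(attr_counts),
    percent = vapply(attr_counts, pct_of, numeric(1), den = n),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(scenarios = scen_df, attribution = attr_df,
                 per_rule = per_rule, attribution_mode = attribution),
            class = "pgx_coverage")
}

#' @export
print.pgx_coverage <- function(x, ...) {
  cat("<pgx_coverage>\n")
  print(x$scenarios, row.names = FALSE)
  blocked <- x$attribution[x$attribution$count > 0, , drop = FALSE]
  if (nrow(blocked) > 0) {
    cat(sprintf("blocking attribution (%s):\n", x$attribution_mode))
    print(blocked, row.names = FALSE)
  }
  invisible(x)
}

#' Write a coverage report as JSON and TSV
#'
#' @param cov A `pgx_coverage` object.
#' @param json_path,scenario_tsv,attribution_tsv Output paths (`NULL`
#'   skips).
#' @return Invisibly, `cov`.
#' @export
write_coverage_report <- function(cov, json_path = NULL,
                                  scenario_tsv = NULL,
                                  attribution_tsv = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(scenarios = cov$scenarios,
                              attribution = cov$attribution,
                              attribution_mode = cov$attribution_mode),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(scenario_tsv)) {
    utils::write.table(cov$scenarios, scenario_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(attribution_tsv)) {
    utils::write.table(cov$attribution, attribution_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(cov)
}

#' Load a capability profile from YAML
#'
#' YAML list of entries `{match: {field_id | kind[, detail]}, status}`
#' plus optional `default_status`.
#'
#' @param path YAML file path.
#' @return A [capability_profile()].
#' @export
load_profile <- function(path) {
  if (!file.exists(path)) {
    pgx_error("MISSING_FILE", paste0("no such profile file: ", path))
  }
  x <- yaml::read_yaml(path)
  capability_profile(
    entries = x$entries,
    default_status = if (is.null(x$default_status)) "ABSENT"
                     else x$default_status
  )
}

#' Save a capability profile to YAML
#'
#' @param profile A [capability_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_profile <- function(profile, path) {
  yaml::write_yaml(list(default_status = profile$default_status,
                        entries = profile$entries), path)
  invisible(path)
}

#' Cross-tabulate rules by support category and presentation type
#'
#' @param catalog Non-empty [rule_catalog()] whose rules all carry a
#'   `general_category` and a `presentation_type` (pre-assigned or
#'   computed by [classify_catalog()] beforehand).
#' @param lexicon Certainty lexicon used to fill in presentation types
#'   for rules that lack one.
#' @return List with `table` (integer matrix category x presentation
#'   type), `category_counts` and `presentation_counts` (named margins).
#' @export
category_distribution <- function(catalog, lexicon = certainty_lexicon()) {
  if (length(catalog$rules) == 0) {
    pgx_error("EMPTY_CATALOG", "cannot tabulate an empty catalog")
  }
  cats <- vapply(catalog$rules, function(r) {
    if (is.null(r$general_category) ||
        !r$general_category %in% SUPPORT_CATEGORIES) {
      pgx_error("MISSING_CATEGORY",
                paste0("rule ", r$rule_id, " lacks a valid general_category"))
    }
    r$general_category
  }, character(1))
  types <- vapply(catalog$rules, function(r) {
    if (is.null(r$presentation_type)) classify_rule(r, lexicon)
    else r$presentation_type
  }, character(1))
  tab <- table(factor(cats, levels = SUPPORT_CATEGORIES),
               factor(types, levels = PRESENTATION_TYPES))
  m <- matrix(as.integer(tab), nrow = length(SUPPORT_CATEGORIES),
              dimnames = list(SUPPORT_CATEGORIES, PRESENTATION_TYPES))
  list(table = m,
       category_counts = rowSums(m),
       presentation_counts = colSums(m))
}
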