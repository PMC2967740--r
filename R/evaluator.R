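## Patient records and three-valued rule evaluation. Missing clinical data
## is a first-class outcome: a rule over absent data is INDETERMINATE, not
## silently unfired, and reports exactly which fields block it.

#' Construct a patient record
#'
#' The clinical facts a rule is evaluated against. Set-valued fields
#' (`medications_active`, `medications_considered`, `disease_statuses`,
#' `tumor_genotypes`) are closed-world when supplied — an empty set means
#' "known none" — and unknown when `NULL`. Map-valued fields
#' (`germline_genotypes`, `lab_values`) are open-world per key: a gene or
#' analyte absent from the map is unknown, not negative.
#'
#' @param patient_id Identifier string.
#' @param age Age in years (`NA` when unknown), non-negative.
#' @param sex `"female"`, `"male"`, or `NA`.
#' @param medications_active,medications_considered Character vectors of
#'   drug names (brands resolve through `synonyms`).
#' @param disease_statuses Character vector of disease names.
#' @param germline_genotypes Named list/vector gene -> diplotype string
#'   (normalized on construction, e.g. `"*3/*2"` becomes `"*2/*3"`).
#' @param tumor_genotypes Character vector of mutation identifiers.
#' @param lab_values Named list analyte -> `list(value=, units=)`.
#' @param synonyms Named alias -> canonical map (default the packaged
#'   table).
#' @return An object of class `pgx_patient`.
#' @export
patient_record <- function(patient_id, age = NA_real_, sex = NA_character_,
                           medications_active = character(),
                           medications_considered = character(),
                           disease_statuses = character(),
                           germline_genotypes = list(),
                           tumor_genotypes = character(),
                           lab_values = list(),
                           synonyms = load_drug_synonyms()) {
  if (!is.na(age) && age < 0) {
    pgx_error("INVALID_AGE", "age must be non-negative")
  }
  norm_set <- function(x, f = identity) {
    if (is.null(x)) NULL else unique(f(as.character(x)))
  }
  gg <- as.list(germline_genotypes)
  gg <- lapply(gg, normalize_diplotype)
  structure(
    list(patient_id = as.character(patient_id),
         age = as.numeric(age), sex = as.character(sex),
         medications_active = norm_set(medications_active,
                                       function(d) resolve_drug(d, synonyms)),
         medications_considered = norm_set(medications_considered,
                                           function(d) resolve_drug(d, synonyms)),
         disease_statuses = norm_set(disease_statuses, tolower),
         germline_genotypes = gg,
         tumor_genotypes = norm_set(tumor_genotypes),
         lab_values = as.list(lab_values)),
    class = "pgx_patient"
  )
}

#' Convert a patient record to raw facts
#'
#' @param patient A [patient_record()].
#' @return A [fact_base()] of `RAW` facts.
#' @export
patient_facts <- function(patient) {
  fs <- list()
  push <- function(f) fs[[length(fs) + 1]] <<- f
  for (d in patient$medications_active) push(fact("medication_active", d))
  for (d in patient$medications_considered) push(fact("medication_considered", d))
  for (d in patient$disease_statuses) push(fact("has_disease", d))
  for (g in names(patient$germline_genotypes)) {
    push(fact("genotype", g, patient$germline_genotypes[[g]]))
  }
  for (m in patient$tumor_genotypes) push(fact("tumor_mutation", m))
  if (!is.na(patient$age)) push(fact("age", patient$age))
  if (!is.na(patient$sex)) push(fact("sex", patient$sex))
  for (an in names(patient$lab_values)) {
    lv <- patient$lab_values[[an]]
    push(fact("lab", an, lv$value, lv$units))
  }
  fact_base(fs)
}

## Kleene strong three-valued connectives ------------------------------------

TV <- c("TRUE", "FALSE", "UNKNOWN")

#' Kleene three-valued AND / OR / NOT
#'
#' Strong Kleene connectives over `"TRUE"` / `"FALSE"` / `"UNKNOWN"`:
#' FALSE dominates AND, TRUE dominates OR, NOT preserves UNKNOWN.
#'
#' @param values Character vector of truth values (for AND/OR).
#' @param value Single truth value (for NOT).
#' @return A single truth value.
#' @export
kleene_and <- function(values) {
  if (any(values == "FALSE")) "FALSE"
  else if (any(values == "UNKNOWN")) "UNKNOWN"
  else "TRUE"
}

#' @rdname kleene_and
#' @export
kleene_or <- function(values) {
  if (any(values == "TRUE")) "TRUE"
  else if (any(values == "UNKNOWN")) "UNKNOWN"
  else "FALSE"
}

#' @rdname kleene_and
#' @export
kleene_not <- function(value) {
  switch(value, "TRUE" = "FALSE", "FALSE" = "TRUE", "UNKNOWN")
}

## Condition evaluation -------------------------------------------------------

#' Evaluate one condition against a patient under three-valued logic
#'
#' Returns `"TRUE"` when a satisfying fact exists, `"UNKNOWN"` when the
#' referenced data is not on record (gene absent from the genotype map,
#' analyte absent from the labs, `NULL` medication list, unknown age),
#' and `"FALSE"` when data is present but unsatisfying. Lab comparisons
#' require matching units and raise `UNIT_MISMATCH` otherwise.
#'
#' @param cond A [condition()].
#' @param patient A [patient_record()].
#' @param facts A [fact_base()], normally the supporting-knowledge closure
#'   of [patient_facts()]; derived phenotype/drug-class conditions read it.
#' @param synonyms Drug synonym map.
#' @return `"TRUE"`, `"FALSE"`, or `"UNKNOWN"`.
#' @export
eval_condition <- function(cond, patient, facts = patient_facts(patient),
                           synonyms = load_drug_synonyms()) {
  a <- cond$args
  set_member <- function(set, x) {
    if (is.null(set)) "UNKNOWN" else if (x %in% set) "TRUE" else "FALSE"
  }
  switch(cond$predicate,
    MEDICATION_ACTIVE = set_member(patient$medications_active,
                                   resolve_drug(a$drug, synonyms)),
    MEDICATION_CONSIDERED = set_member(patient$medications_considered,
                                       resolve_drug(a$drug, synonyms)),
    HAS_DISEASE = set_member(patient$disease_statuses, tolower(a$disease)),
    TUMOR_HAS_MUTATION = set_member(patient$tumor_genotypes, a$mutation),
    HAS_VARIANT = {
      dip <- patient$germline_genotypes[[a$gene]]
      if (is.null(dip)) "UNKNOWN"
      else if (grepl("/", a$allele, fixed = TRUE)) {
        if (identical(dip, normalize_diplotype(a$allele))) "TRUE" else "FALSE"
      } else if (diplotype_has_allele(dip, a$allele)) "TRUE" else "FALSE"
    },
    HAS_PHENOTYPE_CLASS = {
      if (has_fact(facts, fact("phenotype_class", a$gene, a$class))) "TRUE"
      else if (!is.null(patient$germline_genotypes[[a$gene]])) "FALSE"
      else "UNKNOWN"
    },
    TAKING_DRUG_IN_CLASS = {
      if (has_fact(facts, fact("taking_drug_in_class", a$class_id))) "TRUE"
      else if (is.null(patient$medications_active)) "UNKNOWN"
      else "FALSE"
    },
    AGE_COMPARE = {
      if (is.na(patient$age)) "UNKNOWN"
      else if (compare_values(patient$age, a$comparator, a$threshold)) "TRUE"
      else "FALSE"
    },
    LAB_COMPARE = {
      lv <- patient$lab_values[[a$analyte]]
      if (is.null(lv)) "UNKNOWN"
      else if (!identical(lv$units, a$units)) {
        pgx_error("UNIT_MISMATCH",
                  paste0("lab ", a$analyte, ": record in ", lv$units,
                         ", condition in ", a$units))
      }
      else if (compare_values(lv$value, a$comparator, a$threshold)) "TRUE"
      else "FALSE"
    },
    pgx_error("UNKNOWN_PREDICATE", paste0("unknown predicate ", cond$predicate))
  )
}

# evaluate an antecedent tree; returns list(value, unknown_leaves, true_leaves)
eval_tree <- function(tree, patient, facts, synonyms) {
  if (identical(tree$node, "COND")) {
    v <- eval_condition(tree, patient, facts, synonyms)
    return(list(value = v,
                unknown_leaves = if (v == "UNKNOWN") list(tree) else list(),
                true_leaves = if (v == "TRUE") list(tree) else list()))
  }
  kids <- lapply(tree$children, eval_tree, patient = patient, facts = facts,
                 synonyms = synonyms)
  vals <- vapply(kids, function(k) k$value, character(1))
  value <- switch(tree$node,
    AND = kleene_and(vals),
    OR = kleene_or(vals),
    NOT = kleene_not(vals[[1]])
  )
  list(value = value,
       unknown_leaves = unlist(lapply(kids, `[[`, "unknown_leaves"),
                               recursive = FALSE),
       true_leaves = unlist(lapply(kids, `[[`, "true_leaves"),
                            recursive = FALSE))
}

#' Evaluate one rule against a patient
#'
#' Derives the supporting-knowledge closure of the patient's raw facts,
#' then evaluates the antecedent under Kleene three-valued logic. The
#' rule `FIRED` iff the antecedent is TRUE (never on UNKNOWN — the
#' patient-safety conservative default); `INDETERMINATE` iff UNKNOWN,
#' with the blocking fields listed; otherwise `NOT_FIRED`.
#'
#' @param rule A valid [pgx_rule()].
#' @param patient A [patient_record()].
#' @param sk_rules Supporting-knowledge rules (default the packaged set);
#'   use `list()` to evaluate on raw EMR data alone.
#' @param lexicon Certainty lexicon, used to classify the alert when the
#'   rule carries no pre-assigned presentation type.
#' @param synonyms Drug synonym map.
#' @return List with `status` (`"FIRED"`, `"NOT_FIRED"`,
#'   `"INDETERMINATE"`), `missing_fields` (list of `pgx_field`, non-empty
#'   iff INDETERMINATE), and `alert` (`NULL` unless FIRED; a `pgx_alert`
#'   with `rule_id`, `presentation_type`, `message`,
#'   `matched_conditions`).
#' @export
evaluate_rule <- function(rule, patient,
                          sk_rules = default_supporting_knowledge(),
                          lexicon = certainty_lexicon(),
                          synonyms = load_drug_synonyms()) {
  v <- validate_rule(rule)
  if (nrow(v) > 0) {
    pgx_error("INVALID_RULE",
              paste0("rule ", rule$rule_id, " fails validation: ",
                     paste(unique(v$code), collapse = ", ")))
  }
  facts <- derive_facts(patient_facts(patient), sk_rules)
  res <- eval_tree(rule$antecedent, patient, facts, synonyms)
  status <- switch(res$value, "TRUE" = "FIRED", "FALSE" = "NOT_FIRED",
                   "INDETERMINATE")
  missing_fields <- list()
  if (status == "INDETERMINATE") {
    flds <- lapply(res$unknown_leaves, function(l) l$field)
    ids <- vapply(flds, function(f) f$field_id, character(1))
    missing_fields <- flds[!duplicated(ids)][order(unique(ids))]
  }
  alert <- NULL
  if (status == "FIRED") {
    ptype <- if (is.null(rule$presentation_type)) {
      classify_rule(rule, lexicon)
    } else rule$presentation_type
    alert <- structure(
      list(rule_id = rule$rule_id,
           presentation_type = ptype,
           message = vapply(rule$consequents, function(s) s$text,
                            character(1)),
           matched_conditions = res$true_leaves),
      class = "pgx_alert"
    )
  }
  list(status = status, missing_fields = missing_fields, alert = alert)
}

#' Evaluate a catalog against a patient and collect alerts
#'
#' @param catalog Non-empty [rule_catalog()].
#' @param patient A [patient_record()].
#' @param sk_rules,lexicon,synonyms As in [evaluate_rule()].
#' @return List with `alerts` (list of `pgx_alert`, sorted most severe
#'   first, ties broken by rule id) and `statuses` (named character
#'   vector rule_id -> status).
#' @export
evaluate_catalog <- function(catalog, patient,
                             sk_rules = default_supporting_knowledge(),
                             lexicon = certainty_lexicon(),
                             synonyms = load_drug_synonyms()) {
  if (length(catalog$rules) == 0) {
    pgx_error("EMPTY_CATALOG", "cannot evaluate an empty catalog")
  }
  results <- lapply(catalog$rules, evaluate_rule, patient = patient,
                    sk_rules = sk_rules, lexicon = lexicon,
                    synonyms = synonyms)
  ids <- vapply(catalog$rules, function(r) r$rule_id, character(1))
  statuses <- stats::setNames(
    vapply(results, function(r) r$status, character(1)), ids)
  alerts <- Filter(Negate(is.null), lapply(results, `[[`, "alert"))
  if (length(alerts) > 0) {
    sev <- vapply(alerts, function(a) severity_rank(a$presentation_type),
                  integer(1))
    aid <- vapply(alerts, function(a) a$rule_id, character(1))
    alerts <- alerts[order(-sev, aid)]
  }
  list(alerts = alerts, statuses = statuses)
}

## Patient / alert I/O --------------------------------------------------------

#' Load patient records from a JSON file
#'
#' One JSON object per patient (an array of objects), field names exactly
#' as in [patient_record()]; `lab_values` as a map analyte ->
#' `{value, units}`.
#'
#' @param path JSON file path.
#' @param synonyms Drug synonym map.
#' @return List of [patient_record()]s.
#' @export
load_patients <- function(path, synonyms = load_drug_synonyms()) {
  if (!file.exists(path)) {
    pgx_error("MISSING_FILE", paste0("no such patient file: ", path))
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  lapply(raw, function(p) {
    if (is.null(p$patient_id)) {
      pgx_error("SCHEMA_VIOLATION",
                paste0(path, ": patient object missing patient_id"))
    }
    patient_record(
      patient_id = p$patient_id,
      age = if (is.null(p$age)) NA_real_ else p$age,
      sex = if (is.null(p$sex)) NA_character_ else p$sex,
      medications_active = p$medications_active,
      medications_considered = p$medications_considered,
      disease_statuses = p$disease_statuses,
      germline_genotypes = if (is.null(p$germline_genotypes)) list()
                           else p$germline_genotypes,
      tumor_genotypes = p$tumor_genotypes,
      lab_values = if (is.null(p$lab_values)) list() else p$lab_values,
      synonyms = synonyms
    )
  })
}

#' Write alerts as JSON lines and a readable text report
#'
#' @param alerts List of alerts from [evaluate_catalog()].
#' @param jsonl_path,text_path Output paths (either may be `NULL`).
#' @return Invisibly, `alerts`.
#' @export
write_alerts <- function(alerts, jsonl_path = NULL, text_path = NULL) {
  if (!is.null(jsonl_path)) {
    lines <- vapply(alerts, function(a) {
      jsonlite::toJSON(list(rule_id = a$rule_id,
                            presentation_type = a$presentation_type,
                            message = a$message),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, jsonl_path)
  }
  if (!is.null(text_path)) {
    lines <- unlist(lapply(alerts, function(a) {
      c(sprintf("[%s] rule %s", a$presentation_type, a$rule_id),
        paste0("  ", a$message), "")
    }))
    writeLines(lines, text_path)
  }
  invisible(alerts)
}
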