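## Core domain types: clinical-data fields, conditions, condition trees,
## consequent statements, rules, catalogs.

#' Construct a clinical-data field
#'
#' A clinical-data field names one piece of patient data a rule condition
#' reads, together with where an EMR would hold it: the
#' inpatient/outpatient database, a laboratory system, or supporting
#' knowledge (a derived class such as "poor metabolizer").
#'
#' @param field_id Short unique identifier string.
#' @param kind One of `MEDICATION`, `MEDICATION_LIST`, `DISEASE_STATUS`,
#'   `GERMLINE_VARIANT_STATUS`, `TUMOR_PATHOGEN_GENOTYPE`, `DEMOGRAPHIC`,
#'   `LAB_VALUE`, `DERIVED_PHENOTYPE_CLASS`.
#' @param source One of `INPATIENT_OUTPATIENT_DB`, `LABORATORY_DB`,
#'   `SUPPORTING_KNOWLEDGE`. A `DERIVED_PHENOTYPE_CLASS` kind must have
#'   source `SUPPORTING_KNOWLEDGE`.
#' @param detail Free-text qualifier (gene symbol, drug name, disease name).
#' @return An object of class `pgx_field`.
#' @export
clinical_data_field <- function(field_id, kind, source, detail = "") {
  kind <- match.arg(kind, FIELD_KINDS)
  source <- match.arg(source, FIELD_SOURCES)
  structure(
    list(field_id = as.character(field_id), kind = kind,
         source = source, detail = as.character(detail)),
    class = "pgx_field"
  )
}

#' Construct a rule condition
#'
#' A condition is a typed predicate over one clinical-data field. Argument
#' names are predicate-specific: drug names (`drug`), drug-class ids
#' (`class_id`), disease names (`disease`), gene + star allele or diplotype
#' (`gene`, `allele`), phenotype classes (`gene`, `class`), mutation ids
#' (`mutation`), and comparator predicates (`comparator`, `threshold`,
#' plus `analyte` and `units` for labs).
#'
#' @param predicate One of the condition predicates:
#'   `MEDICATION_ACTIVE`, `MEDICATION_CONSIDERED`,
#'   `TAKING_DRUG_IN_CLASS`, `HAS_DISEASE`, `HAS_VARIANT`,
#'   `HAS_PHENOTYPE_CLASS`, `TUMOR_HAS_MUTATION`, `AGE_COMPARE`,
#'   `LAB_COMPARE`.
#' @param args Named list of predicate-specific arguments.
#' @param field The [clinical_data_field()] this condition reads.
#' @return An object of class `pgx_condition` (also a leaf `pgx_condtree`).
#' @export
condition <- function(predicate, args, field) {
  predicate <- match.arg(predicate, PREDICATES)
  stopifnot(inherits(field, "pgx_field"))
  structure(
    list(node = "COND", predicate = predicate, args = args, field = field),
    class = c("pgx_condition", "pgx_condtree")
  )
}

# required argument names per predicate (used by validation)
predicate_arg_spec <- function(predicate) {
  switch(predicate,
    MEDICATION_ACTIVE = "drug",
    MEDICATION_CONSIDERED = "drug",
    TAKING_DRUG_IN_CLASS = "class_id",
    HAS_DISEASE = "disease",
    HAS_VARIANT = c("gene", "allele"),
    HAS_PHENOTYPE_CLASS = c("gene", "class"),
    TUMOR_HAS_MUTATION = "mutation",
    AGE_COMPARE = c("comparator", "threshold"),
    LAB_COMPARE = c("analyte", "comparator", "threshold", "units")
  )
}

#' Combine conditions with AND / OR / NOT
#'
#' Condition trees give rule antecedents an explicit boolean structure so
#' that evaluation and data-requirement extraction are mechanical. `AND`
#' and `OR` require at least two children.
#'
#' @param ... Child condition trees (conditions or nested combinations).
#' @param x A single child condition tree (for `cnd_not`).
#' @return An object of class `pgx_condtree`.
#' @export
cnd_and <- function(...) {
  children <- list(...)
  if (length(children) < 2) {
    pgx_error("BAD_TREE", "AND requires at least 2 children")
  }
  structure(list(node = "AND", children = children), class = "pgx_condtree")
}

#' @rdname cnd_and
#' @export
cnd_or <- function(...) {
  children <- list(...)
  if (length(children) < 2) {
    pgx_error("BAD_TREE", "OR requires at least 2 children")
  }
  structure(list(node = "OR", children = children), class = "pgx_condtree")
}

#' @rdname cnd_and
#' @export
cnd_not <- function(x) {
  stopifnot(inherits(x, "pgx_condtree"))
  structure(list(node = "NOT", children = list(x)), class = "pgx_condtree")
}

# depth-first list of leaf conditions of a tree
tree_leaves <- function(tree) {
  if (identical(tree$node, "COND")) return(list(tree))
  unlist(lapply(tree$children, tree_leaves), recursive = FALSE)
}

#' Construct a consequent (THEN) statement
#'
#' The consequent of an if-then rule, carrying two curator annotations the
#' presentation-type classifier needs: whether the statement specifies a
#' clear, vague, or no action, and whether it states potential
#' consequences. Both annotations reflect manual review of the label
#' passage; the lexical certainty scan supplies the remaining signal.
#'
#' @param text Consequent sentence (non-empty).
#' @param action_specificity `"NONE"`, `"VAGUE"` (directionless, e.g.
#'   "should be adjusted"), or `"CLEAR"` (a concrete executable
#'   instruction, e.g. a specific dose).
#' @param consequence_flag Logical: does the statement state potential
#'   consequences (bleeding risk, toxicity, ...)?
#' @return An object of class `pgx_statement`.
#' @export
then_statement <- function(text, action_specificity = "NONE",
                           consequence_flag = FALSE) {
  action_specificity <- match.arg(action_specificity, ACTION_SPECIFICITIES)
  structure(
    list(text = as.character(text),
         action_specificity = action_specificity,
         consequence_flag = isTRUE(consequence_flag)),
    class = "pgx_statement"
  )
}

#' Construct a PGx decision-support rule
#'
#' @param rule_id Unique identifier within a catalog.
#' @param drug Drug name (generic preferred; brands resolve through the
#'   synonym table at evaluation time).
#' @param biomarker Gene or mutation identifier.
#' @param antecedent A `pgx_condtree` with at least one leaf condition.
#' @param consequents List of [then_statement()]s (at least one).
#' @param general_category One of the seven decision-support categories
#'   (dose adjustment, patient monitoring, pre-treatment consideration,
#'   benefit prediction, testing guidance, coadministration, patient
#'   communication).
#' @param presentation_type Optional pre-assigned presentation type; when
#'   `NULL` the classifier computes it.
#' @param provenance Drug-label section string.
#' @return An object of class `pgx_rule`.
#' @export
pgx_rule <- function(rule_id, drug, biomarker, antecedent, consequents,
                     general_category, presentation_type = NULL,
                     provenance = "") {
  structure(
    list(rule_id = as.character(rule_id),
         drug = as.character(drug),
         biomarker = as.character(biomarker),
         antecedent = antecedent,
         consequents = consequents,
         general_category = as.character(general_category),
         presentation_type = presentation_type,
         provenance = as.character(provenance)),
    class = "pgx_rule"
  )
}

#' Construct a rule catalog
#'
#' @param rules List of [pgx_rule()] objects with pairwise-distinct ids.
#' @param name,version Catalog metadata.
#' @param seed Creation seed when the catalog is synthetic, else `NULL`.
#' @param ground_truth Optional list of planted labels (synthetic catalogs
#'   store their ground truth here for recovery tests).
#' @return An object of class `pgx_catalog`.
#' @export
rule_catalog <- function(rules, name = "catalog", version = "1",
                         seed = NULL, ground_truth = NULL) {
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  if (anyDuplicated(ids)) {
    pgx_error("DUPLICATE_RULE_ID",
              paste0("duplicate rule_id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(
    list(rules = rules,
         metadata = list(name = name, version = as.character(version),
                         seed = if (is.null(seed)) NULL else as.integer(seed),
                         ground_truth = ground_truth)),
    class = "pgx_catalog"
  )
}

#' @export
length.pgx_catalog <- function(x) length(x$rules)

#' @export
print.pgx_catalog <- function(x, ...) {
  cat(sprintf("<pgx_catalog '%s'> %d rule(s)\n", x$metadata$name,
              length(x$rules)))
  invisible(x)
}

#' @export
print.pgx_rule <- function(x, ...) {
  cat(sprintf("<pgx_rule %s> %s / %s [%s]\n", x$rule_id, x$drug,
              x$biomarker, x$general_category))
  invisible(x)
}

## Validation ----------------------------------------------------------------

violation <- function(code, message, where = "") {
  data.frame(code = code, message = message, where = where,
             stringsAsFactors = FALSE)
}

validate_condition <- function(cond, where) {
  v <- violation(character(), character(), character())
  spec <- predicate_arg_spec(cond$predicate)
  missing <- setdiff(spec, names(cond$args))
  if (length(missing) > 0) {
    v <- rbind(v, violation("INCOMPLETE_PREDICATE_ARGS",
      paste0(cond$predicate, " missing arg(s): ",
             paste(missing, collapse = ", ")), where))
  }
  if (cond$predicate %in% c("AGE_COMPARE", "LAB_COMPARE") &&
      "threshold" %in% names(cond$args)) {
    thr <- cond$args$threshold
    if (!is.numeric(thr) || length(thr) != 1 || is.na(thr)) {
      v <- rbind(v, violation("INCOMPLETE_PREDICATE_ARGS",
        paste0(cond$predicate, " threshold must be a single number"), where))
    }
  }
  if ("comparator" %in% names(cond$args) &&
      !identical(cond$args$comparator %in% COMPARATORS, TRUE)) {
    v <- rbind(v, violation("INVALID_COMPARATOR",
      paste0("comparator must be one of ", paste(COMPARATORS, collapse = " ")),
      where))
  }
  if (!inherits(cond$field, "pgx_field") || !nzchar(cond$field$field_id)) {
    v <- rbind(v, violation("MISSING_FIELD",
      "condition must reference a clinical-data field with non-empty id",
      where))
  } else if (cond$field$kind == "DERIVED_PHENOTYPE_CLASS" &&
             cond$field$source != "SUPPORTING_KNOWLEDGE") {
    v <- rbind(v, violation("FIELD_SOURCE_MISMATCH",
      "DERIVED_PHENOTYPE_CLASS fields must come from SUPPORTING_KNOWLEDGE",
      where))
  }
  v
}

validate_tree <- function(tree, where) {
  if (identical(tree$node, "COND")) return(validate_condition(tree, where))
  v <- violation(character(), character(), character())
  if (tree$node %in% c("AND", "OR") && length(tree$children) < 2) {
    v <- rbind(v, violation("BAD_TREE",
      paste0(tree$node, " node with fewer than 2 children"), where))
  }
  for (i in seq_along(tree$children)) {
    v <- rbind(v, validate_tree(tree$children[[i]],
                                paste0(where, "/", tolower(tree$node), i)))
  }
  v
}

#' Validate a rule against the structural invariants
#'
#' Checks every invariant of the rule model and returns each violation as
#' a row with a machine-readable code; a valid rule yields a zero-row
#' report. Violations are data, not exceptions.
#'
#' @param rule A [pgx_rule()].
#' @return A data frame with columns `code`, `message`, `where`; zero rows
#'   means valid.
#' @export
#' @examples
#' v <- validate_rule(table2_rules()$rules[[1]])
#' nrow(v) # 0
validate_rule <- function(rule) {
  v <- violation(character(), character(), character())
  if (!nzchar(rule$rule_id)) {
    v <- rbind(v, violation("MISSING_RULE_ID", "rule_id must be non-empty"))
  }
  if (!nzchar(rule$drug)) {
    v <- rbind(v, violation("MISSING_DRUG", "drug must be non-empty"))
  }
  if (!nzchar(rule$biomarker)) {
    v <- rbind(v, violation("MISSING_BIOMARKER", "biomarker must be non-empty"))
  }
  if (!inherits(rule$antecedent, "pgx_condtree") ||
      length(tree_leaves(rule$antecedent)) == 0) {
    v <- rbind(v, violation("MISSING_ANTECEDENT",
      "antecedent must contain at least one leaf condition"))
  } else {
    v <- rbind(v, validate_tree(rule$antecedent, "antecedent"))
  }
  if (length(rule$consequents) == 0) {
    v <- rbind(v, violation("MISSING_CONSEQUENT",
      "rule must carry at least one consequent statement"))
  } else {
    for (i in seq_along(rule$consequents)) {
      s <- rule$consequents[[i]]
      if (!inherits(s, "pgx_statement") || !nzchar(s$text)) {
        v <- rbind(v, violation("EMPTY_STATEMENT",
          "consequent text must be non-empty", paste0("consequent", i)))
      }
    }
  }
  if (!rule$general_category %in% SUPPORT_CATEGORIES) {
    v <- rbind(v, violation("INVALID_CATEGORY",
      paste0("general_category must be one of ",
             paste(SUPPORT_CATEGORIES, collapse = ", "))))
  }
  if (!is.null(rule$presentation_type) &&
      !rule$presentation_type %in% PRESENTATION_TYPES) {
    v <- rbind(v, violation("INVALID_PRESENTATION_TYPE",
      "presentation_type must be INFORMATION/RECOMMENDATION/WARNING"))
  }
  v
}

#' Validate every rule in a catalog
#'
#' @param catalog A [rule_catalog()].
#' @return Data frame of violations across all rules (with a `rule_id`
#'   column); zero rows means the catalog is structurally valid.
#' @export
validate_catalog <- function(catalog) {
  out <- lapply(catalog$rules, function(r) {
    v <- validate_rule(r)
    if (nrow(v) > 0) v$rule_id <- r$rule_id
    v
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0) {
    return(data.frame(code = character(), message = character(),
                      where = character(), rule_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## Data-requirement extraction -----------------------------------------------

#' Extract the clinical-data fields a rule's antecedent reads
#'
#' Returns the union of fields referenced by the leaf conditions,
#' partitioned by data source: EMR-resident fields
#' (inpatient/outpatient and laboratory databases) versus
#' supporting-knowledge requirements (derived classes the EMR cannot hold
#' directly). Output ordering is deterministic (sorted by field id) and
#' invariant under reordering of AND/OR children.
#'
#' @param rule A valid [pgx_rule()].
#' @return List with components `fields` (list of `pgx_field`, EMR
#'   sources) and `supporting_knowledge` (list of `pgx_field` with source
#'   `SUPPORTING_KNOWLEDGE`), each sorted by `field_id` and deduplicated.
#' @export
#' @examples
#' req <- antecedent_fields(table2_rules()$rules[[1]])
#' vapply(req$fields, function(f) f$field_id, character(1))
antecedent_fields <- function(rule) {
  v <- validate_rule(rule)
  if (nrow(v) > 0) {
    pgx_error("INVALID_RULE",
              paste0("rule ", rule$rule_id, " fails validation: ",
                     paste(unique(v$code), collapse = ", ")))
  }
  leaves <- tree_leaves(rule$antecedent)
  fields <- lapply(leaves, function(l) l$field)
  ids <- vapply(fields, function(f) f$field_id, character(1))
  fields <- fields[!duplicated(ids)]
  ids <- ids[!duplicated(ids)]
  fields <- fields[order(ids)]
  src <- vapply(fields, function(f) f$source, character(1))
  list(
    fields = fields[src != "SUPPORTING_KNOWLEDGE"],
    supporting_knowledge = fields[src == "SUPPORTING_KNOWLEDGE"]
  )
}

# all fields of a rule regardless of source, sorted/deduplicated
all_rule_fields <- function(rule) {
  req <- antecedent_fields(rule)
  c(req$fields, req$supporting_knowledge)
}

## Star-allele helpers --------------------------------------------------------

#' Normalize a star-allele diplotype
#'
#' Diplotypes are written `*a/*b` with alleles ordered ascending
#' numerically (`*3/*2` becomes `*2/*3`) so that exact diplotype matching
#' is well defined regardless of input order. Non-numeric allele names
#' sort lexicographically after numeric ones.
#'
#' @param diplotype String of the form `"*2/*3"` (an optional gene prefix
#'   such as `"CYP2C9*2/*3"` is stripped).
#' @return Normalized `"*a/*b"` string.
#' @export
#' @examples
#' normalize_diplotype("*3/*2") # "*2/*3"
#' normalize_diplotype("CYP2C9*3/*1") # "*1/*3"
normalize_diplotype <- function(diplotype) {
  d <- gsub("^[A-Za-z0-9]+(?=\\*)", "", diplotype, perl = TRUE)
  parts <- strsplit(d, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(grepl("^\\*", parts))) {
    pgx_error("INVALID_DIPLOTYPE",
              paste0("cannot parse diplotype: ", diplotype))
  }
  nums <- suppressWarnings(as.numeric(sub("^\\*", "", parts)))
  key <- ifelse(is.na(nums), Inf, nums)
  ord <- order(key, sub("^\\*", "", parts))
  paste(parts[ord], collapse = "/")
}

# does a diplotype carry a given single allele on either chromosome?
diplotype_has_allele <- function(diplotype, allele) {
  parts <- strsplit(normalize_diplotype(diplotype), "/", fixed = TRUE)[[1]]
  allele %in% parts
}
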