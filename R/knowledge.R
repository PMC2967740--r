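## Forward-chaining derivation of intermediate clinical facts (phenotype
## classes, demographic classes, drug-class membership) from raw patient
## data. Ground, positive facts only — no negation, no retraction — so the
## closure is a unique least fixpoint and derivation is monotone.

## Facts ---------------------------------------------------------------------

#' Construct a ground fact
#'
#' Facts are predicate/argument tuples over a lowercase fact vocabulary:
#' `medication_active(drug)`, `medication_considered(drug)`,
#' `has_disease(d)`, `genotype(gene, diplotype)`, `tumor_mutation(m)`,
#' `age(years)`, `sex(s)`, `lab(analyte, value, units)`,
#' `phenotype_class(gene, class)`, `demographic_class(class)`,
#' `taking_drug_in_class(class_id)`. Arguments are stored as character
#' strings; numeric arguments (age, lab values) are parsed on comparison.
#'
#' @param predicate Fact predicate name.
#' @param ... Argument values (coerced to character).
#' @return An object of class `pgx_fact`.
#' @export
#' @examples
#' fact("phenotype_class", "CYP2C9", "poor_metabolizer")
fact <- function(predicate, ...) {
  args <- as.character(unlist(list(...), use.names = FALSE))
  structure(list(predicate = as.character(predicate), args = args),
            class = "pgx_fact")
}

fact_key <- function(f) paste(c(f$predicate, f$args), collapse = "\x1f")

is_var <- function(x) is.character(x) && length(x) == 1 && startsWith(x, "?")

#' Construct a fact base
#'
#' A set of ground facts with per-fact provenance: `"RAW"` for facts
#' asserted directly (patient data), or the id of the supporting-knowledge
#' rule that derived them.
#'
#' @param facts List of [fact()] objects.
#' @param provenance Character vector of provenance labels, recycled to
#'   the number of facts (default all `"RAW"`).
#' @return An object of class `pgx_factbase`.
#' @export
fact_base <- function(facts = list(), provenance = "RAW") {
  keys <- vapply(facts, fact_key, character(1))
  provenance <- rep_len(provenance, length(facts))
  dup <- duplicated(keys)
  structure(
    list(facts = stats::setNames(facts[!dup], keys[!dup]),
         provenance = stats::setNames(provenance[!dup], keys[!dup])),
    class = "pgx_factbase"
  )
}

#' @export
length.pgx_factbase <- function(x) length(x$facts)

#' Test whether a fact base contains a fact
#'
#' @param base A [fact_base()].
#' @param f A [fact()].
#' @return Logical scalar.
#' @export
has_fact <- function(base, f) fact_key(f) %in% names(base$facts)

# add facts (with provenance) to a base; existing facts keep their original
# provenance — first derivation wins
add_facts <- function(base, facts, provenance) {
  for (i in seq_along(facts)) {
    k <- fact_key(facts[[i]])
    if (!k %in% names(base$facts)) {
      base$facts[[k]] <- facts[[i]]
      base$provenance[[k]] <- provenance[i]
    }
  }
  base
}

## Fact patterns (supporting-knowledge antecedent leaves) --------------------

#' Construct a fact pattern for a supporting-knowledge antecedent
#'
#' A leaf that matches facts of a given predicate. Arguments may be
#' constants or variables (strings starting `?`); variables bind to the
#' matching fact's argument and may be reused in the rule's derived fact.
#'
#' @param predicate Fact predicate name.
#' @param ... Argument values or `?variables`.
#' @return A leaf usable in a supporting-knowledge antecedent tree.
#' @export
#' @examples
#' fact_pattern("medication_active", "?drug")
fact_pattern <- function(predicate, ...) {
  args <- as.character(unlist(list(...), use.names = FALSE))
  structure(list(node = "FACT", predicate = as.character(predicate),
                 args = args),
            class = c("pgx_fact_pattern", "pgx_condtree"))
}

# variables appearing in a pattern or condition leaf
leaf_vars <- function(leaf) {
  args <- if (identical(leaf$node, "FACT")) leaf$args else
    unlist(leaf$args, use.names = FALSE)
  args <- as.character(args)
  args[startsWith(args, "?")]
}

# bindings (list of named lists) under which `leaf` matches the fact base
match_leaf <- function(leaf, base) {
  if (identical(leaf$node, "FACT")) {
    out <- list()
    for (f in base$facts) {
      if (!identical(f$predicate, leaf$predicate)) next
      if (length(f$args) != length(leaf$args)) next
      b <- list()
      ok <- TRUE
      for (j in seq_along(leaf$args)) {
        a <- leaf$args[[j]]
        if (is_var(a)) {
          if (!is.null(b[[a]]) && !identical(b[[a]], f$args[[j]])) {
            ok <- FALSE; break
          }
          b[[a]] <- f$args[[j]]
        } else if (!identical(a, f$args[[j]])) {
          ok <- FALSE; break
        }
      }
      if (ok) out[[length(out) + 1]] <- b
    }
    return(out)
  }
  # typed condition leaf: ground, matches or not
  if (sk_eval_condition(leaf, base)) list(list()) else list()
}

# two-valued (closed-world) evaluation of a ground typed condition against
# a fact base — used both by the engine and, for TRUE-detection, by the
# patient evaluator
sk_eval_condition <- function(cond, base) {
  facts_of <- function(pred) {
    Filter(function(f) identical(f$predicate, pred), base$facts)
  }
  a <- cond$args
  switch(cond$predicate,
    MEDICATION_ACTIVE = has_fact(base, fact("medication_active",
                                            canonical_drug(a$drug))),
    MEDICATION_CONSIDERED = has_fact(base, fact("medication_considered",
                                                canonical_drug(a$drug))),
    HAS_DISEASE = has_fact(base, fact("has_disease", tolower(a$disease))),
    TAKING_DRUG_IN_CLASS = has_fact(base, fact("taking_drug_in_class",
                                               a$class_id)),
    HAS_PHENOTYPE_CLASS = has_fact(base, fact("phenotype_class",
                                              a$gene, a$class)),
    TUMOR_HAS_MUTATION = has_fact(base, fact("tumor_mutation", a$mutation)),
    HAS_VARIANT = {
      gfacts <- facts_of("genotype")
      any(vapply(gfacts, function(f) {
        if (!identical(f$args[[1]], a$gene)) return(FALSE)
        if (grepl("/", a$allele, fixed = TRUE)) {
          identical(f$args[[2]], normalize_diplotype(a$allele))
        } else {
          diplotype_has_allele(f$args[[2]], a$allele)
        }
      }, logical(1)))
    },
    AGE_COMPARE = {
      afacts <- facts_of("age")
      any(vapply(afacts, function(f) {
        compare_values(as.numeric(f$args[[1]]), a$comparator, a$threshold)
      }, logical(1)))
    },
    LAB_COMPARE = {
      lfacts <- facts_of("lab")
      any(vapply(lfacts, function(f) {
        identical(f$args[[1]], a$analyte) &&
          identical(f$args[[3]], a$units) &&
          compare_values(as.numeric(f$args[[2]]), a$comparator, a$threshold)
      }, logical(1)))
    },
    pgx_error("UNKNOWN_PREDICATE", paste0("unknown predicate ", cond$predicate))
  )
}

compare_values <- function(value, comparator, threshold) {
  switch(comparator,
    "<" = value < threshold,
    "<=" = value <= threshold,
    "=" = value == threshold,
    ">=" = value >= threshold,
    ">" = value > threshold,
    pgx_error("INVALID_COMPARATOR", paste0("bad comparator ", comparator))
  )
}

## Supporting-knowledge rules -------------------------------------------------

#' Construct a supporting-knowledge rule
#'
#' A derivation rule producing one intermediate fact from facts already
#' in the base, e.g. "IF genotype CYP2C9*2/*3 THEN the patient is a
#' CYP2C9 poor metabolizer" or "IF age < 18 THEN the patient is a child".
#' Antecedents are condition trees over fact patterns and/or ground typed
#' conditions; `NOT` is rejected (derivation must stay monotone), and
#' variables are only allowed in AND-only antecedents.
#'
#' @param sk_id Unique rule id.
#' @param antecedent A `pgx_condtree` (leaf, `cnd_and`, or `cnd_or` of
#'   leaves; may mix [fact_pattern()] and [condition()] leaves).
#' @param derived A [fact()] template; arguments may reuse antecedent
#'   `?variables`, all of which must be bound by the antecedent.
#' @return An object of class `pgx_sk_rule`.
#' @export
sk_rule <- function(sk_id, antecedent, derived) {
  stopifnot(inherits(antecedent, "pgx_condtree"), inherits(derived, "pgx_fact"))
  r <- structure(list(sk_id = as.character(sk_id), antecedent = antecedent,
                      derived = derived),
                 class = "pgx_sk_rule")
  check_sk_rule(r)
  r
}

tree_has_not <- function(tree) {
  if (identical(tree$node, "NOT")) return(TRUE)
  if (tree$node %in% c("AND", "OR")) {
    return(any(vapply(tree$children, tree_has_not, logical(1))))
  }
  FALSE
}

sk_leaves <- function(tree) {
  if (tree$node %in% c("COND", "FACT")) return(list(tree))
  unlist(lapply(tree$children, sk_leaves), recursive = FALSE)
}

check_sk_rule <- function(rule) {
  if (tree_has_not(rule$antecedent)) {
    pgx_error("NONMONOTONIC_RULE",
              paste0(rule$sk_id, ": NOT is not allowed in supporting-",
                     "knowledge antecedents"))
  }
  leaves <- sk_leaves(rule$antecedent)
  if (length(leaves) == 0) {
    pgx_error("EMPTY_ANTECEDENT", paste0(rule$sk_id, ": empty antecedent"))
  }
  ante_vars <- unique(unlist(lapply(leaves, leaf_vars)))
  der_vars <- rule$derived$args[startsWith(rule$derived$args, "?")]
  unbound <- setdiff(der_vars, ante_vars)
  if (length(unbound) > 0) {
    pgx_error("UNBOUND_DERIVATION",
              paste0(rule$sk_id, ": derived template variable(s) ",
                     paste(unbound, collapse = ", "),
                     " not bound by the antecedent"))
  }
  if (length(ante_vars) > 0 && !and_only(rule$antecedent)) {
    pgx_error("VARIABLE_SCOPE",
              paste0(rule$sk_id, ": variables require an AND-only antecedent"))
  }
  invisible(rule)
}

and_only <- function(tree) {
  if (tree$node %in% c("COND", "FACT")) return(TRUE)
  identical(tree$node, "AND") &&
    all(vapply(tree$children, function(x) x$node %in% c("COND", "FACT"),
               logical(1)))
}

# all bindings under which the rule's antecedent is satisfied
rule_bindings <- function(rule, base) {
  leaves <- sk_leaves(rule$antecedent)
  has_vars <- length(unlist(lapply(leaves, leaf_vars))) > 0
  if (!has_vars) {
    ok <- sk_eval_tree(rule$antecedent, base)
    return(if (ok) list(list()) else list())
  }
  # AND-only with variables: natural join of per-leaf binding sets
  bindings <- list(list())
  for (leaf in leaves) {
    leaf_b <- match_leaf(leaf, base)
    joined <- list()
    for (b1 in bindings) {
      for (b2 in leaf_b) {
        shared <- intersect(names(b1), names(b2))
        if (all(vapply(shared, function(v) identical(b1[[v]], b2[[v]]),
                       logical(1)))) {
          joined[[length(joined) + 1]] <- c(b1, b2[setdiff(names(b2), shared)])
        }
      }
    }
    bindings <- joined
    if (length(bindings) == 0) break
  }
  bindings
}

# ground two-valued evaluation of an antecedent tree (no variables)
sk_eval_tree <- function(tree, base) {
  switch(tree$node,
    COND = sk_eval_condition(tree, base),
    FACT = length(match_leaf(tree, base)) > 0,
    AND = all(vapply(tree$children, sk_eval_tree, logical(1), base = base)),
    OR = any(vapply(tree$children, sk_eval_tree, logical(1), base = base))
  )
}

instantiate_derived <- function(template, binding) {
  args <- vapply(template$args, function(a) {
    if (is_var(a)) binding[[a]] else a
  }, character(1))
  fact(template$predicate, args)
}

#' Derive the closure of a fact base under supporting-knowledge rules
#'
#' Repeatedly applies every rule until no new fact is produced, returning
#' the least fixpoint: the smallest superset of `base` closed under all
#' rules. Derivation is monotone (the output contains the input) and
#' order-independent; derived facts carry the id of the rule that first
#' produced them as provenance.
#'
#' @param base A [fact_base()].
#' @param sk_rules List of [sk_rule()]s.
#' @param max_facts Hard safety cap on the closure size (default 10000);
#'   exceeding it raises `DERIVATION_LIMIT`.
#' @return The closed [fact_base()].
#' @export
#' @examples
#' b <- fact_base(list(fact("genotype", "CYP2C9", "*2/*3")))
#' cl <- derive_facts(b, default_supporting_knowledge())
#' has_fact(cl, fact("phenotype_class", "CYP2C9", "poor_metabolizer"))
derive_facts <- function(base, sk_rules, max_facts = 10000) {
  for (r in sk_rules) check_sk_rule(r)
  repeat {
    n_before <- length(base$facts)
    for (r in sk_rules) {
      for (b in rule_bindings(r, base)) {
        new_fact <- instantiate_derived(r$derived, b)
        if (any(startsWith(new_fact$args, "?"))) {
          pgx_error("UNBOUND_DERIVATION",
                    paste0(r$sk_id, ": derived fact retains unbound variable"))
        }
        base <- add_facts(base, list(new_fact), r$sk_id)
      }
    }
    if (length(base$facts) > max_facts) {
      pgx_error("DERIVATION_LIMIT",
                paste0("closure exceeded ", max_facts, " facts"))
    }
    if (length(base$facts) == n_before) break
  }
  base
}

## Packaged illustrative supporting knowledge ---------------------------------

#' Load a drug-class membership table
#'
#' Two-column TSV (`class_id`, `drug`). The packaged default,
#' `drug_classes_ILLUSTRATIVE.tsv`, holds illustrative (NOT clinically
#' authoritative) member lists for the drug classes the transcribed rules
#' reference; institutions substitute their own table.
#'
#' @param path TSV path; default the packaged illustrative table.
#' @return Data frame with columns `class_id`, `drug` (canonical names).
#' @export
load_drug_classes <- function(path = system.file(
    "extdata", "drug_classes_ILLUSTRATIVE.tsv", package = "pgxcds")) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tab$drug <- canonical_drug(tab$drug)
  tab
}

#' The packaged illustrative supporting-knowledge rule set
#'
#' Returns derivation rules for: CYP2C9, CYP2C19 and CYP2D6
#' poor-metabolizer phenotype classes from star-allele diplotypes
#' (diplotype lists are ILLUSTRATIVE placeholders beyond the canonical
#' CYP2C9*2/*3 example); the age < 18 demographic class "child"; and
#' drug-class membership (one ground rule per listed member, so the class
#' table stays externally editable).
#'
#' @param drug_classes Data frame from [load_drug_classes()].
#' @return List of [sk_rule()]s.
#' @export
default_supporting_knowledge <- function(drug_classes = load_drug_classes()) {
  rules <- list()
  sk_field <- function(id, kind = "GERMLINE_VARIANT_STATUS",
                       source = "LABORATORY_DB", detail = "") {
    clinical_data_field(id, kind, source, detail)
  }
  pm_diplotypes <- list(
    CYP2C9 = c("*2/*2", "*2/*3", "*3/*3"),
    CYP2C19 = c("*2/*2", "*2/*3", "*3/*3"),
    CYP2D6 = c("*3/*4", "*4/*4", "*4/*5", "*5/*5")
  )
  for (gene in names(pm_diplotypes)) {
    for (dip in pm_diplotypes[[gene]]) {
      rules[[length(rules) + 1]] <- sk_rule(
        sk_id = paste0("sk_", tolower(gene), "_pm_", gsub("[*/]", "", dip)),
        antecedent = condition(
          "HAS_VARIANT", list(gene = gene, allele = dip),
          sk_field(paste0(tolower(gene), "_variant_status"),
                   detail = gene)),
        derived = fact("phenotype_class", gene, "poor_metabolizer")
      )
    }
  }
  rules[[length(rules) + 1]] <- sk_rule(
    sk_id = "sk_age_child",
    antecedent = condition(
      "AGE_COMPARE", list(comparator = "<", threshold = 18),
      sk_field("age", kind = "DEMOGRAPHIC",
               source = "INPATIENT_OUTPATIENT_DB", detail = "age")),
    derived = fact("demographic_class", "child")
  )
  for (i in seq_len(nrow(drug_classes))) {
    rules[[length(rules) + 1]] <- sk_rule(
      sk_id = paste0("sk_class_", drug_classes$class_id[i], "_",
                     gsub("[^a-z0-9]", "_", drug_classes$drug[i])),
      antecedent = condition(
        "MEDICATION_ACTIVE", list(drug = drug_classes$drug[i]),
        sk_field("medication_list", kind = "MEDICATION_LIST",
                 source = "INPATIENT_OUTPATIENT_DB")),
      derived = fact("taking_drug_in_class", drug_classes$class_id[i])
    )
  }
  rules
}
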