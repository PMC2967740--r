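## Rule-catalog interchange: versioned YAML (JSON accepted on load since
## JSON is a YAML subset). Serialization and parsing are inverses on every
## field so saved catalogs round-trip identically.

CATALOG_FORMAT_VERSION <- "1"

field_to_list <- function(f) {
  list(field_id = f$field_id, kind = f$kind, source = f$source,
       detail = f$detail)
}

field_from_list <- function(x, ctx) {
  need <- c("field_id", "kind", "source")
  if (!all(need %in% names(x))) {
    pgx_error("SCHEMA_VIOLATION",
              paste0(ctx, ": field requires keys ",
                     paste(need, collapse = ", ")))
  }
  clinical_data_field(x$field_id, x$kind, x$source,
                      detail = if (is.null(x$detail)) "" else x$detail)
}

tree_to_list <- function(tree) {
  switch(tree$node,
    COND = {
      args <- tree$args
      # thresholds serialize as doubles so numeric type survives the trip
      if ("threshold" %in% names(args)) {
        args$threshold <- as.numeric(args$threshold)
      }
      list(predicate = tree$predicate, args = args,
           field = field_to_list(tree$field))
    },
    AND = list(and = lapply(tree$children, tree_to_list)),
    OR = list(or = lapply(tree$children, tree_to_list)),
    NOT = list(not = tree_to_list(tree$children[[1]]))
  )
}

tree_from_list <- function(x, ctx) {
  if (!is.list(x)) {
    pgx_error("SCHEMA_VIOLATION", paste0(ctx, ": antecedent node malformed"))
  }
  if ("and" %in% names(x)) {
    kids <- lapply(seq_along(x$and), function(i) {
      tree_from_list(x$and[[i]], paste0(ctx, "/and", i))
    })
    return(do.call(cnd_and, kids))
  }
  if ("or" %in% names(x)) {
    kids <- lapply(seq_along(x$or), function(i) {
      tree_from_list(x$or[[i]], paste0(ctx, "/or", i))
    })
    return(do.call(cnd_or, kids))
  }
  if ("not" %in% names(x)) {
    return(cnd_not(tree_from_list(x$not, paste0(ctx, "/not"))))
  }
  if (!all(c("predicate", "args", "field") %in% names(x))) {
    pgx_error("SCHEMA_VIOLATION",
              paste0(ctx, ": condition requires predicate/args/field"))
  }
  args <- as.list(x$args)
  if ("threshold" %in% names(args)) args$threshold <- as.numeric(args$threshold)
  condition(x$predicate, args, field_from_list(x$field, ctx))
}

statement_to_list <- function(s) {
  list(text = s$text, action_specificity = s$action_specificity,
       consequence_flag = s$consequence_flag)
}

statement_from_list <- function(x, ctx) {
  if (!all(c("text", "action_specificity", "consequence_flag") %in% names(x))) {
    pgx_error("SCHEMA_VIOLATION",
              paste0(ctx, ": consequent requires text/action_specificity/",
                     "consequence_flag"))
  }
  then_statement(x$text, x$action_specificity, isTRUE(x$consequence_flag))
}

rule_to_list <- function(r) {
  out <- list(
    rule_id = r$rule_id, drug = r$drug, biomarker = r$biomarker,
    antecedent = tree_to_list(r$antecedent),
    consequents = lapply(r$consequents, statement_to_list),
    general_category = r$general_category,
    provenance = r$provenance
  )
  if (!is.null(r$presentation_type)) {
    out$presentation_type <- r$presentation_type
  }
  out
}

rule_from_list <- function(x, ctx) {
  need <- c("rule_id", "drug", "biomarker", "antecedent", "consequents",
            "general_category")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    pgx_error("SCHEMA_VIOLATION",
              paste0(ctx, ": rule missing key(s) ", paste(miss, collapse = ", ")))
  }
  pgx_rule(
    rule_id = x$rule_id, drug = x$drug, biomarker = x$biomarker,
    antecedent = tree_from_list(x$antecedent, paste0(ctx, "/antecedent")),
    consequents = lapply(seq_along(x$consequents), function(i) {
      statement_from_list(x$consequents[[i]], paste0(ctx, "/consequent", i))
    }),
    general_category = x$general_category,
    presentation_type = x$presentation_type,
    provenance = if (is.null(x$provenance)) "" else x$provenance
  )
}

catalog_to_list <- function(catalog) {
  meta <- list(name = catalog$metadata$name,
               version = catalog$metadata$version)
  if (!is.null(catalog$metadata$seed)) {
    meta$seed <- as.integer(catalog$metadata$seed)
  }
  if (!is.null(catalog$metadata$ground_truth)) {
    # named vectors serialize as YAML maps (atomic vectors would drop names)
    meta$ground_truth <- lapply(catalog$metadata$ground_truth, as.list)
  }
  list(format_version = CATALOG_FORMAT_VERSION,
       metadata = meta,
       rules = lapply(catalog$rules, rule_to_list))
}

catalog_from_list <- function(x, where = "catalog") {
  if (is.null(x$format_version)) {
    pgx_error("SCHEMA_VIOLATION",
              paste0(where, ": missing required key format_version"))
  }
  if (!identical(as.character(x$format_version), CATALOG_FORMAT_VERSION)) {
    pgx_error("UNSUPPORTED_FORMAT_VERSION",
              paste0(where, ": unknown format_version '",
                     x$format_version, "' (supported: ",
                     CATALOG_FORMAT_VERSION, ")"))
  }
  meta <- x$metadata
  rules <- lapply(seq_along(x$rules), function(i) {
    rule_from_list(x$rules[[i]], paste0(where, "/rules[", i, "]"))
  })
  rule_catalog(
    rules,
    name = if (is.null(meta$name)) "catalog" else meta$name,
    version = if (is.null(meta$version)) "1" else meta$version,
    seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed),
    # YAML maps parse as named lists; ground-truth label maps are stored
    # in-memory as named character vectors
    ground_truth = if (is.null(meta$ground_truth)) NULL
                   else lapply(meta$ground_truth, function(x) unlist(x))
  )
}

#' Save a rule catalog to a YAML interchange file
#'
#' @param catalog A [rule_catalog()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_catalog <- function(catalog, path) {
  yaml::write_yaml(catalog_to_list(catalog), path)
  invisible(path)
}

#' Load a rule catalog from a YAML (or JSON) interchange file
#'
#' The interchange format is a versioned map
#' `{format_version, metadata, rules: [...]}` with antecedents as nested
#' `and:`/`or:`/`not:`/condition maps. `load_catalog(save_catalog(c))`
#' reproduces `c` field for field.
#'
#' @param path Input file path.
#' @return A [rule_catalog()].
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    pgx_error("MISSING_FILE", paste0("no such catalog file: ", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      pgx_error("SCHEMA_VIOLATION",
                paste0(path, ": not parseable as YAML/JSON: ",
                       conditionMessage(e)))
    }
  )
  catalog_from_list(raw, where = path)
}
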