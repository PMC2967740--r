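## Evidence-catalog analytics: citation-set overlap between knowledge
## resources, evidence-category distributions over publication records,
## and encoded-knowledge matrix summaries.

#' Construct a citation set
#'
#' A named resource's set of evidence articles. Identifiers are
#' normalized (trimmed, case-folded) and deduplicated.
#'
#' @param resource Resource name (e.g. a regulator's website or a curated
#'   knowledge base).
#' @param articles Character vector of article identifiers.
#' @return An object of class `pgx_citation_set`.
#' @export
citation_set <- function(resource, articles) {
  arts <- unique(tolower(trimws(as.character(articles))))
  arts <- arts[nzchar(arts)]
  structure(list(resource = as.character(resource), articles = arts),
            class = "pgx_citation_set")
}

#' Construct a publication record
#'
#' @param article_id Identifier.
#' @param categories Subset of the five evidence categories `CO` (clinical
#'   outcome), `PD` (pharmacodynamics), `PK` (pharmacokinetics), `FA`
#'   (functional assays), `GN` (genotype); may be empty.
#' @param designated_for_pair Logical: is the article designated as
#'   containing evidence for the biomarker-drug pair of interest?
#' @return An object of class `pgx_publication`.
#' @export
publication_record <- function(article_id, categories = character(),
                               designated_for_pair = TRUE) {
  categories <- unique(toupper(as.character(categories)))
  bad <- setdiff(categories, EVIDENCE_CATEGORIES)
  if (length(bad) > 0) {
    pgx_error("INVALID_CATEGORY",
              paste0("unknown evidence category: ", paste(bad, collapse = ", ")))
  }
  structure(list(article_id = tolower(trimws(article_id)),
                 categories = categories,
                 designated_for_pair = isTRUE(designated_for_pair)),
            class = "pgx_publication")
}

#' Overlap statistics between two citation sets
#'
#' Exact set arithmetic; the percentage is of the union (by
#' inclusion-exclusion, `union = |A| + |B| - |A ∩ B|`), rounded half away
#' from zero.
#'
#' @param a,b [citation_set()]s.
#' @return List with `size_a`, `size_b`, `intersection`, `union`,
#'   `pct_of_union`.
#' @export
#' @examples
#' a <- citation_set("fda", c("p1", "p2", "p3"))
#' b <- citation_set("pharmgkb", c("p3", "p4"))
#' overlap_stats(a, b)$intersection # 1
overlap_stats <- function(a, b) {
  if (length(a$articles) == 0 && length(b$articles) == 0) {
    pgx_error("EMPTY_SETS", "both citation sets are empty")
  }
  inter <- length(intersect(a$articles, b$articles))
  uni <- length(a$articles) + length(b$articles) - inter
  list(size_a = length(a$articles), size_b = length(b$articles),
       intersection = inter, union = uni,
       pct_of_union = pct_of(inter, uni))
}

#' Evidence-category distribution over publication records
#'
#' A publication tagged with k categories contributes to k counts, so
#' percentages need not sum to 100.
#'
#' @param pubs Non-empty list of [publication_record()]s.
#' @return Data frame with columns `category`, `count`, `percent`
#'   (percent of the number of publications, shared rounding).
#' @export
evidence_category_distribution <- function(pubs) {
  if (length(pubs) == 0) pgx_error("EMPTY_SET", "no publication records")
  counts <- vapply(EVIDENCE_CATEGORIES, function(cat) {
    sum(vapply(pubs, function(p) cat %in% p$categories, logical(1)))
  }, integer(1))
  data.frame(
    category = EVIDENCE_CATEGORIES,
    count = as.integer(counts),
    percent = vapply(counts, pct_of, numeric(1), den = length(pubs)),
    stringsAsFactors = FALSE
  )
}

#' Count publications not designated for the pair of interest
#'
#' Of the publications found in both resources, how many were not
#' designated as containing evidence for the specific biomarker-drug
#' relationship.
#'
#' @param overlap_pubs Non-empty list of [publication_record()]s.
#' @return List with `count` and `percent` (of `length(overlap_pubs)`).
#' @export
undesignated_fraction <- function(overlap_pubs) {
  if (length(overlap_pubs) == 0) pgx_error("EMPTY_SET", "no publication records")
  n <- sum(vapply(overlap_pubs, function(p) !p$designated_for_pair,
                  logical(1)))
  list(count = as.integer(n), percent = pct_of(n, length(overlap_pubs)))
}

#' Construct an encoded-knowledge matrix
#'
#' Per-drug indicator of which forms of encoded knowledge a curated
#' resource carries: pathway evidence, variant evidence, genotype data,
#' phenotype data, and a compiled clinical PGx section.
#'
#' @param drugs Character vector of unique drug names.
#' @param forms Named list drug -> character vector of knowledge forms
#'   (subset of the five form names above); drugs absent from the list
#'   carry no forms.
#' @return An object of class `pgx_knowledge_matrix`: logical matrix
#'   drugs x forms.
#' @export
knowledge_matrix <- function(drugs, forms = list()) {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) {
    pgx_error("DUPLICATE_DRUG", "drug names must be unique")
  }
  m <- matrix(FALSE, nrow = length(drugs), ncol = length(KNOWLEDGE_FORMS),
              dimnames = list(drugs, KNOWLEDGE_FORMS))
  for (d in names(forms)) {
    f <- toupper(forms[[d]])
    bad <- setdiff(f, KNOWLEDGE_FORMS)
    if (length(bad) > 0) {
      pgx_error("INVALID_FORM",
                paste0(d, ": unknown knowledge form ",
                       paste(bad, collapse = ", ")))
    }
    if (!d %in% drugs) {
      pgx_error("UNKNOWN_DRUG", paste0("forms given for unlisted drug ", d))
    }
    m[d, f] <- TRUE
  }
  structure(m, class = c("pgx_knowledge_matrix", class(m)))
}

#' Summarise an encoded-knowledge matrix
#'
#' @param matrix A [knowledge_matrix()] with at least one drug.
#' @return List with `n_drugs`, `per_form` (named drug counts per
#'   knowledge form) and `per_drug` (named form counts per drug).
#' @export
knowledge_matrix_summary <- function(matrix) {
  if (nrow(matrix) == 0) pgx_error("EMPTY_MATRIX", "no drugs in matrix")
  list(n_drugs = nrow(matrix),
       per_form = colSums(matrix),
       per_drug = rowSums(matrix))
}

## I/O ------------------------------------------------------------------------

#' Read a citation set from a text file
#'
#' Accepts a one-column file of article identifiers or a two-column TSV
#' `(resource, article_id)`.
#'
#' @param path File path.
#' @param resource Resource name (overrides any column value; required
#'   for one-column files).
#' @return A [citation_set()].
#' @export
load_citation_set <- function(path, resource = basename(path)) {
  if (!file.exists(path)) {
    pgx_error("MISSING_FILE", paste0("no such citation file: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) p[[length(p)]], character(1))
  citation_set(resource, ids)
}

#' Read publication records from a TSV
#'
#' Columns: `article_id`, `categories` (semicolon-separated), `designated`
#' (TRUE/FALSE).
#'
#' @param path TSV file path.
#' @return List of [publication_record()]s.
#' @export
load_publications <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  lapply(seq_len(nrow(tab)), function(i) {
    cats <- strsplit(tab$categories[i], ";", fixed = TRUE)[[1]]
    cats <- cats[nzchar(cats)]
    publication_record(tab$article_id[i], cats,
                       toupper(tab$designated[i]) %in% c("TRUE", "T", "1"))
  })
}

#' Save / load an encoded-knowledge matrix as TSV
#'
#' TSV layout mirrors the printed table: a `drug` column plus one column
#' per knowledge form with `x` (present) or blank.
#'
#' @param matrix A [knowledge_matrix()].
#' @param path File path.
#' @return `save_knowledge_matrix`: invisibly `path`;
#'   `load_knowledge_matrix`: a [knowledge_matrix()].
#' @export
save_knowledge_matrix <- function(matrix, path) {
  df <- data.frame(drug = rownames(matrix), stringsAsFactors = FALSE)
  for (f in colnames(matrix)) df[[f]] <- ifelse(matrix[, f], "x", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_knowledge_matrix
#' @export
load_knowledge_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  forms <- lapply(seq_len(nrow(df)), function(i) {
    KNOWLEDGE_FORMS[vapply(KNOWLEDGE_FORMS,
                           function(f) identical(df[[f]][i], "x"),
                           logical(1))]
  })
  names(forms) <- df$drug
  knowledge_matrix(df$drug, forms[vapply(forms, length, integer(1)) > 0])
}
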