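## Seeded synthetic generators. Every generator is a pure function of its
## arguments: the seed drives a private RNG stream (the caller's random
## state is untouched), and categorical mixes are *planted* by exact
## largest-remainder apportionment, not sampled — so recovery tests can
## demand exact agreement with the stored ground truth.

# pool of synthetic field ids shared between generated catalogs and
# generated capability profiles
synthetic_field_pool <- function(n_fields = 40) {
  kinds <- c("MEDICATION", "MEDICATION_LIST", "DISEASE_STATUS",
             "GERMLINE_VARIANT_STATUS", "TUMOR_PATHOGEN_GENOTYPE",
             "DEMOGRAPHIC", "LAB_VALUE", "DERIVED_PHENOTYPE_CLASS")
  lapply(seq_len(n_fields), function(i) {
    kind <- kinds[((i - 1) %% length(kinds)) + 1]
    source <- if (kind == "DERIVED_PHENOTYPE_CLASS") "SUPPORTING_KNOWLEDGE"
              else if (kind %in% c("GERMLINE_VARIANT_STATUS",
                                   "TUMOR_PATHOGEN_GENOTYPE", "LAB_VALUE")) {
                "LABORATORY_DB"
              } else "INPATIENT_OUTPATIENT_DB"
    clinical_data_field(sprintf("synth_field_%02d", i), kind, source,
                        detail = sprintf("synthetic field %02d", i))
  })
}

# consequent templated so the classifier provably returns `label`
planted_consequent <- function(label, drug, variant) {
  switch(label,
    RECOMMENDATION = then_statement(
      sprintf("the dose of %s should be reduced by %d%%", drug,
              c(25, 50, 75)[variant]),
      action_specificity = "CLEAR", consequence_flag = FALSE),
    INFORMATION = if (variant %% 2 == 0) {
      then_statement(
        sprintf("the dose adjustment for %s is unknown for the patient", drug),
        action_specificity = "NONE", consequence_flag = FALSE)
    } else {
      then_statement(sprintf("the dose of %s should be adjusted", drug),
                     action_specificity = "VAGUE", consequence_flag = FALSE)
    },
    WARNING = then_statement(
      sprintf("coadministration of %s carries an increased bleeding risk", drug),
      action_specificity = "VAGUE", consequence_flag = TRUE)
  )
}

#' Generate a seeded synthetic rule catalog with planted ground truth
#'
#' Assembles `n` rules whose presentation labels and support categories
#' follow the requested mixes *exactly* (largest-remainder apportionment,
#' then a seeded shuffle): consequent texts and annotations are templated
#' so the certainty classifier provably recovers each planted label.
#' Antecedent fields are drawn from a fixed synthetic field pool so a
#' generated capability profile can address them by id. Ground truth
#' (planted label and category per rule) is stored in
#' `catalog$metadata$ground_truth`.
#'
#' @param seed Integer seed.
#' @param n Number of rules (>= 1).
#' @param presentation_mix Named non-negative weights over
#'   INFORMATION/RECOMMENDATION/WARNING. The default 0.39/0.39/0.22 is
#'   the published presentation-type mix of the curated rule base.
#' @param category_mix Named non-negative weights over the seven support
#'   categories. The default splits the published general-category mix
#'   (50/24/13/9/4, with the pooled 50% divided 20/15/15 across dose
#'   adjustment, monitoring and pre-treatment consideration).
#' @param n_fields Size of the synthetic field pool.
#' @return A [rule_catalog()] with `metadata$ground_truth`.
#' @export
gen_rule_catalog <- function(seed, n,
                             presentation_mix = c(INFORMATION = 0.39,
                                                  RECOMMENDATION = 0.39,
                                                  WARNING = 0.22),
                             category_mix = c(DOSE_ADJUSTMENT = 0.20,
                                              PATIENT_MONITORING = 0.15,
                                              PRE_TREATMENT_CONSIDERATION = 0.15,
                                              BENEFIT_PREDICTION = 0.24,
                                              TESTING_GUIDANCE = 0.13,
                                              COADMINISTRATION = 0.09,
                                              PATIENT_COMMUNICATION = 0.04),
                             n_fields = 40) {
  if (n < 1) pgx_error("INVALID_N", "n must be >= 1")
  stopifnot(all(names(presentation_mix) %in% PRESENTATION_TYPES),
            all(names(category_mix) %in% SUPPORT_CATEGORIES))
  with_rng(seed, {
    label_counts <- apportion(n, presentation_mix)
    labels <- sample(rep(names(label_counts), label_counts))
    cat_counts <- apportion(n, category_mix)
    cats <- sample(rep(names(cat_counts), cat_counts))
    pool <- synthetic_field_pool(n_fields)
    genes <- c("CYP2C9", "CYP2C19", "CYP2D6")
    rules <- vector("list", n)
    for (i in seq_len(n)) {
      drug <- sprintf("synthdrug%03d", sample.int(999, 1))
      gene <- genes[sample.int(3, 1)]
      chosen <- pool[sample.int(n_fields, 1 + sample.int(3, 1))]
      leaves <- lapply(chosen, function(f) synthetic_leaf(f, drug, gene))
      rules[[i]] <- pgx_rule(
        rule_id = sprintf("SYN_%04d", i),
        drug = drug, biomarker = gene,
        antecedent = do.call(cnd_and, leaves),
        consequents = list(planted_consequent(labels[i], drug,
                                              sample.int(3, 1))),
        general_category = cats[i]
      )
    }
    ids <- vapply(rules, function(r) r$rule_id, character(1))
    rule_catalog(
      rules, name = sprintf("synthetic_seed%d", seed), seed = seed,
      ground_truth = list(
        presentation = stats::setNames(labels, ids),
        category = stats::setNames(cats, ids)
      )
    )
  })
}

# a condition leaf appropriate for a pooled field's kind
synthetic_leaf <- function(field, drug, gene) {
  switch(field$kind,
    MEDICATION = condition("MEDICATION_ACTIVE", list(drug = drug), field),
    MEDICATION_LIST = condition("TAKING_DRUG_IN_CLASS",
                                list(class_id = "cyp2d6_substrates"), field),
    DISEASE_STATUS = condition("HAS_DISEASE",
                               list(disease = field$field_id), field),
    GERMLINE_VARIANT_STATUS = condition("HAS_VARIANT",
                                        list(gene = gene, allele = "*2"),
                                        field),
    TUMOR_PATHOGEN_GENOTYPE = condition("TUMOR_HAS_MUTATION",
                                        list(mutation = field$field_id),
                                        field),
    DEMOGRAPHIC = condition("AGE_COMPARE",
                            list(comparator = "<", threshold = 18), field),
    LAB_VALUE = condition("LAB_COMPARE",
                          list(analyte = field$field_id, comparator = ">",
                               threshold = 2, units = "mg/dL"), field),
    DERIVED_PHENOTYPE_CLASS = condition(
      "HAS_PHENOTYPE_CLASS", list(gene = gene, class = "poor_metabolizer"),
      field)
  )
}

#' Generate a seeded synthetic capability profile
#'
#' Assigns availability statuses to the synthetic field pool with the
#' requested mix planted exactly; the ground-truth assignment is the
#' profile's own entry list.
#'
#' @param seed Integer seed.
#' @param field_ids Field ids to cover (default the standard pool).
#' @param status_mix Named non-negative weights over the eight
#'   availability statuses. The default emulates a mid-size academic EMR:
#'   most fields discrete or derivable, a quarter reachable only through
#'   feasible expansion, a tail requiring full NLP or absent.
#' @return A [capability_profile()] with one exact-id entry per field.
#' @export
gen_capability_profile <- function(seed,
                                   field_ids = vapply(synthetic_field_pool(),
                                                      function(f) f$field_id,
                                                      character(1)),
                                   status_mix = c(
                                     DISCRETE = 0.45,
                                     REQUIRES_SUPPORTING_KNOWLEDGE = 0.20,
                                     EXPANSION_DISEASE_STATUS_DEFINITION = 0.08,
                                     EXPANSION_PATHOLOGY_FIELD = 0.02,
                                     EXPANSION_MICROBIOLOGY_FIELD = 0.10,
                                     EXPANSION_PARSEABLE_FREE_TEXT = 0.05,
                                     REQUIRES_FULL_NLP = 0.05,
                                     ABSENT = 0.05)) {
  stopifnot(all(names(status_mix) %in% AVAILABILITY_STATUSES))
  with_rng(seed, {
    counts <- apportion(length(field_ids), status_mix)
    statuses <- sample(rep(names(counts), counts))
    entries <- lapply(seq_along(field_ids), function(i) {
      list(match = list(field_id = field_ids[i]), status = statuses[i])
    })
    capability_profile(entries, default_status = "ABSENT")
  })
}

#' Generate a seeded synthetic patient record
#'
#' Genotypes are drawn per gene as two independent alleles from the
#' stated allele-frequency vectors (an allele with frequency 1 therefore
#' yields a homozygous diplotype); medications and diseases are sampled
#' from small pools.
#'
#' @param seed Integer seed.
#' @param patient_id Identifier (default derived from the seed).
#' @param allele_freqs Named list gene -> named numeric allele
#'   frequencies. Defaults are rough European-ancestry frequencies for
#'   the common CYP2C9/CYP2C19/CYP2D6 alleles.
#' @param med_pool,disease_pool Sampling pools.
#' @return A [patient_record()].
#' @export
gen_patient <- function(seed, patient_id = sprintf("synth_patient_%d", seed),
                        allele_freqs = list(
                          CYP2C9 = c("*1" = 0.79, "*2" = 0.13, "*3" = 0.08),
                          CYP2C19 = c("*1" = 0.77, "*2" = 0.18, "*3" = 0.05),
                          CYP2D6 = c("*1" = 0.70, "*4" = 0.20, "*5" = 0.10)),
                        med_pool = c("warfarin", "celecoxib", "clopidogrel",
                                     "atomoxetine", "fluoxetine", "codeine",
                                     "metoprolol"),
                        disease_pool = c("asm", "gist", "hepatic impairment",
                                         "atrial fibrillation")) {
  with_rng(seed, {
    gg <- lapply(allele_freqs, function(fr) {
      alleles <- sample(names(fr), 2, replace = TRUE, prob = fr)
      normalize_diplotype(paste(alleles, collapse = "/"))
    })
    patient_record(
      patient_id = patient_id,
      age = sample.int(90, 1),
      sex = sample(c("female", "male"), 1),
      medications_active = sample(med_pool, sample.int(3, 1)),
      disease_statuses = sample(disease_pool, sample(0:2, 1)),
      germline_genotypes = gg
    )
  })
}

#' Generate two citation sets with an exact planted overlap
#'
#' Constructs sets with `|A| = n_a`, `|B| = n_b` and exactly `n_shared`
#' common identifiers, so `overlap_stats` must report an intersection of
#' `n_shared` and a union of `n_a + n_b - n_shared`.
#'
#' @param n_a,n_b Set sizes.
#' @param n_shared Planted intersection size
#'   (`<= min(n_a, n_b)`, else `INVALID_OVERLAP`).
#' @param seed Integer seed.
#' @return List of two [citation_set()]s named `a` and `b`.
#' @export
gen_citation_sets <- function(n_a, n_b, n_shared, seed = 1) {
  if (n_shared > min(n_a, n_b)) {
    pgx_error("INVALID_OVERLAP", "n_shared must be <= min(n_a, n_b)")
  }
  with_rng(seed, {
    total <- n_a + n_b - n_shared
    ids <- sprintf("art%06d", sample.int(10 * total + 10, total))
    shared <- ids[seq_len(n_shared)]
    only_a <- ids[seq_len(n_a - n_shared) + n_shared]
    only_b <- ids[seq_len(n_b - n_shared) + n_a]
    list(a = citation_set("resource_a", c(shared, only_a)),
         b = citation_set("resource_b", c(shared, only_b)))
  })
}

#' Generate publication records with planted category counts
#'
#' Assigns each evidence category to an exact planted number of records
#' (seeded choice of which records), so the category distribution is
#' recoverable exactly.
#'
#' @param n Number of records.
#' @param counts Named integer vector of per-category record counts
#'   (each `<= n`). The default reproduces the published per-category
#'   counts over the 251 non-overlapping articles.
#' @param n_undesignated Number of records with
#'   `designated_for_pair = FALSE`.
#' @param seed Integer seed.
#' @return List of [publication_record()]s.
#' @export
gen_publications <- function(n = 251,
                             counts = c(CO = 49, PD = 80, PK = 141,
                                        FA = 27, GN = 171),
                             n_undesignated = 0, seed = 1) {
  stopifnot(all(names(counts) %in% EVIDENCE_CATEGORIES),
            all(counts <= n), n_undesignated <= n)
  with_rng(seed, {
    cats <- replicate(n, character(), simplify = FALSE)
    for (cat in names(counts)) {
      idx <- sample.int(n, counts[[cat]])
      for (i in idx) cats[[i]] <- c(cats[[i]], cat)
    }
    undes <- if (n_undesignated > 0) sample.int(n, n_undesignated)
             else integer()
    lapply(seq_len(n), function(i) {
      publication_record(sprintf("pub%05d", i), cats[[i]],
                         designated_for_pair = !(i %in% undes))
    })
  })
}
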