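## Transcribed fixtures: the five published example rules, the warfarin
## worked rule, and the encoded-knowledge matrix. Consequent texts, data
## source columns and printed presentation labels follow the published
## table; condition-tree structure, field ids and category assignments
## are this package's encoding.
##
## A drug-class or phenotype-class check reads two data sources (the raw
## EMR field and the supporting-knowledge class definition); since each
## leaf condition reads exactly one field, such a check is encoded as an
## AND of two leaves sharing the same predicate and arguments — identical
## truth value, both fields surfaced to the coverage analysis.

f_med <- function(drug) {
  clinical_data_field(paste0("medication_", gsub("[^a-z0-9]+", "_", drug)),
                      "MEDICATION", "INPATIENT_OUTPATIENT_DB", drug)
}
f_medlist <- function() {
  clinical_data_field("medication_list", "MEDICATION_LIST",
                      "INPATIENT_OUTPATIENT_DB", "active medications")
}
f_variant <- function(gene) {
  clinical_data_field(paste0(tolower(gene), "_variant_status"),
                      "GERMLINE_VARIANT_STATUS", "LABORATORY_DB", gene)
}
f_skclass <- function(id, detail) {
  clinical_data_field(id, "DERIVED_PHENOTYPE_CLASS", "SUPPORTING_KNOWLEDGE",
                      detail)
}
f_disease <- function(id, detail) {
  clinical_data_field(id, "DISEASE_STATUS", "INPATIENT_OUTPATIENT_DB", detail)
}

# phenotype-class check: lab variant-status leaf + supporting-knowledge leaf
pm_check <- function(gene) {
  args <- list(gene = gene, class = "poor_metabolizer")
  cnd_and(
    condition("HAS_PHENOTYPE_CLASS", args, f_variant(gene)),
    condition("HAS_PHENOTYPE_CLASS", args,
              f_skclass(paste0(tolower(gene), "_pm_class"),
                        paste0(gene, " variants causing poor metabolism")))
  )
}

# drug-class check: medication-list leaf + supporting-knowledge leaf
class_check <- function(class_id, detail) {
  args <- list(class_id = class_id)
  cnd_and(
    condition("TAKING_DRUG_IN_CLASS", args, f_medlist()),
    condition("TAKING_DRUG_IN_CLASS", args, f_skclass(class_id, detail))
  )
}

#' The five published example rules
#'
#' Verbatim consequent texts and printed presentation labels
#' (Recommendation, Recommendation, Information, Information, Warning)
#' for imatinib (Gleevec), celecoxib, clopidogrel, atomoxetine and
#' fluoxetine, with data-source columns encoded as clinical-data fields.
#' The printed label is stored as the rule's pre-assigned
#' `presentation_type`; the classifier recomputes it independently from
#' the statement annotations.
#'
#' @return A [rule_catalog()] of 5 rules.
#' @export
table2_rules <- function() {
  gleevec <- pgx_rule(
    rule_id = "T2_01_imatinib",
    drug = "imatinib mesylate", biomarker = "c-Kit D816V",
    antecedent = cnd_and(
      condition("MEDICATION_ACTIVE", list(drug = "imatinib mesylate"),
                f_med("imatinib mesylate")),
      cnd_or(
        condition("HAS_DISEASE", list(disease = "asm"),
                  f_disease("disease_asm_dfsp_gist", "ASM, DFSP, or GIST")),
        condition("HAS_DISEASE", list(disease = "dfsp"),
                  f_disease("disease_asm_dfsp_gist", "ASM, DFSP, or GIST")),
        condition("HAS_DISEASE", list(disease = "gist"),
                  f_disease("disease_asm_dfsp_gist", "ASM, DFSP, or GIST"))
      ),
      condition("TUMOR_HAS_MUTATION", list(mutation = "c-Kit D816V"),
                clinical_data_field("tumor_ckit_genotype",
                                    "TUMOR_PATHOGEN_GENOTYPE", "LABORATORY_DB",
                                    "gastrointestinal stromal tumor c-Kit expression"))
    ),
    consequents = list(then_statement(
      "recommended dose of Gleevec is 400 mg/day",
      action_specificity = "CLEAR", consequence_flag = FALSE)),
    general_category = "DOSE_ADJUSTMENT",
    presentation_type = "RECOMMENDATION",
    provenance = "Dosage and Administration"
  )

  celecoxib <- pgx_rule(
    rule_id = "T2_02_celecoxib",
    drug = "celecoxib", biomarker = "CYP2C9",
    antecedent = cnd_and(
      condition("MEDICATION_ACTIVE", list(drug = "celecoxib"),
                f_med("celecoxib")),
      pm_check("CYP2C9")
    ),
    consequents = list(then_statement(
      "the dose of Celecoxib should be reduced by 50%",
      action_specificity = "CLEAR", consequence_flag = FALSE)),
    general_category = "DOSE_ADJUSTMENT",
    presentation_type = "RECOMMENDATION",
    provenance = "Dosage and Administration"
  )

  clopidogrel <- pgx_rule(
    rule_id = "T2_03_clopidogrel",
    drug = "clopidogrel", biomarker = "CYP2C19",
    antecedent = cnd_and(
      condition("MEDICATION_ACTIVE", list(drug = "clopidogrel"),
                f_med("clopidogrel")),
      pm_check("CYP2C19")
    ),
    consequents = list(then_statement(
      "the dose adjustment for Clopidogrel is unknown for the patient",
      action_specificity = "NONE", consequence_flag = FALSE)),
    general_category = "DOSE_ADJUSTMENT",
    presentation_type = "INFORMATION",
    provenance = "Clinical Pharmacology"
  )

  atomoxetine <- pgx_rule(
    rule_id = "T2_04_atomoxetine",
    drug = "atomoxetine", biomarker = "CYP2D6",
    antecedent = cnd_and(
      condition("MEDICATION_ACTIVE", list(drug = "atomoxetine"),
                f_med("atomoxetine")),
      cnd_or(
        condition("HAS_DISEASE", list(disease = "hepatic impairment"),
                  f_disease("disease_hepatic_impairment", "hepatic impairment")),
        class_check("cyp2d6_strong_inhibitors",
                    "medications that are strong CYP2D6 inhibitors"),
        pm_check("CYP2D6")
      )
    ),
    consequents = list(then_statement(
      "the dose of Atomoxetine should be adjusted",
      action_specificity = "VAGUE", consequence_flag = FALSE)),
    general_category = "DOSE_ADJUSTMENT",
    presentation_type = "INFORMATION",
    provenance = "Dosage and Administration"
  )

  fluoxetine <- pgx_rule(
    rule_id = "T2_05_fluoxetine",
    drug = "fluoxetine", biomarker = "CYP2D6",
    antecedent = cnd_and(
      condition("MEDICATION_CONSIDERED", list(drug = "fluoxetine"),
                f_med("fluoxetine")),
      class_check("cyp2d6_substrates", "medications metabolized by CYP2D6")
    ),
    consequents = list(then_statement(
      "coadministration should be approached with caution",
      action_specificity = "VAGUE", consequence_flag = TRUE)),
    general_category = "COADMINISTRATION",
    presentation_type = "WARNING",
    provenance = "Warnings and Precautions"
  )

  rule_catalog(list(gleevec, celecoxib, clopidogrel, atomoxetine, fluoxetine),
               name = "table2_examples")
}

#' The worked warfarin rule
#'
#' "IF patient is taking Warfarin AND patient has CYP2C9*2 or CYP2C9*3
#' variants, THEN there will be a decrease in S-warfarin clearance AND
#' there is an increased bleeding risk." Carries no pre-assigned
#' presentation type; the consequence statement makes the classifier
#' assign WARNING.
#'
#' @return A [pgx_rule()].
#' @export
warfarin_rule <- function() {
  pgx_rule(
    rule_id = "WARFARIN_CYP2C9",
    drug = "warfarin", biomarker = "CYP2C9",
    antecedent = cnd_and(
      condition("MEDICATION_ACTIVE", list(drug = "warfarin"),
                f_med("warfarin")),
      cnd_or(
        condition("HAS_VARIANT", list(gene = "CYP2C9", allele = "*2"),
                  f_variant("CYP2C9")),
        condition("HAS_VARIANT", list(gene = "CYP2C9", allele = "*3"),
                  f_variant("CYP2C9"))
      )
    ),
    consequents = list(
      then_statement("there will be a decrease in S-warfarin clearance",
                     action_specificity = "NONE", consequence_flag = FALSE),
      then_statement("there is an increased bleeding risk",
                     action_specificity = "NONE", consequence_flag = TRUE)
    ),
    general_category = "PRE_TREATMENT_CONSIDERATION",
    provenance = "Clinical Pharmacology"
  )
}

#' The transcribed encoded-knowledge matrix
#'
#' Per-drug indicators of the five forms of curated knowledge (pathway
#' evidence, variant evidence, genotype data, phenotype data, clinical
#' PGx section) for the biomarker-drug-pair labels, transcribed from the
#' published table (30 drug rows as printed).
#'
#' @return A [knowledge_matrix()].
#' @export
table1_matrix <- function() {
  load_knowledge_matrix(system.file("extdata", "table1_matrix.tsv",
                                    package = "pgxcds"))
}
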