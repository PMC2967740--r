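test_that("Kleene connectives match the hand-enumerated truth tables", {
  for (i in seq_len(nrow(kleene_and_table))) {
    row <- kleene_and_table[i, ]
    expect_equal(kleene_and(c(row$a, row$b)), row$out,
                 info = sprintf("AND(%s, %s)", row$a, row$b))
  }
  for (i in seq_len(nrow(kleene_or_table))) {
    row <- kleene_or_table[i, ]
    expect_equal(kleene_or(c(row$a, row$b)), row$out,
                 info = sprintf("OR(%s, %s)", row$a, row$b))
  }
  for (i in seq_len(nrow(kleene_not_table))) {
    row <- kleene_not_table[i, ]
    expect_equal(kleene_not(row$a), row$out)
  }
})

test_that("condition evaluation distinguishes absent from negative data", {
  p <- patient_record("p1", age = 25, medications_active = "warfarin")
  med_field <- clinical_data_field("med", "MEDICATION",
                                   "INPATIENT_OUTPATIENT_DB", "warfarin")
  gen_field <- clinical_data_field("gen", "GERMLINE_VARIANT_STATUS",
                                   "LABORATORY_DB", "CYP2C9")
  age_field <- clinical_data_field("age", "DEMOGRAPHIC",
                                   "INPATIENT_OUTPATIENT_DB", "age")

  expect_equal(eval_condition(
    condition("MEDICATION_ACTIVE", list(drug = "warfarin"), med_field), p),
    "TRUE")
  # brand name resolves through the synonym table
  expect_equal(eval_condition(
    condition("MEDICATION_ACTIVE", list(drug = "Coumadin"), med_field), p),
    "TRUE")
  expect_equal(eval_condition(
    condition("MEDICATION_ACTIVE", list(drug = "celecoxib"), med_field), p),
    "FALSE")
  # no CYP2C9 entry on file -> unknown, not false
  expect_equal(eval_condition(
    condition("HAS_VARIANT", list(gene = "CYP2C9", allele = "*2"), gen_field),
    p), "UNKNOWN")
  expect_equal(eval_condition(
    condition("AGE_COMPARE", list(comparator = "<", threshold = 18),
              age_field), p), "FALSE")

  lab_field <- clinical_data_field("inr", "LAB_VALUE", "LABORATORY_DB", "INR")
  p_lab <- patient_record("p2", lab_values = list(
    inr = list(value = 3.5, units = "ratio")))
  expect_equal(eval_condition(
    condition("LAB_COMPARE", list(analyte = "inr", comparator = ">",
                                  threshold = 3, units = "ratio"),
              lab_field), p_lab), "TRUE")
  expect_error(eval_condition(
    condition("LAB_COMPARE", list(analyte = "inr", comparator = ">",
                                  threshold = 3, units = "mg/dL"),
              lab_field), p_lab), class = "UNIT_MISMATCH")
})

test_that("the worked warfarin rule fires, blocks, and declines correctly", {
  wr <- warfarin_rule()

  on_drug_variant <- patient_record(
    "p1", age = 60, medications_active = "warfarin",
    germline_genotypes = list(CYP2C9 = "*1/*2"))
  res <- evaluate_rule(wr, on_drug_variant)
  expect_equal(res$status, "FIRED")
  expect_equal(res$alert$presentation_type, "WARNING")
  expect_true(any(grepl("bleeding risk", res$alert$message)))
  expect_gt(length(res$alert$matched_conditions), 0)

  # on the drug, genotype not on file -> indeterminate, variant status named
  no_genotype <- patient_record("p2", age = 60,
                                medications_active = "warfarin")
  res2 <- evaluate_rule(wr, no_genotype)
  expect_equal(res2$status, "INDETERMINATE")
  expect_equal(vapply(res2$missing_fields, function(f) f$field_id,
                      character(1)), "cyp2c9_variant_status")
  expect_null(res2$alert)

  # FALSE AND UNKNOWN = FALSE: not on the drug, no genotype -> not fired
  neither <- patient_record("p3", age = 60)
  expect_equal(evaluate_rule(wr, neither)$status, "NOT_FIRED")
})

test_that("resolving missing data never un-fires a rule", {
  wr <- warfarin_rule()
  fired <- patient_record("p1", medications_active = "warfarin",
                          germline_genotypes = list(CYP2C9 = "*1/*3"))
  expect_equal(evaluate_rule(wr, fired)$status, "FIRED")
  with_more_data <- patient_record(
    "p1", age = 71, sex = "female", medications_active = "warfarin",
    germline_genotypes = list(CYP2C9 = "*1/*3", CYP2D6 = "*1/*1"),
    disease_statuses = "atrial fibrillation")
  expect_equal(evaluate_rule(wr, with_more_data)$status, "FIRED")
})

test_that("supporting knowledge expands the fired set", {
  celecoxib <- table2_rules()$rules[[2]]
  pm_patient <- patient_record("p1", medications_active = "celecoxib",
                               germline_genotypes = list(CYP2C9 = "*2/*3"))
  with_sk <- evaluate_rule(celecoxib, pm_patient)
  without_sk <- evaluate_rule(celecoxib, pm_patient, sk_rules = list())
  expect_equal(with_sk$status, "FIRED")
  expect_equal(with_sk$alert$presentation_type, "RECOMMENDATION")
  expect_false(identical(without_sk$status, "FIRED"))
})

test_that("catalog evaluation orders alerts by severity then rule id", {
  catal <- table2_rules()
  patient <- patient_record(
    "p1", age = 40,
    medications_active = c("celecoxib", "fluoxetine", "atomoxetine"),
    medications_considered = "fluoxetine",
    germline_genotypes = list(CYP2C9 = "*2/*3", CYP2C19 = "*1/*1",
                              CYP2D6 = "*1/*1"),
    disease_statuses = character())
  res <- evaluate_catalog(catal, patient)
  expect_true(length(res$alerts) >= 2)
  sev <- vapply(res$alerts, function(a) severity_rank(a$presentation_type),
                integer(1))
  expect_true(all(diff(sev) <= 0))
  # warning (fluoxetine coadministration) outranks the celecoxib dose rec
  expect_equal(res$alerts[[1]]$presentation_type, "WARNING")

  # every alert corresponds to a FIRED rule; alerts <= catalog size
  for (a in res$alerts) {
    expect_equal(unname(res$statuses[a$rule_id]), "FIRED")
  }
  expect_lte(length(res$alerts), length(catal$rules))
})

test_that("a patient matching nothing yields no alerts", {
  blank <- patient_record("p0", age = 30)
  res <- evaluate_catalog(table2_rules(), blank)
  expect_length(res$alerts, 0)
  expect_true(all(res$statuses %in% c("NOT_FIRED", "INDETERMINATE")))
  expect_error(evaluate_catalog(rule_catalog(list()), blank),
               class = "EMPTY_CATALOG")
})

test_that("catalog evaluation equals the per-rule loop on synthetic rules", {
  catal <- gen_rule_catalog(seed = 5, n = 40)
  patient <- gen_patient(seed = 9)
  sk <- default_supporting_knowledge()
  res <- evaluate_catalog(catal, patient, sk_rules = sk)
  loop <- vapply(catal$rules, function(r) {
    evaluate_rule(r, patient, sk_rules = sk)$status
  }, character(1))
  expect_identical(unname(res$statuses), loop)
})

test_that("patient records round-trip through JSON", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(
    patient_id = "j1", age = 55, sex = "male",
    medications_active = c("warfarin"),
    germline_genotypes = list(CYP2C9 = "*3/*2"),
    lab_values = list(inr = list(value = 2.1, units = "ratio"))
  )), auto_unbox = TRUE), tf)
  ps <- load_patients(tf)
  expect_length(ps, 1)
  expect_equal(ps[[1]]$germline_genotypes$CYP2C9, "*2/*3")
  expect_equal(evaluate_rule(warfarin_rule(), ps[[1]])$status, "FIRED")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"age": 10}]', bad)
  expect_error(load_patients(bad), class = "SCHEMA_VIOLATION")
})
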