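make_profile <- function(statuses) {
  capability_profile(lapply(names(statuses), function(id) {
    list(match = list(field_id = id), status = statuses[[id]])
  }))
}

simple_rule <- function(field, rule_id = "r1") {
  pgx_rule(rule_id, "drugx", "GENE",
           condition("HAS_DISEASE", list(disease = "x"), field),
           list(then_statement("informational note")), "TESTING_GUIDANCE")
}

test_that("rule executability follows the nested scenario status sets", {
  disc_field <- clinical_data_field("meds", "MEDICATION_LIST",
                                    "INPATIENT_OUTPATIENT_DB")
  sk_field <- clinical_data_field("pm_class", "DERIVED_PHENOTYPE_CLASS",
                                  "SUPPORTING_KNOWLEDGE", "poor metabolizer")
  nlp_field <- clinical_data_field("note", "LAB_VALUE", "LABORATORY_DB",
                                   "free-text note")
  prof <- make_profile(c(meds = "DISCRETE",
                         pm_class = "REQUIRES_SUPPORTING_KNOWLEDGE",
                         note = "REQUIRES_FULL_NLP"))

  r_disc <- simple_rule(disc_field)
  expect_true(rule_executable(r_disc, prof, "EMR_ALONE"))

  r_sk <- pgx_rule("r2", "drugx", "GENE",
                   condition("HAS_PHENOTYPE_CLASS",
                             list(gene = "CYP2C9", class = "poor_metabolizer"),
                             sk_field),
                   list(then_statement("note")), "TESTING_GUIDANCE")
  expect_false(rule_executable(r_sk, prof, "EMR_ALONE"))
  expect_true(rule_executable(r_sk, prof, "EMR_PLUS_KNOWLEDGE"))

  r_nlp <- pgx_rule("r3", "drugx", "GENE",
                    condition("LAB_COMPARE",
                              list(analyte = "note", comparator = ">",
                                   threshold = 1, units = "u"), nlp_field),
                    list(then_statement("note")), "TESTING_GUIDANCE")
  for (sc in c("EMR_ALONE", "EMR_PLUS_KNOWLEDGE", "EMR_PLUS_EXPANSION")) {
    expect_false(rule_executable(r_nlp, prof, sc))
  }
})

test_that("a fully discrete catalog has 100% coverage and no attribution", {
  catal <- gen_rule_catalog(seed = 2, n = 12)
  all_ids <- unique(unlist(lapply(catal$rules, function(r) {
    req <- antecedent_fields(r)
    vapply(c(req$fields, req$supporting_knowledge),
           function(f) f$field_id, character(1))
  })))
  prof <- make_profile(setNames(rep("DISCRETE", length(all_ids)), all_ids))
  cov <- coverage(catal, prof)
  expect_true(all(cov$scenarios$percent == 100))
  expect_true(all(cov$attribution$count == 0))
})

test_that("coverage equals the per-rule oracle and is scenario-monotone", {
  for (seed in 1:40) {
    catal <- gen_rule_catalog(seed = seed, n = 10)
    prof <- gen_capability_profile(seed = seed + 1000)
    cov <- coverage(catal, prof)
    expect_equal(setNames(cov$scenarios$executable, cov$scenarios$scenario),
                 oracle_coverage_counts(catal, prof))
    expect_true(all(diff(cov$scenarios$executable) >= 0))
  }
})

test_that("upgrading a field toward DISCRETE never lowers coverage", {
  catal <- gen_rule_catalog(seed = 4, n = 15)
  prof <- gen_capability_profile(seed = 8)
  before <- coverage(catal, prof)$scenarios$executable
  for (i in seq_along(prof$entries)) {
    upgraded <- prof
    upgraded$entries[[i]]$status <- "DISCRETE"
    after <- coverage(catal, upgraded)$scenarios$executable
    expect_true(all(after >= before))
  }
})

test_that("attribution counts rules blocked past supporting knowledge", {
  catal <- gen_rule_catalog(seed = 13, n = 50)
  prof <- gen_capability_profile(seed = 14)
  cov_any <- coverage(catal, prof, attribution = "any")
  cov_sole <- coverage(catal, prof, attribution = "sole")
  n_blocked <- length(catal) -
    cov_any$scenarios$executable[cov_any$scenarios$scenario ==
                                   "EMR_PLUS_KNOWLEDGE"]
  expect_true(all(cov_any$attribution$count <= n_blocked))
  # sole-blocker counting is never larger than any-blocker counting
  expect_true(all(cov_sole$attribution$count <= cov_any$attribution$count))
})

test_that("profile matching is exact-first with conflicts rejected", {
  field <- clinical_data_field("cyp2c9_variant_status",
                               "GERMLINE_VARIANT_STATUS", "LABORATORY_DB",
                               "CYP2C9")
  prof <- capability_profile(list(
    list(match = list(field_id = "cyp2c9_variant_status"),
         status = "DISCRETE"),
    list(match = list(kind = "GERMLINE_VARIANT_STATUS", detail = "CYP*"),
         status = "ABSENT")
  ))
  expect_equal(field_status(prof, field), "DISCRETE")

  other <- clinical_data_field("cyp2d6_variant_status",
                               "GERMLINE_VARIANT_STATUS", "LABORATORY_DB",
                               "CYP2D6")
  expect_equal(field_status(prof, other), "ABSENT")

  # unmatched fields take the default status
  stray <- clinical_data_field("stray", "LAB_VALUE", "LABORATORY_DB", "x")
  expect_equal(field_status(prof, stray), "ABSENT")

  conflicted <- capability_profile(list(
    list(match = list(kind = "GERMLINE_VARIANT_STATUS", detail = "CYP*"),
         status = "DISCRETE"),
    list(match = list(kind = "GERMLINE_VARIANT_STATUS", detail = "*2C9*"),
         status = "ABSENT")
  ))
  expect_error(field_status(conflicted, field), class = "PROFILE_CONFLICT")

  expect_error(capability_profile(list(
    list(match = list(field_id = "a"), status = "DISCRETE"),
    list(match = list(field_id = "a"), status = "ABSENT")
  )), class = "PROFILE_CONFLICT")
})

test_that("profiles round-trip through YAML", {
  prof <- gen_capability_profile(seed = 6)
  tf <- withr::local_tempfile(fileext = ".yaml")
  save_profile(prof, tf)
  expect_identical(load_profile(tf), prof)
})

test_that("category distribution cross-tabulates rules", {
  cd <- category_distribution(table2_rules())
  expect_equal(unname(cd$presentation_counts[c("RECOMMENDATION",
                                               "INFORMATION", "WARNING")]),
               c(2, 2, 1))
  expect_equal(sum(cd$table), 5)
  expect_equal(unname(cd$category_counts[["COADMINISTRATION"]]), 1)

  one <- rule_catalog(list(table2_rules()$rules[[1]]))
  cd1 <- category_distribution(one)
  expect_equal(sum(cd1$table), 1)
  expect_equal(cd1$table["DOSE_ADJUSTMENT", "RECOMMENDATION"], 1)

  # planted category mix recovered exactly
  catal <- gen_rule_catalog(seed = 31, n = 70)
  cd2 <- category_distribution(catal)
  gt <- table(catal$metadata$ground_truth$category)
  expect_equal(unname(cd2$category_counts[names(gt)]), unname(as.integer(gt)))
  # marginal presentation distribution equals the classifier's
  cc <- classify_catalog(catal)
  expect_equal(unname(cd2$presentation_counts),
               cc$distribution$count)

  bad <- catal
  bad$rules[[1]]$general_category <- "NOT_A_CATEGORY"
  expect_error(category_distribution(bad), class = "MISSING_CATEGORY")
})
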