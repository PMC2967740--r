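test_that("certainty extraction matches whole words case-insensitively", {
  r1 <- extract_certainty("coadministration should be approached with caution")
  expect_equal(r1$level, "MEDIUM_HIGH")
  expect_true("should" %in% r1$matched_tokens$token)

  r2 <- extract_certainty(
    "the dose adjustment for Clopidogrel is unknown for the patient")
  expect_equal(r2$level, "MEDIUM_HIGH")
  expect_true("is" %in% r2$matched_tokens$token)

  # substring "may" inside "Maybe" must not match
  r3 <- extract_certainty("Maybe useful")
  expect_equal(r3$level, "NONE")
  expect_equal(nrow(r3$matched_tokens), 0)

  # hedge dominates a co-occurring confident verb
  r4 <- extract_certainty("the dose should be reduced and may be split")
  expect_equal(r4$level, "LOW")

  # offsets point at the matched token
  r5 <- extract_certainty("patients may need monitoring")
  expect_equal(r5$matched_tokens$offset[1], 10L)

  expect_error(extract_certainty(""), class = "EMPTY_STATEMENT")
})

test_that("statement classification reproduces the worked labels", {
  lex <- certainty_lexicon()
  expect_equal(classify_statement(then_statement(
    "recommended dose of Gleevec is 400 mg/day", "CLEAR", FALSE), lex),
    "RECOMMENDATION")
  expect_equal(classify_statement(then_statement(
    "the dose adjustment for Clopidogrel is unknown for the patient",
    "NONE", FALSE), lex), "INFORMATION")
  expect_equal(classify_statement(then_statement(
    "coadministration should be approached with caution", "VAGUE", TRUE),
    lex), "WARNING")
  # directionless "should be adjusted" stays information
  expect_equal(classify_statement(then_statement(
    "the dose of Atomoxetine should be adjusted", "VAGUE", FALSE), lex),
    "INFORMATION")
  # tie-break: recommendation + consequences -> warning
  expect_equal(classify_statement(then_statement(
    "the dose should be halved to avoid toxicity", "CLEAR", TRUE), lex),
    "WARNING")
})

test_that("decision procedure agrees with the hand-enumerated truth table", {
  lex <- certainty_lexicon()
  for (i in seq_len(nrow(classifier_truth_table))) {
    row <- classifier_truth_table[i, ]
    stmt <- then_statement(certainty_texts[[row$certainty]],
                           row$action, row$consequence)
    expect_equal(classify_statement(stmt, lex), row$expected,
                 info = sprintf("action=%s consequence=%s certainty=%s",
                                row$action, row$consequence, row$certainty))
  }
})

test_that("catalog classification reports counts and percentages", {
  res <- classify_catalog(table2_rules())
  counts <- setNames(res$distribution$count, res$distribution$type)
  expect_equal(counts[["RECOMMENDATION"]], 2)
  expect_equal(counts[["INFORMATION"]], 2)
  expect_equal(counts[["WARNING"]], 1)
  expect_equal(sum(res$distribution$count), 5)

  one <- rule_catalog(list(pgx_rule(
    "w1", "drugx", "GENE", table2_rules()$rules[[1]]$antecedent,
    list(then_statement("risk of bleeding", "NONE", TRUE)),
    "PRE_TREATMENT_CONSIDERATION")))
  res1 <- classify_catalog(one)
  expect_equal(res1$distribution$percent[res1$distribution$type == "WARNING"],
               100)

  expect_error(classify_catalog(rule_catalog(list())),
               class = "EMPTY_CATALOG")
})

test_that("classification recovers planted labels and ignores order", {
  catal <- gen_rule_catalog(seed = 21, n = 60)
  res <- classify_catalog(catal)
  gt <- catal$metadata$ground_truth$presentation
  expect_identical(res$assignments[names(gt)], gt)

  shuffled <- catal
  set.seed(1)
  shuffled$rules <- sample(shuffled$rules)
  expect_identical(classify_catalog(shuffled)$distribution, res$distribution)
})

test_that("severity is monotone in the statement annotations", {
  lex <- certainty_lexicon()
  for (action in c("NONE", "VAGUE", "CLEAR")) {
    for (cert in names(certainty_texts)) {
      txt <- certainty_texts[[cert]]
      base <- classify_statement(then_statement(txt, action, FALSE), lex)
      flagged <- classify_statement(then_statement(txt, action, TRUE), lex)
      expect_gte(severity_rank(flagged), severity_rank(base))
    }
  }
  # raising action specificity never lowers severity
  for (cert in names(certainty_texts)) {
    txt <- certainty_texts[[cert]]
    ranks <- vapply(c("NONE", "VAGUE", "CLEAR"), function(a) {
      severity_rank(classify_statement(then_statement(txt, a, FALSE), lex))
    }, integer(1))
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("empty lexicons preclude recommendations", {
  lex <- certainty_lexicon(low_terms = character(),
                           high_terms = character())
  stmt <- then_statement("the dose should be reduced by 50%", "CLEAR", FALSE)
  expect_equal(classify_statement(stmt, lex), "INFORMATION")
})

test_that("lexicons load from YAML and reject overlapping term sets", {
  lex <- load_lexicon(system.file("extdata", "default_lexicon.yaml",
                                  package = "pgxcds"))
  expect_identical(lex, certainty_lexicon())
  expect_error(certainty_lexicon(low_terms = c("may"),
                                 high_terms = c("may", "is")),
               class = "LEXICON_OVERLAP")
})
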