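test_that("the worked derivations hold", {
  sk <- default_supporting_knowledge()

  b1 <- fact_base(list(fact("genotype", "CYP2C9", "*2/*3")))
  cl1 <- derive_facts(b1, sk)
  expect_true(has_fact(cl1, fact("phenotype_class", "CYP2C9",
                                 "poor_metabolizer")))

  b2 <- fact_base(list(fact("age", 12)))
  cl2 <- derive_facts(b2, sk)
  expect_true(has_fact(cl2, fact("demographic_class", "child")))
  # provenance names the deriving rule
  key <- pgxcds:::fact_key(fact("demographic_class", "child"))
  expect_equal(unname(cl2$provenance[key]), "sk_age_child")

  b3 <- fact_base(list(fact("age", 40)))
  expect_false(has_fact(derive_facts(b3, sk),
                        fact("demographic_class", "child")))

  # closure of nothing is the identity
  expect_identical(derive_facts(b1, list()), b1)
})

test_that("packaged supporting knowledge is self-consistent", {
  sk <- default_supporting_knowledge()
  expect_gt(length(sk), 10)
  for (r in sk) expect_silent(pgxcds:::check_sk_rule(r))
  ids <- vapply(sk, function(r) r$sk_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # drug-class membership drives class derivation
  b <- fact_base(list(fact("medication_active", "fluoxetine")))
  expect_true(has_fact(derive_facts(b, sk),
                       fact("taking_drug_in_class", "cyp2d6_strong_inhibitors")))
})

test_that("chained rules close transitively", {
  rules <- list(
    list(op = "AND", atoms = "A", derived = "B"),
    list(op = "AND", atoms = "B", derived = "C"),
    list(op = "AND", atoms = "C", derived = "D")
  )
  cl <- derive_facts(atoms_to_base("A"), atoms_to_sk_rules(rules))
  expect_equal(closure_atoms(cl), c("A", "B", "C", "D"))
  expect_equal(oracle_closure("A", rules), c("A", "B", "C", "D"))
})

test_that("closure is idempotent, monotone, and order independent", {
  for (seed in 1:25) {
    case <- random_atom_ruleset(seed)
    sk <- atoms_to_sk_rules(case$rules)
    base <- atoms_to_base(case$base)
    cl <- derive_facts(base, sk)

    # idempotent
    expect_identical(closure_atoms(derive_facts(cl, sk)), closure_atoms(cl))
    # monotone: output contains input
    expect_true(all(closure_atoms(base) %in% closure_atoms(cl)))
    # monotone in base: closing a subset stays inside
    sub <- atoms_to_base(case$base[seq_len(max(1, length(case$base) %/% 2))])
    expect_true(all(closure_atoms(derive_facts(sub, sk)) %in%
                      closure_atoms(cl)))
    # monotone in rules
    sub_rules <- sk[seq_len(max(1, length(sk) %/% 2))]
    expect_true(all(closure_atoms(derive_facts(base, sub_rules)) %in%
                      closure_atoms(cl)))
    # order independent
    expect_identical(closure_atoms(derive_facts(base, rev(sk))),
                     closure_atoms(cl))
    # equals the naive repeated-scan oracle
    expect_identical(closure_atoms(cl), oracle_closure(case$base, case$rules))
  }
})

test_that("variable binding joins antecedent leaves", {
  # any active medication known to be in a class marks the class as taken
  r <- sk_rule("join",
               cnd_and(fact_pattern("medication_active", "?d"),
                       fact_pattern("member_of", "?c", "?d")),
               fact("taking_drug_in_class", "?c"))
  base <- fact_base(list(
    fact("medication_active", "codeine"),
    fact("member_of", "opioids", "codeine"),
    fact("member_of", "opioids", "morphine"),
    fact("member_of", "nsaids", "celecoxib")
  ))
  cl <- derive_facts(base, list(r))
  expect_true(has_fact(cl, fact("taking_drug_in_class", "opioids")))
  expect_false(has_fact(cl, fact("taking_drug_in_class", "nsaids")))
})

test_that("malformed derivation rules are rejected", {
  expect_error(
    sk_rule("unbound", fact_pattern("atom", "A"), fact("atom", "?x")),
    class = "UNBOUND_DERIVATION")
  expect_error(
    sk_rule("negated", cnd_not(fact_pattern("atom", "A")), fact("atom", "B")),
    class = "NONMONOTONIC_RULE")
  expect_error(
    sk_rule("var_in_or",
            cnd_or(fact_pattern("atom", "?x"), fact_pattern("atom", "B")),
            fact("atom", "C")),
    class = "VARIABLE_SCOPE")
})

test_that("the safety cap bounds runaway closures", {
  r <- sk_rule("grow", fact_pattern("n", "?x"), fact("m", "?x"))
  base <- fact_base(lapply(1:50, function(i) fact("n", i)))
  expect_error(derive_facts(base, list(r), max_facts = 60),
               class = "DERIVATION_LIMIT")
})

test_that("single-allele and diplotype genotype conditions both match", {
  sk <- default_supporting_knowledge()
  # exact diplotype required for the poor-metabolizer rules
  cl_het <- derive_facts(fact_base(list(fact("genotype", "CYP2C9", "*1/*2"))), sk)
  expect_false(has_fact(cl_het, fact("phenotype_class", "CYP2C9",
                                     "poor_metabolizer")))
  # single-allele condition matches either chromosome
  cond <- condition("HAS_VARIANT", list(gene = "CYP2C9", allele = "*2"),
                    clinical_data_field("g", "GERMLINE_VARIANT_STATUS",
                                        "LABORATORY_DB", "CYP2C9"))
  base <- fact_base(list(fact("genotype", "CYP2C9", "*1/*2")))
  expect_true(pgxcds:::sk_eval_condition(cond, base))
})
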