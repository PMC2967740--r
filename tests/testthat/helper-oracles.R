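# Independent oracles used across the suite. These deliberately avoid the
# package's own engine paths: the closure oracle is a naive repeated full
# scan over atom names, the coverage oracle a per-rule/per-scenario loop,
# and the truth tables are written out by hand.

# --- naive fixpoint oracle over abstract atoms ------------------------------
# rules: list of list(op = "AND"|"OR", atoms = character(), derived = atom)
oracle_closure <- function(base_atoms, rules) {
  known <- unique(base_atoms)
  repeat {
    added <- FALSE
    for (r in rev(rules)) {  # reversed order: order must not matter
      sat <- if (r$op == "AND") all(r$atoms %in% known)
             else any(r$atoms %in% known)
      if (sat && !(r$derived %in% known)) {
        known <- c(known, r$derived)
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(known)
}

# build the engine-facing form of an abstract atom rule set
atoms_to_sk_rules <- function(rules) {
  lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    leaves <- lapply(r$atoms, function(a) fact_pattern("atom", a))
    ante <- if (length(leaves) == 1) leaves[[1]]
            else if (r$op == "AND") do.call(cnd_and, leaves)
            else do.call(cnd_or, leaves)
    sk_rule(sprintf("r%02d", i), ante, fact("atom", r$derived))
  })
}

atoms_to_base <- function(base_atoms) {
  fact_base(lapply(base_atoms, function(a) fact("atom", a)))
}

closure_atoms <- function(base) {
  sort(unname(vapply(base$facts, function(f) f$args[[1]], character(1))),
       method = "radix")
}

# seeded random abstract rule set of <= max_rules rules over `n_atoms` atoms
random_atom_ruleset <- function(seed, n_atoms = 12, max_rules = 20) {
  set.seed(seed)
  atoms <- sprintf("a%02d", seq_len(n_atoms))
  n_rules <- sample.int(max_rules, 1)
  rules <- lapply(seq_len(n_rules), function(i) {
    list(op = sample(c("AND", "OR"), 1),
         atoms = sample(atoms, sample.int(3, 1)),
         derived = sample(atoms, 1))
  })
  base <- sample(atoms, sample.int(n_atoms, 1))
  list(rules = rules, base = base)
}

# --- per-rule coverage oracle ------------------------------------------------
oracle_coverage_counts <- function(catalog, profile) {
  vapply(c("EMR_ALONE", "EMR_PLUS_KNOWLEDGE", "EMR_PLUS_EXPANSION"),
         function(sc) {
           sum(vapply(catalog$rules, rule_executable, logical(1),
                      profile = profile, scenario = sc))
         }, numeric(1))
}

# --- hand-enumerated Kleene truth tables ------------------------------------
kleene_and_table <- data.frame(
  a = c("TRUE", "TRUE", "TRUE", "FALSE", "FALSE", "FALSE",
        "UNKNOWN", "UNKNOWN", "UNKNOWN"),
  b = c("TRUE", "FALSE", "UNKNOWN", "TRUE", "FALSE", "UNKNOWN",
        "TRUE", "FALSE", "UNKNOWN"),
  out = c("TRUE", "FALSE", "UNKNOWN", "FALSE", "FALSE", "FALSE",
          "UNKNOWN", "FALSE", "UNKNOWN"),
  stringsAsFactors = FALSE
)

kleene_or_table <- data.frame(
  a = kleene_and_table$a,
  b = kleene_and_table$b,
  out = c("TRUE", "TRUE", "TRUE", "TRUE", "FALSE", "UNKNOWN",
          "TRUE", "UNKNOWN", "UNKNOWN"),
  stringsAsFactors = FALSE
)

kleene_not_table <- data.frame(
  a = c("TRUE", "FALSE", "UNKNOWN"),
  out = c("FALSE", "TRUE", "UNKNOWN"),
  stringsAsFactors = FALSE
)

# --- hand-enumerated classifier truth table ---------------------------------
# statement texts carrying exactly one certainty signal each
certainty_texts <- c(
  LOW = "the dose may require adjustment for the patient",
  MEDIUM_HIGH = "the dose should be reduced for the patient",
  NONE = "dose adjustment unknown for the patient"
)

classifier_truth_table <- data.frame(
  action = rep(c("NONE", "VAGUE", "CLEAR"), each = 6),
  consequence = rep(rep(c(FALSE, TRUE), each = 3), times = 3),
  certainty = rep(c("LOW", "MEDIUM_HIGH", "NONE"), times = 6),
  expected = c(
    # action NONE, no consequence
    "INFORMATION", "INFORMATION", "INFORMATION",
    # action NONE, consequence
    "WARNING", "WARNING", "WARNING",
    # action VAGUE, no consequence
    "INFORMATION", "INFORMATION", "INFORMATION",
    # action VAGUE, consequence
    "WARNING", "WARNING", "WARNING",
    # action CLEAR, no consequence
    "INFORMATION", "RECOMMENDATION", "INFORMATION",
    # action CLEAR, consequence
    "WARNING", "WARNING", "WARNING"
  ),
  stringsAsFactors = FALSE
)
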