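---
title: "Rule-based pharmacogenomic decision support: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based pharmacogenomic decision support: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcds)
```

## The problem

Drug labels increasingly carry pharmacogenomic (PGx) guidance — dose
reductions for poor metabolizers of CYP2C9 or CYP2D6 substrates,
pre-treatment genotype screening, coadministration cautions — but that
guidance lives in free text. To surface it at the point of care, three
things must hold: the guidance must be expressible as computable if-then
rules; each rule's consequent must map to an alert of appropriate
urgency; and the electronic medical record (EMR) must actually hold the
clinical data the rule's antecedent reads. `pgxcds` implements each link
of that chain as a testable component.

## The rule model

A decision rule is `IF antecedent THEN consequents`, where the
antecedent is an explicit AND/OR/NOT tree over typed predicates
(medication active or considered, disease status, germline star-allele
variant, derived phenotype class, tumor mutation, age or lab comparison)
and each leaf reads exactly one *clinical-data field* tagged with the
system that would supply it: the inpatient/outpatient database, a
laboratory system, or supporting knowledge. Source prose uses AND/OR
informally; fixing a grammar makes both evaluation and data-requirement
extraction (`antecedent_fields()`) mechanical.

Two encoding conventions are worth stating:

* **Diplotypes** are normalized to `*a/*b` with alleles ascending
  numerically, so `*3/*2` and `*2/*3` are one genotype. A single-allele
  condition (`HAS_VARIANT *2`) matches either chromosome; a diplotype
  condition matches exactly. This mirrors the two phrasings that occur
  in label text ("CYP2C9\*2 or \*3 variants" vs "genotype CYP2C9\*2/\*3").
* **Two-source checks.** A phenotype-class or drug-class test needs both
  a raw EMR field (variant status, the medication list) and a
  supporting-knowledge definition (which diplotypes count as poor
  metabolizers, which drugs are in the class). Because a leaf reads one
  field, such a check is encoded as an AND of two leaves with identical
  predicate and arguments — the truth value is unchanged, and both data
  requirements surface to the coverage analysis.

Medication names are matched on a normalized lowercase generic form;
brand names resolve through an editable two-column synonym table, since
label text mixes brand and generic naming.

## Presentation-type classification

Each consequent statement is classified as `INFORMATION`,
`RECOMMENDATION`, or `WARNING` — in increasing order of actionability —
by a three-step procedure:

1. if the statement specifies potential consequences → **WARNING**
   (whatever its language);
2. else if it specifies a clear action in medium/high-certainty
   language (`should, will, are, is, must, was, do`) →
   **RECOMMENDATION**;
3. else → **INFORMATION** (no action, or hedged language:
   `might, may, could`).

The step order realizes the tie-breaks warning > recommendation >
information. The source methods list the prioritization once in a
different order, but both worked tie-break sentences imply this one; we
follow the worked sentences.

Design choices where the source is silent:

* **Mixed certainty.** When a hedge and a confident verb co-occur, the
  hedge wins (level `LOW`): hedged language downgrades actionability,
  the conservative reading.
* **"Clear action" operationalized.** `CLEAR` requires a concrete
  executable instruction (a specific dose, test, or contraindication);
  a directionless "should be adjusted" is `VAGUE`. This is what
  reconciles the atomoxetine example being labeled information despite
  its "should".
* **Annotations are curated, not text-mined.** The original
  classification was manual; `action_specificity` and
  `consequence_flag` are therefore explicit annotations on each
  statement. A small consequence lexicon (risk, caution, adverse,
  toxicity, bleeding, fatal) is shipped as advisory vocabulary only —
  it never overrides the flag.
* **Lexical matching** is case-insensitive on word boundaries, so "may"
  never fires inside "Maybe".
* **Multi-statement rules** take the maximum severity across their
  statements: an alert must not understate risk.

All percentages in every module round half away from zero — the
convention consistent with four of the five published evidence-category
percentages and with 11/28 → 39% (the fifth, clinical outcome, is
inconsistent with any uniform convention and is excluded from numeric
checks).

## Supporting knowledge and forward chaining

Supporting-knowledge rules derive intermediate facts from raw data:
`genotype(CYP2C9, *2/*3)` → `phenotype_class(CYP2C9, poor_metabolizer)`;
`age < 18` → `demographic_class(child)`; an active medication in a
class list → `taking_drug_in_class(...)`. `derive_facts()` computes the
least fixpoint: facts are ground and positive only, `NOT` is rejected in
antecedents, and retraction does not exist, so the closure is unique,
monotone, and order-independent — properties the test suite checks
against a naive repeated-scan oracle on randomized rule sets.

Variables (`?x`) are supported in AND-only antecedents via a natural
join over matched leaves; the published examples are all ground, so the
restriction costs no expressiveness there. Derived templates must bind
every variable (`UNBOUND_DERIVATION` otherwise), and a hard cap of
10,000 facts (`DERIVATION_LIMIT`) guards against malformed rule sets.

The packaged diplotype-to-phenotype lists and drug-class memberships
are **illustrative placeholders**: beyond the canonical CYP2C9\*2/\*3
example the source names classes but not members. Both live in editable
TSVs (marked ILLUSTRATIVE) so an institution can substitute
authoritative tables without touching code.

## Three-valued patient evaluation

Missing clinical data is the central obstacle to deploying PGx rules,
so evaluation uses strong Kleene three-valued logic: a condition over
absent data (gene not in the genotype map, analyte not on file, a
`NULL` medication list, unknown age) is `UNKNOWN`, AND is
FALSE-dominant, OR TRUE-dominant, NOT preserves `UNKNOWN`. A rule
**fires only when its antecedent is TRUE** — never on `UNKNOWN`, the
patient-safety conservative default — and an `UNKNOWN` antecedent yields
`INDETERMINATE` with the blocking fields listed, which is exactly the
signal the coverage analysis aggregates. Set-valued record fields
(medication lists, diseases) are closed-world when supplied: an empty
list means "known none", while `NULL` means "not recorded". Lab
comparisons require exact unit agreement and raise `UNIT_MISMATCH`
rather than silently comparing incommensurables.

"Considering" a prescription is a distinct predicate
(`MEDICATION_CONSIDERED`) so pre-prescription decision support is
expressible. A rule with several consequents emits one combined alert;
emitting one alert per statement would be the alternative, and nothing
downstream depends on the choice.

## Coverage analysis

An EMR capability profile maps each clinical-data field to one of eight
availability statuses: `DISCRETE`, `REQUIRES_SUPPORTING_KNOWLEDGE`,
four feasible-expansion categories (disease-status definitions,
pathology fields, microbiology fields, parseable free text),
`REQUIRES_FULL_NLP`, and `ABSENT`. Profiles match fields exactly by id
first, then by (kind, detail-glob) patterns; conflicting pattern
matches are an error (`PROFILE_CONFLICT`), never a silent precedence.

Coverage is computed under three strictly nested scenarios — EMR alone
(discrete data only), plus supporting knowledge, plus feasible
expansion — so executable counts are provably non-decreasing. Fields
requiring full NLP or absent outright are satisfiable in no scenario,
which is what bounds maximum coverage below 100%.

**Attribution.** A rule still blocked after supporting knowledge is
attributed to every blocking category it needs (`attribution = "any"`),
the literal reading of "lack of access would inhibit execution"; a
sole-blocker mode (`"sole"`) counts only rules blocked by exactly one
category, since it cannot be determined which convention produced the
published attribution percentages. Both modes are reported by
`analysis/04_coverage.R`.

## The synthetic generators

No patient data or full rule catalog accompanies the source material
(the complete 106-rule catalog and the specific EMR profile were never
published), so `pgxcds` ships seeded generators whose defaults are the
stated study conditions:

* `gen_rule_catalog()` plants presentation labels with the published
  39/39/22 mix and support categories with the published 50/24/13/9/4
  general-category mix. The pooled 50% (dose adjustment, monitoring,
  pre-treatment consideration) is split 20/15/15 — our choice, fixed
  once; no finer split is published. Mixes are planted by
  largest-remainder apportionment and a seeded shuffle, so recovery
  tests can demand *exact* agreement: at n = 200 the planted mix prints
  as exactly 39/39/22%; at n = 106 no integer split prints as 39/39/22
  and apportionment yields 42/41/23 rules (40/39/22%).
* Consequent texts are templated so the classifier provably returns the
  planted label; antecedent fields are drawn from a fixed 40-field pool
  addressable by generated capability profiles.
* `gen_capability_profile()` plants an availability mix whose default
  (45% discrete, 20% supporting-knowledge, 25% across the four
  expansion categories, 10% NLP-bound or absent) emulates a mid-size
  academic EMR; the published per-rule coverage figures imply no unique
  field-level mix, so this is a package choice, stated here and not
  tuned.
* `gen_patient()` draws two alleles per gene from stated frequencies
  (defaults are rough European-ancestry frequencies for common
  CYP2C9/CYP2C19/CYP2D6 alleles); a frequency-1 allele yields the
  homozygous diplotype deterministically.
* `gen_citation_sets(n_a, n_b, n_shared)` constructs citation sets with
  an exactly planted intersection, and `gen_publications()` plants
  per-category counts exactly.

Each generator runs on a private RNG stream seeded by its argument and
restores the caller's random state. What the generators do **not**
emulate: real label prose (texts come from a small template family),
correlated clinical data (comorbidity, drug-genotype dependence), EMR
field taxonomies, or inter-curator disagreement. Passing the
plant-and-recover suites therefore demonstrates that the pipeline is
exact on data satisfying its representational assumptions — not that
those assumptions capture any particular institution's records.

## Numerical and procedural choices

* Rounding: half away from zero, everywhere a percentage is printed.
* Apportionment ties: largest remainder, first-listed category wins.
* Alert ordering: severity descending, ties by rule id — deterministic
  output for fixed input.
* Catalog interchange is versioned YAML (JSON accepted on load);
  loading rejects unknown `format_version` values, duplicate rule ids,
  and incomplete predicate arguments, reporting each violation with a
  machine-readable code.
* Problem sizes in the default test and reproduction runs — 200
  randomized rule sets for the fixpoint suite, 1,000 catalog/profile
  pairs for scenario monotonicity, 200-rule catalogs for recovery —
  were chosen as the smallest sizes at which the property suites
  exercise all code paths with comfortable margin.

## Known limitations

* The headline curation results (79 passages, 106 rules, the published
  coverage and attribution percentages) depend on manual review of 28
  external drug labels and one institution's EMR; they cannot be
  recomputed from first principles. The property suites above stand in
  for them: exact label recovery, scenario monotonicity mirroring the
  published 32% → 50% → 89% ordering, and oracle equality.
* The published 6.4% citation-overlap percentage matches no recoverable
  denominator (28/425 rounds to 7%, 28/453 to 6%); `overlap_stats`
  reports the union-based percentage and the raw counts.
* The transcribed encoded-knowledge table lists 30 drugs although the
  accompanying text describes 28; the fixture follows the table.
* The classifier's `CLEAR`/`VAGUE` operationalization is validated only
  against the five published example rules; agreement with the original
  curators' judgement beyond those cannot be assessed (single-curator
  assignment was a stated limitation of the original study design).
* No negation-as-failure in supporting knowledge: rules that need
  "patient is NOT in class X" over incomplete data are out of scope by
  design.
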