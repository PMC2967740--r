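test_that("overlap statistics are exact set arithmetic", {
  a <- citation_set("a", c("p1", "p2", "p3"))
  b <- citation_set("b", c("q1", "q2", "q3", "q4"))
  s <- overlap_stats(a, b)
  expect_equal(s$intersection, 0)
  expect_equal(s$union, 7)
  expect_equal(s$pct_of_union, 0)

  s2 <- overlap_stats(a, a)
  expect_equal(s2$pct_of_union, 100)

  # identifiers normalize case-insensitively with whitespace trimmed
  s3 <- overlap_stats(citation_set("x", c(" P1", "p2")),
                      citation_set("y", c("p1 ", "P3")))
  expect_equal(s3$intersection, 1)

  expect_error(overlap_stats(citation_set("x", character()),
                             citation_set("y", character())),
               class = "EMPTY_SETS")
})

test_that("planted citation overlaps are recovered by inclusion-exclusion", {
  cs <- gen_citation_sets(185, 268, 28, seed = 3)
  s <- overlap_stats(cs$a, cs$b)
  expect_equal(s$size_a, 185)
  expect_equal(s$size_b, 268)
  expect_equal(s$intersection, 28)
  expect_equal(s$union, 425)

  # inclusion-exclusion identity on random instances
  for (seed in 1:10) {
    set.seed(seed)
    na <- sample(5:60, 1); nb <- sample(5:60, 1)
    ns <- sample.int(min(na, nb), 1)
    cs <- gen_citation_sets(na, nb, ns, seed = seed)
    s <- overlap_stats(cs$a, cs$b)
    expect_equal(s$union, s$size_a + s$size_b - s$intersection)
    expect_lte(s$intersection, min(s$size_a, s$size_b))
  }

  expect_error(gen_citation_sets(5, 6, 7, seed = 1),
               class = "INVALID_OVERLAP")
  ident <- gen_citation_sets(5, 5, 5, seed = 1)
  expect_setequal(ident$a$articles, ident$b$articles)
})

test_that("evidence-category percentages follow the shared rounding", {
  pubs <- gen_publications(n = 251,
                           counts = c(CO = 49, PD = 80, PK = 141,
                                      FA = 27, GN = 171), seed = 4)
  d <- evidence_category_distribution(pubs)
  got <- setNames(d$percent, d$category)
  expect_equal(got[["PD"]], 32)
  expect_equal(got[["PK"]], 56)
  expect_equal(got[["FA"]], 11)
  expect_equal(got[["GN"]], 68)

  all5 <- list(publication_record("p1", c("CO", "PD", "PK", "FA", "GN")))
  d5 <- evidence_category_distribution(all5)
  expect_true(all(d5$percent == 100))

  # counts equal a naive per-record tally, order-invariant
  set.seed(7)
  rnd <- lapply(1:40, function(i) {
    publication_record(paste0("r", i),
                       sample(c("CO", "PD", "PK", "FA", "GN"),
                              sample(0:5, 1)))
  })
  d_rnd <- evidence_category_distribution(rnd)
  naive <- vapply(c("CO", "PD", "PK", "FA", "GN"), function(cat) {
    n <- 0L
    for (p in rnd) if (cat %in% p$categories) n <- n + 1L
    n
  }, integer(1))
  expect_equal(setNames(d_rnd$count, d_rnd$category), naive)
  d_shuf <- evidence_category_distribution(rev(rnd))
  expect_identical(d_shuf, d_rnd)
  expect_true(all(d_rnd$count <= length(rnd)))

  expect_error(evidence_category_distribution(list()), class = "EMPTY_SET")
})

test_that("the undesignated fraction counts unflagged overlap articles", {
  pubs <- gen_publications(n = 28, counts = c(GN = 20),
                           n_undesignated = 11, seed = 2)
  u <- undesignated_fraction(pubs)
  expect_equal(u$count, 11)
  expect_equal(u$percent, 39)

  all_des <- gen_publications(n = 10, counts = c(GN = 5),
                              n_undesignated = 0, seed = 1)
  expect_equal(undesignated_fraction(all_des)$count, 0)
  expect_equal(undesignated_fraction(all_des)$percent, 0)
})

test_that("the transcribed knowledge matrix matches the printed table", {
  m <- table1_matrix()
  s <- knowledge_matrix_summary(m)
  expect_equal(s$n_drugs, 30)
  # warfarin carries all five knowledge forms; atomoxetine none
  expect_equal(unname(s$per_drug[["Warfarin"]]), 5)
  expect_equal(unname(s$per_drug[["Atomoxetine"]]), 0)
  expect_true(m["Abacavir", "VARIANT_EVIDENCE"])
  expect_false(m["Abacavir", "PATHWAY_EVIDENCE"])

  # fixture integrity: committed file checksum
  path <- system.file("extdata", "table1_matrix.tsv", package = "pgxcds")
  expect_equal(unname(tools::md5sum(path)),
               "3c0217c49ba6f776f0dc5080a7f03cc1")

  # round-trips through the TSV layout
  tf <- withr::local_tempfile(fileext = ".tsv")
  save_knowledge_matrix(m, tf)
  expect_equal(load_knowledge_matrix(tf), m)
})

test_that("degenerate matrices are handled", {
  m <- knowledge_matrix("OnlyDrug")
  s <- knowledge_matrix_summary(m)
  expect_true(all(s$per_form == 0))
  expect_error(knowledge_matrix_summary(knowledge_matrix(character())),
               class = "EMPTY_MATRIX")
  expect_error(knowledge_matrix(c("A", "A")), class = "DUPLICATE_DRUG")
})

test_that("citation sets and publications load from text files", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PMID100", "pmid101", "PMID100 "), tf)
  cs <- load_citation_set(tf, resource = "test")
  expect_length(cs$articles, 2)

  tp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("article_id\tcategories\tdesignated",
               "p1\tPD;GN\tTRUE", "p2\t\tFALSE"), tp)
  pubs <- load_publications(tp)
  expect_length(pubs, 2)
  expect_setequal(pubs[[1]]$categories, c("PD", "GN"))
  expect_false(pubs[[2]]$designated_for_pair)
})
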