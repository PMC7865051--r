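make_annotated <- function(ids, seqs, matures = seqs) {
  tibble::tibble(id = ids, protein = seqs, mature_seq = matures)
}

test_that("global identity agrees with a brute-force alignment oracle", {
  expect_equal(global_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(global_identity("AAAA", "TTTT"), 0.0)
  expect_equal(global_identity("ACDEFG", "ACDKFG"), 5 / 6)
  expect_error(global_identity("", "AAA"), "empty")

  set.seed(5)
  for (r in 1:25) {
    a <- random_peptide(sample(5:25, 1))
    b <- random_peptide(sample(5:25, 1))
    expect_equal(global_identity(a, b), oracle_global_identity(a, b),
                 tolerance = 1e-9)
  }
})

test_that("clustering recovers planted families and respects the scaffold constraint", {
  set.seed(9)
  specs <- list(
    crp_family_spec("A", 6, "family1", "family1", 19, "DEQR", "GK",
                    divergence = 0.05),
    crp_family_spec("B", 5, "family10", NULL, 0, mature_offset = c(7L, 10L),
                    divergence = 0.05),
    crp_family_spec("C", 4, "family15", NULL, 0, mature_offset = c(12L, 12L),
                    divergence = 0.05)
  )
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 13, families = specs))
  ann <- annotate_precursors(sim$proteins)
  fams <- classify_families(ann)
  expect_equal(nrow(attr(fams, "families")), 3L)
  tab <- table(tidy(fams)$family, sim$proteins$family)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # all-identical records collapse to one family
  one <- make_annotated(c("a", "b", "c"), rep("MKCACA", 3), rep("CACA", 3))
  f1 <- classify_families(one)
  expect_equal(nrow(attr(f1, "families")), 1L)

  # high identity but different cysteine counts -> separate families
  s6 <- paste0("MKLL", paste(rep("C", 6), collapse = "AAAA"))
  s8 <- paste0("MKLL", paste(rep("C", 8), collapse = "AAAA"))
  two <- make_annotated(c("x", "y"), c(s6, s8),
                        c(sub("^MKLL", "", s6), sub("^MKLL", "", s8)))
  f2 <- classify_families(two, id_threshold = 0.3)
  expect_equal(nrow(attr(f2, "families")), 2L)

  expect_error(classify_families(make_annotated("z", "MKAA", NA_character_)),
               "z")
})

test_that("clustering is invariant to input order", {
  set.seed(17)
  specs <- default_family_specs()[c(1, 9, 12)]
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 29, families = specs))
  ann <- annotate_precursors(sim$proteins)
  base <- tidy(classify_families(ann))
  for (r in 1:3) {
    perm <- sample(nrow(ann))
    shuffled <- tidy(classify_families(ann[perm, ]))
    expect_equal(dplyr::arrange(shuffled, id), dplyr::arrange(base, id))
  }
})

test_that("raising the identity threshold never decreases the family count", {
  set.seed(23)
  specs <- default_family_specs()[c(1, 2, 10)]
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 31, families = specs))
  ann <- annotate_precursors(sim$proteins)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(th) {
    nrow(attr(classify_families(ann, id_threshold = th), "families"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
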