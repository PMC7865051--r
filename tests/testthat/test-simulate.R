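test_that("generation is a pure function of (spec, seed)", {
  spec <- crp_generator_spec(seed = 77)
  s1 <- simulate_crp_dataset(spec)
  s2 <- simulate_crp_dataset(spec)
  expect_identical(s1, s2)
  s3 <- simulate_crp_dataset(crp_generator_spec(seed = 78))
  expect_false(identical(s1$proteins$seq, s3$proteins$seq))
})

test_that("generated precursors satisfy their own architecture", {
  set.seed(3)
  for (fs in default_family_specs()) {
    g <- gen_precursor(fs)
    t <- g$truth
    expect_equal(translate_cds(g$cdna), g$protein)
    expect_equal(substr(g$protein, t$mature_start + 1L, t$mature_end),
                 t$mature_seq)
    if (!is.na(t$pqm)) {
      expect_equal(substr(g$protein, t$propeptide_end - 3L, t$propeptide_end),
                   fs$pqm)
    }
    if (t$amidated) {
      expect_match(substr(g$protein, t$cterm_start + 1L, t$cterm_end),
                   "^G[K]{0,2}$")
    }
  }
})

test_that("a propeptide-free spec yields an absent propeptide", {
  fs <- crp_family_spec("nopro", 1, "family10", NULL, 0,
                        mature_offset = c(8L, 8L))
  set.seed(5)
  g <- gen_precursor(fs)
  expect_true(is.na(g$truth$propeptide_start))
})

test_that("evolution at omega 0 only ever changes codons synonymously", {
  set.seed(15)
  anc <- random_sense_cds(200)
  cds <- evolve_family(anc, 5, 0, 0.1)
  for (d in cds) {
    expect_equal(translate_cds(paste0(d, "TAA")),
                 translate_cds(paste0(anc, "TAA")))
  }
  h <- attr(cds, "history")
  expect_true(all(h$synonymous))
})

test_that("realized history dN/dS converges to the target at large scale", {
  set.seed(25)
  anc <- random_sense_cds(3334)   # ~10,000 nucleotide sites
  for (target in c(0.2, 1.0)) {
    cds <- evolve_family(anc, 2, target, 0.08)
    h <- attr(cds, "history")
    tab <- venomcrp:::ng_tables(Biostrings::GENETIC_CODE)
    S <- sum(tab$s_site[venomcrp:::split_codons(anc)])
    N <- 3 * 3334 - S
    realized <- (sum(!h$synonymous) / N) / (sum(h$synonymous) / S)
    expect_equal(realized, target, tolerance = 0.15)
  }
  expect_error(evolve_family(anc, 2, -1, 0.1), "omega")
})

test_that("mass observation generation is noiseless at sd 0 and seeded", {
  recs <- tibble::tibble(id = c("a", "b"),
                         mature_seq = c("AACCAA", "WWCCWW"),
                         amidated = c(FALSE, TRUE))
  mm <- gen_mass_observations(recs, noise_sd = 0, n_decoys = 0)
  expect_equal(mm$observations$m, mm$truth$m_theoretical)

  m1 <- gen_mass_observations(recs, noise_sd = 0.2, n_decoys = 5, seed = 3)
  m2 <- gen_mass_observations(recs, noise_sd = 0.2, n_decoys = 5, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(m1$observations$m[m1$observations$source == "decoy"] >= 2800 &
                  m1$observations$m[m1$observations$source == "decoy"] <= 8000))

  # decoy-only observation set has an empty truth pairing with any record set
  dec <- gen_mass_observations(recs[0, ], noise_sd = 0, n_decoys = 10, seed = 4)
  expect_equal(nrow(dec$truth), 0L)
})
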