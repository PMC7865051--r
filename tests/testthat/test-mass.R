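test_that("peptide masses match the residue sums and reject bad input", {
  expect_equal(peptide_mass("G"), 75.032025, tolerance = 1e-5)
  expect_equal(peptide_mass("GG"), 132.053485, tolerance = 1e-5)
  expect_error(peptide_mass(""), "empty")
  expect_error(peptide_mass("GXG"), "nonstandard")
})

test_that("monoisotopic masses agree with the atomic-composition oracle", {
  set.seed(91)
  for (r in 1:1000) {
    s <- random_peptide(sample(3:60, 1))
    expect_lt(abs(peptide_mass(s) - oracle_peptide_mass(s)), 1e-4)
  }
})

test_that("PTM adjustments apply the disulfide and amidation arithmetic", {
  expect_equal(apply_ptm(1000, 0, FALSE), 1000)
  expect_equal(apply_ptm(1000, 3, FALSE), 993.95305, tolerance = 1e-6)
  expect_equal(apply_ptm(1000, 0, TRUE), 999.015984, tolerance = 1e-6)
  expect_error(apply_ptm(1, 3, FALSE), "positive")
})

test_that("hypothesis enumeration covers the disulfide extremes and flags", {
  h <- enumerate_hypotheses(6, amidated = TRUE)
  expect_equal(h$n_disulfide, c(3L, 0L))
  expect_true(all(h$amidated))

  h0 <- enumerate_hypotheses(0, amidated = FALSE)
  expect_equal(nrow(h0), 1L)

  h8 <- enumerate_hypotheses(8, amidated = FALSE, all_intermediates = TRUE)
  expect_setequal(h8$n_disulfide, 0:4)

  hna <- enumerate_hypotheses(6, amidated = NA)
  expect_setequal(hna$amidated, c(TRUE, FALSE))
})

test_that("mass matching is exact at tol 0, monotone in tol, and decoy-safe", {
  set.seed(101)
  recs <- tibble::tibble(
    id = paste0("p", 1:10),
    mature_seq = replicate(10, random_peptide(30)),
    amidated = FALSE
  )
  theo <- vapply(seq_len(10), function(i) {
    ncys <- stringr::str_count(recs$mature_seq[i], "C")
    apply_ptm(peptide_mass(recs$mature_seq[i]), floor(ncys / 2), FALSE)
  }, numeric(1))

  exact <- match_masses(recs, theo, tol = 1e-9)
  expect_true(all(paste0("p", 1:10) %in% exact$id))
  planted <- exact[abs(exact$delta) < 1e-9, ]
  expect_equal(sort(unique(planted$id)), sort(recs$id))

  m1 <- match_masses(recs, theo + 0.3, tol = 0.4)
  m2 <- match_masses(recs, theo + 0.3, tol = 1.0)
  key <- function(m) paste(m$id, m$n_disulfide, m$amidated, round(m$observed, 6))
  expect_true(all(key(m1) %in% key(m2)))

  # decoys offset by +7 Da never match when masses are well separated
  sep <- tibble::tibble(id = c("a", "b"),
                        mature_seq = c("AAAACCAAAA", "WWWWCCWWWW"),
                        amidated = FALSE)
  dec <- vapply(sep$mature_seq, function(s) peptide_mass(s) + 7, numeric(1))
  expect_equal(nrow(match_masses(sep, unname(dec), tol = 0.5)), 0L)

  expect_equal(nrow(match_masses(recs, numeric(0), tol = 0.5)), 0L)
})

test_that("planted observations are recovered at tol = 5 sigma with decoys present", {
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 47))
  ann <- annotate_precursors(sim$proteins)
  mm <- gen_mass_observations(ann, noise_sd = 0.1, n_decoys = 30, seed = 48)
  matches <- match_masses(ann, mm$observations$m, tol = 0.5)
  planted <- paste(mm$truth$id, signif(mm$truth$m_observed, 10))
  got <- paste(matches$id, signif(matches$observed, 10))
  expect_gte(mean(planted %in% got), 0.99)
})
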