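test_that("codon site fractions match enumeration for the worked codons", {
  expect_equal(codon_sites("GGG"), list(s = 1, n = 2))
  expect_equal(codon_sites("TGG"), list(s = 0, n = 3))
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("NGG"), "codon")
})

test_that("site counting matches brute-force enumeration on all sense codons", {
  for (cd in SENSE) {
    got <- codon_sites(cd)
    ora <- oracle_codon_sites(cd)
    expect_equal(got$s, unname(ora["s"]), tolerance = 1e-12)
    expect_equal(got$s + got$n, 3)   # one site per position, always
  }
})

test_that("codon differences average over stop-free mutational pathways", {
  expect_equal(codon_differences("TTT", "TTT")[c("sd", "nd")],
               list(sd = 0, nd = 0))
  expect_equal(codon_differences("TTT", "TTC")[c("sd", "nd")],
               list(sd = 1, nd = 0))
  d <- codon_differences("TTT", "GTA")
  expect_equal(d$sd + d$nd, 2)
  ora <- oracle_codon_diff("TTT", "GTA")
  expect_equal(d$sd, unname(ora["sd"]))

  # a pathway through a stop codon is excluded and the result flagged
  d2 <- codon_differences("TGC", "TTA")   # TGC->TGA->TTA passes a stop
  expect_true(d2$flagged)
  expect_equal(d2$n_paths, 1L)
  expect_equal(c(d2$sd, d2$nd), c(0, 2))

  expect_error(codon_differences("TGT", "TAA"), "stop")
})

test_that("pathway counts match enumeration on 500 random codon pairs", {
  set.seed(55)
  for (r in 1:500) {
    c1 <- sample(SENSE, 1); c2 <- sample(SENSE, 1)
    got <- codon_differences(c1, c2)
    ora <- oracle_codon_diff(c1, c2)
    expect_equal(got$sd, unname(ora["sd"]), tolerance = 1e-12)
    expect_equal(got$nd, unname(ora["nd"]), tolerance = 1e-12)
  }
})

test_that("pairwise NG counting is symmetric and matches the brute-force oracle", {
  r0 <- ng_pair("ATGGGGAAA", "ATGGGGAAA")
  expect_equal(c(r0$pS, r0$pN, r0$omega), c(0, 0, 0))

  # one synonymous change only
  r1 <- ng_pair("ATGGGGAAA", "ATGGGAAAA")
  expect_equal(r1$pN, 0)
  expect_equal(r1$omega, 0)

  set.seed(61)
  for (r in 1:20) {
    a <- random_sense_cds(10)
    b <- random_sense_cds(10)
    got <- ng_pair(a, b)
    ora <- oracle_ng_pair(a, b)
    expect_equal(got$S, ora[["S"]], tolerance = 1e-10)
    expect_equal(got$Sd, ora[["Sd"]], tolerance = 1e-10)
    expect_equal(got$Nd, ora[["Nd"]], tolerance = 1e-10)
    ba <- ng_pair(b, a)
    expect_equal(got$pS, ba$pS)
    expect_equal(got$pN, ba$pN)
  }
})

test_that("gap and ambiguity codon columns are deleted pairwise", {
  got <- ng_pair("ATG---AAA", "ATGGGGAAA")
  expect_equal(got$n_codons, 2L)
  expect_error(ng_pair("---", "---"), "comparable")
})

test_that("region-wise family omega honours the stated conventions", {
  ids <- c("a", "b", "c")
  same <- rep("ATGAAACCTGGA", 3)
  aln <- codon_alignment(ids, same, regions = c("signal", "signal",
                                                "mature", "mature"))
  for (rg in c("signal", "mature")) {
    expect_equal(family_omega(aln, rg)$omega, 0)
  }
  expect_error(family_omega(aln, "propeptide"), "absent")

  # pS = 0 with pN > 0 is a flagged infinity
  aln2 <- codon_alignment(c("a", "b"), c("TTTAAA", "TTTGAA"))
  res2 <- family_omega(aln2, "mature")
  expect_true(res2$omega_undefined)
  expect_true(is.infinite(res2$omega))
})

test_that("the bootstrap Z-test is reproducible and handles degeneracy", {
  aln <- codon_alignment(c("a", "b"), rep("ATGAAACCTGGA", 2))
  expect_equal(ng_z_test(aln, reps = 100, seed = 1)$p_value, 1)

  set.seed(71)
  cds <- evolve_family(random_sense_cds(120), 6, 0.1, 0.1)
  aln2 <- codon_alignment(paste0("s", 1:6), cds)
  z1 <- ng_z_test(aln2, reps = 200, seed = 5)
  z2 <- ng_z_test(aln2, reps = 200, seed = 5)
  expect_identical(z1, z2)
  expect_lt(z1$p_value, 0.05)   # strong purifying signal
})

test_that("strong purifying selection is detected in most seeded replicates", {
  set.seed(81)
  hits <- replicate(20, {
    cds <- evolve_family(random_sense_cds(200), 8, 0.05, 0.1)
    aln <- codon_alignment(paste0("s", 1:8), cds)
    ng_z_test(aln, reps = 200, seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
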