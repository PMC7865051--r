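test_that("p-distance uses pairwise deletion of gaps and ambiguity", {
  expect_equal(p_distance("ACD-", "ACD-"), list(p = 0, sites = 3L))
  expect_equal(p_distance("ACDE", "ACDK"), list(p = 0.25, sites = 4L))
  expect_equal(p_distance("A-DE", "ACDK"), list(p = 1 / 3, sites = 3L))
  expect_true(is.na(p_distance("--", "AA")$p))
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("Poisson correction is the closed form and is monotone", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2))
  expect_equal(poisson_correct(0.9), -log(0.1))
  expect_true(is.na(poisson_correct(1)))
  p <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(poisson_correct(p)) > 0))
})

test_that("neighbor-joining reproduces the three-taxon closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("neighbor-joining recovers random additive trees exactly (n <= 12)", {
  set.seed(41)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    D <- random_additive_matrix(n)
    tr <- nj_tree(D)
    path <- stats::cophenetic(tr)[rownames(D), colnames(D)]
    expect_equal(unname(path), unname(D), tolerance = 1e-10)
    # independent cross-check: same topology as ape's NJ
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))[1], 0)
  }
})

test_that("degenerate and invalid distance matrices are handled", {
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(Z)
  expect_equal(sort(tr$tip.label), letters[1:4])
  expect_true(all(tr$edge.length == 0))

  NAd <- Z; NAd[1, 2] <- NAd[2, 1] <- NA
  expect_error(nj_tree(NAd), "a/b")
})

test_that("progressive alignment handles the stated base cases", {
  idt <- progressive_align(c(x = "MKAC", y = "MKAC", z = "MKAC"))
  expect_equal(unique(nchar(idt$seq)), 4L)
  expect_false(any(grepl("-", idt$seq)))

  gap <- progressive_align(c(a = "ACDE", b = "ACE"))
  expect_equal(unique(nchar(gap$seq)), 4L)
  expect_equal(sum(stringr::str_count(gap$seq, "-")), 1L)

  pre <- tibble::tibble(id = c("a", "b"), seq = c("AC-E", "ACDE"))
  expect_equal(progressive_align(pre), pre)
})

test_that("the full alignment-distance-NJ pipeline keeps every leaf and is monophyletic per family", {
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 37))
  ph <- crp_phylo(sim$proteins)
  expect_setequal(ph$tree$tip.label, sim$proteins$id)
  nwk <- newick(ph)
  expect_true(startsWith(nwk, "(") && endsWith(nwk, ";"))
  # members of well-separated families generated from one ancestor cluster
  fams <- split(sim$proteins$id, sim$proteins$family)
  mono <- vapply(fams, function(tips) ape::is.monophyletic(ph$tree, tips),
                 logical(1))
  expect_gte(mean(mono), 0.95)
})

test_that("the tree autoplot builds a ggplot without plotting devices", {
  sim <- simulate_crp_dataset(
    crp_generator_spec(seed = 53, families = default_family_specs()[1:2]))
  ph <- crp_phylo(sim$proteins)
  p <- autoplot(ph)
  expect_s3_class(p, "ggplot")
})
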