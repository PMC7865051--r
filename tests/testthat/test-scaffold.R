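test_that("framework extraction performs an exact positional cysteine census", {
  fw <- extract_framework("ACAAAAAACAAAAACCAAAACAAACAAAA")
  expect_equal(fw$n_term_offset, 1L)
  expect_equal(fw$gaps, c(6L, 5L, 0L, 4L, 3L))
  expect_equal(fw$c_term_tail, 4L)
  expect_equal(fw$n_cys, 6L)

  fw0 <- extract_framework("AAAA")
  expect_equal(fw0$n_cys, 0L)
  expect_equal(fw0$n_term_offset, 4L)
})

test_that("framework reconstruction length is the identity on random peptides", {
  set.seed(7)
  for (r in 1:2000) {
    len <- sample(1:200, 1)
    s <- random_peptide(len)
    fw <- extract_framework(s)
    expect_equal(fw$n_term_offset + fw$n_cys + sum(fw$gaps) + fw$c_term_tail,
                 len)
  }
})

test_that("template parsing reads the scaffold pattern language", {
  tpl <- parse_template("XC X6 C X5 C C X4 C X3 C X4-6")
  expect_equal(tpl$offset, c(1L, 1L))
  expect_equal(tpl$gaps, list(c(6L, 6L), c(5L, 5L), c(0L, 0L),
                              c(4L, 4L), c(3L, 3L)))
  expect_equal(tpl$tail, c(4L, 6L))

  tpl2 <- parse_template("C X13 C X2 C X12 C X3 C X8 C")
  expect_equal(tpl2$offset, c(0L, 0L))
  expect_equal(vapply(tpl2$gaps, `[[`, integer(1), 1L), c(13L, 2L, 12L, 3L, 8L))
  expect_equal(tpl2$tail, c(0L, 0L))

  expect_error(parse_template("C XQ C"), "malformed token")
})

test_that("pattern serialization round-trips random frameworks", {
  set.seed(11)
  for (r in 1:1000) {
    s <- random_peptide(sample(5:150, 1))
    fw <- extract_framework(s)
    tpl <- parse_template(framework_to_pattern(fw))
    expect_true(match_template(fw, tpl))
    # and the parsed template is exact (degenerate ranges)
    expect_equal(tpl$n_cys, fw$n_cys)
    expect_equal(tpl$offset, rep(fw$n_term_offset, 2))
  }
})

test_that("template matching agrees with brute-force range enumeration", {
  tpl <- parse_template("X0-2 C X1-3 C X0-1 C X2-4",
                        name = "toy", label = "other")
  for (off in 0:3) {
    for (g1 in 0:4) {
      for (g2 in 0:2) {
        for (tl in 0:5) {
          s <- paste0(strrep("A", off), "C", strrep("A", g1), "C",
                      strrep("A", g2), "C", strrep("A", tl))
          fw <- extract_framework(s)
          manual <- off <= 2 && g1 >= 1 && g1 <= 3 && g2 <= 1 &&
            tl >= 2 && tl <= 4
          expect_identical(match_template(fw, tpl), manual)
        }
      }
    }
  }
  # boundary: tail just outside the range
  fam1 <- parse_template("X C X6 C X5 C C X4 C X3 C X4-6")
  fw7 <- extract_framework(paste0("A", "C", strrep("A", 6), "C", strrep("A", 5),
                                  "CC", strrep("A", 4), "C", strrep("A", 3),
                                  "C", strrep("A", 7)))
  expect_false(match_template(fw7, fam1))
})

test_that("motif classification follows registry order with count fallback", {
  reg <- default_template_registry()
  fw_ick <- extract_framework("ACAAAAAACAAAAACCAAAACAAACAAAA")
  expect_equal(classify_motif(fw_ick, reg)$label, "ICK-6")

  fw_f9 <- extract_framework(paste0("C", strrep("A", 5), "C", strrep("A", 3),
                                    "C", strrep("A", 5), "C", "A", "C", "A", "C"))
  expect_equal(classify_motif(fw_f9, reg)$label, "non-ICK-6")

  fw_12 <- extract_framework(paste(rep("C", 12), collapse = "AA"))
  expect_equal(classify_motif(fw_12, reg)$label, "12-cys")
  expect_true(is.na(classify_motif(fw_12, reg)$template_name))
})

test_that("generator-emitted matures classify back to their source template", {
  specs <- default_family_specs()
  reg <- default_template_registry()
  set.seed(3)
  for (fs in specs) {
    for (r in 1:5) {
      g <- gen_precursor(fs)
      cls <- classify_motif(extract_framework(g$truth$mature_seq), reg)
      expect_equal(cls$template_name, fs$template)
      # collisions are visible, never silently resolved
      expect_true(fs$template %in% cls$matches)
    }
  }
})
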