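test_that("signal mode grammar matches the canonical prefix and nothing else", {
  p <- paste0("MK", strrep("L", 12), "S", strrep("V", 5), "DEQRGGC")
  expect_equal(match_signal_mode(p, "MKh12Sh5"), 20L)
  expect_true(is.na(match_signal_mode(paste0("MA", strrep("L", 20)), "MKh12Sh5")))

  # count shortfall: 11 hydrophobics instead of 12 fails at every prefix
  p_short <- paste0("MK", strrep("L", 11), "S", strrep("V", 5), "DEQRG")
  expect_true(is.na(match_signal_mode(p_short, "MKh12Sh5")))
})

test_that("h-runs accept at most two S/T positions", {
  ok <- paste0("MK", "LLLLLSTLLLLL", "S", "VVVVV", "X")
  expect_equal(match_signal_mode(ok, "MKh12Sh5"), 20L)
  bad <- paste0("MK", "LLLLSTSLLLLL", "S", "VVVVV", "X")
  expect_true(is.na(match_signal_mode(bad, "MKh12Sh5")))
})

test_that("PQM search prefers canonical motifs and takes the rightmost", {
  # canonical DEQR inside the window
  p <- paste0("MKLLLLLLLLLLLLSVVVVV", "SLADEQR", "QCAAAC")
  hit <- find_pqm(p, 20L)
  expect_equal(hit$motif, "DEQR")
  expect_equal(hit$position, 27L)   # cleavage before the Q

  # no R before the first cysteine -> none
  expect_null(find_pqm("MAAAAAAACDDDD", 4L))

  # canonical AVAR beats a more-rightward generic quadruplet ending in R;
  # verify against enumeration of all window quadruplets
  p2 <- paste0("MKLLL", "AVAR", "GTSR", "AACDD")
  hit2 <- find_pqm(p2, 3L)
  expect_equal(hit2$motif, "AVAR")
  win <- substr(p2, 4L, 13L)
  quads <- substring(win, 1:(nchar(win) - 3), 4:nchar(win))
  expect_true("AVAR" %in% quads && "GTSR" %in% quads)

  # with no canonical in the window the rightmost generic wins
  p3 <- paste0("MKLLL", "GTSR", "AKWR", "AACDD")
  expect_equal(find_pqm(p3, 3L)$motif, "AKWR")
})

test_that("C-terminal processing handles amidation, dibasic tails and errors", {
  am <- process_cterminus("ACAAAACNCAAAAGK")
  expect_equal(am$mature, "ACAAAACNCAAAA")
  expect_true(am$amidated)

  none <- process_cterminus("ACAAAACNCAAAA")
  expect_equal(none$mature, "ACAAAACNCAAAA")
  expect_false(none$amidated)
  expect_true(is.na(none$cterm))

  dib <- process_cterminus("AAAACRKDDDDD")
  expect_equal(dib$mature, "AAAAC")
  expect_equal(nchar(dib$cterm), 7L)
  expect_false(dib$amidated)

  expect_error(process_cterminus("GK"), "empty")
})

test_that("annotation recovers a canonical family-1 style precursor exactly", {
  p <- paste0("MK", strrep("L", 12), "S", strrep("I", 5),      # signal, 20
              "ESEENRALSDEQR",                                 # propeptide, 13
              "ACAAAAAACAAAAACCAAAACAAACAAAA", "GK")           # mature + GK
  a <- annotate_precursor(p)
  expect_equal(a$signal_end, 20L)
  expect_equal(c(a$propeptide_start, a$propeptide_end), c(20L, 33L))
  expect_equal(c(a$mature_start, a$mature_end), c(33L, 62L))
  expect_true(a$amidated)
  expect_equal(a$pqm, "DEQR")
  expect_equal(a$mature_seq, "ACAAAAAACAAAAACCAAAACAAACAAAA")
})

test_that("degenerate and propeptide-free precursors annotate deterministically", {
  # cysteine right after the initiator: fallback signal, no propeptide
  p <- paste0("M", "C", strrep("A", 40))
  a <- annotate_precursor(p)
  expect_equal(a$signal_grammar, "fallback")
  expect_true(is.na(a$propeptide_start))

  # mature directly after a grammar signal, no PQM
  p2 <- paste0("MK", strrep("L", 12), "S", strrep("I", 5),
               "ACAAAAAACAAAAACCAAAACAAACAAAA")
  a2 <- annotate_precursor(p2)
  expect_true(is.na(a2$propeptide_start))
  expect_equal(a2$mature_start, a2$signal_end)

  expect_error(annotate_precursor("KMAAA"), "initiator")
  expect_error(annotate_precursor(paste0("M", strrep("L", 5))), "shorter")
})

test_that("region intervals tile the precursor and amidation implies G+basics", {
  sim <- simulate_crp_dataset(crp_generator_spec(seed = 21))
  ann <- annotate_precursors(sim$proteins)
  for (i in seq_len(nrow(ann))) {
    ends <- c(ann$signal_end[i], ann$propeptide_end[i], ann$mature_end[i],
              ann$cterm_end[i])
    starts <- c(ann$signal_start[i], ann$propeptide_start[i],
                ann$mature_start[i], ann$cterm_start[i])
    keep <- !is.na(starts)
    # consecutive regions abut
    expect_equal(starts[keep][-1], ends[keep][-length(ends[keep])])
    expect_true(ann$mature_end[i] > ann$mature_start[i])
    if (ann$amidated[i]) {
      expect_match(substr(ann$protein[i], ann$cterm_start[i] + 1L,
                          nchar(ann$protein[i])), "^G[KR]{0,2}$")
    }
  }
})

test_that("annotation recovers generator ground truth on 1000 canonical draws", {
  specs <- default_family_specs()[1:8]       # grammar + canonical-PQM families
  n_ok <- 0L
  set.seed(424242)
  for (r in 1:1000) {
    g <- gen_precursor(specs[[(r - 1L) %% 8L + 1L]])
    a <- annotate_precursor(g$protein)
    t <- g$truth
    ok <- a$signal_end == t$signal_end &&
      identical(a$propeptide_start, t$propeptide_start) &&
      identical(a$propeptide_end, t$propeptide_end) &&
      a$mature_start == t$mature_start && a$mature_end == t$mature_end &&
      a$amidated == t$amidated
    n_ok <- n_ok + as.integer(isTRUE(ok))
  }
  expect_gte(n_ok / 1000, 0.99)
})
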