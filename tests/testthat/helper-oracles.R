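# Independent oracles used to cross-check the package implementations.
# Each is written as directly as possible (enumeration / closed form /
# atomic composition) and shares no code with the functions it checks.

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]
NUC4 <- c("T", "C", "A", "G")

# --- Nei-Gojobori oracles: plain enumeration ------------------------------

oracle_codon_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (alt in NUC4) {
      if (alt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (GC[[mut]] == "*") next
      tot <- tot + 1
      if (GC[[mut]] == GC[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

# all orderings of the differing positions, via explicit recursion
oracle_codon_diff <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  sd <- 0; nd <- 0; legal <- 0
  for (ord in perms(dpos)) {
    cur <- c1; s <- 0; n <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC[[nxt]] == "*") { ok <- FALSE; break }
      if (GC[[nxt]] == GC[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { legal <- legal + 1; sd <- sd + s; nd <- nd + n }
  }
  if (legal == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd / legal, nd = nd / legal)
}

oracle_ng_pair <- function(cds1, cds2) {
  n <- nchar(cds1)
  starts <- seq(1, n, 3)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (st in starts) {
    a <- substr(cds1, st, st + 2)
    b <- substr(cds2, st, st + 2)
    if (!(a %in% SENSE) || !(b %in% SENSE)) next
    sa <- oracle_codon_sites(a); sb <- oracle_codon_sites(b)
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- oracle_codon_diff(a, b)
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  c(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd))
}

# --- peptide mass oracle: atomic composition ------------------------------

ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
# residue (= amino acid minus water) elemental compositions
RESIDUE_ATOMS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_peptide_mass <- function(seq) {
  atoms <- c(C = 0, H = 2, N = 0, O = 1, S = 0)   # water
  for (r in strsplit(seq, "")[[1]]) {
    a <- RESIDUE_ATOMS[[r]]
    atoms[names(a)] <- atoms[names(a)] + a
  }
  sum(atoms * ATOM_MONO[names(atoms)])
}

# --- alignment oracle: brute-force global DP ------------------------------
# match +1, mismatch 0, a gap of length k costs 5 + k; returns the identity
# (matches / columns) of the optimal-score alignment.

oracle_global_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(5 + i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(5 + j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (A[i] == B[j]) 1 else 0
      M[i + 1, j + 1] <- sc + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - 6, X[i, j + 1] - 1)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - 6, Y[i + 1, j] - 1)
    }
  }
  # traceback for matches and columns
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  matches <- 0; cols <- 0
  while (i > 1 || j > 1) {
    if (i == 1) state <- 3
    if (j == 1) state <- 2
    cols <- cols + 1
    if (state == 1) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev); i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- if (M[i - 1, j] - 6 >= X[i - 1, j] - 1) 1 else 2
      i <- i - 1
    } else {
      state <- if (M[i, j - 1] - 6 >= Y[i, j - 1] - 1) 1 else 3
      j <- j - 1
    }
  }
  matches / cols
}

# --- misc helpers ---------------------------------------------------------

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE, n_codons, replace = TRUE), collapse = "")
}

random_peptide <- function(len) {
  paste(sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], character(0)),
               len, replace = TRUE), collapse = "")
}

# additive distance matrix from a random tree with positive branch lengths
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  stats::cophenetic(tr)
}
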