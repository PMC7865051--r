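# Shared constants (collated first).

`%||%` <- function(x, y) if (is.null(x)) y else x

# Amino-acid vocabularies used across modules.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O")

# Kyte-Doolittle hydropathy, used by the fallback signal-peptide scorer.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Strict hydrophobic core set for signal-peptide 'h' tokens; S/T tolerated at
# a bounded number of positions per run (published modes annotate S
# explicitly, so the core stays discriminative).
HYDROPHOBIC_CORE <- c("A", "V", "L", "I", "M", "F", "W")

# Canonical Processing Quadruplet Motifs (PQMs): conserved four-residue
# endoproteolytic signals ending in R that terminate CRP propeptides.
CANONICAL_PQMS <- c("DEQR", "AVAR", "VAAR", "VQAR", "ATGR", "VTGR", "ITVR", "VQER")
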