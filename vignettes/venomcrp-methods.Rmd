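---
title: "Models and methods behind venomcrp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind venomcrp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomcrp)
```

`venomcrp` analyses repertoires of venom cysteine-rich peptide (CRP)
precursors. This vignette explains the models each stage implements, the
parameters that matter, the design choices made where several conventions
were defensible, and what the synthetic-data generator does and does not
emulate — and therefore what a green test suite does and does not show about
real data.

## The precursor model

A CRP precursor is a single protein chain

```
signal peptide | propeptide (optional) | mature peptide | C-terminal signal (optional)
```

All coordinates in the package are 0-based, half-open, on the protein; CDS
coordinates are three times the protein coordinates. This convention removes
the off-by-one ambiguity that plagues region tables: `signal_end == 20` means
residues 0–19 are signal, and the next region starts at residue 20.

### Signal peptides: mode grammars and the hydropathy fallback

Secretory signal peptides of CRP families are strongly stereotyped, so the
package matches them with compact *mode grammars* such as `MKh12Sh5` (literal
Met-Lys, twelve hydrophobics, literal Ser, five hydrophobics). The
hydrophobic class `h` is the strict core set `{A,V,L,I,M,F,W}` with at most
two S/T positions tolerated per run: published modes annotate serines
explicitly, so admitting S/T freely would make distinct grammars collide.
Grammars are tried in configuration order, first match wins; ranged runs
match greedily (longest first).

When no grammar matches, the signal cut is chosen inside a fallback length
range (default 19–25 residues, the observed span of CRP signal peptides) by
maximizing the mean Kyte–Doolittle hydropathy of the h-core (positions
3..cut−4, 0-based), ties going to the shortest cut. This is a deterministic,
dependency-free replacement for external signal-peptide predictors; it
recovers grammar-less signals only up to the ambiguity inherent in a
uniformly hydrophobic core, which is why the generator's ground-truth
guarantees (below) are stated for grammar families.

### Propeptides and the PQM

The propeptide, when present, ends at a Processing Quadruplet Motif — four
residues ending in R, canonically `DEQR` — the recognition site of venom
prohormone convertases. The search window is (signal end, first cysteine):
a convertase site beyond the first cysteine would cut inside the disulfide
scaffold. Within the window the package prefers an exact member of the
canonical motif list (`DEQR`, `AVAR`, `VAAR`, `VQAR`, `ATGR`, `VTGR`,
`ITVR`, `VQER`) over the generic `xxxR` rule, and takes the rightmost
candidate of the winning class — the standard convertase reading that the
mature peptide starts after the last basic site. Absence of a PQM is a valid
outcome (several families carry none), not an error.

### C-terminal processing

Two signals are recognised, in order of precedence: a trailing
`G[K/R]{0,2}` marks amidation (the glycine is consumed as the amide donor;
mass change −0.984 Da), and otherwise a dibasic `RK`/`KR` beginning within
the terminal window (default 8 residues, matching the short `RKX4–5` tails
seen in real repertoires) cleaves off a C-terminal propeptide. Processing
that would empty the mature peptide is an error.

## Cysteine frameworks and motif classes

The framework of a mature peptide is its exact cysteine census: N-terminal
offset, the ordered inter-cysteine spacings (loops), and the C-terminal
tail. Frameworks serialize to the field's pattern language
(`X1-C-X6-C-X5-C-C-X4-C-X3-C-X4`), and templates add ranges (`X4-6`), with
`CC` adjacency encoded as a zero-width gap. The default registry carries the
eight 6-cys ICK family modes, the acidic non-ICK and CHH-like 6-cys
scaffolds, the extended-ICK 8-cys scaffold, a novel 8-cys scaffold, three
10-cys scaffolds, two 12-cys scaffolds, and a 2-cys scaffold. Scaffolds
whose printed pattern begins or ends at a cysteine receive permissive
offset/tail ranges (0–10 and 0–40), because termini are the most variable
parts of mature peptides; disulfide connectivity (e.g. I–IV, II–V, III–VI
for the knot) is stored as template metadata only — the package does not
predict connectivity.

Classification is first-match-wins in registry order (ascending cysteine
count, then family number); all matching templates are reported so range
collisions are visible rather than silently resolved. Unmatched frameworks
fall back on the cysteine count (2, 6, 10, 12 have named classes; 8 is
deliberately *not* auto-labelled extended-ICK, because that label implies a
connectivity that only a template can vouch for).

## Family clustering

Families are single-linkage components of the graph joining precursor pairs
with global identity ≥ `id_threshold` *and* equal mature cysteine count.
Identity is Needleman–Wunsch over the full precursor (match +1, mismatch 0,
a gap of length k costs 5 + k), matches divided by alignment columns. The
cysteine-count constraint implements the rule that scaffold changes demarcate
families even at high precursor identity, while loop-length variation within
a scaffold does not. The default threshold 0.40 is a deliberately permissive
full-precursor identity (signal peptides alone contribute ~25% of columns at
high conservation); it is a tuning parameter, and family counts should be
read from a threshold sweep, not one magic value. Numbering is deterministic:
descending size, ties by smallest member id, so reruns and input permutations
give identical output.

## Phylogeny

The tree stage is the classical distance pipeline: a multiple alignment,
p-distances with pairwise deletion (columns with a gap or ambiguity in either
row of a pair are dropped for that pair), Poisson correction
d = −ln(1 − p), and neighbor-joining (Saitou–Nei, Q-criterion) with
deterministic lowest-index tie-breaking. Negative branch lengths are clamped
to zero by default (`allow_negative` restores the raw estimates), matching
common tool behaviour. An alignment produced elsewhere passes through
verbatim (any input whose sequences already share one length is treated as
aligned); the built-in progressive aligner exists so that the pipeline and
its tests run without an external binary. It uses 3-mer distances with a
UPGMA merge order — a rooted guide with a well-defined merge sequence, the
standard choice for progressive aligners; a neighbor-joining guide would
first need an arbitrary rooting — and merges column profiles with
affine-gap Needleman–Wunsch on expected-identity scores. It is a utility
aligner adequate for clustering conserved-scaffold families, not a
replacement for a production MSA tool.

## Selection analysis (original Nei–Gojobori, p-distance)

For each sense codon, each of the three positions contributes one site,
split into a synonymous fraction `syn/(syn + nonsyn)` over its non-stop
single-nucleotide changes; changes to stop codons are excluded. This is the
normalization under which S + N = 3 × (compared codons) exactly. Codon
pairs differing at one position are classified directly; two- and
three-fold differences are averaged over all orderings of single-step
pathways, excluding any pathway through a stop codon (if every pathway is
illegal the pair is flagged and skipped from difference counts). Columns
with gaps, ambiguity, or stops in either row are deleted pairwise at codon
granularity.

Per family and region, `pS` and `pN` are averaged over all unordered pairs
and ω = pN/pS is formed from the averages, with the conventions pN = 0 → ω
= 0 and pS = 0 with pN > 0 → a flagged infinity. No multiple-hit correction
is applied to pS/pN — this is the *p-distance* variant, chosen to match the
method as named; the cost is documented below.

The neutrality test is a bootstrap Z: codon columns are resampled with
replacement, the bootstrap standard error of pN − pS yields
Z = (pN − pS)/SE and a two-tailed normal p-value. It is seeded and
reproducible; identical sequences (zero variance, zero difference) return
p = 1 by convention. One thousand replicates is the default; the test's
type-I error at ω = 1 measured over 200 simulated families is close to the
nominal 5% (the acceptance script recomputes this rate).

### Estimator behaviour the tests quantify

Two properties of the p-distance estimator matter at realistic divergences
(the package's tests and `scripts/acceptance.R` compute all numbers cited
here). First, on families simulated at pairwise divergence ≈ 0.2 with n = 10
and 150 codons, the median ω estimate over 50 replicates tracks targets 0.5,
1.0 and 2.0 within 20%. Second, under strong purifying selection (target
ω = 0.1) the same conditions yield a median estimate around 0.14: synonymous
sites then carry divergence ≈ 0.6 per site, where uncorrected p-distances
undercount synonymous differences, and pathway averaging attributes
nonsynonymous fractions to multi-difference codons whose history was purely
synonymous. The simulator itself is unbiased — ω counted on the true
mutation history converges to the target (a property test checks this at
10,000 sites) — so the gap is the estimator's, shared by any faithful
original-NG implementation, and should be kept in mind when reading very low
ω values off deeply diverged families.

## Mass matching

Theoretical masses are residue-mass sums plus water (monoisotopic by
default; average masses available). PTM hypotheses adjust the mass by
−2.015650 Da per disulfide bond and −0.984016 Da for C-terminal amidation
(monoisotopic). By default only the two disulfide extremes are hypothesised —
fully oxidized, the norm for CRPs, and fully reduced — with full enumeration
available by option to bound the combinatorics; an unknown amidation state
hypothesises both. The default tolerance ±0.5 Da (±1.0 Da average) is the
externally calibrated MALDI-TOF scale and is configurable. Observed lists
are read as neutral masses by default, with an `[M+H]+` flag to subtract a
proton explicitly rather than risk a silent 1.007 Da bias. Every
(record, hypothesis, observation) triple within tolerance is reported;
ambiguity is the caller's information, never silently resolved.

## Trend statistics

Propeptide lengths bin into <10, 10–25 (inclusive) and >25 residues;
precursors without a propeptide count as length 0, because the trend of
interest is precisely that propeptides shrink and vanish — excluding them
would delete the signal being measured. Cysteine counts default to the
classes 6 and ≥8; records falling in no class are excluded from the
denominator and their number reported, since published splits do not state
their denominator convention. Scaffold inventories collapse X-runs to the
field's adjacency notation (`C...C...CC...`). All percentages recompute
exactly from retained raw counts.

## The synthetic-data generator

The generator emulates the precursor architecture: a signal peptide drawn
from a mode grammar (or a plain 19-residue hydrophobic signal for
grammar-less families), an acidic/polar propeptide ending in a canonical
PQM, a mature region drawn from a scaffold template, an optional C-terminal
signal, and a uniformly back-translated CDS. Families then evolve by
independent descent: per lineage, Poisson(divergence × length) accepted
single-nucleotide substitutions, with stop-creating proposals rejected and
synonymous : nonsynonymous acceptance odds 1 : ω (rescaled so the favoured
class is accepted with probability 1). The default repertoire is 21 family
specs totalling 151 precursors whose copy numbers and scaffolds mirror a
huntsman-spider venom survey, including an ~55%/45% six- versus
eight-plus-cysteine split.

Three generator choices keep the ground truth well-defined, and should be
understood as deliberate idealisations:

* X positions never draw cysteine; the stretch before the first cysteine
  draws no R (so no spurious PQM appears where none was planted); the last
  eight mature positions draw no K/R and the final position no G (so
  C-terminal processing is unambiguous). The first propeptide residue is
  hydrophilic so no signal grammar can absorb it.
* Family evolution is *architecture-constrained*: each position carries the
  residue set compatible with the planted processing signals (grammar class
  in the signal, exact PQM and C-terminal signal, fixed cysteine scaffold,
  clean termini), emulating the structural purifying selection that keeps
  real scaffolds recognisable. Nonsynonymous proposals outside a position's
  set are rejected; realized ω at such positions is accordingly below the
  family's nominal target.
* Grammar-less families use a fixed 19-residue signal; the hydropathy
  fallback recovers the *mature* boundary of such records via the PQM (or a
  protected N-terminal offset of at least 7 for propeptide-free scaffolds)
  even when the exact signal cut is ambiguous.

What the generator does **not** emulate: indels and alignment uncertainty
within regions, codon-usage bias (back-translation is uniform), realistic
amino-acid substitution matrices, internal propeptides between cysteines,
heterodimeric two-chain toxins, truncation/degradation mass variants, and
isotopic envelopes or charge states in mass lists. Green pipeline tests
therefore certify the algorithms against a clean architecture, not
robustness to messy real transcriptome data; on real inputs the external
alignment pass-through and the configurable registries/thresholds are the
intended escape hatches.

## Numerical and interface conventions

* Ambiguity characters (X, B, Z; N in nucleotides) are preserved on input,
  excluded from cysteine counts, pairwise-deleted in distances, and skipped
  in codon statistics.
* All stochastic functions take explicit seeds and restore the caller's RNG
  state; reruns are byte-identical, which the tests assert on CSV output.
* Problem sizes in the test suite: 1,000 generated precursors for
  region-recovery, the 151-record default repertoire for clustering and
  phylogeny, 50 replicates per ω target, 200 replicates for the type-I rate,
  1,000 random peptides against the mass oracle — sizes chosen to give
  stable rates while keeping the suite quick to run.
* The pipeline entry point is `run_crp_pipeline()` on a validated config
  list (unknown keys are rejected before any work); per-stage functions are
  the primary interface for interactive use.

## Known limitations

Reproducing published family counts from real deposits additionally requires
homology evidence (database searches) that the package deliberately treats
as input annotations, not computation; exact counts should be read from an
identity-threshold sweep. The ω estimator's low-ω bias at high synonymous
divergence is documented above. The bootstrap-Z neutrality test is one
defensible choice among several codon-based tests; it is seeded and
swappable, and its p-values should not be expected to match spreadsheets or
other tools decimal-for-decimal.
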