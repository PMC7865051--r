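# Seeded generators emulating CRP precursor architecture (signal peptide from
# a mode grammar, propeptide terminated by a PQM, mature region from a
# cysteine-scaffold template, optional C-terminal processing signal) and
# codon-level family evolution under a controllable dN/dS, with full ground
# truth so every pipeline stage can be checked against construction.
#
# Family evolution is architecture-constrained: each residue position carries
# the set of amino acids compatible with the precursor's processing signals
# (grammar class in the signal, exact PQM, cysteine scaffold, clean termini),
# emulating the structural purifying selection that keeps real CRP scaffolds
# recognisable while the rest of the sequence diverges.

# Residue pools for generated regions (all exclude cysteine):
# propeptides are acidic/polar; the pre-first-cysteine stretch carries no R
# (keeps the PQM window free of spurious motifs); the mature terminus carries
# no K/R (and no terminal G) so C-terminal processing stays unambiguous.
PRO_POOL <- c("D", "E", "N", "Q", "S", "T", "A", "P", "G", "H")
PRO_HEAD_POOL <- c("D", "E", "N", "Q", "H")   # first propeptide residue is
                                              # hydrophilic so no signal
                                              # grammar can absorb it
MATURE_POOL <- setdiff(AA_STANDARD, "C")
MATURE_PRE_POOL <- setdiff(AA_STANDARD, c("C", "R"))
MATURE_TAIL_POOL <- setdiff(AA_STANDARD, c("C", "K", "R"))

#' Specification of one synthetic CRP family
#'
#' @param name Family label (ground truth for clustering).
#' @param n Copy number (precursors generated).
#' @param template Template name from the registry (mature scaffold).
#' @param signal A signal-grammar name from [default_signal_grammars()], a
#'   mode string, or `NULL` for a plain 19-residue hydrophobic signal (the
#'   no-grammar families annotated by the hydropathy fallback).
#' @param propeptide_len Propeptide length (including the 4-residue PQM);
#'   `0` = no propeptide.
#' @param pqm Canonical PQM motif terminating the propeptide.
#' @param cterm C-terminal processing signal appended to the mature core:
#'   `"none"`, an amidation signal (`"G"`, `"GK"`, `"GKK"`), or `"RKn"` for a
#'   dibasic followed by an n-residue tail propeptide.
#' @param omega Target dN/dS for within-family codon evolution.
#' @param divergence Expected substitutions per nucleotide site per lineage.
#' @param mature_offset Optional `c(min, max)` override for the mature
#'   N-terminal offset draw (defaults to the template's offset range).
#' @return A `crp_family_spec` list.
#' @export
crp_family_spec <- function(name, n, template, signal = NULL,
                            propeptide_len = 0L, pqm = "DEQR",
                            cterm = "none", omega = 0.3, divergence = 0.1,
                            mature_offset = NULL) {
  stopifnot(n >= 1L, propeptide_len == 0L || propeptide_len >= 4L,
            omega >= 0, divergence >= 0, divergence < 0.5)
  structure(list(name = name, n = as.integer(n), template = template,
                 signal = signal, propeptide_len = as.integer(propeptide_len),
                 pqm = pqm, cterm = cterm, omega = omega,
                 divergence = divergence, mature_offset = mature_offset),
            class = "crp_family_spec")
}

#' Generator specification for a full synthetic dataset
#'
#' The default family table emulates a huntsman-spider-like repertoire:
#' 21 family specs totalling 151 precursors spanning the 6-cys ICK modes
#' (grammar signals, canonical PQMs, amidation/dibasic C-termini), the
#' acidic non-ICK and CHH-like 6-cys scaffolds, 8-, 10- and 12-cys scaffolds
#' and a 2-cys family, several of them without a propeptide.
#'
#' @param seed Mandatory seed; all generation is a pure function of
#'   (spec, seed).
#' @param families List of [crp_family_spec()] objects.
#' @param mass_noise_sd Gaussian noise (Da) on generated mass observations.
#' @param n_decoys Decoy masses drawn uniformly in the 2800-8000 Da range.
#' @return A `crp_generator_spec`.
#' @export
crp_generator_spec <- function(seed, families = default_family_specs(),
                               mass_noise_sd = 0.1, n_decoys = 30L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, mass_noise_sd >= 0)
  structure(list(seed = as.integer(seed), families = families,
                 mass_noise_sd = mass_noise_sd,
                 n_decoys = as.integer(n_decoys)),
            class = "crp_generator_spec")
}

#' Default synthetic family table
#' @return List of `crp_family_spec`.
#' @export
default_family_specs <- function() {
  fs <- crp_family_spec
  off <- c(7L, 10L)   # no-propeptide scaffolds keep the first cysteine clear
                      # of the fallback signal-cut range
  list(
    fs("F1", 11, "family1", "family1", 19, "DEQR", "GK", omega = 0.33),
    fs("F2", 8, "family2", "family2", 15, "AVAR", "G", omega = 0.1),
    fs("F3", 8, "family3", "family3", 15, "VAAR", "GKK", omega = 0.1),
    fs("F4", 8, "family4", "family4", 11, "VQAR", "GK", omega = 0.13),
    fs("F5", 8, "family5", "family5", 16, "ATGR", "none", omega = 0.24),
    fs("F6", 8, "family6", "family6", 15, "VTGR", "RK5", omega = 1.1),
    fs("F7", 8, "family7", "family7", 15, "ITVR", "G", omega = 0.9),
    fs("F8", 6, "family8", "family8", 12, "VQER", "none", omega = 0.3),
    fs("F9", 6, "family9", NULL, 12, "DEQR", "none", omega = 0.42),
    fs("F10", 11, "family10", NULL, 0, cterm = "none", omega = 0.42,
       mature_offset = off),
    fs("F11", 8, "family11_14", NULL, 0, cterm = "none", omega = 0.3,
       mature_offset = off),
    fs("F15", 20, "family15", NULL, 0, cterm = "none", omega = 0.84,
       divergence = 0.05, mature_offset = c(12L, 12L)),
    fs("F16", 6, "family16", NULL, 12, "DEQR", "none", omega = 0.22),
    fs("F17", 6, "family17_18", NULL, 0, cterm = "none", omega = 0.11,
       mature_offset = off),
    fs("F18", 6, "family17_18", NULL, 0, cterm = "none", omega = 0.26,
       mature_offset = off),
    fs("F19", 5, "family19_21", NULL, 0, cterm = "none", omega = 0.44,
       mature_offset = off),
    fs("F20", 4, "family19_21", NULL, 0, cterm = "none", omega = 0.3,
       mature_offset = off),
    fs("F21", 4, "family19_21", NULL, 0, cterm = "none", omega = 0.1,
       mature_offset = off),
    fs("F22", 5, "family22", NULL, 0, cterm = "none", omega = 0.26,
       mature_offset = off),
    fs("F23", 3, "family23", NULL, 0, cterm = "none", omega = 0.1,
       mature_offset = off),
    fs("F24", 2, "family24", NULL, 12, "DEQR", "none", omega = 0.3)
  )
}

sample_from <- function(pool, k) {
  if (k == 0L) return(character(0))
  sample(pool, k, replace = TRUE)
}

# Signal residues + per-position allowed sets (grammar-compatible evolution).
gen_signal <- function(spec, grammars) {
  if (is.null(spec$signal)) {
    res <- c("M", sample_from(HYDROPHOBIC_CORE, 18L))
    pools <- c(list("M"), rep(list(HYDROPHOBIC_CORE), 18L))
    return(list(res = res, pools = pools))
  }
  g <- if (inherits(spec$signal, "crp_signal_grammar")) {
    spec$signal
  } else if (spec$signal %in% names(grammars)) {
    grammars[[spec$signal]]
  } else {
    parse_signal_grammar(spec$signal)
  }
  res <- character(0)
  pools <- list()
  for (tok in g$tokens) {
    if (tok$type == "lit") {
      res <- c(res, tok$residue)
      pools <- c(pools, list(tok$residue))
    } else {
      len <- if (tok$min == tok$max) tok$min else sample(tok$min:tok$max, 1L)
      res <- c(res, sample_from(HYDROPHOBIC_CORE, len))
      pools <- c(pools, rep(list(HYDROPHOBIC_CORE), len))
    }
  }
  list(res = res, pools = pools)
}

draw_in <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

# Mature core residues + per-position allowed sets from a scaffold template.
gen_mature <- function(tpl, offset_range = NULL) {
  if (tpl$n_cys == 0L) abort("template without cysteines")
  offset <- draw_in(offset_range %||% tpl$offset)
  gaps <- if (length(tpl$gaps) > 0L) map_int(tpl$gaps, draw_in) else integer(0)
  tl <- draw_in(tpl$tail)
  res <- sample_from(MATURE_PRE_POOL, offset)
  pools <- rep(list(MATURE_PRE_POOL), offset)
  for (k in seq_len(tpl$n_cys)) {
    res <- c(res, "C")
    pools <- c(pools, list("C"))
    g <- if (k <= length(gaps)) gaps[k] else tl
    res <- c(res, sample_from(MATURE_POOL, g))
    pools <- c(pools, rep(list(MATURE_POOL), g))
  }
  n <- length(res)
  tail_idx <- which(seq_len(n) > n - 8L & map_lgl(pools, function(p) length(p) > 1L))
  for (i in tail_idx) {
    pools[[i]] <- MATURE_TAIL_POOL
    if (!res[i] %in% MATURE_TAIL_POOL) res[i] <- sample(MATURE_TAIL_POOL, 1L)
  }
  if (length(pools[[n]]) > 1L) {
    pools[[n]] <- setdiff(MATURE_TAIL_POOL, "G")
    if (!res[n] %in% pools[[n]]) res[n] <- sample(pools[[n]], 1L)
  }
  list(res = res, pools = pools)
}

#' Generate one synthetic CRP precursor with ground truth
#'
#' Draws a precursor from a family spec using the current RNG state: signal
#' peptide from the mode grammar, propeptide with a canonical PQM suffix,
#' mature region from the scaffold template, optional C-terminal processing
#' signal, and a back-translated CDS.
#'
#' @param spec A [crp_family_spec()].
#' @param registry Template registry.
#' @param grammars Signal grammar set.
#' @return List with `protein`, `cdna`, `truth` (a one-row tibble of 0-based
#'   half-open region coordinates, `amidated`, `pqm`, `template`) and
#'   `allowed` (per-position residue sets compatible with the architecture,
#'   used to constrain family evolution).
#' @export
gen_precursor <- function(spec, registry = default_template_registry(),
                          grammars = default_signal_grammars()) {
  tpl <- if (inherits(spec$template, "crp_framework_template")) {
    spec$template
  } else {
    registry[[spec$template]] %||% abort(paste0("unknown template: ", spec$template))
  }
  sig <- gen_signal(spec, grammars)
  if (spec$propeptide_len > 0L) {
    stopifnot(nchar(spec$pqm) == 4L, endsWith(spec$pqm, "R"))
    pqm_res <- strsplit(spec$pqm, "")[[1]]
    n_int <- spec$propeptide_len - 4L
    pro_res <- c(sample_from(PRO_HEAD_POOL, min(1L, n_int)),
                 sample_from(PRO_POOL, max(0L, n_int - 1L)), pqm_res)
    pro_pools <- c(rep(list(PRO_HEAD_POOL), min(1L, n_int)),
                   rep(list(PRO_POOL), max(0L, n_int - 1L)),
                   as.list(pqm_res))
  } else {
    pro_res <- character(0)
    pro_pools <- list()
  }
  mat <- gen_mature(tpl, spec$mature_offset)
  ct <- spec$cterm
  amidated <- FALSE
  ct_res <- character(0)
  if (ct != "none") {
    if (grepl("^G[K]{0,2}$", ct)) {
      ct_res <- strsplit(ct, "")[[1]]
      amidated <- TRUE
    } else if (grepl("^RK[0-9]+$", ct)) {
      ntail <- as.integer(sub("^RK", "", ct))
      ct_res <- c("R", "K", sample_from(setdiff(MATURE_TAIL_POOL, "G"), ntail))
    } else {
      abort(paste0("unknown cterm signal: ", ct))
    }
  }
  res <- c(sig$res, pro_res, mat$res, ct_res)
  allowed <- c(sig$pools, pro_pools, mat$pools, as.list(ct_res))
  protein <- paste(res, collapse = "")
  s_end <- length(sig$res)
  m_start <- s_end + length(pro_res)
  m_end <- m_start + length(mat$res)
  truth <- tibble(
    family = spec$name,
    template = tpl$name,
    signal_end = s_end,
    propeptide_start = if (length(pro_res) > 0L) s_end else NA_integer_,
    propeptide_end = if (length(pro_res) > 0L) m_start else NA_integer_,
    mature_start = m_start,
    mature_end = m_end,
    cterm_start = if (length(ct_res) > 0L) m_end else NA_integer_,
    cterm_end = if (length(ct_res) > 0L) m_end + length(ct_res) else NA_integer_,
    amidated = amidated,
    pqm = if (length(pro_res) > 0L) spec$pqm else NA_character_,
    mature_seq = paste(mat$res, collapse = "")
  )
  list(protein = protein, cdna = back_translate(protein), truth = truth,
       allowed = allowed)
}

#' Back-translate a protein to a CDS
#'
#' Uniform random choice among each residue's synonymous codons, plus a
#' terminal stop codon.
#'
#' @param protein Amino-acid string (standard residues).
#' @param code Genetic code.
#' @param stop_codon Appended stop (`""` for none).
#' @return Nucleotide string; `translate_cds()` of the result returns
#'   `protein`.
#' @export
back_translate <- function(protein, code = Biostrings::GENETIC_CODE,
                           stop_codon = "TAA") {
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(aa) {
    cand <- names(code)[code == aa]
    if (length(cand) == 0L) abort(paste0("no codon for residue: ", aa))
    cand[sample.int(length(cand), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), stop_codon)
}

#' Evolve a family of coding sequences under a target dN/dS
#'
#' Independent descent of `n` lineages from an ancestor CDS. Single-
#' nucleotide changes are proposed at random positions; stop-creating
#' proposals are always rejected, and synonymous/nonsynonymous proposals are
#' accepted with relative probability `1 : omega` (scaled so the more
#' favoured class is accepted with probability 1). Each lineage accumulates
#' `Poisson(divergence x length)` accepted substitutions; frames are
#' preserved (no indels).
#'
#' @param ancestor_cds In-frame, stop-free CDS (a terminal stop is allowed
#'   and kept fixed).
#' @param n Number of descendant lineages.
#' @param target_omega Target dN/dS (>= 0).
#' @param divergence Expected substitutions per nucleotide site, in (0, 0.5).
#' @param protect_aa Integer vector of 1-based amino-acid positions whose
#'   residue may only change synonymously (e.g. scaffold cysteines under
#'   absolute purifying selection).
#' @param allowed_aa Optional list of per-position residue sets (1-based
#'   amino-acid positions); a nonsynonymous change to a residue outside the
#'   position's set is rejected. `NULL` entries leave a position free.
#' @param code Genetic code.
#' @return Character vector of `n` descendant CDS, plus a `history`
#'   attribute: tibble of accepted substitutions (`lineage`, `pos`,
#'   `synonymous`).
#' @export
evolve_family <- function(ancestor_cds, n, target_omega, divergence,
                          protect_aa = integer(0), allowed_aa = NULL,
                          code = Biostrings::GENETIC_CODE) {
  if (target_omega < 0) abort("target_omega must be >= 0")
  stopifnot(divergence > 0, divergence < 0.5)
  cds <- toupper(ancestor_cds)
  L <- nchar(cds)
  stopifnot(L %% 3L == 0L)
  n_cod <- L / 3L
  anc_codons <- split_codons(cds)
  has_stop <- code[anc_codons[n_cod]] == "*"
  mut_cod <- if (has_stop) n_cod - 1L else n_cod
  p_syn <- if (target_omega > 1) 1 / target_omega else 1
  p_non <- if (target_omega > 1) 1 else target_omega
  hist <- list()
  out <- vapply(seq_len(n), function(lineage) {
    codons <- anc_codons
    m <- rpois(1L, divergence * (mut_cod * 3L))
    accepted <- 0L
    tries <- 0L
    while (accepted < m && tries < 1000L * (m + 10L)) {
      tries <- tries + 1L
      pos <- sample.int(mut_cod * 3L, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      cur <- codons[ci]
      alt <- sample(setdiff(NUCS, substr(cur, off, off)), 1L)
      nxt <- cur
      substr(nxt, off, off) <- alt
      if (code[nxt] == "*") next
      syn <- code[nxt] == code[cur]
      if (!syn) {
        if (ci %in% protect_aa) next
        if (!is.null(allowed_aa) && ci <= length(allowed_aa) &&
            !is.null(allowed_aa[[ci]]) &&
            !code[nxt] %in% allowed_aa[[ci]]) next
      }
      p <- if (syn) p_syn else p_non
      if (p < 1 && runif(1L) >= p) next
      codons[ci] <- nxt
      accepted <- accepted + 1L
      hist[[length(hist) + 1L]] <<- c(lineage, pos, as.integer(syn))
    }
    paste(codons, collapse = "")
  }, character(1))
  history <- if (length(hist) > 0L) {
    h <- do.call(rbind, hist)
    tibble(lineage = h[, 1], pos = h[, 2], synonymous = h[, 3] == 1L)
  } else {
    tibble(lineage = integer(0), pos = integer(0), synonymous = logical(0))
  }
  attr(out, "history") <- history
  out
}

#' Generate a full synthetic CRP dataset
#'
#' For each family spec, an ancestor precursor is drawn and `n` descendant
#' CDS are evolved at the family's target dN/dS under the architecture
#' constraint (grammar-compatible signal, exact PQM and C-terminal signal,
#' fixed cysteine scaffold), so the annotation/clustering ground truth is
#' preserved while the sequences diverge.
#'
#' @param spec A [crp_generator_spec()] (carries the mandatory seed).
#' @param registry Template registry.
#' @param grammars Signal grammar set.
#' @return List with `proteins` (tibble `id`, `seq`, `cdna`, true `family`)
#'   and `truth` (per-record ground-truth regions).
#' @export
#' @examples
#' sim <- simulate_crp_dataset(crp_generator_spec(seed = 1,
#'   families = default_family_specs()[1:2]))
#' sim$proteins
simulate_crp_dataset <- function(spec,
                                 registry = default_template_registry(),
                                 grammars = default_signal_grammars()) {
  stopifnot(inherits(spec, "crp_generator_spec"))
  with_preserved_seed(spec$seed, {
    fams <- purrr::map(spec$families, function(fs) {
      anc <- gen_precursor(fs, registry, grammars)
      cds <- evolve_family(anc$cdna, fs$n, fs$omega, fs$divergence,
                           allowed_aa = anc$allowed)
      ids <- sprintf("%s_%02d", fs$name, seq_len(fs$n))
      prots <- vapply(cds, translate_cds, character(1), USE.NAMES = FALSE)
      tr <- anc$truth
      truth <- dplyr::bind_rows(purrr::map(seq_len(fs$n), function(i) tr)) |>
        mutate(id = ids, .before = 1L) |>
        mutate(mature_seq = substr(prots, mature_start + 1L, mature_end))
      list(proteins = tibble(id = ids, seq = prots, cdna = cds,
                             family = fs$name),
           truth = truth)
    })
    list(
      proteins = dplyr::bind_rows(purrr::map(fams, "proteins")),
      truth = dplyr::bind_rows(purrr::map(fams, "truth"))
    )
  })
}

#' Generate synthetic mass observations with ground truth
#'
#' One observation per record at its PTM-adjusted theoretical mass (fully
#' oxidized; amidation per record) plus Gaussian noise, together with
#' uniform decoys in the 2800-8000 Da range typical of venom MALDI surveys.
#'
#' @param records Tibble with `id`, `mature_seq`, `amidated`.
#' @param noise_sd Gaussian noise SD in Da.
#' @param n_decoys Number of decoy masses.
#' @param mode Mass mode.
#' @param seed Optional seed (uses and restores the RNG when given).
#' @return List with `observations` (tibble `m`, `source` = "signal"/"decoy")
#'   and `truth` (tibble `id`, `m_theoretical`, `m_observed`).
#' @export
gen_mass_observations <- function(records, noise_sd = 0.1, n_decoys = 0L,
                                  mode = "monoisotopic", seed = NULL) {
  run <- function() {
    theo <- vapply(seq_len(nrow(records)), function(i) {
      ncys <- str_count(records$mature_seq[i], stringr::fixed("C"))
      apply_ptm(peptide_mass(records$mature_seq[i], mode),
                n_disulfide = floor(ncys / 2),
                amidated = isTRUE(records$amidated[i]), mode = mode)
    }, numeric(1))
    obs <- theo + rnorm(length(theo), 0, noise_sd)
    decoys <- if (n_decoys > 0L) runif(n_decoys, 2800, 8000) else numeric(0)
    list(
      observations = tibble(
        m = c(obs, decoys),
        source = c(rep("signal", length(obs)), rep("decoy", length(decoys)))
      ),
      truth = tibble(id = records$id, m_theoretical = theo, m_observed = obs)
    )
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}
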