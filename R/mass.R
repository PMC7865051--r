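# Residue masses (Da). Peptide mass = sum of residue masses + water.
RESIDUE_MASS_MONO <- c(
  G = 57.0214637, A = 71.0371138, S = 87.0320284, P = 97.0527638,
  V = 99.0684139, T = 101.0476784, C = 103.0091845, L = 113.0840640,
  I = 113.0840640, N = 114.0429274, D = 115.0269431, Q = 128.0585775,
  K = 128.0949630, E = 129.0425931, M = 131.0404846, H = 137.0589118,
  F = 147.0684139, R = 156.1011110, Y = 163.0633285, W = 186.0793129
)
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528
PROTON_MONO <- 1.007276
DISULFIDE_LOSS <- c(monoisotopic = 2.015650, average = 2.0159)
AMIDATION_LOSS <- c(monoisotopic = 0.984016, average = 0.98476)

#' Theoretical peptide mass
#'
#' Sum of residue masses plus water, for the unmodified (fully reduced,
#' free-acid) peptide.
#'
#' @param seq Amino-acid string over the 20 standard residues.
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da.
#' @export
#' @examples
#' peptide_mass("GG")
peptide_mass <- function(seq, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (nchar(seq) == 0L) abort("empty peptide")
  res <- strsplit(toupper(seq), "")[[1]]
  tab <- if (mode == "monoisotopic") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  m <- tab[res]
  if (anyNA(m)) {
    abort(paste0("nonstandard residue(s): ",
                 paste(unique(res[is.na(m)]), collapse = ", ")))
  }
  sum(m) + if (mode == "monoisotopic") WATER_MONO else WATER_AVG
}

#' Apply a PTM hypothesis to a peptide mass
#'
#' Each disulfide bond removes two hydrogens; C-terminal amidation converts
#' the terminal -OH to -NH2 (-0.984 Da monoisotopic).
#'
#' @param m Unmodified mass (Da), > 0.
#' @param n_disulfide Number of disulfide bonds.
#' @param amidated C-terminally amidated?
#' @param mode Mass mode.
#' @return Adjusted mass in Da.
#' @export
#' @examples
#' apply_ptm(1000, n_disulfide = 3)
apply_ptm <- function(m, n_disulfide = 0L, amidated = FALSE,
                      mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  stopifnot(m > 0, n_disulfide >= 0)
  out <- m - n_disulfide * DISULFIDE_LOSS[[mode]] -
    if (isTRUE(amidated)) AMIDATION_LOSS[[mode]] else 0
  if (out <= 0) abort("PTM-adjusted mass is not positive")
  out
}

#' Enumerate PTM hypotheses for an annotated record
#'
#' By default the two disulfide extremes are considered: fully oxidized
#' (`floor(n_cys / 2)` bonds, the norm for CRPs) and fully reduced. When the
#' amidation flag is missing both states are hypothesised.
#'
#' @param n_cys Mature-region cysteine count.
#' @param amidated Logical flag from annotation (`NA` = ambiguous).
#' @param all_intermediates Hypothesise every disulfide count
#'   `0..floor(n_cys/2)` instead of the two extremes.
#' @return Tibble with columns `n_disulfide`, `amidated`.
#' @export
#' @examples
#' enumerate_hypotheses(6, amidated = TRUE)
enumerate_hypotheses <- function(n_cys, amidated = FALSE,
                                 all_intermediates = FALSE) {
  maxdb <- floor(n_cys / 2)
  dbs <- if (all_intermediates) seq(maxdb, 0L) else unique(c(maxdb, 0L))
  ams <- if (is.na(amidated)) c(TRUE, FALSE) else amidated
  tidyr::expand_grid(n_disulfide = as.integer(dbs), amidated = ams)
}

#' Match theoretical PTM-adjusted masses against an observed mass list
#'
#' Every (record, hypothesis, observation) triple whose mass difference lies
#' within the tolerance is reported; one observation may match several
#' records, and the ambiguity is reported rather than resolved.
#'
#' @param records Annotated tibble with `id` and `mature_seq` (and optionally
#'   `amidated`) columns.
#' @param observations Numeric vector of observed masses (Da), or a data
#'   frame with column `m`.
#' @param tol Tolerance in Da (default 0.5 for monoisotopic, 1.0 for average
#'   masses: external-calibration MALDI-TOF scale).
#' @param mode Mass mode.
#' @param observed_as `"neutral"` (default) or `"mh"` when the list contains
#'   \[M+H\]+ values (a proton is subtracted before comparison).
#' @param all_intermediates Passed to [enumerate_hypotheses()].
#' @return Tibble of matches (`id`, `n_disulfide`, `amidated`, `theoretical`,
#'   `observed`, `delta`), sorted by |delta|.
#' @export
match_masses <- function(records, observations,
                         tol = if (mode == "monoisotopic") 0.5 else 1.0,
                         mode = c("monoisotopic", "average"),
                         observed_as = c("neutral", "mh"),
                         all_intermediates = FALSE) {
  mode <- match.arg(mode)
  observed_as <- match.arg(observed_as)
  stopifnot(tol >= 0)
  obs <- if (is.data.frame(observations)) observations$m else observations
  if (observed_as == "mh") obs <- obs - PROTON_MONO
  if (length(obs) == 0L) {
    return(tibble(id = character(0), n_disulfide = integer(0),
                  amidated = logical(0), theoretical = numeric(0),
                  observed = numeric(0), delta = numeric(0)))
  }
  am_col <- if ("amidated" %in% names(records)) records$amidated else
    rep(FALSE, nrow(records))
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    mat <- records$mature_seq[i]
    base <- peptide_mass(mat, mode)
    ncys <- str_count(mat, stringr::fixed("C"))
    hyp <- enumerate_hypotheses(ncys, am_col[i], all_intermediates)
    purrr::map(seq_len(nrow(hyp)), function(h) {
      theo <- apply_ptm(base, hyp$n_disulfide[h], hyp$amidated[h], mode)
      delta <- theo - obs
      hit <- which(abs(delta) <= tol)
      if (length(hit) == 0L) return(NULL)
      tibble(id = records$id[i], n_disulfide = hyp$n_disulfide[h],
             amidated = hyp$amidated[h], theoretical = theo,
             observed = obs[hit], delta = delta[hit])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(id = character(0), n_disulfide = integer(0),
                  amidated = logical(0), theoretical = numeric(0),
                  observed = numeric(0), delta = numeric(0)))
  }
  out |> arrange(abs(delta), id, n_disulfide, observed)
}
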