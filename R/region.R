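#' Locate the Processing Quadruplet Motif (PQM)
#'
#' The propeptide of a CRP precursor is terminated by a four-residue
#' endoproteolytic signal ending in R (canonically DEQR), the Processing
#' Quadruplet Motif. The search window runs from the end of the signal peptide
#' to the first cysteine of the precursor; canonical motifs are preferred over
#' the generic `xxxR` rule, and among candidates of equal standing the
#' rightmost wins (the standard convertase reading).
#'
#' @param protein Amino-acid string.
#' @param signal_end 0-based end of the signal peptide (= signal length).
#' @param canonical_motifs Character vector of canonical PQMs.
#' @return A list with `position` (0-based index of the first mature residue,
#'   i.e. the residue after the R) and `motif`, or `NULL` when no quadruplet
#'   ending in R lies in the window.
#' @export
#' @examples
#' find_pqm("MKLLLLLLLLLLLLSVVVVVSLADEQRQCAAAC", 20)
find_pqm <- function(protein, signal_end, canonical_motifs = CANONICAL_PQMS) {
  res <- strsplit(protein, "")[[1]]
  first_c <- match("C", res)                       # 1-based; NA if none
  win_end <- if (is.na(first_c)) length(res) else first_c - 1L
  # quadruplet occupies 1-based j..j+3, fully inside (signal_end, first C)
  j_min <- signal_end + 1L
  j_max <- win_end - 3L
  if (j_max < j_min) return(NULL)
  starts <- j_min:j_max
  ends_in_r <- res[starts + 3L] == "R"
  if (!any(ends_in_r)) return(NULL)
  starts <- starts[ends_in_r]
  quads <- vapply(starts, function(j) paste(res[j:(j + 3L)], collapse = ""),
                  character(1))
  canon <- quads %in% canonical_motifs
  pick <- if (any(canon)) max(starts[canon]) else max(starts)
  motif <- paste(res[pick:(pick + 3L)], collapse = "")
  list(position = pick + 3L, motif = motif)       # 0-based index after the R
}

#' Resolve C-terminal processing of a raw mature peptide
#'
#' Two processing signals are recognised, in order of precedence:
#' * amidation: a trailing G optionally followed by up to two basic residues
#'   (K/R) is removed and the peptide is flagged amidated (the glycine donates
#'   the amide);
#' * a short C-terminal propeptide: a dibasic RK/KR starting within the
#'   terminal window (default 8 residues) cleaves the tail off.
#'
#' @param mature_raw Non-empty amino-acid string (mature region before
#'   C-terminal processing).
#' @param dibasic_window Terminal window (residues) searched for a dibasic.
#' @return List with `mature`, `amidated`, `cterm` (removed suffix or
#'   `NA_character_`), and `cut` (0-based position of the cut within
#'   `mature_raw`; equals `nchar(mature_raw)` when unprocessed).
#' @export
#' @examples
#' process_cterminus("ACAAAACNCAAAAGK")
process_cterminus <- function(mature_raw, dibasic_window = 8L) {
  if (nchar(mature_raw) == 0L) abort("empty mature region")
  n <- nchar(mature_raw)
  m <- regmatches(mature_raw, regexpr("G[KR]{0,2}$", mature_raw))
  if (length(m) == 1L) {
    cut <- n - nchar(m)
    if (cut == 0L) abort("C-terminal processing would leave an empty mature peptide")
    return(list(mature = substr(mature_raw, 1L, cut), amidated = TRUE,
                cterm = m, cut = cut))
  }
  win_start <- max(1L, n - dibasic_window + 1L)
  hits <- gregexpr("(?=RK|KR)", mature_raw, perl = TRUE)[[1]]
  hits <- hits[hits >= win_start & hits > 0L]
  if (length(hits) > 0L) {
    i <- min(hits)                                # leftmost dibasic in window
    if (i == 1L) abort("C-terminal processing would leave an empty mature peptide")
    return(list(mature = substr(mature_raw, 1L, i - 1L), amidated = FALSE,
                cterm = substr(mature_raw, i, n), cut = i - 1L))
  }
  list(mature = mature_raw, amidated = FALSE, cterm = NA_character_, cut = n)
}

# Fallback signal scoring when no grammar matches: mean Kyte-Doolittle
# hydropathy of the h-core (0-based positions 3..cut-4).
fallback_signal_cut <- function(protein, range = c(19L, 25L)) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  cuts <- seq(range[1], range[2])
  cuts <- cuts[cuts <= n - 1L]                    # leave >= 1 mature residue
  if (length(cuts) == 0L) {
    abort(paste0("protein of length ", n, " shorter than the minimal signal"))
  }
  kd <- KYTE_DOOLITTLE[res]
  kd[is.na(kd)] <- 0
  scores <- vapply(cuts, function(cut) {
    idx <- 4:(cut - 3L)                           # 1-based = 0-based 3..cut-4
    mean(kd[idx])
  }, numeric(1))
  cuts[which.max(scores)]                         # ties -> smallest cut
}

#' Annotate a single CRP precursor
#'
#' Applies the region grammar in order: signal peptide by mode grammars
#' (first match wins; hydropathy-scored fallback cut in
#' `fallback_signal_range` when none matches), then PQM search for the
#' propeptide boundary, then C-terminal processing of the mature region.
#'
#' @param protein Amino-acid string beginning with M.
#' @param grammars List of `crp_signal_grammar` (order = priority).
#' @param fallback_signal_range Signal length range tried when no grammar
#'   matches (default 19-25 residues).
#' @param canonical_pqms Canonical PQM list.
#' @param dibasic_window See [process_cterminus()].
#' @return One-row tibble of region coordinates (0-based half-open on the
#'   protein), region sequences, `amidated`, `pqm` motif and the matched
#'   grammar name.
#' @export
annotate_precursor <- function(protein,
                               grammars = default_signal_grammars(),
                               fallback_signal_range = c(19L, 25L),
                               canonical_pqms = CANONICAL_PQMS,
                               dibasic_window = 8L) {
  if (nchar(protein) == 0L) abort("empty protein")
  if (substr(protein, 1L, 1L) != "M") {
    abort("precursor does not start with the initiator M")
  }
  signal_end <- NA_integer_
  grammar_name <- NA_character_
  for (g in grammars) {
    len <- match_signal_mode(protein, g)
    if (!is.na(len) && len < nchar(protein)) {
      signal_end <- len
      grammar_name <- g$name
      break
    }
  }
  if (is.na(signal_end)) {
    signal_end <- fallback_signal_cut(protein, fallback_signal_range)
    grammar_name <- "fallback"
  }

  res <- strsplit(protein, "")[[1]]
  first_c <- match("C", res)
  pqm <- NULL
  if (is.na(first_c) || signal_end < first_c - 1L) {
    pqm <- find_pqm(protein, signal_end, canonical_pqms)
  }
  mature_start <- if (is.null(pqm)) signal_end else pqm$position
  mature_raw <- substr(protein, mature_start + 1L, nchar(protein))
  ct <- process_cterminus(mature_raw, dibasic_window)
  mature_end <- mature_start + ct$cut
  has_pro <- !is.null(pqm)
  has_ct <- !is.na(ct$cterm)
  tibble(
    protein = protein,
    signal_start = 0L,
    signal_end = as.integer(signal_end),
    propeptide_start = if (has_pro) as.integer(signal_end) else NA_integer_,
    propeptide_end = if (has_pro) as.integer(mature_start) else NA_integer_,
    mature_start = as.integer(mature_start),
    mature_end = as.integer(mature_end),
    cterm_start = if (has_ct) as.integer(mature_end) else NA_integer_,
    cterm_end = if (has_ct) nchar(protein) else NA_integer_,
    amidated = ct$amidated,
    pqm = if (has_pro) pqm$motif else NA_character_,
    signal_grammar = grammar_name,
    signal_seq = substr(protein, 1L, signal_end),
    propeptide_seq = if (has_pro) {
      substr(protein, signal_end + 1L, mature_start)
    } else NA_character_,
    mature_seq = ct$mature,
    cterm_seq = ct$cterm
  )
}

#' Annotate a table of CRP precursors
#'
#' Tibble-first wrapper over [annotate_precursor()]: one input row per
#' precursor, one output row per precursor with all region columns.
#'
#' @param records Data frame with columns `id` and `seq` (protein sequences),
#'   e.g. from [read_fasta()]. A `cdna` column, if present, is carried through.
#' @inheritParams annotate_precursor
#' @return Tibble of annotations; see [annotate_precursor()].
#' @export
#' @examples
#' p <- paste0("MK", strrep("L", 12), "S", strrep("I", 5),
#'             "ESEENRALSDEQR", "ACAAAAAACAAAAACCAAAACAAACAAAAGK")
#' annotate_precursors(tibble::tibble(id = "tx1", seq = p))
annotate_precursors <- function(records,
                                grammars = default_signal_grammars(),
                                fallback_signal_range = c(19L, 25L),
                                canonical_pqms = CANONICAL_PQMS,
                                dibasic_window = 8L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  ann <- purrr::map(records$seq, annotate_precursor,
                    grammars = grammars,
                    fallback_signal_range = fallback_signal_range,
                    canonical_pqms = canonical_pqms,
                    dibasic_window = dibasic_window)
  out <- dplyr::bind_cols(tibble(id = records$id), dplyr::bind_rows(ann))
  if ("cdna" %in% names(records)) out$cdna <- records$cdna
  out
}
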