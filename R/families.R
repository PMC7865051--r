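#' Global identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with fixed default parameters
#' (match +1, mismatch 0, gap open -5, gap extend -1; a gap of length k costs
#' 5 + k) via [Biostrings::pairwiseAlignment()]. Identity is matches divided
#' by alignment columns.
#'
#' @param a,b Non-empty amino-acid strings. `b` may be a character vector, in
#'   which case one identity per element is returned.
#' @param match,mismatch,gap_open,gap_extend Alignment parameters.
#' @return Identity fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' global_identity("ACDEFG", "ACDKFG")
global_identity <- function(a, b, match = 1, mismatch = 0,
                            gap_open = 5, gap_extend = 1) {
  if (any(nchar(c(a, b)) == 0L)) abort("empty sequence")
  alphabet <- unique(c(AA_STANDARD, AA_AMBIGUOUS, "*"))
  sub <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(b),
    subject = Biostrings::AAString(a),
    type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / ncol_aln
}

#' Cluster annotated precursors into families
#'
#' Single-linkage clustering on the graph whose edges join precursor pairs
#' with global identity at or above `id_threshold` (over the full precursor)
#' AND equal mature-region cysteine count. Families are numbered by
#' descending size, ties broken by the lexicographically smallest member id.
#'
#' @param records Annotated tibble (needs `id`, `protein`/`seq`, and
#'   `mature_seq`).
#' @param id_threshold Identity threshold in `[0, 1]` (default 0.40).
#' @param registry Template registry used for the per-family consensus
#'   framework column.
#' @return A `crp_families` object: the input tibble with a `family` column,
#'   plus a `families` summary tibble (id, representative, size, consensus
#'   framework) as attribute; [tidy()] and [glance()] methods apply.
#' @export
classify_families <- function(records, id_threshold = 0.40,
                              registry = default_template_registry()) {
  seq_col <- if ("protein" %in% names(records)) "protein" else "seq"
  stopifnot(seq_col %in% names(records), "id" %in% names(records))
  if (!"mature_seq" %in% names(records) ||
      anyNA(records$mature_seq)) {
    bad <- if ("mature_seq" %in% names(records)) {
      records$id[is.na(records$mature_seq)]
    } else records$id
    abort(paste0("records without mature annotation: ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  n <- nrow(records)
  ord <- order(records$id)                 # input-order invariance
  seqs <- records[[seq_col]][ord]
  ids <- records$id[ord]
  ncys <- str_count(records$mature_seq[ord], stringr::fixed("C"))

  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      cand <- which(ncys[(i + 1L):n] == ncys[i]) + i
      if (length(cand) == 0L) next
      idv <- global_identity(seqs[i], seqs[cand])
      hit <- cand[idv >= id_threshold]
      adj[i, hit] <- TRUE
      adj[hit, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  # deterministic family numbering: by descending size, then smallest id
  info <- tibble(comp = comp, id = ids) |>
    group_by(comp) |>
    summarise(size = n(), rep_id = min(id), .groups = "drop") |>
    arrange(desc(size), rep_id) |>
    mutate(family = row_number())
  fam_of <- setNames(info$family, info$comp)
  assignment <- tibble(id = ids, family = unname(fam_of[as.character(comp)]))

  out <- records |>
    select(-dplyr::any_of("family")) |>
    left_join(assignment, by = "id")
  consensus <- out |>
    group_by(family) |>
    summarise(
      n_members = n(),
      representative = min(id),
      n_cys = as.integer(str_count(mature_seq, stringr::fixed("C"))[1L]),
      consensus_framework = consensus_pattern(mature_seq),
      .groups = "drop"
    ) |>
    arrange(family)
  structure(out, class = c("crp_families", class(out)),
            families = consensus, id_threshold = id_threshold)
}

# Consensus framework over a family: elementwise min-max ranges of the member
# frameworks, serialized in the pattern language.
consensus_pattern <- function(matures) {
  fws <- purrr::map(matures, extract_framework)
  ncys <- map_int(fws, "n_cys")
  if (length(unique(ncys)) != 1L) return(NA_character_)
  rng <- function(v) {
    lo <- min(v); hi <- max(v)
    if (lo == hi) {
      if (lo == 0L) NULL else paste0("X", lo)
    } else paste0("X", lo, "-", hi)
  }
  toks <- rng(map_int(fws, "n_term_offset"))
  k <- ncys[1L]
  if (k == 0L) return(paste0("X", min(map_int(fws, "n_term_offset")),
                             "-", max(map_int(fws, "n_term_offset"))))
  gaps <- do.call(rbind, purrr::map(fws, function(f) {
    if (f$n_cys > 1L) f$gaps else integer(0)
  }))
  for (j in seq_len(k)) {
    toks <- c(toks, "C")
    if (j < k) toks <- c(toks, rng(gaps[, j]))
  }
  toks <- c(toks, rng(map_int(fws, "c_term_tail")))
  paste(toks, collapse = "-")
}

#' @export
tidy.crp_families <- function(x, ...) {
  as_tibble(x) |> select(id, family, dplyr::any_of(c("motif", "framework")))
}

#' @export
glance.crp_families <- function(x, ...) {
  fams <- attr(x, "families")
  tibble(
    n_records = nrow(x),
    n_families = nrow(fams),
    largest_family = max(fams$n_members),
    id_threshold = attr(x, "id_threshold")
  )
}

#' @export
print.crp_families <- function(x, ...) {
  fams <- attr(x, "families")
  cat("<crp_families> ", nrow(x), " precursors in ", nrow(fams),
      " families (identity threshold ", attr(x, "id_threshold"), ")\n",
      sep = "")
  print(fams, ...)
  invisible(x)
}
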