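#' Read a FASTA file into a tibble
#'
#' Reads a (possibly aligned) multi-record FASTA file. Sequences are uppercased;
#' gap characters are preserved, so aligned FASTA round-trips.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKCA", ">b", "MKCG"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(paste0("empty FASTA file: ", path))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    abort(paste0("not a FASTA file (first line is not a header): ", path))
  }
  grp <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(
    split(lines[!is_header], grp[!is_header]),
    function(x) toupper(paste(x, collapse = "")),
    character(1)
  )
  # headers with no sequence lines still count as (empty) records
  all_seqs <- setNames(character(length(ids)), as.character(seq_along(ids)))
  all_seqs[names(seqs)] <- seqs
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, seq = unname(all_seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  out <- unlist(purrr::map2(records$id, records$seq, function(id, s) {
    if (nchar(s) == 0L) return(c(paste0(">", id), ""))
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", id), chunks)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard-code translation of an in-frame CDS. A terminal stop codon is
#' dropped; an internal stop is an error.
#'
#' @param cdna Nucleotide string, length divisible by 3. Codons containing
#'   ambiguity characters (e.g. N) translate to `X`.
#' @param code Genetic code table, a named character vector mapping codons to
#'   single-letter amino acids with `"*"` for stops. Defaults to the standard
#'   code ([Biostrings::GENETIC_CODE]).
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_cds("ATGAAATGTTGA")
translate_cds <- function(cdna, code = Biostrings::GENETIC_CODE) {
  cdna <- toupper(gsub("\\s", "", cdna))
  cdna <- chartr("U", "T", cdna)
  n <- nchar(cdna)
  if (n == 0L) abort("empty CDS")
  if (n %% 3L != 0L) {
    abort(paste0("CDS length ", n, " is not a multiple of 3"))
  }
  codons <- substring(cdna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  n_cod <- length(aa)
  if (aa[n_cod] == "*") aa <- aa[-n_cod]
  internal <- which(aa == "*")
  if (length(internal) > 0L) {
    abort(paste0("internal stop codon at codon ", internal[1L]))
  }
  paste(aa, collapse = "")
}

#' Write a per-record family report
#'
#' One row per record with region coordinates (0-based, half-open, on the
#' protein), mature cysteine count, framework pattern string and family label.
#' Missing annotations become empty fields and a warning is emitted.
#'
#' @param records Annotated tibble, as produced by [annotate_precursors()]
#'   (optionally with `family` from [classify_families()]).
#' @param path Output CSV path.
#' @return The report tibble, invisibly.
#' @export
write_family_report <- function(records, path) {
  need <- c("id", "signal_start", "signal_end")
  missing_ann <- !all(need %in% names(records)) ||
    (nrow(records) > 0 && anyNA(records$signal_end))
  if (missing_ann && nrow(records) > 0) {
    warn("some records lack annotations; writing empty fields for them")
  }
  col_or_na <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else rep(NA, nrow(records))
  }
  fw_pattern <- if ("mature_seq" %in% names(records)) {
    map_chr(records$mature_seq, function(s) {
      if (is.na(s)) NA_character_ else framework_to_pattern(extract_framework(s))
    })
  } else {
    rep(NA_character_, nrow(records))
  }
  n_cys <- if ("mature_seq" %in% names(records)) {
    map_int(records$mature_seq, function(s) {
      if (is.na(s)) NA_integer_ else str_count(s, stringr::fixed("C"))
    })
  } else {
    rep(NA_integer_, nrow(records))
  }
  report <- tibble(
    id = records$id,
    signal_start = col_or_na("signal_start"),
    signal_end = col_or_na("signal_end"),
    propeptide_start = col_or_na("propeptide_start"),
    propeptide_end = col_or_na("propeptide_end"),
    mature_start = col_or_na("mature_start"),
    mature_end = col_or_na("mature_end"),
    cterm_start = col_or_na("cterm_start"),
    cterm_end = col_or_na("cterm_end"),
    amidated = col_or_na("amidated"),
    n_cys = n_cys,
    framework = fw_pattern,
    family = col_or_na("family")
  )
  write.csv(report, path, row.names = FALSE, na = "")
  invisible(report)
}
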