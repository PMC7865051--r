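#' Extract the cysteine framework of a mature peptide
#'
#' A cysteine framework is the positional census of C residues: the number of
#' residues before the first cysteine, the ordered inter-cysteine spacings
#' (loops), and the tail after the last cysteine.
#'
#' @param mature Amino-acid string (non-empty). Ambiguity characters are never
#'   counted as cysteine.
#' @return A `crp_framework` list: `n_term_offset`, `gaps`, `c_term_tail`,
#'   `n_cys`.
#' @export
#' @examples
#' extract_framework("ACAAAAAACAAAAACCAAAACAAACAAAA")
extract_framework <- function(mature) {
  if (nchar(mature) == 0L) abort("empty mature peptide")
  res <- strsplit(mature, "")[[1]]
  pos <- which(res == "C")
  n_cys <- length(pos)
  if (n_cys == 0L) {
    fw <- list(n_term_offset = length(res), gaps = integer(0),
               c_term_tail = 0L, n_cys = 0L)
  } else {
    fw <- list(
      n_term_offset = pos[1L] - 1L,
      gaps = if (n_cys > 1L) as.integer(diff(pos) - 1L) else integer(0),
      c_term_tail = as.integer(length(res) - pos[n_cys]),
      n_cys = as.integer(n_cys)
    )
  }
  structure(fw, class = "crp_framework")
}

#' @export
print.crp_framework <- function(x, ...) {
  cat("<crp_framework> ", framework_to_pattern(x),
      " (", x$n_cys, " cys)\n", sep = "")
  invisible(x)
}

#' Serialize a cysteine framework to the pattern language
#'
#' Canonical form: hyphen-separated `C` and `Xn` tokens, e.g.
#' `"X1-C-X6-C-X5-C-C-X4-C-X3-C-X4"`. Zero-length runs are omitted; a
#' cysteine-free peptide serializes to `"X<len>"`.
#'
#' @param fw A `crp_framework`.
#' @return Pattern string; [parse_template()] of the result matches `fw`
#'   exactly.
#' @export
framework_to_pattern <- function(fw) {
  if (fw$n_cys == 0L) return(paste0("X", fw$n_term_offset))
  toks <- character(0)
  if (fw$n_term_offset > 0L) toks <- paste0("X", fw$n_term_offset)
  for (g in c(fw$gaps, -1L)) {
    toks <- c(toks, "C")
    if (g > 0L) toks <- c(toks, paste0("X", g))
  }
  if (fw$c_term_tail > 0L) toks <- c(toks, paste0("X", fw$c_term_tail))
  paste(toks, collapse = "-")
}

#' Parse a framework template pattern
#'
#' Parses the pattern language used for cysteine scaffolds: `C` for cysteine,
#' `Xn` for a run of n non-cysteine residues, `Xn-m` for a run of between n
#' and m residues, bare `X` for a single residue. Tokens may be separated by
#' spaces or hyphens; underscores are ignored, so `"C_X_13_C"` style strings
#' parse too. Adjacent cysteines (`CC`) yield a `(0,0)` gap.
#'
#' @param pattern Pattern string.
#' @param name Template name.
#' @param label Motif-class label attached to the template (see
#'   [classify_motif()]).
#' @param offset_range,tail_range Optional `c(min, max)` overrides for the
#'   N-terminal offset / C-terminal tail, for scaffolds whose termini are
#'   variable and not part of the printed pattern.
#' @param connectivity Optional disulfide-connectivity annotation (metadata
#'   only).
#' @return A `crp_framework_template` with `offset`, `gaps` (list of
#'   `c(min, max)`), `tail`, `n_cys`.
#' @export
#' @examples
#' parse_template("X-C-X6-C-X5-C-C-X4-C-X3-C-X4-6")
#' parse_template("C X13 C X2 C X12 C X3 C X8 C")
parse_template <- function(pattern, name = pattern, label = NA_character_,
                           offset_range = NULL, tail_range = NULL,
                           connectivity = NA_character_) {
  clean <- gsub("[ _]", "", pattern)
  n <- nchar(clean)
  runs <- list()      # alternating X-runs between C tokens
  cys_at <- integer(0)
  cur <- NULL         # accumulating X-run range, or NULL
  i <- 1L
  push_run <- function() {
    runs[[length(runs) + 1L]] <<- cur %||% c(0L, 0L)
    cur <<- NULL
  }
  while (i <= n) {
    ch <- substr(clean, i, i)
    if (ch == "C") {
      push_run()
      cys_at <- c(cys_at, length(runs))
      i <- i + 1L
    } else if (ch == "X") {
      rest <- substr(clean, i, n)
      m <- regmatches(rest, regexpr("^X([0-9]+(-[0-9]+(?![0-9]*[^-C0-9X]))?)?",
                                    rest, perl = TRUE))
      body <- sub("^X", "", m)
      if (nchar(body) == 0L) {
        rng <- c(1L, 1L)
      } else {
        parts <- as.integer(strsplit(body, "-")[[1]])
        rng <- if (length(parts) == 2L) parts else c(parts, parts)
      }
      if (is.na(rng[1]) || rng[1] > rng[2]) {
        abort(paste0("malformed token at position ", i, " in pattern: ", pattern))
      }
      cur <- if (is.null(cur)) rng else cur + rng   # merge adjacent X tokens
      i <- i + nchar(m)
      # a following character that is not C/X/-/digit is malformed (e.g. "XQ")
      nxt <- substr(clean, i, i)
      if (i <= n && !nxt %in% c("C", "X", "-")) {
        abort(paste0("malformed token 'X", nxt, "' at position ", i - 1L,
                     " in pattern: ", pattern))
      }
    } else if (ch == "-") {
      i <- i + 1L
    } else {
      abort(paste0("unexpected character '", ch, "' at position ", i,
                   " in pattern: ", pattern))
    }
  }
  push_run()                                      # trailing tail run
  n_cys <- length(cys_at)
  if (n_cys == 0L) {
    offset <- runs[[1L]]
    gaps <- list()
    tail_rng <- c(0L, 0L)
  } else {
    offset <- runs[[1L]]
    gaps <- runs[seq.int(2L, length.out = n_cys - 1L)]
    tail_rng <- runs[[length(runs)]]
  }
  structure(list(
    name = name, label = label, pattern = pattern,
    offset = as.integer(offset_range %||% offset),
    gaps = lapply(gaps, as.integer),
    tail = as.integer(tail_range %||% tail_rng),
    n_cys = as.integer(n_cys),
    connectivity = connectivity
  ), class = "crp_framework_template")
}

#' @export
print.crp_framework_template <- function(x, ...) {
  cat("<crp_framework_template> ", x$name, " [", x$label, "]: ",
      x$pattern, "\n", sep = "")
  invisible(x)
}

#' Match a framework against a template
#'
#' @param fw A `crp_framework`.
#' @param tpl A `crp_framework_template`.
#' @return `TRUE` iff cysteine counts agree and offset, every gap, and tail
#'   fall within the template's ranges.
#' @export
match_template <- function(fw, tpl) {
  if (fw$n_cys != tpl$n_cys) return(FALSE)
  in_rng <- function(v, r) v >= r[1] && v <= r[2]
  if (!in_rng(fw$n_term_offset, tpl$offset)) return(FALSE)
  if (fw$n_cys > 1L) {
    for (k in seq_along(tpl$gaps)) {
      if (!in_rng(fw$gaps[k], tpl$gaps[[k]])) return(FALSE)
    }
  }
  in_rng(fw$c_term_tail, tpl$tail)
}

#' Default cysteine-scaffold template registry
#'
#' Templates transcribed from a huntsman-spider venom CRP repertoire: the
#' eight 6-cys ICK family modes, the acidic non-ICK and CHH-like 6-cys
#' scaffolds, the extended-ICK 8-cys scaffold, a novel 8-cys scaffold, three
#' 10-cys scaffolds, two 12-cys scaffolds and a 2-cys scaffold. Ordered by
#' ascending cysteine count then family number; classification is
#' first-match-wins in this order. Scaffolds whose printed pattern starts or
#' ends at a cysteine get permissive offset/tail ranges (termini are the most
#' variable parts of mature peptides).
#'
#' @return Named list of `crp_framework_template` objects.
#' @export
default_template_registry <- function() {
  t <- function(...) parse_template(...)
  ick <- "I-IV,II-V,III-VI"
  free_off <- c(0L, 10L); free_tail <- c(0L, 40L)
  reg <- list(
    t("C-X6-C-X16", name = "family24", label = "2-cys",
      offset_range = free_off),
    t("X-C-X6-C-X5-C-C-X4-C-X3-C-X4-6", name = "family1", label = "ICK-6",
      connectivity = ick),
    t("X2-C-X6-C-X5-C-C-X4-C-X3-C-X3", name = "family2", label = "ICK-6",
      connectivity = ick),
    t("X5-C-X6-C-X6-C-C-X3-C-X3-C-X5", name = "family3", label = "ICK-6",
      connectivity = ick),
    t("X-C-X6-C-X6-C-C-X4-C-X4-C-X6", name = "family4", label = "ICK-6",
      connectivity = ick),
    t("X3-C-X6-C-X5-C-C-X4-C-X5-C-X", name = "family5", label = "ICK-6",
      connectivity = ick),
    t("X2-4-C-X6-C-X5-C-C-X4-C-X5-C-X3", name = "family6", label = "ICK-6",
      connectivity = ick),
    t("X2-3-C-X6-C-X5-C-C-X4-C-X9-C-X4", name = "family7", label = "ICK-6",
      connectivity = ick),
    t("X2-C-X6-C-X4-C-C-X4-C-X8-C-X3", name = "family8", label = "ICK-6",
      connectivity = ick),
    t("C-X5-C-X3-C-X5-C-X-C-X-C", name = "family9", label = "non-ICK-6",
      offset_range = free_off, tail_range = free_tail),
    t("C-X13-C-X2-C-X12-C-X3-C-X8-C", name = "family10", label = "CHH-like-6",
      offset_range = free_off, tail_range = free_tail,
      connectivity = "I-V,II-IV,III-VI"),
    t("C-X6-C-X1-40-C-C-X4-C-X-C-X1-40-C-X-C", name = "family11_14",
      label = "extended-ICK-8", offset_range = free_off,
      tail_range = free_tail, connectivity = "I-IV,II-V,III-VIII,VI-VII"),
    t("C-X21-C-X4-C-X9-C-X10-C-X11-C-C-X4-C", name = "family15",
      label = "other", offset_range = c(0L, 15L), tail_range = free_tail),
    t("C-X6-8-C-X-C-X6-C-X-C-X7-11-C-X-C-X7-C-X5-C-X19-20-C",
      name = "family16", label = "10-cys",
      offset_range = free_off, tail_range = free_tail),
    t("C-X1-40-C-X4-C-C-X1-40-C-X9-C-X1-40-C-X-C-X5-C-X1-40-C",
      name = "family17_18", label = "10-cys",
      offset_range = free_off, tail_range = free_tail),
    t("C-X7-C-X8-C-C-X4-C-X5-C-C-X3-C-X3-C-X17-C", name = "family19_21",
      label = "10-cys", offset_range = free_off, tail_range = free_tail),
    t("C-X6-C-X3-C-X-C-C-X5-C-X-C-X4-C-X-C-X8-C-X6-C-X12-C",
      name = "family22", label = "12-cys",
      offset_range = free_off, tail_range = free_tail),
    t("C-X7-C-X23-C-X9-C-X7-C-X22-C-X15-C-X11-C-X11-C-X8-C-X8-C-X22-C",
      name = "family23", label = "12-cys",
      offset_range = free_off, tail_range = free_tail)
  )
  setNames(reg, map_chr(reg, "name"))
}

#' Classify a framework into a motif class
#'
#' First matching template in registry order wins. With no template match the
#' label falls back on cysteine count (2 -> "2-cys", 6 -> "non-ICK-6",
#' 10 -> "10-cys", 12 -> "12-cys", otherwise "other"; the extended-ICK-8
#' label is only ever assigned through a template).
#'
#' @param fw A `crp_framework`.
#' @param registry List of `crp_framework_template` (order = priority).
#' @return List with `label`, `template_name` (`NA` when unmatched), and
#'   `matches` (names of all matching templates, so range collisions are
#'   visible rather than silently resolved).
#' @export
classify_motif <- function(fw, registry = default_template_registry()) {
  hits <- map_lgl(registry, function(tpl) match_template(fw, tpl))
  matches <- names(registry)[hits]
  if (length(matches) > 0L) {
    tpl <- registry[[matches[1L]]]
    return(list(label = tpl$label, template_name = tpl$name, matches = matches))
  }
  label <- switch(as.character(fw$n_cys),
                  "2" = "2-cys", "6" = "non-ICK-6",
                  "10" = "10-cys", "12" = "12-cys", "other")
  list(label = label, template_name = NA_character_, matches = character(0))
}

#' Classify the scaffolds of an annotated precursor table
#'
#' Adds `n_cys`, the canonical `framework` pattern, `motif` label and matched
#' `template` columns to an annotation table.
#'
#' @param records Annotated tibble with a `mature_seq` column
#'   (see [annotate_precursors()]).
#' @param registry Template registry (see [default_template_registry()]).
#' @return `records` with scaffold columns appended.
#' @export
classify_scaffolds <- function(records, registry = default_template_registry()) {
  stopifnot("mature_seq" %in% names(records))
  fws <- purrr::map(records$mature_seq, extract_framework)
  cls <- purrr::map(fws, classify_motif, registry = registry)
  records |>
    mutate(
      n_cys = map_int(fws, "n_cys"),
      framework = map_chr(fws, framework_to_pattern),
      motif = map_chr(cls, "label"),
      template = map_chr(cls, "template_name")
    )
}
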