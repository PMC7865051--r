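#' Parse a signal-peptide mode grammar
#'
#' Signal peptides of venom CRP families follow compact "modes" written as a
#' string of literal residues and hydrophobic runs, e.g. `"MKh12Sh5"`: literal
#' Met-Lys, twelve hydrophobic residues, literal Ser, five hydrophobic
#' residues. Run lengths may be ranges (`"h11-13"`).
#'
#' @param mode Mode string. Uppercase letters are literal residues; `h`
#'   followed by a count (or `min-max` range) is a hydrophobic run.
#'   Underscores and spaces are ignored, so `"MKh_12_Sh_5_"` also parses.
#' @param name Optional grammar name.
#' @return A `crp_signal_grammar`: list of tokens plus metadata.
#' @export
#' @examples
#' parse_signal_grammar("MKh12Sh5", name = "family1")
parse_signal_grammar <- function(mode, name = mode) {
  clean <- gsub("[ _]", "", mode)
  if (!startsWith(clean, "M")) {
    abort(paste0("signal grammar must begin with literal M: ", mode))
  }
  tokens <- list()
  i <- 1L
  n <- nchar(clean)
  while (i <= n) {
    ch <- substr(clean, i, i)
    if (ch == "h") {
      m <- regmatches(substr(clean, i, n),
                      regexpr("^h([0-9]+)(-([0-9]+))?", substr(clean, i, n)))
      if (length(m) == 0L) {
        abort(paste0("malformed hydrophobic run at position ", i, " in ", mode))
      }
      parts <- strsplit(sub("^h", "", m), "-")[[1]]
      lo <- as.integer(parts[1]); hi <- if (length(parts) > 1) as.integer(parts[2]) else lo
      tokens[[length(tokens) + 1L]] <- list(type = "h", min = lo, max = hi)
      i <- i + nchar(m)
    } else if (ch %in% c(AA_STANDARD)) {
      tokens[[length(tokens) + 1L]] <- list(type = "lit", residue = ch)
      i <- i + 1L
    } else {
      abort(paste0("unknown grammar character '", ch, "' in ", mode))
    }
  }
  structure(list(name = name, mode = mode, tokens = tokens),
            class = "crp_signal_grammar")
}

#' @export
print.crp_signal_grammar <- function(x, ...) {
  cat("<crp_signal_grammar> ", x$name, ": ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Match a signal grammar against a protein prefix
#'
#' Greedy left-to-right match starting at position 0. Hydrophobic runs take
#' residues from the strict core set `{A,V,L,I,M,F,W}` with up to two S/T
#' positions allowed per run; for ranged runs the longest feasible length is
#' taken first.
#'
#' @param protein Amino-acid string starting with the initiator M.
#' @param grammar A `crp_signal_grammar` (or mode string).
#' @param hydrophobic_set Residues accepted in `h` runs.
#' @param st_slack Maximum S/T positions tolerated per `h` run.
#' @return Matched signal length (integer) or `NA_integer_` if no match.
#' @export
#' @examples
#' p <- paste0("MK", strrep("L", 12), "S", strrep("V", 5), "DEQRGC")
#' match_signal_mode(p, "MKh12Sh5")
match_signal_mode <- function(protein, grammar,
                              hydrophobic_set = HYDROPHOBIC_CORE,
                              st_slack = 2L) {
  if (is.character(grammar)) grammar <- parse_signal_grammar(grammar)
  if (nchar(protein) == 0L) abort("empty protein")
  res <- strsplit(protein, "")[[1]]
  is_h <- res %in% hydrophobic_set
  is_st <- res %in% c("S", "T")

  run_ok <- function(from, len) {
    if (len == 0L) return(TRUE)
    if (from + len - 1L > length(res)) return(FALSE)
    idx <- from:(from + len - 1L)
    core <- sum(is_h[idx])
    st <- sum(is_st[idx])
    (core + st == len) && st <= st_slack
  }

  match_from <- function(pos, tok_i) {
    if (tok_i > length(grammar$tokens)) return(pos - 1L)  # matched length
    tok <- grammar$tokens[[tok_i]]
    if (tok$type == "lit") {
      if (pos <= length(res) && res[pos] == tok$residue) {
        return(match_from(pos + 1L, tok_i + 1L))
      }
      return(NA_integer_)
    }
    for (len in seq(tok$max, tok$min)) {     # longest first (greedy)
      if (run_ok(pos, len)) {
        out <- match_from(pos + len, tok_i + 1L)
        if (!is.na(out)) return(out)
      }
    }
    NA_integer_
  }
  match_from(1L, 1L)
}

#' Default signal-peptide grammar set
#'
#' The eight signal-peptide modes observed across the 6-cys ICK toxin families
#' of a huntsman-spider venom repertoire. Order matters: annotation applies
#' them first-match-wins.
#'
#' @return Named list of `crp_signal_grammar` objects.
#' @export
default_signal_grammars <- function() {
  modes <- c(
    family1 = "MKh12Sh5",
    family2 = "MKTh11Sh5",
    family3 = "MKh18",
    family4 = "MKITh15",
    family5 = "MKTTh3Th6Sh5",
    family6 = "MKTTh3Th6Sh5",
    family7 = "MKh5Th6Sh5",
    family8 = "MKSSh7Th4Sh2EFTRS"
  )
  purrr::imap(as.list(modes), function(m, nm) parse_signal_grammar(m, name = nm))
}
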