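# Original Nei-Gojobori (p-distance) synonymous / non-synonymous counting.
# Site fractions use the per-position normalization syn/(syn+nonsyn) over
# non-stop single-nucleotide changes, so every codon contributes exactly
# three sites (S + N = 3 x codons); multi-nucleotide codon differences are
# averaged over all stop-free single-step pathways.

NUCS <- c("T", "C", "A", "G")

.ng_cache <- new.env(parent = emptyenv())

sense_codons <- function(code = Biostrings::GENETIC_CODE) {
  names(code)[code != "*"]
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Each of the codon's three positions contributes one site, split into a
#' synonymous fraction `syn/(syn + nonsyn)` over its non-stop
#' single-nucleotide changes (changes to stop codons are excluded).
#'
#' @param codon A sense codon (3-mer, no gaps or ambiguity).
#' @param code Genetic code (named vector, `"*"` = stop).
#' @return List with `s` and `n`; `s + n == 3`.
#' @export
#' @examples
#' codon_sites("GGG")   # 1 synonymous, 2 nonsynonymous sites
codon_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  aa <- code[codon]
  if (is.na(aa)) abort(paste0("not an unambiguous codon: ", codon))
  if (aa == "*") abort(paste0("stop codon: ", codon))
  s <- 0
  for (pos in 1:3) {
    nt <- substr(codon, pos, pos)
    syn <- 0L; tot <- 0L
    for (alt in setdiff(NUCS, nt)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      maa <- code[mut]
      if (maa == "*") next
      tot <- tot + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  list(s = s, n = 3 - s)
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Zero differing positions give `(0, 0)`; one is classified directly; two or
#' three are averaged over all orderings of single-step mutational pathways,
#' excluding any pathway passing through a stop codon.
#'
#' @param c1,c2 Sense codons.
#' @param code Genetic code.
#' @return List with `sd`, `nd`, `n_paths` (stop-free pathways used) and
#'   `flagged` (`TRUE` when some pathways were excluded; with no legal
#'   pathway `sd`/`nd` are `NA`).
#' @export
#' @examples
#' codon_differences("TTT", "GTA")
codon_differences <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  for (cc in c(c1, c2)) {
    if (is.na(code[cc])) abort(paste0("not an unambiguous codon: ", cc))
    if (code[cc] == "*") abort(paste0("stop codon: ", cc))
  }
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(list(sd = 0, nd = 0, n_paths = 1L, flagged = FALSE))
  perms <- switch(k, list(diff_pos),
                  list(diff_pos, rev(diff_pos)),
                  {
                    p <- diff_pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  sd_tot <- 0; nd_tot <- 0; legal <- 0L
  for (ord in perms) {
    cur <- c1
    sd_p <- 0L; nd_p <- 0L; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[nxt] == "*") { ok <- FALSE; break }
      if (code[nxt] == code[cur]) sd_p <- sd_p + 1L else nd_p <- nd_p + 1L
      cur <- nxt
    }
    if (ok) {
      legal <- legal + 1L
      sd_tot <- sd_tot + sd_p
      nd_tot <- nd_tot + nd_p
    }
  }
  if (legal == 0L) {
    return(list(sd = NA_real_, nd = NA_real_, n_paths = 0L, flagged = TRUE))
  }
  list(sd = sd_tot / legal, nd = nd_tot / legal, n_paths = legal,
       flagged = legal < length(perms))
}

# Cached lookup tables over the 61 sense codons: per-codon site fractions and
# 61x61 pathway-averaged difference counts.
ng_tables <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste(code, collapse = "")
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  sc <- sense_codons(code)
  s_site <- vapply(sc, function(cd) codon_sites(cd, code)$s, numeric(1))
  k <- length(sc)
  SD <- matrix(0, k, k, dimnames = list(sc, sc))
  ND <- matrix(0, k, k, dimnames = list(sc, sc))
  for (i in seq_len(k)) {
    for (j in i:k) {
      d <- codon_differences(sc[i], sc[j], code)
      SD[i, j] <- SD[j, i] <- d$sd
      ND[i, j] <- ND[j, i] <- d$nd
    }
  }
  tab <- list(sense = sc, s_site = s_site, SD = SD, ND = ND)
  .ng_cache[[key]] <- tab
  tab
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length not a multiple of 3")
  substring(toupper(cds), seq(1L, n, 3L), seq(3L, n, 3L))
}

# Per-column NG contributions for one aligned pair; NA rows = skipped columns
# (gap, ambiguity or stop in either codon: pairwise deletion at codon
# granularity).
ng_pair_cols <- function(cod1, cod2, tab) {
  ok <- cod1 %in% tab$sense & cod2 %in% tab$sense
  m <- length(cod1)
  out <- list(s = rep(NA_real_, m), n = rep(NA_real_, m),
              sd = rep(NA_real_, m), nd = rep(NA_real_, m))
  if (any(ok)) {
    s1 <- tab$s_site[cod1[ok]]; s2 <- tab$s_site[cod2[ok]]
    out$s[ok] <- (s1 + s2) / 2
    out$n[ok] <- 3 - out$s[ok]
    idx <- cbind(match(cod1[ok], tab$sense), match(cod2[ok], tab$sense))
    out$sd[ok] <- tab$SD[idx]
    out$nd[ok] <- tab$ND[idx]
  }
  out
}

ng_from_sums <- function(S, N, Sd, Nd, n_codons) {
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  omega <- if (pN == 0) 0 else if (pS == 0) Inf else pN / pS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 omega = omega, omega_undefined = is.infinite(omega),
                 n_codons = n_codons, p_value = NA_real_),
            class = "crp_ng")
}

#' Nei-Gojobori comparison of one aligned CDS pair
#'
#' @param row1,row2 Aligned coding sequences of equal length (gaps in whole
#'   codons). Codon columns with a gap, ambiguity or stop in either row are
#'   skipped.
#' @param code Genetic code.
#' @return A `crp_ng` result: `S`, `N` (mean sites over the pair), `Sd`, `Nd`,
#'   `pS`, `pN`, `omega` (`0` when `pN = 0`; `Inf`, flagged, when `pS = 0`
#'   with `pN > 0`).
#' @export
#' @examples
#' ng_pair("ATGAAACCT", "ATGAAGCCA")
ng_pair <- function(row1, row2, code = Biostrings::GENETIC_CODE) {
  if (nchar(row1) != nchar(row2)) abort("aligned rows differ in length")
  tab <- ng_tables(code)
  cols <- ng_pair_cols(split_codons(row1), split_codons(row2), tab)
  ok <- !is.na(cols$s)
  if (!any(ok)) abort("no comparable codons in pair")
  ng_from_sums(sum(cols$s[ok]), sum(cols$n[ok]),
               sum(cols$sd[ok]), sum(cols$nd[ok]), sum(ok))
}

#' @export
print.crp_ng <- function(x, ...) {
  cat("<crp_ng> S=", round(x$S, 2), " N=", round(x$N, 2),
      " pS=", signif(x$pS, 4), " pN=", signif(x$pN, 4),
      " omega=", if (x$omega_undefined) "Inf (pS=0)" else signif(x$omega, 4),
      if (!is.na(x$p_value)) paste0(" p=", signif(x$p_value, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.crp_ng <- function(x, ...) {
  tibble(S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
         omega = x$omega, p_value = x$p_value, n_codons = x$n_codons)
}

#' Construct a region-partitioned codon alignment
#'
#' @param ids Sequence ids (unique).
#' @param cds Aligned CDS rows (equal length, multiple of 3; gaps `-` in
#'   whole-codon units).
#' @param regions Region label per codon column (e.g. `"signal"`,
#'   `"propeptide"`, `"mature"`), length = codons.
#' @return A `crp_codon_alignment`.
#' @export
codon_alignment <- function(ids, cds, regions = NULL) {
  stopifnot(length(ids) == length(cds), !anyDuplicated(ids))
  L <- unique(nchar(cds))
  if (length(L) != 1L) abort("aligned CDS rows differ in length")
  if (L %% 3L != 0L) abort("alignment length not a multiple of 3")
  n_cod <- L / 3L
  regions <- regions %||% rep("mature", n_cod)
  if (length(regions) != n_cod) {
    abort(paste0("need one region label per codon column (", n_cod, ")"))
  }
  structure(list(ids = ids, cds = toupper(cds), regions = regions),
            class = "crp_codon_alignment")
}

#' @export
print.crp_codon_alignment <- function(x, ...) {
  cat("<crp_codon_alignment> ", length(x$ids), " sequences, ",
      length(x$regions), " codons (",
      paste(unique(x$regions), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Per-pair per-column contribution arrays for one region of an alignment.
ng_region_cols <- function(aln, region, code = Biostrings::GENETIC_CODE) {
  sel <- which(aln$regions == region)
  if (length(sel) == 0L) {
    abort(paste0("region '", region, "' absent from alignment"))
  }
  tab <- ng_tables(code)
  codons <- purrr::map(aln$cds, function(s) split_codons(s)[sel])
  n <- length(codons)
  if (n < 2L) abort("need at least 2 sequences")
  pairs <- utils::combn(n, 2L)
  cols <- purrr::map(seq_len(ncol(pairs)), function(k) {
    ng_pair_cols(codons[[pairs[1, k]]], codons[[pairs[2, k]]], tab)
  })
  list(cols = cols, n_codons = length(sel))
}

stat_from_cols <- function(cols, idx = NULL) {
  per_pair <- vapply(cols, function(cl) {
    s <- cl$s; n <- cl$n; sd_ <- cl$sd; nd_ <- cl$nd
    if (!is.null(idx)) { s <- s[idx]; n <- n[idx]; sd_ <- sd_[idx]; nd_ <- nd_[idx] }
    ok <- !is.na(s)
    S <- sum(s[ok]); N <- sum(n[ok])
    c(pS = if (S > 0) sum(sd_[ok]) / S else 0,
      pN = if (N > 0) sum(nd_[ok]) / N else 0,
      S = S, N = N, Sd = sum(sd_[ok]), Nd = sum(nd_[ok]))
  }, numeric(6))
  rowMeans(per_pair)
}

#' Region-wise selection analysis of a family alignment
#'
#' Restricts the alignment to one region's codon columns, averages `pS` and
#' `pN` over all unordered sequence pairs (original Nei-Gojobori, p-distance)
#' and forms `omega = pN/pS` from the averages.
#'
#' @param aln A `crp_codon_alignment`.
#' @param region Region label.
#' @param code Genetic code.
#' @return A `crp_ng` result (pair-averaged; `p_value` unset, see
#'   [ng_z_test()]).
#' @export
family_omega <- function(aln, region = "mature",
                         code = Biostrings::GENETIC_CODE) {
  rc <- ng_region_cols(aln, region, code)
  st <- stat_from_cols(rc$cols)
  out <- ng_from_sums(st["S"], st["N"], st["Sd"], st["Nd"], rc$n_codons)
  # pair-averaged proportions override the ratio-of-sums view
  out$pS <- unname(st["pS"]); out$pN <- unname(st["pN"])
  out$omega <- if (out$pN == 0) 0 else if (out$pS == 0) Inf else out$pN / out$pS
  out$omega_undefined <- is.infinite(out$omega)
  out
}

#' Bootstrap Z-test of neutrality for one region
#'
#' Codon columns are resampled with replacement; the bootstrap standard error
#' of `mean(pN) - mean(pS)` gives a Z statistic and a two-tailed normal
#' p-value. With zero bootstrap variance the p-value is 1 when the observed
#' difference is 0 (the identical-sequences convention) and 0 otherwise.
#'
#' @param aln A `crp_codon_alignment`.
#' @param region Region label.
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Seed for reproducible resampling.
#' @param code Genetic code.
#' @return List with `p_value`, `z`, `observed` (pN - pS) and `se`.
#' @export
ng_z_test <- function(aln, region = "mature", reps = 1000L, seed = 1L,
                      code = Biostrings::GENETIC_CODE) {
  stopifnot(reps >= 100L)
  rc <- ng_region_cols(aln, region, code)
  obs <- stat_from_cols(rc$cols)
  observed <- unname(obs["pN"] - obs["pS"])
  L <- rc$n_codons
  boot <- with_preserved_seed(seed, {
    vapply(seq_len(reps), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      st <- stat_from_cols(rc$cols, idx)
      unname(st["pN"] - st["pS"])
    }, numeric(1))
  })
  se <- sd(boot)
  if (is.na(se) || se == 0) {
    p <- if (abs(observed) < .Machine$double.eps^0.5) 1 else 0
    return(list(p_value = p, z = NA_real_, observed = observed, se = se))
  }
  z <- observed / se
  list(p_value = 2 * pnorm(-abs(z)), z = z, observed = observed, se = se)
}

#' Selection summary across regions
#'
#' Convenience wrapper producing one row per region: sites, differences,
#' `pS`, `pN`, `omega` and the bootstrap-Z neutrality p-value.
#'
#' @param aln A `crp_codon_alignment`.
#' @param regions Regions to analyse (default: all present, in order).
#' @param reps,seed Passed to [ng_z_test()].
#' @param code Genetic code.
#' @return Tibble, one row per region.
#' @export
region_selection <- function(aln, regions = unique(aln$regions),
                             reps = 1000L, seed = 1L,
                             code = Biostrings::GENETIC_CODE) {
  purrr::map(regions, function(rg) {
    res <- family_omega(aln, rg, code)
    zt <- ng_z_test(aln, rg, reps = reps, seed = seed, code = code)
    res$p_value <- zt$p_value
    tidy(res) |> mutate(region = rg, .before = 1L)
  }) |> dplyr::bind_rows()
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
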