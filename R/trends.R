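#' Propeptide-length bins for a species dataset
#'
#' Bins annotated precursors by propeptide length into `<10`, `10-25`
#' (inclusive) and `>25` residues. Precursors without a predicted propeptide
#' count as length 0 (a vanished propeptide is a short one).
#'
#' @param records Annotated tibble (needs `propeptide_start`/`propeptide_end`
#'   or a `propeptide_len` column), one species.
#' @param species Optional species label for the output row.
#' @return One-row tibble with raw counts (`n_*`) and percentages (`pct_*`);
#'   percentages sum to 100.
#' @export
propeptide_bins <- function(records, species = NA_character_) {
  if (nrow(records) == 0L) abort("empty dataset")
  len <- if ("propeptide_len" %in% names(records)) {
    records$propeptide_len
  } else {
    records$propeptide_end - records$propeptide_start
  }
  len[is.na(len)] <- 0L
  n_short <- sum(len < 10)
  n_mid <- sum(len >= 10 & len <= 25)
  n_long <- sum(len > 25)
  n <- length(len)
  tibble(
    species = species, n = n,
    n_short = n_short, n_mid = n_mid, n_long = n_long,
    pct_short = 100 * n_short / n,
    pct_mid = 100 * n_mid / n,
    pct_long = 100 * n_long / n
  )
}

#' Mature-region cysteine-count classes for a species dataset
#'
#' Percentage of peptides per cysteine-count class. The default classes are
#' the 6-cys motif versus >= 8 cysteines; records falling in no class (e.g. a
#' 2-cys peptide under the default classes) are excluded from the denominator
#' and their count reported.
#'
#' @param records Annotated tibble with `mature_seq` (or `n_cys`).
#' @param classes Named list of predicates on the cysteine count, or the
#'   default `list("6" = 6, ">=8" = c(8, Inf))`: a scalar means exact count,
#'   a length-2 vector an inclusive range.
#' @param species Optional species label.
#' @return One-row tibble with per-class counts and percentages plus
#'   `n_excluded`.
#' @export
#' @examples
#' d <- tibble::tibble(n_cys = c(rep(6, 11), rep(8, 9)))
#' cys_count_classes(d)
cys_count_classes <- function(records,
                              classes = list("6" = 6, ">=8" = c(8, Inf)),
                              species = NA_character_) {
  if (nrow(records) == 0L) abort("empty dataset")
  ncys <- if ("n_cys" %in% names(records)) {
    records$n_cys
  } else {
    str_count(records$mature_seq, stringr::fixed("C"))
  }
  member <- purrr::map(classes, function(cl) {
    if (length(cl) == 1L) ncys == cl else ncys >= cl[1] & ncys <= cl[2]
  })
  in_any <- Reduce(`|`, member)
  denom <- sum(in_any)
  if (denom == 0L) abort("no record falls in any cysteine class")
  counts <- map_int(member, sum)
  row <- tibble(species = species, n = denom,
                n_excluded = sum(!in_any))
  for (nm in names(classes)) {
    row[[paste0("n_", nm)]] <- counts[[nm]]
    row[[paste0("pct_", nm)]] <- 100 * counts[[nm]] / denom
  }
  row
}

#' Scaffold inventory across grouped datasets
#'
#' Counts canonical cysteine-adjacency patterns (X-runs collapsed to
#' ellipses, so `C-X6-C-X5-C-C-...` prints as `C...C...CC...`) per group
#' (e.g. spider suborder).
#'
#' @param datasets Named list of annotated tibbles (names = group labels),
#'   or a single tibble with a `group` column.
#' @return Tibble of (`group`, `scaffold`, `n_cys`, `count`, `pct` within
#'   group), deterministically ordered.
#' @export
scaffold_inventory <- function(datasets) {
  if (is.data.frame(datasets)) {
    stopifnot("group" %in% names(datasets))
    datasets <- split(datasets, datasets$group)
  }
  purrr::imap(datasets, function(ds, grp) {
    fw <- purrr::map(ds$mature_seq, extract_framework)
    tibble(
      group = grp,
      scaffold = map_chr(fw, adjacency_pattern),
      n_cys = map_int(fw, "n_cys")
    )
  }) |>
    dplyr::bind_rows() |>
    count(group, scaffold, n_cys, name = "count") |>
    group_by(group) |>
    mutate(pct = 100 * count / sum(count)) |>
    ungroup() |>
    arrange(group, desc(count), scaffold)
}

# Collapse a framework to cysteine-adjacency notation: runs of >= 2
# non-cysteine residues become "...", single residues "X".
adjacency_pattern <- function(fw) {
  if (fw$n_cys == 0L) return("...")
  run <- function(g) if (g == 0L) "" else if (g == 1L) "X" else "..."
  out <- "C"
  for (g in fw$gaps) out <- paste0(out, run(g), "C")
  out
}

#' Bar chart of propeptide-length bins across species
#'
#' @param trend Tibble of [propeptide_bins()] rows (one per species).
#' @return A ggplot.
#' @export
plot_propeptide_bins <- function(trend) {
  long <- trend |>
    select(species, pct_short, pct_mid, pct_long) |>
    tidyr::pivot_longer(-species, names_to = "bin", values_to = "pct") |>
    mutate(bin = factor(bin, levels = c("pct_short", "pct_mid", "pct_long"),
                        labels = c("<10", "10-25", ">25")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$pct,
                                     fill = .data$bin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of precursors",
                  fill = "propeptide length (aa)") +
    ggplot2::theme_minimal()
}

#' Bar chart of cysteine-count classes across species
#'
#' @param trend Tibble of [cys_count_classes()] rows (one per species).
#' @return A ggplot.
#' @export
plot_cys_classes <- function(trend) {
  long <- trend |>
    select(species, dplyr::starts_with("pct_")) |>
    tidyr::pivot_longer(-species, names_to = "class", values_to = "pct") |>
    mutate(class = sub("^pct_", "", class))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$pct,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of peptides", fill = "cysteines") +
    ggplot2::theme_minimal()
}
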