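#' Pairwise p-distance with pairwise deletion
#'
#' Proportion of differing sites over the columns where both rows carry an
#' unambiguous residue (gaps and ambiguity characters are removed per pair:
#' the pairwise-deletion option).
#'
#' @param row_a,row_b Aligned amino-acid strings of equal length.
#' @param ambiguous Characters treated as missing.
#' @return List with `p` (fraction; `NA` when no shared sites) and `sites`.
#' @export
#' @examples
#' p_distance("A-DE", "ACDK")
p_distance <- function(row_a, row_b, ambiguous = c("-", ".", "X", "B", "Z", "J", "?", "*")) {
  if (nchar(row_a) != nchar(row_b)) abort("aligned rows differ in length")
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  ok <- !(a %in% ambiguous) & !(b %in% ambiguous)
  sites <- sum(ok)
  if (sites == 0L) return(list(p = NA_real_, sites = 0L))
  list(p = sum(a[ok] != b[ok]) / sites, sites = as.integer(sites))
}

#' Poisson correction of an amino-acid p-distance
#'
#' `d = -ln(1 - p)`, the expected number of substitutions per site under a
#' Poisson model of amino-acid change.
#'
#' @param p Proportion(s) of differing sites, `0 <= p < 1`.
#' @return Corrected distance(s); `NA` (undefined) where `p >= 1` or `p` is
#'   missing.
#' @export
poisson_correct <- function(p) {
  d <- ifelse(!is.na(p) & p < 1, -log(1 - p), NA_real_)
  ifelse(!is.na(p) & p < 0, NA_real_, d)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param msa Tibble with `id` and aligned `seq` columns (equal lengths), or
#'   a named character vector.
#' @param correction `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return A symmetric `dist`-convertible matrix with ids as dimnames;
#'   undefined pairs are `NA`.
#' @export
distance_matrix <- function(msa, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  if (is.character(msa)) msa <- tibble(id = names(msa), seq = unname(msa))
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pd <- p_distance(msa$seq[i], msa$seq[j])
        d <- if (correction == "poisson") poisson_correct(pd$p) else pd$p
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration with the Q-criterion. Ties are broken
#' deterministically by the lowest index pair; negative branch lengths are
#' clamped to zero by default.
#'
#' @param D Symmetric distance matrix with ids as dimnames (>= 2 taxa).
#' @param allow_negative Keep negative branch lengths instead of clamping.
#' @return An [ape::phylo] tree (unrooted).
#' @export
#' @examples
#' D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(D)
nj_tree <- function(D, allow_negative = FALSE) {
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    pairs <- apply(bad, 1L, function(ij) {
      paste(rownames(D)[ij[1]], colnames(D)[ij[2]], sep = "/")
    })
    abort(paste0("undefined distances for pairs: ",
                 paste(head(pairs, 5L), collapse = ", ")))
  }
  n <- nrow(D)
  ids <- rownames(D)
  if (n < 2L) abort("need at least 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(D[1, 2] / 2, 2), tip.label = ids,
               Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # node bookkeeping: tips 1..n, internal nodes n+1.. (root-ish last)
  n_internal <- n - 2L
  edge <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  active <- seq_len(n)              # node numbers of active clusters
  next_node <- n + n_internal       # allocate internal nodes downward so the
  # final join gets the lowest internal number (ape convention: root = n+1)
  Dm <- D
  clamp <- function(x) if (allow_negative) x else pmax(x, 0)

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(pmin(k[, 1], k[, 2]), pmax(k[, 1], k[, 2])), , drop = FALSE]
    i <- min(k[1, ]); j <- max(k[1, ])
    vi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    new_node <- next_node
    next_node <- next_node - 1L
    edge <- rbind(edge, c(new_node, active[i]), c(new_node, active[j]))
    elen <- c(elen, clamp(vi), clamp(vj))
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active <- c(active[keep], new_node)
  }
  # final 3-way join onto the last internal node
  root <- next_node
  stopifnot(root == n + 1L)
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  edge <- rbind(edge, cbind(root, active))
  elen <- c(elen, clamp(v))
  tr <- list(edge = edge, edge.length = elen, tip.label = ids,
             Nnode = n - 2L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Build a CRP phylogeny from annotated precursors
#'
#' The computation behind a precursor NJ tree figure: align the precursors
#' (built-in progressive aligner, or verbatim if already aligned), compute
#' Poisson-corrected p-distances with pairwise deletion, and run
#' neighbor-joining.
#'
#' @param records Tibble with `id` and a sequence column (`protein` or `seq`).
#' @param correction Distance correction, see [distance_matrix()].
#' @return List of class `crp_phylo` with elements `msa` (tibble), `dist`
#'   (matrix) and `tree` ([ape::phylo]); `newick(x)` serializes the tree.
#' @export
crp_phylo <- function(records, correction = "poisson") {
  seq_col <- if ("protein" %in% names(records)) "protein" else "seq"
  msa <- progressive_align(tibble(id = records$id, seq = records[[seq_col]]))
  D <- distance_matrix(msa, correction = correction)
  tree <- nj_tree(D)
  structure(list(msa = msa, dist = D, tree = tree), class = "crp_phylo")
}

#' Newick serialization
#'
#' @param x A `crp_phylo` result or [ape::phylo] tree.
#' @param digits Branch-length precision.
#' @return Newick string.
#' @export
newick <- function(x, digits = 10) {
  tree <- if (inherits(x, "crp_phylo")) x$tree else x
  ape::write.tree(tree, digits = digits)
}

#' @export
print.crp_phylo <- function(x, ...) {
  cat("<crp_phylo> ", length(x$tree$tip.label), " leaves, alignment of ",
      nchar(x$msa$seq[1]), " columns\n", sep = "")
  invisible(x)
}

#' @export
autoplot.crp_phylo <- function(object, ...) {
  # rightwards phylogram: x = root-to-node path length, y = tip rank with
  # internal nodes centred on their children
  tr <- ape::reorder.phylo(object$tree, "postorder")
  n <- length(tr$tip.label)
  n_nodes <- n + tr$Nnode
  root <- n + 1L
  x <- numeric(n_nodes); y <- rep(NA_real_, n_nodes)
  y[seq_len(n)] <- match(seq_len(n), unique(tr$edge[tr$edge[, 2] <= n, 2]))
  for (k in seq_len(nrow(tr$edge))) {          # postorder: children first
    par <- tr$edge[k, 1]
    kids <- tr$edge[tr$edge[, 1] == par, 2]
    y[par] <- mean(y[kids])
  }
  for (k in rev(seq_len(nrow(tr$edge)))) {     # preorder for depths
    x[tr$edge[k, 2]] <- x[tr$edge[k, 1]] + tr$edge.length[k]
  }
  seg <- data.frame(x0 = x[tr$edge[, 1]], y0 = y[tr$edge[, 1]],
                    x1 = x[tr$edge[, 2]], y1 = y[tr$edge[, 2]])
  tips <- data.frame(label = tr$tip.label, x = x[seq_len(n)],
                     y = y[seq_len(n)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y1,
                                       xend = .data$x1, yend = .data$y1)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x0, yend = .data$y1)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 2.5) +
    ggplot2::theme_void()
}
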