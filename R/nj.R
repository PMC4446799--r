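# JC distances from a character alignment matrix (rows = taxa); gap/N
# columns deleted pairwise; saturated pairs (p >= 0.75) capped at 10
# subs/site. Returns NULL if any pair has no comparable sites.
# One-hot encoding + tcrossprod: matches(i,j) = sum_b I_b I_b^T, comparable
# sites = V V^T with V = valid indicator.
.jc_from_matrix <- function(m, taxa = rownames(m)) {
  n <- nrow(m)
  valid <- (m != "-" & m != "N") * 1
  nc <- tcrossprod(valid)
  if (any(nc[upper.tri(nc)] == 0)) return(NULL)
  match_cnt <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T"))
    match_cnt <- match_cnt + tcrossprod((m == b) * 1)
  p <- 1 - match_cnt / nc
  d <- ifelse(p >= 0.75, 10, -0.75 * log(pmax(1 - 4 * p / 3, 1e-12)))
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Jukes-Cantor distance matrix from a codon alignment
#'
#' Pairwise deletion: gap/N columns are dropped per pair. Saturated pairs
#' (p >= 0.75, JC undefined) are given a large finite distance (10
#' substitutions/site) so tree building can proceed.
#'
#' @param aln A \code{codon_alignment}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(aln) {
  d <- .jc_from_matrix(alignment_matrix(aln), aln$taxa)
  if (is.null(d)) stop("no comparable sites for at least one taxon pair")
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Deterministic implementation: ties in the Q-criterion are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member leaf). Negative branch length estimates are
#' clamped to zero with the deficit moved onto the sibling branch, so the
#' path length between the joined pair is preserved.
#'
#' @param d Symmetric distance matrix with zero diagonal and row/col names.
#' @return Unrooted \code{ape} phylo object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have row names")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa for neighbor-joining")

  # cluster state: newick fragment and representative (smallest leaf) label
  nwk <- labels
  rep_lab <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    key2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    dimnames(d) <- NULL
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    n <- n - 1
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(va), nwk[2], fmt(vb), nwk[3], fmt(vc))
  ape::read.tree(text = txt)
}

# Canonical non-trivial splits of an (un)rooted tree: each internal edge's
# leaf bipartition, represented by the side not containing the reference
# (alphabetically first) taxon, as a sorted "|"-joined string.
tree_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(phy)
  all_tips <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- sort(all_tips[cl])
    if (ref %in% side) side <- sort(setdiff(tips, side))
    if (length(side) >= 2 && length(side) <= length(tips) - 2)
      out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Codon-column bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree from JC distances on the full alignment, then
#' resamples codon columns (not nucleotide columns, respecting the codon
#' threading) with replacement \code{n_replicates} times; the support of an
#' internal split is the percentage of replicate NJ trees containing it.
#' Deterministic given \code{seed}.
#'
#' If the alignment carries no variable columns the topology is arbitrary
#' and supports are reported as \code{NA} with
#' \code{zero_information = TRUE} rather than a misleading 100.
#'
#' @param aln A \code{codon_alignment} of 3+ taxa.
#' @param n_replicates Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List of class \code{"bootstrap_tree"}: \code{tree} (phylo, with
#'   supports as internal node labels), \code{supports} (named vector,
#'   split id -> percent), \code{n_replicates}, \code{zero_information}.
#' @export
bootstrap_supports <- function(aln, n_replicates = 100, seed = 1L) {
  stopifnot(n_replicates >= 1)
  M <- alignment_matrix(aln)
  rownames(M) <- aln$taxa
  d <- .jc_from_matrix(M)
  if (is.null(d)) stop("no comparable sites for at least one taxon pair")
  main <- nj_tree(d)
  n_cod <- ncol(M) %/% 3
  zero_info <- all(d == 0)
  splits <- tree_splits(main)
  counts <- setNames(numeric(length(splits)), splits)
  n_ok <- 0
  if (!zero_info) {
    set.seed(seed)
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(n_cod, n_cod, replace = TRUE)
      cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
      rep_d <- .jc_from_matrix(M[, cols, drop = FALSE])
      if (is.null(rep_d)) next
      rep_splits <- tree_splits(nj_tree(rep_d))
      hit <- splits %in% rep_splits
      counts[hit] <- counts[hit] + 1
      n_ok <- n_ok + 1
    }
  }
  supports <- if (zero_info || n_ok == 0)
    setNames(rep(NA_real_, length(splits)), splits)
  else 100 * counts / n_ok
  tree <- .annotate_supports(main, supports)
  structure(list(tree = tree, supports = supports,
                 n_replicates = n_replicates,
                 zero_information = zero_info || n_ok == 0),
            class = "bootstrap_tree")
}

# write split supports onto internal node labels of a phylo object
.annotate_supports <- function(phy, supports) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(phy)
  all_tips <- attr(pp, "labels")
  labs <- character(phy$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(all_tips[pp[[k]]])
    if (ref %in% side) side <- sort(setdiff(tips, side))
    id <- paste(side, collapse = "|")
    if (id %in% names(supports) && !is.na(supports[[id]]))
      labs[k] <- sprintf("%g", round(supports[[id]], 1))
  }
  phy$node.label <- labs
  phy
}

#' Support of the split separating a given taxon set
#'
#' @param bt A \code{"bootstrap_tree"}.
#' @param taxa Leaf labels on one side of the split.
#' @return Support percent, or \code{NA} if the split is absent or
#'   uninformative.
#' @export
split_support <- function(bt, taxa) {
  tips <- sort(bt$tree$tip.label)
  side <- sort(taxa)
  if (tips[1] %in% side) side <- sort(setdiff(tips, side))
  id <- paste(side, collapse = "|")
  if (id %in% names(bt$supports)) bt$supports[[id]] else NA_real_
}
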