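#' Read a dated (ultrametric) species tree
#'
#' The tree must be rooted, carry branch lengths in millions of years, and be
#' ultrametric: every leaf sits at the same depth, within tolerance. Leaf
#' depths are compared with an absolute tolerance of \code{tol} times the
#' tree height (floor 1e-6).
#'
#' @param path Newick file.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#' @return Object of class \code{c("species_tree", "phylo")}.
#' @export
read_species_tree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick in ", path)
  validate_species_tree(phy, tol)
}

#' @rdname read_species_tree
#' @param phy An \code{ape} phylo object.
#' @export
validate_species_tree <- function(phy, tol = 1e-6) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("species tree must have a branch length on every edge")
  if (any(phy$edge.length < 0)) stop("negative branch length in species tree")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  h <- max(depths)
  if (diff(range(depths)) > max(tol * h, 1e-6))
    stop("species tree is not ultrametric: leaf depths range ",
         signif(min(depths), 6), " to ", signif(max(depths), 6))
  class(phy) <- c("species_tree", "phylo")
  phy
}

#' Leaves of a species tree
#' @param tree A \code{species_tree}.
#' @return Character vector of leaf labels.
#' @export
tree_leaves <- function(tree) tree$tip.label

# Leaf set below each node, as a list indexed by node number.
.leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # postorder guarantees children are filled before their parent
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chi <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets, sort)
}

#' Stable branch identifiers
#'
#' Every branch (edge) of the tree is identified by the sorted set of leaf
#' labels below it, joined with \code{"+"}; a terminal branch's id is the
#' species label itself. Ids are stable across tree reorderings.
#'
#' @param tree A \code{species_tree}.
#' @return Character vector of branch ids, one per edge, in edge order.
#' @export
branch_ids <- function(tree) {
  sets <- .leafsets(tree)
  vapply(tree$edge[, 2], function(nd) paste(sets[[nd]], collapse = "+"), "")
}

#' Leaves below a branch id
#' @param tree A \code{species_tree}.
#' @param id A branch id from [branch_ids()].
#' @return Character vector of leaf labels in that branch's subtree.
#' @export
leaves_below_branch <- function(tree, id) {
  ids <- branch_ids(tree)
  if (!id %in% ids) stop("unknown branch id: ", id)
  strsplit(id, "+", fixed = TRUE)[[1]]
}

#' Divergence time between two species
#'
#' Depth (millions of years) of the most recent common ancestor of two
#' leaves on an ultrametric dated tree. Symmetric in its arguments;
#' \code{divergence_time(tree, s, s)} is 0.
#'
#' @param tree A \code{species_tree}.
#' @param a,b Leaf labels.
#' @return Divergence time in millions of years.
#' @export
divergence_time <- function(tree, a, b) {
  tips <- tree$tip.label
  if (!a %in% tips) stop("unknown species: ", a)
  if (!b %in% tips) stop("unknown species: ", b)
  if (a == b) return(0)
  d <- ape::node.depth.edgelength(tree)
  h <- max(d[seq_along(tips)])
  m <- ape::getMRCA(tree, c(a, b))
  h - d[m]
}

#' Restrict a species tree to a subset of leaves
#'
#' Used when a gene family is scored only in some species (e.g. genes in the
#' X/Y-added region do not exist in marsupials): Dollo inference runs on the
#' induced subtree.
#'
#' @param tree A \code{species_tree}.
#' @param species Leaf labels to keep (at least 2).
#' @return The induced \code{species_tree}.
#' @export
restrict_tree <- function(tree, species) {
  unk <- setdiff(species, tree$tip.label)
  if (length(unk)) stop("unknown species: ", paste(unk, collapse = ", "))
  if (length(species) < 2) stop("need at least 2 species to induce a tree")
  validate_species_tree(ape::keep.tip(tree, species))
}

#' Stem branch of the most recent common ancestor of a species set
#'
#' @param tree A \code{species_tree}.
#' @param species Non-empty set of leaf labels.
#' @return Branch id of the edge above the MRCA (for a single species, its
#'   terminal branch).
#' @export
mrca_branch_id <- function(tree, species) {
  if (!length(species)) stop("empty species set")
  unk <- setdiff(species, tree$tip.label)
  if (length(unk)) stop("unknown species: ", paste(unk, collapse = ", "))
  species <- unique(species)
  if (length(species) == 1) return(species)
  m <- ape::getMRCA(tree, species)
  sets <- .leafsets(tree)
  paste(sets[[m]], collapse = "+")
}

#' The packaged dated species tree
#'
#' Thirteen study species with TimeTree-style divergence dates (millions of
#' years); the mouse-rat split (25 mya) and the opossum-wallaby split
#' (88 mya) anchor the retrogene dating bounds.
#'
#' @return A \code{species_tree}.
#' @export
yrescue_tree <- function() {
  path <- system.file("extdata", "species_tree.nwk", package = "yrescue")
  if (!nzchar(path)) stop("packaged species tree not found")
  read_species_tree(path)
}
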