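#' Parse a gene-tree taxon label
#'
#' Family trees label tips as \code{species__class__locus}
#' (class in X/Y/A), the convention produced by [align_codons()] on
#' \code{gene_copy} input.
#'
#' @param label Character vector of tip labels.
#' @return Data frame with columns species, chrom_class, locus_id.
#' @export
parse_taxon <- function(label) {
  parts <- strsplit(label, "__", fixed = TRUE)
  data.frame(species = vapply(parts, `[`, "", 1),
             chrom_class = vapply(parts, function(p)
               if (length(p) >= 2) p[2] else NA_character_, ""),
             locus_id = vapply(parts, function(p)
               if (length(p) >= 3) p[3] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' Classify the parental origin of autosomal copies
#'
#' On the family tree rooted with the declared outgroup, the verdict is
#' \code{"Y"} when the focal autosomal tip (or clade of tips) has a sister
#' group consisting only of Y-linked copies, with bootstrap support at or
#' above \code{bootstrap_support_min}; symmetrically for \code{"X"}.
#' Anything else — mixed sister group, non-monophyletic focal set, or
#' insufficient support — is \code{"unresolved"}.
#'
#' @param bt A \code{"bootstrap_tree"} from [bootstrap_supports()] whose tip
#'   labels follow the \code{species__class__locus} convention.
#' @param family Gene-family identifier (reported in the call).
#' @param outgroup_taxa Tip labels to root on; must be present.
#' @param target_taxa Focal autosomal tip labels; default: all A-class tips.
#' @param config An [analysis_config()].
#' @return List of class \code{"origin_call"}: \code{family}, \code{taxa},
#'   \code{verdict}, \code{support}, \code{sister_taxa}.
#' @export
classify_origin <- function(bt, family, outgroup_taxa, target_taxa = NULL,
                            config = analysis_config()) {
  phy <- bt$tree
  tips <- phy$tip.label
  missing_og <- setdiff(outgroup_taxa, tips)
  if (length(missing_og))
    stop("outgroup taxa absent from tree: ",
         paste(missing_og, collapse = ", "))
  info <- parse_taxon(tips)
  if (is.null(target_taxa))
    target_taxa <- tips[info$chrom_class == "A" & !(tips %in% outgroup_taxa)]
  if (!length(target_taxa)) stop("no autosomal target taxa in tree")
  if (!any(info$chrom_class == "X")) stop("tree contains no X-linked copy")

  unresolved <- function(sister = character(0), support = NA_real_)
    structure(list(family = family, taxa = target_taxa,
                   verdict = "unresolved", support = support,
                   sister_taxa = sister),
              class = "origin_call")

  rooted <- tryCatch(
    ape::root(phy, outgroup = outgroup_taxa, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    warning("could not root on declared outgroup; origin unresolved")
    return(unresolved())
  }
  if (!ape::is.monophyletic(rooted, target_taxa))
    return(unresolved())
  target_node <- if (length(target_taxa) == 1)
    which(rooted$tip.label == target_taxa)
  else ape::getMRCA(rooted, target_taxa)
  root_node <- length(rooted$tip.label) + 1
  if (target_node == root_node) return(unresolved())
  parent <- rooted$edge[rooted$edge[, 2] == target_node, 1]
  parent_tips <- ape::extract.clade(rooted, parent)$tip.label
  sister <- setdiff(parent_tips, target_taxa)
  if (!length(sister)) return(unresolved())
  sister_class <- unique(parse_taxon(sister)$chrom_class)
  # Support for the claim "the focal copy descends from this gametolog":
  # prefer the split placing the focal clade inside the full clade of the
  # sister's class (the gametolog-clade membership split), falling back to
  # the focal-plus-sister split and then the focal clade split when the
  # larger splits are trivial or absent from the tree.
  support <- NA_real_
  if (length(sister_class) == 1 && sister_class %in% c("X", "Y")) {
    class_tips <- tips[info$chrom_class == sister_class]
    support <- split_support(bt, union(target_taxa, class_tips))
  }
  if (is.na(support)) support <- split_support(bt, parent_tips)
  if (is.na(support)) support <- split_support(bt, target_taxa)
  verdict <- if (length(sister_class) == 1 && sister_class %in% c("X", "Y") &&
                 !is.na(support) && support >= config$bootstrap_support_min)
    sister_class
  else "unresolved"
  structure(list(family = family, taxa = target_taxa, verdict = verdict,
                 support = support, sister_taxa = sister),
            class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> %s: %s (support %s) sister={%s}\n",
              x$family, x$verdict,
              ifelse(is.na(x$support), "NA", sprintf("%.1f", x$support)),
              paste(x$sister_taxa, collapse = ",")))
  invisible(x)
}
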