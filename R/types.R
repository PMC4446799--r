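#' Construct a gene copy record
#'
#' A gene copy is one homolog of a gene family in one species: the X-linked
#' or Y-linked gametolog, or an autosomal copy (ancestral, retrotransposed,
#' or DNA-transposed).
#'
#' @param family Gene-family identifier (e.g. \code{"EIF1A"}).
#' @param species Species label; must match a leaf of the species tree in use.
#' @param chrom_class One of \code{"X"}, \code{"Y"}, \code{"A"}.
#' @param locus_id Genomic-locus identifier, unique within (family, species).
#' @param cds Coding sequence over \code{A,C,G,T,N}, or \code{NA} when only
#'   presence/absence is known.
#' @param has_introns Logical; retrocopies are intronless by construction.
#' @param mechanism_hint One of \code{"retro"}, \code{"dna"},
#'   \code{"ancestral"}, \code{"unknown"}. Only autosomal copies may be
#'   \code{"retro"} or \code{"dna"}.
#' @return An object of class \code{"gene_copy"} (a named list).
#' @export
gene_copy <- function(family, species, chrom_class, locus_id,
                      cds = NA_character_, has_introns = NA,
                      mechanism_hint = "unknown") {
  chrom_class <- match.arg(chrom_class, c("X", "Y", "A"))
  mechanism_hint <- match.arg(mechanism_hint,
                              c("retro", "dna", "ancestral", "unknown"))
  if (mechanism_hint %in% c("retro", "dna") && chrom_class != "A")
    stop("mechanism_hint '", mechanism_hint,
         "' requires chrom_class 'A' (", family, "/", species, ")")
  if (!is.na(cds)) {
    cds <- normalize_dna(cds)
    if (nchar(cds) < 3)
      stop("cds shorter than one codon for ", family, "/", species)
  }
  structure(list(family = family, species = species,
                 chrom_class = chrom_class, locus_id = locus_id,
                 cds = cds, has_introns = has_introns,
                 mechanism_hint = mechanism_hint),
            class = "gene_copy")
}

#' @export
print.gene_copy <- function(x, ...) {
  cat(sprintf("<gene_copy> %s %s [%s] locus=%s cds=%s\n",
              x$family, x$species, x$chrom_class, x$locus_id,
              if (is.na(x$cds)) "absent" else paste0(nchar(x$cds), " nt")))
  invisible(x)
}

# Uppercase, RNA U -> T, validate alphabet. Used by every sequence entry point.
normalize_dna <- function(x) {
  x <- chartr("u", "T", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- gsub("[ACGTN-]", "", x)
  if (any(nzchar(bad)))
    stop("sequence contains characters outside {A,C,G,T,N,-}: '",
         substr(bad[nzchar(bad)][1], 1, 10), "'")
  x
}

#' Validate a homolog table
#'
#' A homolog table is a data frame with one row per gene copy, columns
#' \code{family}, \code{species}, \code{chrom_class}, \code{locus_id},
#' \code{has_introns}, and optionally \code{mechanism_hint} and \code{cds}.
#' The study design restricts attention to genes that are single copy on the
#' Y chromosome, so at most one Y row per (family, species) is allowed, and
#' (family, species, locus_id) must be unique.
#'
#' @param tab Data frame of gene copies.
#' @param tree Optional \code{species_tree}; if given, all species must be
#'   among its leaves.
#' @return The table, invisibly, with \code{mechanism_hint} filled in.
#' @export
validate_homolog_table <- function(tab, tree = NULL) {
  need <- c("family", "species", "chrom_class", "locus_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("homolog table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$chrom_class %in% c("X", "Y", "A")))
    stop("chrom_class must be X, Y or A")
  if (is.null(tab$mechanism_hint)) tab$mechanism_hint <- "unknown"
  if (is.null(tab$has_introns)) tab$has_introns <- NA
  bad_mech <- tab$mechanism_hint %in% c("retro", "dna") & tab$chrom_class != "A"
  if (any(bad_mech))
    stop("retro/dna mechanism on non-autosomal copy: ",
         paste(tab$family[bad_mech], tab$species[bad_mech], collapse = "; "))
  ykey <- with(tab[tab$chrom_class == "Y", , drop = FALSE],
               paste(family, species))
  if (anyDuplicated(ykey))
    stop("more than one Y copy per (family, species): ",
         ykey[duplicated(ykey)][1])
  key <- with(tab, paste(family, species, locus_id))
  if (anyDuplicated(key))
    stop("duplicate (family, species, locus_id): ", key[duplicated(key)][1])
  if (!is.null(tree)) {
    unk <- setdiff(unique(tab$species), tree_leaves(tree))
    if (length(unk)) stop("species not in tree: ", paste(unk, collapse = ", "))
  }
  invisible(tab)
}

#' Presence/absence view of a homolog table
#'
#' @param tab Validated homolog table.
#' @param family Gene family.
#' @param species Species label (vectorised).
#' @param chrom_class Chromosome class to query.
#' @return Logical vector: is a copy of that class present?
#' @export
has_copy <- function(tab, family, species, chrom_class) {
  sub <- tab[tab$family == family & tab$chrom_class == chrom_class, ]
  species %in% sub$species
}
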