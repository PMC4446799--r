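# longest common subsequence length of two symbol vectors
.lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) return(0L)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m))
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(cur[j], prev[j + 1])
    prev <- cur
  }
  prev[m + 1]
}

#' Are two transposed loci syntenic?
#'
#' Two loci (in different species) are syntenic — i.e. descend from a single
#' insertion event — when they share at least
#' \code{synteny_min_shared_flanks} flanking ortholog symbols in a
#' consistent relative order. Order consistency is measured by the longest
#' common subsequence of the ordered flank lists (upstream then downstream);
#' a locus pair whose shared flanks only agree after reversal (an inversion)
#' needs one extra shared symbol.
#'
#' @param a,b Synteny records: lists/rows with \code{species},
#'   \code{locus_id}, \code{flanks_up}, \code{flanks_down} (character
#'   vectors of ortholog symbols, ordered along the chromosome).
#' @param config An [analysis_config()].
#' @return Logical; symmetric in \code{a}, \code{b}.
#' @export
is_syntenic <- function(a, b, config = analysis_config()) {
  fa <- c(unlist(a$flanks_up), unlist(a$flanks_down))
  fb <- c(unlist(b$flanks_up), unlist(b$flanks_down))
  shared <- intersect(fa, fb)
  if (!length(shared)) return(FALSE)
  fa_s <- fa[fa %in% shared]
  fb_s <- fb[fb %in% shared]
  k <- config$synteny_min_shared_flanks
  if (.lcs_length(fa_s, fb_s) >= k) return(TRUE)
  .lcs_length(fa_s, rev(fb_s)) >= k + 1
}

#' Group loci by shared origin
#'
#' Partition of one family's (species, locus_id) records into shared-origin
#' groups: the transitive closure of pairwise synteny across species. Each
#' group is one candidate origination event.
#'
#' @param records Synteny data frame (one family; see
#'   [read_synteny_table()]).
#' @param config An [analysis_config()].
#' @return List of data frames (the groups), ordered by their smallest
#'   (species, locus_id) key; attribute \code{"membership"} maps record
#'   index to group.
#' @export
locus_groups <- function(records, config = analysis_config()) {
  n <- nrow(records)
  if (!n) return(list())
  if (length(unique(records$family)) > 1)
    stop("locus_groups expects records from a single family")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (records$species[i] == records$species[j]) next
    if (is_syntenic(records[i, ], records[j, ], config)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), comp)
  keys <- vapply(groups, function(ix)
    min(paste(records$species[ix], records$locus_id[ix])), "")
  groups <- groups[order(keys)]
  out <- lapply(groups, function(ix) records[ix, , drop = FALSE])
  membership <- integer(n)
  for (g in seq_along(out)) membership[groups[[g]]] <- g
  attr(out, "membership") <- membership
  out
}

#' Minimum origination age of a locus group
#'
#' A shared insertion must predate the divergence of any two carrier
#' species, so the maximum pairwise divergence time among the group's
#' species is a lower bound (in millions of years) on the event's age. A
#' singleton group gives no bound (0).
#'
#' @param group Character vector of carrier species, or a group data frame
#'   from [locus_groups()].
#' @param tree A \code{species_tree}.
#' @return Age lower bound in millions of years.
#' @export
min_origin_age <- function(group, tree) {
  species <- if (is.data.frame(group)) unique(group$species)
             else unique(group)
  if (!length(species)) stop("empty locus group")
  if (length(species) == 1) return(0)
  cmb <- utils::combn(species, 2)
  max(apply(cmb, 2, function(p) divergence_time(tree, p[1], p[2])))
}
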