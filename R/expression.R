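#' Paralog-aware assignment of reads to homologs
#'
#' Each read is compared to every homolog of the family by its best
#' ungapped alignment (all offsets, both strands, mismatch count). The read
#' is assigned to the homolog with the fewest mismatches if that minimum is
#' at most \code{mismatch_tolerance} and strictly smaller than against every
#' other homolog; reads tying across homologs are discarded as ambiguous
#' (they carry no paralog-distinguishing information), and reads beating the
#' tolerance nowhere are unassigned.
#'
#' @param reads Read-set data frame (columns id, seq, tissue, species).
#' @param homologs List of \code{gene_copy} objects from one family and
#'   species, each with a CDS.
#' @param mismatch_tolerance Maximum mismatches for assignment (default 2).
#' @return List of class \code{"read_assignment"}: \code{counts} (matrix,
#'   homolog x tissue), \code{ambiguous}, \code{unassigned} (named
#'   per-tissue vectors), \code{assignments} (per-read data frame with
#'   columns id, tissue, assigned_to, best_mm).
#' @export
assign_reads <- function(reads, homologs, mismatch_tolerance = 2) {
  if (!length(homologs)) stop("empty homolog list")
  labs <- vapply(homologs, function(h)
    paste(h$species, h$chrom_class, h$locus_id, sep = "__"), "")
  if (anyDuplicated(labs)) stop("duplicate homolog labels")
  tissues <- sort(unique(reads$tissue))
  counts <- matrix(0L, length(labs), length(tissues),
                   dimnames = list(labs, tissues))
  ambiguous <- setNames(integer(length(tissues)), tissues)
  unassigned <- setNames(integer(length(tissues)), tissues)
  # minimum mismatches of every read against every homolog (seed-and-verify;
  # exact for all values <= tolerance, see expression_assign.R); reads are
  # batched by length, reads with ambiguity codes fall back to a direct scan
  n_r <- nrow(reads)
  mm_mat <- matrix(Inf, n_r, length(labs))
  clean <- !grepl("[^ACGT]", reads$seq)
  for (L in unique(nchar(reads$seq[clean]))) {
    ix <- which(clean & nchar(reads$seq) == L)
    idx <- .read_seed_index(reads$seq[ix], mismatch_tolerance)
    for (h in seq_along(homologs))
      mm_mat[ix, h] <- .min_mm_homolog(idx, homologs[[h]]$cds)
  }
  for (r in which(!clean)) {
    rd <- Biostrings::DNAString(reads$seq[r])
    for (h in seq_along(homologs)) {
      s <- Biostrings::DNAString(homologs[[h]]$cds)
      if (length(rd) > length(s)) next
      at <- seq_len(length(s) - length(rd) + 1)
      mm_mat[r, h] <- min(
        Biostrings::neditStartingAt(rd, s, starting.at = at,
                                    with.indels = FALSE),
        Biostrings::neditStartingAt(rd, Biostrings::reverseComplement(s),
                                    starting.at = at, with.indels = FALSE))
    }
  }
  assigned_to <- character(n_r)
  best_mm <- numeric(n_r)
  for (r in seq_len(n_r)) {
    mm <- mm_mat[r, ]
    o <- order(mm)
    m1 <- mm[o[1]]
    ti <- reads$tissue[r]
    if (m1 > mismatch_tolerance) {
      assigned_to[r] <- "unassigned"
      unassigned[ti] <- unassigned[ti] + 1L
    } else if (length(mm) > 1 && mm[o[2]] <= m1) {
      assigned_to[r] <- "ambiguous"
      ambiguous[ti] <- ambiguous[ti] + 1L
    } else {
      assigned_to[r] <- labs[o[1]]
      counts[o[1], ti] <- counts[o[1], ti] + 1L
    }
    best_mm[r] <- m1
  }
  structure(list(counts = counts, ambiguous = ambiguous,
                 unassigned = unassigned,
                 assignments = data.frame(id = reads$id,
                                          tissue = reads$tissue,
                                          assigned_to = assigned_to,
                                          best_mm = best_mm,
                                          stringsAsFactors = FALSE)),
            class = "read_assignment")
}

#' Length-normalised autosomal:X expression ratio
#'
#' \code{(countsA / lenA) / (countsX / lenX)}; counts are assigned reads,
#' lengths are CDS lengths (any consistent unit). When the X-linked copy has
#' zero assigned reads the ratio is undefined and \code{NA} is returned
#' with attribute \code{undefined = TRUE}.
#'
#' @param countsA,countsX Assigned read counts (non-negative).
#' @param lenA,lenX CDS lengths (> 0).
#' @return Dimensionless ratio.
#' @export
expression_ratio <- function(countsA, lenA, countsX, lenX) {
  if (countsA < 0 || countsX < 0) stop("negative read counts")
  if (lenA <= 0 || lenX <= 0) stop("lengths must be positive")
  if (countsX == 0)
    return(structure(NA_real_, undefined = TRUE))
  (countsA / lenA) / (countsX / lenX)
}

#' Build an expression profile for one gene copy
#'
#' @param copy_label Homolog label (row of the assignment count matrix).
#' @param assignment A \code{"read_assignment"}.
#' @param cds_length CDS length in nucleotides.
#' @param x_label Optional label of the X-linked homolog for per-tissue
#'   A:X ratios.
#' @param x_length CDS length of the X-linked homolog.
#' @return List of class \code{"expression_profile"}: \code{counts},
#'   \code{normalized} (reads per kb of CDS), \code{ratio_vs_X} per tissue.
#' @export
expression_profile <- function(copy_label, assignment, cds_length,
                               x_label = NULL, x_length = NULL) {
  cnt <- assignment$counts[copy_label, ]
  norm <- cnt / (cds_length / 1000)
  ratio <- rep(NA_real_, length(cnt))
  names(ratio) <- names(cnt)
  if (!is.null(x_label)) {
    xc <- assignment$counts[x_label, ]
    for (t in names(cnt))
      ratio[t] <- expression_ratio(cnt[t], cds_length, xc[t], x_length)
  }
  structure(list(copy = copy_label, counts = cnt, normalized = norm,
                 ratio_vs_X = ratio),
            class = "expression_profile")
}

#' Transcriptional-activity criterion
#'
#' The second functionality criterion: a copy counts as transcribed when at
#' least \code{min_reads_expressed} reads are assigned to it in at least one
#' tissue. Copies expressed at barely detectable levels fail this.
#'
#' @param profile An \code{"expression_profile"}.
#' @param config An [analysis_config()].
#' @return Logical.
#' @export
has_transcription_evidence <- function(profile, config = analysis_config()) {
  any(profile$counts >= config$min_reads_expressed)
}

#' Classify an expression pattern and its breadth
#'
#' Breadth is the number of tissues in which the copy is expressed (assigned
#' reads at or above \code{min_reads_expressed}). The pattern is
#' \code{"silent"} at breadth 0; \code{"testis_specific"} when the copy is
#' expressed in testis and its length-normalised testis level is at least
#' \code{testis_fold_min} times the highest non-testis level; otherwise
#' \code{"broad"}.
#'
#' @param profile An \code{"expression_profile"}.
#' @param tissue_panel Tissue labels; must include \code{"testis"}.
#' @param config An [analysis_config()].
#' @return List: \code{pattern}, \code{breadth}.
#' @export
classify_pattern <- function(profile, tissue_panel = names(profile$counts),
                             config = analysis_config()) {
  if (!"testis" %in% tissue_panel)
    stop("tissue panel must include 'testis'")
  cnt <- profile$counts[tissue_panel]
  norm <- profile$normalized[tissue_panel]
  expressed <- cnt >= config$min_reads_expressed
  breadth <- sum(expressed)
  non_testis <- setdiff(tissue_panel, "testis")
  max_other <- if (length(non_testis)) max(norm[non_testis]) else 0
  pattern <- if (breadth == 0) "silent"
  else if (expressed[["testis"]] &&
           norm[["testis"]] >= config$testis_fold_min * max(max_other, 1e-12))
    "testis_specific"
  else "broad"
  list(pattern = pattern, breadth = as.integer(breadth))
}
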