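#' Protein-guided codon alignment of a gene family
#'
#' Sequences are translated (terminal stops stripped; a disrupted copy is
#' translated up to its first stop), the proteins are aligned progressively
#' — Needleman-Wunsch global pairwise alignments (BLOSUM62, affine gaps)
#' against a centre sequence chosen by total percent identity, merged on the
#' centre's coordinates — and the protein alignment is back-threaded onto
#' the codons. Gap runs in the result are therefore always a multiple of 3.
#'
#' @param copies Named character vector of CDS, or list of
#'   \code{gene_copy} objects (names/labels become alignment taxa).
#' @param gap_opening,gap_extension Affine gap penalties for the protein
#'   alignment (defaults 10 and 0.5).
#' @return Object of class \code{"codon_alignment"}: list with \code{taxa},
#'   \code{rows} (named character, equal lengths, gaps as \code{-}),
#'   \code{codon_threaded = TRUE}.
#' @export
align_codons <- function(copies, gap_opening = 10, gap_extension = 0.5) {
  if (is.list(copies) && all(vapply(copies, inherits, TRUE, "gene_copy"))) {
    nm <- vapply(copies, function(g)
      paste(g$species, g$chrom_class, g$locus_id, sep = "__"), "")
    copies <- setNames(vapply(copies, `[[`, "", "cds"), nm)
  }
  if (is.null(names(copies)) || any(!nzchar(names(copies))))
    stop("sequences must be named")
  if (length(copies) < 2) stop("need at least 2 sequences to align")
  copies <- vapply(copies, normalize_dna, "")

  # translate to first stop; drop untranslatable entries
  prot <- character(0); cod <- list()
  for (nm in names(copies)) {
    aa <- translate_codons(copies[[nm]])
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1)]
    if (!length(aa)) {
      warning("untranslatable sequence excluded: ", nm)
      next
    }
    prot[nm] <- paste(aa, collapse = "")
    n <- length(aa)
    cod[[nm]] <- substring(copies[[nm]], 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  if (length(prot) < 2) stop("fewer than 2 translatable sequences")

  taxa <- names(prot)
  if (length(unique(prot)) == 1) {
    rows <- vapply(taxa, function(nm) paste(cod[[nm]], collapse = ""), "")
    return(structure(list(taxa = taxa, rows = rows, codon_threaded = TRUE),
                     class = "codon_alignment"))
  }

  aas <- Biostrings::AAStringSet(prot)
  pid <- matrix(100, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  # percent identity guides centre selection; when all proteins have equal
  # length an ungapped comparison suffices (and is much cheaper than n^2
  # alignments), otherwise align each pair
  protu <- lapply(prot, utf8ToInt)
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i >= j) next
    pid[i, j] <- pid[j, i] <-
      if (length(protu[[i]]) == length(protu[[j]]))
        100 * mean(protu[[i]] == protu[[j]])
      else Biostrings::pid(Biostrings::pairwiseAlignment(
        aas[[i]], aas[[j]], type = "global",
        substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension))
  }
  centre <- taxa[which.max(rowSums(pid))]
  others <- setdiff(taxa, centre)
  # guide order: most similar to the centre first (determinism: name ties
  # broken by input order)
  others <- others[order(-pid[centre, others])]

  L <- nchar(prot[[centre]])
  pair <- lapply(others, function(o) {
    al <- Biostrings::pairwiseAlignment(
      aas[[centre]], aas[[o]], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension)
    list(c = as.character(Biostrings::alignedPattern(al)),
         s = as.character(Biostrings::alignedSubject(al)))
  })
  names(pair) <- others

  # insertions relative to the centre, after centre position p (0..L)
  ins_counts <- function(caln) {
    cv <- strsplit(caln, "")[[1]]
    ins <- integer(L + 1); p <- 0
    for (ch in cv) {
      if (ch == "-") ins[p + 1] <- ins[p + 1] + 1L else p <- p + 1
    }
    ins
  }
  ins_by_seq <- lapply(pair, function(x) ins_counts(x$c))
  ins <- Reduce(pmax, ins_by_seq, integer(L + 1))

  # protein-level merged rows
  merged <- list()
  merged[[centre]] <- unlist(lapply(0:L, function(p) {
    c(rep("-", ins[p + 1]),
      if (p < L) substr(prot[[centre]], p + 1, p + 1) else character(0))
  }))
  for (o in others) {
    cv <- strsplit(pair[[o]]$c, "")[[1]]
    sv <- strsplit(pair[[o]]$s, "")[[1]]
    out <- character(0); p <- 0; buf <- character(0)
    flush <- function(buf, p) c(buf, rep("-", ins[p + 1] - length(buf)))
    for (k in seq_along(cv)) {
      if (cv[k] == "-") buf <- c(buf, sv[k])
      else {
        out <- c(out, flush(buf, p), sv[k]); buf <- character(0); p <- p + 1
      }
    }
    out <- c(out, flush(buf, p))
    merged[[o]] <- out
  }

  # back-thread each protein row onto its codons
  rows <- vapply(taxa, function(nm) {
    rr <- merged[[nm]]; codons <- cod[[nm]]; ci <- 0
    paste(vapply(rr, function(ch) {
      if (ch == "-") "---" else { ci <<- ci + 1; codons[ci] }
    }, ""), collapse = "")
  }, "")

  if (length(unique(nchar(rows))) != 1)
    stop("internal error: merged rows have unequal lengths")
  structure(list(taxa = taxa, rows = rows, codon_threaded = TRUE),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d nt (%d codon columns)\n",
              length(x$taxa), nchar(x$rows[[1]]), nchar(x$rows[[1]]) %/% 3))
  invisible(x)
}

#' Character matrix view of a codon alignment
#' @param aln A \code{codon_alignment}.
#' @return Character matrix, rows = taxa, columns = nucleotide positions.
#' @export
alignment_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, function(r) strsplit(r, "")[[1]]))
}

#' Subset a codon alignment by codon-column indices
#'
#' Used by the codon-column bootstrap; indices may repeat.
#' @param aln A \code{codon_alignment}.
#' @param idx Codon-column indices (1-based).
#' @return A new \code{codon_alignment}.
#' @export
subset_codon_columns <- function(aln, idx) {
  nt_idx <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  m <- alignment_matrix(aln)[, nt_idx, drop = FALSE]
  rows <- setNames(apply(m, 1, paste, collapse = ""), aln$taxa)
  structure(list(taxa = aln$taxa, rows = rows, codon_threaded = TRUE),
            class = "codon_alignment")
}
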