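#' Translate a CDS codon-wise
#'
#' Standard genetic code, frame 0. Codons containing \code{N} translate to
#' \code{"X"} (unknown) and are never treated as stops; a trailing partial
#' codon is dropped.
#'
#' @param cds Nucleotide string over \code{A,C,G,T,N}.
#' @return Character vector of one-letter amino acids (\code{"*"} = stop).
#' @export
translate_codons <- function(cds) {
  cds <- normalize_dna(cds)
  n <- nchar(cds) %/% 3
  if (n == 0) return(character(0))
  cod <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"
  aa
}

#' Scan an open reading frame
#'
#' @param cds CDS over \code{A,C,G,T,N}; at least one codon.
#' @return List: \code{has_start} (first codon is ATG), \code{stop_index}
#'   (0-based codon index of the first premature stop, or \code{NA}; a stop
#'   in the final codon position is terminal, not premature),
#'   \code{orf_length_codons} (coding codons before the first stop,
#'   excluding any terminal stop), \code{frame_ok} (length divisible by 3).
#' @export
scan_orf <- function(cds) {
  cds <- normalize_dna(cds)
  if (nchar(cds) < 3) stop("cds shorter than one codon")
  aa <- translate_codons(cds)
  n <- length(aa)
  stops <- which(aa == "*")
  frame_ok <- nchar(cds) %% 3 == 0
  # a stop in the last codon slot of an in-frame CDS is terminal
  terminal <- frame_ok && any(stops == n)
  premature <- stops[!(stops == n & frame_ok)]
  first_stop <- if (length(premature)) premature[1] - 1L else NA_integer_
  orf_len <- if (length(premature)) premature[1] - 1L
             else n - as.integer(terminal)
  list(has_start = aa[1] == "M",
       stop_index = first_stop,
       orf_length_codons = as.integer(orf_len),
       frame_ok = frame_ok)
}

#' Assess ORF integrity of a candidate against its sex-linked counterpart
#'
#' First functionality criterion: a transposed copy must keep an intact open
#' reading frame relative to the X- or Y-linked parent. A copy is
#' \emph{intact} if it has no premature stop, its length is a multiple of 3,
#' and its ORF is at least \code{orf_length_ratio_min} times the reference
#' ORF; \emph{truncated} if it is clean but falls below that length ratio
#' (how "slightly truncated" pseudogenes are caught); \emph{disrupted}
#' otherwise (premature stop or broken frame).
#'
#' @param candidate,reference \code{gene_copy} objects (or bare CDS strings);
#'   the reference is the sex-linked counterpart.
#' @param config An [analysis_config()].
#' @return List of class \code{"orf_report"}: fields of [scan_orf()] for the
#'   candidate plus \code{length_ratio} and \code{status} (one of
#'   \code{"intact"}, \code{"truncated"}, \code{"disrupted"}).
#' @export
assess_integrity <- function(candidate, reference,
                             config = analysis_config()) {
  cand_cds <- if (inherits(candidate, "gene_copy")) candidate$cds else candidate
  ref_cds <- if (inherits(reference, "gene_copy")) reference$cds else reference
  cand <- scan_orf(cand_cds)
  ref <- scan_orf(ref_cds)
  if (!is.na(ref$stop_index) || !ref$frame_ok)
    warning("reference ORF is itself disrupted; comparison performed anyway")
  ratio <- cand$orf_length_codons / max(ref$orf_length_codons, 1L)
  status <- if (!is.na(cand$stop_index) || !cand$frame_ok) "disrupted"
            else if (ratio >= config$orf_length_ratio_min) "intact"
            else "truncated"
  structure(c(cand, list(length_ratio = ratio, status = status)),
            class = "orf_report")
}
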