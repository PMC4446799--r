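#' Read a FASTA file
#'
#' Identifiers (full header lines after \code{>}) are preserved verbatim;
#' sequences are uppercased and RNA \code{U} is converted to \code{T}.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are identifiers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    stop("FASTA parse error at line 1: sequence line before any header")
  rec <- cumsum(is_hdr)
  ids <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(x, collapse = ""), "")
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  empty <- !nzchar(out)
  if (any(empty)) stop("FASTA record with no sequence: ", ids[empty][1])
  setNames(vapply(out, normalize_dna, ""), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a read set to FASTQ (Phred+33)
#'
#' The read set is a data frame with columns \code{id}, \code{seq},
#' \code{tissue}, \code{species} (plus optional truth columns). Tissue and
#' species are carried in the header as \code{id|species|tissue} so the file
#' round-trips; qualities are constant because the assigner ignores them.
#'
#' @param reads Read-set data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  hdr <- paste0("@", reads$id, "|", reads$species, "|", reads$tissue)
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  writeLines(rbind(hdr, reads$seq, "+", qual), path)
  invisible(path)
}

#' Read a FASTQ file written by [write_fastq()]
#'
#' @param path FASTQ path.
#' @return Read-set data frame with columns id, seq, tissue, species.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  hdr <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  parts <- strsplit(hdr, "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("FASTQ headers must be id|species|tissue")
  data.frame(id = vapply(parts, `[`, "", 1),
             seq = vapply(lines[seq(2, length(lines), by = 4)],
                          normalize_dna, "", USE.NAMES = FALSE),
             tissue = vapply(parts, `[`, "", 3),
             species = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Read / write the homolog table (TSV)
#'
#' Columns: family, species, chrom_class, locus_id, has_introns, and
#' optionally mechanism_hint.
#'
#' @param path TSV path.
#' @param tree Optional species tree for validation.
#' @return Validated homolog data frame.
#' @export
read_homolog_table <- function(path, tree = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- as.data.frame(tab)
  validate_homolog_table(tab, tree)
  tab
}

#' @rdname read_homolog_table
#' @param tab Homolog data frame.
#' @export
write_homolog_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a synteny table (TSV)
#'
#' Columns: family, species, locus_id, flanks_up, flanks_down; the flank
#' columns are comma-separated ordered ortholog symbols (upstream list runs
#' toward the locus, downstream list away from it).
#'
#' @param path TSV path.
#' @return Data frame with list-columns \code{flanks_up}, \code{flanks_down}.
#' @export
read_synteny_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$flanks_up <- strsplit(tab$flanks_up, ",", fixed = TRUE)
  tab$flanks_down <- strsplit(tab$flanks_down, ",", fixed = TRUE)
  if (any(lengths(tab$flanks_up) == 0) || any(lengths(tab$flanks_down) == 0))
    stop("every locus needs at least one flanking gene on each side")
  tab
}

#' @rdname read_synteny_table
#' @param tab Synteny data frame (list-columns allowed).
#' @export
write_synteny_table <- function(tab, path) {
  out <- tab
  out$flanks_up <- vapply(tab$flanks_up, paste, "", collapse = ",")
  out$flanks_down <- vapply(tab$flanks_down, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an evidence table (TSV)
#'
#' Per-copy functional evidence feeding the rescue caller: columns family,
#' species, locus_id, orf_status (intact/truncated/disrupted/unknown),
#' transcribed (logical), p_parent (uncorrected nucleotide divergence to the
#' parental copy), omega (dN/dS, NA when undefined), origin (X/Y/unresolved),
#' pattern (broad/testis_specific/silent/unknown).
#'
#' @param path TSV path.
#' @return Evidence data frame.
#' @export
read_evidence_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("family", "species", "locus_id", "orf_status", "transcribed",
            "p_parent")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("evidence table missing columns: ",
                         paste(miss, collapse = ", "))
  tab$transcribed <- as.logical(tab$transcribed)
  tab
}
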