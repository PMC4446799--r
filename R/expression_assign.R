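# Internals of the paralog-aware read assigner.
#
# Exact semantics: for each read and homolog, the best ungapped alignment
# over all offsets and both strands, by mismatch count. Implemented as
# seed-and-verify: a read within `tol` mismatches of some placement must
# contain at least one error-free seed among tol+1 non-overlapping seeds
# (pigeonhole), so exact seed hits (PDict) enumerate every placement with
# <= tol mismatches and only those candidates are verified by Hamming
# distance. Placements worse than tol are never needed: such reads are
# unassigned, and ties at values <= tol are always discovered on both
# homologs.

.hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# one seed dictionary per read batch, reused against every homolog/strand
.read_seed_index <- function(seqs, tol) {
  L <- nchar(seqs[1])
  slen <- max(L %/% (tol + 1), 1)
  seed_starts <- (seq_len(tol + 1) - 1) * slen + 1
  seeds <- unlist(lapply(seed_starts, function(s)
    substr(seqs, s, s + slen - 1)))
  list(seqs = seqs, L = L,
       seed_read = rep(seq_along(seqs), times = tol + 1),
       seed_off = rep(seed_starts, each = length(seqs)),
       pdict = Biostrings::PDict(Biostrings::DNAStringSet(seeds)))
}

# minimum mismatches of each indexed read against one subject string
.min_mm_batch <- function(idx, subject_str) {
  best <- rep(Inf, length(idx$seqs))
  subj_len <- nchar(subject_str)
  if (idx$L > subj_len) return(best)
  hits <- Biostrings::matchPDict(idx$pdict, Biostrings::DNAString(subject_str))
  starts <- Biostrings::startIndex(hits)
  cand_read <- integer(0); cand_start <- integer(0)
  for (k in which(lengths(starts) > 0)) {
    st <- starts[[k]] - idx$seed_off[k] + 1L
    st <- st[st >= 1 & st <= subj_len - idx$L + 1]
    if (length(st)) {
      cand_read <- c(cand_read, rep(idx$seed_read[k], length(st)))
      cand_start <- c(cand_start, st)
    }
  }
  if (!length(cand_read)) return(best)
  keep <- !duplicated(paste(cand_read, cand_start))
  cand_read <- cand_read[keep]; cand_start <- cand_start[keep]
  windows <- substring(subject_str, cand_start, cand_start + idx$L - 1)
  mm <- vapply(seq_along(cand_read), function(i)
    .hamming(idx$seqs[cand_read[i]], windows[i]), 0)
  for (i in seq_along(cand_read))
    if (mm[i] < best[cand_read[i]]) best[cand_read[i]] <- mm[i]
  best
}

# minimum mismatches of every indexed read against one homolog, both strands
.min_mm_homolog <- function(idx, cds) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  pmin(.min_mm_batch(idx, cds), .min_mm_batch(idx, rc))
}
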