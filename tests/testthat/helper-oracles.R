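# Independent oracles used by the property tests. These deliberately use
# different algorithms from the package implementation.

GC <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GC)[GC != "*"]

# --- NG86 oracle: recursive DFS over single-base mutation paths -----------

# synonymous-site fraction of one codon, counted mutation by mutation
oracle_syn_sites <- function(codon) {
  stopifnot(GC[codon] != "*")
  bases <- c("A", "C", "G", "T")
  tot <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      m <- codon
      substr(m, pos, pos) <- b
      if (GC[m] == "*") next
      valid <- valid + 1
      if (GC[m] == GC[codon]) syn <- syn + 1
    }
    if (valid > 0) tot <- tot + syn / valid
  }
  tot
}

# average syn/nonsyn differences over all stop-free mutation paths a -> b,
# by depth-first search (not permutation enumeration)
oracle_path_counts <- function(a, b) {
  if (a == b) return(c(sd = 0, nd = 0))
  acc <- list(sd = 0, nd = 0, n = 0)
  dfs <- function(cur, sd, nd) {
    if (cur == b) {
      acc$sd <<- acc$sd + sd; acc$nd <<- acc$nd + nd; acc$n <<- acc$n + 1
      return(invisible(NULL))
    }
    for (pos in 1:3) {
      want <- substr(b, pos, pos)
      if (substr(cur, pos, pos) == want) next
      nxt <- cur
      substr(nxt, pos, pos) <- want
      if (GC[nxt] == "*") next
      dfs(nxt, sd + (GC[nxt] == GC[cur]), nd + (GC[nxt] != GC[cur]))
    }
  }
  dfs(a, 0, 0)
  if (acc$n == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = acc$sd / acc$n, nd = acc$nd / acc$n)
}

# full NG86 on two codon vectors, assembled only from the oracle pieces
oracle_ng86 <- function(ca, cb) {
  keep <- !is.na(ca) & !is.na(cb)
  ca <- ca[keep]; cb <- cb[keep]
  cnt <- vapply(seq_along(ca), function(i)
    oracle_path_counts(ca[i], cb[i]), c(sd = 0, nd = 0))
  ok <- !is.na(cnt["sd", ])
  S <- (sum(vapply(ca[ok], oracle_syn_sites, 0)) +
          sum(vapply(cb[ok], oracle_syn_sites, 0))) / 2
  list(S = S, N = 3 * sum(ok) - S,
       Sd = sum(cnt["sd", ok]), Nd = sum(cnt["nd", ok]))
}

# --- Dollo oracle: exhaustive search over branch subsets ------------------

# minimal sets of branches whose subtended leaves exactly cover the absent
# species (brute force over all subsets)
oracle_dollo <- function(tree, absent) {
  ids <- branch_ids(tree)
  below <- lapply(ids, function(b) leaves_below_branch(tree, b))
  best <- NULL
  n <- length(ids)
  for (mask in seq_len(2^n) - 1) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    covered <- sort(unique(unlist(below[sel])))
    if (identical(covered, sort(absent))) {
      if (is.null(best) || length(sel) < length(best)) best <- sel
    }
  }
  if (is.null(best)) return(NULL)
  sort(ids[best])
}

# --- random additive (and ultrametric) trees ------------------------------

random_additive_tree <- function(n_taxa, min_edge = 0.05) {
  phy <- ape::rtree(n_taxa, rooted = FALSE,
                    tip.label = paste0("t", seq_len(n_taxa)))
  phy$edge.length <- stats::runif(nrow(phy$edge), min_edge, 1)
  phy
}

random_ultrametric_tree <- function(n_taxa) {
  phy <- ape::rcoal(n_taxa, tip.label = paste0("s", seq_len(n_taxa)))
  phy$edge.length <- phy$edge.length * 10
  validate_species_tree(phy)
}

# --- brute-force global alignment score with affine gaps ------------------

# maximum score over all global alignments of two short peptides, by
# recursion over alignment columns (match/insert/delete with affine gaps)
oracle_align_score <- function(a, b, go = 10, ge = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, B[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(av))
      best <- max(best,
                  -(if (state == "d") ge else go + ge) + rec(i + 1, j, "d"))
    if (j <= length(bv))
      best <- max(best,
                  -(if (state == "i") ge else go + ge) + rec(i, j + 1, "i"))
    best
  }
  rec(1, 1, "m")
}

# --- misc helpers ---------------------------------------------------------

random_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

codons_of <- function(x) {
  n <- nchar(x) %/% 3
  substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

tiny_tree <- function(txt = "((mouse:25,rat:25):65,human:90);") {
  tf <- tempfile(fileext = ".nwk")
  writeLines(txt, tf)
  read_species_tree(tf)
}
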