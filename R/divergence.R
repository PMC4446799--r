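#' Uncorrected and Jukes-Cantor nucleotide distance
#'
#' Columns with a gap (\code{-}) or \code{N} in either sequence are excluded
#' from the comparison. The JC69 correction is
#' \eqn{-\frac{3}{4}\ln(1-\frac{4}{3}p)}; it is undefined (returned as
#' \code{NA}) when \eqn{p \ge 0.75}.
#'
#' @param a,b Equal-length aligned nucleotide strings.
#' @return List of class \code{"divergence_result"}: \code{compared_sites},
#'   \code{differing_sites}, \code{p_distance}, \code{jc_distance}.
#' @export
p_distance <- function(a, b) {
  a <- normalize_dna(a); b <- normalize_dna(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0) stop("no comparable sites (all columns gapped or ambiguous)")
  d <- sum(av[ok] != bv[ok])
  p <- d / n
  jc <- if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  structure(list(compared_sites = n, differing_sites = d,
                 p_distance = p, jc_distance = jc),
            class = "divergence_result")
}

#' Recency filter for candidate retrocopies
#'
#' Retrocopies less than the recency threshold (default 2\%) diverged from
#' their parental copy are too young to have been vetted by purifying
#' selection and are dismissed. The comparison uses the uncorrected
#' p-distance and a strict inequality, so a copy at exactly the threshold is
#' kept.
#'
#' @param div A \code{"divergence_result"} (or a bare p-distance).
#' @param config An [analysis_config()].
#' @return \code{"dismiss"} or \code{"keep"}.
#' @export
recency_filter <- function(div, config = analysis_config()) {
  p <- if (inherits(div, "divergence_result")) div$p_distance else div
  if (p < config$recency_threshold) "dismiss" else "keep"
}

# ---- Nei-Gojobori (1986) codon tables -------------------------------------

.ng86 <- new.env(parent = emptyenv())

.codon_list <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0)) # 64 codons
}

.is_stop <- function(codon) Biostrings::GENETIC_CODE[codon] == "*"

# Fraction of synonymous sites per codon. For each of the 3 positions the 3
# single-base alternatives are enumerated; mutations creating stop codons are
# dropped from the denominator, so syn + nonsyn fractions still sum to 1 per
# position and S + N = 3 per codon.
.ng86_sites <- function() {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- .codon_list()
  s <- setNames(rep(NA_real_, 64), codons)
  for (cod in codons) {
    if (gc[cod] == "*") next
    tot <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(bases, substr(cod, pos, pos)), function(nb) {
        m <- cod; substr(m, pos, pos) <- nb; m
      }, "")
      valid <- alts[gc[alts] != "*"]
      if (length(valid))
        tot <- tot + sum(gc[valid] == gc[cod]) / length(valid)
    }
    s[cod] <- tot
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all orderings of the differing positions, discarding pathways that pass
# through a stop codon. NA where either codon is a stop or no pathway exists.
.ng86_path_counts <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(diffpos) == 1) list(diffpos)
           else if (length(diffpos) == 2)
             list(diffpos, rev(diffpos))
           else {
    out <- list()
    for (i in 1:3) for (j in setdiff(1:3, i))
      out[[length(out) + 1]] <- diffpos[c(i, j, setdiff(1:3, c(i, j)))]
    out
  }
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0
  for (ord in perms) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (gc[nxt] == "*") { ok <- FALSE; break }
      if (gc[nxt] == gc[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
}

.ng86_tables <- function() {
  if (!is.null(.ng86$sites)) return(invisible(NULL))
  codons <- .codon_list()
  .ng86$sites <- .ng86_sites()
  sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_along(codons)) for (j in seq_along(codons)) {
    if (gc[codons[i]] == "*" || gc[codons[j]] == "*") next
    cnt <- .ng86_path_counts(codons[i], codons[j])
    sd[i, j] <- cnt["sd"]; nd[i, j] <- cnt["nd"]
  }
  .ng86$sd <- sd; .ng86$nd <- nd
  invisible(NULL)
}

#' Nei-Gojobori (1986) dN/dS for a codon-aligned sequence pair
#'
#' Counting-method estimate of synonymous and nonsynonymous substitution
#' rates. Synonymous site fractions per codon are computed by enumerating
#' the nine single-base mutations, with mutations to stop codons removed
#' from the denominator; differences between codon pairs are averaged over
#' all shortest substitution pathways that avoid stop-codon intermediates
#' (equal pathway weighting). Site counts are averaged over the two
#' sequences. Proportions are Jukes-Cantor corrected:
#' \eqn{d = -\frac{3}{4}\ln(1-\frac{4}{3}p)}.
#'
#' Codons containing \code{N} or a gap in either sequence are excluded, as
#' are codon pairs connected only through stop codons (with a warning).
#' Terminal stop codons are stripped; internal stops are an error.
#'
#' @param a,b Equal-length, in-frame codon-aligned nucleotide strings.
#' @return List of class \code{"dnds_result"}: \code{S_sites},
#'   \code{N_sites}, \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{dS},
#'   \code{dN}, \code{omega} (NA when undefined), \code{omega_defined},
#'   \code{compared_codons}.
#' @export
ng86_dnds <- function(a, b) {
  a <- normalize_dna(a); b <- normalize_dna(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3 != 0) stop("aligned length must be a multiple of 3")
  .ng86_tables()
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(a) %/% 3
  ca <- substring(a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  # strip a shared terminal stop
  if (n >= 1 && !anyNA(gc[ca[n]]) && !anyNA(gc[cb[n]]) &&
      (gc[ca[n]] == "*" || gc[cb[n]] == "*")) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1
  }
  clean <- !grepl("[N-]", ca) & !grepl("[N-]", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop("internal stop codon in input")
  sd_v <- .ng86$sd[cbind(ca, cb)]
  nd_v <- .ng86$nd[cbind(ca, cb)]
  skip <- is.na(sd_v)
  if (any(skip))
    warning(sum(skip), " codon pair(s) skipped: all mutational pathways ",
            "pass through stop codons")
  ca <- ca[!skip]; cb <- cb[!skip]
  sd_v <- sd_v[!skip]; nd_v <- nd_v[!skip]
  m <- length(ca)
  if (m == 0) stop("no comparable codons")
  S <- (sum(.ng86$sites[ca]) + sum(.ng86$sites[cb])) / 2
  N <- 3 * m - S
  Sd <- sum(sd_v); Nd <- sum(nd_v)
  # degenerate short inputs can have no synonymous (or nonsynonymous)
  # sites at all; the proportion is 0 without differences, undefined with
  pS <- if (S > 0) Sd / S else if (Sd == 0) 0 else NA_real_
  pN <- if (N > 0) Nd / N else if (Nd == 0) 0 else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  # omega is undefined when there is no synonymous signal (dS = 0 or JC
  # saturation), except in the pure-purifying corner where every observed
  # difference is synonymous: then omega = 0 regardless of dS
  defined <- (!is.na(dS) && dS > 0 && !is.na(dN)) ||
    (!is.na(dN) && dN == 0 && Sd > 0)
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 omega = if (!defined) NA_real_
                         else if (!is.na(dN) && dN == 0) 0
                         else dN / dS,
                 omega_defined = defined, compared_codons = m),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(paste0("<dnds_result> codons=%d S=%.2f N=%.2f Sd=%.2f ",
                     "Nd=%.2f dS=%.4g dN=%.4g omega=%s\n"),
              x$compared_codons, x$S_sites, x$N_sites, x$Sd, x$Nd,
              x$dS, x$dN,
              if (x$omega_defined) sprintf("%.4g", x$omega) else "undefined"))
  invisible(x)
}
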