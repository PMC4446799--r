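#' Choose a rooting outgroup for a family tree
#'
#' The declared rooting rule: prefer the X-linked copy of the
#' earliest-diverging species among the family's species that is not a
#' carrier of the focal autosomal copies (marsupials when present), ties
#' broken alphabetically.
#'
#' @param tips Tip labels of the family tree
#'   (\code{species__class__locus}).
#' @param carriers Species carrying the focal autosomal copies.
#' @param tree The dated \code{species_tree}.
#' @return A single tip label to root on.
#' @export
choose_outgroup <- function(tips, carriers, tree) {
  info <- parse_taxon(tips)
  x_sp <- sort(unique(info$species[info$chrom_class == "X"]))
  cand <- setdiff(x_sp, carriers)
  if (!length(cand)) cand <- x_sp
  if (!length(cand)) stop("no X-linked copy available for rooting")
  fam_sp <- unique(info$species)
  age <- vapply(cand, function(s)
    min(vapply(setdiff(fam_sp, s), function(t)
      divergence_time(tree, s, t), 0)), 0)
  best <- cand[age == max(age)][1]
  tips[info$species == best & info$chrom_class == "X"][1]
}

# synteny records of one family restricted to its autosomal loci (X/Y loci
# may carry synteny context, e.g. for DNA transpositions, but only
# autosomal insertions form candidate gain events)
.autosomal_synteny <- function(synteny, homologs, fam) {
  syn <- synteny[synteny$family == fam, , drop = FALSE]
  a_key <- with(homologs[homologs$family == fam &
                           homologs$chrom_class == "A", , drop = FALSE],
                paste(species, locus_id))
  syn[paste(syn$species, syn$locus_id) %in% a_key, , drop = FALSE]
}

# evidence for the autosomal copies of one family, computed from sequences,
# trees and (optionally) reads
.family_evidence <- function(fam, homologs, tree, reads, synteny, config,
                             boot_seed) {
  rows <- homologs[homologs$family == fam, , drop = FALSE]
  with_cds <- rows[!is.na(rows$cds), , drop = FALSE]
  copies <- lapply(seq_len(nrow(with_cds)), function(i)
    gene_copy(with_cds$family[i], with_cds$species[i],
              with_cds$chrom_class[i], with_cds$locus_id[i],
              cds = with_cds$cds[i],
              has_introns = with_cds$has_introns[i],
              mechanism_hint = with_cds$mechanism_hint[i]))
  labs <- vapply(copies, function(g)
    paste(g$species, g$chrom_class, g$locus_id, sep = "__"), "")
  aln <- align_codons(copies)
  bt <- bootstrap_supports(aln, config$bootstrap_replicates, boot_seed)
  info <- parse_taxon(aln$taxa)

  syn_rows <- .autosomal_synteny(synteny, homologs, fam)
  groups <- locus_groups(syn_rows, config)

  # expression per carrier species: assign reads against that species'
  # homolog set (A + X copies)
  assignments <- list()
  if (!is.null(reads) && nrow(reads)) {
    for (sp in unique(with_cds$species[with_cds$chrom_class == "A"])) {
      sp_reads <- reads[reads$species == sp, , drop = FALSE]
      if (!nrow(sp_reads)) next
      hom_sp <- copies[vapply(copies, function(g)
        g$species == sp && g$chrom_class %in% c("A", "X"), TRUE)]
      if (!length(hom_sp)) next
      assignments[[sp]] <- assign_reads(sp_reads, hom_sp,
                                        config$mismatch_tolerance)
    }
  }

  ev <- list(); origin_calls <- list()
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    targets <- intersect(paste(grp$species, "A", grp$locus_id, sep = "__"),
                         aln$taxa)
    if (!length(targets)) next
    carriers <- unique(grp$species)
    og <- choose_outgroup(aln$taxa, carriers, tree)
    oc <- classify_origin(bt, fam, outgroup_taxa = og,
                          target_taxa = targets, config = config)
    origin_calls[[length(origin_calls) + 1]] <- oc

    # group-level omega: between the two most divergent carrier copies, or
    # the single copy against its nearest parental-class copy
    omega <- NA_real_
    rowseq <- aln$rows
    parent_classes <- if (oc$verdict %in% c("X", "Y")) oc$verdict
                      else c("X", "Y")
    if (length(targets) >= 2) {
      pr <- utils::combn(targets, 2)
      pdv <- apply(pr, 2, function(p)
        p_distance(rowseq[[p[1]]], rowseq[[p[2]]])$p_distance)
      pick <- pr[, which.max(pdv)]
      dn <- tryCatch(ng86_dnds(rowseq[[pick[1]]], rowseq[[pick[2]]]),
                     error = function(e) NULL)
      if (!is.null(dn) && dn$omega_defined) omega <- dn$omega
    }

    for (t in targets) {
      ti <- parse_taxon(t)
      # parental copy: minimum-p sequence among parental-class tips
      ptips <- aln$taxa[info$chrom_class %in% parent_classes &
                          !(aln$taxa %in% targets)]
      p_parent <- NA_real_; nearest <- NULL
      if (length(ptips)) {
        pd <- vapply(ptips, function(p)
          p_distance(rowseq[[t]], rowseq[[p]])$p_distance, 0)
        p_parent <- min(pd)
        nearest <- ptips[which.min(pd)]
      }
      if (length(targets) < 2 && !is.null(nearest)) {
        dn <- tryCatch(ng86_dnds(rowseq[[t]], rowseq[[nearest]]),
                       error = function(e) NULL)
        if (!is.null(dn) && dn$omega_defined) omega <- dn$omega
      }
      # ORF against the same-species sex-linked counterpart, else nearest
      ref_pick <- with_cds[with_cds$species == ti$species &
                             with_cds$chrom_class %in% parent_classes, ,
                           drop = FALSE]
      if (!nrow(ref_pick))
        ref_pick <- with_cds[with_cds$species == ti$species &
                               with_cds$chrom_class == "X", , drop = FALSE]
      if (!nrow(ref_pick) && !is.null(nearest)) {
        ni <- parse_taxon(nearest)
        ref_pick <- with_cds[with_cds$species == ni$species &
                               with_cds$chrom_class == ni$chrom_class, ,
                             drop = FALSE]
      }
      cand_cds <- with_cds$cds[with_cds$species == ti$species &
                                 with_cds$chrom_class == "A" &
                                 with_cds$locus_id == ti$locus_id]
      orf <- if (nrow(ref_pick))
        suppressWarnings(
          assess_integrity(cand_cds, ref_pick$cds[1], config))$status
      else "unknown"

      transcribed <- NA; pattern <- "unknown"; breadth <- NA_integer_
      asg <- assignments[[ti$species]]
      if (!is.null(asg) && t %in% rownames(asg$counts)) {
        xlab <- grep(paste0("^", ti$species, "__X__"),
                     rownames(asg$counts), value = TRUE)
        prof <- expression_profile(
          t, asg, nchar(cand_cds),
          x_label = if (length(xlab)) xlab[1] else NULL,
          x_length = if (length(xlab))
            nchar(with_cds$cds[match(xlab[1], labs)]) else NULL)
        transcribed <- has_transcription_evidence(prof, config)
        pat <- classify_pattern(prof, config = config)
        pattern <- pat$pattern; breadth <- pat$breadth
      }
      ev[[length(ev) + 1]] <- data.frame(
        family = fam, species = ti$species, locus_id = ti$locus_id,
        orf_status = orf, transcribed = transcribed, p_parent = p_parent,
        omega = omega, origin = oc$verdict, origin_support = oc$support,
        pattern = pattern, breadth = breadth, stringsAsFactors = FALSE)
    }
  }
  list(evidence = if (length(ev)) do.call(rbind, ev) else NULL,
       origin_calls = origin_calls, groups = groups, tree = bt)
}

#' Run the full rescue-detection pipeline
#'
#' Orchestrates all stages in the order of the functionality criteria: per
#' family, codon alignment and bootstrapped NJ tree; synteny locus groups;
#' parental-origin classification per group; ORF integrity, parental
#' divergence (recency), group dN/dS; read assignment and expression
#' classification; then Dollo loss/gain placement and rescue calling.
#'
#' Deterministic given \code{config$random_seed}: identical inputs and seed
#' give a byte-identical report.
#'
#' @param homologs Homolog table; a \code{cds} column drives the sequence
#'   stages (families whose copies lack CDS need a precomputed
#'   \code{evidence} table).
#' @param tree Dated \code{species_tree}.
#' @param synteny Synteny records for the autosomal loci.
#' @param reads Optional read-set data frame.
#' @param evidence Optional precomputed evidence table; when supplied the
#'   sequence/expression stages are skipped.
#' @param config An [analysis_config()].
#' @return List of class \code{"pipeline_result"}: \code{report} (an
#'   \code{event_report}), \code{evidence}, \code{losses}, \code{gains},
#'   \code{origin_calls}, \code{stage_counts}.
#' @export
run_pipeline <- function(homologs, tree, synteny, reads = NULL,
                         evidence = NULL, config = analysis_config()) {
  set.seed(config$random_seed)
  validate_homolog_table(homologs, tree)
  families <- sort(unique(homologs$family))
  if (!length(families)) {
    rep0 <- call_rescues(tree,
                         data.frame(family = character(0),
                                    branch_id = character(0),
                                    species = character(0)),
                         dollo_gains(tree, "x", list()),
                         data.frame(family = character(0),
                                    species = character(0),
                                    locus_id = character(0),
                                    orf_status = character(0),
                                    transcribed = logical(0),
                                    p_parent = numeric(0)), config)
    return(structure(list(report = rep0, evidence = NULL,
                          losses = NULL, gains = NULL,
                          origin_calls = list(), stage_counts = NULL),
                     class = "pipeline_result"))
  }
  losses <- list(); gains <- list(); evs <- list(); ocs <- list()
  counts <- list()
  for (k in seq_along(families)) {
    fam <- families[k]
    rows <- homologs[homologs$family == fam, , drop = FALSE]
    presence <- vapply(unique(rows$species), function(s)
      any(rows$chrom_class == "Y" & rows$species == s), TRUE)
    fl <- dollo_losses(tree, fam, presence)
    losses[[fam]] <- fl

    if (is.null(evidence) && "cds" %in% names(rows) &&
        any(!is.na(rows$cds))) {
      fe <- .family_evidence(fam, homologs, tree, reads, synteny, config,
                             boot_seed = config$random_seed + 1000L * k)
      evs[[fam]] <- fe$evidence
      ocs <- c(ocs, fe$origin_calls)
      groups <- fe$groups
    } else {
      groups <- locus_groups(.autosomal_synteny(synteny, homologs, fam),
                             config)
    }
    gains[[fam]] <- dollo_gains(tree, fam, groups, homologs)
    counts[[fam]] <- data.frame(
      family = fam, n_copies = nrow(rows),
      n_losses = nrow(fl), n_locus_groups = length(groups),
      n_gains = nrow(gains[[fam]]))
  }
  all_losses <- do.call(rbind, losses)
  all_gains <- do.call(rbind, gains)
  all_ev <- if (!is.null(evidence)) evidence else do.call(rbind, evs)
  report <- call_rescues(tree, all_losses, all_gains, all_ev, config)
  structure(list(report = report, evidence = all_ev, losses = all_losses,
                 gains = all_gains, origin_calls = ocs,
                 stage_counts = do.call(rbind, counts)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' The packaged curated study fixture
#'
#' The presence/absence matrix, synteny groupings and per-copy functional
#' verdicts for the four gene families (EIF1A, EIF2S3, RPS4, UBA1) across
#' the study species, as plain-text tables under \code{extdata}.
#'
#' @return List: \code{tree}, \code{homologs}, \code{synteny},
#'   \code{evidence}.
#' @export
yrescue_fixture <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "yrescue")
    if (!nzchar(p)) stop("fixture file not found: ", f)
    p
  }
  tree <- yrescue_tree()
  list(tree = tree,
       homologs = read_homolog_table(path("homologs.tsv"), tree),
       synteny = read_synteny_table(path("synteny.tsv")),
       evidence = read_evidence_table(path("evidence.tsv")))
}
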