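#' Dollo-parsimony placement of Y-loss events
#'
#' Under Dollo parsimony the Y-linked gene has a single origin at the root
#' of the (induced) species tree and can only be lost, irreversibly. The
#' minimum set of loss branches is then the set of maximal all-absent
#' clades: a branch is a loss branch when every scored leaf below it lacks
#' the Y copy and the branch's parent clade contains at least one carrier.
#'
#' @param tree A \code{species_tree}.
#' @param family Gene-family identifier (carried through to the output).
#' @param presence Named logical vector over the scored species (TRUE = Y
#'   copy present). Species not named are unscored and ignored; the tree is
#'   restricted to the scored species first.
#' @return Data frame of loss events: family, branch_id, species
#'   (\code{"+"}-joined affected leaves). Zero rows when nothing was lost.
#' @export
dollo_losses <- function(tree, family, presence) {
  sp <- names(presence)
  if (is.null(sp) || !length(sp)) stop("presence must be a named vector")
  unk <- setdiff(sp, tree$tip.label)
  if (length(unk)) stop("unknown species: ", paste(unk, collapse = ", "))
  if (!any(presence))
    stop("gene '", family, "' absent from all scored species: no origin")
  if (all(presence))
    return(data.frame(family = character(0), branch_id = character(0),
                      species = character(0), stringsAsFactors = FALSE))
  sub <- if (length(sp) >= 2) restrict_tree(tree, sp) else NULL
  if (is.null(sub)) { # single scored species, absent
    return(data.frame(family = family, branch_id = sp, species = sp,
                      stringsAsFactors = FALSE))
  }
  sets <- .leafsets(sub)
  n_tip <- length(sub$tip.label)
  all_absent <- vapply(sets, function(s) all(!presence[s]), TRUE)
  # root node is never all-absent (checked above); losses are nodes that are
  # all-absent with a parent that is not
  parent_of <- integer(n_tip + sub$Nnode)
  parent_of[sub$edge[, 2]] <- sub$edge[, 1]
  loss_nodes <- which(all_absent &
                      seq_along(all_absent) != n_tip + 1 &
                      !all_absent[pmax(parent_of, 1)])
  loss_nodes <- loss_nodes[order(vapply(sets[loss_nodes], `[`, "", 1))]
  data.frame(family = family,
             branch_id = vapply(sets[loss_nodes], paste, "", collapse = "+"),
             species = vapply(sets[loss_nodes], paste, "", collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Dollo placement of autosomal-gain events
#'
#' Each locus group (shared-origin set of transposed loci) is placed on the
#' stem branch of the most recent common ancestor of its carrier species.
#' Locus groups of the same family landing on the same branch are collapsed
#' into one gain event (they cannot be distinguished as separate events at
#' branch granularity); the per-locus detail is preserved in \code{loci} and
#' \code{n_locus_groups}.
#'
#' @param tree A \code{species_tree}.
#' @param family Gene-family identifier.
#' @param groups Locus groups from [locus_groups()] (list of data frames
#'   with species and locus_id), or a list of character vectors of carrier
#'   species.
#' @param homologs Optional homolog table used to annotate the mechanism
#'   (\code{"dna"} if any member locus is a DNA transposition, else
#'   \code{"retro"}).
#' @return Data frame of gain events: family, branch_id, carriers, loci,
#'   n_locus_groups, mechanism.
#' @export
dollo_gains <- function(tree, family, groups, homologs = NULL) {
  if (!length(groups))
    return(data.frame(family = character(0), branch_id = character(0),
                      carriers = character(0), loci = character(0),
                      n_locus_groups = integer(0), mechanism = character(0),
                      stringsAsFactors = FALSE))
  info <- lapply(groups, function(g) {
    if (is.data.frame(g))
      list(species = unique(g$species),
           loci = paste(g$species, g$locus_id, sep = ":"))
    else list(species = unique(g), loci = unique(g))
  })
  branch <- vapply(info, function(x) mrca_branch_id(tree, x$species), "")
  mech_of <- function(loci_species) {
    if (is.null(homologs)) return("retro")
    rows <- homologs[homologs$family == family &
                     homologs$species %in% loci_species &
                     homologs$chrom_class == "A", , drop = FALSE]
    if (nrow(rows) && any(rows$mechanism_hint == "dna")) "dna" else "retro"
  }
  out <- do.call(rbind, lapply(unique(branch), function(b) {
    ix <- which(branch == b)
    carriers <- sort(unique(unlist(lapply(info[ix], `[[`, "species"))))
    data.frame(family = family, branch_id = b,
               carriers = paste(carriers, collapse = "+"),
               loci = paste(sort(unlist(lapply(info[ix], `[[`, "loci"))),
                            collapse = ","),
               n_locus_groups = length(ix),
               mechanism = mech_of(carriers),
               stringsAsFactors = FALSE)
  }))
  out[order(out$branch_id), , drop = FALSE]
}

#' Pair gains with Y losses into rescue events
#'
#' A gain event becomes a rescue event when (i) its carrier lineages and a
#' Y-loss of the same family overlap — either every carrier lies in a lost
#' lineage (loss before, or without record of, the gain) or the lost
#' lineage is a subset of the carriers (an ancient gain predating the loss);
#' the ordering is reported, not assumed — and (ii) at least one carrier
#' locus passes all three functionality criteria: intact ORF, transcription
#' evidence, and the recency filter.
#'
#' Gains failing (ii) with a non-intact ORF or no transcription are listed
#' as pseudogenes; recent copies and gains with no matching loss are listed
#' with their own exclusion reasons.
#'
#' @param tree A \code{species_tree}.
#' @param losses Loss events from [dollo_losses()] (possibly several
#'   families row-bound).
#' @param gains Gain events from [dollo_gains()] (ditto).
#' @param evidence Evidence table (see [read_evidence_table()]).
#' @param config An [analysis_config()].
#' @return List of class \code{"event_report"}: \code{events} (rescue
#'   events with their evidence bundle), \code{excluded} (non-rescue gains
#'   with reasons), \code{n_events}, \code{filter_counts}.
#' @export
call_rescues <- function(tree, losses, gains, evidence,
                         config = analysis_config()) {
  ev_key <- paste(evidence$family, evidence$species, evidence$locus_id)
  events <- list(); excluded <- list()
  filt <- c(no_matching_loss = 0L, pseudogene = 0L, recent = 0L,
            rescued = 0L)
  for (g in seq_len(nrow(gains))) {
    fam <- gains$family[g]
    carriers <- strsplit(gains$carriers[g], "+", fixed = TRUE)[[1]]
    fam_losses <- losses[losses$family == fam, , drop = FALSE]
    loss_sets <- strsplit(fam_losses$species, "+", fixed = TRUE)
    covered <- vapply(carriers, function(cc)
      any(vapply(loss_sets, function(s) cc %in% s, TRUE)), TRUE)
    subset_loss <- vapply(loss_sets, function(s) all(s %in% carriers), TRUE)
    matched <- vapply(loss_sets, function(s)
      length(intersect(s, carriers)) > 0, TRUE)
    ordering <- if (all(covered)) "loss_lineages_cover_carriers"
                else if (any(subset_loss)) "gain_predates_loss"
                else NA_character_
    loci <- strsplit(gains$loci[g], ",", fixed = TRUE)[[1]]
    loci_sp <- sub(":.*$", "", loci)
    loci_id <- sub("^[^:]*:", "", loci)
    ev_rows <- match(paste(fam, loci_sp, loci_id), ev_key)
    ev <- evidence[ev_rows[!is.na(ev_rows)], , drop = FALSE]
    passes <- nrow(ev) > 0 &
      ev$orf_status == "intact" &
      ev$transcribed %in% TRUE &
      !is.na(ev$p_parent) & ev$p_parent >= config$recency_threshold
    best <- if (nrow(ev) && any(passes, na.rm = TRUE))
      ev[which(passes)[1], , drop = FALSE] else NULL
    if (is.null(best)) {
      # a defective ORF or absent transcription marks a pseudogene; an
      # otherwise-clean copy failing only the recency filter is "recent"
      reason <- if (nrow(ev) == 0) "no_evidence"
        else if (any(ev$orf_status != "intact" |
                     !(ev$transcribed %in% TRUE), na.rm = TRUE)) "pseudogene"
        else "recent"
      if (!reason %in% names(filt)) filt[reason] <- 0L
      filt[reason] <- filt[reason] + 1L
      excluded[[length(excluded) + 1]] <-
        cbind(gains[g, , drop = FALSE], reason = reason)
    } else if (is.na(ordering)) {
      filt["no_matching_loss"] <- filt["no_matching_loss"] + 1L
      excluded[[length(excluded) + 1]] <-
        cbind(gains[g, , drop = FALSE], reason = "no_matching_loss")
    } else {
      filt["rescued"] <- filt["rescued"] + 1L
      age <- min_origin_age(carriers, tree)
      events[[length(events) + 1]] <- data.frame(
        family = fam, branch_id = gains$branch_id[g],
        carriers = gains$carriers[g], loci = gains$loci[g],
        n_locus_groups = gains$n_locus_groups[g],
        mechanism = gains$mechanism[g],
        matched_losses = paste(fam_losses$branch_id[matched],
                               collapse = ";"),
        ordering = ordering,
        orf_status = best$orf_status,
        transcribed = best$transcribed,
        recency = "keep",
        omega = if ("omega" %in% names(best)) best$omega else NA_real_,
        origin = if ("origin" %in% names(best)) best$origin
                 else NA_character_,
        min_age_mya = age,
        stringsAsFactors = FALSE)
    }
  }
  empty_events <- data.frame(family = character(0), branch_id = character(0),
                             carriers = character(0), loci = character(0),
                             n_locus_groups = integer(0),
                             mechanism = character(0),
                             matched_losses = character(0),
                             ordering = character(0),
                             orf_status = character(0),
                             transcribed = logical(0),
                             recency = character(0), omega = numeric(0),
                             origin = character(0), min_age_mya = numeric(0),
                             stringsAsFactors = FALSE)
  events <- if (length(events)) do.call(rbind, events) else empty_events
  events <- events[order(events$family, events$branch_id), , drop = FALSE]
  rownames(events) <- NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded)
              else cbind(dollo_gains(tree, "x", list())[0, ],
                         reason = character(0))
  rownames(excluded) <- NULL
  structure(list(events = events, excluded = excluded,
                 n_events = nrow(events), filter_counts = filt),
            class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf("<event_report> %d rescue event(s), %d excluded gain(s)\n",
              x$n_events, nrow(x$excluded)))
  if (x$n_events) {
    tab <- table(x$events$family)
    cat("  per family:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$excluded))
    cat("  excluded:",
        paste(x$excluded$family, x$excluded$carriers, x$excluded$reason,
              sep = "/", collapse = "; "), "\n")
  invisible(x)
}

#' Write an event report as TSV + JSON
#'
#' @param report An \code{"event_report"}.
#' @param prefix Output path prefix; writes \code{<prefix>_events.tsv},
#'   \code{<prefix>_excluded.tsv}, \code{<prefix>.json}.
#' @return The JSON path, invisibly.
#' @export
write_event_report <- function(report, prefix) {
  utils::write.table(report$events, paste0(prefix, "_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$excluded, paste0(prefix, "_excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- jsonlite::toJSON(list(n_events = report$n_events,
                                filter_counts = as.list(report$filter_counts),
                                events = report$events,
                                excluded = report$excluded),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           na = "null")
  writeLines(json, paste0(prefix, ".json"))
  invisible(paste0(prefix, ".json"))
}
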