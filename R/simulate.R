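#' Evolve a coding sequence under purifying selection
#'
#' Mutation-rejection codon model: the number of attempted point mutations
#' is Poisson with mean \code{branch_length} (expected substitutions per
#' site under neutrality) times the sequence length; each attempt picks a
#' uniform site and a uniform alternative base. Synonymous changes are
#' always accepted, nonsynonymous changes with probability \code{omega},
#' and changes creating stop codons are rejected, so the realised dN/dS
#' equals \code{omega} in expectation.
#'
#' @param cds In-frame coding sequence (stop-free except possibly planted
#'   pseudogene stops, which are preserved by the stop-rejection rule).
#' @param branch_length Expected neutral substitutions/site (>= 0).
#' @param omega Acceptance probability for nonsynonymous changes (>= 0).
#' @param seed Optional integer seed; if \code{NULL} the current RNG stream
#'   is used (callers seed once per simulation).
#' @return List: \code{cds}, \code{n_attempts}, \code{n_syn},
#'   \code{n_nonsyn} (accepted counts).
#' @export
evolve_codon_sequence <- function(cds, branch_length, omega, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(branch_length >= 0, omega >= 0)
  cds <- normalize_dna(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("cds length must be a multiple of 3")
  aa64 <- .codon_aa_codes()
  # integer encoding A,C,G,T -> 0..3; codon index = 16 b1 + 4 b2 + b3 + 1
  w <- match(strsplit(cds, "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(w)) stop("cds must be over {A,C,G,T} to evolve")
  mult <- c(16L, 4L, 1L)
  n_att <- stats::rpois(1, branch_length * n)
  n_syn <- 0L; n_nonsyn <- 0L
  if (n_att > 0) {
    sites <- sample.int(n, n_att, replace = TRUE)
    us <- stats::runif(n_att)
    ub <- sample.int(3, n_att, replace = TRUE)
    for (k in seq_len(n_att)) {
      s <- sites[k]
      cur <- w[s]
      alt <- ((cur + ub[k]) %% 4L)  # uniform over the 3 other bases
      c0 <- (s - 1L) %/% 3L
      pos <- (s - 1L) %% 3L + 1L
      i1 <- 3L * c0 + 1L
      idx_old <- w[i1] * 16L + w[i1 + 1L] * 4L + w[i1 + 2L] + 1L
      idx_new <- idx_old + (alt - cur) * mult[pos]
      if (aa64[idx_new] == 0L) next             # mutation to stop: rejected
      if (aa64[idx_new] == aa64[idx_old]) {
        w[s] <- alt; n_syn <- n_syn + 1L
      } else if (us[k] < omega) {
        w[s] <- alt; n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(cds = paste(c("A", "C", "G", "T")[w + 1L], collapse = ""),
       n_attempts = n_att, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# amino-acid codes per codon index (16 b1 + 4 b2 + b3 + 1, bases 0..3 in
# A,C,G,T order); 0 marks a stop codon
.sim_env <- new.env(parent = emptyenv())
.codon_aa_codes <- function() {
  if (is.null(.sim_env$aa64)) {
    b <- c("A", "C", "G", "T")
    codons <- as.vector(sapply(b, function(x1)
      sapply(b, function(x2) paste0(x1, x2, b))))
    # codons vector in index order: b3 fastest, then b2, then b1
    aa <- Biostrings::GENETIC_CODE[codons]
    codes <- match(aa, c("*", setdiff(unique(aa), "*"))) - 1L
    .sim_env$aa64 <- codes
  }
  .sim_env$aa64
}

#' Random stop-free coding sequence
#' @param n_codons Number of codons; the first is ATG.
#' @return CDS string.
#' @export
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}

#' Simulation configuration
#'
#' Defaults encode a mammalian study design: a neutral substitution rate of
#' 0.005 substitutions/site/million years, strong purifying selection on
#' functional copies (omega 0.05 on X and autosomal functional copies, 0.10
#' on the faster-evolving Y), neutral evolution (omega 1) on pseudogenes,
#' and a gametolog split predating the eutherian-marsupial divergence.
#'
#' @param tree Dated \code{species_tree} (default: the packaged tree).
#' @param family_species Named list: family -> species subset carrying the
#'   gene (default: all leaves for every family in \code{event_specs}).
#' @param subs_rate Neutral substitutions/site/my.
#' @param omega_by_copy_class Named vector over X, Y, A_functional,
#'   A_pseudo.
#' @param gametolog_split_my Age of the X/Y divergence (mya); must be at
#'   least the tree height.
#' @param event_specs Data frame: family, parent_class (X/Y), branch_id,
#'   mechanism (retro/dna), pseudogenize, recent.
#' @param loss_specs Data frame: family, branch_id (Y copies deleted in all
#'   leaves below).
#' @param cds_length_codons Codons per gene.
#' @param tissue_panel Tissue labels including \code{"testis"}.
#' @param depth Reads per kb of CDS per tissue at multiplier 1.
#' @param read_length Read length in bases.
#' @param error_rate Per-base sequencing error rate.
#' @param seed Integer seed; fixes the whole simulation.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(tree = yrescue_tree(),
                       family_species = NULL,
                       subs_rate = 0.005,
                       omega_by_copy_class = c(X = 0.05, Y = 0.10,
                                               A_functional = 0.05,
                                               A_pseudo = 1.0),
                       gametolog_split_my = 180,
                       event_specs,
                       loss_specs = NULL,
                       cds_length_codons = 300,
                       tissue_panel = c("brain", "liver", "kidney", "testis"),
                       depth = 100,
                       read_length = 75,
                       error_rate = 0.005,
                       seed = 1L) {
  stopifnot(all(omega_by_copy_class >= 0), "testis" %in% tissue_panel)
  h <- max(ape::node.depth.edgelength(tree))
  if (gametolog_split_my < h)
    stop("gametolog_split_my must be at least the tree height (", h, ")")
  structure(list(tree = tree, family_species = family_species,
                 subs_rate = subs_rate,
                 omega_by_copy_class = omega_by_copy_class,
                 gametolog_split_my = gametolog_split_my,
                 event_specs = event_specs, loss_specs = loss_specs,
                 cds_length_codons = cds_length_codons,
                 tissue_panel = tissue_panel, depth = depth,
                 read_length = read_length, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evolve a gametolog (or planted copy) down a subtree, returning sequences
# at every node, the sequence at each edge midpoint (where transposition
# events tap the parental lineage, so a planted copy shares the parent's
# first-half mutations), and realised counts per edge.
.evolve_down <- function(tree, start_node, start_seq, rate, omega) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  mids <- vector("list", n_tip + tree$Nnode)
  seqs[[start_node]] <- start_seq
  counts <- list()
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chi <- ord$edge[k, 2]
    if (is.null(seqs[[par]])) next
    half <- ord$edge.length[k] * rate / 2
    e1 <- evolve_codon_sequence(seqs[[par]], half, omega)
    e2 <- evolve_codon_sequence(e1$cds, half, omega)
    mids[[chi]] <- e1$cds
    seqs[[chi]] <- e2$cds
    counts[[length(counts) + 1]] <-
      data.frame(parent = par, child = chi,
                 n_syn = e1$n_syn + e2$n_syn,
                 n_nonsyn = e1$n_nonsyn + e2$n_nonsyn,
                 branch_subs = ord$edge.length[k] * rate)
  }
  list(seqs = seqs, mids = mids, counts = do.call(rbind, counts))
}

#' Simulate gene families with planted transposition events
#'
#' For each family: an ancestral CDS splits into X and Y gametologs at
#' \code{gametolog_split_my}, each gametolog evolves down the (restricted)
#' species tree under its class omega, planted events duplicate the parent
#' copy at the midpoint of the chosen branch onto a new autosomal locus (with a
#' fresh flanking-gene context inherited by all carrier descendants; a DNA
#' transposition instead carries its parent chromosome's flank symbols),
#' pseudogenised copies get one in-frame stop at a uniform internal codon,
#' "recent" copies are planted on a terminal branch with ~1\% divergence,
#' and Y copies are deleted below each loss branch.
#'
#' @param cfg A [sim_config()].
#' @return List: \code{homologs} (homolog table with CDS), \code{synteny}
#'   (synteny records), \code{truth} (planted events, losses, locus
#'   partition, per-edge realised substitution counts).
#' @export
simulate_family <- function(cfg) {
  set.seed(cfg$seed)
  tree <- cfg$tree
  omg <- cfg$omega_by_copy_class
  rate <- cfg$subs_rate
  ev_specs <- cfg$event_specs
  families <- unique(ev_specs$family)
  hom <- list(); syn <- list(); truth_ev <- list(); truth_loss <- list()
  edge_counts <- list()
  for (fam in families) {
    fam_sp <- if (!is.null(cfg$family_species) &&
                  fam %in% names(cfg$family_species))
      cfg$family_species[[fam]] else tree$tip.label
    ftree <- restrict_tree(tree, fam_sp)
    n_tip <- length(ftree$tip.label)
    root <- n_tip + 1
    h <- max(ape::node.depth.edgelength(ftree))
    anc <- random_cds(cfg$cds_length_codons)
    stem <- (cfg$gametolog_split_my - h) * rate
    x_root <- evolve_codon_sequence(anc, stem, omg[["X"]])$cds
    y_root <- evolve_codon_sequence(anc, stem, omg[["Y"]])$cds
    gx <- .evolve_down(ftree, root, x_root, rate, omg[["X"]])
    gy <- .evolve_down(ftree, root, y_root, rate, omg[["Y"]])
    edge_counts[[fam]] <- rbind(cbind(family = fam, class = "X", gx$counts),
                                cbind(family = fam, class = "Y", gy$counts))
    ids <- branch_ids(ftree)
    node_of_branch <- setNames(ftree$edge[, 2], ids)
    parent_of <- setNames(ftree$edge[, 1], ids)
    sets <- .leafsets(ftree)

    loss_leaves <- character(0)
    fl <- cfg$loss_specs[cfg$loss_specs$family == fam, , drop = FALSE]
    if (!is.null(fl) && nrow(fl)) for (b in fl$branch_id) {
      if (!b %in% ids) stop("loss branch not in tree: ", b)
      loss_leaves <- union(loss_leaves, sets[[node_of_branch[[b]]]])
      truth_loss[[length(truth_loss) + 1]] <-
        data.frame(family = fam, branch_id = b,
                   species = paste(sort(sets[[node_of_branch[[b]]]]),
                                   collapse = "+"))
    }

    # X and Y flank contexts (a DNA transposition carries its parent's)
    ctx <- function(tag) list(up = paste0(fam, "_", tag, "_U", 2:1),
                              down = paste0(fam, "_", tag, "_D", 1:2))
    x_ctx <- ctx("X"); y_ctx <- ctx("Y")

    for (s in ftree$tip.label) {
      hom[[length(hom) + 1]] <- data.frame(
        family = fam, species = s, chrom_class = "X", locus_id = "X",
        has_introns = TRUE, mechanism_hint = "ancestral",
        cds = gx$seqs[[which(ftree$tip.label == s)]])
      syn[[length(syn) + 1]] <- data.frame(
        family = fam, species = s, locus_id = "X",
        flanks_up = paste(x_ctx$up, collapse = ","),
        flanks_down = paste(x_ctx$down, collapse = ","))
      if (!s %in% loss_leaves)
        hom[[length(hom) + 1]] <- data.frame(
          family = fam, species = s, chrom_class = "Y", locus_id = "Y",
          has_introns = TRUE, mechanism_hint = "ancestral",
          cds = gy$seqs[[which(ftree$tip.label == s)]])
    }

    fe <- ev_specs[ev_specs$family == fam, , drop = FALSE]
    for (e in seq_len(nrow(fe))) {
      b <- fe$branch_id[e]
      if (!b %in% ids) stop("event branch not in tree: ", b)
      carriers <- sets[[node_of_branch[[b]]]]
      pc <- fe$parent_class[e]
      if (pc == "Y" && !is.null(fl) && nrow(fl)) {
        for (lb in fl$branch_id) {
          ls <- sets[[node_of_branch[[lb]]]]
          # a loss strictly ancestral to the event branch contradicts a
          # Y-parented event (same-branch loss/gain is the rescue case)
          if (all(carriers %in% ls) && !setequal(carriers, ls))
            stop("event planted on a branch whose Y parent was already ",
                 "deleted (loss on ", lb, ")")
        }
      }
      locus <- paste0("A", e)
      gp <- if (pc == "X") gx else gy
      recent <- isTRUE(fe$recent[e])
      pseudo <- isTRUE(fe$pseudogenize[e])
      omega_a <- if (pseudo) omg[["A_pseudo"]] else omg[["A_functional"]]
      leaf_seqs <- list()
      if (recent) {
        if (length(carriers) != 1)
          stop("recent events must be planted on a terminal branch")
        par_seq <- gp$seqs[[which(ftree$tip.label == carriers)]]
        if (pseudo) par_seq <- .plant_stop(par_seq)
        leaf_seqs[[carriers]] <-
          evolve_codon_sequence(par_seq, 0.0105, 1)$cds
      } else {
        # tap the parental lineage at the event branch's midpoint, so the
        # planted copy shares the parent's first-half mutations and the
        # gene tree places it inside the parental gametolog clade
        dup <- gp$mids[[node_of_branch[[b]]]]
        if (pseudo) dup <- .plant_stop(dup)
        blen <- ftree$edge.length[which(ids == b)]
        top <- evolve_codon_sequence(dup, blen * rate / 2, omega_a)$cds
        ga <- .evolve_down(ftree, node_of_branch[[b]], top, rate, omega_a)
        for (s in carriers)
          leaf_seqs[[s]] <- ga$seqs[[which(ftree$tip.label == s)]]
      }
      actx <- if (fe$mechanism[e] == "dna") {
        if (pc == "X") x_ctx else y_ctx
      } else ctx(paste0("E", e))
      for (s in carriers) {
        hom[[length(hom) + 1]] <- data.frame(
          family = fam, species = s, chrom_class = "A", locus_id = locus,
          has_introns = fe$mechanism[e] == "dna",
          mechanism_hint = fe$mechanism[e], cds = leaf_seqs[[s]])
        syn[[length(syn) + 1]] <- data.frame(
          family = fam, species = s, locus_id = locus,
          flanks_up = paste(actx$up, collapse = ","),
          flanks_down = paste(actx$down, collapse = ","))
      }
      truth_ev[[length(truth_ev) + 1]] <- data.frame(
        family = fam, event_id = paste0(fam, ":", locus),
        parent_class = pc, branch_id = b,
        carriers = paste(sort(carriers), collapse = "+"),
        mechanism = fe$mechanism[e], pseudogenize = pseudo,
        recent = recent,
        is_rescue = !pseudo && !recent && all(carriers %in% loss_leaves))
    }
  }
  homologs <- do.call(rbind, hom)
  rownames(homologs) <- NULL
  synteny <- do.call(rbind, syn)
  synteny$flanks_up <- strsplit(synteny$flanks_up, ",", fixed = TRUE)
  synteny$flanks_down <- strsplit(synteny$flanks_down, ",", fixed = TRUE)
  truth <- list(
    events = do.call(rbind, truth_ev),
    losses = if (length(truth_loss)) do.call(rbind, truth_loss)
             else data.frame(family = character(0), branch_id = character(0),
                             species = character(0)),
    edge_counts = do.call(rbind, edge_counts))
  validate_homolog_table(homologs, cfg$tree)
  list(homologs = homologs, synteny = synteny, truth = truth)
}

# replace a uniform internal codon (not the first or last) with TAA
.plant_stop <- function(cds) {
  n <- nchar(cds) %/% 3
  at <- sample(2:(n - 1), 1)
  paste0(substr(cds, 1, 3 * (at - 1)), "TAA", substr(cds, 3 * at + 1, 3 * n))
}

#' Simulate tissue-stratified read sets
#'
#' Per tissue and copy, \code{round(depth x CDS-kb x multiplier)} reads are
#' drawn with uniform start positions on the sense strand and i.i.d.
#' per-base errors. Pattern multipliers: \code{broad} = 1 in every tissue;
#' \code{testis_specific} = \code{fold} in testis and 1 elsewhere;
#' \code{silent} = \code{fold} (normally << 1) in every tissue.
#'
#' @param copies Homolog table rows (with \code{cds}) to generate reads for.
#' @param specs Data frame: family, species, locus_id, pattern, fold.
#'   Copies without a spec row default to broad.
#' @param depth Reads per kb per tissue at multiplier 1.
#' @param read_length Read length (must not exceed any CDS length).
#' @param error_rate Per-base error probability.
#' @param tissue_panel Tissue labels.
#' @param seed Optional seed.
#' @return Read-set data frame: id, seq, tissue, species, truth_copy.
#' @export
simulate_reads <- function(copies, specs = NULL, depth = 100,
                           read_length = 75, error_rate = 0.005,
                           tissue_panel = c("brain", "liver", "kidney",
                                            "testis"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depth > 0)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (i in seq_len(nrow(copies))) {
    cds <- copies$cds[i]
    L <- nchar(cds)
    if (read_length > L)
      stop("read_length exceeds CDS length for ",
           copies$family[i], "/", copies$species[i])
    lab <- paste(copies$species[i], copies$chrom_class[i],
                 copies$locus_id[i], sep = "__")
    spec <- NULL
    if (!is.null(specs)) {
      hit <- specs$family == copies$family[i] &
        specs$species == copies$species[i] &
        specs$locus_id == copies$locus_id[i]
      if (any(hit)) spec <- specs[which(hit)[1], ]
    }
    pattern <- if (is.null(spec)) "broad" else spec$pattern
    fold <- if (is.null(spec)) 1 else spec$fold
    for (t in tissue_panel) {
      mult <- switch(pattern,
                     broad = 1,
                     testis_specific = if (t == "testis") fold else 1,
                     silent = fold,
                     stop("unknown pattern: ", pattern))
      n_reads <- round(depth * (L / 1000) * mult)
      if (n_reads < 1) next
      starts <- sample.int(L - read_length + 1, n_reads, replace = TRUE)
      seqs <- substring(cds, starts, starts + read_length - 1)
      n_err <- stats::rbinom(n_reads, read_length, error_rate)
      for (r in which(n_err > 0)) {
        pos <- sample.int(read_length, n_err[r])
        v <- strsplit(seqs[r], "")[[1]]
        for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1)
        seqs[r] <- paste(v, collapse = "")
      }
      out[[length(out) + 1]] <- data.frame(
        id = paste0(lab, "_", t, "_", seq_len(n_reads)),
        seq = seqs, tissue = t, species = copies$species[i],
        truth_copy = lab, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(0), seq = character(0),
                      tissue = character(0), species = character(0),
                      truth_copy = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standard simulated study scenario
#'
#' Four gene families over the packaged species tree with planted events
#' mirroring the real study's event structure: one Y-derived rodent
#' retrogene with a rodent Y loss (EIF1A-like, plus a planted autosomal
#' pseudogene in cattle), three independent X-derived primate retrogenes
#' with a simian Y loss (EIF2S3-like, plus a recent pseudogenised cattle
#' copy), three independent retrogenes in rodents, marsupials and cattle
#' with matching Y losses (RPS4-like), and one Y-derived DNA transposition
#' in marmoset (UBA1-like). Expression is broad or testis-predominant per
#' copy as in the study's profiles; planted pseudogenes are near-silent.
#'
#' @param seed Integer seed (drives sequences, reads, everything).
#' @param cds_length_codons,depth,read_length,error_rate Overrides passed
#'   to [sim_config()] / [simulate_reads()].
#' @return List: \code{config}, \code{homologs}, \code{synteny},
#'   \code{reads}, \code{expression_specs}, \code{truth}.
#' @export
simulate_study <- function(seed = 1L, cds_length_codons = 300, depth = 60,
                           read_length = 75, error_rate = 0.005) {
  tree <- yrescue_tree()
  fam_sp <- list(
    FAM1 = c("human", "rhesus", "marmoset", "mouse", "rat", "cattle"),
    FAM2 = c("human", "chimpanzee", "gorilla", "orangutan", "rhesus",
             "baboon", "marmoset", "squirrel_monkey", "mouse", "cattle"),
    FAM3 = c("human", "rhesus", "mouse", "rat", "cattle", "opossum",
             "wallaby"),
    FAM4 = c("human", "marmoset", "squirrel_monkey", "mouse", "opossum"))
  ev <- rbind(
    data.frame(family = "FAM1", parent_class = "Y", branch_id = "mouse+rat",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM1", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = TRUE, recent = FALSE),
    data.frame(family = "FAM2", parent_class = "X",
               branch_id = "chimpanzee+gorilla+human+orangutan",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM2", parent_class = "X",
               branch_id = "baboon+rhesus", mechanism = "retro",
               pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM2", parent_class = "X",
               branch_id = "marmoset+squirrel_monkey", mechanism = "retro",
               pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM2", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = TRUE, recent = TRUE),
    data.frame(family = "FAM3", parent_class = "X", branch_id = "mouse+rat",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM3", parent_class = "X",
               branch_id = "opossum+wallaby", mechanism = "retro",
               pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM3", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "FAM4", parent_class = "Y", branch_id = "marmoset",
               mechanism = "dna", pseudogenize = FALSE, recent = FALSE))
  losses <- rbind(
    data.frame(family = "FAM1", branch_id = "mouse+rat"),
    data.frame(family = "FAM2",
               branch_id = paste(sort(c("human", "chimpanzee", "gorilla",
                                        "orangutan", "rhesus", "baboon",
                                        "marmoset", "squirrel_monkey")),
                                 collapse = "+")),
    data.frame(family = "FAM3", branch_id = "mouse+rat"),
    data.frame(family = "FAM3", branch_id = "cattle"),
    data.frame(family = "FAM3", branch_id = "opossum+wallaby"),
    data.frame(family = "FAM4", branch_id = "marmoset"),
    data.frame(family = "FAM4", branch_id = "human"))
  cfg <- sim_config(tree = tree, family_species = fam_sp, event_specs = ev,
                    loss_specs = losses,
                    cds_length_codons = cds_length_codons, depth = depth,
                    read_length = read_length, error_rate = error_rate,
                    seed = seed)
  sim <- simulate_family(cfg)
  # expression: testis-predominant where the study saw it, broad elsewhere;
  # pseudogenes near-silent
  es <- sim$homologs[sim$homologs$chrom_class == "A",
                     c("family", "species", "locus_id")]
  es$pattern <- "broad"; es$fold <- 1
  testis <- with(es, (family == "FAM2" &
                        species %in% c("human", "chimpanzee", "gorilla",
                                       "orangutan", "rhesus", "baboon")) |
                   (family == "FAM3" &
                      species %in% c("mouse", "rat", "cattle")) |
                   family == "FAM4")
  es$pattern[testis] <- "testis_specific"; es$fold[testis] <- 10
  pseudo_ids <- sim$truth$events$event_id[sim$truth$events$pseudogenize]
  pseudo <- paste(es$family, paste0(es$family, ":", es$locus_id)) %in%
    paste(sub(":.*", "", pseudo_ids), pseudo_ids)
  es$pattern[pseudo] <- "silent"; es$fold[pseudo] <- 0.02
  carrier_sp <- unique(sim$homologs[sim$homologs$chrom_class == "A",
                                    c("family", "species")])
  key <- paste(sim$homologs$family, sim$homologs$species)
  want <- key %in% paste(carrier_sp$family, carrier_sp$species) &
    sim$homologs$chrom_class %in% c("A", "X")
  reads <- simulate_reads(sim$homologs[want, ], es, depth = depth,
                          read_length = read_length,
                          error_rate = error_rate,
                          tissue_panel = cfg$tissue_panel)
  list(config = cfg, homologs = sim$homologs, synteny = sim$synteny,
       reads = reads, expression_specs = es, truth = sim$truth)
}
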