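test_that("codon evolution respects branch length, omega and stop avoidance", {
  set.seed(81)
  cds <- random_cds(200)
  expect_identical(evolve_codon_sequence(cds, 0, 0.5)$cds, cds)

  # omega = 0: only synonymous change, dN must be exactly 0
  out <- evolve_codon_sequence(cds, 0.3, 0)
  expect_equal(out$n_nonsyn, 0L)
  r <- ng86_dnds(cds, out$cds)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)

  # no stop codons ever created
  aa <- translate_codons(evolve_codon_sequence(cds, 1.5, 1)$cds)
  expect_false("*" %in% aa)

  # same seed, same output
  e1 <- evolve_codon_sequence(cds, 0.2, 0.3, seed = 99)
  e2 <- evolve_codon_sequence(cds, 0.2, 0.3, seed = 99)
  expect_identical(e1, e2)
})

test_that("neutral simulation yields dN/dS near 1 on long sequences", {
  set.seed(82)
  cds <- random_cds(10000)
  a <- evolve_codon_sequence(cds, 0.15, 1)$cds
  b <- evolve_codon_sequence(cds, 0.15, 1)$cds
  r <- ng86_dnds(a, b)
  expect_gt(r$omega, 0.8)
  expect_lt(r$omega, 1.2)
})

test_that("simulated families are consistent with their truth tables", {
  ev <- rbind(
    data.frame(family = "G", parent_class = "Y", branch_id = "mouse+rat",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "G", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = TRUE, recent = FALSE),
    data.frame(family = "G", parent_class = "X", branch_id = "human",
               mechanism = "retro", pseudogenize = FALSE, recent = TRUE))
  cfg <- sim_config(
    family_species = list(G = c("human", "rhesus", "mouse", "rat",
                                "cattle", "opossum")),
    event_specs = ev,
    loss_specs = data.frame(family = "G", branch_id = "mouse+rat"),
    cds_length_codons = 150, seed = 83)
  sim <- simulate_family(cfg)
  hom <- sim$homologs

  # Y deleted exactly below the loss branch
  expect_false(any(hom$chrom_class == "Y" &
                     hom$species %in% c("mouse", "rat")))
  expect_true(any(hom$chrom_class == "Y" & hom$species == "human"))

  # every truth event has homolog rows for each carrier
  for (i in seq_len(nrow(sim$truth$events))) {
    tev <- sim$truth$events[i, ]
    carriers <- strsplit(tev$carriers, "+", fixed = TRUE)[[1]]
    locus <- sub("^G:", "", tev$event_id)
    present <- hom$species[hom$chrom_class == "A" & hom$locus_id == locus]
    expect_setequal(present, carriers)
  }

  # pseudogenised copy carries a premature stop
  pseudo_locus <- sub("^G:", "",
                      sim$truth$events$event_id[sim$truth$events$pseudogenize])
  pcds <- hom$cds[hom$locus_id == pseudo_locus][1]
  expect_false(is.na(scan_orf(pcds)$stop_index))

  # recent copy sits under 2% divergence from its parent copy
  recent_locus <- sub("^G:", "",
                      sim$truth$events$event_id[sim$truth$events$recent])
  rcds <- hom$cds[hom$locus_id == recent_locus & hom$species == "human"]
  xcds <- hom$cds[hom$chrom_class == "X" & hom$species == "human"]
  expect_lt(p_distance(rcds, xcds)$p_distance, 0.02)

  # contradictory spec: Y-parented event below an ancestral Y loss
  bad <- data.frame(family = "G", parent_class = "Y", branch_id = "mouse",
                    mechanism = "retro", pseudogenize = FALSE,
                    recent = FALSE)
  cfg_bad <- sim_config(
    family_species = list(G = c("human", "mouse", "rat", "opossum")),
    event_specs = bad,
    loss_specs = data.frame(family = "G", branch_id = "mouse+rat"),
    cds_length_codons = 60, seed = 84)
  expect_error(simulate_family(cfg_bad), "already")
})

test_that("realised substitution ratios track the configured omega", {
  ev <- data.frame(family = "G", parent_class = "X", branch_id = "mouse+rat",
                   mechanism = "retro", pseudogenize = FALSE, recent = FALSE)
  cfg <- sim_config(
    family_species = list(G = c("human", "mouse", "rat", "opossum")),
    event_specs = ev, cds_length_codons = 1000, seed = 85)
  sim <- simulate_family(cfg)
  cnt <- sim$truth$edge_counts
  # pool realised counts per class; expected nonsyn/syn attempt ratio is
  # roughly (N/S) * omega with N/S ~ 3 for random codons
  for (cl in c("X", "Y")) {
    rows <- cnt[cnt$class == cl & cnt$branch_subs > 0.05, ]
    ratio <- sum(rows$n_nonsyn) / sum(rows$n_syn)
    om <- cfg$omega_by_copy_class[[cl]]
    expect_gt(ratio, 3.2 * om * 0.6)
    expect_lt(ratio, 3.2 * om * 1.6)
  }
})

test_that("read simulation is exact in the no-noise limit and seeded", {
  set.seed(86)
  copies <- data.frame(family = "G", species = "m", chrom_class = "X",
                       locus_id = "X", has_introns = TRUE,
                       mechanism_hint = "unknown", cds = random_cds(120))
  reads <- simulate_reads(copies, depth = 200, read_length = 50,
                          error_rate = 0, tissue_panel = c("testis"),
                          seed = 1)
  expect_true(all(vapply(reads$seq, function(s)
    grepl(s, copies$cds, fixed = TRUE), TRUE)))

  r1 <- simulate_reads(copies, depth = 50, read_length = 50,
                       error_rate = 0.01, tissue_panel = c("testis"),
                       seed = 7)
  r2 <- simulate_reads(copies, depth = 50, read_length = 50,
                       error_rate = 0.01, tissue_panel = c("testis"),
                       seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_reads(copies, depth = 10, read_length = 500,
                              error_rate = 0, tissue_panel = "testis"),
               "read_length")
})
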