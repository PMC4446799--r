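test_that("Dollo loss placement finds maximal all-absent clades", {
  tr <- yrescue_tree()
  # Y present in all scored eutherians except the two rodents
  sp <- c("human", "chimpanzee", "rhesus", "marmoset", "mouse", "rat",
          "cattle")
  presence <- setNames(!(sp %in% c("mouse", "rat")), sp)
  losses <- dollo_losses(tr, "EIF1A", presence)
  expect_equal(nrow(losses), 1L)
  expect_equal(losses$branch_id, "mouse+rat")

  all_there <- setNames(rep(TRUE, length(sp)), sp)
  expect_equal(nrow(dollo_losses(tr, "G", all_there)), 0L)
  none <- setNames(rep(FALSE, length(sp)), sp)
  expect_error(dollo_losses(tr, "G", none), "no origin")
})

test_that("Dollo loss sets match exhaustive minimal search on small trees", {
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    tr <- random_ultrametric_tree(n)
    leaves <- tree_leaves(tr)
    for (k in 1:12) {
      pres <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), leaves)
      if (!any(pres)) next
      got <- dollo_losses(tr, "G", pres)
      best <- oracle_dollo(tr, leaves[!pres])
      if (all(pres)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(sort(got$branch_id), best)
      }
    }
  }
})

test_that("gains sit on MRCA stems and same-branch locus groups collapse", {
  fx <- yrescue_fixture()
  tr <- fx$tree
  syn <- fx$synteny

  primate <- locus_groups(syn[syn$family == "EIF2S3" &
                                syn$species != "cattle", ])
  g3 <- dollo_gains(tr, "EIF2S3", primate, fx$homologs)
  expect_equal(nrow(g3), 3L)
  expect_true("baboon+rhesus" %in% g3$branch_id)

  rodent <- locus_groups(syn[syn$family == "EIF1A" &
                               syn$species %in% c("mouse", "rat"), ])
  g1 <- dollo_gains(tr, "EIF1A", rodent, fx$homologs)
  expect_equal(g1$branch_id, "mouse+rat")

  # two marsupial RPS4 locus groups on the same stem collapse to one event
  mars <- locus_groups(syn[syn$family == "RPS4" &
                             syn$species %in% c("opossum", "wallaby"), ])
  expect_equal(length(mars), 2L)
  gm <- dollo_gains(tr, "RPS4", mars, fx$homologs)
  expect_equal(nrow(gm), 1L)
  expect_equal(gm$n_locus_groups, 2L)
  expect_equal(gm$branch_id, "opossum+wallaby")

  # mechanism annotation: the marmoset copy is a DNA transposition
  uba <- dollo_gains(tr, "UBA1",
                     locus_groups(syn[syn$family == "UBA1", ]),
                     fx$homologs)
  expect_equal(uba$mechanism, "dna")
})

test_that("rescue calling pairs gains with losses and filters evidence", {
  fx <- yrescue_fixture()
  res <- run_pipeline(fx$homologs, fx$tree, fx$synteny,
                      evidence = fx$evidence)
  rep <- res$report
  expect_equal(rep$n_events, 8L)
  expect_equal(as.vector(table(rep$events$family)[c("EIF1A", "EIF2S3",
                                                    "RPS4", "UBA1")]),
               c(1L, 3L, 3L, 1L))
  excl <- rep$excluded
  expect_setequal(paste(excl$family, excl$carriers),
                  c("EIF1A cattle", "EIF2S3 cattle"))
  expect_true(all(excl$reason == "pseudogene"))
  # every rescue satisfies the three criteria by construction
  expect_true(all(rep$events$orf_status == "intact"))
  expect_true(all(rep$events$transcribed))
  expect_true(all(rep$events$recency == "keep"))
})

test_that("reports are deterministic and empty input yields an empty report", {
  fx <- yrescue_fixture()
  r1 <- run_pipeline(fx$homologs, fx$tree, fx$synteny,
                     evidence = fx$evidence)
  r2 <- run_pipeline(fx$homologs, fx$tree, fx$synteny,
                     evidence = fx$evidence)
  expect_identical(r1$report$events, r2$report$events)
  d1 <- tempfile(); d2 <- tempfile()
  write_event_report(r1$report, d1)
  write_event_report(r2$report, d2)
  expect_identical(readLines(paste0(d1, ".json")),
                   readLines(paste0(d2, ".json")))

  empty <- fx$homologs[0, ]
  r0 <- run_pipeline(empty, fx$tree, fx$synteny[0, ])
  expect_equal(r0$report$n_events, 0L)
})

test_that("planted rescues and pseudogenes are separated on simulated data", {
  ev <- rbind(
    data.frame(family = "G1", parent_class = "Y", branch_id = "mouse+rat",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE),
    data.frame(family = "G1", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = TRUE, recent = FALSE),
    data.frame(family = "G2", parent_class = "X", branch_id = "cattle",
               mechanism = "retro", pseudogenize = FALSE, recent = FALSE))
  losses <- rbind(
    data.frame(family = "G1", branch_id = "mouse+rat"),
    data.frame(family = "G2", branch_id = "cattle"))
  fam_sp <- list(G1 = c("human", "rhesus", "mouse", "rat", "cattle",
                        "opossum"),
                 G2 = c("human", "rhesus", "mouse", "cattle", "opossum"))
  cfg <- sim_config(family_species = fam_sp, event_specs = ev,
                    loss_specs = losses, seed = 72)
  sim <- simulate_family(cfg)
  es <- sim$homologs[sim$homologs$chrom_class == "A",
                     c("family", "species", "locus_id")]
  es$pattern <- "broad"; es$fold <- 1
  es$pattern[es$family == "G1" & es$species == "cattle"] <- "silent"
  es$fold[es$family == "G1" & es$species == "cattle"] <- 0.02
  carriers <- unique(sim$homologs[sim$homologs$chrom_class == "A",
                                  c("family", "species")])
  keep <- paste(sim$homologs$family, sim$homologs$species) %in%
    paste(carriers$family, carriers$species) &
    sim$homologs$chrom_class %in% c("A", "X")
  reads <- simulate_reads(sim$homologs[keep, ], es, depth = 60,
                          read_length = 75, error_rate = 0.005,
                          tissue_panel = cfg$tissue_panel, seed = 72)
  res <- run_pipeline(sim$homologs, cfg$tree, sim$synteny, reads = reads,
                      config = analysis_config(random_seed = 72))
  expect_equal(res$report$n_events, 2L)
  expect_setequal(paste(res$report$events$family,
                        res$report$events$branch_id),
                  c("G1 mouse+rat", "G2 cattle"))
  excl <- res$report$excluded
  expect_true(any(excl$family == "G1" & excl$carriers == "cattle" &
                    excl$reason == "pseudogene"))
})
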