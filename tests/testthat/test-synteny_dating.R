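rec <- function(species, locus, up, down, family = "G")
  data.frame(family = family, species = species, locus_id = locus,
             flanks_up = I(list(up)), flanks_down = I(list(down)))

test_that("synteny calls require shared, order-consistent flanks", {
  cfg <- analysis_config()
  a <- rec("mouse", "L1", c("G1", "G2"), c("G3", "G4"))
  b <- rec("rat", "L1", c("G1", "G2"), c("G3", "G4"))
  expect_true(is_syntenic(a, b, cfg))
  z <- rec("rat", "L2", c("H1", "H2"), c("H3", "H4"))
  expect_false(is_syntenic(a, z, cfg))

  # one shared symbol is not enough at the default threshold
  one <- rec("rat", "L3", c("G1", "Q2"), c("Q3", "Q4"))
  expect_false(is_syntenic(a, one, cfg))

  # inverted locus: two shared symbols in reversed order need a third
  inv2 <- rec("rat", "L4", c("G4", "G3"), c("Q1", "Q2"))
  expect_false(is_syntenic(a, inv2, cfg))
  inv3 <- rec("rat", "L5", c("G4", "G3"), c("G2", "Q2"))
  expect_true(is_syntenic(a, inv3, cfg))

  # symmetry over random flank lists
  set.seed(61)
  pool <- paste0("S", 1:12)
  for (k in 1:20) {
    r1 <- rec("a", "x", sample(pool, 2), sample(pool, 2))
    r2 <- rec("b", "y", sample(pool, 2), sample(pool, 2))
    expect_identical(is_syntenic(r1, r2, cfg), is_syntenic(r2, r1, cfg))
  }
})

test_that("locus groups partition the fixture's primate insertions correctly", {
  fx <- yrescue_fixture()
  eif2s3 <- fx$synteny[fx$synteny$family == "EIF2S3" &
                         fx$synteny$species != "cattle", ]
  groups <- locus_groups(eif2s3)
  expect_equal(length(groups), 3L)
  sp <- lapply(groups, function(g) sort(unique(g$species)))
  expect_true(any(vapply(sp, identical, TRUE, c("baboon", "rhesus"))))
  expect_true(any(vapply(sp, identical, TRUE,
                         c("marmoset", "squirrel_monkey"))))
  expect_true(any(vapply(sp, identical, TRUE,
                         c("chimpanzee", "gorilla", "human", "orangutan"))))

  single <- locus_groups(rec("mouse", "L1", "G1", "G2"))
  expect_equal(length(single), 1L)
  expect_equal(nrow(single[[1]]), 1L)

  # partition property: disjoint and covering
  memb <- attr(groups, "membership")
  expect_equal(length(memb), nrow(eif2s3))
  expect_true(all(memb >= 1 & memb <= length(groups)))
  expect_equal(sum(vapply(groups, nrow, 0L)), nrow(eif2s3))
})

test_that("a single simulated insertion inherited by two species forms one group", {
  ev <- data.frame(family = "G", parent_class = "X",
                   branch_id = "mouse+rat", mechanism = "retro",
                   pseudogenize = FALSE, recent = FALSE)
  cfg <- sim_config(family_species =
                      list(G = c("human", "mouse", "rat", "opossum")),
                    event_specs = ev, cds_length_codons = 60, seed = 62)
  sim <- simulate_family(cfg)
  a_syn <- sim$synteny[sim$synteny$locus_id != "X", ]
  groups <- locus_groups(a_syn)
  expect_equal(length(groups), 1L)
  expect_setequal(groups[[1]]$species, c("mouse", "rat"))
})

test_that("minimum origination ages are the deepest intra-group divergences", {
  tr <- yrescue_tree()
  expect_equal(min_origin_age(c("mouse", "rat"), tr), 25)
  expect_equal(min_origin_age(c("opossum", "wallaby"), tr), 88)
  expect_equal(min_origin_age("cattle", tr), 0)
  expect_error(min_origin_age(character(0), tr), "empty")

  # monotone: adding a species never decreases the bound
  set.seed(63)
  leaves <- tree_leaves(tr)
  for (k in 1:20) {
    grp <- sample(leaves, sample(2:4, 1))
    extra <- sample(setdiff(leaves, grp), 1)
    expect_gte(min_origin_age(c(grp, extra), tr), min_origin_age(grp, tr))
  }
})
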