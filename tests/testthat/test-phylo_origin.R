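test_that("codon alignment handles identity and clean in-frame indels", {
  set.seed(41)
  cds <- paste(c("ATG", random_codons(20)), collapse = "")
  aln <- align_codons(c(a = cds, b = cds))
  expect_false(grepl("-", aln$rows[["a"]]))
  expect_equal(aln$rows[["a"]], aln$rows[["b"]])

  # one extra codon in b -> a single 3-column gap in a's row
  ins <- paste0(substr(cds, 1, 3), "TGGTGGTGG", substr(cds, 4, nchar(cds)))
  aln2 <- align_codons(c(a = cds, b = ins))
  expect_equal(nchar(aln2$rows[["a"]]), nchar(cds) + 9)
  gaps <- regmatches(aln2$rows[["a"]],
                     gregexpr("-+", aln2$rows[["a"]]))[[1]]
  expect_equal(sum(nchar(gaps)), 9)
  expect_true(all(nchar(gaps) %% 3 == 0))
  expect_false(grepl("-", aln2$rows[["b"]]))
})

test_that("codon threading yields equal-length rows with codon-sized gaps", {
  set.seed(42)
  base <- paste(c("ATG", random_codons(30)), collapse = "")
  seqs <- c(s1 = base,
            s2 = evolve_codon_sequence(base, 0.1, 0.3)$cds,
            s3 = paste0(substr(base, 1, 30), "AAATTTGGG",
                        substr(base, 31, nchar(base))),
            s4 = evolve_codon_sequence(base, 0.2, 0.3)$cds)
  aln <- align_codons(seqs)
  lens <- nchar(aln$rows)
  expect_equal(length(unique(lens)), 1L)
  expect_equal(unique(lens) %% 3, 0)
  for (r in aln$rows) {
    runs <- regmatches(r, gregexpr("-+", r))[[1]]
    expect_true(all(nchar(runs) %% 3 == 0))
  }
  # untranslatable entries are dropped with a warning
  expect_warning(align_codons(c(a = base, b = base, z = "TAATAA")),
                 "untranslatable")
})

test_that("pairwise protein alignment score matches a brute-force oracle", {
  set.seed(43)
  aa <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "")
  for (rep in 1:12) {
    p1 <- paste(sample(aa, 3, replace = TRUE), collapse = "")
    p2 <- paste(sample(aa, sample(2:3, 1), replace = TRUE), collapse = "")
    got <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(got), oracle_align_score(p1, p2),
                 tolerance = 1e-9)
  }
})

test_that("neighbor-joining is exact on 3 taxa and additive matrices", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  pc <- ape::cophenetic.phylo(phy)
  expect_equal(pc[rownames(d), colnames(d)], d, tolerance = 1e-9)

  # 4-taxon additive metric recovers the generating split
  gen <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:3):0.5);")
  dm <- ape::cophenetic.phylo(gen)
  rec <- nj_tree(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), rec)), 0)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive topologies and matches ape's NJ", {
  set.seed(44)
  for (rep in 1:15) {
    gen <- random_additive_tree(sample(4:8, 1))
    dm <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(gen, rec)), 0)
    # independent route: ape's own neighbor-joining agrees on topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(dm), rec)), 0)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("degenerate equal distances give a deterministic tree", {
  d <- matrix(1, 5, 5) - diag(5)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("codon-column bootstrap flags no-signal input and is seeded", {
  set.seed(45)
  cds <- paste(random_codons(50), collapse = "")
  same <- align_codons(c(a = cds, b = cds, c = cds, d = cds))
  bt <- bootstrap_supports(same, 50, seed = 1)
  expect_true(bt$zero_information)
  expect_true(all(is.na(bt$supports)))

  # two deep clades -> near-certain split support
  anc <- random_cds(200)
  l <- evolve_codon_sequence(anc, 0.3, 0.5)$cds
  r <- evolve_codon_sequence(anc, 0.3, 0.5)$cds
  seqs <- c(a1 = evolve_codon_sequence(l, 0.02, 0.5)$cds,
            a2 = evolve_codon_sequence(l, 0.02, 0.5)$cds,
            b1 = evolve_codon_sequence(r, 0.02, 0.5)$cds,
            b2 = evolve_codon_sequence(r, 0.02, 0.5)$cds)
  aln <- align_codons(seqs)
  bt2 <- bootstrap_supports(aln, 100, seed = 9)
  expect_gte(split_support(bt2, c("a1", "a2")), 95)
  bt3 <- bootstrap_supports(aln, 100, seed = 9)
  expect_identical(bt2$supports, bt3$supports)
})

test_that("origin classification calls the parental gametolog on planted events", {
  spec_y <- data.frame(family = "G", parent_class = "Y",
                       branch_id = "mouse+rat", mechanism = "retro",
                       pseudogenize = FALSE, recent = FALSE)
  cfg <- sim_config(
    family_species = list(G = c("human", "rhesus", "marmoset", "mouse",
                                "rat", "cattle", "opossum")),
    event_specs = spec_y,
    loss_specs = data.frame(family = "G", branch_id = "mouse+rat"),
    seed = 46)
  sim <- simulate_family(cfg)
  hom <- sim$homologs
  copies <- lapply(seq_len(nrow(hom)), function(i)
    gene_copy(hom$family[i], hom$species[i], hom$chrom_class[i],
              hom$locus_id[i], cds = hom$cds[i]))
  aln <- align_codons(copies)
  bt <- bootstrap_supports(aln, 100, seed = 46)
  targets <- grep("__A__", aln$taxa, value = TRUE)
  og <- choose_outgroup(aln$taxa, c("mouse", "rat"), cfg$tree)
  expect_match(og, "opossum__X")
  call_y <- classify_origin(bt, "G", outgroup_taxa = og,
                            target_taxa = targets)
  expect_equal(call_y$verdict, "Y")
  expect_gte(call_y$support, 70)
  expect_true(all(grepl("__Y__", call_y$sister_taxa)))

  # invariance to input order of the copies
  aln2 <- align_codons(rev(copies))
  bt2 <- bootstrap_supports(aln2, 100, seed = 46)
  call2 <- classify_origin(bt2, "G", outgroup_taxa = og,
                           target_taxa = targets)
  expect_equal(call2$verdict, "Y")

  expect_error(classify_origin(bt, "G", outgroup_taxa = "yeti__X__X",
                               target_taxa = targets), "outgroup")
})
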