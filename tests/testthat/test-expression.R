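make_copy <- function(species, class, locus, cds)
  gene_copy("G", species, class, locus, cds = cds,
            mechanism_hint = if (class == "A") "retro" else "ancestral")

test_that("reads are assigned uniquely, ties discarded, totals conserved", {
  set.seed(51)
  x <- paste(random_codons(100), collapse = "")
  # autosomal copy differing at a handful of known sites
  a <- x
  for (p in c(30, 90, 150, 210)) substr(a, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  homs <- list(make_copy("m", "A", "A1", a), make_copy("m", "X", "X", x))

  reads <- data.frame(
    id = c("diag", "shared", "far"),
    seq = c(substr(a, 10, 59),            # spans diagnostic site 30
            substr(x, 240, 289),          # identical region in both copies
            strrep("ACGT", 13)),          # matches neither
    tissue = "testis", species = "m")
  asg <- assign_reads(reads, homs, mismatch_tolerance = 2)
  expect_equal(unname(asg$counts["m__A__A1", "testis"]), 1L)
  expect_equal(unname(asg$ambiguous[["testis"]]), 1L)
  expect_equal(unname(asg$unassigned[["testis"]]), 1L)
  expect_equal(sum(asg$counts) + sum(asg$ambiguous) + sum(asg$unassigned),
               nrow(reads))
  expect_error(assign_reads(reads, list()), "empty homolog")

  # reverse-complement reads map too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(a, 10, 59))))
  asg2 <- assign_reads(data.frame(id = "rc", seq = rc, tissue = "brain",
                                  species = "m"), homs, 2)
  expect_equal(unname(asg2$counts["m__A__A1", "brain"]), 1L)
})

test_that("seed-and-verify assignment equals the direct full scan", {
  set.seed(52)
  x <- paste(random_codons(80), collapse = "")
  a <- evolve_codon_sequence(x, 0.05, 1)$cds
  homs <- list(make_copy("m", "A", "A1", a), make_copy("m", "X", "X", x))
  starts <- sample.int(nchar(a) - 40, 60, replace = TRUE)
  seqs <- substring(c(a, x)[1 + (seq_along(starts) %% 2)],
                    starts, starts + 39)
  # sprinkle errors
  for (i in seq_along(seqs)) if (i %% 3 == 0) {
    p <- sample.int(40, 1)
    substr(seqs[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  reads <- data.frame(id = paste0("r", seq_along(seqs)), seq = seqs,
                      tissue = "testis", species = "m")
  fast <- assign_reads(reads, homs, 2)
  # direct route: exhaustive neditStartingAt over all offsets and strands
  direct_mm <- function(read, cds) {
    rd <- Biostrings::DNAString(read); s <- Biostrings::DNAString(cds)
    at <- seq_len(length(s) - length(rd) + 1)
    min(Biostrings::neditStartingAt(rd, s, starting.at = at,
                                    with.indels = FALSE),
        Biostrings::neditStartingAt(rd, Biostrings::reverseComplement(s),
                                    starting.at = at, with.indels = FALSE))
  }
  for (i in seq_along(seqs)) {
    mm <- vapply(homs, function(h) direct_mm(seqs[i], h$cds), 0)
    expected <- if (min(mm) > 2) "unassigned"
      else if (sum(mm == min(mm)) > 1) "ambiguous"
      else paste("m", c("A", "X")[which.min(mm)],
                 c("A1", "X")[which.min(mm)], sep = "__")
    expect_equal(fast$assignments$assigned_to[i], expected,
                 label = paste("read", i))
  }
})

test_that("expression ratios are length-normalised and scale-invariant", {
  expect_equal(expression_ratio(100, 1000, 100, 1000), 1.0)
  expect_equal(expression_ratio(50, 500, 100, 1000), 1.0)
  expect_equal(expression_ratio(0, 1000, 100, 1000), 0.0)
  und <- expression_ratio(10, 1000, 0, 1000)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(expression_ratio(-1, 1000, 5, 1000), "negative")
  for (c_mult in c(2, 10)) {
    expect_equal(expression_ratio(30 * c_mult, 600, 90 * c_mult, 900),
                 expression_ratio(30, 600, 90, 900))
  }
})

test_that("transcription evidence and pattern classification follow thresholds", {
  cfg <- analysis_config()
  prof <- structure(list(copy = "c",
                         counts = c(brain = 0, liver = 0, testis = 0),
                         normalized = c(brain = 0, liver = 0, testis = 0)),
                    class = "expression_profile")
  expect_false(has_transcription_evidence(prof, cfg))
  expect_equal(classify_pattern(prof, config = cfg)$pattern, "silent")

  prof$counts <- c(brain = 0, liver = 0, testis = 10)  # inclusive boundary
  prof$normalized <- prof$counts / 0.9
  expect_true(has_transcription_evidence(prof, cfg))
  expect_equal(classify_pattern(prof, config = cfg)$pattern,
               "testis_specific")

  prof$counts <- c(brain = 40, liver = 40, testis = 40)
  prof$normalized <- prof$counts / 0.9
  pat <- classify_pattern(prof, config = cfg)
  expect_equal(pat$pattern, "broad")
  expect_equal(pat$breadth, 3L)

  prof$counts <- c(brain = 20, liver = 15, testis = 200)
  prof$normalized <- prof$counts / 0.9
  expect_equal(classify_pattern(prof, config = cfg)$pattern,
               "testis_specific")

  expect_error(classify_pattern(prof, tissue_panel = c("brain", "liver")),
               "testis")
})

test_that("simulated reads recover assignment accuracy and A:X ratios", {
  set.seed(53)
  x <- random_cds(300)
  a <- evolve_codon_sequence(x, 0.052, 1)$cds   # ~5% diverged paralog
  copies <- data.frame(family = "G", species = "m",
                       chrom_class = c("A", "X"), locus_id = c("A1", "X"),
                       has_introns = FALSE, mechanism_hint = "unknown",
                       cds = c(a, x))
  reads <- simulate_reads(copies, depth = 700, read_length = 75,
                          error_rate = 0.01,
                          tissue_panel = c("brain", "testis"), seed = 53)
  homs <- list(make_copy("m", "A", "A1", a), make_copy("m", "X", "X", x))
  asg <- assign_reads(reads, homs, 2)
  hit <- asg$assignments$assigned_to
  truth <- reads$truth_copy
  assigned <- !(hit %in% c("ambiguous", "unassigned"))
  expect_gte(mean(hit[assigned] == truth[assigned]), 0.90)
  # both copies got >= 500 assigned reads; A:X ratio within 15% of truth (1)
  expect_gte(min(rowSums(asg$counts)), 500)
  ratio <- expression_ratio(sum(asg$counts["m__A__A1", ]), nchar(a),
                            sum(asg$counts["m__X__X", ]), nchar(x))
  expect_lt(abs(ratio - 1), 0.15)
})
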