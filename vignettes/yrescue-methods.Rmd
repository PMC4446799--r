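---
title: "Methods: detecting autosomal rescue of Y-linked gene loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting autosomal rescue of Y-linked gene loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, thresholds and
design choices. Every stage of the pipeline is a stated, testable rule;
where the underlying biology admits more than one reasonable
formalisation, the choice made here is declared and its rationale given.

## The inference problem

Across a set of mammalian species with known X/Y/autosomal homolog
content, we want to identify autosomal copies of sex-linked genes that
plausibly *rescue* a lineage-specific loss of the Y-linked copy, and to
characterise each event: which gametolog it came from, when it happened
(at the latest), by what mechanism (retrotransposition vs DNA
transposition), and whether the copy behaves like a functional gene.

The pipeline is a funnel of explicit filters. A candidate autosomal copy
becomes part of a rescue event only if it (i) keeps an intact open
reading frame relative to its sex-linked counterpart, (ii) shows
transcription evidence, and (iii) is not so recently derived (< 2%
nucleotide divergence from the parental copy) that selection cannot yet
have vetted it. Gains and Y losses are placed on a dated species tree by
Dollo parsimony and paired by lineage overlap.

## Dated species tree

The packaged tree covers thirteen species with TimeTree-style divergence
dates in millions of years and is validated as ultrametric (leaf depths
equal within a relative tolerance of 1e-6). Two dates act as anchors for
the dating bounds: the mouse–rat split at 25 mya and the opossum–wallaby
split at 88 mya; the remaining node ages are conventional round figures
(human–chimpanzee 6, great-ape crown 16, catarrhine–platyrrhine 43,
primate–rodent 90, boreoeutherian 96, eutherian–marsupial 160). Branches
are identified by the sorted set of leaves below them
(e.g. `mouse+rat`), which is stable under any tree reordering.

Gene families that do not exist in part of the tree (e.g. genes in the
X/Y-added region, which marsupials lack) are analysed on the induced
subtree of the species actually scored; presence/absence is never
extrapolated to unscored species.

## ORF integrity

`scan_orf()` translates in frame 0 with the standard code; codons
containing `N` translate to unknown and are never counted as stops (the
real data motivating this rule are assembly gaps). A stop in the final
in-frame codon slot is terminal, anything earlier is premature.
`assess_integrity()` then classifies a candidate against its sex-linked
reference:

* **intact** — no premature stop, length a multiple of 3, and ORF length
  at least `orf_length_ratio_min` (default 0.95) of the reference ORF;
* **truncated** — clean frame but below the length ratio. The 0.95
  default operationalises "slightly truncated" as non-intact: combined
  with weak expression it is what demotes a barely transcribed,
  marginally shortened retrocopy to pseudogene status;
* **disrupted** — premature stop or broken frame.

A disrupted *reference* (it happens: an X-linked copy can itself carry an
ORF-disrupting mutation) triggers a warning but not an error, since the
comparison is still informative.

## Divergence, the recency filter, and dN/dS

Pairwise divergence is the uncorrected proportion of differing sites
(`p_distance`), with gap/`N` columns excluded pairwise. The recency
filter dismisses copies with `p < 0.02`, strict inequality, and is
deliberately applied to the *uncorrected* distance: at 2% the JC
correction is negligible and the plain proportion matches how such
thresholds are quoted.

dN/dS uses the Nei–Gojobori (1986) counting method with equal pathway
weighting:

* per codon, the nine single-base mutations are enumerated; mutations to
  stop codons are removed from the denominator, so the synonymous and
  nonsynonymous site fractions still sum to 1 per position and
  *S* + *N* = 3 per codon exactly (this is asserted to 1e-9 in tests);
* differences between a codon pair are averaged over all orderings of the
  differing positions whose intermediates avoid stop codons; a codon pair
  whose every pathway crosses a stop is skipped with a warning;
* proportions are Jukes–Cantor corrected,
  d = −(3/4)·ln(1 − (4/3)p), undefined at p ≥ 0.75;
* ω = dN/dS, with one declared edge rule: when every observed difference
  is synonymous (dN = 0, Sd > 0), ω is 0 even if dS itself is saturated
  or the synonymous proportion exceeds the JC domain — this happens on
  very short inputs, where pS = Sd/S can exceed 1. Otherwise ω is
  *undefined* (never infinity) when dS is 0 or undefined.

The per-codon site counts and pathway-averaged difference counts are
precomputed once for all 64×64 codon pairs and cached, making the
estimator a table lookup; the tests compare those tables against an
independent depth-first pathway enumeration written differently on
purpose.

A counting method was chosen over maximum-likelihood codon models because
it is self-contained, exactly oracle-checkable, and adequate for the
magnitude-level question asked of it here (ω ≪ 1 vs ω ≈ 1). ML estimates
from other tools will differ in the third decimal; comparisons at
two significant figures are the intended use.

## Alignment, trees and parental origin

`align_codons()` aligns translated proteins and back-threads the result
onto codons, so gap runs are always codon-sized. The protein alignment is
progressive in the simplest robust sense: a centre sequence (highest mean
percent identity) is chosen, all others are globally aligned to it
(Needleman–Wunsch, BLOSUM62, gap opening 10, extension 0.5), and the
pairwise alignments are merged on the centre's coordinates, taking the
maximum insertion length per centre position. Sequences are translated to
their first stop; untranslatable entries are excluded with a warning.
When two proteins have equal length, percent identity for centre
selection is computed ungapped — a pure speed optimisation that cannot
change any alignment.

Trees are neighbor-joining (Saitou–Nei) on JC-corrected nucleotide
distances with pairwise deletion. Three numerical rules make the
implementation deterministic and safe:

* ties in the Q-criterion are broken by the lexicographically smallest
  pair of cluster labels (a cluster is labelled by its smallest leaf);
* negative branch-length estimates are clamped to zero with the deficit
  moved to the sibling branch, preserving the joined pair's path length;
* saturated distances (p ≥ 0.75) are capped at 10 substitutions/site so
  a single saturated pair cannot abort a bootstrap replicate.

Support comes from resampling *codon columns* (respecting the codon
threading) with replacement; the support of a split is the percentage of
replicate NJ trees containing it. An alignment with no variable columns
yields `NA` supports flagged `zero_information` — reporting 100 for an
arbitrary topology would be misleading. The default of 100 replicates is
the study condition; it is configurable.

`classify_origin()` roots the family tree on a declared outgroup — by
rule, the X-linked copy of the earliest-diverging non-carrier species
(marsupials when present) — and examines the focal autosomal tip or
clade: if its sister group consists solely of Y-linked copies, the
verdict is Y; symmetrically for X; anything else (mixed sister,
non-monophyletic focal set, weak support) is unresolved. The support
attached to the verdict is, in order of preference, the split placing the
focal clade *inside the full clade of the parental gametolog class*, then
the focal-plus-sister split, then the focal clade split. The first is the
phylogenetically meaningful quantity — "this copy descends from the Y" —
and is robust to the short internal branches that surround a duplication
node, which can legitimately leave the exact sister relationship
uncertain while class membership is certain. Verdicts require support at
or above `bootstrap_support_min` (default 70, configurable; no published
threshold exists for this kind of claim).

## Expression

Reads are assigned to homologs by best ungapped alignment over all
offsets and both strands: a read goes to the homolog with strictly the
fewest mismatches, provided that minimum is at most `mismatch_tolerance`
(default 2); ties are discarded as ambiguous rather than split
fractionally, because fractional splitting biases the autosome:X ratio
toward the longer copy. The implementation is seed-and-verify (pigeonhole
over `tolerance + 1` non-overlapping exact seeds, then Hamming
verification of candidate placements), which is exact for every value at
or below the tolerance; the test suite checks it read-by-read against a
direct full scan. Gapped alignment is intentionally out of scope: the
synthetic reads contain no indels and the statistic of interest is a
count ratio, not a spliced alignment.

Expression levels are reads per kb of CDS; the autosome:X ratio is
`(countsA/lenA)/(countsX/lenX)`, flagged undefined when the X copy has
zero assigned reads. A copy is *transcribed* when at least
`min_reads_expressed` (default 10) reads land on it in at least one
tissue — this is also the operationalisation of "barely detectable":
below threshold in every tissue. Breadth is the count of tissues at or
above that threshold (the count-of-expressed-tissues definition is this
package's declared definition). The pattern is `silent` at breadth 0;
`testis_specific` when the copy is expressed in testis and its
length-normalised testis level is at least `testis_fold_min` (default 5)
times the best non-testis level; otherwise `broad`. A copy expressed in
exactly one non-testis tissue therefore falls into `broad` — the
three-way partition has no better slot for it, and the case does not
arise in the scenarios modelled.

## Synteny and dating

Two loci in different species are syntenic — one insertion event — when
they share at least `synteny_min_shared_flanks` (default 2) flanking
ortholog symbols in consistent relative order, measured by the longest
common subsequence of the ordered flank lists. A locus pair whose shared
flanks agree only after reversal (an inversion) needs one extra shared
symbol: inversions within a conserved neighbourhood are real, but a
2-symbol reversed match is too weak. Locus groups are the transitive
closure of pairwise synteny; each group is a candidate origination event,
and its minimum age is the deepest divergence among its carrier species —
a lower bound, since the insertion must predate it. Singletons carry no
bound (0).

The packaged fixture's flank identifiers are synthetic placeholder
symbols that encode only the grouping structure (which loci share an
insertion context); they are not the real genomic neighbours.

## Dollo placement and rescue calling

Y presence/absence per family is modelled under Dollo parsimony: one
origin at the (induced) root, losses irreversible. The minimal loss set
is exactly the set of maximal all-absent clades, found directly; tests
verify minimality against exhaustive search over all branch subsets on
small trees. Gains are placed on the stem of the MRCA of each locus
group's carriers. Locus groups of the same family on the same branch are
collapsed into one gain event — at branch granularity they are one
addition arrow, even when two loci were inserted (the marsupial
ribosomal-protein case); per-locus detail is preserved in the event
record. This collapse rule is what makes event counts well-defined.

A gain becomes a rescue event when (i) its carriers and a same-family
Y loss overlap — either every carrier lies in a lost lineage, or the lost
lineage is a subset of the carriers (an old gain predating the loss);
both temporal orders are admitted and the ordering is *reported*, because
presence/absence data cannot distinguish "loss then rescue" from "gain
then relaxed selection on Y" — and (ii) at least one carrier copy passes
all three functionality criteria. Exclusions are reported with reasons:
`pseudogene` (ORF defect or no transcription), `recent` (only the
recency filter failed), `no_matching_loss`, `no_evidence`. A defective
ORF takes precedence over a missing loss in the reason, since a dead copy
is a pseudogene wherever it sits.

## The synthetic-data generator

`evolve_codon_sequence()` is a mutation–rejection codon model: attempted
point mutations are Poisson with mean branch-length × sites; synonymous
changes are always accepted, nonsynonymous with probability ω, mutations
to stops rejected. Realised dN/dS therefore equals ω in expectation —
this is the property the estimator-recovery tests rely on — at the price
of not modelling transition/transversion bias, codon frequencies, or
rate variation. A full rate-matrix simulator would be more realistic but
not oracle-simple.

`simulate_family()` evolves an ancestral CDS into X and Y gametologs
splitting at `gametolog_split_my` (default 180 mya, at least the tree
height, so every species carries both gametologs), then down the species
tree under per-class ω (defaults: X 0.05, Y 0.10, autosomal functional
0.05, pseudogene 1.0). Planted events tap the parental lineage at the
*midpoint* of the chosen branch, so the new copy shares the parent's
first-half mutations and the gene tree genuinely contains the
duplication node; pseudogenisation inserts one in-frame stop at a
uniform internal codon immediately after duplication; "recent" events
copy a terminal-branch parent with ~1% neutral divergence, landing under
the 2% filter by construction. DNA-transposition events carry their
parent chromosome's flank symbols (so synteny can see the mechanism);
retro events get a fresh context shared by all carrier descendants.

Simulation defaults are study conditions, chosen once: neutral rate
0.005 substitutions/site/my (a mammalian-average figure; fast enough
that events planted on short primate branches accumulate measurable
divergence), CDS length 300 codons, read length 75, per-base error 0.005,
four tissues including testis, and read depth 60 reads/kb/tissue in the
standard scenario — depths at which every expressed copy sits far above
the 10-read detection threshold while the full 20-replicate end-to-end
battery stays within a routine test run. The standard scenario
(`simulate_study()`) plants ten events in four families mirroring the
canonical rescue configurations: one Y-derived rodent retrogene plus a
cattle pseudogene; three independent X-derived primate retrogenes plus a
recent pseudogenised cattle copy; three independent retrogenes in
rodents, marsupials and cattle; one Y-derived DNA transposition in
marmoset. Eight are true rescues; two must be excluded.

What the generator does *not* emulate: indels (alignment is exercised by
constructed indel cases instead), splice variation and introns beyond a
presence flag, GC/isochore structure, expression noise beyond Poisson
sampling, and genuinely unresolved origins (the real marsupial case where
X- vs Y-parentage is unknowable). Passing the end-to-end battery
therefore shows the machinery is correct under the declared model, not
that real genomes will be as clean; in particular, real bootstrap
supports and origin calls will be weaker than simulated ones.

## Problem sizes in the test suite

The oracle batteries run at the sizes that make them exhaustive where
exhaustiveness is the point: all 64×64 codon-pair counts against a DFS
oracle via 1000 random short pairs; all presence/absence patterns on
trees of 4–6 leaves against brute-force minimal-set search; 25 random
additive trees of up to 8 taxa for NJ; ω recovery at 10 kb for
ω ∈ {0.05, 0.5, 1.0} within ±30% relative error; and 20 seeded
end-to-end replicates of the standard scenario, of which at least 19 must
match the planted truth exactly (one unresolved origin call is allowed).

## Known limitations

* Origin calls are topological; no likelihood-based test of alternative
  placements is performed, and a duplication landing exactly at a
  speciation node is intrinsically unresolvable at the sister level.
* The recency filter uses a fixed 2% cutoff; lineages with unusual
  substitution rates would deserve a rate-scaled threshold.
* Dollo parsimony cannot see a loss followed by re-gain on the Y, and
  presence/absence scored from incomplete assemblies will propagate into
  loss placement.
* dN/dS here is a pairwise counting estimate; it is not a substitute for
  codon-model branch tests when ω is near 1.
* The expression module quantifies CDS-level read support only; isoform
  structure and spliced alignment are out of scope.
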