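---
title: "Models and methods behind gbsforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbsforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gbsforge` emulates the computational arm of a restriction-enzyme
genotyping-by-sequencing (GBS) study: enzyme selection by in silico
digestion, multiplexed library simulation, tag-based SNP discovery with
the standard coverage/frequency filters, and the validation statistics
used to certify such callsets. This vignette records the models, the
parameter choices and their rationale, the numerical conventions, and
what the synthetic world does and does not establish.

## Digestion model

Digestion is exact-motif matching on the forward strand. Only palindromic
recognition sites are supported (both classical GBS screening enzymes,
PstI `CTGCA^G` and SbfI `CCTGCA^GG`, are palindromic), which makes a
reverse-strand scan redundant and avoids strand bookkeeping. Coordinates
are 0-based half-open throughout; the cut point is `motif start +
cut_offset`. Terminal (chromosome-end) fragments are counted and all
sequences of an assembly are digested — a stated convention, because
published fragment totals rarely say whether terminal fragments or
unplaced scaffolds were included, and the difference is exactly one
fragment per sequence. Motif occurrences overlapping an ambiguous base
(N) never match, so assembly gaps are handled without special cases.
The size-selection window is inclusive on both bounds ("between 200 and
500 bp" read inclusively); narrowing it can only shrink the selection.

The *cut-site remnant* is the motif prefix up to the cut (PstI: `CTGCA`),
following the GBS literature's convention for the expected read prefix
after the inline barcode. The sticky-end chemistry would instead leave
`TGCAG` at the read start; both are expressible (`gbs_enzyme()` takes a
custom remnant), but the simulator, demultiplexer and tag aligner share
the prefix convention, and the palindromic symmetry makes the
reverse-strand read of a fragment's far end begin with the same remnant.
Each retained fragment therefore contributes two tag windows of exactly
64 genomic bases anchored at its two cut sites, one per strand
(`tag_footprints()`), and those windows are the package's operational
definition of "within 64 bp of a cut site".

## The synthetic world

The generator emulates the chicken-style study design at desk scale. Its
defaults are the stated world of the tests and are not tuned:

* **Genome** — 10 chromosomes totalling ~10 Mb in three size classes
  (2 large of 2.5 Mb, 3 medium of 1 Mb, 5 micro of 0.4 Mb), i.i.d.
  sequence at GC 0.42 (the chicken genome is ~42% GC). I.i.d. sequence has
  no repeats, so tag alignment is easier than on a real genome; the
  multi-mapping tie rule is exercised by dedicated constructed fixtures
  instead.
* **Truth variants** — density 0.01/bp, emulating a whole-genome
  resequencing truth set between strongly divergent lines (roughly
  12 × 10⁶ SNPs on a ~1 Gb genome). 80% of variants are fixed-divergent
  between the TT and CC founder pools; the rest are shared-polymorphic
  with alternative-allele frequency uniform on [0.05, 0.95]. Variants are
  strictly biallelic SNPs, and positions inside the digestion enzyme's
  motif occurrences are avoided so that planted variants never silently
  destroy a cut site (real allele dropout at polymorphic cut sites is out
  of scope).
* **Pedigree** — 5 + 5 founders, 8 F1 from TT×CC couples, F2 families
  from F1 males mated to non-full-sib F1 females. Founder residual
  heterozygosity at shared sites is tuned to ≈ 0.25 by an
  inbreeding-style homozygosity excess. Transmission uses a Haldane
  (no-interference) Markov walk with inter-site crossover probability
  `0.5 (1 − exp(−2 · rate · d))` at 3 × 10⁻⁸ crossovers/bp (≈ 3 cM/Mb);
  Kosambi is used only for map-distance reporting, mirroring the
  ordinary division of labour between a generative model and a mapping
  function. Sexes alternate; no sex chromosomes are simulated.
* **Reads** — single-end 100 bp, both fragment ends. Per (sample, tag
  site) counts are negative-binomial with mean depth 8 (tests use 10)
  and size 2; GBS depth is strongly overdispersed, and size 2 at mean 10
  gives a ~97% per-taxon call rate, matching the call-rate regime of real
  48-plex runs. Base errors are i.i.d. at 0.5% over the whole read, with
  quality Q35 everywhere except Q10 at error positions — a deliberately
  simple quality model that makes the Phred ≥ 24 trimming rule testable.

Because the pedigree is produced by gamete sampling, truth genotypes have
exactly zero Mendelian errors, F1 individuals are heterozygous at every
fixed-divergent site, and F2 heterozygosity at those sites is 1/2 in
expectation; these are the anchors for the validation-statistics tests.

## Tag processing and calling

Demultiplexing is exact: a read is assigned iff it begins with
`barcode + remnant`. Barcode sets are built greedily under the published
constraints — no recognition motif inside a barcode, pairwise Levenshtein
distance ≥ 3, prefix-freeness of `barcode + remnant` (which makes
assignment unambiguous), variable lengths 4–8 with positional base
balance minimized. Longer lengths get more slots because the code space
at distance ≥ 3 grows with length, and a deletion between lengths costs
only one edit.

Tags are the first 64 bases of a demultiplexed read (remnant included),
truncated first at any internal full recognition site (read-through into
the next fragment; the cut-site copy at the very start of every read does
not count). Reads left shorter than 64 bases are discarded rather than
poly-A padded as Tassel does: padding manufactures artificial tag
sequences, and discarding keeps the catalog a pure function of genomic
64-mers. This is a documented divergence from Tassel's behaviour.

Alignment replaces a general short-read aligner with a cut-site-anchored
search: candidate placements are the two 64-mer windows at every cut site
of the reference, and a tag is placed at the unique candidate minimizing
Hamming mismatches with at most 3; ties leave it unaligned
(multi-mapping exclusion). A pigeonhole seed search (a tag within 3
mismatches matches at least one of 4 16-mer chunks exactly) keeps this
linear in practice. The simplification is sound because genuine GBS tags
can only originate at cut sites.

Genotypes are called per locus column from allele depths `(dref, dalt)`
by maximum likelihood with a fixed per-read error rate ε = 0.01:
`L(homRef) = (1−ε)^dref ε^dalt`, symmetric for homAlt, and
`L(het) = 0.5^(dref+dalt)`; zero depth or ties give a missing call. The
exact genotype rule of the original Tassel pipeline is unpublished; this
documented rule is simple, testable in closed form, and reproduces the
canonical GBS behaviour — at depth ≤ 6 a single discordant read calls a
heterozygote, and heterozygotes sampled one-sided at low depth are
undercalled as homozygotes, which is precisely the het-deficit signature
real GBS studies report.

An alternative allele is *present* at a column only if it carries ≥ 1% of
the locus read depth (`min_allele_frac`). This threshold is the package's
interpretation of "the two most frequent alleles define the site":
without it, at realistic depths nearly every true SNP column would be
declared multi-allelic by sporadic third-allele sequencing errors.
Columns with two or more present alternatives are recorded and excluded,
as in the published analysis. In small cohorts (a few dozen taxa) one or
two error-driven heterozygote calls can still clear the MAF gate, so
small-scale callsets contain a visible false-positive fraction; the
acceptance-scale run (118 taxa) does not.

Filters run in the published order: taxa below 20% call rate are removed
first (the study removed 2 of 464 individuals before reporting any
site-filtered count), then sites below 90% call rate or 1% minor allele
frequency. The duplicate-site rule (`misMat`) is applied to co-located
sites called from different tag loci: groups whose genotype mismatch rate
over taxa called in both exceeds 5% are removed entirely, otherwise
merged missing-aware (conflicting calls become missing, depths are
summed). The misMat semantics are not fully specified in the source
material; this interpretation mirrors the duplicate-SNP merge intent of
the original pipeline and is flagged as such.

## Validation statistics

Genotype concordance excludes missing calls pairwise (not listwise), to
maximize comparisons. The heterozygote section reports all three
denominators in circulation — either-callset-het, reference-het, and
both-het — because published heterozygote-validation percentages are
ambiguous about which is intended; any convention can be read off the
report. The both-het agreement is trivially 100% for biallelic sites
whose alleles match, so values below 100% indicate allele-identity
disagreements. Mendelian testing uses the full 3×3 transmission table
for trios (anything is compatible with het × het), a share-an-allele rule
for duos, and skips sites with any missing member; per-family summaries
are mean ± SD of per-individual error counts and percent of markers.

## Linkage

Markers are classified from the F1 parents' genotypes (AA×AB, AB×AA,
AB×AB); segregation distortion is tested per family with Pearson χ²
against 1:2:1 (df 2) or 1:1 over the two observable classes (df 1) and
markers with p < 0.001 are dropped. Two-point recombination fractions
use direct recombinant counting for pairs informative in one shared
parent (pseudo-testcross; phase chosen to minimize r), and an EM
maximum-likelihood estimate under the F2 intercross 3×3 cell likelihood
for AB×AB pairs, run under both linkage phases with the better
likelihood kept — which also makes the estimate invariant to allele
relabeling. The EM iterates the expected recombinant-gamete count until
the log-likelihood moves by < 10⁻⁸; the vectorized all-pairs version
iterates until every pair converges, so single-pair and all-pairs
estimates agree to EM precision rather than machine precision. Mixed
pairs (one single-parent-het, one AB×AB) use only meioses informative in
the shared parent: the shared parent's transmitted allele at an AB×AB
marker is determinable exactly when the offspring is homozygous there,
and that conditioning is unbiased. Grouping is connected components of
the LOD ≥ 8 ∧ r ≤ 0.35 graph, with singletons reported unlinked and
groups spanning several reference chromosomes flagged fragmented. Marker
ordering and multipoint map construction are out of scope (they were
external-tool contributions in the source workflow).

In the linkage acceptance simulation (5 chromosomes × 40 markers,
200 F2), chromosomes are 1 Mb with a crossover rate of 10⁻⁶/bp, i.e.
~1 Morgan of genetic length per chromosome — genetically realistic for a
macrochromosome even though physically compressed, so adjacent markers
sit ~2.5 cM apart and chromosome ends are effectively unlinked within a
group while the adjacency chain keeps each chromosome one component.

## Annotation

Variants are classified per overlapping transcript: intron (or splicing
within 2 intronic bases of an edge — the canonical splice-site width, as
the source tables give none), exon with strand-aware codon translation
for CDS positions (synonymous / non-synonymous / start-lost /
stop-gained / stop-lost), 5′/3′ UTR, ncRNA exon, and 1 kb upstream /
downstream flanks; a variant touching nothing is intergenic. One variant
may carry annotations from several transcripts. Start-gain is not
implemented: the source's category table lists start-lost/stop-gain/
stop-lost only, and its prose mention of "startgain" conflicts with that
table. SIFT-style deleteriousness is out of computational scope (it
requires homology databases); the ≤ 0.05 classification rule for
externally supplied scores is the only hook.

## What a green test establishes — and what it does not

The synthetic world has no repeats, no indels or structural variants, no
PCR duplicates, no lane effects, no methylation sensitivity, and no
allele dropout at polymorphic cut sites. Green end-to-end tests
therefore establish that the pipeline's logic is correct — conservation
of reads through every stage, exact demultiplexing, correct allele
accounting, filter semantics, and statistically faithful recovery of
planted truth — not that real-genome performance figures (mapping rates,
concordance percentages against an independent resequencing callset)
would be reproduced. The published real-data headline numbers depend on
unreleased raw reads and are represented here by property-based
analogues: discovery ≥ 95% of cohort-segregating variants in tag
footprints, homozygous concordance ≥ 99.5%, both-het agreement ≥ 99%,
zero Mendelian errors on truth and proportional response to injected
errors, and exact recovery of the simulated chromosome partition by
LOD 8 / rf 0.35 grouping.

Two source-data inconsistencies are handled explicitly. The five F2
family sizes (72, 82, 94, 100, 96) sum to 444, not the stated 446, so
the full design totals 462 birds (10 F0 + 8 F1 + 444 F2) — matching the
"462 analysed" figure used elsewhere — and the simulator follows the
per-family arithmetic. And the claim that 40% of SbfI fragments exceed
15 Mb is not reproducible under any digestion convention tried; it is
not modelled.

## Numerical conventions

Randomness funnels through one integer master seed; each stage derives
its own 32-bit sub-seed, so stages are reproducible independently and
whole runs are bit-identical under a fixed configuration. Likelihood
ties and zero depth yield missing genotypes rather than arbitrary calls.
EM recombination fractions are clamped to [10⁻⁹, 0.5] and reported LOD
is never negative. The Kosambi function `d = 25 ln((1+2r)/(1−2r))` is
undefined at r ≥ 0.5 and errors there; its closed-form inverse
`r = tanh(d/50)/2` is exact.
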