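## hand-built single-gene world for codon-level cases: one plus-strand gene
## with 5'UTR 0..9, CDS 10..27 (6 codons), 3'UTR 28..37, flanks beyond
codon_world <- function(cds_codons = c("ATG", "GCT", "TGG", "TAC", "AAA", "TAA"),
                        strand = "+") {
  cds <- paste(cds_codons, collapse = "")
  left <- strrep("T", 1500)
  utr5 <- strrep("A", 10); utr3 <- strrep("A", 10)
  right <- strrep("T", 1500)
  exonseq <- paste0(utr5, cds, utr3)
  if (strand == "-") exonseq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(exonseq)))
  g <- Biostrings::DNAStringSet(c(chr = paste0(left, exonseq, right)))
  tstart <- 1500L; tend <- tstart + 38L
  mk <- function(type, s, e) data.table::data.table(
    gene_id = "g1", transcript_id = "t1", chrom = "chr", strand = strand,
    type = type, start = s, end = e, biotype = "coding")
  fx <- rbind(mk("exon", tstart, tend),
              if (strand == "+") rbind(mk("five_prime_UTR", tstart, tstart + 10L),
                                       mk("CDS", tstart + 10L, tstart + 28L),
                                       mk("three_prime_UTR", tstart + 28L, tend))
              else rbind(mk("three_prime_UTR", tstart, tstart + 10L),
                         mk("CDS", tstart + 10L, tstart + 28L),
                         mk("five_prime_UTR", tstart + 28L, tend)))
  list(genome = g, fx = fx, cds_start = tstart + 10L)
}

variant_at <- function(w, pos, alt) {
  ref <- substring(as.character(w$genome[[1]]), pos + 1, pos + 1)
  data.table::data.table(chrom = "chr", pos = as.integer(pos), ref = ref,
                         alt = alt, id = paste0("chr:", pos))
}

test_that("codon-level consequences classify the enumerated cases", {
  w <- codon_world()
  cs <- w$cds_start
  cat1 <- function(v) annotate_variants(v, w$fx, w$genome)$category
  ## GCT -> GCC (Ala -> Ala): synonymous at codon 2, third base
  expect_equal(cat1(variant_at(w, cs + 5L, "C")), "exonic:synonymous")
  ## ATG -> GTG: start lost
  expect_equal(cat1(variant_at(w, cs, "G")), "exonic:start-lost")
  ## TGG -> TGA: stop gained (codon 3, third base)
  expect_equal(cat1(variant_at(w, cs + 8L, "A")), "exonic:stop-gained")
  ## terminal TAA -> CAA: stop lost
  expect_equal(cat1(variant_at(w, cs + 15L, "C")), "exonic:stop-lost")
  ## TAC -> TAT (Tyr -> Tyr): synonymous; TAC -> GAC: non-synonymous
  expect_equal(cat1(variant_at(w, cs + 11L, "T")), "exonic:synonymous")
  expect_equal(cat1(variant_at(w, cs + 9L, "G")), "exonic:non-synonymous")
  ## UTRs and flanks
  expect_equal(cat1(variant_at(w, 1505L, "C")), "5'UTR")
  expect_equal(cat1(variant_at(w, cs + 20L, "C")), "3'UTR")
  expect_equal(cat1(variant_at(w, 1000L, "C")), "upstream1kb")   # 500 bp 5'
  expect_equal(cat1(variant_at(w, 1540L, "C")), "downstream1kb")
  expect_equal(cat1(variant_at(w, 100L, "C")), "intergenic")     # >1 kb away
  ## ref mismatches are rejected with the position named
  bad <- variant_at(w, cs, "G"); bad$ref <- "N"
  expect_error(annotate_variants(bad, w$fx, w$genome), "ref allele mismatch")
})

test_that("minus-strand codon logic mirrors the plus strand", {
  w <- codon_world(strand = "-")
  ## the CDS runs right-to-left; its genomic footprint is [cs, cs+18)
  cs <- w$cds_start
  ## last genomic base of the CDS footprint = first CDS base (ATG's A)
  v <- variant_at(w, cs + 17L, setdiff(c("A", "C", "G", "T"),
                                       substring(as.character(w$genome[[1]]),
                                                 cs + 18L, cs + 18L))[1])
  cat <- annotate_variants(v, w$fx, w$genome)$category
  expect_equal(cat, "exonic:start-lost")
})

test_that("annotation equals the brute-force interval classifier", {
  g <- simulate_genome(c(3e5), "large", seed = 61)
  res <- simulate_gene_models(g, 12, ncrna_fraction = 0.15, seed = 62)
  v <- plant_variants(res$genome, density = 2e-3, seed = 63)
  ann <- annotate_variants(v, res$features, res$genome)
  oracle <- oracle_annotate(as.data.frame(v), as.data.frame(res$features),
                            res$genome)
  a <- sort(paste(ann$variant_id, ann$transcript_id, ann$category))
  b <- sort(paste(oracle$variant_id, oracle$transcript_id, oracle$category))
  expect_equal(a, b)
  ## every variant receives at least one category
  expect_setequal(unique(ann$variant_id), v$id)
  ## splicing and intronic occur on this substrate
  expect_true("intronic" %in% ann$category)
})

test_that("adjacent-SNP distances reproduce the clustered-GBS signature", {
  v <- data.frame(chrom = "c1", pos = c(100L, 155L, 210L, 1000000L))
  ds <- distance_summary(v)
  expect_equal(sort(ds$distances), c(55, 55, 999790))
  expect_equal(ds$overall$median, 55)
  expect_equal(ds$overall$mean, 333300)
  expect_equal(ds$overall$min, 55)
  expect_equal(ds$overall$max, 999790)
  ## distances never cross chromosomes
  v2 <- data.frame(chrom = c("a", "a", "b"), pos = c(1L, 11L, 5L))
  expect_equal(distance_summary(v2)$distances, 10)
  ## single variant -> empty summary
  expect_equal(length(distance_summary(
    data.frame(chrom = "a", pos = 1L))$distances), 0L)
  ## evenly spaced -> mean == median
  v3 <- data.frame(chrom = "c", pos = seq(0L, 10000L, by = 1000L))
  ds3 <- distance_summary(v3)
  expect_equal(ds3$overall$mean, 1000)
  expect_equal(ds3$overall$median, 1000)
  ## bin fractions sum to 1
  expect_equal(sum(ds$bins$fraction), 1)
})

test_that("density by chromosome class normalizes counts and sizes", {
  cls <- c(c1 = "large", c2 = "medium", c3 = "micro")
  sizes <- c(c1 = 68e6, c2 = 15e6, c3 = 17e6)
  ## all variants on one micro chromosome
  v <- data.frame(chrom = rep("c3", 7), pos = 1:7)
  d <- density_by_class(v, cls, sizes)
  expect_equal(d$pct_of_snps[d$class == "micro"], 100)
  expect_equal(d$n_snps[d$class != "micro"], c(0L, 0L))
  ## uniform density -> percentages proportional to class sizes
  set.seed(64)
  n <- 20000
  ch <- sample(names(sizes), n, TRUE, prob = sizes / sum(sizes))
  v2 <- data.frame(chrom = ch, pos = seq_len(n))
  d2 <- density_by_class(v2, cls, sizes)
  expect_equal(d2$pct_of_snps[match(c("large", "medium", "micro"), d2$class)],
               100 * sizes / sum(sizes), tolerance = 0.05,
               ignore_attr = TRUE)
  ## SNP/Mbp uses the class size
  expect_equal(d$snp_per_mbp[d$class == "micro"], 7 / 17)
  ## empty set -> zeros; unlabeled chromosome -> error
  d0 <- density_by_class(v[0, ], cls, sizes)
  expect_true(all(d0$n_snps == 0L))
  expect_error(density_by_class(data.frame(chrom = "cX", pos = 1L), cls,
                                sizes), "no class label")
})
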