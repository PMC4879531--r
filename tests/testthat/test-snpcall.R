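test_that("tags align to their source position with mismatch counting", {
  set.seed(41)
  w <- small_world()
  idx <- ref_tag_index(w$genome, "PstI")
  expect_true(all(nchar(idx$seq) == 64L))
  expect_true(all(startsWith(idx$seq, "CTGCA")))
  ## a verbatim reference tag aligns with zero mismatches at its source
  ctag <- idx$seq[10]
  fake <- structure(list(counts = data.table::data.table(
    tag = ctag, sample = "s1", n = 5L)), class = "tag_catalog")
  aln <- align_tags(fake, w$genome, "PstI")
  expect_equal(nrow(aln$alignments), 1L)
  expect_equal(aln$alignments$cand_id, idx$cand_id[10])
  expect_equal(aln$alignments$nmis, 0L)
  ## one substitution -> one mismatch, recorded at the right genomic base
  mt <- ctag
  substr(mt, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(ctag, 30, 30))[1]
  fake$counts$tag <- mt
  aln <- align_tags(fake, w$genome, "PstI")
  expect_equal(aln$alignments$nmis, 1L)
  expect_equal(aln$mismatches$off, 29L)
  gpos <- aln$mismatches$gpos
  gbase <- substring(as.character(w$genome[[aln$mismatches$chrom]]),
                     gpos + 1, gpos + 1)
  ref_at_off <- substr(idx$seq[10], 30, 30)
  if (idx$strand[10] == "-") ref_at_off <- chartr("ACGT", "TGCA", ref_at_off)
  expect_equal(gbase, ref_at_off)
  ## too many mismatches -> unaligned
  mt2 <- ctag
  for (p in c(10, 20, 30, 40)) substr(mt2, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(ctag, p, p))[1]
  fake$counts$tag <- mt2
  aln <- align_tags(fake, w$genome, "PstI", k = 3)
  expect_equal(nrow(aln$alignments), 0L)
  expect_equal(aln$unaligned, mt2)
})

test_that("tags from duplicated regions are left unaligned (tie rule)", {
  ## two chromosomes with an identical cut-site context
  set.seed(42)
  core <- paste0("CTGCAG", gsub("CTGCAG", "ACGCAT", rand_seq(80)))
  g <- Biostrings::DNAStringSet(c(
    c1 = paste0(gsub("CTGCAG", "ACGCAT", rand_seq(150)), core,
                gsub("CTGCAG", "ACGCAT", rand_seq(150))),
    c2 = paste0(gsub("CTGCAG", "ACGCAT", rand_seq(200)), core,
                gsub("CTGCAG", "ACGCAT", rand_seq(100)))))
  idx <- ref_tag_index(g, "PstI")
  dup <- idx$seq[duplicated(idx$seq) | duplicated(idx$seq, fromLast = TRUE)]
  expect_gte(length(dup), 2L)
  fake <- structure(list(counts = data.table::data.table(
    tag = dup[1], sample = "s", n = 1L)), class = "tag_catalog")
  aln <- align_tags(fake, g, "PstI")
  expect_equal(nrow(aln$alignments), 0L)
  expect_equal(aln$unaligned, dup[1])
})

test_that("the genotype likelihood rule matches its closed form", {
  ## independent likelihood oracle
  oracle <- function(dr, da, eps = 0.01) {
    ll <- c(homRef = dr * log(1 - eps) + da * log(eps),
            het = (dr + da) * log(0.5),
            homAlt = dr * log(eps) + da * log(1 - eps))
    if (dr + da == 0 || sum(ll == max(ll)) > 1) return(NA_integer_)
    c(0L, 1L, 2L)[which.max(ll)]
  }
  cases <- rbind(c(5, 0), c(3, 4), c(0, 0), c(0, 7), c(1, 1), c(9, 1),
                 c(8, 2), c(1, 0), c(20, 3), c(6, 1), c(7, 1))
  got <- gbsforge:::call_genotypes(matrix(cases[, 1]), matrix(cases[, 2]),
                                   epsilon = 0.01)
  want <- apply(cases, 1, function(x) oracle(x[1], x[2]))
  expect_equal(as.integer(got), as.integer(want))
  ## the spec's worked examples
  expect_equal(want[1], 0L)   # (5,0) -> homRef
  expect_equal(want[2], 1L)   # (3,4) -> het
  expect_true(is.na(want[3])) # (0,0) -> missing
})

test_that("error-free simulation recovers planted variants and genotypes", {
  w <- small_catalog(base_error = 0)
  aln <- align_tags(w$catalog, w$genome, "PstI")
  ## every error-free tag comes from a cut-site window: all align
  expect_gte(nrow(aln$alignments) / length(unique(w$catalog$counts$tag)),
             0.99)
  calls <- discover_and_call(aln, w$catalog, w$genome)
  truth_keys <- paste0(w$variants$chrom, ":", w$variants$pos)
  call_keys <- paste0(calls$sites$chrom, ":", calls$sites$pos)
  ## without sequencing error, every discovered site is a planted variant
  expect_true(all(call_keys %in% truth_keys))
  ## called alt alleles match the planted alt alleles
  vv <- w$variants[match(call_keys, truth_keys), ]
  expect_equal(calls$sites$ref, vv$ref)
  expect_equal(calls$sites$alt, vv$alt)
  ## without errors, genotype mistakes can only be het undercalls from
  ## single-haplotype sampling at low depth: truth-homozygous calls are
  ## essentially perfect, and every het miscall shows one-sided depth
  tm <- truth_as_matrix(w$truth, calls$sites)
  taxa <- intersect(calls$taxa, tm$taxa)
  q <- calls$geno[, taxa]; t <- tm$geno[, taxa]
  ar <- calls$ad_ref[, taxa]; aa <- calls$ad_alt[, taxa]
  ok <- !is.na(q)
  hom <- ok & t != 1L
  expect_gte(mean(q[hom] == t[hom]), 0.999)
  ## every discordance is a het undercall (no hom -> het overcalls)
  disc <- ok & q != t
  expect_true(all(t[disc] == 1L))
})

test_that("the documented filter fixture gives 4 taxa x 2 sites", {
  ## rows = sites, cols = taxa; taxon t5 has call rate 0 (< mnTCov 0.2).
  ## After t5 is removed: s1 full call rate, MAF .125 -> keep;
  ## s2 call rate .75 (< .9) -> drop; s3 MAF 0 -> drop; s4 MAF .25 -> keep.
  g <- rbind(
    s1 = c(0L, 0L, 1L, 0L, NA),
    s2 = c(0L, 1L, 0L, NA, NA),
    s3 = c(0L, 0L, 0L, 0L, NA),
    s4 = c(1L, 1L, 0L, 0L, NA))
  colnames(g) <- paste0("t", 1:5)
  gm <- as_genotype_matrix(g, chrom = "c1", pos = 1:4 * 10L)
  out <- apply_filters(gm, mnTCov = 0.2, mnScov = 0.9, mnMAF = 0.01,
                       misMat = 0.05)
  expect_equal(out$taxa, paste0("t", 1:4))
  expect_equal(out$sites$pos, c(10L, 40L))
  rep <- attr(out, "filter_report")
  expect_equal(rep$taxa_removed, 1L)
  expect_equal(rep$sites_failed_cov_or_maf, 2L)
})

test_that("degenerate filter inputs behave as specified", {
  ## all-homRef matrix -> zero sites (MAF 0 < mnMAF)
  g <- matrix(0L, 3, 4, dimnames = list(NULL, paste0("t", 1:4)))
  gm <- as_genotype_matrix(g, chrom = "c", pos = 1:3)
  expect_warning(out <- apply_filters(gm), "no sites survive")
  expect_equal(nrow(out$geno), 0L)
  ## thresholds all 0 -> identity (no duplicate positions present)
  g2 <- matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  gm2 <- as_genotype_matrix(g2, chrom = "c", pos = c(1L, 2L))
  out2 <- apply_filters(gm2, 0, 0, 0, 1)
  expect_equal(out2$geno, gm2$geno)
  expect_error(apply_filters(gm2, mnMAF = 1.5), "in \\[0,1\\]")
})

test_that("filters are monotone and every survivor satisfies the thresholds", {
  set.seed(44)
  n_s <- 60; n_t <- 30
  g <- matrix(sample(c(0L, 1L, 2L, NA), n_s * n_t, TRUE,
                     prob = c(.4, .3, .2, .1)), n_s, n_t,
              dimnames = list(NULL, paste0("t", 1:n_t)))
  gm <- as_genotype_matrix(g, chrom = "c",
                           pos = as.integer(seq_len(n_s) * 5L))
  prev <- Inf
  for (sc in c(0.2, 0.5, 0.7, 0.9)) {
    out <- apply_filters(gm, mnTCov = 0.1, mnScov = sc, mnMAF = 0.05)
    expect_lte(nrow(out$geno), prev)
    prev <- nrow(out$geno)
    if (nrow(out$geno)) {
      scr <- rowMeans(!is.na(out$geno))
      p <- rowMeans(out$geno, na.rm = TRUE) / 2
      expect_true(all(scr >= sc))
      expect_true(all(pmin(p, 1 - p) >= 0.05))   # MAF invariant
    }
  }
})

test_that("co-located duplicate sites merge or drop by mismatch rate", {
  taxa <- paste0("t", 1:10)
  base <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 0L, 1L)
  ## identical duplicates (mismatch 0) -> merged into one site
  g <- rbind(base, base); colnames(g) <- taxa
  gm <- as_genotype_matrix(g, chrom = "c", pos = c(5L, 5L),
                           site_id = c("a", "b"))
  out <- apply_filters(gm, 0, 0, 0, misMat = 0.05)
  expect_equal(nrow(out$geno), 1L)
  expect_equal(unname(out$geno[1, ]), base)
  ## discordant duplicates (mismatch 40%) -> both removed
  other <- base; other[1:4] <- 2L - other[1:4]
  g2 <- rbind(base, other); colnames(g2) <- taxa
  gm2 <- as_genotype_matrix(g2, chrom = "c", pos = c(5L, 5L),
                            site_id = c("a", "b"))
  expect_warning(out2 <- apply_filters(gm2, 0, 0, 0, misMat = 0.05),
                 "no sites survive")
  expect_equal(nrow(out2$geno), 0L)
  ## a single conflicting call (10% > 5%) also drops; at misMat .2 it merges
  one <- base; one[1] <- 2L
  g3 <- rbind(base, one); colnames(g3) <- taxa
  gm3 <- as_genotype_matrix(g3, chrom = "c", pos = c(5L, 5L),
                            site_id = c("a", "b"))
  out3 <- apply_filters(gm3, 0, 0, 0, misMat = 0.2)
  expect_equal(nrow(out3$geno), 1L)
  expect_true(is.na(out3$geno[1, 1]))          # conflict -> missing
  expect_equal(unname(out3$geno[1, -1]), base[-1])
})

test_that("VCF callsets round-trip", {
  set.seed(45)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 30, TRUE), 6, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  ar <- matrix(sample(0:9, 30, TRUE), 6, 5)
  aa <- matrix(sample(0:9, 30, TRUE), 6, 5)
  gm <- as_genotype_matrix(g, chrom = rep(c("c1", "c2"), each = 3),
                           pos = c(10L, 20L, 30L, 10L, 40L, 50L),
                           ref = "A", alt = "G", ad_ref = ar, ad_alt = aa)
  path <- tempfile(fileext = ".vcf")
  write_callset(gm, path)
  back <- read_callset(path)
  expect_equal(unname(back$geno), unname(gm$geno))
  expect_equal(back$taxa, gm$taxa)
  expect_equal(unname(back$ad_ref), unname(ar))
  expect_equal(unname(back$ad_alt), unname(aa))
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$sites$ref, gm$sites$ref)
  ## missing genotypes serialize as ./.
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(sum(grepl("\\./\\.", body)), sum(apply(is.na(g), 1, any)))
  ## external VCF parser agrees on genotypes (oracle cross-check)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "./." = NA_integer_)
  expect_equal(matrix(unname(code[gt]), nrow(gt)), unname(gm$geno))
})
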