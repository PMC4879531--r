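mk_gm <- function(geno, pos = NULL, chrom = "c1", alt = "C") {
  pos <- pos %||% as.integer(seq_len(nrow(geno)) * 10L)
  as_genotype_matrix(geno, chrom = chrom, pos = pos, ref = "A", alt = alt)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("position concordance is a set intersection with multiallelic exclusion", {
  q <- data.frame(chrom = "c1", pos = c(1L, 2L, 3L, 4L, 5L,
                                        6L, 7L, 8L, 9L, 10L))
  r <- data.frame(chrom = "c1", pos = c(1:8, 20L, 30L))
  pc <- position_concordance(q, r)
  expect_equal(pc$fraction, 0.8)
  expect_equal(pc$n_concordant, 8L)
  ## identity
  expect_equal(position_concordance(q, q)$fraction, 1.0)
  ## multi-allelic reference positions are removed before comparison
  r2 <- data.frame(chrom = "c1", pos = c(1L, 1L, 2L),
                   alt = c("C", "G", "C"))
  pc2 <- position_concordance(q, r2)
  expect_equal(pc2$n_reference, 1L)
  expect_equal(pc2$fraction, 0.1)
  ## matches a set-intersection oracle on random data
  set.seed(51)
  qp <- sample(1:500, 200); rp <- sample(1:500, 300)
  pc3 <- position_concordance(data.frame(chrom = "x", pos = qp),
                              data.frame(chrom = "x", pos = rp))
  expect_equal(pc3$fraction, length(intersect(qp, rp)) / length(qp))
})

test_that("the worked genotype-concordance example evaluates by hand", {
  ## 1 sample x 4 sites: query (AB,AA,AB,BB) vs reference (AB,AB,AA,BB)
  q <- mk_gm(matrix(c(1L, 0L, 1L, 2L), ncol = 1,
                    dimnames = list(NULL, "s")))
  r <- mk_gm(matrix(c(1L, 1L, 0L, 2L), ncol = 1,
                    dimnames = list(NULL, "s")))
  cr <- genotype_concordance(q, r)
  expect_equal(cr$n_genotype_comparisons, 4L)
  expect_equal(cr$genotype_concordance, 50)
  expect_equal(cr$het$n_either_het, 3L)
  expect_equal(cr$het$pct_validated_either_het, 100 / 3)
  expect_equal(cr$het$pct_discordant_query_hom_ref_het, 50)
  expect_equal(cr$het$n_both_het, 1L)
  expect_equal(cr$het$pct_both_het_agree, 100)
  ## identical matrices: 100% everywhere
  cr2 <- genotype_concordance(q, q)
  expect_equal(cr2$genotype_concordance, 100)
  expect_equal(cr2$het$pct_validated_either_het, 100)
  ## overall concordance is symmetric under swapping
  cr3 <- genotype_concordance(r, q)
  expect_equal(cr3$genotype_concordance, cr$genotype_concordance)
  expect_error(genotype_concordance(q, mk_gm(
    matrix(0L, 4, 1, dimnames = list(NULL, "other")))), "no overlapping")
})

test_that("injected het->hom undercalling is recovered by the decomposition", {
  set.seed(52)
  n_s <- 400; n_t <- 20; u <- 0.3
  truthg <- matrix(sample(c(0L, 1L, 2L), n_s * n_t, TRUE,
                          prob = c(.3, .4, .3)), n_s, n_t,
                   dimnames = list(NULL, paste0("t", 1:n_t)))
  qg <- truthg
  hets <- which(truthg == 1L)
  flip <- hets[runif(length(hets)) < u]
  qg[flip] <- sample(c(0L, 2L), length(flip), TRUE)
  cr <- genotype_concordance(mk_gm(qg), mk_gm(truthg))
  ## all discordance is query-hom vs reference-het by construction
  expect_equal(cr$het$pct_discordant_query_hom_ref_het, 100)
  measured_u <- 1 - cr$het$pct_validated_reference_het / 100
  expect_equal(measured_u, u, tolerance = 3 * sqrt(u * (1 - u) / length(hets)) / u)
})

test_that("Mendelian trio rules match the allele-set oracle on all 27 combos", {
  combos <- expand.grid(s = 0:2, d = 0:2, o = 0:2)
  got <- gbsforge:::mendel_incompatible(combos$s, combos$d, combos$o)
  want <- !mapply(oracle_mendel_ok, combos$s, combos$d, combos$o)
  expect_equal(got, unname(want))
  ## the canonical case: AA x BB -> offspring AA is an error, AB is not
  expect_true(gbsforge:::mendel_incompatible(0L, 2L, 0L))
  expect_false(gbsforge:::mendel_incompatible(0L, 2L, 1L))
  ## anything is compatible with AB x AB
  expect_false(any(gbsforge:::mendel_incompatible(rep(1L, 3), rep(1L, 3),
                                                  0:2)))
  ## duo rule: offspring must share an allele with the genotyped parent
  expect_true(gbsforge:::duo_incompatible(2L, 0L))
  expect_false(gbsforge:::duo_incompatible(1L, 0L))
})

test_that("injecting 1% genotype errors raises Mendelian errors proportionally", {
  w <- small_world()
  truth <- w$truth
  v <- w$variants
  gm <- as_genotype_matrix(truth_geno(truth), chrom = v$chrom, pos = v$pos,
                           ref = v$ref, alt = v$alt)
  expect_equal(mendelian_errors(gm, truth$pedigree)$total_errors, 0L)
  set.seed(53)
  u <- 0.01
  kids <- truth$pedigree$id[truth$pedigree$generation == "F2"]
  g <- gm$geno
  ## corrupt F2 calls at rate u; expected detection from the oracle table
  n_expected <- 0
  for (k in kids) {
    hit <- which(runif(nrow(g)) < u)
    for (i in hit) {
      old <- g[i, k]
      new <- sample(setdiff(0:2, old), 1)
      g[i, k] <- new
      ped <- truth$pedigree
      s <- g[i, ped$sire[ped$id == k]]; d <- g[i, ped$dam[ped$id == k]]
      if (!oracle_mendel_ok(s, d, new)) n_expected <- n_expected + 1
    }
  }
  gm2 <- gm; gm2$geno <- g
  mr <- mendelian_errors(gm2, truth$pedigree)
  f2err <- sum(mr$per_individual$n_errors[mr$per_individual$id %in% kids])
  expect_equal(f2err, n_expected)
  expect_gt(f2err, 0)
})

test_that("heterozygosity and call-rate summaries evaluate by hand", {
  g <- matrix(c(1L, 0L, 1L, NA,        # individual a: het 2/3
                1L, 1L, 1L, 1L,        # individual b: het 1
                NA, NA, NA, NA),       # individual c: all missing
              nrow = 4,
              dimnames = list(NULL, c("a", "b", "c")))
  gm <- mk_gm(g)
  hs <- heterozygosity_summary(gm, list(g1 = c("a", "b"), g2 = "c"))
  expect_equal(hs$per_individual$het_proportion[1], 2 / 3)
  expect_equal(hs$per_individual$het_proportion[2], 1)
  expect_equal(hs$missing_fraction, 5 / 12)
  grp <- hs$per_group[hs$per_group$group == "g1", ]
  expect_equal(grp$mean_het, mean(c(2 / 3, 1)))
  expect_equal(grp$cv, grp$sd_het / grp$mean_het)
  cr <- taxon_call_rates(gm)
  expect_equal(cr$per_taxon$call_rate, c(3 / 4, 1, 0))
  ## uniform masking moves the mean call rate accordingly
  set.seed(54)
  big <- matrix(1L, 200, 30, dimnames = list(NULL, paste0("x", 1:30)))
  big[runif(length(big)) < 0.1] <- NA
  expect_equal(taxon_call_rates(mk_gm(big))$mean_call_rate, 0.9,
               tolerance = 0.02)
})

test_that("truth matrices and F2 heterozygosity follow Mendelian expectation", {
  w <- small_world()
  v <- w$variants
  tm <- truth_as_matrix(w$truth)
  ped <- w$truth$pedigree
  fixed_ids <- v$id[v$origin != "shared"]
  sub <- truth_as_matrix(w$truth, v[v$origin != "shared", ])
  hs <- heterozygosity_summary(sub, split(ped$id, ped$generation))
  f1 <- hs$per_group[hs$per_group$group == "F1", ]
  f2 <- hs$per_group[hs$per_group$group == "F2", ]
  expect_equal(f1$mean_het, 1.0)
  expect_equal(f2$mean_het, 0.5, tolerance = 0.06)
})
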