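## direct gamete-level simulator used as an independent check of the EM:
## both parents het, coupling phase, true recombination fraction r
sim_f2_pair <- function(r, n) {
  a1 <- rbinom(n, 1, 0.5); a2 <- ifelse(runif(n) < r, 1L - a1, a1)
  b1 <- rbinom(n, 1, 0.5); b2 <- ifelse(runif(n) < r, 1L - b1, b1)
  list(g1 = a1 + b1, g2 = a2 + b2)
}

test_that("segregation classes follow the parental-genotype rule", {
  expect_equal(classify_segregation(1L, 0L), "maleHet")    # AB x AA
  expect_equal(classify_segregation(0L, 1L), "femaleHet")  # AA x AB
  expect_equal(classify_segregation(1L, 1L), "bothHet")
  expect_equal(classify_segregation(0L, 2L), "uninformative")
  expect_equal(classify_segregation(NA_integer_, 1L), "uninformative")
  expect_equal(classify_segregation(c(1L, 2L), c(2L, 1L)),
               c("maleHet", "femaleHet"))
})

test_that("segregation chi-square matches closed forms", {
  ## perfect 1:2:1
  s <- segregation_chi2(c(25, 50, 25), "bothHet")
  expect_equal(s$chi2, 0); expect_equal(s$p, 1); expect_true(s$keep)
  ## (30,50,20): chi2 = 2, df 2, p = exp(-1)
  s <- segregation_chi2(c(30, 50, 20), "bothHet")
  expect_equal(s$chi2, 2)
  expect_equal(s$df, 2L)
  expect_equal(s$p, exp(-1), tolerance = 1e-12)
  expect_true(s$keep)
  ## (100,0,0): chi2 = 300, dropped at P < 0.001
  s <- segregation_chi2(c(100, 0, 0), "bothHet")
  expect_equal(s$chi2, 300)
  expect_false(s$keep)
  ## single-het markers test 1:1 over the two observable classes (df 1)
  s <- segregation_chi2(c(30, 30, 0), "maleHet", hom_geno = 0L)
  expect_equal(s$chi2, 0); expect_equal(s$df, 1L)
  s <- segregation_chi2(c(50, 10, 0), "maleHet", hom_geno = 0L)
  expect_equal(s$chi2, (50 - 30)^2 / 30 + (10 - 30)^2 / 30)
  expect_error(segregation_chi2(c(0, 0, 0), "bothHet"), "zero offspring")
})

test_that("two-point estimates recover true recombination fractions", {
  set.seed(71)
  ## EM route: r = 0.1, n = 200, 100 replicates -> mean within 0.1 +- 0.02
  rs <- replicate(100, {
    p <- sim_f2_pair(0.1, 200)
    twopoint_rf(p$g1, p$g2, "bothHet", "bothHet")$r
  })
  expect_gt(mean(rs), 0.08); expect_lt(mean(rs), 0.12)
  ## unlinked markers: r ~ 0.5, LOD ~ 0
  p <- sim_f2_pair(0.5, 400)
  res <- twopoint_rf(p$g1, p$g2, "bothHet", "bothHet")
  expect_gt(res$r, 0.4)
  expect_lt(res$lod, 3)
  ## allele relabeling leaves r invariant (coupling vs repulsion)
  p <- sim_f2_pair(0.1, 300)
  r1 <- twopoint_rf(p$g1, p$g2, "bothHet", "bothHet")$r
  r2 <- twopoint_rf(p$g1, 2L - p$g2, "bothHet", "bothHet")$r
  expect_equal(r1, r2, tolerance = 1e-6)
  ## LOD is never negative
  expect_gte(twopoint_rf(p$g1, p$g2, "bothHet", "bothHet")$lod, 0)
})

test_that("testcross pairs count recombinants directly; self pair LOD = n log10 2", {
  set.seed(72)
  t1 <- rbinom(100, 1, 0.5)
  g1 <- t1 + 0L                       # sire AB x dam AA, offspring AA/AB
  res <- twopoint_rf(g1, g1, "maleHet", "maleHet", dam1 = 0L, dam2 = 0L)
  expect_equal(res$r, 0)
  expect_equal(res$lod, 100 * log10(2), tolerance = 1e-10)
  expect_equal(res$n, 100L)
  ## known recombinants: 10 of 100 discordant transmissions
  t2 <- t1; t2[1:10] <- 1L - t2[1:10]
  res <- twopoint_rf(g1, t2 + 0L, "maleHet", "maleHet", dam1 = 0L, dam2 = 0L)
  expect_equal(res$r, 0.1)
  ## disjoint parents (maternal-only x paternal-only): no estimate
  res <- twopoint_rf(g1, g1, "maleHet", "femaleHet", dam1 = 0L, sire2 = 0L)
  expect_equal(res$method, "uninformative")
  ## below min_n: no estimate
  res <- twopoint_rf(g1[1:10], g1[1:10], "maleHet", "maleHet",
                     dam1 = 0L, dam2 = 0L)
  expect_true(is.na(res$r))
})

test_that("twopoint_all agrees with the per-pair path and routes classes", {
  set.seed(73)
  n <- 150
  ## marker set: m1,m2 bothHet linked; m3 maleHet linked to nothing;
  ## m4,m5 maleHet linked pair
  p12 <- sim_f2_pair(0.08, n)
  t4 <- rbinom(n, 1, 0.5); t5 <- ifelse(runif(n) < 0.1, 1L - t4, t4)
  geno <- rbind(m1 = p12$g1, m2 = p12$g2,
                m3 = rbinom(n, 1, 0.5) + rbinom(n, 1, 0.5),
                m4 = t4 + 0L, m5 = t5 + 0L)
  sire <- c(1L, 1L, 1L, 1L, 1L)
  dam <- c(1L, 1L, 1L, 0L, 0L)
  pairs <- twopoint_all(geno, sire, dam)
  key <- paste(pairs$marker1, pairs$marker2)
  em12 <- twopoint_rf(geno["m1", ], geno["m2", ], "bothHet", "bothHet")
  ## the vectorized EM keeps iterating until every pair converges, so the
  ## two paths agree to EM precision, not to machine precision
  expect_equal(pairs$r[key == "m1 m2"], em12$r, tolerance = 1e-4)
  expect_equal(pairs$lod[key == "m1 m2"], em12$lod, tolerance = 1e-4)
  tc45 <- twopoint_rf(geno["m4", ], geno["m5", ], "maleHet", "maleHet",
                      dam1 = 0L, dam2 = 0L)
  expect_equal(pairs$r[key == "m4 m5"], tc45$r)
  expect_equal(pairs$method[key == "m4 m5"], "testcross_sire")
  ## mixed pair m1 (bothHet) x m4 (maleHet) estimated through the sire
  expect_true("m1 m4" %in% key || "m4 m1" %in% key)
})

test_that("marker grouping finds connected components under LOD/rf gates", {
  pairs <- data.table::data.table(
    marker1 = c("a", "b", "d", "a"),
    marker2 = c("b", "c", "e", "d"),
    r = c(0.05, 0.10, 0.08, 0.45),
    lod = c(20, 15, 12, 9),
    n = 100L, method = "em_f2")
  ## the a-d edge fails the rf gate -> two clusters
  g <- group_markers(pairs, min_lod = 8, max_rf = 0.35)
  expect_equal(g$n_groups, 2L)
  grp <- setNames(g$groups$group, g$groups$marker)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["d"]], grp[["e"]])
  expect_true(grp[["a"]] != grp[["d"]])
  ## all pairs below LOD 8 -> everything unlinked
  g0 <- group_markers(pairs[lod < 8], min_lod = 8, max_rf = 0.35,
                      markers = c("a", "b", "c", "d", "e"))
  expect_equal(g0$n_groups, 0L)
  expect_setequal(g0$unlinked, c("a", "b", "c", "d", "e"))
  ## fragmented flag from a marker-chromosome map
  gf <- group_markers(pairs, 8, 0.35,
                      marker_chrom = c(a = "c1", b = "c1", c = "c2",
                                       d = "c3", e = "c3"))
  ## {a,b,c} spans chromosomes c1 and c2 -> fragmented; {d,e} is not
  fr <- setNames(gf$fragmented$fragmented, gf$fragmented$group)
  grpf <- setNames(gf$groups$group, gf$groups$marker)
  expect_true(fr[[as.character(grpf[["a"]])]])
  expect_false(fr[[as.character(grpf[["d"]])]])
})

test_that("the Kosambi function matches its closed form and inverts", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.2), 25 * log(1.4 / 0.6))
  expect_equal(round(kosambi(0.2), 2), 21.18)
  expect_equal(kosambi(0.01), 1.0001, tolerance = 1e-4)  # ~100r for small r
  expect_error(kosambi(0.5), "undefined")
  ## strictly increasing; numerical inverse within 1e-10
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_equal(kosambi_inv(d), r, tolerance = 1e-10)
})
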