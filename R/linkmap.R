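#' Classify marker segregation from the F1 parents' genotypes
#'
#' An F2 marker is informative when at least one F1 parent is
#' heterozygous: \code{femaleHet} (sire homozygous x dam heterozygous,
#' AA x AB), \code{maleHet} (AB x AA), or \code{bothHet} (AB x AB).
#' Everything else (hom x hom, missing) is \code{uninformative}.
#'
#' @param sire_geno,dam_geno integer genotype vectors (0/1/2/NA) of the
#'   two F1 parents across markers.
#' @return character vector of classes.
#' @export
classify_segregation <- function(sire_geno, dam_geno) {
  out <- rep("uninformative", length(sire_geno))
  s_het <- !is.na(sire_geno) & sire_geno == 1L
  d_het <- !is.na(dam_geno) & dam_geno == 1L
  s_hom <- !is.na(sire_geno) & sire_geno != 1L
  d_hom <- !is.na(dam_geno) & dam_geno != 1L
  out[s_het & d_hom] <- "maleHet"
  out[s_hom & d_het] <- "femaleHet"
  out[s_het & d_het] <- "bothHet"
  out
}

#' Segregation-distortion chi-square test
#'
#' Pearson chi-square of observed F2 genotype counts against the Mendelian
#' expectation: 1:2:1 over (homRef, het, homAlt) for \code{bothHet}
#' markers (df 2), and 1:1 over the two observable classes (the
#' homozygous parent's genotype and het) for single-parent-heterozygous
#' markers (df 1). Markers with \code{p < alpha} are flagged for removal
#' (the mapping default is \code{alpha = 0.001}).
#'
#' @param counts integer vector of length 3: offspring counts of genotypes
#'   (homRef, het, homAlt).
#' @param seg_class one of \code{"bothHet"}, \code{"maleHet"},
#'   \code{"femaleHet"}.
#' @param hom_geno for single-het classes, the homozygous parent's
#'   genotype code (0 or 2); defaults to the homozygous class with the
#'   larger count.
#' @param alpha distortion significance threshold.
#' @return list: \code{chi2}, \code{df}, \code{p}, \code{keep}.
#' @export
segregation_chi2 <- function(counts, seg_class, hom_geno = NULL,
                             alpha = 0.001) {
  assert_that(sum(counts) > 0, "zero offspring")
  if (seg_class == "bothHet") {
    expd <- sum(counts) * c(1, 2, 1) / 4
    chi2 <- sum((counts - expd)^2 / expd)
    df <- 2L
  } else {
    hom_geno <- hom_geno %||% (if (counts[1] >= counts[3]) 0L else 2L)
    obs <- c(counts[hom_geno / 2L + 1L], counts[2])
    expd <- sum(obs) * c(0.5, 0.5)
    chi2 <- sum((obs - expd)^2 / expd)
    df <- 1L
  }
  p <- pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, keep = p >= alpha)
}

## ---- two-point machinery -------------------------------------------------

## gamete enumeration for the F2 intercross EM (coupling phase):
## gamete g = (allele at M1, allele at M2); types 1..4 = 00,01,10,11
## with probabilities ((1-r)/2, r/2, r/2, (1-r)/2); rec = 0,1,1,0
f2_pair_enum <- local({
  a1 <- c(0L, 0L, 1L, 1L); a2 <- c(0L, 1L, 0L, 1L); rec <- c(0L, 1L, 1L, 0L)
  gi <- rep(1:4, each = 4L); gj <- rep(1:4, times = 4L)
  cell <- 3L * (a1[gi] + a1[gj]) + (a2[gi] + a2[gj]) + 1L   # 1..9
  list(gi = gi, gj = gj, cell = cell, rec = rec[gi] + rec[gj],
       isr = rec)
})

## EM over rows of a (npairs x 9) cell-count matrix N (cells indexed
## 3*g1 + g2 + 1); returns list(r, loglik, loglik_null)
f2_em <- function(N, tol = 1e-8, max_iter = 1000L) {
  en <- f2_pair_enum
  np <- nrow(N)
  r <- rep(0.25, np)
  ntot <- rowSums(N)
  pair_prob <- function(r) {
    gp <- cbind((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)   # np x 4
    gp[, en$gi, drop = FALSE] * gp[, en$gj, drop = FALSE] # np x 16
  }
  cellP <- function(pp) {
    out <- matrix(0, np, 9L)
    for (c9 in 1:9) {
      sel <- en$cell == c9
      out[, c9] <- if (sum(sel) == 1L) pp[, sel] else rowSums(pp[, sel, drop = FALSE])
    }
    out
  }
  ll_of <- function(r) {
    cp <- cellP(pair_prob(r))
    rowSums(N * log(pmax(cp, 1e-300)))
  }
  ll <- ll_of(r)
  for (it in seq_len(max_iter)) {
    pp <- pair_prob(r)
    cp <- cellP(pp)
    wrec <- matrix(0, np, 9L)
    for (c9 in 1:9) {
      sel <- en$cell == c9
      m <- pp[, sel, drop = FALSE] *
        matrix(en$rec[sel], np, sum(sel), byrow = TRUE)
      wrec[, c9] <- rowSums(m)
    }
    erec <- wrec / pmax(cp, 1e-300)
    rnew <- rowSums(N * erec) / (2 * pmax(ntot, 1))
    rnew <- pmin(pmax(rnew, 1e-9), 0.5)
    llnew <- ll_of(rnew)
    conv <- abs(llnew - ll) < tol
    r <- rnew; ll <- llnew
    if (all(conv)) break
  }
  list(r = r, loglik = ll, loglik_null = ll_of(rep(0.5, np)))
}

## cell counts (3*g1+g2+1) with phase flip of marker 2 (g2 -> 2-g2)
flip_cells <- function(N) N[, c(3L, 2L, 1L, 6L, 5L, 4L, 9L, 8L, 7L), drop = FALSE]

#' Two-point recombination fraction and LOD for one marker pair
#'
#' For a pair of markers heterozygous in both F1 parents (AB x AB), the
#' recombination fraction is the EM maximum-likelihood estimate under the
#' F2 intercross 3x3 genotype-class likelihood, maximized over the two
#' possible linkage phases. For pairs informative in a single shared
#' parent (pseudo-testcross), the recombination fraction is counted
#' directly from that parent's observable meioses, with the phase chosen
#' to minimize it. Pairs informative in disjoint parents (one
#' maternal-only, one paternal-only) have no estimate.
#'
#' @param g1,g2 offspring genotype vectors (0/1/2/NA) at the two markers.
#' @param class1,class2 segregation classes
#'   (\code{\link{classify_segregation}}).
#' @param sire1,sire2,dam1,dam2 parental genotypes at the two markers
#'   (needed to orient single-het transmissions; default AB x AA
#'   orientation inferred from the class and offspring codes).
#' @param min_n minimum jointly informative meioses (default 20).
#' @return list: \code{r}, \code{lod}, \code{n} (informative meioses),
#'   \code{method}; or \code{NULL} components when the pair is
#'   uninformative.
#' @export
twopoint_rf <- function(g1, g2, class1, class2,
                        sire1 = NULL, sire2 = NULL, dam1 = NULL, dam2 = NULL,
                        min_n = 20L) {
  no <- list(r = NA_real_, lod = NA_real_, n = 0L, method = "uninformative")
  if (class1 == "uninformative" || class2 == "uninformative") return(no)
  if (class1 == "bothHet" && class2 == "bothHet") {
    ok <- !is.na(g1) & !is.na(g2)
    if (sum(ok) < min_n) return(no)
    N <- matrix(tabulate(3L * g1[ok] + g2[ok] + 1L, 9L), 1L)
    f1 <- f2_em(N); f2v <- f2_em(flip_cells(N))
    use <- if (f2v$loglik > f1$loglik) f2v else f1
    return(list(r = use$r, lod = (use$loglik - use$loglik_null) / log(10),
                n = 2L * sum(ok), method = "em_f2"))
  }
  ## pseudo-testcross: a shared heterozygous parent must exist
  par1 <- c(maleHet = "sire", femaleHet = "dam", bothHet = "both")[class1]
  par2 <- c(maleHet = "sire", femaleHet = "dam", bothHet = "both")[class2]
  shared <- intersect(
    if (par1 == "both") c("sire", "dam") else par1,
    if (par2 == "both") c("sire", "dam") else par2)
  if (!length(shared)) return(no)
  sh <- shared[1]
  hom1 <- if (class1 == "bothHet") NA_integer_ else
    hom_parent_geno(g1, if (sh == "sire") dam1 else sire1)
  hom2 <- if (class2 == "bothHet") NA_integer_ else
    hom_parent_geno(g2, if (sh == "sire") dam2 else sire2)
  t1 <- transmitted_allele(g1, class1, hom1)
  t2 <- transmitted_allele(g2, class2, hom2)
  ok <- !is.na(t1) & !is.na(t2)
  n <- sum(ok)
  if (n < min_n) return(no)
  R <- sum(t1[ok] != t2[ok])
  R <- min(R, n - R)                      # ML phase
  r <- R / n
  lod <- if (r == 0) n * log10(2) else
    R * log10(2 * r) + (n - R) * log10(2 * (1 - r))
  list(r = r, lod = lod, n = n, method = "testcross")
}

## genotype of the homozygous parent at a single-het marker; inferred from
## the offspring codes when not supplied (the absent hom class is ~0)
hom_parent_geno <- function(g, parent_geno = NULL) {
  if (!is.null(parent_geno) && !is.na(parent_geno) && parent_geno != 1L)
    return(as.integer(parent_geno))
  n0 <- sum(g == 0L, na.rm = TRUE); n2 <- sum(g == 2L, na.rm = TRUE)
  if (n0 >= n2) 0L else 2L
}

## allele transmitted by the focal het parent, NA when not determinable
transmitted_allele <- function(g, cls, hom_geno) {
  if (cls == "bothHet") {
    ## determinable only when the offspring is homozygous
    t <- rep(NA_integer_, length(g))
    t[!is.na(g) & g == 0L] <- 0L
    t[!is.na(g) & g == 2L] <- 1L
    t
  } else {
    a_hom <- hom_geno / 2L                # allele the hom parent always gives
    t <- g - a_hom                        # focal parent's allele
    t[is.na(g) | t < 0L | t > 1L] <- NA_integer_
    t
  }
}

#' All pairwise two-point estimates for a marker set
#'
#' Vectorized two-point analysis: direct recombinant counting for
#' pseudo-testcross pairs (shared heterozygous parent) and a vectorized
#' EM over all AB x AB pairs. Offspring counts may be pooled over several
#' families by summing per-family cell counts, provided marker phases and
#' classes agree.
#'
#' @param geno markers x offspring integer genotype matrix (rownames =
#'   marker ids).
#' @param sire_geno,dam_geno parental genotype vectors across markers.
#' @param min_n minimum jointly informative meioses per pair.
#' @return \code{data.table(marker1, marker2, r, lod, n, method)} for all
#'   estimable pairs.
#' @export
twopoint_all <- function(geno, sire_geno, dam_geno, min_n = 20L) {
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  cls <- classify_segregation(sire_geno, dam_geno)
  res <- list()
  ## --- EM route: bothHet x bothHet pairs
  bh <- which(cls == "bothHet")
  if (length(bh) >= 2L) {
    G <- geno[bh, , drop = FALSE]
    Ia <- lapply(0:2, function(a) {
      m <- (!is.na(G)) & G == a; storage.mode(m) <- "numeric"; m
    })
    prs <- which(upper.tri(matrix(0, length(bh), length(bh))), arr.ind = TRUE)
    N <- matrix(0, nrow(prs), 9L)
    for (a in 0:2) for (b in 0:2) {
      cnt <- Ia[[a + 1L]] %*% t(Ia[[b + 1L]])
      N[, 3L * a + b + 1L] <- cnt[prs]
    }
    ok <- rowSums(N) >= min_n
    if (any(ok)) {
      Nk <- N[ok, , drop = FALSE]
      e1 <- f2_em(Nk); e2 <- f2_em(flip_cells(Nk))
      take2 <- e2$loglik > e1$loglik
      r <- ifelse(take2, e2$r, e1$r)
      ll <- ifelse(take2, e2$loglik, e1$loglik)
      ll0 <- ifelse(take2, e2$loglik_null, e1$loglik_null)
      res[[length(res) + 1L]] <- data.table(
        marker1 = ids[bh[prs[ok, 1L]]], marker2 = ids[bh[prs[ok, 2L]]],
        r = r, lod = (ll - ll0) / log(10),
        n = as.integer(2 * rowSums(Nk)), method = "em_f2")
    }
  }
  ## --- testcross route: pairs sharing one informative parent
  for (par in c("sire", "dam")) {
    focal_het <- if (par == "sire") sire_geno == 1L else dam_geno == 1L
    other <- if (par == "sire") dam_geno else sire_geno
    mk <- which(!is.na(focal_het) & focal_het &
                  cls %in% c("maleHet", "femaleHet", "bothHet"))
    ## restrict to pairs where at least one is single-het (bothHet x bothHet
    ## pairs are covered by the EM route)
    if (length(mk) < 2L) next
    Tm <- matrix(NA_integer_, length(mk), ncol(geno))
    for (i in seq_along(mk)) {
      Tm[i, ] <- transmitted_allele(geno[mk[i], ], cls[mk[i]],
                                    if (cls[mk[i]] == "bothHet") NA_integer_
                                    else other[mk[i]])
    }
    A0 <- (!is.na(Tm)) & Tm == 0L; A1 <- (!is.na(Tm)) & Tm == 1L
    storage.mode(A0) <- "numeric"; storage.mode(A1) <- "numeric"
    Rm <- A1 %*% t(A0) + A0 %*% t(A1)
    Nm <- (A0 + A1) %*% t(A0 + A1)
    prs <- which(upper.tri(Nm), arr.ind = TRUE)
    single <- cls[mk] != "bothHet"
    use <- (single[prs[, 1L]] | single[prs[, 2L]]) & Nm[prs] >= min_n
    if (!any(use)) next
    prs <- prs[use, , drop = FALSE]
    n <- Nm[prs]; R <- pmin(Rm[prs], n - Rm[prs])
    r <- R / n
    lod <- ifelse(r == 0, n * log10(2),
                  R * log10(2 * r) + (n - R) * log10(2 * (1 - r)))
    res[[length(res) + 1L]] <- data.table(
      marker1 = ids[mk[prs[, 1L]]], marker2 = ids[mk[prs[, 2L]]],
      r = r, lod = lod, n = as.integer(n),
      method = paste0("testcross_", par))
  }
  if (!length(res))
    return(data.table(marker1 = character(), marker2 = character(),
                      r = numeric(), lod = numeric(), n = integer(),
                      method = character()))
  out <- rbindlist(res)
  ## a pair can be estimable through both parents; keep the higher-n estimate
  out[, key := paste(pmin(marker1, marker2), pmax(marker1, marker2))]
  setorder(out, key, -n, -lod)
  out <- out[!duplicated(key)][, key := NULL]
  out[]
}

#' Group markers into linkage groups
#'
#' Builds the graph whose edges connect marker pairs with
#' \code{lod >= min_lod} and \code{r <= max_rf} and reports its connected
#' components as linkage groups (the OneMap-style grouping rule, default
#' LOD 8 and recombination fraction 0.35). Markers without any edge are
#' reported as unlinked. When a marker-to-chromosome map is supplied,
#' groups spanning more than one chromosome are flagged as fragmented.
#'
#' @param pairs \code{\link{twopoint_all}} output.
#' @param min_lod minimum LOD (default 8).
#' @param max_rf maximum recombination fraction (default 0.35).
#' @param marker_chrom optional named vector marker id -> chromosome.
#' @param markers optional full marker-id universe (to list unlinked
#'   markers absent from \code{pairs}).
#' @return list of class \code{linkage_groups}: \code{groups}
#'   (\code{data.table(group, marker, chrom)}), \code{n_groups},
#'   \code{unlinked}, \code{fragmented} (logical per group).
#' @export
group_markers <- function(pairs, min_lod = 8, max_rf = 0.35,
                          marker_chrom = NULL, markers = NULL) {
  edges <- pairs[!is.na(r) & !is.na(lod) & lod >= min_lod & r <= max_rf]
  universe <- unique(c(markers, pairs$marker1, pairs$marker2))
  comp <- components_of(edges$marker1, edges$marker2)
  linked <- names(comp)
  unlinked <- setdiff(universe, linked)
  groups <- data.table(marker = linked, group = unname(comp))
  ## renumber groups by size then first marker
  if (nrow(groups)) {
    sz <- groups[, .N, by = group][order(-N)]
    sz[, newid := seq_len(.N)]
    groups <- groups[sz[, .(group, newid)], on = "group"]
    groups[, group := newid][, newid := NULL]
    setorder(groups, group, marker)
  }
  groups[, chrom := if (!is.null(marker_chrom)) marker_chrom[marker] else
    NA_character_]
  frag <- if (nrow(groups) && !is.null(marker_chrom)) {
    groups[, .(fragmented = uniqueN(chrom) > 1L), by = group]
  } else data.table(group = integer(), fragmented = logical())
  structure(list(groups = groups, n_groups = uniqueN(groups$group),
                 unlinked = unlinked, fragmented = frag),
            class = "linkage_groups")
}

## connected components by union-find over an edge list
components_of <- function(a, b) {
  nodes <- unique(c(a, b))
  if (!length(nodes)) return(setNames(integer(0), character(0)))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ai <- match(a, nodes); bi <- match(b, nodes)
  for (k in seq_along(ai)) {
    ra <- find(ai[k]); rb <- find(bi[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  setNames(match(roots, unique(roots)), nodes)
}

#' @export
print.linkage_groups <- function(x, ...) {
  cat(sprintf("<linkage_groups> %d groups, %d linked + %d unlinked markers\n",
              x$n_groups, nrow(x$groups), length(x$unlinked)))
  invisible(x)
}

#' Kosambi map distance
#'
#' Converts a recombination fraction to centimorgans with the Kosambi
#' mapping function \code{d = 25 ln((1 + 2r) / (1 - 2r))}, which allows
#' partial crossover interference; \code{d ~ 100 r} for small \code{r}.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return map distance(s) in cM.
#' @examples
#' kosambi(0.2)   # ~21.18 cM
#' @export
kosambi <- function(r) {
  assert_that(all(r >= 0 & r < 0.5), "kosambi is undefined for r >= 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#' @param d map distance(s) in cM.
#' @return recombination fraction(s).
#' @export
kosambi_inv <- function(d) {
  assert_that(all(d >= 0), "map distance must be non-negative")
  tanh(d / 50) / 2
}
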