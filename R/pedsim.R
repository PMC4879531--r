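#' Simulate founder genotypes for two divergent lines
#'
#' Founders belong to a broiler-type line (TT) or a layer-type line (CC).
#' At fixed-divergent variants one line is homozygous reference and the
#' other homozygous alternative (which line carries the alternative is
#' recorded in the variant's \code{origin}). At shared-polymorphic variants
#' alleles are drawn from the site's population frequency, with a
#' within-line heterozygosity tuned to approximately \code{residual_het}
#' via an inbreeding-style homozygosity excess.
#'
#' @param variants \code{\link{plant_variants}} output.
#' @param n_tt,n_cc founders per line (the classic design uses 5 + 5).
#' @param residual_het target mean within-line heterozygosity at
#'   shared-polymorphic sites.
#' @param seed integer seed.
#' @return object of class \code{gbs_truth}: list with \code{pedigree}
#'   (a \code{data.table}: id, sire, dam, sex, generation, line, family),
#'   \code{variants}, and phased haplotype matrices \code{hap1},
#'   \code{hap2} (variants x samples, 0 = ref allele, 1 = alt allele).
#' @export
simulate_founders <- function(variants, n_tt = 5, n_cc = 5,
                              residual_het = 0.25, seed = 1) {
  assert_that(n_tt >= 1 && n_cc >= 1, "need at least one founder per line")
  set.seed(derive_seed(seed, "founders"))
  nv <- nrow(variants)
  ids <- c(sprintf("TT%02d", seq_len(n_tt)), sprintf("CC%02d", seq_len(n_cc)))
  line <- c(rep("TT", n_tt), rep("CC", n_cc))
  n <- length(ids)
  hap1 <- matrix(0L, nv, n, dimnames = list(variants$id, ids))
  hap2 <- hap1
  ## fixed-divergent: alt fixed in the named line, ref fixed in the other
  tt_alt <- variants$origin == "TT-fixed"
  cc_alt <- variants$origin == "CC-fixed"
  hap1[tt_alt, line == "TT"] <- 1L; hap2[tt_alt, line == "TT"] <- 1L
  hap1[cc_alt, line == "CC"] <- 1L; hap2[cc_alt, line == "CC"] <- 1L
  sh <- which(variants$origin == "shared")
  if (length(sh)) {
    p <- variants$freq[sh]
    het_iid <- mean(2 * p * (1 - p))
    f_inb <- max(0, min(1, 1 - residual_het / het_iid))
    for (j in seq_len(n)) {
      a1 <- as.integer(runif(length(sh)) < p)
      a2 <- as.integer(runif(length(sh)) < p)
      forcehom <- runif(length(sh)) < f_inb
      a2[forcehom] <- a1[forcehom]
      hap1[sh, j] <- a1
      hap2[sh, j] <- a2
    }
  }
  ped <- data.table(id = ids, sire = NA_character_, dam = NA_character_,
                    sex = rep_len(c("M", "F"), n), generation = "F0",
                    line = line, family = NA_character_)
  ## guarantee each line has both sexes when it has >= 2 founders
  ped[line == "TT", sex := rep_len(c("M", "F"), .N)]
  ped[line == "CC", sex := rep_len(c("M", "F"), .N)]
  structure(list(pedigree = ped, variants = variants,
                 hap1 = hap1, hap2 = hap2),
            class = "gbs_truth")
}

#' @export
print.gbs_truth <- function(x, ...) {
  cat(sprintf("<gbs_truth> %d samples x %d variants (%s)\n",
              nrow(x$pedigree), nrow(x$variants),
              paste(sprintf("%s:%d", names(table(x$pedigree$generation)),
                            table(x$pedigree$generation)), collapse = " ")))
  invisible(x)
}

#' Unphased genotype codes of a truth object
#'
#' @param truth a \code{gbs_truth}.
#' @return integer matrix variants x samples with 0 = homRef, 1 = het,
#'   2 = homAlt.
#' @export
truth_geno <- function(truth) truth$hap1 + truth$hap2

## gametes from one parent: Markov walk per chromosome with Haldane
## (no-interference) inter-site crossover probability
## p = 0.5 (1 - exp(-2 * rate * d)); returns variants x n matrix of alleles
make_gametes <- function(hap1, hap2, variants, n, rate) {
  d <- c(Inf, diff(variants$pos))
  d[c(TRUE, variants$chrom[-1] != variants$chrom[-nrow(variants)])] <- Inf
  p <- 0.5 * (1 - exp(-2 * rate * d))
  p[is.infinite(d)] <- 0.5            # fresh 50/50 start per chromosome
  nv <- length(p)
  flips <- matrix(rbinom(nv * n, 1L, rep(p, times = n)), nv, n)
  h <- apply(flips, 2L, cumsum) %% 2L
  hap1 * (1L - h) + hap2 * h
}

#' Simulate offspring of one mating
#'
#' Each offspring receives one recombinant gamete from each parent,
#' generated by a per-chromosome Markov walk with Haldane inter-site
#' crossover probabilities. Offspring therefore satisfy Mendelian
#' transmission exactly (zero Mendelian errors by construction).
#'
#' @param truth \code{gbs_truth} containing both parents.
#' @param sire,dam parent sample ids.
#' @param n_offspring number of offspring.
#' @param ids offspring ids (default generated).
#' @param recomb_rate_per_bp expected crossovers per bp per meiosis
#'   (default 3e-8, i.e. 3 cM/Mb).
#' @param family family label for the offspring.
#' @param generation generation label.
#' @param seed integer seed.
#' @return the truth object extended with the offspring.
#' @export
simulate_cross <- function(truth, sire, dam, n_offspring,
                           ids = NULL, recomb_rate_per_bp = 3e-8,
                           family = NA_character_, generation = "F2",
                           seed = 1) {
  assert_that(all(c(sire, dam) %in% truth$pedigree$id),
              "sire/dam not found in pedigree")
  set.seed(derive_seed(seed, paste0("cross:", sire, "x", dam, ":", family)))
  ids <- ids %||% sprintf("%s_%s%03d", family %||% "X", generation,
                          seq_len(n_offspring))
  gs <- make_gametes(truth$hap1[, sire], truth$hap2[, sire], truth$variants,
                     n_offspring, recomb_rate_per_bp)
  gd <- make_gametes(truth$hap1[, dam], truth$hap2[, dam], truth$variants,
                     n_offspring, recomb_rate_per_bp)
  colnames(gs) <- colnames(gd) <- ids
  pid <- truth$pedigree$id
  line <- paste0(truth$pedigree$line[match(sire, pid)],
                 truth$pedigree$line[match(dam, pid)])
  ped <- data.table(id = ids, sire = sire, dam = dam,
                    sex = rep_len(c("M", "F"), n_offspring),
                    generation = generation, line = line, family = family)
  truth$pedigree <- rbind(truth$pedigree, ped)
  truth$hap1 <- cbind(truth$hap1, gs)
  truth$hap2 <- cbind(truth$hap2, gd)
  truth
}

#' Build the TT x CC -> F1 -> F2 intercross design
#'
#' Mates TT x CC founder couples to produce the F1, then mates F1 males to
#' unrelated F1 females to produce the requested F2 family sizes. The
#' classic design is 5 + 5 founders, 8 F1 and five F2 families of sizes
#' 72, 82, 94, 100 and 96 (464 birds in total).
#'
#' @param variants \code{\link{plant_variants}} output.
#' @param family_sizes integer vector of F2 family sizes.
#' @param n_tt,n_cc,n_f1 design counts.
#' @param residual_het founder within-line heterozygosity target.
#' @param recomb_rate_per_bp crossover rate per bp per meiosis.
#' @param seed integer seed.
#' @return a \code{gbs_truth} with F0, F1 and F2 samples.
#' @export
build_f2_design <- function(variants,
                            family_sizes = c(72, 82, 94, 100, 96),
                            n_tt = 5, n_cc = 5, n_f1 = 8,
                            residual_het = 0.25,
                            recomb_rate_per_bp = 3e-8, seed = 1) {
  assert_that(length(family_sizes) >= 1 && all(family_sizes >= 1),
              "family_sizes must be a non-empty positive vector")
  truth <- simulate_founders(variants, n_tt, n_cc, residual_het, seed)
  ped <- truth$pedigree
  tt_m <- ped[line == "TT" & sex == "M"]$id
  tt_f <- ped[line == "TT" & sex == "F"]$id
  cc_m <- ped[line == "CC" & sex == "M"]$id
  cc_f <- ped[line == "CC" & sex == "F"]$id
  ## TT male x CC female and CC male x TT female couples, alternating
  couples <- rbind(
    data.table(sire = tt_m, dam = cc_f[seq_along(tt_m)]),
    data.table(sire = cc_m, dam = tt_f[seq_along(cc_m)]))
  couples <- couples[!is.na(sire) & !is.na(dam)]
  assert_that(nrow(couples) >= 1, "insufficient founders to form TT x CC couples")
  per <- ceiling(n_f1 / nrow(couples))
  k <- 0L
  for (ci in seq_len(nrow(couples))) {
    take <- min(per, n_f1 - k)
    if (take <= 0) break
    truth <- simulate_cross(truth, couples$sire[ci], couples$dam[ci], take,
                            ids = sprintf("F1_%02d", k + seq_len(take)),
                            recomb_rate_per_bp = recomb_rate_per_bp,
                            family = sprintf("F1cross%d", ci),
                            generation = "F1", seed = seed + ci)
    k <- k + take
  }
  ped <- truth$pedigree
  f1_m <- ped[generation == "F1" & sex == "M"]$id
  f1_f <- ped[generation == "F1" & sex == "F"]$id
  assert_that(length(f1_m) >= 1 && length(f1_f) >= 1,
              "insufficient F1 of each sex for F2 matings")
  for (j in seq_along(family_sizes)) {
    sire <- f1_m[(j - 1L) %% length(f1_m) + 1L]
    ## pick an unrelated dam: a different F1 cross where possible
    sire_fam <- ped$family[match(sire, ped$id)]
    dams <- setdiff(f1_f, ped$id[!is.na(ped$family) & ped$family == sire_fam])
    dam <- if (length(dams)) dams[(j - 1L) %% length(dams) + 1L] else
      f1_f[(j - 1L) %% length(f1_f) + 1L]
    fam <- sprintf("F2-%d", j)
    truth <- simulate_cross(truth, sire, dam, family_sizes[j],
                            ids = sprintf("%s_%03d", fam, seq_len(family_sizes[j])),
                            recomb_rate_per_bp = recomb_rate_per_bp,
                            family = fam, generation = "F2",
                            seed = seed + 100L + j)
  }
  truth
}

#' Write a pedigree TSV
#' @param truth \code{gbs_truth} or pedigree \code{data.table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_pedigree_tsv <- function(truth, path) {
  ped <- if (methods::is(truth, "gbs_truth")) truth$pedigree else truth
  fwrite(ped, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a pedigree TSV
#' @param path TSV written by \code{\link{write_pedigree_tsv}}.
#' @return pedigree \code{data.table}.
#' @export
read_pedigree_tsv <- function(path) {
  fread(path, sep = "\t", colClasses = list(character = 1:7), na.strings = "NA")
}
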