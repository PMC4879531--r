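#' Position concordance between two callsets
#'
#' Fraction of query site positions present in a reference callset, after
#' excluding multi-allelic reference positions (positions listed with more
#' than one distinct alternative allele).
#'
#' @param query,reference site tables (\code{data.table}/data.frame with
#'   \code{chrom}, \code{pos} and, for the reference, optionally
#'   \code{alt}) or \code{genotype_matrix} objects.
#' @return list: \code{fraction}, \code{n_query}, \code{n_concordant},
#'   \code{n_reference} (after multi-allelic exclusion).
#' @export
position_concordance <- function(query, reference) {
  qs <- site_table(query); rs <- site_table(reference)
  if ("alt" %in% names(rs)) {
    nalt <- rs[, .(k = uniqueN(alt)), by = .(chrom, pos)]
    rs <- rs[nalt[k == 1L], on = c("chrom", "pos")]
  }
  qk <- unique(paste0(qs$chrom, ":", qs$pos))
  rk <- unique(paste0(rs$chrom, ":", rs$pos))
  n_conc <- sum(qk %in% rk)
  list(fraction = if (length(qk)) n_conc / length(qk) else NA_real_,
       n_query = length(qk), n_concordant = n_conc, n_reference = length(rk))
}

site_table <- function(x) {
  if (methods::is(x, "genotype_matrix")) as.data.table(x$sites)
  else as.data.table(x)
}

#' Genotype concordance report
#'
#' Compares genotypes of two callsets over shared sites (matched by
#' chromosome and position) and overlapping samples, excluding pairs with
#' a missing call in either set (pairwise, not listwise). Beyond overall
#' concordance, the heterozygote section reports all three denominators
#' used in GBS validation studies: pairs where either callset is
#' heterozygous (with the fraction validated, and the decomposition of
#' discordance into query-homozygous-vs-reference-heterozygous calls),
#' pairs where the reference is heterozygous, and pairs where both are
#' heterozygous.
#'
#' @param query,reference \code{genotype_matrix} objects.
#' @return list of class \code{concordance_report}.
#' @export
genotype_concordance <- function(query, reference) {
  shared_samples <- intersect(query$taxa, reference$taxa)
  assert_that(length(shared_samples) > 0, "no overlapping samples")
  qk <- paste0(query$sites$chrom, ":", query$sites$pos)
  rk <- paste0(reference$sites$chrom, ":", reference$sites$pos)
  ## first occurrence wins when a callset holds duplicate positions
  qi <- match(unique(intersect(qk, rk)), qk)
  ri <- match(unique(intersect(qk, rk)), rk)
  qg <- query$geno[qi, shared_samples, drop = FALSE]
  rg <- reference$geno[ri, shared_samples, drop = FALSE]
  both <- !is.na(qg) & !is.na(rg)
  n_pairs <- sum(both)
  agree <- both & qg == rg
  either_het <- both & (qg == 1L | rg == 1L)
  both_het <- both & qg == 1L & rg == 1L
  disc <- both & qg != rg
  disc_eh <- disc & either_het
  hom_vs_het <- disc & qg != 1L & rg == 1L
  out <- list(
    n_query_sites = nrow(query$geno),
    n_shared_sites = length(qi),
    n_samples = length(shared_samples),
    n_genotype_comparisons = n_pairs,
    genotype_concordance = 100 * sum(agree) / n_pairs,
    het = list(
      n_either_het = sum(either_het),
      pct_validated_either_het = 100 * sum(agree & either_het) / sum(either_het),
      n_reference_het = sum(both & rg == 1L),
      pct_validated_reference_het =
        100 * sum(agree & rg == 1L) / sum(both & rg == 1L),
      n_both_het = sum(both_het),
      pct_both_het_agree = 100 * sum(agree & both_het) / sum(both_het),
      pct_discordant_query_hom_ref_het =
        if (sum(disc_eh)) 100 * sum(hom_vs_het) / sum(disc_eh) else NA_real_,
      query_het_calls = sum(both & qg == 1L),
      reference_het_calls = sum(both & rg == 1L),
      query_het_pct_of_comparisons = 100 * sum(both & qg == 1L) / n_pairs,
      reference_het_pct_of_comparisons = 100 * sum(both & rg == 1L) / n_pairs))
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    paste0("<concordance_report> %d shared sites, %d samples, %d comparisons\n",
           "  genotype concordance %.2f%%; either-het validated %.2f%%; ",
           "both-het agreement %.2f%%\n"),
    x$n_shared_sites, x$n_samples, x$n_genotype_comparisons,
    x$genotype_concordance, x$het$pct_validated_either_het,
    x$het$pct_both_het_agree))
  invisible(x)
}

## Mendelian trio compatibility: parent genotype g contributes allele set
## {0}:{0}, {1}:{0,1}, {2}:{1}; the offspring allele pair must be composable
mendel_incompatible <- function(sire, dam, off) {
  ## vectorized over equal-length integer vectors; NA anywhere -> FALSE
  bad_lo <- off == 0L & (sire == 2L | dam == 2L)
  bad_hi <- off == 2L & (sire == 0L | dam == 0L)
  bad_het <- off == 1L & ((sire == 0L & dam == 0L) | (sire == 2L & dam == 2L))
  out <- bad_lo | bad_hi | bad_het
  out[is.na(out)] <- FALSE
  out
}

## duo rule: offspring must share an allele with the single genotyped parent
duo_incompatible <- function(parent, off) {
  out <- (off == 0L & parent == 2L) | (off == 2L & parent == 0L)
  out[is.na(out)] <- FALSE
  out
}

#' Mendelian-error testing
#'
#' Counts, for every individual with at least one genotyped parent, the
#' sites at which the trio (or duo) genotypes are incompatible with
#' biparental Mendelian transmission of a biallelic marker. A site with a
#' missing call in any member of the trio is not evaluated. Results are
#' aggregated per family (and per generation) as mean and SD of the
#' per-individual error count and as percent of markers.
#'
#' @param gm \code{genotype_matrix} containing offspring and parents.
#' @param pedigree pedigree table with columns \code{id}, \code{sire},
#'   \code{dam}, \code{generation}, \code{family} (a \code{gbs_truth} is
#'   also accepted).
#' @return list of class \code{mendel_report}: \code{per_individual}
#'   (\code{data.table(id, family, generation, n_errors, n_evaluated)}),
#'   \code{per_family}, \code{total_errors}, \code{n_markers}.
#' @export
mendelian_errors <- function(gm, pedigree) {
  if (methods::is(pedigree, "gbs_truth")) pedigree <- pedigree$pedigree
  ped <- as.data.table(pedigree)
  g <- gm$geno
  have <- function(id) !is.na(id) & id %in% colnames(g)
  kids <- ped[have(id) & (have(sire) | have(dam))]
  rows <- lapply(seq_len(nrow(kids)), function(i) {
    o <- g[, kids$id[i]]
    s <- if (have(kids$sire[i])) g[, kids$sire[i]] else NULL
    d <- if (have(kids$dam[i])) g[, kids$dam[i]] else NULL
    if (!is.null(s) && !is.null(d)) {
      err <- mendel_incompatible(s, d, o)
      ev <- !is.na(s) & !is.na(d) & !is.na(o)
    } else {
      p <- if (is.null(s)) d else s
      err <- duo_incompatible(p, o)
      ev <- !is.na(p) & !is.na(o)
    }
    data.table(id = kids$id[i], family = kids$family[i],
               generation = kids$generation[i],
               n_errors = sum(err & ev), n_evaluated = sum(ev))
  })
  per_ind <- rbindlist(rows)
  nm <- nrow(g)
  per_fam <- per_ind[, .(n_individuals = .N,
                         mean_errors = mean(n_errors),
                         sd_errors = if (.N > 1) sd(n_errors) else 0,
                         pct_of_markers = 100 * mean(n_errors) / nm),
                     by = .(generation, family)]
  out <- list(per_individual = per_ind, per_family = per_fam,
              total_errors = sum(per_ind$n_errors), n_markers = nm)
  class(out) <- "mendel_report"
  out
}

#' @export
print.mendel_report <- function(x, ...) {
  cat(sprintf("<mendel_report> %d markers, %d individuals, %d errors total\n",
              x$n_markers, nrow(x$per_individual), x$total_errors))
  print(x$per_family)
  invisible(x)
}

#' Heterozygosity summary
#'
#' Per-individual heterozygous-call proportion (of non-missing calls) and
#' per-group mean, SD and coefficient of variation, plus the overall
#' missing-data fraction.
#'
#' @param gm \code{genotype_matrix}.
#' @param groups named list of sample-id vectors, or a named character
#'   vector mapping sample id to group; \code{NULL} puts all taxa in one
#'   group.
#' @return list: \code{per_individual}, \code{per_group},
#'   \code{missing_fraction}.
#' @export
heterozygosity_summary <- function(gm, groups = NULL) {
  g <- gm$geno
  het <- colSums(g == 1L, na.rm = TRUE) / colSums(!is.na(g))
  per_ind <- data.table(id = gm$taxa, het_proportion = het,
                        n_het = colSums(g == 1L, na.rm = TRUE))
  grp <- if (is.null(groups)) setNames(rep("all", length(gm$taxa)), gm$taxa)
  else if (is.list(groups)) {
    v <- unlist(lapply(names(groups), function(nm)
      setNames(rep(nm, length(groups[[nm]])), groups[[nm]])))
    v
  } else groups
  per_ind[, group := grp[id]]
  per_grp <- per_ind[!is.na(group),
                     .(n = .N, n_het = sum(n_het),
                       mean_het = mean(het_proportion),
                       sd_het = if (.N > 1) sd(het_proportion) else 0),
                     by = group]
  per_grp[, cv := sd_het / mean_het]
  list(per_individual = per_ind, per_group = per_grp,
       missing_fraction = mean(is.na(g)))
}

#' Per-taxon call-rate distribution
#'
#' @param gm \code{genotype_matrix}.
#' @return list: \code{per_taxon} (\code{data.table(id, call_rate)}),
#'   \code{mean_call_rate}.
#' @export
taxon_call_rates <- function(gm) {
  cr <- colMeans(!is.na(gm$geno))
  list(per_taxon = data.table(id = gm$taxa, call_rate = cr),
       mean_call_rate = mean(cr))
}

#' Convert truth genotypes to a genotype matrix at chosen sites
#'
#' Extracts the truth genotype codes at the (chrom, pos) coordinates of a
#' called matrix (or at all truth variants), producing a
#' \code{genotype_matrix} directly comparable with a callset.
#'
#' @param truth \code{gbs_truth}.
#' @param sites optional site table (\code{chrom}, \code{pos}) or
#'   \code{genotype_matrix} whose coordinates to extract.
#' @param taxa samples to include (default all).
#' @return a \code{genotype_matrix} of truth calls (no missing data).
#' @export
truth_as_matrix <- function(truth, sites = NULL, taxa = NULL) {
  taxa <- taxa %||% truth$pedigree$id
  v <- truth$variants
  if (is.null(sites)) {
    idx <- seq_len(nrow(v))
    st <- v[, .(chrom, pos, ref, alt)]
  } else {
    st <- site_table(sites)[, .(chrom, pos)]
    idx <- v[st, on = c("chrom", "pos"), which = TRUE]
    assert_that(!anyNA(idx), "some sites are not truth variants")
    st <- v[idx, .(chrom, pos, ref, alt)]
  }
  geno <- truth$hap1[idx, taxa, drop = FALSE] +
    truth$hap2[idx, taxa, drop = FALSE]
  as_genotype_matrix(geno, chrom = st$chrom, pos = st$pos,
                     ref = st$ref, alt = st$alt)
}
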