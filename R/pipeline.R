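#' Default end-to-end run configuration
#'
#' Desk-scale defaults: a ~10 Mb ten-chromosome genome (2 large, 3
#' medium, 5 micro), PstI digestion with a 200-500 bp size window,
#' a 5 + 5 founder / 8 F1 / five-family F2 design, 48-plex lanes, and the
#' published genotype-matrix filters (mnTCov 0.20, mnScov 0.90, mnMAF
#' 0.01, misMat 0.05). Any element can be overridden through \code{...}.
#'
#' @param ... named overrides of the defaults.
#' @return a \code{gbs_config} list.
#' @export
gbs_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 2500000L, chr2 = 2500000L, chr3 = 1000000L,
                      chr4 = 1000000L, chr5 = 1000000L, chr6 = 400000L,
                      chr7 = 400000L, chr8 = 400000L, chr9 = 400000L,
                      chr10 = 400000L),
    chrom_classes = c("large", "large", "medium", "medium", "medium",
                      "micro", "micro", "micro", "micro", "micro"),
    gc = 0.42,
    enzyme = "PstI",
    window = c(200, 500),
    n_genes = 120L,
    variant_density = 0.01,
    divergence_fraction = 0.8,
    residual_het = 0.25,
    n_tt = 5L, n_cc = 5L, n_f1 = 8L,
    family_sizes = c(6L, 6L, 6L, 6L, 6L),
    recomb_rate_per_bp = 3e-8,
    plex = 48L,
    barcode_lengths = c(4, 8),
    read_len = 100L,
    mean_depth = 8,
    nb_size = 2,
    base_error = 0.005,
    min_quality = 24L,
    min_read_len = 50L,
    epsilon = 0.01,
    max_mismatch = 3L,
    min_allele_frac = 0.01,
    mnTCov = 0.20, mnScov = 0.90, mnMAF = 0.01, misMat = 0.05,
    min_lod = 8, max_rf = 0.35, seg_alpha = 0.001,
    run_linkage = TRUE,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0, "unknown config entries: %s",
              paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "gbs_config")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[gbsforge] ", fmt), ...))
}

#' Run the full GBS study emulation end to end
#'
#' Executes the whole flow on synthetic data: genome and gene-model
#' simulation, variant planting, pedigree simulation, in silico digestion
#' and size selection, barcode/key design, read simulation, quality
#' filtering, demultiplexing, master-catalog construction, tag alignment,
#' SNP discovery/calling/filtering, and the evaluation suite (concordance
#' vs truth, Mendelian errors, heterozygosity, call rates, annotation,
#' distance and density tables, and optional two-point linkage grouping).
#' Re-running with the same configuration is bit-identical.
#'
#' @param config a \code{\link{gbs_config}}.
#' @param out_dir optional directory for artifacts (FASTA/VCF/TSV/manifest);
#'   \code{NULL} keeps everything in memory.
#' @param quiet suppress progress messages.
#' @return list of class \code{gbs_run} with all intermediate objects,
#'   reports and a \code{manifest} of stage counts.
#' @export
run_end_to_end <- function(config = gbs_config(), out_dir = NULL,
                           quiet = FALSE) {
  cfg <- config
  t0 <- Sys.time()
  manifest <- list(seed = cfg$seed, config = unclass(cfg))

  log_stage(quiet, "simulating genome (%d chromosomes, %.1f Mb)",
            length(cfg$chrom_lengths), sum(cfg$chrom_lengths) / 1e6)
  genome <- simulate_genome(cfg$chrom_lengths, cfg$chrom_classes,
                            gc = cfg$gc, seed = cfg$seed)
  gm <- simulate_gene_models(genome, cfg$n_genes, seed = cfg$seed)
  genome <- gm$genome
  log_stage(quiet, "planting variants (density %g)", cfg$variant_density)
  variants <- plant_variants(genome, cfg$variant_density,
                             cfg$divergence_fraction, seed = cfg$seed,
                             avoid_enzyme = cfg$enzyme)
  manifest$n_variants <- nrow(variants)

  log_stage(quiet, "simulating pedigree (%d F0 + %d F1 + %d F2)",
            cfg$n_tt + cfg$n_cc, cfg$n_f1, sum(cfg$family_sizes))
  truth <- if (length(cfg$family_sizes) && sum(cfg$family_sizes) > 0) {
    build_f2_design(variants, cfg$family_sizes, cfg$n_tt, cfg$n_cc,
                    cfg$n_f1, cfg$residual_het, cfg$recomb_rate_per_bp,
                    seed = cfg$seed)
  } else {
    log_stage(quiet, "no F2 families requested; founders only")
    simulate_founders(variants, cfg$n_tt, cfg$n_cc, cfg$residual_het,
                      seed = cfg$seed)
  }
  manifest$n_samples <- nrow(truth$pedigree)

  log_stage(quiet, "digesting with %s", gbs_enzyme(cfg$enzyme)$name)
  frags <- digest_genome(genome, cfg$enzyme)
  fsel <- size_select(frags, cfg$window)
  manifest$n_fragments <- nrow(frags)
  manifest$n_fragments_in_window <- nrow(fsel)
  plan <- plan_multiplex(nrow(fsel), 2, cfg$plex,
                         reads_per_lane = cfg$mean_depth * cfg$plex *
                           2 * nrow(fsel))

  log_stage(quiet, "designing barcodes and key (%d samples, %d-plex)",
            nrow(truth$pedigree), cfg$plex)
  plex_eff <- min(cfg$plex, nrow(truth$pedigree))
  bset <- design_barcodes(plex_eff, cfg$barcode_lengths, enzyme = cfg$enzyme,
                          seed = cfg$seed)
  key <- make_key_file(truth$pedigree$id, bset, plex = plex_eff)

  log_stage(quiet, "simulating reads (depth %g, error %g)",
            cfg$mean_depth, cfg$base_error)
  sim <- simulate_reads(genome, truth, fsel, key, cfg$enzyme,
                        read_len = cfg$read_len, mean_depth = cfg$mean_depth,
                        nb_size = cfg$nb_size, base_error = cfg$base_error,
                        seed = cfg$seed)
  manifest$n_reads <- sum(vapply(sim$lanes, nrow, integer(1)))

  log_stage(quiet, "quality filter + demultiplex (%d lanes)",
            length(sim$lanes))
  demuxed <- list(); qc_in <- 0L; qc_kept <- 0L; dm_un <- 0L
  for (ln in names(sim$lanes)) {
    lane_no <- as.integer(sub(".*_", "", ln))
    qf <- quality_filter(sim$lanes[[ln]], cfg$min_quality, cfg$min_read_len)
    qc_in <- qc_in + qf$tally$n_in; qc_kept <- qc_kept + qf$tally$retained
    dm <- demultiplex(qf$reads, sim$key[Lane == lane_no], cfg$enzyme)
    dm_un <- dm_un + dm$tally$unassigned
    demuxed[[ln]] <- dm$reads
  }
  demuxed <- rbindlist(demuxed)
  manifest$reads_qc_in <- qc_in
  manifest$reads_qc_retained <- qc_kept
  manifest$reads_unassigned <- dm_un
  manifest$reads_assigned <- nrow(demuxed)

  log_stage(quiet, "building master tag catalog")
  catalog <- build_master_catalog(demuxed, cfg$enzyme)
  manifest$catalog_tags <- length(unique(catalog$counts$tag))
  manifest$catalog_reads <- catalog$totals$retained

  log_stage(quiet, "aligning %d tags", manifest$catalog_tags)
  aln <- align_tags(catalog, genome, cfg$enzyme, k = cfg$max_mismatch)
  manifest$tags_aligned <- nrow(aln$alignments)
  manifest$tags_unaligned <- length(aln$unaligned)
  manifest$tag_mapped_fraction <-
    manifest$tags_aligned / max(1L, manifest$catalog_tags)

  log_stage(quiet, "discovering and calling SNPs")
  calls_raw <- discover_and_call(aln, catalog, genome, epsilon = cfg$epsilon,
                                 min_allele_frac = cfg$min_allele_frac)
  manifest$sites_unfiltered <- nrow(calls_raw$geno)
  calls <- apply_filters(calls_raw, cfg$mnTCov, cfg$mnScov, cfg$mnMAF,
                         cfg$misMat)
  manifest$sites_filtered <- nrow(calls$geno)
  manifest$filter_report <- attr(calls, "filter_report")

  reports <- list()
  has_ped <- any(truth$pedigree$generation == "F2")
  if (nrow(calls$geno)) {
    log_stage(quiet, "evaluating against truth")
    tm_sites <- calls$sites[paste0(chrom, ":", pos) %in%
                              truth$variants[, paste0(chrom, ":", pos)]]
    reports$position_concordance <-
      position_concordance(calls, truth$variants)
    tmat <- truth_as_matrix(truth, tm_sites)
    qsub <- subset_sites(calls, tm_sites$site_id)
    reports$concordance <- genotype_concordance(qsub, tmat)
    reports$het_summary <- heterozygosity_summary(
      calls, split(truth$pedigree$id,
                   ifelse(truth$pedigree$generation == "F2",
                          truth$pedigree$family,
                          paste0(truth$pedigree$generation, "_",
                                 truth$pedigree$line))))
    reports$call_rates <- taxon_call_rates(calls)
    if (has_ped) {
      reports$mendel <- mendelian_errors(calls, truth$pedigree)
    } else {
      log_stage(quiet, "skipping Mendelian testing: no F2 pedigree")
    }
    log_stage(quiet, "annotating and summarizing distances")
    reports$annotation <- annotate_variants(calls$sites, gm$features, genome)
    reports$annotation_counts <-
      reports$annotation[, .N, by = category][order(-N)]
    reports$distance <- distance_summary(calls$sites)
    reports$density <- density_by_class(calls$sites, chrom_classes(genome),
                                        setNames(Biostrings::width(genome),
                                                 names(genome)))
    if (cfg$run_linkage && has_ped) {
      log_stage(quiet, "two-point linkage analysis")
      reports$linkage <- linkage_from_calls(calls, truth, cfg)
      manifest$n_linkage_groups <- reports$linkage$groups$n_groups
    } else if (cfg$run_linkage) {
      log_stage(quiet, "skipping linkage: no F2 pedigree")
    }
  } else {
    warning("no sites survived filtering; evaluation skipped")
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  run <- structure(list(config = cfg, genome = genome,
                        features = gm$features, variants = variants,
                        truth = truth, fragments = frags,
                        fragments_in_window = fsel, plan = plan,
                        barcodes = bset, key = key, sites = sim$sites,
                        catalog = catalog, alignments = aln,
                        calls_unfiltered = calls_raw, calls = calls,
                        reports = reports, manifest = manifest),
                   class = "gbs_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

## pooled-family two-point analysis on the called F2 genotypes
linkage_from_calls <- function(calls, truth, cfg) {
  ped <- truth$pedigree
  fams <- unique(ped[generation == "F2"]$family)
  ## use the largest family's offspring with its two parents
  fam <- fams[which.max(tabulate(match(ped$family, fams)))]
  kids <- ped[family == fam & generation == "F2"]
  sire <- unique(kids$sire); dam <- unique(kids$dam)
  g <- calls$geno
  have <- intersect(c(kids$id), colnames(g))
  assert_that(all(c(sire, dam) %in% colnames(g)),
              "F1 parents missing from the callset")
  off <- g[, have, drop = FALSE]
  sg <- g[, sire]; dg <- g[, dam]
  cls <- classify_segregation(sg, dg)
  ## segregation-distortion filter
  keep <- rep(FALSE, nrow(off))
  for (i in which(cls != "uninformative")) {
    cnt <- tabulate(off[i, ] + 1L, 3L)
    if (sum(cnt) == 0) next
    keep[i] <- segregation_chi2(cnt, cls[i], alpha = cfg$seg_alpha)$keep
  }
  mk <- which(keep)
  pairs <- twopoint_all(off[mk, , drop = FALSE], sg[mk], dg[mk])
  marker_chrom <- setNames(calls$sites$chrom, calls$sites$site_id)
  groups <- group_markers(pairs, cfg$min_lod, cfg$max_rf, marker_chrom,
                          markers = rownames(off)[mk])
  list(seg_class = data.table(marker = rownames(off), class = cls,
                              kept = keep),
       pairs = pairs, groups = groups, family = fam)
}

#' Extract a subset of sites from a genotype matrix
#' @param gm \code{genotype_matrix}.
#' @param site_ids site ids to keep (order preserved).
#' @return a \code{genotype_matrix}.
#' @export
subset_sites <- function(gm, site_ids) {
  idx <- match(site_ids, gm$sites$site_id)
  assert_that(!anyNA(idx), "unknown site ids")
  structure(list(sites = gm$sites[idx], taxa = gm$taxa,
                 geno = gm$geno[idx, , drop = FALSE],
                 ad_ref = gm$ad_ref[idx, , drop = FALSE],
                 ad_alt = gm$ad_alt[idx, , drop = FALSE],
                 multiallelic = gm$multiallelic),
            class = "genotype_matrix")
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(run$genome, file.path(out_dir, "genome.fa.gz"))
  write_gene_models_gff3(run$features, file.path(out_dir, "genes.gff3"))
  write_truth_vcf(run$truth, file.path(out_dir, "truth.vcf.gz"))
  write_pedigree_tsv(run$truth, file.path(out_dir, "pedigree.tsv"))
  write_fragments_bed(run$fragments_in_window,
                      file.path(out_dir, "fragments_in_window.bed"))
  write_key_file(run$key, file.path(out_dir, "key.tsv"))
  write_catalog_tsv(run$catalog, file.path(out_dir, "catalog.tsv"))
  write_callset(run$calls, file.path(out_dir, "calls.vcf.gz"))
  manifest <- run$manifest
  manifest$config$window <- as.numeric(manifest$config$window)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.gbs_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "<gbs_run> seed %d\n",
    "  genome: %.1f Mb, fragments %d (in window %d)\n",
    "  samples %d, reads %d (assigned %d), tags %d (aligned %d)\n",
    "  sites: %d unfiltered -> %d filtered\n"),
    m$seed, sum(x$config$chrom_lengths) / 1e6, m$n_fragments,
    m$n_fragments_in_window, m$n_samples, m$n_reads, m$reads_assigned,
    m$catalog_tags, m$tags_aligned, m$sites_unfiltered, m$sites_filtered))
  invisible(x)
}
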