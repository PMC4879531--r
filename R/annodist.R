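#' Functional-context annotation of SNPs
#'
#' Classifies each variant against a set of transcript models using
#' interval logic plus strand-aware codon translation for CDS overlaps.
#' Categories per overlapping transcript: \code{intronic} (or
#' \code{splicing} within \code{splice_width} bases of an intron edge),
#' \code{exonic:synonymous} / \code{exonic:non-synonymous} /
#' \code{exonic:start-lost} / \code{exonic:stop-gained} /
#' \code{exonic:stop-lost} for CDS positions, \code{5'UTR}, \code{3'UTR},
#' \code{ncRNA} (exon of a non-coding transcript), \code{upstream1kb} /
#' \code{downstream1kb} for the flanks. A variant overlapping no
#' transcript or flank is \code{intergenic}. One variant may carry
#' multiple annotations across transcripts.
#'
#' @param variants table with \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt} (a \code{truth_variants} or
#'   \code{genotype_matrix} sites table works).
#' @param features gene-model feature table
#'   (\code{\link{simulate_gene_models}} layout).
#' @param genome \code{DNAStringSet} (for codon lookups; ref alleles are
#'   verified against it).
#' @param flank flank width in bp (default 1000).
#' @param splice_width intronic bases at each intron edge classified as
#'   splicing (default 2).
#' @return \code{data.table(variant_id, chrom, pos, transcript_id,
#'   category)}; every variant has at least one row.
#' @export
annotate_variants <- function(variants, features, genome, flank = 1000L,
                              splice_width = 2L) {
  genome <- as_genome(genome)
  v <- site_table(variants)
  if (!"id" %in% names(v)) v[, id := paste0(chrom, ":", pos)]
  ## verify ref alleles
  if ("ref" %in% names(v)) {
    v[, gref := {
      substring(as.character(genome[[chrom[1]]]), pos + 1L, pos + 1L)
    }, by = chrom]
    bad <- v[ref != gref]
    assert_that(nrow(bad) == 0,
                "ref allele mismatch vs genome at %s:%d",
                bad$chrom[1], bad$pos[1])
  }
  fx <- as.data.table(features)
  out <- list()
  if (nrow(fx)) {
    tx <- fx[type == "exon", .(tstart = min(start), tend = max(end),
                               strand = strand[1], chrom = chrom[1],
                               biotype = biotype[1]),
             by = transcript_id]
    vgr <- GenomicRanges::GRanges(v$chrom,
                                  IRanges::IRanges(v$pos + 1L, v$pos + 1L))
    tgr <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$tstart + 1L - flank,
                                                   tx$tend + flank))
    hits <- GenomicRanges::findOverlaps(vgr, tgr)
    hv <- S4Vectors::queryHits(hits); ht <- S4Vectors::subjectHits(hits)
    cds_cache <- new.env(parent = emptyenv())
    for (h in seq_along(hv)) {
      vi <- hv[h]; ti <- ht[h]
      out[[length(out) + 1L]] <-
        classify_one(v[vi], tx[ti], fx, genome, flank, splice_width,
                     cds_cache)
    }
  }
  ann <- rbindlist(out)
  done <- if (nrow(ann)) unique(ann$variant_id) else character(0)
  inter <- v[!id %in% done,
             .(variant_id = id, chrom, pos, transcript_id = NA_character_,
               category = "intergenic")]
  ann <- rbind(ann, inter)
  setorder(ann, chrom, pos)
  ann[]
}

## category rows for one variant x one transcript
classify_one <- function(vr, txr, fx, genome, flank, splice_width, cache) {
  p <- vr$pos
  tid <- txr$transcript_id
  strand <- txr$strand
  base <- data.table(variant_id = vr$id, chrom = vr$chrom, pos = p,
                     transcript_id = tid)
  if (p < txr$tstart || p >= txr$tend) {    # flank
    before <- p < txr$tstart
    cat <- if ((strand == "+") == before) "upstream1kb" else "downstream1kb"
    return(base[, .(variant_id, chrom, pos, transcript_id, category = cat)])
  }
  ex <- fx[transcript_id == tid & type == "exon"]
  in_exon <- any(p >= ex$start & p < ex$end)
  if (!in_exon) {
    ## intron; splice region = first/last splice_width intronic bases
    setorder(ex, start)
    dedge <- min(abs(p - ex$end[-nrow(ex)]),
                 abs(ex$start[-1L] - 1L - p))
    cat <- if (dedge < splice_width) "splicing" else "intronic"
    return(base[, .(variant_id, chrom, pos, transcript_id, category = cat)])
  }
  if (txr$biotype != "coding")
    return(base[, .(variant_id, chrom, pos, transcript_id,
                    category = "ncRNA")])
  u5 <- fx[transcript_id == tid & type == "five_prime_UTR"]
  u3 <- fx[transcript_id == tid & type == "three_prime_UTR"]
  if (nrow(u5) && any(p >= u5$start & p < u5$end))
    return(base[, .(variant_id, chrom, pos, transcript_id,
                    category = "5'UTR")])
  if (nrow(u3) && any(p >= u3$start & p < u3$end))
    return(base[, .(variant_id, chrom, pos, transcript_id,
                    category = "3'UTR")])
  ## CDS: codon classification
  key <- tid
  m <- get0(key, envir = cache)
  if (is.null(m)) {
    m <- cds_map(fx, tid)
    m$seq <- {
      b <- substring(as.character(genome[[m$chrom]]), m$gpos + 1L, m$gpos + 1L)
      if (m$strand == "-") comp_base(b) else b
    }
    assign(key, m, envir = cache)
  }
  cpos <- match(p, m$gpos)
  if (is.na(cpos))
    return(base[, .(variant_id, chrom, pos, transcript_id,
                    category = "exonic:unclassified")])
  cat <- paste0("exonic:", codon_consequence(m, cpos, vr$alt))
  base[, .(variant_id, chrom, pos, transcript_id, category = cat)]
}

## consequence of substituting the CDS base at cpos (1-based) with alt
## (alt given on the genomic forward strand)
codon_consequence <- function(m, cpos, alt) {
  stops <- c("TAA", "TAG", "TGA")
  alt_cds <- if (m$strand == "-") comp_base(alt) else alt
  ci <- (cpos - 1L) %/% 3L              # 0-based codon index
  off <- (cpos - 1L) %% 3L
  cs <- ci * 3L + 1L
  ref_codon <- paste(m$seq[cs:(cs + 2L)], collapse = "")
  altv <- m$seq[cs:(cs + 2L)]; altv[off + 1L] <- alt_cds
  alt_codon <- paste(altv, collapse = "")
  n_codon <- length(m$seq) %/% 3L
  if (ci == 0L && ref_codon == "ATG" && alt_codon != "ATG")
    return("start-lost")
  if (ref_codon %in% stops && !(alt_codon %in% stops))
    return("stop-lost")
  if (!(ref_codon %in% stops) && alt_codon %in% stops)
    return("stop-gained")
  aa <- function(cod) as.character(Biostrings::translate(
    Biostrings::DNAString(cod), no.init.codon = TRUE))
  if (aa(ref_codon) == aa(alt_codon)) "synonymous" else "non-synonymous"
}

#' Adjacent-SNP distance summary
#'
#' Computes distances between adjacent variant positions within each
#' chromosome and summarizes them per chromosome and genome-wide (mean,
#' median, min, max) together with binned fractions of the pooled
#' distance list. The GBS signature is a mean far larger than the median,
#' reflecting clusters of SNPs inside the sequenced tag regions.
#'
#' @param variants table with \code{chrom}, \code{pos}.
#' @param bin_edges distance bin edges in bp.
#' @return list: \code{per_chrom} (\code{data.table}), \code{overall}
#'   (list with mean/median/min/max), \code{bins}
#'   (\code{data.table(bin_lo, bin_hi, fraction)}), \code{distances}.
#' @export
distance_summary <- function(variants,
                             bin_edges = c(0, 1e3, 1e4, 1e5, 1e6, Inf)) {
  v <- site_table(variants)
  v <- unique(v[, .(chrom, pos)])
  setorder(v, chrom, pos)
  v[, d := c(NA_integer_, diff(pos)), by = chrom]
  d <- v$d[!is.na(v$d)]
  if (!length(d)) {
    return(list(per_chrom = data.table(), overall = list(),
                bins = data.table(), distances = numeric(0)))
  }
  per_chrom <- v[!is.na(d), .(n = .N, mean = mean(d), median = median(d),
                              min = min(d), max = max(d)), by = chrom]
  overall <- list(n = length(d), mean = mean(d), median = median(d),
                  min = min(d), max = max(d))
  bin <- cut(d, bin_edges, labels = FALSE, right = FALSE,
             include.lowest = TRUE)
  nb <- length(bin_edges) - 1L
  frac <- tabulate(bin, nb) / length(d)
  bins <- data.table(bin_lo = bin_edges[-length(bin_edges)],
                     bin_hi = bin_edges[-1L], fraction = frac)
  list(per_chrom = per_chrom, overall = overall, bins = bins, distances = d)
}

#' SNP density by chromosome size class
#'
#' @param variants table with \code{chrom}, \code{pos}.
#' @param chrom_classes named vector mapping chromosome to class
#'   (large/medium/micro); see \code{\link{chrom_classes}}.
#' @param class_sizes named numeric vector of total bp per chromosome, or
#'   per class when names are class labels.
#' @return \code{data.table(class, n_snps, pct_of_snps, snp_per_mbp)}.
#' @export
density_by_class <- function(variants, chrom_classes, class_sizes) {
  v <- site_table(variants)
  miss <- setdiff(unique(v$chrom), names(chrom_classes))
  assert_that(length(miss) == 0, "no class label for chromosome(s): %s",
              paste(miss, collapse = ", "))
  cls_bp <- if (all(names(class_sizes) %in% unique(chrom_classes))) {
    class_sizes
  } else {
    tapply(class_sizes[names(chrom_classes)], chrom_classes, sum)
  }
  v[, class := chrom_classes[chrom]]
  out <- v[, .(n_snps = .N), by = class]
  base <- data.table(class = names(cls_bp))
  out <- out[base, on = "class"]
  out[is.na(n_snps), n_snps := 0L]
  out[, pct_of_snps := if (sum(n_snps) > 0) 100 * n_snps / sum(n_snps) else 0]
  out[, snp_per_mbp := n_snps / (as.numeric(cls_bp[class]) / 1e6)]
  out[]
}
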