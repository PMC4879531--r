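#' Write gene models as GFF3
#'
#' Exports the feature table of \code{\link{simulate_gene_models}} (0-based
#' half-open) as standard 1-based GFF3 with gene/mRNA/exon/CDS/UTR rows.
#' Uses \pkg{rtracklayer} when available, else writes the (simple) format
#' directly; \code{\link{read_gene_models_gff3}} round-trips either output.
#'
#' @param features feature \code{data.table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gene_models_gff3 <- function(features, path) {
  fx <- as.data.table(features)
  typ <- c(exon = "exon", CDS = "CDS", five_prime_UTR = "five_prime_UTR",
           three_prime_UTR = "three_prime_UTR")
  gene_rows <- fx[type == "exon",
                  .(start = min(start), end = max(end), strand = strand[1],
                    chrom = chrom[1], biotype = biotype[1]),
                  by = .(gene_id, transcript_id)]
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gene_rows))) {
    gr <- gene_rows[i]
    lines <- c(lines,
               sprintf("%s\tgbsforge\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       gr$chrom, gr$start + 1L, gr$end, gr$strand, gr$gene_id,
                       gr$biotype),
               sprintf("%s\tgbsforge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gr$chrom, gr$start + 1L, gr$end, gr$strand,
                       gr$transcript_id, gr$gene_id))
    sub <- fx[transcript_id == gr$transcript_id]
    for (j in seq_len(nrow(sub))) {
      lines <- c(lines,
                 sprintf("%s\tgbsforge\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                         sub$chrom[j], typ[sub$type[j]], sub$start[j] + 1L,
                         sub$end[j], sub$strand[j],
                         if (sub$type[j] == "CDS") "0" else ".",
                         gr$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses exon/CDS/UTR rows (via \pkg{rtracklayer} when installed) back
#' into the internal 0-based feature layout.
#'
#' @param path GFF3 path.
#' @return feature \code{data.table}.
#' @export
read_gene_models_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    d <- as.data.table(as.data.frame(gr))
    d[, type := as.character(type)]
    keep <- d[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
    par <- vapply(keep$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    keep[, transcript_id := par]
    mrna <- d[type == "mRNA"]
    gene_of <- setNames(vapply(mrna$Parent, function(p) p[[1]], character(1)),
                        mrna$ID)
    genes <- d[type == "gene"]
    biotype_of <- setNames(
      if ("biotype" %in% names(genes)) as.character(genes$biotype)
      else rep("coding", nrow(genes)), genes$ID)
    out <- keep[, .(gene_id = gene_of[transcript_id], transcript_id,
                    chrom = as.character(seqnames), strand = as.character(strand),
                    type, start = start - 1L, end = end,
                    biotype = biotype_of[gene_of[transcript_id]])]
  } else {
    raw <- fread(path, sep = "\t", header = FALSE, skip = "\t",
                 col.names = c("chrom", "src", "type", "start", "end", "score",
                               "strand", "phase", "attr"))
    gattr <- function(a, k) sub(sprintf(".*%s=([^;]+).*", k), "\\1", a)
    mrna <- raw[type == "mRNA"]
    gene_of <- setNames(gattr(mrna$attr, "Parent"), gattr(mrna$attr, "ID"))
    genes <- raw[type == "gene"]
    biotype_of <- setNames(gattr(genes$attr, "biotype"), gattr(genes$attr, "ID"))
    keep <- raw[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
    keep[, transcript_id := gattr(attr, "Parent")]
    out <- keep[, .(gene_id = gene_of[transcript_id], transcript_id, chrom,
                    strand, type, start = start - 1L, end = as.integer(end),
                    biotype = biotype_of[gene_of[transcript_id]])]
  }
  setorder(out, chrom, transcript_id, type, start)
  out[]
}

#' Write truth variants (with founder-origin tags) as VCF
#'
#' Sites-only VCF with INFO fields \code{ORIGIN} (TT-fixed / CC-fixed /
#' shared) and \code{AF}; with a \code{gbs_truth}, phased \code{GT}
#' columns are added for all samples.
#'
#' @param x \code{truth_variants} table or \code{gbs_truth} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_truth_vcf <- function(x, path) {
  truth <- NULL
  v <- if (methods::is(x, "gbs_truth")) { truth <- x; x$variants } else x
  lines <- c("##fileformat=VCFv4.2",
             "##source=gbsforge-truth",
             '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Founder origin">',
             '##INFO=<ID=AF,Number=1,Type=Float,Description="Population alt frequency">')
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  info <- sprintf("ORIGIN=%s;AF=%.4f", v$origin, v$freq)
  if (!is.null(truth)) {
    hdr <- c(hdr, "FORMAT", truth$pedigree$id)
    lines <- c(lines,
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">')
    gt <- matrix(paste0(truth$hap1, "|", truth$hap2), nrow = nrow(truth$hap1))
    body <- paste(v$chrom, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS", info,
                  "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    body <- paste(v$chrom, v$pos + 1L, v$id, v$ref, v$alt, ".", "PASS", info,
                  sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(lines, paste(hdr, collapse = "\t"), body), con)
  close(con)
  invisible(path)
}
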