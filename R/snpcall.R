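#' Reference tag index
#'
#' Enumerates the candidate tag placements of a genome for a given enzyme:
#' one forward and one reverse read-oriented \code{tag_len}-mer anchored at
#' every cut site (the simplified stand-in for a general short-read
#' aligner; genuine GBS tags can only originate at cut sites).
#'
#' @param genome \code{DNAStringSet}.
#' @param enzyme digestion enzyme.
#' @param tag_len tag length (default 64).
#' @return \code{data.table(cand_id, chrom, wstart, wend, strand, seq)}
#'   with \code{seq} in read orientation.
#' @export
ref_tag_index <- function(genome, enzyme, tag_len = 64L) {
  genome <- as_genome(genome)
  enzyme <- gbs_enzyme(enzyme)
  frags <- digest_genome(genome, enzyme)
  fps <- tag_footprints(frags, genome, enzyme, tag_len = tag_len)
  fps[, seq := {
    s <- seq_windows(genome[[chrom[1]]], wstart, tag_len)
    if (.BY$strand == "-") revcomp(s) else s
  }, by = .(chrom, strand)]
  fps[, cand_id := sprintf("%s:%d:%s", chrom, wstart, strand)]
  setcolorder(fps, c("cand_id", "chrom", "wstart", "wend", "strand", "cut", "seq"))
  fps[]
}

#' Align catalog tags to the reference
#'
#' Places each unique tag at the candidate position (either strand)
#' minimizing the Hamming mismatch count, requiring at most \code{k}
#' mismatches. Ties across distinct placements leave the tag unaligned
#' (the multi-mapping exclusion rule). Uses a pigeonhole seed search: a
#' tag within \code{k} mismatches of a candidate matches it exactly on at
#' least one of \code{k + 1} equal chunks.
#'
#' @param catalog a \code{\link{build_master_catalog}} result.
#' @param genome \code{DNAStringSet}.
#' @param enzyme digestion enzyme.
#' @param k maximum mismatches (default 3).
#' @param tag_len tag length.
#' @return list of class \code{tag_alignments}: \code{alignments}
#'   (\code{data.table(tag, cand_id, chrom, wstart, wend, strand, nmis)}),
#'   \code{mismatches} (\code{data.table(tag, cand_id, off, read_base,
#'   gpos, allele)} with \code{allele} on the genomic forward strand),
#'   \code{unaligned} (character), \code{index} (the reference tag index).
#' @export
align_tags <- function(catalog, genome, enzyme, k = 3L, tag_len = 64L) {
  idx <- ref_tag_index(genome, enzyme, tag_len)
  queries <- unique(catalog$counts$tag)
  queries <- queries[nchar(queries) == tag_len & !grepl("[^ACGT]", queries)]
  nchunk <- k + 1L
  bounds <- floor(seq(0L, tag_len, length.out = nchunk + 1L))
  qdt <- data.table(tag = queries)
  cdt <- idx[, .(cand_id, seq)]
  pairs <- rbindlist(lapply(seq_len(nchunk), function(ci) {
    a <- bounds[ci] + 1L; b <- bounds[ci + 1L]
    q <- qdt[, .(tag, kk = substr(tag, a, b))]
    cc <- cdt[, .(cand_id, kk = substr(seq, a, b))]
    q[cc, on = "kk", nomatch = NULL, allow.cartesian = TRUE,
      .(tag = x.tag, cand_id = i.cand_id)]
  }))
  pairs <- unique(pairs)
  if (nrow(pairs) == 0) {
    return(structure(list(alignments = data.table(), mismatches = data.table(),
                          unaligned = queries, index = idx),
                     class = "tag_alignments"))
  }
  cand_seq <- cdt$seq[match(pairs$cand_id, cdt$cand_id)]
  pairs[, nmis := hamming_pairs(tag, cand_seq)]
  pairs <- pairs[nmis <= k]
  if (nrow(pairs) == 0) {
    return(structure(list(alignments = data.table(), mismatches = data.table(),
                          unaligned = queries, index = idx),
                     class = "tag_alignments"))
  }
  ## unique best placement per tag; ties -> unaligned
  best <- pairs[pairs[, .I[nmis == min(nmis)], by = tag]$V1]
  nb <- best[, .N, by = tag]
  best <- best[nb, on = "tag"][N == 1L][, N := NULL]
  aln <- idx[best, on = "cand_id",
             .(tag = i.tag, cand_id, chrom, wstart, wend, strand,
               nmis = i.nmis)]
  ## mismatch details for aligned tags
  mm <- mismatch_detail(aln, cdt)
  structure(list(alignments = aln, mismatches = mm,
                 unaligned = setdiff(queries, aln$tag), index = idx),
            class = "tag_alignments")
}

## vectorized Hamming distance between equal-length string vectors
hamming_pairs <- function(a, b, chunk = 50000L) {
  n <- length(a)
  if (n == 0) return(integer(0))
  L <- nchar(a[1])
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    am <- matrix(charToRaw(paste(a[s:e], collapse = "")), nrow = L)
    bm <- matrix(charToRaw(paste(b[s:e], collapse = "")), nrow = L)
    out[s:e] <- colSums(am != bm)
  }
  out
}

## per-alignment mismatch positions -> genomic coordinates and alleles
mismatch_detail <- function(aln, cdt, chunk = 20000L) {
  withm <- aln[nmis > 0L]
  if (nrow(withm) == 0)
    return(data.table(tag = character(), cand_id = character(),
                      off = integer(), read_base = character(),
                      gpos = integer(), allele = character()))
  L <- nchar(withm$tag[1])
  res <- list()
  cseq <- cdt$seq[match(withm$cand_id, cdt$cand_id)]
  for (s in seq(1L, nrow(withm), by = chunk)) {
    e <- min(nrow(withm), s + chunk - 1L)
    am <- matrix(charToRaw(paste(withm$tag[s:e], collapse = "")), nrow = L)
    bm <- matrix(charToRaw(paste(cseq[s:e], collapse = "")), nrow = L)
    d <- which(am != bm, arr.ind = TRUE)
    res[[length(res) + 1L]] <- data.table(
      row = d[, 2L] + s - 1L, off = d[, 1L] - 1L,
      read_base = rawToChar(am[d], multiple = TRUE))
  }
  mm <- rbindlist(res)
  mm[, tag := withm$tag[row]]
  mm[, cand_id := withm$cand_id[row]]
  mm[, strand := withm$strand[row]]
  mm[, gpos := ifelse(strand == "+", withm$wstart[row] + off,
                      withm$wend[row] - 1L - off)]
  mm[, allele := ifelse(strand == "-", comp_base(read_base), read_base)]
  mm[, chrom := withm$chrom[row]]
  mm[, c("row", "strand") := NULL]
  setcolorder(mm, c("tag", "cand_id", "chrom", "off", "read_base", "gpos",
                    "allele"))
  mm[]
}

#' Discover and call biallelic SNPs from aligned tags
#'
#' At each aligned tag-locus column where tags disagree with the
#' reference, the reference base and the most frequent alternative allele
#' define a biallelic site. An alternative allele is considered present
#' when it carries at least \code{min_allele_frac} of the locus read
#' depth, which keeps sporadic sequencing-error alleles out of the allele
#' count; columns with two or more present alternatives are recorded as
#' multi-allelic and excluded, as in the published analysis. Genotypes
#' are called per sample from the allele depths \code{(dref, dalt)} by
#' maximum likelihood with a fixed per-read error rate \code{epsilon}:
#' \code{L(homRef) = (1-e)^dref * e^dalt}, symmetric for homAlt, and
#' \code{L(het) = 0.5^(dref+dalt)}; zero depth or likelihood ties give a
#' missing call.
#'
#' Because each tag locus is called independently, the same genomic
#' position can appear in two loci (duplicate sites); these are handled
#' downstream by the mismatch-rate filter of \code{\link{apply_filters}}.
#'
#' @param aln a \code{\link{align_tags}} result.
#' @param catalog the corresponding \code{tag_catalog}.
#' @param genome reference genome.
#' @param epsilon per-read base error rate (default 0.01).
#' @param min_allele_frac minimum locus read fraction for an allele to be
#'   considered present (default 0.01).
#' @param min_depth minimum allele depth for a genotype call (default 1).
#' @param taxa taxa to genotype; defaults to all samples in the catalog.
#' @return object of class \code{genotype_matrix}: list with \code{sites}
#'   (\code{data.table(site_id, chrom, pos, ref, alt, cand_id)}),
#'   \code{taxa}, integer matrices \code{geno} (0 homRef / 1 het /
#'   2 homAlt / NA missing), \code{ad_ref}, \code{ad_alt} (sites x taxa),
#'   and \code{multiallelic} (excluded columns).
#' @export
discover_and_call <- function(aln, catalog, genome, epsilon = 0.01,
                              min_allele_frac = 0.01, min_depth = 1L,
                              taxa = NULL) {
  assert_that(epsilon > 0 && epsilon < 0.5, "epsilon must be in (0, 0.5)")
  genome <- as_genome(genome)
  taxa <- taxa %||% sort(unique(catalog$counts$sample))
  cnt <- catalog$counts[sample %in% taxa]
  percand <- aln$alignments[, .(tag, cand_id)][cnt, on = "tag", nomatch = NULL]
  D <- percand[, .(D = sum(n)), by = .(cand_id, sample)]
  Dtot <- D[, .(Dtot = sum(D)), by = cand_id]
  mm <- aln$mismatches[cnt, on = "tag", nomatch = NULL, allow.cartesian = TRUE]
  empty <- emptym(taxa)
  if (nrow(mm) == 0) return(empty)
  altdep <- mm[, .(d = sum(n)), by = .(cand_id, chrom, gpos, allele, sample)]
  coltot <- altdep[, .(dcol = sum(d)), by = .(cand_id, chrom, gpos, allele)]
  coltot <- Dtot[coltot, on = "cand_id"]
  coltot[, present := dcol / Dtot >= min_allele_frac]
  nalt <- coltot[present == TRUE, .(n_present = .N), by = .(cand_id, gpos)]
  multi <- coltot[nalt[n_present >= 2L], on = c("cand_id", "gpos")]
  keepcols <- coltot[present == TRUE][nalt[n_present == 1L],
                                      on = c("cand_id", "gpos")]
  if (nrow(keepcols) == 0) { empty$multiallelic <- multi; return(empty) }
  ## site table with reference alleles from the genome
  sites <- keepcols[, .(cand_id, chrom, pos = gpos, alt = allele)]
  sites[, ref := {
    substring(as.character(genome[[chrom[1]]]), pos + 1L, pos + 1L)
  }, by = chrom]
  sites[, site_id := sprintf("%s:%d:%s", chrom, pos, cand_id)]
  setorder(sites, chrom, pos, cand_id)
  ns <- nrow(sites); nt <- length(taxa)
  srow <- setNames(seq_len(ns), sites$site_id)
  tcol <- setNames(seq_len(nt), taxa)
  ## per-sample alt depth at kept sites
  ad_alt <- matrix(0L, ns, nt, dimnames = list(sites$site_id, taxa))
  a <- altdep[sites, on = c("cand_id", gpos = "pos"), nomatch = NULL,
              .(site_id, sample, allele = x.allele, alt = i.alt, d = x.d)]
  akeep <- a[allele == alt]
  ad_alt[cbind(srow[akeep$site_id], tcol[akeep$sample])] <- akeep$d
  ## other-allele depth (errors at this column) to subtract from ref
  aoth <- a[allele != alt, .(d = sum(d)), by = .(site_id, sample)]
  d_other <- matrix(0L, ns, nt)
  d_other[cbind(srow[aoth$site_id], tcol[aoth$sample])] <- aoth$d
  ## total locus depth per sample
  Dm <- matrix(0L, ns, nt)
  dj <- D[sites[, .(cand_id, site_id)], on = "cand_id",
          nomatch = NULL, allow.cartesian = TRUE]
  Dm[cbind(srow[dj$site_id], tcol[dj$sample])] <- dj$D
  ad_ref <- Dm - ad_alt - d_other
  stopifnot(all(ad_ref >= 0L))
  geno <- call_genotypes(ad_ref, ad_alt, epsilon, min_depth)
  structure(list(sites = sites[, .(site_id, chrom, pos, ref, alt, cand_id)],
                 taxa = taxa, geno = geno, ad_ref = ad_ref, ad_alt = ad_alt,
                 multiallelic = multi),
            class = "genotype_matrix")
}

emptym <- function(taxa) {
  structure(list(sites = data.table(site_id = character(), chrom = character(),
                                    pos = integer(), ref = character(),
                                    alt = character(), cand_id = character()),
                 taxa = taxa,
                 geno = matrix(NA_integer_, 0, length(taxa),
                               dimnames = list(NULL, taxa)),
                 ad_ref = matrix(0L, 0, length(taxa)),
                 ad_alt = matrix(0L, 0, length(taxa)),
                 multiallelic = data.table()),
            class = "genotype_matrix")
}

## ML genotype from allele-depth matrices
call_genotypes <- function(ad_ref, ad_alt, epsilon, min_depth = 1L) {
  ll0 <- ad_ref * log(1 - epsilon) + ad_alt * log(epsilon)
  ll2 <- ad_ref * log(epsilon) + ad_alt * log(1 - epsilon)
  ll1 <- (ad_ref + ad_alt) * log(0.5)
  g <- matrix(NA_integer_, nrow(ad_ref), ncol(ad_ref),
              dimnames = dimnames(ad_ref))
  top <- pmax(ll0, ll1, ll2)
  tie <- (ll0 == top) + (ll1 == top) + (ll2 == top) > 1L
  g[ll0 == top] <- 0L
  g[ll1 == top] <- 1L
  g[ll2 == top] <- 2L
  g[tie] <- NA_integer_
  g[(ad_ref + ad_alt) < min_depth] <- NA_integer_
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d taxa; missing %.2f%%\n",
              nrow(x$geno), length(x$taxa),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Construct a genotype matrix from components
#'
#' Convenience constructor used by tests, the truth-set converter and the
#' VCF reader.
#'
#' @param geno integer matrix (sites x taxa) of 0/1/2/NA codes.
#' @param chrom,pos,ref,alt per-site fields (\code{pos} 0-based).
#' @param ad_ref,ad_alt optional allele-depth matrices.
#' @param site_id optional site identifiers.
#' @return a \code{genotype_matrix}.
#' @export
as_genotype_matrix <- function(geno, chrom, pos, ref = "A", alt = "C",
                               ad_ref = NULL, ad_alt = NULL, site_id = NULL) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  sites <- data.table(chrom = rep_len(chrom, ns), pos = as.integer(pos),
                      ref = rep_len(ref, ns), alt = rep_len(alt, ns),
                      cand_id = NA_character_)
  sites[, site_id := site_id %||% sprintf("%s:%d", chrom, pos)]
  setcolorder(sites, c("site_id", "chrom", "pos", "ref", "alt", "cand_id"))
  rownames(geno) <- sites$site_id
  zero <- matrix(0L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  structure(list(sites = sites, taxa = colnames(geno), geno = geno,
                 ad_ref = ad_ref %||% zero, ad_alt = ad_alt %||% zero,
                 multiallelic = data.table()),
            class = "genotype_matrix")
}

#' Apply the GBS genotype-matrix filters
#'
#' First removes taxa whose call rate is below \code{mnTCov}; then removes
#' sites whose call rate is below \code{mnScov} or whose minor allele
#' frequency is below \code{mnMAF}; finally resolves co-located duplicate
#' sites (identical chrom and position called from different tag loci):
#' groups whose genotype mismatch rate over taxa called in both exceeds
#' \code{misMat} are removed entirely, otherwise the duplicates are merged
#' missing-aware (conflicting calls become missing, depths are summed).
#'
#' @param gm a \code{genotype_matrix}.
#' @param mnTCov minimum per-taxon call rate (default 0.20).
#' @param mnScov minimum per-site call rate (default 0.90).
#' @param mnMAF minimum minor allele frequency (default 0.01).
#' @param misMat maximum duplicate-site mismatch rate (default 0.05).
#' @return filtered \code{genotype_matrix} with a \code{filter_report}
#'   attribute (taxa/site counts removed by each rule).
#' @export
apply_filters <- function(gm, mnTCov = 0.20, mnScov = 0.90, mnMAF = 0.01,
                          misMat = 0.05) {
  for (v in c(mnTCov, mnScov, mnMAF, misMat))
    assert_that(v >= 0 && v <= 1, "filter thresholds must be in [0,1]")
  g <- gm$geno
  tcr <- colMeans(!is.na(g))
  keep_taxa <- tcr >= mnTCov
  g <- g[, keep_taxa, drop = FALSE]
  taxa <- gm$taxa[keep_taxa]
  ar <- gm$ad_ref[, keep_taxa, drop = FALSE]
  aa <- gm$ad_alt[, keep_taxa, drop = FALSE]
  scr <- rowMeans(!is.na(g))
  p <- rowMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_site <- scr >= mnScov & maf >= mnMAF
  keep_site[is.na(keep_site)] <- FALSE
  sites <- gm$sites[keep_site]
  g <- g[keep_site, , drop = FALSE]
  ar <- ar[keep_site, , drop = FALSE]
  aa <- aa[keep_site, , drop = FALSE]
  n_dup_removed <- 0L; n_dup_merged <- 0L
  dup <- sites[, .N, by = .(chrom, pos)][N >= 2L]
  if (nrow(dup)) {
    drop_rows <- integer(0); merge_groups <- list()
    for (r in seq_len(nrow(dup))) {
      rows <- which(sites$chrom == dup$chrom[r] & sites$pos == dup$pos[r])
      mism <- 0
      for (i in seq_along(rows)) for (j in seq_len(i - 1L)) {
        a <- g[rows[i], ]; b <- g[rows[j], ]
        both <- !is.na(a) & !is.na(b)
        mism <- max(mism, if (any(both)) mean(a[both] != b[both]) else 0)
      }
      if (mism > misMat) {
        drop_rows <- c(drop_rows, rows)
        n_dup_removed <- n_dup_removed + length(rows)
      } else {
        merge_groups[[length(merge_groups) + 1L]] <- rows
        n_dup_merged <- n_dup_merged + length(rows)
      }
    }
    merged_g <- list(); merged_ar <- list(); merged_aa <- list()
    merged_sites <- list()
    for (rows in merge_groups) {
      sub <- g[rows, , drop = FALSE]
      cons <- sub[1L, ]
      for (i in seq_len(nrow(sub))[-1L]) {
        b <- sub[i, ]
        conflict <- !is.na(cons) & !is.na(b) & cons != b
        cons[is.na(cons)] <- b[is.na(cons)]
        cons[conflict] <- NA_integer_
      }
      merged_g[[length(merged_g) + 1L]] <- cons
      merged_ar[[length(merged_ar) + 1L]] <- colSums(ar[rows, , drop = FALSE])
      merged_aa[[length(merged_aa) + 1L]] <- colSums(aa[rows, , drop = FALSE])
      s <- sites[rows[1L]]
      s[, cand_id := paste(sites[rows]$cand_id, collapse = ";")]
      merged_sites[[length(merged_sites) + 1L]] <- s
    }
    all_dup_rows <- c(drop_rows, unlist(merge_groups))
    keep <- setdiff(seq_len(nrow(g)), all_dup_rows)
    g2 <- g[keep, , drop = FALSE]
    ar2 <- ar[keep, , drop = FALSE]
    aa2 <- aa[keep, , drop = FALSE]
    sites2 <- sites[keep]
    if (length(merged_g)) {
      g2 <- rbind(g2, do.call(rbind, merged_g))
      ar2 <- rbind(ar2, do.call(rbind, merged_ar))
      aa2 <- rbind(aa2, do.call(rbind, merged_aa))
      sites2 <- rbind(sites2, rbindlist(merged_sites))
    }
    ord <- order(sites2$chrom, sites2$pos)
    g <- g2[ord, , drop = FALSE]; ar <- ar2[ord, , drop = FALSE]
    aa <- aa2[ord, , drop = FALSE]; sites <- sites2[ord]
  }
  rownames(g) <- sites$site_id
  if (nrow(g) == 0) warning("no sites survive filtering")
  out <- structure(list(sites = sites, taxa = taxa, geno = g,
                        ad_ref = ar, ad_alt = aa,
                        multiallelic = gm$multiallelic),
                   class = "genotype_matrix")
  attr(out, "filter_report") <- list(
    taxa_in = length(gm$taxa), taxa_removed = sum(!keep_taxa),
    sites_in = nrow(gm$geno),
    sites_failed_cov_or_maf = sum(!keep_site),
    duplicate_sites_removed = n_dup_removed,
    duplicate_sites_merged = n_dup_merged)
  out
}

#' Write a callset as VCF 4.2
#'
#' Emits GT and AD fields; 0-based site positions become 1-based VCF
#' positions. \code{\link{read_callset}} round-trips the file to an equal
#' genotype matrix.
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output path (".gz" writes gzip).
#' @return invisibly, \code{path}.
#' @export
write_callset <- function(gm, path) {
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt[which(gm$geno == 0L)] <- "0/0"
  gt[which(gm$geno == 1L)] <- "0/1"
  gt[which(gm$geno == 2L)] <- "1/1"
  ad <- matrix(paste0(gm$ad_ref, ",", gm$ad_alt), nrow(gm$geno))
  body <- matrix(paste0(gt, ":", ad), nrow(gm$geno))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=gbsforge",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$taxa), collapse = "\t"))
  if (nrow(gm$geno)) {
    rows <- paste(gm$sites$chrom, gm$sites$pos + 1L, gm$sites$site_id,
                  gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT:AD",
                  apply(body, 1L, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, rows)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read a VCF callset written by \code{\link{write_callset}}
#'
#' Minimal VCF reader for biallelic GT(:AD) records.
#'
#' @param path VCF path.
#' @return a \code{genotype_matrix}.
#' @export
read_callset <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[startsWith(lines, "#")]
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  assert_that(length(chrom_line) == 1, "not a VCF: missing #CHROM header")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  taxa <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(as_genotype_matrix(matrix(NA_integer_, 0, length(taxa),
                                     dimnames = list(NULL, taxa)),
                              character(0), integer(0)))
  }
  f <- fread(text = body, sep = "\t", header = FALSE)
  setnames(f, seq_along(cols), cols)
  fmt <- strsplit(f$FORMAT[1], ":", fixed = TRUE)[[1]]
  gti <- which(fmt == "GT"); adi <- which(fmt == "AD")
  parse_col <- function(x) {
    parts <- tstrsplit(x, ":", fixed = TRUE)
    gt <- parts[[gti]]
    g <- rep(NA_integer_, length(gt))
    g[gt %in% c("0/0", "0|0")] <- 0L
    g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    g[gt %in% c("1/1", "1|1")] <- 2L
    ad <- if (length(adi)) tstrsplit(parts[[adi]], ",", fixed = TRUE) else
      list("0", "0")
    list(g = g, ar = suppressWarnings(as.integer(ad[[1]])),
         aa = suppressWarnings(as.integer(ad[[2]])))
  }
  parsed <- lapply(taxa, function(tx) parse_col(f[[tx]]))
  geno <- do.call(cbind, lapply(parsed, `[[`, "g"))
  ar <- do.call(cbind, lapply(parsed, `[[`, "ar"))
  aa <- do.call(cbind, lapply(parsed, `[[`, "aa"))
  ar[is.na(ar)] <- 0L; aa[is.na(aa)] <- 0L
  colnames(geno) <- colnames(ar) <- colnames(aa) <- taxa
  as_genotype_matrix(geno, chrom = as.character(f$`#CHROM`),
                     pos = f$POS - 1L, ref = f$REF, alt = f$ALT,
                     ad_ref = ar, ad_alt = aa, site_id = f$ID)
}
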