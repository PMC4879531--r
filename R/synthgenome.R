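#' Simulate a synthetic genome with chromosome size classes
#'
#' Generates random i.i.d. sequence at a requested GC content for a set of
#' chromosomes labelled \code{large} / \code{medium} / \code{micro},
#' mirroring the three chromosome size classes of the chicken karyotype.
#' Optionally plants a restriction motif at a fixed spacing and destroys
#' every accidental occurrence elsewhere, which gives downstream digestion
#' tests an exactly known fragment structure (k planted sites per
#' chromosome imply k + 1 fragments).
#'
#' @param lengths integer vector of chromosome lengths (bp), named or not.
#' @param classes character vector of class labels (\code{"large"},
#'   \code{"medium"}, \code{"micro"}), recycled to \code{length(lengths)}.
#' @param gc target GC fraction in (0, 1).
#' @param motif_spacing optional planted-motif spacing in bp.
#' @param enzyme enzyme whose motif is planted/destroyed when
#'   \code{motif_spacing} is set.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return \code{DNAStringSet} with chromosome classes stored in
#'   \code{metadata(.)$chrom_class} (see \code{\link{chrom_classes}}).
#' @examples
#' g <- simulate_genome(c(5e4, 2e4), c("large", "micro"), seed = 1)
#' @export
simulate_genome <- function(lengths,
                            classes = c("large", "medium", "micro"),
                            gc = 0.42, motif_spacing = NULL,
                            enzyme = "PstI", seed = 1) {
  assert_that(all(lengths > 0), "chromosome lengths must be positive")
  assert_that(gc > 0 && gc < 1, "gc must be in (0,1)")
  classes <- rep(classes, length.out = length(lengths))
  assert_that(all(classes %in% c("large", "medium", "micro")),
              "classes must be large/medium/micro")
  nm <- names(lengths) %||% paste0("chr", seq_along(lengths))
  if (is.null(names(lengths))) names(lengths) <- nm
  set.seed(derive_seed(seed, "genome"))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nm
  if (!is.null(motif_spacing)) {
    enzyme <- gbs_enzyme(enzyme)
    ml <- nchar(enzyme$recognition)
    assert_that(motif_spacing >= ml,
                "motif spacing must be at least the motif length (%d)", ml)
    genome <- plant_motifs(genome, enzyme, motif_spacing)
  }
  S4Vectors::metadata(genome)$chrom_class <- setNames(classes, nm)
  genome
}

## plant motif every `spacing` bp (at offsets 0, spacing, 2*spacing, ...)
## and scrub accidental occurrences everywhere else
plant_motifs <- function(genome, enzyme, spacing) {
  motif <- enzyme$recognition
  ml <- nchar(motif)
  spacing <- as.integer(spacing)
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    k <- (L - ml) %/% spacing + 1L
    planted0 <- (seq_len(k) - 1L) * spacing          # 0-based motif starts
    s <- genome[[i]]
    at <- IRanges::IRanges(start = planted0 + 1L, width = ml)
    s <- Biostrings::replaceAt(s, at, rep(motif, k))
    planted_fp <- unlist(lapply(planted0 + 1L, function(a) a:(a + ml - 1L)))
    for (iter in 1:25) {
      hits <- IRanges::start(Biostrings::matchPattern(motif, s, fixed = TRUE))
      bad <- setdiff(hits, planted0 + 1L)
      if (!length(bad)) break
      ## mutate one base of each stray occurrence, outside planted footprints
      for (b in bad) {
        cand <- setdiff(b:(b + ml - 1L), planted_fp)
        p <- cand[1L]
        cur <- as.character(Biostrings::subseq(s, p, p))
        repl <- setdiff(c("A", "C", "G", "T"), cur)[sample.int(3L, 1L)]
        s <- Biostrings::replaceAt(s, IRanges::IRanges(p, p), repl)
      }
    }
    hits <- IRanges::start(Biostrings::matchPattern(motif, s, fixed = TRUE))
    assert_that(identical(sort(hits), sort(planted0 + 1L)),
                "motif scrubbing failed to converge on %s", names(genome)[i])
    genome[[i]] <- s
  }
  genome
}

#' Simulate gene models on a genome
#'
#' Places non-overlapping multi-exon gene models (a fraction of them
#' non-coding) and rewrites the underlying genome so that every coding
#' sequence starts with ATG, contains no internal stop codon, and ends with
#' a stop codon on its own strand. This provides a consistent substrate for
#' functional-context annotation of variants (intron/exon/UTR/flank and
#' codon-level consequences).
#'
#' @param genome \code{DNAStringSet}; the returned genome carries the codon
#'   edits, so downstream steps must use \code{$genome} of the result.
#' @param n_genes number of gene models to place.
#' @param ncrna_fraction fraction of models that are non-coding.
#' @param exon_count_range,exon_len_range,intron_len_range,utr_len_range
#'   integer ranges the per-gene structure is drawn from.
#' @param seed integer seed.
#' @param max_tries placement attempts per gene before declaring the
#'   packing infeasible.
#' @return list with elements \code{genome} (edited \code{DNAStringSet})
#'   and \code{features}: a \code{data.table} with columns \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{strand}, \code{type}
#'   (\code{exon}, \code{CDS}, \code{five_prime_UTR},
#'   \code{three_prime_UTR}), \code{start}, \code{end} (0-based half-open),
#'   \code{biotype} (\code{coding}/\code{ncRNA}).
#' @export
simulate_gene_models <- function(genome, n_genes, ncrna_fraction = 0.05,
                                 exon_count_range = c(2L, 6L),
                                 exon_len_range = c(120L, 360L),
                                 intron_len_range = c(200L, 1500L),
                                 utr_len_range = c(40L, 200L),
                                 seed = 1, max_tries = 200L) {
  genome <- as_genome(genome)
  set.seed(derive_seed(seed, "genes"))
  lens <- Biostrings::width(genome)
  occupied <- lapply(seq_along(genome), function(i) integer(0))  # interval list
  feats <- vector("list", n_genes)
  if (n_genes == 0)
    return(list(genome = genome,
                features = data.table(gene_id = character(), transcript_id = character(),
                                      chrom = character(), strand = character(),
                                      type = character(), start = integer(),
                                      end = integer(), biotype = character())))
  occ <- data.table(chrom = character(), start = integer(), end = integer())
  for (g in seq_len(n_genes)) {
    coding <- runif(1) >= ncrna_fraction
    ne <- sample(exon_count_range[1]:exon_count_range[2], 1L)
    el <- sample(exon_len_range[1]:exon_len_range[2], ne, replace = TRUE)
    il <- if (ne > 1) sample(intron_len_range[1]:intron_len_range[2], ne - 1L,
                             replace = TRUE) else integer(0)
    span <- sum(el) + sum(il)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(length(genome), 1L, prob = lens)
      if (lens[ci] < span + 2L) next
      st <- sample.int(lens[ci] - span, 1L) - 1L     # 0-based gene start
      cand <- c(st, st + span)
      hit <- occ[chrom == names(genome)[ci] & start < cand[2] & end > cand[1]]
      if (nrow(hit) == 0) { placed <- TRUE; break }
    }
    assert_that(placed, "infeasible gene packing: could not place gene %d", g)
    chrom <- names(genome)[ci]
    strand <- sample(c("+", "-"), 1L)
    ex_st <- st + cumsum(c(0L, head(el, -1L) + il))
    exons <- data.table(start = ex_st, end = ex_st + el)
    occ <- rbind(occ, data.table(chrom = chrom, start = st, end = st + span))
    gid <- sprintf("gene%04d", g)
    tid <- sprintf("tx%04d", g)
    rows <- data.table(gene_id = gid, transcript_id = tid, chrom = chrom,
                       strand = strand, type = "exon",
                       start = exons$start, end = exons$end,
                       biotype = if (coding) "coding" else "ncRNA")
    if (coding) {
      total <- sum(el)
      u5 <- sample(utr_len_range[1]:utr_len_range[2], 1L)
      u3 <- sample(utr_len_range[1]:utr_len_range[2], 1L)
      ## shrink the UTRs when the transcript is short: the CDS keeps >= 24 bp
      while (total - u5 - u3 < 24L && (u5 > 10L || u3 > 10L)) {
        u5 <- max(10L, u5 %/% 2L); u3 <- max(10L, u3 %/% 2L)
      }
      cds_len <- total - u5 - u3
      cds_len <- cds_len - cds_len %% 3L
      assert_that(cds_len >= 18L, "gene %d too short for a CDS", g)
      u3 <- total - u5 - cds_len
      ## transcript-coordinate intervals -> genomic, strand aware
      rows <- rbind(rows,
                    tx_to_genomic(exons, strand, 0L, u5, gid, tid, chrom,
                                  "five_prime_UTR"),
                    tx_to_genomic(exons, strand, u5, u5 + cds_len, gid, tid,
                                  chrom, "CDS"),
                    tx_to_genomic(exons, strand, u5 + cds_len, total, gid, tid,
                                  chrom, "three_prime_UTR"))
    }
    feats[[g]] <- rows
  }
  features <- rbindlist(feats)
  genome <- enforce_orfs(genome, features)
  list(genome = genome, features = features)
}

## map a [lo, hi) interval in transcript (5'->3') coordinates onto genomic
## exon pieces; exons table is genomic-sorted 0-based half-open
tx_to_genomic <- function(exons, strand, lo, hi, gid, tid, chrom, type) {
  el <- exons$end - exons$start
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  off <- cumsum(c(0L, el[ord][-length(el)]))
  out <- list()
  for (j in seq_along(ord)) {
    a <- max(lo, off[j]); b <- min(hi, off[j] + el[ord[j]])
    if (a >= b) next
    if (strand == "+") {
      gs <- exons$start[ord[j]] + (a - off[j]); ge <- gs + (b - a)
    } else {
      ge <- exons$end[ord[j]] - (a - off[j]); gs <- ge - (b - a)
    }
    out[[length(out) + 1L]] <- data.table(gene_id = gid, transcript_id = tid,
                                          chrom = chrom, strand = strand,
                                          type = type, start = gs, end = ge,
                                          biotype = "coding")
  }
  rbindlist(out)
}

## spliced CDS sequence (5'->3') and the genomic position of each CDS base
cds_map <- function(features, tid) {
  cds <- features[transcript_id == tid & type == "CDS"]
  setorder(cds, start)
  gpos <- unlist(lapply(seq_len(nrow(cds)),
                        function(j) cds$start[j]:(cds$end[j] - 1L)))
  if (cds$strand[1] == "-") gpos <- rev(gpos)
  list(gpos = gpos, strand = cds$strand[1], chrom = cds$chrom[1])
}

## rewrite genome bases so every CDS is a clean ORF
enforce_orfs <- function(genome, features) {
  stops <- c("TAA", "TAG", "TGA")
  edits <- list()
  for (tid in unique(features[type == "CDS"]$transcript_id)) {
    m <- cds_map(features, tid)
    chromseq <- as.character(genome[[m$chrom]])
    base <- substring(chromseq, m$gpos + 1L, m$gpos + 1L)
    if (m$strand == "-") base <- comp_base(base)
    n <- length(base)
    codon_start <- seq(1L, n, by = 3L)
    fix <- function(i, want) {           # set CDS positions i to bases want
      for (k in seq_along(i)) {
        if (base[i[k]] != want[k]) {
          g <- m$gpos[i[k]]
          b <- if (m$strand == "-") comp_base(want[k]) else want[k]
          edits[[length(edits) + 1L]] <<- data.table(chrom = m$chrom,
                                                     pos = g, base = b)
          base[i[k]] <<- want[k]
        }
      }
    }
    fix(1:3, c("A", "T", "G"))
    ## destroy internal stops (mutate 3rd codon base; TAA/TAG -> TAC, TGA -> TGC)
    for (cs in codon_start[-c(1L, length(codon_start))]) {
      cod <- paste0(base[cs], base[cs + 1L], base[cs + 2L])
      if (cod %in% stops) fix(cs + 2L, "C")
    }
    fix((n - 2L):n, c("T", "A", "A"))
  }
  if (length(edits)) {
    ed <- rbindlist(edits)
    for (ch in unique(ed$chrom)) {
      e <- ed[chrom == ch]
      genome[[ch]] <- Biostrings::replaceLetterAt(
        genome[[ch]], e$pos + 1L, paste(e$base, collapse = ""))
    }
  }
  genome
}

#' Plant true biallelic SNPs on a genome
#'
#' Draws variant positions at a mean density per bp (Poisson per
#' chromosome), assigns each a founder-line origin -- fixed-divergent
#' between the two founder pools (TT vs CC) with probability
#' \code{divergence_fraction}, otherwise shared-polymorphic with a
#' population alternative-allele frequency drawn uniformly from
#' \code{shared_freq_range} -- and verifies every reference allele against
#' the genome. Positions overlapping an occurrence of the digestion
#' enzyme's motif can be excluded (\code{avoid_enzyme}) so that planted
#' variants never silently destroy a cut site.
#'
#' The default density of 0.01 variants/bp emulates the density of a
#' whole-genome resequencing truth set for strongly divergent lines
#' (roughly 12 million SNPs on a 1 Gb genome).
#'
#' @param genome \code{DNAStringSet}.
#' @param density expected variants per bp.
#' @param divergence_fraction fraction of variants fixed-divergent between
#'   founder lines.
#' @param seed integer seed.
#' @param avoid_enzyme optional enzyme whose motif occurrences are excluded.
#' @param shared_freq_range range of alternative-allele frequencies for
#'   shared-polymorphic variants.
#' @return \code{data.table} of class \code{truth_variants}: \code{chrom},
#'   \code{pos} (0-based), \code{ref}, \code{alt}, \code{origin}
#'   (\code{TT-fixed}, \code{CC-fixed}, \code{shared}), \code{freq}.
#' @export
plant_variants <- function(genome, density = 0.01, divergence_fraction = 0.8,
                           seed = 1, avoid_enzyme = NULL,
                           shared_freq_range = c(0.05, 0.95)) {
  genome <- as_genome(genome)
  assert_that(density > 0, "density must be positive")
  set.seed(derive_seed(seed, "variants"))
  rows <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    n <- rpois(1L, density * L)
    allowed <- rep(TRUE, L)
    if (!is.null(avoid_enzyme)) {
      e <- gbs_enzyme(avoid_enzyme)
      hits <- Biostrings::matchPattern(e$recognition, genome[[i]], fixed = TRUE)
      for (j in seq_along(hits)) {
        allowed[IRanges::start(hits)[j]:IRanges::end(hits)[j]] <- FALSE
      }
    }
    pos1 <- sample(which(allowed), min(n, sum(allowed)))
    pos1 <- sort(pos1)
    ref <- substring(as.character(genome[[i]]), pos1, pos1)
    ok <- ref %in% c("A", "C", "G", "T")
    pos1 <- pos1[ok]; ref <- ref[ok]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  character(1), USE.NAMES = FALSE)
    rows[[i]] <- data.table(chrom = names(genome)[i], pos = pos1 - 1L,
                            ref = ref, alt = alt)
  }
  v <- rbindlist(rows)
  nv <- nrow(v)
  fixed <- runif(nv) < divergence_fraction
  which_line <- sample(c("TT-fixed", "CC-fixed"), nv, replace = TRUE)
  v[, origin := ifelse(fixed, which_line, "shared")]
  v[, freq := ifelse(fixed, 0.5,
                     runif(nv, shared_freq_range[1], shared_freq_range[2]))]
  setorder(v, chrom, pos)
  v[, id := paste0(chrom, ":", pos)]
  setattr(v, "class", c("truth_variants", class(v)))
  v[]
}
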