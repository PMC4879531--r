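#' In silico restriction digestion
#'
#' Cleaves every sequence of a genome at each exact occurrence of the
#' enzyme's recognition motif on the forward strand (palindromic motifs make
#' a reverse scan redundant), placing the cut at \code{motif start +
#' cut_offset}. Motif occurrences overlapping an ambiguous base (N) are
#' ignored. Fragments tile each sequence exactly: the two terminal fragments
#' are included, so a sequence with \code{k} sites yields \code{k + 1}
#' fragments.
#'
#' @param genome \code{DNAStringSet} (or character vector) of ACGTN
#'   sequences; all sequences, including scaffolds, are digested.
#' @param enzyme a \code{\link{gbs_enzyme}} or built-in enzyme name.
#' @return a \code{data.table} of class \code{gbs_fragments} with columns
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open) and
#'   \code{length}.
#' @examples
#' digest_genome(c(chr1 = "AAACTGCAGAAA"), "PstI")
#' @export
digest_genome <- function(genome, enzyme) {
  genome <- as_genome(genome)
  enzyme <- gbs_enzyme(enzyme)
  cuts <- cut_sites(genome, enzyme)
  lens <- Biostrings::width(genome)
  frags <- rbindlist(lapply(seq_along(genome), function(i) {
    b <- c(0L, cuts[[i]], lens[i])
    data.table(chrom = names(genome)[i],
               start = b[-length(b)], end = b[-1L])
  }))
  frags[, length := end - start]
  setattr(frags, "class", c("gbs_fragments", class(frags)))
  frags[]
}

## 0-based cut positions per sequence (list parallel to genome)
cut_sites <- function(genome, enzyme) {
  m <- Biostrings::vmatchPattern(enzyme$recognition, genome, fixed = TRUE)
  lapply(seq_along(genome), function(i) {
    s <- IRanges::start(m[[i]])          # 1-based motif starts
    sort(s - 1L + enzyme$cut_offset)     # 0-based cut points
  })
}

#' Select fragments by length window
#'
#' Keeps exactly the fragments whose length lies inside the inclusive
#' window, preserving coordinates and order. The canonical GBS window for
#' Illumina short-read libraries is 200-500 bp.
#'
#' @param fragments output of \code{\link{digest_genome}}.
#' @param window length-2 numeric \code{c(lo, hi)} in bp, inclusive;
#'   \code{hi} may be \code{Inf}.
#' @return fragments subset, same columns.
#' @export
size_select <- function(fragments, window = c(200, 500)) {
  assert_that(length(window) == 2 && window[1] > 0 && window[1] <= window[2],
              "window must be c(lo, hi) with 0 < lo <= hi")
  fragments[fragments$length >= window[1] & fragments$length <= window[2], ]
}

#' Fragment length histogram by chromosome class
#'
#' Tabulates fragment counts in length bins, split by chromosome size class
#' (large / medium / micro). Fragments outside the outermost bin edges are
#' dropped; bins are left-closed, right-open except the last (right-closed),
#' following \code{cut}-style conventions.
#'
#' @param fragments a \code{gbs_fragments} table.
#' @param bin_edges strictly increasing numeric vector of bin edges.
#' @param chrom_classes named character vector mapping every chromosome in
#'   \code{fragments} to a class label; \code{NULL} puts everything in one
#'   \code{"all"} class.
#' @return \code{data.table} with columns \code{class}, \code{bin_lo},
#'   \code{bin_hi}, \code{count}.
#' @export
fragment_histogram <- function(fragments, bin_edges, chrom_classes = NULL) {
  assert_that(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
              "bin edges must be strictly increasing")
  cls <- if (is.null(chrom_classes)) {
    rep("all", nrow(fragments))
  } else {
    miss <- setdiff(unique(fragments$chrom), names(chrom_classes))
    assert_that(length(miss) == 0, "no class label for chromosome(s): %s",
                paste(miss, collapse = ", "))
    unname(chrom_classes[fragments$chrom])
  }
  nb <- length(bin_edges) - 1L
  grid <- CJ(class = sort(unique(cls)), bin = seq_len(nb))
  bin <- cut(fragments$length, bin_edges, labels = FALSE,
             right = FALSE, include.lowest = TRUE)
  ## cut(right = FALSE) makes the LAST bin [lo, hi]; earlier ones [lo, hi)
  tab <- data.table(class = cls, bin = bin)[!is.na(bin),
                                            .(count = .N), by = .(class, bin)]
  out <- tab[grid, on = c("class", "bin")]
  out[is.na(count), count := 0L]
  out[, `:=`(bin_lo = bin_edges[bin], bin_hi = bin_edges[bin + 1L], bin = NULL)]
  setcolorder(out, c("class", "bin_lo", "bin_hi", "count"))
  out[]
}

#' Compare candidate enzymes on one genome
#'
#' Digests the genome with each enzyme, applies the size window, and
#' reports total fragments, in-window fragments, and the in-window ratio of
#' the first enzyme to each other enzyme (how many times fewer fragments the
#' alternative yields).
#'
#' @param genome genome sequences.
#' @param enzymes list of \code{\link{gbs_enzyme}} objects or names
#'   (at least two).
#' @param window inclusive size window, see \code{\link{size_select}}.
#' @return \code{data.table} with columns \code{enzyme}, \code{total_fragments},
#'   \code{in_window}, \code{ratio_vs_first}.
#' @export
compare_enzymes <- function(genome, enzymes, window = c(200, 500)) {
  assert_that(length(enzymes) >= 2, "need at least two enzymes to compare")
  genome <- as_genome(genome)
  rows <- lapply(enzymes, function(e) {
    e <- gbs_enzyme(e)
    fr <- digest_genome(genome, e)
    data.table(enzyme = e$name, total_fragments = nrow(fr),
               in_window = nrow(size_select(fr, window)))
  })
  out <- rbindlist(rows)
  out[, ratio_vs_first := out$in_window[1] / in_window]
  out[]
}

#' Multiplex and coverage planning
#'
#' Computes the expected per-tag-site sequencing depth for a multiplexed GBS
#' lane: \code{depth = reads_per_lane / (plex * tag_sites)} where
#' \code{tag_sites = ends_per_fragment * n_fragments_in_window}. Used to
#' choose the enzyme/plex combination delivering the target coverage
#' (the original design aimed for roughly 7X at 48-plex).
#'
#' @param n_fragments_in_window size-selected fragment count.
#' @param ends_per_fragment 1 or 2 sequenced ends per fragment.
#' @param plex samples multiplexed per lane.
#' @param reads_per_lane usable reads per lane.
#' @return list of class \code{multiplex_plan} echoing the inputs plus
#'   \code{tag_sites} and \code{expected_depth}.
#' @examples
#' plan_multiplex(159673, 2, 48, 144e6)
#' @export
plan_multiplex <- function(n_fragments_in_window, ends_per_fragment = 2,
                           plex = 48, reads_per_lane = 150e6) {
  assert_that(ends_per_fragment %in% c(1, 2), "ends_per_fragment must be 1 or 2")
  vals <- c(n_fragments_in_window, plex, reads_per_lane)
  assert_that(all(vals > 0), "all multiplex-plan inputs must be positive")
  tag_sites <- ends_per_fragment * n_fragments_in_window
  structure(list(n_fragments_in_window = n_fragments_in_window,
                 ends_per_fragment = ends_per_fragment,
                 tag_sites = tag_sites, plex = plex,
                 reads_per_lane = reads_per_lane,
                 expected_depth = reads_per_lane / (plex * tag_sites)),
            class = "multiplex_plan")
}

#' @export
print.multiplex_plan <- function(x, ...) {
  cat(sprintf(
    "<multiplex_plan> %d fragments x %d ends = %d tag sites; %d-plex; %.3g reads/lane -> %.2fX\n",
    x$n_fragments_in_window, x$ends_per_fragment, x$tag_sites, x$plex,
    x$reads_per_lane, x$expected_depth))
  invisible(x)
}

#' Tag footprints of size-selected fragments
#'
#' For each retained fragment, the sequenced 64-base tags cover one window
#' anchored at each cut-site end: reading into the fragment from its start
#' cut (forward strand) and from its end cut (reverse strand). Each window
#' spans exactly \code{tag_len} genomic bases including the cut-site remnant
#' bases. Fragment ends that coincide with a chromosome boundary carry no
#' cut site and produce no tag.
#'
#' @param fragments size-selected \code{gbs_fragments}.
#' @param genome the digested genome (for boundary clipping).
#' @param enzyme the digestion enzyme.
#' @param tag_len tag length in bases (default 64).
#' @return \code{data.table}: \code{chrom}, \code{wstart}, \code{wend}
#'   (0-based half-open genomic window), \code{strand} (+/-), \code{cut}
#'   (the 0-based cut coordinate the tag is anchored at).
#' @export
tag_footprints <- function(fragments, genome, enzyme, tag_len = 64L) {
  genome <- as_genome(genome)
  enzyme <- gbs_enzyme(enzyme)
  rl <- nchar(enzyme$remnant)
  ## window geometry assumes the remnant is the motif prefix up to the cut
  ## (the convention the read simulator and demultiplexer share)
  assert_that(identical(enzyme$remnant,
                        substr(enzyme$recognition, 1L, enzyme$cut_offset)),
              "tag footprints require remnant == motif prefix up to the cut")
  lens <- setNames(Biostrings::width(genome), names(genome))
  f <- as.data.table(fragments)
  ## rlp = motif bases 3' of the cut; by palindromic symmetry the
  ## reverse-strand read (revcomp of the window ending rlp past the cut)
  ## starts with the same remnant as the forward read
  rlp <- nchar(enzyme$recognition) - enzyme$cut_offset
  fwd <- f[start > 0L,
           .(chrom, wstart = start - rl, wend = start - rl + tag_len,
             strand = "+", cut = start)]
  rev <- f[end < lens[chrom],
           .(chrom, wstart = end + rlp - tag_len, wend = end + rlp,
             strand = "-", cut = end)]
  out <- rbind(fwd, rev)
  out <- out[wstart >= 0L & wend <= lens[chrom]]
  setorder(out, chrom, wstart, strand)
  out[]
}

#' Write fragments as BED3+length
#' @param fragments \code{gbs_fragments}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_fragments_bed <- function(fragments, path) {
  fwrite(as.data.table(fragments)[, .(chrom, start, end, length)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}
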