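#' Quality filter reads
#'
#' Trims 3' bases while the base quality is below \code{min_quality}
#' (Phred+33), then discards reads shorter than \code{min_length}. These
#' are the cleaning semantics of the standard GBS preprocessing (quality
#' >= 24, length >= 50).
#'
#' @param reads \code{data.table(id, seq, qual)} (one lane of
#'   \code{\link{simulate_reads}} output, or \code{\link{read_fastq_chr}}).
#' @param min_quality minimum 3' Phred score retained (default 24).
#' @param min_length minimum read length after trimming (default 50).
#' @return list: \code{reads} (trimmed, retained), \code{tally} with
#'   \code{n_in}, \code{retained}, \code{discarded_short}.
#' @export
quality_filter <- function(reads, min_quality = 24L, min_length = 50L) {
  assert_that(min_quality >= 0 && min_length >= 1,
              "invalid quality-filter parameters")
  if (nrow(reads) == 0)
    return(list(reads = reads,
                tally = list(n_in = 0L, retained = 0L, discarded_short = 0L)))
  ## strip the maximal 3' run of sub-threshold quality characters
  if (min_quality > 0) {
    ## retained chars are [chr(33+minq), 0x7e]; hex escapes keep the class safe
    pat <- sprintf("[^\\x%02x-\\x7e]+$", 33L + min_quality)
    trimmed_q <- sub(pat, "", reads$qual, perl = TRUE)
  } else trimmed_q <- reads$qual
  newlen <- nchar(trimmed_q)
  keep <- newlen >= min_length
  out <- reads[keep]
  out[, seq := substr(seq, 1L, newlen[keep])]
  out[, qual := trimmed_q[keep]]
  list(reads = out,
       tally = list(n_in = nrow(reads), retained = sum(keep),
                    discarded_short = sum(!keep)))
}

#' Demultiplex reads by barcode + cut-site remnant
#'
#' A read is assigned to a sample iff it begins with that sample's barcode
#' immediately followed by the enzyme's cut-site remnant (exact match).
#' The barcode is removed; the remnant is retained at the read start.
#' The prefix-free barcode-set invariant guarantees unambiguous
#' assignment. Reads matching no \code{barcode + remnant} are counted as
#' unassigned.
#'
#' @param reads one lane's reads (\code{data.table(id, seq, qual)}).
#' @param key key-file rows for this lane (columns \code{Barcode},
#'   \code{Sample}); within-lane barcodes must be unique.
#' @param enzyme digestion enzyme.
#' @return list: \code{reads} (\code{data.table(sample, id, seq, qual)}
#'   with barcode stripped), \code{tally} with \code{n_in},
#'   \code{assigned}, \code{unassigned}.
#' @export
demultiplex <- function(reads, key, enzyme) {
  enzyme <- gbs_enzyme(enzyme)
  assert_that(anyDuplicated(key$Barcode) == 0,
              "duplicate barcode within lane")
  assigned <- rep(NA_integer_, nrow(reads))
  ord <- order(-nchar(key$Barcode))
  for (j in ord) {
    pre <- paste0(key$Barcode[j], enzyme$remnant)
    hit <- is.na(assigned) & startsWith(reads$seq, pre)
    assigned[hit] <- j
  }
  ok <- !is.na(assigned)
  out <- reads[ok]
  out[, sample := key$Sample[assigned[ok]]]
  out[, seq := substr(seq, nchar(key$Barcode[assigned[ok]]) + 1L, nchar(seq))]
  out[, qual := substr(qual, nchar(key$Barcode[assigned[ok]]) + 1L, nchar(qual))]
  setcolorder(out, c("sample", "id", "seq", "qual"))
  list(reads = out,
       tally = list(n_in = nrow(reads), assigned = sum(ok),
                    unassigned = sum(!ok)))
}

#' Build the pooled "master" tag catalog
#'
#' Each demultiplexed, remnant-anchored read is truncated at the first
#' internal occurrence of the full recognition site (read-through into the
#' next fragment; the cut-site copy at the very start of the read does not
#' count), then cut to \code{tag_len} bases. Reads left with fewer than
#' \code{tag_len} bases are discarded and tallied (they are not poly-A
#' padded). Identical tags are merged across all samples with per-sample
#' counts.
#'
#' @param demuxed \code{data.table(sample, seq)} of demultiplexed reads
#'   (pooled over lanes).
#' @param enzyme digestion enzyme.
#' @param tag_len tag length (default 64, remnant included).
#' @return object of class \code{tag_catalog}: list with \code{counts}
#'   (\code{data.table(tag, sample, n)}), \code{totals} (reads in /
#'   retained / discarded by reason).
#' @export
build_master_catalog <- function(demuxed, enzyme, tag_len = 64L) {
  enzyme <- gbs_enzyme(enzyme)
  n_in <- nrow(demuxed)
  seqs <- demuxed$seq
  ## internal full-site occurrence: search from the 2nd base on
  rel <- regexpr(enzyme$recognition, substring(seqs, 2L), fixed = TRUE)
  trunc_len <- ifelse(rel > 0L, rel, nchar(seqs))
  had_internal <- rel > 0L
  keep <- trunc_len >= tag_len
  counts <- data.table(tag = substr(seqs[keep], 1L, tag_len),
                       sample = demuxed$sample[keep])[
                         , .(n = .N), by = .(tag, sample)]
  setorder(counts, tag, sample)
  structure(list(counts = counts,
                 totals = list(
                   reads_in = n_in,
                   retained = sum(keep),
                   discarded_short = sum(!keep & !had_internal),
                   discarded_truncated = sum(!keep & had_internal))),
            class = "tag_catalog")
}

#' @export
print.tag_catalog <- function(x, ...) {
  cat(sprintf("<tag_catalog> %d unique tags, %d samples, %d reads retained of %d\n",
              length(unique(x$counts$tag)), length(unique(x$counts$sample)),
              x$totals$retained, x$totals$reads_in))
  invisible(x)
}

#' Write a tag catalog TSV (tag, total, per-sample counts)
#' @param catalog a \code{tag_catalog}.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
write_catalog_tsv <- function(catalog, path) {
  wide <- dcast(catalog$counts, tag ~ sample, value.var = "n", fill = 0L)
  tot <- catalog$counts[, .(total = sum(n)), by = tag]
  out <- tot[wide, on = "tag"]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
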