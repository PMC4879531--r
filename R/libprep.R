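#' Design a set of inline barcodes
#'
#' Greedily builds \code{n} variable-length barcodes satisfying the GBS
#' adapter constraints: no barcode contains the enzyme recognition motif;
#' no \code{barcode + remnant} string is a prefix of another
#' \code{barcode + remnant} string (which makes demultiplexing
#' unambiguous); all pairwise edit distances are at least
#' \code{min_edit_distance}; and per-position base balance deviation is
#' minimized greedily among random candidates (variable lengths guard the
#' Illumina color-matrix estimation, mimicking barcode-generator practice).
#' Deterministic for a fixed seed.
#'
#' @param n number of barcodes.
#' @param length_range \code{c(min, max)} barcode length in bp.
#' @param min_edit_distance minimum pairwise Levenshtein distance.
#' @param enzyme digestion enzyme (for motif/remnant constraints).
#' @param seed integer seed.
#' @param pool_size random candidates examined per barcode slot.
#' @return object of class \code{barcode_set}: list with \code{barcodes}
#'   (character vector), \code{balance_deviation}, \code{min_edit_distance}.
#' @export
design_barcodes <- function(n, length_range = c(4, 8), min_edit_distance = 3,
                            enzyme = "PstI", seed = 1, pool_size = 300L) {
  assert_that(n >= 1, "n must be >= 1")
  enzyme <- gbs_enzyme(enzyme)
  set.seed(derive_seed(seed, "barcodes"))
  ## longer barcodes get more slots: the code space (and hence the number of
  ## mutually distant words) grows with length, and edit distance across
  ## lengths is tight (a deletion costs only 1)
  lranges <- seq(length_range[1], length_range[2])
  w <- 2^(lranges - length_range[1])
  slots <- rep(lranges, times = pmax(1L, round(n * w / sum(w))))
  lens <- sort(rep_len(sort(slots, decreasing = TRUE), n), decreasing = TRUE)
  chosen <- character(0)
  for (i in seq_len(n)) {
    pool <- character(0)
    for (L in seq(lens[i], length_range[2])) {   # bump length if infeasible
      pool <- unique(vapply(seq_len(pool_size), function(j)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1)))
      pool <- pool[!grepl(enzyme$recognition, pool, fixed = TRUE)]
      if (length(chosen)) {
        keep <- vapply(pool, function(b) {
          full <- paste0(b, enzyme$remnant)
          oth <- paste0(chosen, enzyme$remnant)
          if (any(startsWith(full, oth) | startsWith(oth, full))) return(FALSE)
          all(adist(b, chosen) >= min_edit_distance)
        }, logical(1))
        pool <- pool[keep]
      }
      if (length(pool)) break
    }
    if (!length(pool))
      stopf(paste0("infeasible barcode design at barcode %d: no candidate in ",
                   "lengths %d-%d satisfies motif/prefix/edit-distance >= %d ",
                   "constraints against the %d already chosen"),
            i, lens[i], length_range[2], min_edit_distance, length(chosen))
    dev <- vapply(pool, function(b)
      balance_deviation(c(chosen, b)), numeric(1))
    chosen <- c(chosen, pool[which.min(dev)])
  }
  structure(list(barcodes = chosen,
                 balance_deviation = balance_deviation(chosen),
                 min_edit_distance = min_edit_distance,
                 enzyme = enzyme$name),
            class = "barcode_set")
}

## total absolute deviation from uniform base usage at each position
balance_deviation <- function(barcodes) {
  maxlen <- max(nchar(barcodes))
  dev <- 0
  for (p in seq_len(maxlen)) {
    b <- substr(barcodes[nchar(barcodes) >= p], p, p)
    if (!length(b)) next
    cnt <- table(factor(b, levels = c("A", "C", "G", "T")))
    dev <- dev + sum(abs(cnt - length(b) / 4))
  }
  dev
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("<barcode_set> %d barcodes (len %d-%d), balance dev %.1f\n",
              length(x$barcodes), min(nchar(x$barcodes)),
              max(nchar(x$barcodes)), x$balance_deviation))
  invisible(x)
}

#' Build a Tassel-style key file
#'
#' Assigns samples round-robin to flowcell lanes with at most \code{plex}
#' samples per lane and unique within-lane barcodes.
#'
#' @param samples sample id vector.
#' @param barcode_set a \code{\link{design_barcodes}} result (or character
#'   vector of barcodes).
#' @param plex maximum samples per lane (the study multiplexed ~48).
#' @param flowcell flowcell name.
#' @param lanes number of lanes; default the minimum needed.
#' @return \code{data.table} with columns \code{Flowcell}, \code{Lane},
#'   \code{Barcode}, \code{Sample}.
#' @export
make_key_file <- function(samples, barcode_set, plex = 48,
                          flowcell = "SIMFC1", lanes = NULL) {
  barcodes <- if (methods::is(barcode_set, "barcode_set"))
    barcode_set$barcodes else barcode_set
  assert_that(anyDuplicated(barcodes) == 0, "barcodes must be unique")
  assert_that(plex <= length(barcodes),
              "plex (%d) exceeds barcode set size (%d)", plex, length(barcodes))
  n <- length(samples)
  lanes <- lanes %||% ceiling(n / plex)
  assert_that(n <= lanes * plex,
              "%d samples exceed capacity of %d lanes x %d plex",
              n, lanes, plex)
  lane <- (seq_len(n) - 1L) %% lanes + 1L
  idx <- (seq_len(n) - 1L) %/% lanes + 1L     # barcode slot within lane
  key <- data.table(Flowcell = flowcell, Lane = lane,
                    Barcode = barcodes[idx], Sample = samples)
  setorder(key, Lane)
  key[]
}

#' Write / read a key file TSV
#' @param key key table from \code{\link{make_key_file}}.
#' @param path TSV path.
#' @return invisibly \code{path}; \code{read_key_file} returns the table.
#' @export
write_key_file <- function(key, path) {
  fwrite(key, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_key_file
#' @export
read_key_file <- function(path) {
  key <- fread(path, sep = "\t",
               colClasses = list(character = c("Flowcell", "Barcode", "Sample")))
  assert_that(all(c("Flowcell", "Lane", "Barcode", "Sample") %in% names(key)),
              "key file must have columns Flowcell Lane Barcode Sample")
  key
}

#' Simulate barcoded GBS reads
#'
#' Generates single-end reads for both ends of every size-selected
#' fragment: each read is \code{barcode + remnant + genomic sequence} where
#' the genomic part is the sampled individual's haplotype at the fragment
#' end (carrying its alleles at planted variants), cut to the read length.
#' Per (sample, fragment end) read counts are negative-binomial around the
#' mean depth; haplotypes are sampled 50/50; base errors are injected
#' i.i.d. at \code{base_error} over the whole read, with error positions
#' assigned the low quality score and all others the high score.
#'
#' @param genome \code{DNAStringSet} used for digestion.
#' @param truth \code{gbs_truth} with phased haplotypes for all samples in
#'   the key.
#' @param fragments size-selected fragments (\code{\link{size_select}}).
#' @param key key table (\code{\link{make_key_file}}).
#' @param enzyme digestion enzyme.
#' @param read_len read length in bp (default 100).
#' @param mean_depth mean reads per tag site per sample.
#' @param nb_size negative-binomial size (dispersion) of depth.
#' @param base_error per-base error probability.
#' @param qual_high,qual_low Phred scores for correct/error bases.
#' @param seed integer seed.
#' @return list of class \code{gbs_readsim}: \code{lanes} (named list of
#'   \code{data.table(id, seq, qual)} per \code{<flowcell>_<lane>}),
#'   \code{key}, \code{sites} (tag-site window table), \code{params}.
#' @export
simulate_reads <- function(genome, truth, fragments, key, enzyme,
                           read_len = 100L, mean_depth = 8, nb_size = 2,
                           base_error = 0.005, qual_high = 35L, qual_low = 10L,
                           seed = 1) {
  genome <- as_genome(genome)
  enzyme <- gbs_enzyme(enzyme)
  assert_that(base_error >= 0 && base_error < 1, "base_error must be in [0,1)")
  max_bc <- max(nchar(key$Barcode))
  assert_that(read_len >= 64L + max_bc,
              "read length %d too short for 64-base tags after a %d-base barcode",
              read_len, max_bc)
  assert_that(all(key$Sample %in% truth$pedigree$id),
              "key contains samples absent from the truth pedigree")
  set.seed(derive_seed(seed, "reads"))
  lmax <- read_len - min(nchar(key$Barcode))
  sites <- tag_footprints(fragments, genome, enzyme, tag_len = lmax)
  assert_that(nrow(sites) > 0, "no tag sites: empty size-selected fragment set")
  sites[, site_id := sprintf("%s_%d_%s", chrom, cut, strand)]
  ## reference window sequence in read orientation
  sites[, refseq := {
    s <- seq_windows(genome[[chrom[1]]], wstart, wend[1] - wstart[1])
    if (.BY$strand == "-") revcomp(s) else s
  }, by = .(chrom, strand)]
  ## variants inside windows, with read-orientation offsets and alleles
  v <- as.data.table(truth$variants)[, .(chrom, pos, ref, alt, vid = id)]
  wv <- v[sites, on = .(chrom, pos >= wstart, pos < wend), nomatch = NULL,
          .(site_id, vid, gpos = x.pos, strand = i.strand,
            wstart = i.wstart, wend = i.wend, alt = x.alt)]
  wv[, off := ifelse(strand == "+", gpos - wstart, wend - 1L - gpos)]
  wv[, read_alt := ifelse(strand == "-", comp_base(alt), alt)]
  lanes <- split(key, paste0(key$Flowcell, "_", key$Lane))
  out <- list()
  vidx <- setNames(seq_len(nrow(truth$variants)), truth$variants$id)
  for (ln in names(lanes)) {
    lk <- lanes[[ln]]
    grid <- CJ(site_id = sites$site_id, Sample = lk$Sample, sorted = FALSE)
    grid[, depth := rnbinom(.N, size = nb_size, mu = mean_depth)]
    grid <- grid[depth > 0L]
    grid[, d1 := rbinom(.N, depth, 0.5)]
    long <- rbind(grid[d1 > 0L, .(site_id, Sample, hap = 1L, n = d1)],
                  grid[depth - d1 > 0L, .(site_id, Sample, hap = 2L,
                                          n = depth - d1)])
    ## allele pattern per (site, sample, hap) from the truth haplotypes
    pat <- wv[long, on = "site_id", nomatch = NULL, allow.cartesian = TRUE]
    pat[, allele := {
      a <- integer(.N)
      i1 <- hap == 1L
      a[i1] <- truth$hap1[cbind(vidx[vid[i1]], match(Sample[i1], colnames(truth$hap1)))]
      a[!i1] <- truth$hap2[cbind(vidx[vid[!i1]], match(Sample[!i1], colnames(truth$hap2)))]
      a
    }]
    patkey <- pat[allele == 1L,
                  .(pattern = paste(sort(off), collapse = ","),
                    offs = list(sort(off)),
                    alts = list(read_alt[order(off)])),
                  by = .(site_id, Sample, hap)]
    long <- patkey[long, on = c("site_id", "Sample", "hap")]
    long[is.na(pattern), pattern := ""]
    ## build one mutated sequence per distinct (site, pattern)
    uniqs <- long[, .(offs = offs[1], alts = alts[1]),
                  by = .(site_id, pattern)]
    uniqs <- sites[, .(site_id, refseq)][uniqs, on = "site_id"]
    uniqs[, seq := refseq]
    mut <- uniqs[pattern != ""]
    if (nrow(mut)) {
      for (r in seq_len(nrow(mut))) {
        s <- mut$seq[r]
        for (k in seq_along(mut$offs[[r]])) {
          substr(s, mut$offs[[r]][k] + 1L, mut$offs[[r]][k] + 1L) <- mut$alts[[r]][k]
        }
        mut$seq[r] <- s
      }
      uniqs[pattern != "", seq := mut$seq]
    }
    long <- uniqs[, .(site_id, pattern, seq)][long,
                                              on = c("site_id", "pattern")]
    long <- lk[, .(Sample, Barcode)][long, on = "Sample"]
    ## expand to individual reads
    reads <- long[rep(seq_len(.N), n)]
    reads[, serial := seq_len(.N)]
    reads[, seq := paste0(Barcode,
                          substr(seq, 1L, read_len - nchar(Barcode)))]
    reads[, id := sprintf("%s|%s|h%d|%d", Sample, site_id, hap, serial)]
    qhi <- strrep(phred_char(qual_high), read_len)
    reads[, qual := qhi]
    ## i.i.d. base errors with low quality at the error positions
    if (base_error > 0) {
      ne <- rbinom(nrow(reads), read_len, base_error)
      aff <- which(ne > 0L)
      if (length(aff)) {
        sm <- matrix(charToRaw(paste(reads$seq[aff], collapse = "")),
                     nrow = read_len)
        qm <- matrix(charToRaw(paste(reads$qual[aff], collapse = "")),
                     nrow = read_len)
        qlo <- charToRaw(phred_char(qual_low))
        bases <- charToRaw("ACGT")
        for (jj in seq_along(aff)) {
          ps <- sample.int(read_len, ne[aff[jj]])
          for (p in ps) {
            cur <- sm[p, jj]
            sm[p, jj] <- sample(bases[bases != cur], 1L)
            qm[p, jj] <- qlo
          }
        }
        big <- rawToChar(as.raw(sm))
        reads$seq[aff] <- substring(big, (seq_along(aff) - 1L) * read_len + 1L,
                                    seq_along(aff) * read_len)
        bigq <- rawToChar(as.raw(qm))
        reads$qual[aff] <- substring(bigq, (seq_along(aff) - 1L) * read_len + 1L,
                                     seq_along(aff) * read_len)
      }
    }
    out[[ln]] <- reads[, .(id, seq, qual)]
  }
  structure(list(lanes = out, key = key, sites = sites,
                 params = list(read_len = read_len, mean_depth = mean_depth,
                               nb_size = nb_size, base_error = base_error,
                               enzyme = enzyme, seed = seed)),
            class = "gbs_readsim")
}

#' Write simulated lanes as FASTQ
#' @param sim a \code{gbs_readsim}.
#' @param dir output directory; files are \code{<flowcell>_<lane>.fastq.gz}.
#' @return invisibly, the written paths.
#' @export
write_lane_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$lanes), function(ln) {
    p <- file.path(dir, paste0(ln, ".fastq.gz"))
    write_fastq_chr(sim$lanes[[ln]]$id, sim$lanes[[ln]]$seq,
                    sim$lanes[[ln]]$qual, p)
    p
  }, character(1))
  invisible(paths)
}
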