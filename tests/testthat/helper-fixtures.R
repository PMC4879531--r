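## shared fixtures, built once per test run and cached in this environment
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

## a small genome + variants + two-family pedigree used across modules
small_world <- function() {
  fixture("small_world", function() {
    g <- simulate_genome(c(1e6, 5e5), c("large", "micro"), seed = 11)
    v <- plant_variants(g, density = 0.01, divergence_fraction = 0.8,
                        seed = 2, avoid_enzyme = "PstI")
    truth <- build_f2_design(v, family_sizes = c(20, 10), seed = 3)
    frags <- digest_genome(g, "PstI")
    fsel <- size_select(frags, c(200, 500))
    list(genome = g, variants = v, truth = truth, frags = frags, fsel = fsel)
  })
}

## reads simulated from the small world (error-free and with errors)
small_reads <- function(base_error = 0) {
  name <- paste0("small_reads_", base_error)
  fixture(name, function() {
    w <- small_world()
    b <- design_barcodes(48, c(4, 8), 3, "PstI", seed = 1)
    key <- make_key_file(w$truth$pedigree$id, b, plex = 48)
    sim <- simulate_reads(w$genome, w$truth, w$fsel, key, "PstI",
                          mean_depth = 10, base_error = base_error, seed = 5)
    c(w, list(barcodes = b, key = key, sim = sim))
  })
}

## demultiplexed reads + catalog from the small world
small_catalog <- function(base_error = 0) {
  name <- paste0("small_catalog_", base_error)
  fixture(name, function() {
    w <- small_reads(base_error)
    dm <- data.table::rbindlist(lapply(names(w$sim$lanes), function(ln) {
      qf <- quality_filter(w$sim$lanes[[ln]])
      lane_no <- as.integer(sub(".*_", "", ln))
      demultiplex(qf$reads, w$key[w$key$Lane == lane_no, ], "PstI")$reads
    }))
    ctl <- build_master_catalog(dm[, c("sample", "seq")], "PstI")
    c(w, list(demuxed = dm, catalog = ctl))
  })
}

## random ACGT string
rand_seq <- function(n, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

## independent digestion oracle: naive substring scan for motif starts
oracle_cut_positions <- function(seq, motif = "CTGCAG", cut_offset = 5L) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L + cut_offset
}

## independent Mendelian compatibility oracle: explicit allele-set table
oracle_mendel_ok <- function(s, d, o) {
  sets <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  if (anyNA(c(s, d, o))) return(NA)
  oa <- list(`0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L))[[as.character(o)]]
  any(oa[1] %in% sets[[as.character(s)]] & oa[2] %in% sets[[as.character(d)]]) ||
    any(oa[2] %in% sets[[as.character(s)]] & oa[1] %in% sets[[as.character(d)]])
}

## independent brute-force per-variant interval classifier for annotation
oracle_annotate <- function(v, fx, genome, flank = 1000L, splice = 2L) {
  rows <- list()
  txs <- unique(fx$transcript_id)
  for (ti in txs) {
    ex <- fx[fx$transcript_id == ti & fx$type == "exon", ]
    ex <- ex[order(ex$start), ]
    tstart <- min(ex$start); tend <- max(ex$end)
    strand <- ex$strand[1]; chrom <- ex$chrom[1]; bio <- ex$biotype[1]
    cds <- fx[fx$transcript_id == ti & fx$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    u5 <- fx[fx$transcript_id == ti & fx$type == "five_prime_UTR", ]
    u3 <- fx[fx$transcript_id == ti & fx$type == "three_prime_UTR", ]
    vv <- v[v$chrom == chrom & v$pos >= tstart - flank & v$pos < tend + flank, ]
    if (!nrow(vv)) next
    ## spliced CDS in 5'->3' order with genomic positions
    gpos <- unlist(lapply(seq_len(nrow(cds)),
                          function(j) cds$start[j]:(cds$end[j] - 1L)))
    if (length(gpos) && strand == "-") gpos <- rev(gpos)
    cseq <- if (length(gpos)) {
      b <- substring(as.character(genome[[chrom]]), gpos + 1L, gpos + 1L)
      if (strand == "-") chartr("ACGT", "TGCA", b) else b
    } else character(0)
    for (k in seq_len(nrow(vv))) {
      p <- vv$pos[k]
      cat <- if (p < tstart || p >= tend) {
        if ((strand == "+") == (p < tstart)) "upstream1kb" else "downstream1kb"
      } else if (!any(p >= ex$start & p < ex$end)) {
        near <- FALSE
        for (j in seq_len(nrow(ex) - 1L)) {
          if (p >= ex$end[j] && p < ex$start[j + 1L]) {
            near <- (p - ex$end[j] < splice) ||
              (ex$start[j + 1L] - 1L - p < splice)
          }
        }
        if (near) "splicing" else "intronic"
      } else if (bio != "coding") {
        "ncRNA"
      } else if (nrow(u5) && any(p >= u5$start & p < u5$end)) {
        "5'UTR"
      } else if (nrow(u3) && any(p >= u3$start & p < u3$end)) {
        "3'UTR"
      } else {
        cp <- match(p, gpos)
        alt <- if (strand == "-") chartr("ACGT", "TGCA", vv$alt[k]) else vv$alt[k]
        ci <- (cp - 1L) %/% 3L; off <- (cp - 1L) %% 3L
        cod <- cseq[(ci * 3L + 1L):(ci * 3L + 3L)]
        refc <- paste(cod, collapse = "")
        cod[off + 1L] <- alt
        altc <- paste(cod, collapse = "")
        tr <- function(x) as.character(Biostrings::translate(
          Biostrings::DNAString(x), no.init.codon = TRUE))
        stops <- c("TAA", "TAG", "TGA")
        paste0("exonic:", if (ci == 0L && refc == "ATG") "start-lost"
               else if (refc %in% stops && !(altc %in% stops)) "stop-lost"
               else if (!(refc %in% stops) && altc %in% stops) "stop-gained"
               else if (tr(refc) == tr(altc)) "synonymous"
               else "non-synonymous")
      }
      rows[[length(rows) + 1L]] <- data.frame(variant_id = vv$id[k],
                                              transcript_id = ti,
                                              category = cat)
    }
  }
  covered <- if (length(rows)) unique(do.call(rbind, rows)$variant_id)
  else character(0)
  inter <- v[!v$id %in% covered, ]
  if (nrow(inter)) {
    rows[[length(rows) + 1L]] <- data.frame(variant_id = inter$id,
                                            transcript_id = NA_character_,
                                            category = "intergenic")
  }
  do.call(rbind, rows)
}
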