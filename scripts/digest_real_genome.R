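#!/usr/bin/env Rscript

## Optional real-genome digestion check (requires network / a local copy).
##
## Reproduces the enzyme-selection counts for the chicken galGal4 assembly:
## in silico PstI and SbfI digestion of every assembly sequence (scaffolds
## included, terminal fragments counted) and the 200-500 bp size-selected
## counts. Expected order of magnitude on galGal4: ~8.1e5 PstI fragments,
## ~4.5e4 SbfI fragments, ~1.6e5 PstI fragments in the 200-500 bp window,
## ~1.2e3 SbfI fragments in window (the exact totals depend on the
## terminal-fragment and scaffold conventions, which this implementation
## states explicitly: both included).
##
## Usage:
##   Rscript scripts/digest_real_genome.R /path/to/galGal4.fa.gz [out.tsv]

suppressMessages(library(gbsforge))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: Rscript scripts/digest_real_genome.R <galGal4.fa[.gz]> [out.tsv]")
fasta <- args[1]
out <- if (length(args) >= 2) args[2] else "galgal4_digestion.tsv"

genome <- read_genome_fasta(fasta)
message(sprintf("loaded %d sequences, %.2f Gb", length(genome),
                sum(as.numeric(Biostrings::width(genome))) / 1e9))
rep <- compare_enzymes(genome, c("PstI", "SbfI"), window = c(200, 500))
print(rep)
data.table::fwrite(rep, out, sep = "\t")
message("wrote ", out)
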