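#' @import data.table
#' @importFrom methods is
#' @importFrom stats dnbinom optimize pchisq rbinom rnbinom rpois runif sd setNames
#' @importFrom utils adist head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the package funnels through one integer master seed;
#' each pipeline stage draws from an offset of it so that stages are
#' reproducible independently of one another. Result always fits in a
#' 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

## reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

is_palindrome <- function(motif) identical(revcomp(motif), motif)

## genome accessors ---------------------------------------------------------

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  assert_that(methods::is(genome, "DNAStringSet"),
              "genome must be a (named) DNAStringSet or character vector")
  assert_that(length(genome) > 0, "genome is empty")
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  genome
}

#' Chromosome size-class labels of a genome
#'
#' Returns the per-chromosome class labels (\code{"large"}, \code{"medium"},
#' \code{"micro"}) stored in the genome's metadata by
#' \code{\link{simulate_genome}}, or \code{NULL} when absent.
#'
#' @param genome a \code{DNAStringSet}.
#' @return named character vector or \code{NULL}.
#' @export
chrom_classes <- function(genome) S4Vectors::metadata(genome)$chrom_class

## fast per-window substring extraction on one chromosome
seq_windows <- function(chromseq, starts0, width) {
  as.character(Biostrings::extractAt(
    chromseq, IRanges::IRanges(start = starts0 + 1L, width = width)))
}

## FASTA / FASTQ helpers ----------------------------------------------------

#' Read a genome FASTA (plain or gzip)
#' @param path FASTA file path.
#' @return \code{DNAStringSet}.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome \code{DNAStringSet}.
#' @param path output path (".gz" suffix compresses).
#' @return invisibly, \code{path}.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

write_fastq_chr <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(id)) {
    writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

read_fastq_chr <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  x <- readLines(con)
  if (length(x) %% 4L != 0L)
    stopf("malformed FASTQ %s: %d lines (not a multiple of 4)", path, length(x))
  n <- length(x) / 4L
  i <- seq_len(n) * 4L - 3L
  hdr <- x[i]
  bad <- which(!startsWith(hdr, "@") | !startsWith(x[i + 2L], "+"))
  if (length(bad))
    stopf("malformed FASTQ %s at record %d", path, bad[1])
  data.table(id = sub("^@", "", hdr), seq = x[i + 1L], qual = x[i + 3L])
}

## phred+33 <-> integer
phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)
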