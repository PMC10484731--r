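# shared fixture builders (everything is generated in code; no data files)

library(GenomicRanges)
library(IRanges)
library(Biostrings)

# per-base SignalTrack from plain numeric vectors, one per chromosome
flatTrack <- function(..., binSize = 1L) {
  v <- list(...)
  SignalTrack(methods::as(lapply(v, S4Vectors::Rle), "RleList"),
              binSize = binSize)
}

# random sequence string of given GC content (alphabet ACGT, no N)
randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

grKey <- function(gr) {
  paste(seqnames(gr), start(gr), end(gr), strand(gr))
}

# single-gene model helper
oneGene <- function(chrom, start, end, strand, id = "g1", exons = NULL) {
  g <- GRanges(chrom, IRanges(start, end), strand = strand, gene_id = id)
  makeGeneModels(g, exons)
}

# evenly spaced single-chromosome gene models (spacing >> any TSS window,
# so peak-to-gene assignment is unambiguous)
spacedGenes <- function(n, spacing = 10000, width = 1000, strand = "+") {
  makeGeneModels(GRanges("chr1",
                         IRanges(seq(5001, by = spacing, length.out = n),
                                 width = width),
                         strand = strand,
                         gene_id = sprintf("g%03d", seq_len(n))))
}

# base-level Jaccard between two interval sets
baseJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(granges(a), ignore.strand = TRUE)
  b <- GenomicRanges::reduce(granges(b), ignore.strand = TRUE)
  sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE))) /
    sum(width(GenomicRanges::reduce(c(a, b), ignore.strand = TRUE)))
}

# a small planted study used by several suites: no motifs, default regions
smallStudy <- function(seed = 1, ...) {
  cfg <- simConfig(seed = seed,
                   motifPlan = data.frame(stringency = character(),
                                          base = character(),
                                          inside = integer(),
                                          outside = integer()),
                   ...)
  simulateStudy(cfg)
}
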