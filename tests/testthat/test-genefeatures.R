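test_that("annotation priority and signed TSS distances are respected", {
  # + strand gene [5001, 9000] with two exons and an intron between
  gene <- oneGene("chr1", 5001, 9000, "+",
                  exons = methods::as(list(IRanges(c(5001, 8001),
                                                   c(6000, 9000))),
                                      "IRangesList"))
  pkUp <- GRanges("chr1", IRanges(4501, 4501))     # 500 bp upstream of TSS
  pkExon2 <- GRanges("chr1", IRanges(8401, 8401))  # inside exon 2
  pkIntron <- GRanges("chr1", IRanges(7001, 7001))
  pkDown <- GRanges("chr1", IRanges(10001, 10001)) # 1 kb past 3' end
  pkFar <- GRanges("chr1", IRanges(55001, 55001))
  ann <- annotatePeaks(c(pkUp, pkExon2, pkIntron, pkDown, pkFar), gene,
                       promoterWindow = c(-1000, 1000))
  expect_equal(as.character(ann$category),
               c("Promoter", "Exon", "Intron", "Downstream",
                 "Distal intergenic"))
  expect_equal(ann$distanceToTSS[1], -500L)
  expect_equal(ann$distanceToTSS[2], 3400L)
  expect_true(all(ann$geneId == "g1"))
})

test_that("minus-strand promoter windows and distances are strand-aware", {
  gene <- oneGene("chr1", 5001, 9000, "-")   # TSS at 9000
  pkUp <- GRanges("chr1", IRanges(9500, 9500))   # upstream for a - gene
  pkDown <- GRanges("chr1", IRanges(4500, 4500)) # past the 3' end (5001)
  ann <- annotatePeaks(c(pkUp, pkDown), gene, promoterWindow = c(-1000, 1000))
  expect_equal(as.character(ann$category), c("Promoter", "Downstream"))
  expect_equal(ann$distanceToTSS[1], -500L)
  expect_equal(ann$distanceToTSS[2], 4500L)
})

test_that("promoter has priority over exon; empty gene set warns", {
  gene <- oneGene("chr1", 5001, 9000, "+")   # single exon = whole span
  pkTss <- GRanges("chr1", IRanges(5001, 5001))  # in exon AND promoter
  ann <- annotatePeaks(pkTss, gene, promoterWindow = c(-1000, 1000))
  expect_equal(as.character(ann$category), "Promoter")

  emptyGenes <- GRanges()
  emptyGenes$gene_id <- character()
  expect_warning(
    ann0 <- annotatePeaks(pkTss, makeGeneModels(emptyGenes),
                          promoterWindow = c(-1000, 1000)),
    "empty gene set")
  expect_equal(as.character(ann0$category), "Distal intergenic")
  expect_true(is.na(ann0$distanceToTSS))
})

test_that("peaks planted in promoter windows annotate as Promoter", {
  genes <- simulateGenes(c(chr1 = 500000L), n = 60, geneWidth = 2000,
                         seed = 81)
  tss <- geneTSS(genes)
  set.seed(82)
  peaks <- GRanges(seqnames(tss),
                   IRanges(pmax(1, start(tss) + sample(-700:700, 60,
                                                       replace = TRUE) - 50),
                           width = 100))
  ann <- annotatePeaks(peaks, genes, promoterWindow = c(-1000, 1000))
  expect_gte(mean(ann$category == "Promoter"), 0.99)
  expect_equal(sum(table(ann$category)), length(peaks))
})

test_that("feature distribution normalizes by genomic abundance", {
  # hand-checkable single-gene design on a 10 kb genome: footprints are
  # Promoter 2001 bp, Downstream 2999 bp, Distal 5000 bp (Exon and Intron
  # are fully shadowed by the promoter window)
  gene <- oneGene("chr1", 5001, 6000, "+")
  pkProm <- GRanges("chr1", IRanges(seq(4001, 4981, by = 20), width = 1))
  pkDist <- GRanges("chr1", IRanges(seq(101, 1081, by = 20), width = 1))
  ann <- annotatePeaks(c(pkProm, pkDist), gene,
                       promoterWindow = c(-1000, 1000))
  dist <- normalizedFeatureDistribution(ann, c(chr1 = 10000L), gene,
                                        promoterWindow = c(-1000, 1000))
  expect_equal(dist$genomeFraction,
               c(2001, 0, 0, 2999, 5000) / 10000)
  ratios <- c(0.5 / 0.2001, 0, 0, 0, 0.5 / 0.5)
  expect_equal(dist$normalizedPct, 100 * ratios / sum(ratios))
  expect_equal(sum(dist$peakCount), length(ann))
})

test_that("uniformly placed peaks give flat normalized percentages", {
  genes <- simulateGenes(c(chr1 = 200000L), n = 20, geneWidth = 3000,
                         seed = 83)
  for (seed in 1:3) {
    set.seed(seed)
    peaks <- GRanges("chr1", IRanges(sample.int(199000, 800), width = 200))
    ann <- annotatePeaks(peaks, genes, promoterWindow = c(-1000, 1000))
    dist <- normalizedFeatureDistribution(ann, c(chr1 = 200000L), genes,
                                          promoterWindow = c(-1000, 1000))
    ok <- dist$genomeFraction > 0.01   # categories large enough to sample
    expect_true(all(abs(dist$normalizedPct[ok] - 100 / 5) < 12))
  }
})

test_that("TSS matrix geometry, orientation flip and z-scoring", {
  # constant track: every cell the constant; z-scored variant all zero
  constTrack <- flatTrack(chr1 = rep(4, 20000))
  genes <- makeGeneModels(GRanges("chr1", IRanges(c(5001, 12001),
                                                  c(7000, 14000)),
                                  strand = c("+", "-"),
                                  gene_id = c("gp", "gm")))
  tm <- tssMatrix(constTrack, genes, flank = 1000, bin = 25)
  expect_equal(dim(tm$matrix), c(2, 80))
  expect_true(all(tm$matrix == 4))
  tz <- tssMatrix(constTrack, genes, flank = 1000, bin = 25,
                  scale = "zscore")
  expect_true(all(tz$matrix == 0))

  # minus-strand gene [2001, 3000], TSS 3000; signal only at coordinates
  # below the TSS, i.e. transcriptionally downstream: after the
  # orientation flip the elevated cells must sit in downstream columns
  v <- numeric(20000); v[2000:2999] <- 10
  tdir <- tssMatrix(flatTrack(chr1 = v),
                    makeGeneModels(GRanges("chr1", IRanges(2001, 3000),
                                           strand = "-", gene_id = "gm")),
                    flank = 1000, bin = 25)
  expect_true(all(tdir$matrix[1, 41:80] == 10))
  expect_true(all(tdir$matrix[1, 1:40] <= 10 * 1 / 25 + 1e-9))

  expect_error(tssMatrix(constTrack, genes, flank = 1000, bin = 30),
               "divisible")
})

test_that("bins clipped at chromosome edges are missing, not zero", {
  v <- rep(2, 3000)
  gene <- makeGeneModels(GRanges("chr1", IRanges(201, 1200), strand = "+",
                                 gene_id = "edge"))
  tm <- tssMatrix(flatTrack(chr1 = v), gene, flank = 1000, bin = 25)
  expect_true(all(is.na(tm$matrix[1, 1:32])))   # 800 bp before position 1
  expect_true(all(tm$matrix[1, 33:80] == 2))
  expect_equal(tm$profile$value[33], 2)
})
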