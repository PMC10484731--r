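test_that("simulated genome honours GC content and determinism", {
  cfgGC1 <- simConfig(chromLengths = c(chr1 = 100L), gc = 1, seed = 2,
                      peakRegions = GRanges("chr1", IRanges(1, 10)))
  g1 <- simulateGenome(cfgGC1)
  expect_true(grepl("^[GC]+$", as.character(g1[[1]])))

  cfg <- simConfig(chromLengths = c(chr1 = 200000L), gc = 0.5, seed = 3,
                   peakRegions = GRanges("chr1", IRanges(1, 10)))
  g <- simulateGenome(cfg)
  obs <- sum(letterFrequency(g, "GC")) / 200000
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 200000))  # binomial oracle

  expect_identical(as.character(simulateGenome(cfg)),
                   as.character(simulateGenome(cfg)))
  expect_error(simConfig(chromLengths = c(chr1 = 1000L), gc = 1.2,
                         peakRegions = GRanges("chr1", IRanges(1, 10))),
               "gc")
})

test_that("planted motifs appear verbatim at recorded coordinates", {
  gen <- DNAStringSet(c(chr1 = strrep("T", 5000)))
  regions <- GRanges("chr1", IRanges(1001, 1500))
  plan <- data.frame(stringency = "low", base = "C",
                     inside = 1L, outside = 0L)
  res <- plantMotifs(gen, plan, regions, seed = 5)
  tr <- res$truth
  expect_length(tr, 1)
  expect_identical(
    as.character(subseq(res$genome[[1]], start(tr), end(tr))),
    canonicalMotif(motifSpec("low", 7, "C")))
  expect_true(all(overlapsAny(tr, regions, type = "within")))
})

test_that("inside plants stay inside regions; capacity errors are raised", {
  gen <- DNAStringSet(c(chr1 = strrep("T", 50000)))
  regions <- randomRegions(c(chr1 = 50000L), 5, 1000, seed = 1)  # 10% share
  plan <- data.frame(stringency = c("low", "medium"), base = c("C", "G"),
                     inside = c(25L, 25L), outside = 0L)
  res <- plantMotifs(gen, plan, regions, seed = 6)
  expect_length(res$truth, 50)
  expect_true(all(overlapsAny(res$truth, regions, type = "within")))

  crowded <- data.frame(stringency = "high", base = "C",
                        inside = 200L, outside = 0L)
  expect_error(plantMotifs(gen, crowded, regions, seed = 7),
               "insufficient space")
  expect_error(plantMotifs(gen, data.frame(stringency = "ultra", base = "C",
                                           inside = 1L, outside = 0L),
                           regions, seed = 8))
})

test_that("fragment midpoints follow the two-rate mixture", {
  # ratio 10, regions 1% of the genome: expected in-region midpoint
  # fraction = 10 x 0.01 / (10 x 0.01 + 0.99)
  cfg <- simConfig(seed = 9, fragmentsPerReplicate = 4000)
  frags <- simulateFragments(cfg)
  expect_length(frags, 3)
  share <- sum(width(cfg@peakRegions)) / sum(as.numeric(cfg@chromLengths))
  expected <- cfg@enrichmentRatio * share /
    (cfg@enrichmentRatio * share + (1 - share))
  for (fr in frags) {
    mids <- GRanges(seqnames(fr), IRanges(start(fr) + width(fr) %/% 2,
                                          width = 1))
    obs <- mean(overlapsAny(mids, cfg@peakRegions))
    expect_lt(abs(obs - expected),
              3 * sqrt(expected * (1 - expected) / length(fr)))
  }
  # replicates are independent draws
  expect_false(identical(grKey(frags[[1]]), grKey(frags[[2]])))
})

test_that("ratio 1 gives uniform midpoints; duplicateRate 1 collapses", {
  cfg <- simConfig(seed = 10, enrichmentRatio = 1, nReplicates = 1,
                   fragmentsPerReplicate = 5000)
  fr <- simulateFragments(cfg)[[1]]
  mids <- GRanges(seqnames(fr), IRanges(start(fr) + width(fr) %/% 2,
                                        width = 1))
  share <- sum(width(cfg@peakRegions)) / sum(as.numeric(cfg@chromLengths))
  expect_lt(abs(mean(overlapsAny(mids, cfg@peakRegions)) - share),
            3 * sqrt(share * (1 - share) / 5000))

  cfgDup <- simConfig(seed = 11, duplicateRate = 1, nReplicates = 1,
                      fragmentsPerReplicate = 500)
  fd <- simulateFragments(cfgDup)[[1]]
  expect_length(fd, 500)
  expect_equal(length(unique(grKey(fd))), 1L)
})

test_that("gene and expression simulation recover the planted design", {
  genes <- simulateGenes(c(chr1 = 300000L), n = 900, geneWidth = 200,
                         minGap = 50, seed = 12)
  expect_length(genes, 900)
  expect_true(all(countOverlaps(genes, genes, ignore.strand = TRUE) == 1))

  labels <- rep(c("none", "iM", "G4"), each = 300)
  expr <- simulateExpression(genes, labels,
                             labelMedians = c(none = 1, iM = 2, G4 = 8,
                                              both = 12),
                             zeroFraction = 0, seed = 13)
  med <- tapply(expr$tpm, expr$label, median)
  expect_lt(med[["none"]], med[["iM"]])   # log-normal sampling oracle
  expect_lt(med[["iM"]], med[["G4"]])

  allZero <- simulateExpression(genes, labels, zeroFraction = 1, seed = 14)
  expect_true(all(allZero$tpm == 0))
  expect_error(simulateExpression(genes, labels,
                                  labelMedians = c(none = -1, iM = 2,
                                                   G4 = 8, both = 12)),
               "invalid")
})

test_that("the whole study is byte-deterministic under a fixed seed", {
  cfg <- simConfig(chromLengths = c(chr1 = 60000L, chr2 = 40000L),
                   fragmentsPerReplicate = 500, seed = 15,
                   peakRegions = randomRegions(c(chr1 = 60000L,
                                                 chr2 = 40000L),
                                               4, 500, seed = 99),
                   motifPlan = data.frame(stringency = "low", base = "C",
                                          inside = 3L, outside = 3L))
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(grKey(s1$truth), grKey(s2$truth))
  expect_identical(lapply(s1$fragments, grKey), lapply(s2$fragments, grKey))
})

test_that("YAML study configuration round-trips and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "chromosomes: {chr1: 50000, chr2: 30000}",
    "gc: 0.4",
    "regions: {count: 3, width: 400}",
    "fragmentsPerReplicate: 800",
    "nReplicates: 2",
    "seed: 21",
    "motifPlan:",
    "  - {stringency: low, base: C, inside: 2, outside: 2}"), f)
  cfg <- readSimConfig(f)
  expect_s4_class(cfg, "SimConfig")
  expect_equal(unname(cfg@chromLengths), c(50000L, 30000L))
  expect_equal(cfg@nReplicates, 2L)
  expect_equal(nrow(cfg@motifPlan), 1L)

  writeLines(c("chromosomes: {chr1: 1000}", "coverage: 5"), f)
  expect_error(readSimConfig(f), "unknown configuration key.*coverage")
})
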