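test_that("pattern membership follows the stringency definitions", {
  expect_true(grepl(quadPattern(motifSpec("low", 7, "C")), "CCACCACCACC",
                    perl = TRUE))
  expect_true(grepl(quadPattern(motifSpec("high", 7, "G")),
                    "GGGTGGGTGGGTGGGTGGG", perl = TRUE))
  # tracts of 2 do not satisfy the medium class
  expect_false(grepl(quadPattern(motifSpec("medium", 7, "C")), "CCACCACCACC",
                     perl = TRUE))
  # N never matches, in tracts or loops
  expect_false(grepl(quadPattern(motifSpec("low", 7, "C")), "CCNCCACCACCAA",
                     perl = TRUE))
})

test_that("scanning finds canonical instances with correct strand logic", {
  hit <- scanQuadMotifs("CCACCACCACC", motifSpec("low", 7, "C"),
                        strand = "+")
  expect_length(hit, 1)
  expect_equal(c(start(hit), end(hit)), c(1L, 11L))

  expect_length(scanQuadMotifs("AAAAAAAAAA", allMotifSpecs("C")), 0)

  # a C-run on the plus strand is a G-quadruplex on the minus strand
  gMinus <- scanQuadMotifs("CCCACCCACCCACCC", motifSpec("medium", 7, "G"),
                           strand = "-")
  expect_length(gMinus, 1)
  expect_equal(as.character(strand(gMinus)), "-")
  expect_length(scanQuadMotifs("CCCACCCACCCACCC", motifSpec("medium", 7, "G"),
                               strand = "+"), 0)
})

test_that("scan equals the brute-force oracle on random sequences", {
  # the heavier 50 x 10 kb sweep lives in the acceptance suite; this is a
  # quick cross-check including N characters
  set.seed(61)
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T", if (i > 4) "N"),
                      2000, replace = TRUE,
                      prob = c(.26, .24, .24, .26, if (i > 4) .02)[
                        seq_len(4 + (i > 4))] /
                        sum(c(.26, .24, .24, .26, if (i > 4) .02))),
               collapse = "")
    for (spec in allMotifSpecs("C")[c("low_short", "medium_long",
                                      "high_short")]) {
      for (st in c("+", "-")) {
        hits <- scanQuadMotifs(setNames(s, "x"), spec, strand = st)
        ora <- oracleScanSpec(s, spec, st)
        expect_equal(start(hits), ora$start)
        expect_equal(width(hits), ora$width)
      }
    }
  }
})

test_that("plus-strand iM and minus-strand G4 matches coincide", {
  set.seed(62)
  s <- randomSeq(20000, gc = 0.55)
  for (str in c("low", "medium", "high")) {
    iM <- scanQuadMotifs(setNames(s, "x"), motifSpec(str, 12, "C"),
                         strand = "+")
    g4 <- scanQuadMotifs(setNames(s, "x"), motifSpec(str, 12, "G"),
                         strand = "-")
    expect_identical(paste(start(iM), end(iM)), paste(start(g4), end(g4)))
  }
})

test_that("region shuffling preserves widths, bounds and seeds", {
  lens <- c(chr1 = 40000L, chr2 = 20000L)
  set.seed(63)
  regions <- GRanges(sample(names(lens), 50, replace = TRUE),
                     IRanges(sample.int(15000, 50),
                             width = sample.int(800, 50)))
  sh <- shuffleRegions(regions, lens, seed = 7)
  expect_equal(sort(width(sh)), sort(width(regions)))
  expect_true(all(start(sh) >= 1 &
                  end(sh) <= lens[as.character(seqnames(sh))]))
  expect_identical(grKey(shuffleRegions(regions, lens, seed = 7)), grKey(sh))
  expect_false(identical(grKey(shuffleRegions(regions, lens, seed = 8)),
                         grKey(sh)))
  expect_error(shuffleRegions(GRanges("chr1", IRanges(1, 90000)), lens),
               "longer than every chromosome")
})

test_that("whole-genome regions give fold exactly 1", {
  cfg <- simConfig(chromLengths = c(chr1 = 20000L), gc = 0.5, seed = 64,
                   peakRegions = GRanges("chr1", IRanges(1, 100)))
  gen <- simulateGenome(cfg)
  whole <- GRanges("chr1", IRanges(1, 20000))
  fe <- foldEnrichment(whole, gen, n = 3, seed = 65)
  pos <- fe$observed > 0
  expect_true(any(pos))
  expect_true(all(fe$fold[pos] == 1))
})

test_that("planted-in-regions enrichment approaches the analytic fold", {
  # 40 medium instances inside regions covering 10% of a low-GC genome,
  # none outside: shuffled expectation ~ 40 x 0.10, so fold ~ 10
  lens <- c(chr1 = 200000L)
  regions <- randomRegions(lens, 20, 1000, seed = 66)
  cfg <- simConfig(chromLengths = lens, gc = 0.2, seed = 67,
                   peakRegions = regions,
                   motifPlan = data.frame(stringency = "medium", base = "C",
                                          inside = 40L, outside = 0L))
  study <- simulateStudy(cfg)
  fe <- foldEnrichment(regions, study$genome,
                       motifSpec("medium", 7, "C"), n = 50, seed = 68)
  expect_equal(fe$observed, 40L)
  expect_gt(fe$fold, 7)
  expect_lt(fe$fold, 13)

  # zero observed count: fold 0, flagged, no division error
  feHigh <- foldEnrichment(regions,
                           DNAStringSet(c(chr1 = strrep("AT", 100000))),
                           motifSpec("high", 7, "C"), n = 3, seed = 69)
  expect_equal(feHigh$fold, 0)
  expect_equal(feHigh$flag, "zero_observed")
})

test_that("enrichment grows with prediction stringency on high-only plants", {
  lens <- c(chr1 = 200000L)
  regions <- randomRegions(lens, 20, 1000, seed = 70)
  cfg <- simConfig(chromLengths = lens, gc = 0.45, seed = 71,
                   peakRegions = regions,
                   motifPlan = data.frame(stringency = "high", base = "C",
                                          inside = 30L, outside = 0L))
  study <- simulateStudy(cfg)
  fe <- foldEnrichment(regions, study$genome,
                       list(low = motifSpec("low", 7, "C"),
                            medium = motifSpec("medium", 7, "C"),
                            high = motifSpec("high", 7, "C")),
                       n = 20, seed = 72)
  folds <- setNames(fe$fold, fe$label)
  expect_gte(folds[["high_short"]], folds[["medium_short"]])
  expect_gte(folds[["medium_short"]], folds[["low_short"]])
})

test_that("GC enrichment permutation test hits its extremes", {
  set.seed(73)
  chars <- randomSeq(50000, gc = 0.4)
  substr(chars, 1, 2000) <- strrep("GC", 1000)
  gen <- DNAStringSet(c(chr1 = chars))
  zone <- GRanges("chr1", IRanges(1, 2000))
  res <- gcEnrichment(zone, gen, n = 199, seed = 74)
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 200)   # all null draws below the observed GC
  expect_gt(res$effect, 0.5)

  whole <- GRanges("chr1", IRanges(1, 50000))
  resW <- gcEnrichment(whole, gen, n = 19, seed = 75)
  expect_equal(resW$observed, resW$nullMean)  # shuffle is a no-op
  expect_error(gcEnrichment(GRanges(), gen), "empty")
})
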