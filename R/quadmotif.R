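#' Regular expression for a quadruplex pattern class
#'
#' \code{k - 1} repetitions of (tract of >= m bases, loop of 0..L bases
#' over \code{A,C,G,T}) followed by a final tract; tracts and loops are
#' greedy; N never matches.
#'
#' @param spec A \linkS4class{MotifSpec}.
#' @return A PCRE pattern string.
#' @examples
#' quadPattern(motifSpec("low", 7, "C"))
#' @export
quadPattern <- function(spec) {
  sprintf("(?:%s{%d,}[ACGT]{0,%d}){%d}%s{%d,}",
          spec@base, spec@tractLength, spec@maxLoop, spec@nTracts - 1L,
          spec@base, spec@tractLength)
}

.complementBase <- c(C = "G", G = "C")

## leftmost non-overlapping greedy matches of one spec on one plus-strand
## sequence string; minus-strand structures are found by scanning for the
## complementary-base pattern
.scanOne <- function(s, spec, strandSym) {
  sp <- spec
  if (strandSym == "-") {
    sp <- spec
    sp@base <- .complementBase[[spec@base]]
  }
  m <- gregexpr(quadPattern(sp), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), width = integer()))
  data.frame(start = as.integer(m), width = attr(m, "match.length"))
}

#' Scan sequences for putative quadruplex-forming motifs
#'
#' Per (class, strand): non-overlapping, leftmost, greedy matches.  A
#' minus-strand match is a match of the complementary-base pattern on the
#' plus-strand sequence, reported in plus-strand coordinates with strand
#' \code{-} (the strand the structure would form on).  Matches of
#' different classes may overlap; each class is scanned independently.
#'
#' @param x Named \code{DNAStringSet} (or a single character string).
#' @param specs A \linkS4class{MotifSpec} or list of them (default: all
#'   six i-motif classes).
#' @param strand \code{"+"}, \code{"-"} or \code{"both"}.
#' @return \code{GRanges} of matches with columns \code{label} and
#'   \code{base}, sorted by coordinate.
#' @examples
#' scanQuadMotifs("CCACCACCACC", motifSpec("low", 7, "C"), strand = "+")
#' @export
scanQuadMotifs <- function(x, specs = allMotifSpecs("C"), strand = "both") {
  if (is(specs, "MotifSpec")) specs <- list(specs)
  strands <- if (strand == "both") c("+", "-") else strand
  if (is.character(x)) {
    nm <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    x <- setNames(DNAStringSet(toupper(x)), nm)
  }
  stopifnot(is(x, "DNAStringSet"))
  out <- list()
  for (chr in names(x)) {
    s <- as.character(x[[chr]])
    for (spec in specs) for (st in strands) {
      hits <- .scanOne(s, spec, st)
      if (nrow(hits))
        out[[length(out) + 1L]] <- GRanges(
          chr, IRanges(hits$start, width = hits$width), strand = st,
          label = spec@label, base = spec@base)
    }
  }
  if (!length(out))
    return(GRanges(label = character(), base = character()))
  BiocGenerics::sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
}

## count matches per spec on sequences extracted from a region set; region
## sequences are joined with an N spacer longer than any loop, so no match
## can bridge two regions (mirrors scanning a per-peak FASTA)
.countInRegions <- function(genome, regions, specs, strand = "both") {
  seqs <- as.character(regionSequences(genome, regions))
  joined <- setNames(paste(seqs, collapse = strrep("N", 13L)), "regions")
  hits <- scanQuadMotifs(joined, specs, strand = strand)
  cnt <- table(factor(hits$label,
                      levels = vapply(specs, motifLabel, character(1))))
  setNames(as.integer(cnt), names(cnt))
}

#' Randomly relocate regions across the genome (shuffle null)
#'
#' Each region is independently relocated: a chromosome is drawn with
#' probability proportional to its length among those long enough to hold
#' the region, and the start is uniform within it.  Widths are preserved
#' exactly; shuffled regions may overlap each other.
#'
#' @param regions \code{GRanges} to relocate.
#' @param genome \code{DNAStringSet} or named chromosome-length vector.
#' @param seed Integer seed.
#' @return Relocated \code{GRanges} (same widths, same order).
#' @export
shuffleRegions <- function(regions, genome, seed = 1) {
  lens <- chromLengths(genome)
  w <- width(regions)
  if (any(w > max(lens)))
    stop("region longer than every chromosome")
  set.seed(seed)
  chrIdx <- integer(length(regions))
  starts <- integer(length(regions))
  for (i in seq_along(regions)) {
    fits <- which(lens >= w[i])
    chrIdx[i] <- fits[sample.int(length(fits), 1L,
                                 prob = as.numeric(lens[fits]))]
    starts[i] <- sample.int(lens[[chrIdx[i]]] - w[i] + 1L, 1L)
  }
  GRanges(names(lens)[chrIdx], IRanges(starts, width = w))
}

#' Motif fold enrichment against a shuffle null
#'
#' The observed count of each pattern class within the regions (scanned on
#' the extracted region sequences) is divided by the mean count over
#' \code{n} random region reshuffles.  Per-randomization counts are
#' retained for variance reporting.
#'
#' @param regions Region (peak) \code{GRanges}.
#' @param genome Named \code{DNAStringSet}.
#' @param specs List of \linkS4class{MotifSpec}s (default: the six i-motif
#'   classes).
#' @param n Number of randomizations (default 10).
#' @param seed Integer seed.
#' @param strand Strand(s) scanned, default \code{"both"}.
#' @return \code{DataFrame} with one row per class: \code{label},
#'   \code{base}, \code{observed}, \code{nullMean}, \code{nullSd},
#'   \code{fold}, \code{flag} (\code{"ok"}, \code{"zero_observed"} or
#'   \code{"infinite"}) and the per-randomization \code{nullCounts}.
#'   When the null mean is 0 with a positive observed count, \code{fold}
#'   carries the observed count and the row is flagged \code{"infinite"}.
#' @export
foldEnrichment <- function(regions, genome, specs = allMotifSpecs("C"),
                           n = 10, seed = 1, strand = "both") {
  stopifnot(n >= 1L, length(regions) >= 1L)
  if (is(specs, "MotifSpec")) specs <- list(specs)
  .checkBounds(regions, chromLengths(genome), "region")
  observed <- unname(.countInRegions(genome, regions, specs, strand))
  nullMat <- vapply(seq_len(n), function(i) {
    shuf <- shuffleRegions(regions, genome,
                           seed = deriveSeed(seed, paste0("shuffle", i)))
    .countInRegions(genome, shuf, specs, strand)
  }, integer(length(specs)))
  nullMat <- matrix(nullMat, nrow = length(specs))
  nullMean <- rowMeans(nullMat)
  nullSd <- apply(nullMat, 1L, stats::sd)
  fold <- ifelse(nullMean > 0, observed / nullMean,
                 ifelse(observed > 0, observed, 0))
  flag <- ifelse(observed == 0, "zero_observed",
                 ifelse(nullMean == 0, "infinite", "ok"))
  DataFrame(label = vapply(specs, motifLabel, character(1)),
            base = vapply(specs, function(s) s@base, character(1)),
            observed = as.integer(observed), nullMean = nullMean,
            nullSd = nullSd, fold = fold, flag = flag,
            nullCounts = IRanges::IntegerList(
              lapply(seq_along(specs), function(i) nullMat[i, ])),
            nRandomizations = n, seed = as.integer(seed))
}

#' GC-content enrichment of a region set
#'
#' One-sided permutation test: the observed GC fraction over the
#' concatenated region sequence is compared with \code{n} shuffled region
#' sets; \code{p = (1 + #\{null >= observed\}) / (n + 1)}.
#'
#' @param regions Region \code{GRanges} (non-empty).
#' @param genome Named \code{DNAStringSet}.
#' @param n Number of shuffles (default 100).
#' @param seed Integer seed.
#' @return List: \code{observed}, \code{nullMean}, \code{effect}
#'   (observed - null mean), \code{p}, \code{nullValues}.
#' @export
gcEnrichment <- function(regions, genome, n = 100, seed = 1) {
  if (length(regions) == 0L) stop("empty region set")
  gcOf <- function(rg) {
    s <- regionSequences(genome, rg)
    sum(letterFrequency(s, "GC")) / sum(Biostrings::width(s))
  }
  obs <- gcOf(regions)
  nullv <- vapply(seq_len(n), function(i)
    gcOf(shuffleRegions(regions, genome,
                        seed = deriveSeed(seed, paste0("gc", i)))),
    numeric(1))
  list(observed = obs, nullMean = mean(nullv), effect = obs - mean(nullv),
       p = (1 + sum(nullv >= obs)) / (n + 1), nullValues = nullv)
}
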