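#' Call peaks from a signal track (SEACR-style block thresholding)
#'
#' Maximal contiguous blocks of strictly positive signal are enumerated
#' and scored by their total signal (area under the curve, value x bp);
#' the top \code{ceiling(threshold x B)} blocks by AUC are kept (B = number
#' of blocks), with ties at the cutoff AUC all included.  This emulates
#' SEACR's numeric-threshold stringent mode; control-track mode is out of
#' scope.
#'
#' @param track A \linkS4class{SignalTrack}.
#' @param threshold Fraction of blocks to keep, in (0, 1); default 0.01.
#' @return Peak \code{GRanges}, coordinate-sorted, with columns
#'   \code{totalSignal} and \code{maxSignal}.  An all-zero track returns an
#'   empty set with a warning.
#' @export
callPeaks <- function(track, threshold = 0.01) {
  stopifnot(is(track, "SignalTrack"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sig <- trackValues(track)
  blocks <- lapply(names(sig), function(chr) {
    v <- IRanges::slice(sig[[chr]], lower = 0, includeLower = FALSE)
    if (length(v) == 0L) return(GRanges(totalSignal = numeric(),
                                        maxSignal = numeric()))
    GRanges(chr, IRanges(BiocGenerics::start(v), BiocGenerics::end(v)),
            totalSignal = as.numeric(IRanges::viewSums(v)),
            maxSignal = as.numeric(IRanges::viewMaxs(v)))
  })
  gr <- suppressWarnings(do.call(c, blocks))
  if (length(gr) == 0L) {
    warning("all-zero track: no signal blocks, returning no peaks")
    return(gr)
  }
  keep <- ceiling(threshold * length(gr))
  cutoff <- sort(gr$totalSignal, decreasing = TRUE)[keep]
  gr <- gr[gr$totalSignal >= cutoff]
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Replicate-consensus (high-confidence) peak regions
#'
#' Chained pairwise coordinate intersection: the returned regions are the
#' maximal intervals present (>= 1 bp overlap at each step) in every
#' replicate's peak set.
#'
#' @param peakList List of >= 2 peak \code{GRanges}.
#' @return Sorted, non-overlapping consensus \code{GRanges}.
#' @export
consensusPeaks <- function(peakList) {
  stopifnot(is.list(peakList), length(peakList) >= 2L)
  Reduce(function(a, b)
    GenomicRanges::intersect(granges(a), granges(b), ignore.strand = TRUE),
    peakList)
}

#' Classify peaks into bottom / middle / top signal ranges
#'
#' Quartile division of total signal: Q1 and Q3 are interpolated (type 7)
#' quantiles; a peak is \code{top} if its total signal >= Q3, else
#' \code{bottom} if <= Q1, else \code{middle}.  The top rule is applied
#' first, so a degenerate all-equal distribution is classified all-top.
#'
#' @param peaks Peak \code{GRanges} with a \code{totalSignal} column.
#' @return The peaks with an added \code{signalClass} factor column; the
#'   quartile cutoffs used are stored in
#'   \code{metadata(x)$signalCutoffs}.
#' @export
classifySignalQuartiles <- function(peaks) {
  if (length(peaks) == 0L) stop("empty peak set")
  stopifnot(!is.null(peaks$totalSignal))
  q <- .quartiles(peaks$totalSignal)
  cls <- ifelse(peaks$totalSignal >= q[2L], "top",
                ifelse(peaks$totalSignal <= q[1L], "bottom", "middle"))
  peaks$signalClass <- factor(cls, levels = c("bottom", "middle", "top"))
  S4Vectors::metadata(peaks)$signalCutoffs <- c(Q1 = q[1L], Q3 = q[2L])
  peaks
}

#' Shared / unique peak counts between two sets (Venn logic)
#'
#' An interval of A is "shared" if it overlaps (>= 1 bp) at least one
#' interval of B.  Counts are anchored on each set independently --
#' sharedA need not equal sharedB when intervals split or merge across
#' sets.  Percentages are rounded half-up to integers.
#'
#' @param setA,setB \code{GRanges} on the same genome.
#' @return List with \code{sharedA}, \code{uniqueA}, \code{pctSharedA},
#'   the B-anchored counterparts, and set sizes.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), width = 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 8))
#' sharedUnique(a, b)$pctSharedA  # 50
#' @export
sharedUnique <- function(setA, setB) {
  lv <- union(GenomeInfoDb::seqlevels(setA), GenomeInfoDb::seqlevels(setB))
  GenomeInfoDb::seqlevels(setA) <- lv
  GenomeInfoDb::seqlevels(setB) <- lv
  sharedA <- sum(IRanges::overlapsAny(setA, setB, ignore.strand = TRUE))
  sharedB <- sum(IRanges::overlapsAny(setB, setA, ignore.strand = TRUE))
  list(nA = length(setA), nB = length(setB),
       sharedA = sharedA, uniqueA = length(setA) - sharedA,
       sharedB = sharedB, uniqueB = length(setB) - sharedB,
       pctSharedA = if (length(setA)) roundHalfUp(100 * sharedA /
                                                  length(setA)) else 0,
       pctSharedB = if (length(setB)) roundHalfUp(100 * sharedB /
                                                  length(setB)) else 0)
}

#' Peak-width summary
#'
#' @param peaks Peak \code{GRanges}.
#' @param binWidth Histogram bin width (bp).
#' @return List with interpolated \code{median}, \code{q1}, \code{q3} and
#'   a histogram \code{data.frame(binStart, count)}.
#' @export
peakWidthStats <- function(peaks, binWidth = 50) {
  if (length(peaks) == 0L) stop("empty peak set")
  w <- width(peaks)
  q <- stats::quantile(w, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  breaks <- seq(0, (max(w) %/% binWidth + 1) * binWidth, by = binWidth)
  h <- hist(w, breaks = breaks, plot = FALSE)
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       histogram = data.frame(binStart = breaks[-length(breaks)],
                              count = h$counts))
}
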