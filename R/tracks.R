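## bin a per-base Rle into bin means, returned as a per-base Rle constant
## within bins (last partial bin averaged over its actual width)
.binRle <- function(r, binSize) {
  if (binSize <= 1L) return(r)
  len <- length(r)
  starts <- seq.int(1L, len, by = binSize)
  w <- pmin(binSize, len - starts + 1L)
  v <- IRanges::viewMeans(IRanges::Views(r, IRanges(starts, width = w)))
  S4Vectors::Rle(as.numeric(v), w)
}

#' Build a normalized coverage track from fragments
#'
#' Per-bin values are mean per-base fragment coverage over the bin; RPGC
#' (1x genome coverage) scaling multiplies by genome length / summed
#' fragment length, so the genome-wide mean per-base value is exactly 1.
#'
#' @param fragments Fragment \code{GRanges}.
#' @param genome \code{DNAStringSet} or named chromosome-length vector.
#' @param binSize Bin width (bp), default 5.
#' @param normalize \code{"RPGC"} (default) or \code{"none"} (raw mean
#'   coverage).
#' @return A \linkS4class{SignalTrack}.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
#' coverageTrack(fr, c(chr1 = 1000L), binSize = 5)  # covered bins = 20
#' @export
coverageTrack <- function(fragments, genome, binSize = 5,
                          normalize = c("RPGC", "none")) {
  normalize <- match.arg(normalize)
  lens <- chromLengths(genome)
  if (length(fragments) == 0L) stop("empty fragment set")
  if (binSize < 1L) stop("binSize must be >= 1")
  .checkBounds(fragments, lens, "fragment")
  cov <- GenomicRanges::coverage(.withSeqlengths(granges(fragments), lens))
  cov <- cov[names(lens)]
  scale <- if (normalize == "RPGC")
    sum(as.numeric(lens)) / sum(as.numeric(width(fragments))) else 1
  rl <- methods::as(lapply(cov, function(r)
    .binRle(methods::as(r, "Rle") * scale, as.integer(binSize))), "RleList")
  names(rl) <- names(lens)
  SignalTrack(rl, binSize = as.integer(binSize))
}

#' Pearson correlation between two signal tracks
#'
#' Both tracks are re-binned to a common bin size (bin value = mean
#' per-base value) and the product-moment correlation is computed over all
#' genome bins, zero-signal bins included.  Zero variance in either binned
#' track is an error rather than a silent value.
#'
#' @param trackA,trackB \linkS4class{SignalTrack}s on the same genome.
#' @param binSize Common re-binning width (bp).
#' @return Pearson r in [-1, 1].
#' @export
trackPearson <- function(trackA, trackB, binSize) {
  a <- trackValues(trackA); b <- trackValues(trackB)
  if (!identical(names(a), names(b)) ||
      !identical(lengths(a), lengths(b)))
    stop("tracks are not on the same genome")
  va <- unlist(lapply(a, function(r)
    as.numeric(.binRle(r, as.integer(binSize))[
      seq.int(1L, length(r), by = binSize)])), use.names = FALSE)
  vb <- unlist(lapply(b, function(r)
    as.numeric(.binRle(r, as.integer(binSize))[
      seq.int(1L, length(r), by = binSize)])), use.names = FALSE)
  if (length(va) < 2L) stop("need at least 2 bins")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("undefined correlation: zero variance in a binned track")
  stats::cor(va, vb)
}

#' Fraction of reads (fragments) in peaks
#'
#' \code{exact}: fraction of fragments overlapping at least one peak.
#' \code{sampled}: the position-sampling estimator -- \code{nPositions}
#' 1 bp genome positions are drawn uniformly without replacement, and the
#' summed fragment coverage at in-peak positions is divided by the summed
#' coverage at all sampled positions.
#'
#' @param fragments Fragment \code{GRanges}.
#' @param peaks Peak \code{GRanges}; an empty set yields FRiP 0 (this is
#'   documented behaviour, not an error).
#' @param method \code{"exact"} or \code{"sampled"}.
#' @param genome Genome or named length vector (needed for
#'   \code{"sampled"}).
#' @param nPositions Number of sampled positions (default 10000).
#' @param seed Integer seed for position sampling.
#' @return Fraction in [0, 1] (\code{NA} if no sampled position carries
#'   coverage).
#' @export
frip <- function(fragments, peaks, method = c("exact", "sampled"),
                 genome = NULL, nPositions = 10000, seed = 1) {
  method <- match.arg(method)
  if (length(fragments) == 0L) stop("empty fragment set")
  if (length(peaks) == 0L) return(0)
  if (method == "exact")
    return(mean(IRanges::overlapsAny(fragments, peaks, ignore.strand = TRUE)))
  if (is.null(genome)) stop("sampled FRiP needs a genome")
  lens <- chromLengths(genome)
  if (nPositions < 1L) stop("nPositions must be >= 1")
  set.seed(seed)
  total <- sum(as.numeric(lens))
  offs <- sort(sample(total, min(nPositions, total)))
  cum <- cumsum(as.numeric(lens))
  chr <- findInterval(offs - 1, cum) + 1L
  pos <- as.integer(offs - c(0, cum)[chr])
  posGr <- GRanges(names(lens)[chr], IRanges(pos, width = 1L))
  cov <- GenomicRanges::coverage(.withSeqlengths(granges(fragments), lens))
  depth <- vapply(seq_along(posGr), function(i)
    as.numeric(cov[[chr[i]]][pos[i]]), numeric(1))
  inPeak <- IRanges::overlapsAny(posGr, peaks, ignore.strand = TRUE)
  if (sum(depth) == 0) {
    warning("no sampled position carries coverage; sampled FRiP undefined")
    return(NA_real_)
  }
  sum(depth[inPeak]) / sum(depth)
}

#' Sequencing-saturation curve
#'
#' For each fraction, every replicate's fragments are subsampled without
#' replacement, the coverage track is rebuilt, peaks are re-called, and
#' the number of subsampled fragments falling in the called peaks is
#' averaged over replicates.  At fraction 1 the point equals the
#' un-subsampled analysis.
#'
#' @param fragmentList Named list of per-replicate fragment \code{GRanges}.
#' @param fractions Ascending subsample fractions in (0, 1].
#' @param genome Genome or named length vector.
#' @param binSize Coverage bin size passed to \code{\link{coverageTrack}}.
#' @param threshold Peak-calling threshold passed to
#'   \code{\link{callPeaks}}.
#' @param seed Integer seed.
#' @return \code{data.frame(fraction, meanReadsInPeaks)}.
#' @export
saturationCurve <- function(fragmentList, fractions, genome, binSize = 5,
                            threshold = 0.01, seed = 1) {
  stopifnot(length(fragmentList) >= 1L)
  if (length(fractions) == 0L)
    return(data.frame(fraction = numeric(), meanReadsInPeaks = numeric()))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be ascending")
  pts <- vapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    mean(vapply(seq_along(fragmentList), function(r) {
      fr <- fragmentList[[r]]
      set.seed(deriveSeed(seed, paste0("sat_", fi, "_", r)))
      sub <- fr[sample.int(length(fr), round(f * length(fr)))]
      tr <- coverageTrack(sub, genome, binSize = binSize)
      pk <- suppressWarnings(callPeaks(tr, threshold = threshold))
      sum(IRanges::overlapsAny(sub, pk, ignore.strand = TRUE))
    }, numeric(1)))
  }, numeric(1))
  data.frame(fraction = fractions, meanReadsInPeaks = pts)
}

#' Library-complexity curve
#'
#' Expected number of distinct fragments among \code{n} drawn without
#' replacement, for \code{n = step, 2 step, ...}.  Duplicate identity is
#' the exact (chrom, start, end, strand) tuple.  \code{"exact"} uses the
#' hypergeometric expectation
#' \eqn{\sum_u [1 - C(N - c_u, n) / C(N, n)]} over unique fragments
#' \eqn{u} with copy count \eqn{c_u}; \code{"empirical"} averages
#' subsampling over \code{nSim} seeds.
#'
#' @param fragments Fragment \code{GRanges} (with duplicates).
#' @param step Curve step size (fragments).
#' @param method \code{"exact"} or \code{"empirical"}.
#' @param nSim Subsampling repetitions for the empirical method.
#' @param seed Integer seed (empirical method).
#' @return \code{data.frame(sampled, distinct)}.
#' @export
complexityCurve <- function(fragments, step, method = c("exact", "empirical"),
                            nSim = 20, seed = 1) {
  method <- match.arg(method)
  if (step < 1L) stop("step must be >= 1")
  N <- length(fragments)
  if (N == 0L) stop("empty fragment set")
  key <- paste(seqnames(fragments), start(fragments), end(fragments),
               strand(fragments))
  cnt <- as.integer(table(key))
  ns <- seq.int(step, N, by = step)
  if (method == "exact") {
    distinct <- vapply(ns, function(n)
      sum(1 - exp(lchoose(N - cnt, n) - lchoose(N, n))), numeric(1))
  } else {
    id <- as.integer(factor(key))
    distinct <- vapply(ns, function(n) {
      mean(vapply(seq_len(nSim), function(s) {
        set.seed(deriveSeed(seed, paste0("cc_", n, "_", s)))
        length(unique(id[sample.int(N, n)]))
      }, numeric(1)))
    }, numeric(1))
  }
  data.frame(sampled = ns, distinct = distinct)
}

#' Assemble the QC report for a replicated experiment
#'
#' Computes per-replicate exact and sampled FRiP against a peak set,
#' pairwise replicate Pearson correlations of RPGC tracks, the saturation
#' curve and the pooled library-complexity curve.
#'
#' @param fragmentList Named list of per-replicate fragment \code{GRanges}.
#' @param peaks Peak \code{GRanges} (e.g. the replicate consensus).
#' @param genome Genome or named length vector.
#' @param binSize Coverage bin size.
#' @param pearsonBin Bin size for replicate correlation (no consensus
#'   bin size is implied by the method; it must be chosen explicitly).
#' @param fripPositions Positions for the sampled FRiP estimator.
#' @param fractions Saturation-curve subsample fractions.
#' @param threshold Peak-calling threshold for the saturation curve.
#' @param complexityStep Step of the complexity curve (default: a tenth of
#'   the pooled library).
#' @param seed Root seed; stage sub-seeds are recorded in the report.
#' @return A \linkS4class{QcReport}.
#' @export
qcReport <- function(fragmentList, peaks, genome, binSize = 5,
                     pearsonBin = 500, fripPositions = 10000,
                     fractions = c(0.25, 0.5, 0.75, 1), threshold = 0.01,
                     complexityStep = NULL, seed = 1) {
  stopifnot(is.list(fragmentList), length(fragmentList) >= 1L)
  seeds <- c(frip = deriveSeed(seed, "frip"),
             saturation = deriveSeed(seed, "saturation"),
             complexity = deriveSeed(seed, "complexity"))
  fripTab <- data.frame(
    replicate = names(fragmentList),
    exact = vapply(fragmentList, frip, numeric(1), peaks = peaks,
                   method = "exact"),
    sampled = vapply(fragmentList, frip, numeric(1), peaks = peaks,
                     method = "sampled", genome = genome,
                     nPositions = fripPositions, seed = seeds[["frip"]]),
    row.names = NULL)
  tracks <- lapply(fragmentList, coverageTrack, genome = genome,
                   binSize = binSize)
  k <- length(tracks)
  pear <- matrix(1, k, k, dimnames = list(names(tracks), names(tracks)))
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
      pear[i, j] <- pear[j, i] <-
        trackPearson(tracks[[i]], tracks[[j]], binSize = pearsonBin)
  sat <- saturationCurve(fragmentList, fractions, genome, binSize = binSize,
                         threshold = threshold, seed = seeds[["saturation"]])
  pooled <- suppressWarnings(do.call(c, unname(lapply(fragmentList, granges))))
  if (is.null(complexityStep))
    complexityStep <- max(1L, length(pooled) %/% 10L)
  comp <- complexityCurve(pooled, step = complexityStep, method = "exact")
  new("QcReport", frip = fripTab, pearson = pear, saturation = sat,
      complexity = comp, seeds = seeds)
}
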