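#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges RleList
#' @importFrom stats setNames
#' @importFrom graphics hist
NULL

## ---------------------------------------------------------------------------
## MotifSpec: one of the six quadruplex pattern classes
## ---------------------------------------------------------------------------

#' Quadruplex pattern class
#'
#' A putative quadruplex-forming sequence class is defined by the tract base
#' (C for i-motifs, G for G-quadruplexes), a minimum tract length, a tract
#' count and a maximum loop length.  Three stringency levels are used:
#' \emph{low} (four tracts of >= 2 bases), \emph{medium} (four tracts of
#' >= 3 bases) and \emph{high} (five tracts of >= 3 bases, the
#' "spare-tyre" arrangement); each is scanned with short (0--7) or long
#' (0--12) loops, giving six classes per base.
#'
#' @slot base Tract base, \code{"C"} or \code{"G"}.
#' @slot tractLength Minimum bases per tract (2 or 3).
#' @slot nTracts Number of tracts (4 or 5).
#' @slot maxLoop Maximum loop length (7 or 12); loops always start at 0.
#' @slot label Derived label, e.g. \code{"medium_short"}.
#' @export
setClass("MotifSpec",
  representation(base = "character", tractLength = "integer",
                 nTracts = "integer", maxLoop = "integer",
                 label = "character"))

setValidity("MotifSpec", function(object) {
  msg <- character()
  if (!object@base %in% c("C", "G")) msg <- c(msg, "base must be 'C' or 'G'")
  key <- paste(object@tractLength, object@nTracts)
  if (!key %in% c("2 4", "3 4", "3 5"))
    msg <- c(msg, "tract length/count must be one of (2,4), (3,4), (3,5)")
  if (!object@maxLoop %in% c(7L, 12L)) msg <- c(msg, "maxLoop must be 7 or 12")
  if (length(msg)) msg else TRUE
})

#' Construct a quadruplex pattern class
#'
#' @param stringency \code{"low"} (4 tracts of >= 2), \code{"medium"}
#'   (4 tracts of >= 3) or \code{"high"} (5 tracts of >= 3).
#' @param maxLoop Maximum loop length, 7 (short) or 12 (long).
#' @param base Tract base: \code{"C"} for i-motif, \code{"G"} for
#'   G-quadruplex.
#' @return A \linkS4class{MotifSpec}.
#' @examples
#' motifSpec("low", 7, "C")
#' @export
motifSpec <- function(stringency = c("low", "medium", "high"), maxLoop = 7,
                      base = c("C", "G")) {
  stringency <- match.arg(stringency)
  base <- match.arg(base)
  par <- switch(stringency, low = c(2L, 4L), medium = c(3L, 4L),
                high = c(3L, 5L))
  label <- paste(stringency, if (maxLoop == 7) "short" else "long", sep = "_")
  new("MotifSpec", base = base, tractLength = par[1L], nTracts = par[2L],
      maxLoop = as.integer(maxLoop), label = label)
}

#' All six pattern classes for one base
#'
#' @param base Tract base, \code{"C"} or \code{"G"}.
#' @return Named list of six \linkS4class{MotifSpec} objects
#'   (stringency x loop length).
#' @export
allMotifSpecs <- function(base = c("C", "G")) {
  base <- match.arg(base)
  specs <- list()
  for (s in c("low", "medium", "high"))
    for (L in c(7L, 12L))
      specs[[paste(s, if (L == 7L) "short" else "long", sep = "_")]] <-
        motifSpec(s, L, base)
  specs
}

#' @describeIn motifSpec Derived class label
#' @param spec A \linkS4class{MotifSpec}.
#' @export
motifLabel <- function(spec) spec@label

setMethod("show", "MotifSpec", function(object) {
  cat(sprintf("MotifSpec %s (%s): %d tracts of >=%d %s, loops 0-%d\n",
              object@label, if (object@base == "C") "iM" else "G4",
              object@nTracts, object@tractLength, object@base,
              object@maxLoop))
})

## ---------------------------------------------------------------------------
## SignalTrack: per-base signal with bedGraph semantics
## ---------------------------------------------------------------------------

#' Genome-wide signal track
#'
#' A per-base, non-negative signal over a genome, stored run-length encoded
#' per chromosome (the in-memory equivalent of a bedGraph).  When built with
#' \code{\link{coverageTrack}} at a bin size > 1, values are constant within
#' bins.
#'
#' @slot signal An \code{RleList}, one numeric \code{Rle} per chromosome;
#'   \code{length} of each Rle equals the chromosome length.
#' @slot binSize Bin width (bp) the values were averaged over (1 = per-base).
#' @export
setClass("SignalTrack",
  representation(signal = "RleList", binSize = "integer"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  nm <- names(object@signal)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "chromosome names must be unique and non-empty")
  for (i in seq_along(object@signal)) {
    v <- S4Vectors::runValue(object@signal[[i]])
    if (any(!is.finite(v)) || any(v < 0)) {
      msg <- c(msg, "signal values must be finite and >= 0")
      break
    }
  }
  if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack from an RleList
#'
#' @param signal \code{RleList} of per-base values, one element per
#'   chromosome.
#' @param binSize Bin width the values are averaged over.
#' @return A \linkS4class{SignalTrack}.
#' @export
SignalTrack <- function(signal, binSize = 1L) {
  if (is.list(signal)) signal <- methods::as(signal, "RleList")
  new("SignalTrack", signal = signal, binSize = as.integer(binSize))
}

#' @describeIn SignalTrack Per-chromosome signal as an \code{RleList}.
#' @param x A \linkS4class{SignalTrack}.
#' @export
trackValues <- function(x) x@signal

#' @describeIn SignalTrack Genome-wide mean per-base value.
#' @export
trackMean <- function(x) {
  tot <- sum(vapply(x@signal, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                    S4Vectors::runLength(r)), numeric(1)))
  tot / sum(vapply(x@signal, length, numeric(1)))
}

setMethod("show", "SignalTrack", function(object) {
  len <- vapply(object@signal, length, numeric(1))
  cat(sprintf("SignalTrack: %d chromosome(s), %.0f bp, bin %d bp, mean %.4g\n",
              length(len), sum(len), object@binSize, trackMean(object)))
})

## ---------------------------------------------------------------------------
## SimConfig: study conditions for the synthetic-data generator
## ---------------------------------------------------------------------------

#' Synthetic-study configuration
#'
#' Bundles every parameter of the synthetic-data generator: the genome, the
#' designated peak regions, the fragment model and the motif planting plan.
#' A fixed \code{seed} makes every derived artifact byte-identical across
#' runs.
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot gc Background GC fraction in [0, 1].
#' @slot peakRegions \code{GRanges} of designated enriched regions.
#' @slot fragmentsPerReplicate Fragments simulated per replicate.
#' @slot fragLenMean,fragLenSd,fragLenMin Fragment-length distribution
#'   (normal, truncated below at \code{fragLenMin}).
#' @slot enrichmentRatio In-region over background fragment rate (>= 1).
#' @slot nReplicates Number of biological replicates.
#' @slot duplicateRate Fraction in [0, 1] of fragments that are PCR-style
#'   copies of earlier templates (0 = all independent draws).
#' @slot motifPlan \code{data.frame} with columns \code{stringency},
#'   \code{base}, \code{inside}, \code{outside}: canonical instances of each
#'   class to plant inside / outside the peak regions.
#' @slot seed Integer root seed.
#' @export
setClass("SimConfig",
  representation(chromLengths = "integer", gc = "numeric",
                 peakRegions = "GRanges", fragmentsPerReplicate = "integer",
                 fragLenMean = "numeric", fragLenSd = "numeric",
                 fragLenMin = "integer", enrichmentRatio = "numeric",
                 nReplicates = "integer", duplicateRate = "numeric",
                 motifPlan = "data.frame", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@chromLengths <= 0) || is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be positive and named")
  if (object@gc < 0 || object@gc > 1) msg <- c(msg, "gc must be in [0, 1]")
  if (object@enrichmentRatio < 1) msg <- c(msg, "enrichmentRatio must be >= 1")
  if (object@fragLenMean < object@fragLenMin)
    msg <- c(msg, "fragLenMean must be >= fragLenMin")
  if (object@fragmentsPerReplicate < 1) msg <- c(msg, "need >= 1 fragment")
  if (object@nReplicates < 1) msg <- c(msg, "need >= 1 replicate")
  if (object@duplicateRate < 0 || object@duplicateRate > 1)
    msg <- c(msg, "duplicateRate must be in [0, 1]")
  if (nrow(object@motifPlan) &&
      !all(c("stringency", "base", "inside", "outside") %in%
           colnames(object@motifPlan)))
    msg <- c(msg, "motifPlan needs columns stringency, base, inside, outside")
  if (length(object@peakRegions)) {
    bad <- tryCatch({.checkBounds(object@peakRegions, object@chromLengths,
                                  "peak region"); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(bad)) msg <- c(msg, bad)
  }
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' Defaults describe the package's standard toy study: a two-chromosome
#' 1 Mb genome at 45\% GC with ten 1 kb enriched regions, three replicates
#' of 2200 fragments (~150 bp) at a 10-fold in-region rate ratio, and a
#' small motif planting plan.
#'
#' @param chromLengths Named vector of chromosome lengths.
#' @param gc Background GC fraction.
#' @param peakRegions \code{GRanges} of enriched regions; by default ten
#'   1 kb regions placed reproducibly with \code{\link{randomRegions}}.
#' @param fragmentsPerReplicate,fragLenMean,fragLenSd,fragLenMin Fragment
#'   model.
#' @param enrichmentRatio In-region / background fragment rate ratio.
#' @param nReplicates Number of replicates.
#' @param duplicateRate Fraction of duplicate fragments.
#' @param motifPlan Planting plan data.frame (see \linkS4class{SimConfig}).
#' @param seed Root seed.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(chromLengths = c(chr1 = 600000L, chr2 = 400000L),
                      gc = 0.45, peakRegions = NULL,
                      fragmentsPerReplicate = 4000, fragLenMean = 150,
                      fragLenSd = 30, fragLenMin = 50, enrichmentRatio = 10,
                      nReplicates = 3, duplicateRate = 0,
                      motifPlan = data.frame(
                        stringency = rep(c("low", "medium", "high"), 2),
                        base = rep(c("C", "G"), each = 3),
                        inside = 20, outside = 40),
                      seed = 1) {
  chromLengths <- chromLengths(chromLengths)
  if (is.null(peakRegions))
    peakRegions <- randomRegions(chromLengths, n = 10, width = 1000,
                                 seed = deriveSeed(seed, "regions"))
  new("SimConfig", chromLengths = chromLengths, gc = gc,
      peakRegions = peakRegions,
      fragmentsPerReplicate = as.integer(fragmentsPerReplicate),
      fragLenMean = fragLenMean, fragLenSd = fragLenSd,
      fragLenMin = as.integer(fragLenMin), enrichmentRatio = enrichmentRatio,
      nReplicates = as.integer(nReplicates), duplicateRate = duplicateRate,
      motifPlan = motifPlan, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d chromosome(s), %.0f bp, GC %.2f\n",
    "  %d peak region(s); %d replicate(s) x %d fragments (ratio %.1f)\n",
    "  motif plan: %d class(es); seed %d\n"),
    length(object@chromLengths), sum(as.numeric(object@chromLengths)),
    object@gc, length(object@peakRegions), object@nReplicates,
    object@fragmentsPerReplicate, object@enrichmentRatio,
    nrow(object@motifPlan), object@seed))
})

## ---------------------------------------------------------------------------
## QcReport
## ---------------------------------------------------------------------------

#' Quality-control report
#'
#' Collects the per-sample QC metrics of a CUT&Tag-style experiment:
#' fraction of reads in peaks (exact and position-sampled), pairwise
#' replicate Pearson correlations, the sequencing-saturation curve and the
#' library-complexity curve, together with the seeds used.
#'
#' @slot frip \code{data.frame}: replicate, exact and sampled FRiP.
#' @slot pearson Numeric matrix of pairwise replicate correlations.
#' @slot saturation \code{data.frame}: fraction, meanReadsInPeaks.
#' @slot complexity \code{data.frame}: sampled, distinct.
#' @slot seeds Named integer vector of sub-seeds used.
#' @export
setClass("QcReport",
  representation(frip = "data.frame", pearson = "matrix",
                 saturation = "data.frame", complexity = "data.frame",
                 seeds = "integer"))

setValidity("QcReport", function(object) {
  msg <- character()
  fr <- c(object@frip$exact, object@frip$sampled)
  fr <- fr[!is.na(fr)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    msg <- c(msg, "FRiP values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n  FRiP (exact): ",
      paste(sprintf("%.3f", object@frip$exact), collapse = ", "), "\n", sep = "")
  if (nrow(object@pearson))
    cat("  Pearson r range: ",
        sprintf("%.3f-%.3f",
                min(object@pearson[lower.tri(object@pearson)]),
                max(object@pearson[lower.tri(object@pearson)])), "\n", sep = "")
  cat(sprintf("  saturation points: %d; complexity points: %d\n",
              nrow(object@saturation), nrow(object@complexity)))
})

#' @describeIn QcReport Accessors for the report components.
#' @param x A \code{QcReport}.
#' @param what One of \code{"frip"}, \code{"pearson"}, \code{"saturation"},
#'   \code{"complexity"}, \code{"seeds"}.
#' @export
qcMetric <- function(x, what = c("frip", "pearson", "saturation",
                                 "complexity", "seeds")) {
  slot(x, match.arg(what))
}
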