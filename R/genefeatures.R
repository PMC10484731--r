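## strand-aware promoter windows [TSS + w1, TSS + w2] (w1 <= 0 <= w2,
## relative to the direction of transcription), clipped at position 1
.promoterWindows <- function(genes, promoterWindow) {
  t <- start(geneTSS(genes))
  neg <- as.character(strand(genes)) == "-"
  st <- ifelse(neg, t - promoterWindow[2L], t + promoterWindow[1L])
  en <- ifelse(neg, t - promoterWindow[1L], t + promoterWindow[2L])
  GRanges(seqnames(genes), IRanges(pmax(1L, as.integer(st)), as.integer(en)))
}

.exonRanges <- function(genes) {
  ex <- genes$exons
  GRanges(rep(seqnames(genes), lengths(ex)), unlist(ex, use.names = FALSE))
}

.featureLevels <- c("Promoter", "Exon", "Intron", "Downstream",
                    "Distal intergenic")

#' Annotate peaks to genomic features
#'
#' Each peak is anchored at its midpoint and assigned exactly one category
#' by priority: Promoter (midpoint within the strand-aware
#' \code{promoterWindow} of a TSS) > Exon > Intron > Downstream (within
#' \code{downstreamWindow} past the gene 3' end) > Distal intergenic.
#' The signed distance to the nearest TSS is reported in the gene's
#' transcriptional orientation (negative = upstream); ties go to the
#' lexicographically smallest gene id.
#'
#' @param peaks Peak \code{GRanges}.
#' @param genes Gene-model \code{GRanges} (\code{\link{makeGeneModels}}).
#' @param promoterWindow Length-2 numeric, bp around the TSS (e.g.
#'   \code{c(-1000, 1000)}).  No silent default is appropriate here --
#'   the window materially changes the annotation -- so it is a mandatory
#'   argument.
#' @param downstreamWindow bp past the 3' end counted as Downstream.
#' @return The peaks with added columns \code{category} (factor),
#'   \code{distanceToTSS} and \code{geneId}.
#' @export
annotatePeaks <- function(peaks, genes, promoterWindow,
                          downstreamWindow = 3000) {
  stopifnot(length(promoterWindow) == 2L,
            promoterWindow[1L] <= 0, promoterWindow[2L] >= 0,
            downstreamWindow > 0)
  midPos <- start(peaks) + (width(peaks) - 1L) %/% 2L
  mid <- GRanges(seqnames(peaks), IRanges(midPos, width = 1L))
  if (length(genes) == 0L) {
    warning("empty gene set: all peaks Distal intergenic, distance undefined")
    peaks$category <- factor(rep("Distal intergenic", length(peaks)),
                             levels = .featureLevels)
    peaks$distanceToTSS <- NA_integer_
    peaks$geneId <- NA_character_
    return(peaks)
  }
  prom <- .promoterWindows(genes, promoterWindow)
  exons <- .exonRanges(genes)
  down <- GenomicRanges::flank(.noSeqinfo(genes),
                               as.integer(downstreamWindow),
                               start = FALSE, ignore.strand = FALSE)
  down <- IRanges::restrict(down, start = 1L)
  cat <- rep("Distal intergenic", length(peaks))
  cat[IRanges::overlapsAny(mid, down, ignore.strand = TRUE)] <- "Downstream"
  cat[IRanges::overlapsAny(mid, genes, ignore.strand = TRUE)] <- "Intron"
  cat[IRanges::overlapsAny(mid, exons, ignore.strand = TRUE)] <- "Exon"
  cat[IRanges::overlapsAny(mid, prom, ignore.strand = TRUE)] <- "Promoter"
  tss <- geneTSS(genes)
  hits <- GenomicRanges::nearest(mid, tss, select = "all",
                                 ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ## resolve exact-distance ties by gene id
  ord <- order(qh, genes$gene_id[sh])
  keep <- !duplicated(qh[ord])
  sel <- integer(length(peaks))
  sel[qh[ord][keep]] <- sh[ord][keep]
  raw <- midPos - start(tss)[sel]
  dist <- ifelse(as.character(strand(genes))[sel] == "-", -raw, raw)
  peaks$category <- factor(cat, levels = .featureLevels)
  peaks$distanceToTSS <- as.integer(dist)
  peaks$geneId <- genes$gene_id[sel]
  peaks
}

#' Feature distribution normalized by genomic abundance
#'
#' For each category, the fraction of peaks annotated to it is divided by
#' the fraction of genome bases belonging to it (base-level membership
#' resolved with the same Promoter > Exon > Intron > Downstream > Distal
#' priority); the ratios are rescaled to sum to 100.
#'
#' @param annotated Output of \code{\link{annotatePeaks}}.
#' @param genome \code{DNAStringSet} or named chromosome-length vector.
#' @param genes Gene-model \code{GRanges}.
#' @param promoterWindow,downstreamWindow Same windows that were used for
#'   the annotation.
#' @return \code{data.frame(category, peakCount, peakFraction,
#'   genomeFraction, ratio, normalizedPct)}.  A category with zero genomic
#'   footprint but annotated peaks is flagged \code{NA} and excluded from
#'   the normalization, with a warning.
#' @export
normalizedFeatureDistribution <- function(annotated, genome, genes,
                                          promoterWindow,
                                          downstreamWindow = 3000) {
  lens <- chromLengths(genome)
  total <- sum(as.numeric(lens))
  clip <- function(gr) {
    gr <- .noSeqinfo(granges(gr))
    sn <- as.character(seqnames(gr))
    st <- pmax(1L, start(gr))
    en <- pmin(end(gr), lens[sn])
    keep <- st <= en
    GenomicRanges::reduce(GRanges(sn[keep], IRanges(st[keep], en[keep])),
                          ignore.strand = TRUE)
  }
  setdiffR <- function(a, b) GenomicRanges::setdiff(a, b,
                                                    ignore.strand = TRUE)
  promF <- clip(.promoterWindows(genes, promoterWindow))
  exonF <- setdiffR(clip(.exonRanges(genes)), promF)
  used <- GenomicRanges::reduce(c(promF, exonF))
  intrF <- setdiffR(clip(genes), used)
  used <- GenomicRanges::reduce(c(used, intrF))
  downF <- setdiffR(clip(IRanges::restrict(
    GenomicRanges::flank(.noSeqinfo(genes), as.integer(downstreamWindow),
                         start = FALSE), start = 1L)), used)
  footBases <- c(sum(as.numeric(width(promF))), sum(as.numeric(width(exonF))),
                 sum(as.numeric(width(intrF))), sum(as.numeric(width(downF))))
  footBases <- c(footBases, total - sum(footBases))
  names(footBases) <- .featureLevels
  peakCount <- table(annotated$category)[.featureLevels]
  peakFrac <- as.numeric(peakCount) / length(annotated)
  genomeFrac <- footBases / total
  ratio <- ifelse(genomeFrac > 0, peakFrac / genomeFrac,
                  ifelse(peakFrac > 0, NA_real_, 0))
  if (any(is.na(ratio)))
    warning("category with peaks but zero genomic footprint excluded: ",
            paste(.featureLevels[is.na(ratio)], collapse = ", "))
  norm <- 100 * ratio / sum(ratio, na.rm = TRUE)
  data.frame(category = .featureLevels, peakCount = as.integer(peakCount),
             peakFraction = peakFrac, genomeFraction = as.numeric(genomeFrac),
             ratio = as.numeric(ratio), normalizedPct = as.numeric(norm),
             row.names = NULL)
}

#' TSS-centered signal matrix and metaprofile
#'
#' One row per gene over \code{[TSS - flank, TSS + flank)} in fixed-width
#' bins; each cell is the mean per-base track value over the bin.
#' Minus-strand rows are orientation-flipped so columns always run
#' upstream to downstream.  Bins extending past a chromosome edge are
#' missing (NA) and excluded from the column-mean profile.
#'
#' @param track A \linkS4class{SignalTrack}.
#' @param genes Gene-model \code{GRanges}.
#' @param flank Half-window around the TSS (bp); must be divisible by
#'   \code{bin}.
#' @param bin Bin width (bp), default 25.
#' @param scale \code{"none"} or \code{"zscore"} (matrix-global z-score;
#'   zero SD yields all-zero).
#' @return List: \code{matrix} (genes x bins, column names = bin start
#'   offsets relative to the TSS), \code{profile}
#'   (\code{data.frame(position, value)}), and the parameters used.
#' @export
tssMatrix <- function(track, genes, flank = 1000, bin = 25,
                      scale = c("none", "zscore")) {
  scale <- match.arg(scale)
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  sig <- trackValues(track)
  nb <- as.integer(2 * flank / bin)
  offsets <- seq(-flank, flank - bin, by = bin)
  mat <- matrix(NA_real_, length(genes), nb,
                dimnames = list(genes$gene_id, offsets))
  tssPos <- start(geneTSS(genes))
  sn <- as.character(seqnames(genes))
  for (i in seq_along(genes)) {
    r <- sig[[sn[i]]]
    starts <- tssPos[i] - flank + (seq_len(nb) - 1L) * bin
    valid <- starts >= 1L & (starts + bin - 1L) <= length(r)
    if (any(valid))
      mat[i, valid] <- as.numeric(IRanges::viewMeans(
        IRanges::Views(r, IRanges(starts[valid], width = bin))))
    if (as.character(strand(genes))[i] == "-") mat[i, ] <- rev(mat[i, ])
  }
  if (scale == "zscore") {
    v <- mat[!is.na(mat)]
    s <- stats::sd(v)
    mat[] <- if (is.na(s) || s == 0) ifelse(is.na(mat), NA, 0) else
      (mat - mean(v)) / s
  }
  profile <- data.frame(position = offsets,
                        value = colMeans(mat, na.rm = TRUE))
  list(matrix = mat, profile = profile, flank = flank, bin = bin,
       scale = scale)
}
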