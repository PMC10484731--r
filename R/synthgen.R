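#' Place non-overlapping random regions on a genome
#'
#' Chromosomes receive regions in proportion to their length; on each
#' chromosome, placements are uniform among sorted non-overlapping
#' configurations separated by at least \code{minGap}.
#'
#' @param chromLengths Named chromosome lengths (or a \code{DNAStringSet}).
#' @param n Number of regions.
#' @param width Region width (bp).
#' @param seed Integer seed.
#' @param minGap Minimum gap between regions (bp).
#' @return Sorted \code{GRanges} of \code{n} regions.
#' @export
randomRegions <- function(chromLengths, n, width, seed, minGap = width) {
  lens <- chromLengths(chromLengths)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, prob = as.numeric(lens)))
  grl <- lapply(seq_along(lens), function(i) {
    k <- counts[i]
    if (k == 0L) return(GRanges())
    slack <- lens[[i]] - k * (width + minGap)
    if (slack < 0) stop("regions do not fit on ", names(lens)[i])
    st <- sort(sample.int(slack + 1L, k, replace = TRUE)) +
      (seq_len(k) - 1L) * (width + minGap)
    GRanges(names(lens)[i], IRanges(st + 1L, width = width))
  })
  BiocGenerics::sort(.withSeqlengths(suppressWarnings(do.call(c, grl)), lens),
                     ignore.strand = TRUE)
}

#' Simulate a random genome
#'
#' Bases are drawn independently with \code{P(G) + P(C)} equal to the
#' configured GC fraction, split evenly between G and C (and between A and
#' T).
#'
#' @param config A \linkS4class{SimConfig}.
#' @return Named \code{DNAStringSet}.
#' @examples
#' gen <- simulateGenome(simConfig(chromLengths = c(chr1 = 1000L), seed = 1))
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(deriveSeed(config@seed, "genome"))
  p <- c(A = (1 - config@gc) / 2, C = config@gc / 2, G = config@gc / 2,
         T = (1 - config@gc) / 2)
  seqs <- vapply(names(config@chromLengths), function(chr) {
    paste(sample(names(p), config@chromLengths[[chr]], replace = TRUE,
                 prob = p), collapse = "")
  }, character(1))
  DNAStringSet(seqs)
}

#' Canonical instance of a quadruplex pattern class
#'
#' The minimal-tract, single-base-loop realization of the class (e.g.
#' \code{"CCACCACCACC"} for the low-stringency i-motif class), used for
#' motif planting so that class membership is unambiguous.
#'
#' @param spec A \linkS4class{MotifSpec} (its \code{maxLoop} is irrelevant:
#'   single-base loops satisfy both loop ranges).
#' @return Character instance string.
#' @export
canonicalMotif <- function(spec) {
  loop <- if (spec@base == "C") "A" else "T"
  tract <- strrep(spec@base, spec@tractLength)
  paste(rep(tract, spec@nTracts), collapse = loop)
}

## neutral spacer planted around each instance so that scanning recovers the
## plant at its exact coordinates: 13 bp (> max loop of 12) of the loop base
## on both sides cannot be crossed by any loop, and cannot extend a tract
.plantFlank <- 13L

#' Plant canonical motif instances into a genome
#'
#' Each plant replaces genome bases with a canonical class instance plus a
#' 13 bp neutral spacer on either side (so no pattern match can bridge a
#' plant and its background).  Plants never overlap each other; placement
#' is uniform over the allowed space.
#'
#' @param genome Named \code{DNAStringSet}.
#' @param plan \code{data.frame} with columns \code{stringency}
#'   (low/medium/high), \code{base} (C/G), \code{inside}, \code{outside}:
#'   instance counts to plant inside and outside \code{regions}.
#' @param regions \code{GRanges} defining "inside"; \code{NULL} plants
#'   everything genome-wide (all counts treated as outside).
#' @param seed Integer seed.
#' @return \code{list(genome, truth)}: the modified genome and a
#'   \code{GRanges} truth set with columns \code{label} (stringency),
#'   \code{base}, \code{inside}.
#' @export
plantMotifs <- function(genome, plan, regions = NULL, seed = 1) {
  lens <- chromLengths(genome)
  stopifnot(all(c("stringency", "base") %in% colnames(plan)))
  if (is.null(plan$inside)) plan$inside <- 0L
  if (is.null(plan$outside)) plan$outside <- 0L
  if (any(plan$inside > 0) && is.null(regions))
    stop("inside counts require a region set")
  set.seed(seed)
  inside <- if (is.null(regions)) GRanges() else
    GenomicRanges::reduce(granges(regions), ignore.strand = TRUE)
  outside <- GenomicRanges::gaps(.withSeqlengths(inside, lens))
  outside <- outside[strand(outside) == "*"]
  ## occupied footprints tracked per chromosome as plain vectors (a GRanges
  ## accumulator is quadratic in the number of plants)
  occ <- setNames(lapply(names(lens), function(x)
    list(st = integer(), en = integer())), names(lens))
  tChr <- character(); tSt <- integer(); tW <- integer()
  tLab <- character(); tBase <- character(); tIn <- logical()
  fpStr <- character(); fpSt <- integer(); fpEn <- integer()
  for (i in seq_len(nrow(plan))) {
    spec <- motifSpec(plan$stringency[i], 7, plan$base[i])
    inst <- canonicalMotif(spec)
    fc <- if (spec@base == "C") "A" else "T"
    footprint <- paste0(strrep(fc, .plantFlank), inst, strrep(fc, .plantFlank))
    fpw <- nchar(footprint)
    for (side in c("inside", "outside")) {
      count <- plan[[side]][i]
      if (count == 0L) next
      allowed <- if (side == "inside") inside else outside
      allowedChr <- as.character(seqnames(allowed))
      cap <- width(allowed) - fpw + 1L
      if (!length(allowed) || all(cap < 1L))
        stop("no room to plant ", side, " instances of ", spec@label)
      ok <- which(cap >= 1L)
      placed <- 0L
      attempts <- 0L
      while (placed < count) {
        attempts <- attempts + 1L
        if (attempts > 200L * count)
          stop("insufficient space to plant ", count, " ", side,
               " instances of class ", plan$stringency[i], "/", plan$base[i])
        j <- ok[sample.int(length(ok), 1L, prob = cap[ok])]
        st <- start(allowed)[j] + sample.int(cap[j], 1L) - 1L
        en <- st + fpw - 1L
        chr <- allowedChr[j]
        if (any(st <= occ[[chr]]$en & en >= occ[[chr]]$st)) next
        occ[[chr]]$st <- c(occ[[chr]]$st, st)
        occ[[chr]]$en <- c(occ[[chr]]$en, en)
        fpStr <- c(fpStr, footprint); fpSt <- c(fpSt, st); fpEn <- c(fpEn, en)
        tChr <- c(tChr, chr); tSt <- c(tSt, st + .plantFlank)
        tW <- c(tW, nchar(inst)); tLab <- c(tLab, plan$stringency[i])
        tBase <- c(tBase, plan$base[i]); tIn <- c(tIn, side == "inside")
        placed <- placed + 1L
      }
    }
  }
  for (chr in unique(tChr)) {
    sel <- tChr == chr
    genome[[chr]] <- Biostrings::replaceAt(
      genome[[chr]], IRanges(fpSt[sel], fpEn[sel]), fpStr[sel])
  }
  truth <- if (length(tChr)) BiocGenerics::sort(.withSeqlengths(
    GRanges(tChr, IRanges(tSt, width = tW), strand = "+", label = tLab,
            base = tBase, inside = tIn), lens), ignore.strand = TRUE)
    else GRanges()
  list(genome = genome, truth = truth)
}

#' Simulate per-replicate fragment sets
#'
#' Fragment midpoints follow a two-rate mixture: the rate inside the
#' configured peak regions is \code{enrichmentRatio} times the background
#' rate.  Lengths are normal (truncated below); fragments are clipped at
#' chromosome ends.  Replicates are independent given distinct sub-seeds.
#' With \code{duplicateRate} > 0, fragments are resampled with replacement
#' from a reduced template pool, emulating PCR duplicates for
#' complexity-curve analyses.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return Named list (\code{rep1}, ...) of fragment \code{GRanges}; each
#'   carries \code{name} and \code{score} columns so it round-trips as
#'   BED6.
#' @export
simulateFragments <- function(config) {
  stopifnot(is(config, "SimConfig"))
  lens <- config@chromLengths
  regions <- GenomicRanges::reduce(granges(config@peakRegions),
                                   ignore.strand = TRUE)
  gapsGr <- GenomicRanges::gaps(.withSeqlengths(regions, lens))
  gapsGr <- gapsGr[strand(gapsGr) == "*"]
  rb <- vapply(names(lens), function(chr)
    sum(width(regions)[as.character(seqnames(regions)) == chr]), numeric(1))
  W <- as.numeric(lens) + (config@enrichmentRatio - 1) * rb
  reps <- lapply(seq_len(config@nReplicates), function(r) {
    set.seed(deriveSeed(config@seed, paste0("fragments_rep", r)))
    n <- config@fragmentsPerReplicate
    nT <- if (config@duplicateRate > 0)
      max(1L, as.integer(round(n * (1 - config@duplicateRate)))) else n
    chrIdx <- sample.int(length(lens), nT, replace = TRUE, prob = W)
    pIn <- (config@enrichmentRatio * rb / W)[chrIdx]
    inReg <- stats::runif(nT) < pIn
    mid <- integer(nT)
    for (ci in seq_along(lens)) {
      chr <- names(lens)[ci]
      selIn <- which(inReg & chrIdx == ci)
      if (length(selIn)) {
        rs <- regions[as.character(seqnames(regions)) == chr]
        ri <- sample.int(length(rs), length(selIn), replace = TRUE,
                         prob = width(rs))
        mid[selIn] <- start(rs)[ri] +
          floor(stats::runif(length(selIn)) * width(rs)[ri])
      }
      selOut <- which(!inReg & chrIdx == ci)
      if (length(selOut)) {
        gs <- gapsGr[as.character(seqnames(gapsGr)) == chr]
        gi <- sample.int(length(gs), length(selOut), replace = TRUE,
                         prob = width(gs))
        mid[selOut] <- start(gs)[gi] +
          floor(stats::runif(length(selOut)) * width(gs)[gi])
      }
    }
    len <- pmax(config@fragLenMin,
                as.integer(round(stats::rnorm(nT, config@fragLenMean,
                                              config@fragLenSd))))
    st <- pmax(1L, mid - len %/% 2L)
    en <- pmin(lens[chrIdx], st + len - 1L)
    frag <- GRanges(names(lens)[chrIdx], IRanges(st, en))
    if (config@duplicateRate > 0)
      frag <- frag[sample.int(nT, n, replace = TRUE)]
    frag <- .withSeqlengths(frag, lens)
    frag$name <- sprintf("rep%d_frag%06d", r, seq_along(frag))
    frag$score <- 0L
    frag
  })
  names(reps) <- paste0("rep", seq_len(config@nReplicates))
  reps
}

#' Simulate non-overlapping gene models
#'
#' Genes of fixed width are placed non-overlapping (uniform over ordered
#' configurations), with random strand and 1--\code{maxExons} exons whose
#' first/last boundaries coincide with the gene span.
#'
#' @param chromLengths Named chromosome lengths (or a \code{DNAStringSet}).
#' @param n Number of genes.
#' @param geneWidth Gene span width (bp).
#' @param maxExons Maximum exons per gene.
#' @param minGap Minimum inter-gene gap (bp).
#' @param seed Integer seed.
#' @return Gene-model \code{GRanges} (see \code{\link{makeGeneModels}}).
#' @export
simulateGenes <- function(chromLengths, n, geneWidth = 2000, maxExons = 3,
                          minGap = 500, seed = 1) {
  lens <- chromLengths(chromLengths)
  spans <- randomRegions(lens, n, geneWidth, seed = deriveSeed(seed, "genes"),
                         minGap = minGap)
  set.seed(deriveSeed(seed, "genestruct"))
  strand(spans) <- sample(c("+", "-"), n, replace = TRUE)
  spans$gene_id <- sprintf("gene%04d", seq_len(n))
  exons <- methods::as(lapply(seq_len(n), function(i) {
    nE <- sample.int(maxExons, 1L)
    if (nE == 1L) return(IRanges(start(spans)[i], end(spans)[i]))
    cuts <- sort(sample(seq_len(geneWidth - 1L), 2L * (nE - 1L)))
    bounds <- c(0L, cuts, geneWidth)
    odd <- seq(1L, length(bounds) - 1L, by = 2L)
    IRanges(start(spans)[i] + bounds[odd],
            start(spans)[i] + bounds[odd + 1L] - 1L)
  }), "IRangesList")
  makeGeneModels(spans, exons)
}

#' Simulate a TPM expression table with structure-dependent levels
#'
#' TPM values are log-normal with a per-label median (\code{none < iM <
#' G4 <= both} by default), plus a configurable fraction of silent (TPM 0)
#' genes, so that downstream expression-category integration can recover
#' the planted ordering.
#'
#' @param genes Gene-model \code{GRanges}.
#' @param labels Character vector (aligned with \code{genes} or named by
#'   \code{gene_id}) with values among \code{names(labelMedians)}.
#' @param labelMedians Named positive medians per structure label.
#' @param sdLog Log-scale standard deviation of the TPM distribution.
#' @param zeroFraction Fraction of genes forced to TPM 0.
#' @param seed Integer seed.
#' @return \code{data.frame(gene_id, tpm, label)}.
#' @export
simulateExpression <- function(genes, labels,
                               labelMedians = c(none = 1, iM = 2, G4 = 8,
                                                both = 12),
                               sdLog = 0.8, zeroFraction = 0.1, seed = 1) {
  if (any(labelMedians <= 0) || sdLog < 0 || zeroFraction < 0 ||
      zeroFraction > 1)
    stop("invalid expression parameters")
  if (!is.null(names(labels))) labels <- labels[genes$gene_id]
  stopifnot(length(labels) == length(genes),
            all(labels %in% names(labelMedians)))
  set.seed(deriveSeed(seed, "expression"))
  tpm <- stats::rlnorm(length(genes), meanlog = log(labelMedians[labels]),
                       sdlog = sdLog)
  tpm[stats::runif(length(genes)) < zeroFraction] <- 0
  data.frame(gene_id = genes$gene_id, tpm = as.numeric(tpm),
             label = as.character(labels), stringsAsFactors = FALSE)
}

#' Run the full synthetic-study generator
#'
#' Generates the genome, plants the configured motifs, simulates the
#' replicate fragment sets, and (optionally) writes everything to disk as
#' FASTA / BED6 / TSV.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param dir Optional output directory; created if missing.
#' @return \code{list(genome, truth, fragments, regions)}.
#' @export
simulateStudy <- function(config, dir = NULL) {
  stopifnot(is(config, "SimConfig"))
  genome <- simulateGenome(config)
  planted <- plantMotifs(genome, config@motifPlan, config@peakRegions,
                         seed = deriveSeed(config@seed, "plants"))
  fragments <- simulateFragments(config)
  out <- list(genome = planted$genome, truth = planted$truth,
              fragments = fragments, regions = config@peakRegions)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGenomeFasta(out$genome, file.path(dir, "genome.fa"))
    if (length(out$truth)) {
      tr <- out$truth
      tr$name <- paste0(tr$base, "_", tr$label)
      tr$score <- 0L
      writeBed(tr, file.path(dir, "motif_truth.bed"))
    }
    writeBed(out$regions, file.path(dir, "regions.bed"))
    for (r in names(fragments))
      writeBed(fragments[[r]], file.path(dir, paste0("fragments_", r, ".bed")))
  }
  out
}

## keys accepted in a YAML study configuration
.simKeys <- c("chromosomes", "gc", "regions", "fragmentsPerReplicate",
              "fragLenMean", "fragLenSd", "fragLenMin", "enrichmentRatio",
              "nReplicates", "duplicateRate", "motifPlan", "seed")

#' Read a synthetic-study configuration from YAML
#'
#' Keys mirror the \linkS4class{SimConfig} fields (\code{chromosomes} is a
#' named length map; \code{regions} is either \code{\{count, width\}} for
#' random placement or a list of \code{\{chrom, start, end\}} records,
#' 0-based half-open).  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  conf <- yaml::read_yaml(path)
  unknown <- setdiff(names(conf), .simKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(conf$chromosomes)) stop("missing key: chromosomes")
  lens <- chromLengths(unlist(conf$chromosomes))
  seed <- if (is.null(conf$seed)) 1L else as.integer(conf$seed)
  regions <- NULL
  if (!is.null(conf$regions)) {
    if (!is.null(conf$regions$count)) {
      regions <- randomRegions(lens, conf$regions$count, conf$regions$width,
                               seed = deriveSeed(seed, "regions"))
    } else {
      regions <- GRanges(
        vapply(conf$regions, `[[`, character(1), "chrom"),
        IRanges(vapply(conf$regions, `[[`, numeric(1), "start") + 1L,
                vapply(conf$regions, `[[`, numeric(1), "end")))
    }
  }
  plan <- if (is.null(conf$motifPlan))
    data.frame(stringency = character(), base = character(),
               inside = integer(), outside = integer()) else
    do.call(rbind, lapply(conf$motifPlan, as.data.frame))
  args <- list(chromLengths = lens, peakRegions = regions, motifPlan = plan,
               seed = seed)
  for (k in c("gc", "fragmentsPerReplicate", "fragLenMean", "fragLenSd",
              "fragLenMin", "enrichmentRatio", "nReplicates",
              "duplicateRate"))
    if (!is.null(conf[[k]])) args[[k]] <- conf[[k]]
  do.call(simConfig, args)
}
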