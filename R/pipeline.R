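## allowed keys per pipeline-configuration section
.pipeKeys <- list(
  seed = NULL,
  genome = c("chromosomes", "gc"),
  regions = c("count", "width"),
  fragments = c("perReplicate", "lengthMean", "lengthSd", "lengthMin",
                "enrichmentRatio", "replicates", "duplicateRate"),
  motifs = c("insidePerClass", "outsidePerClass"),
  peaks = c("threshold", "binSize"),
  enrichment = c("nShuffles"),
  annotation = c("promoterWindow", "downstreamWindow"),
  profile = c("flank", "bin", "scale"),
  expression = c("nGenes", "geneWidth", "tssWindow", "labelMedians",
                 "sdLog", "zeroFraction", "labelWeights"),
  qc = c("fripPositions", "fractions", "pearsonBin"))

.validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), names(.pipeKeys))
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(.pipeKeys)) {
    if (is.null(.pipeKeys[[sec]]) || is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), .pipeKeys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) stop("missing mandatory key: seed")
  if (is.null(config$annotation$promoterWindow))
    stop("missing mandatory key: annotation$promoterWindow")
  invisible(config)
}

#' Demo pipeline configuration
#'
#' The package's standard toy study: a 1 Mb two-chromosome genome at 45\%
#' GC, ten 1 kb enriched regions, three replicates of 4000 ~150 bp
#' fragments at a 10-fold rate ratio, 20/40 planted canonical instances
#' per class inside/outside the regions, and 200 genes with
#' structure-dependent expression.
#'
#' @param seed Root seed.
#' @return Nested configuration list accepted by \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    genome = list(chromosomes = list(chr1 = 600000L, chr2 = 400000L),
                  gc = 0.45),
    regions = list(count = 10L, width = 1000L),
    fragments = list(perReplicate = 4000L, lengthMean = 150, lengthSd = 30,
                     lengthMin = 50L, enrichmentRatio = 10, replicates = 3L,
                     duplicateRate = 0),
    motifs = list(insidePerClass = 20L, outsidePerClass = 40L),
    peaks = list(threshold = 0.01, binSize = 5L),
    enrichment = list(nShuffles = 10L),
    annotation = list(promoterWindow = c(-1000L, 1000L),
                      downstreamWindow = 3000L),
    profile = list(flank = 1000L, bin = 25L, scale = "none"),
    expression = list(nGenes = 200L, geneWidth = 2000L, tssWindow = 3000L,
                      labelMedians = list(none = 1, iM = 2, G4 = 8,
                                          both = 12),
                      sdLog = 0.8, zeroFraction = 0.1,
                      labelWeights = list(none = 0.4, iM = 0.2, G4 = 0.2,
                                          both = 0.2)),
    qc = list(fripPositions = 10000L, fractions = c(0.25, 0.5, 1),
              pearsonBin = 500L))
}

## average a list of SignalTracks (replicate-mean track for profiles)
.meanTrack <- function(tracks) {
  sig <- trackValues(tracks[[1L]])
  for (t in tracks[-1L]) {
    s2 <- trackValues(t)
    sig <- methods::as(lapply(names(sig), function(chr)
      sig[[chr]] + s2[[chr]]), "RleList")
    names(sig) <- names(trackValues(tracks[[1L]]))
  }
  SignalTrack(methods::as(lapply(sig, function(r) r / length(tracks)),
                          "RleList"), binSize = tracks[[1L]]@binSize)
}

#' Run the full synthetic-study pipeline
#'
#' Executes every stage in dependency order on a synthetic study --
#' generation, coverage tracks, peak calling and consensus, QC, motif
#' enrichment, annotation, TSS profiles, expression integration -- writes
#' all declared outputs under \code{outDir}, and records a run manifest
#' (config snapshot, derived sub-seeds, parameters, output digests) as
#' \code{manifest.json}.  Re-running with the same configuration
#' reproduces the output tree byte-identically.
#'
#' @param config Configuration list (see \code{\link{demoConfig}}) or path
#'   to a YAML file with the same structure.
#' @param outDir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = demoConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  message("[quadtag] simulate: genome + motifs + fragments")
  plan <- data.frame(stringency = rep(c("low", "medium", "high"), 2),
                     base = rep(c("C", "G"), each = 3),
                     inside = config$motifs$insidePerClass,
                     outside = config$motifs$outsidePerClass)
  lens <- chromLengths(unlist(config$genome$chromosomes))
  cfg <- simConfig(
    chromLengths = lens, gc = config$genome$gc,
    peakRegions = randomRegions(lens, config$regions$count,
                                config$regions$width,
                                seed = deriveSeed(seed, "regions")),
    fragmentsPerReplicate = config$fragments$perReplicate,
    fragLenMean = config$fragments$lengthMean,
    fragLenSd = config$fragments$lengthSd,
    fragLenMin = config$fragments$lengthMin,
    enrichmentRatio = config$fragments$enrichmentRatio,
    nReplicates = config$fragments$replicates,
    duplicateRate = config$fragments$duplicateRate,
    motifPlan = plan, seed = seed)
  study <- simulateStudy(cfg, dir = outDir)

  message("[quadtag] tracks: RPGC coverage per replicate")
  tracks <- lapply(study$fragments, coverageTrack, genome = study$genome,
                   binSize = config$peaks$binSize)
  for (r in names(tracks))
    writeBedGraph(tracks[[r]], file.path(outDir, paste0("coverage_", r,
                                                        ".bedgraph")))

  message("[quadtag] peaks: SEACR-style calling + consensus")
  peaks <- lapply(tracks, callPeaks, threshold = config$peaks$threshold)
  consensus <- consensusPeaks(peaks)
  writeBed(consensus, file.path(outDir, "consensus_peaks.bed"))
  pk1 <- classifySignalQuartiles(peaks[[1L]])
  utils::write.table(
    data.frame(chrom = as.character(seqnames(pk1)), start = start(pk1) - 1L,
               end = end(pk1), totalSignal = pk1$totalSignal,
               maxSignal = pk1$maxSignal, signalClass = pk1$signalClass),
    file.path(outDir, "peaks_rep1.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  message("[quadtag] qc: FRiP / correlation / saturation / complexity")
  qc <- qcReport(study$fragments, consensus, study$genome,
                 binSize = config$peaks$binSize,
                 pearsonBin = config$qc$pearsonBin,
                 fripPositions = config$qc$fripPositions,
                 fractions = unlist(config$qc$fractions),
                 threshold = config$peaks$threshold,
                 seed = deriveSeed(seed, "qc"))
  jsonlite::write_json(
    list(frip = qcMetric(qc, "frip"), pearson = qcMetric(qc, "pearson"),
         saturation = qcMetric(qc, "saturation"),
         complexity = qcMetric(qc, "complexity"),
         seeds = as.list(qcMetric(qc, "seeds"))),
    file.path(outDir, "qc.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  message("[quadtag] quadmotif: fold enrichment + GC test")
  enr <- foldEnrichment(consensus, study$genome,
                        specs = allMotifSpecs("C"),
                        n = config$enrichment$nShuffles,
                        seed = deriveSeed(seed, "enrichment"))
  utils::write.table(as.data.frame(enr[, c("label", "base", "observed",
                                           "nullMean", "nullSd", "fold",
                                           "flag")]),
                     file.path(outDir, "fold_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gc <- gcEnrichment(consensus, study$genome, n = 100,
                     seed = deriveSeed(seed, "gc"))

  message("[quadtag] genes: models + expression + annotation + profile")
  genes <- simulateGenes(study$genome, n = config$expression$nGenes,
                         geneWidth = config$expression$geneWidth,
                         seed = deriveSeed(seed, "genes"))
  set.seed(deriveSeed(seed, "labels"))
  lw <- unlist(config$expression$labelWeights)
  labels <- sample(names(lw), length(genes), replace = TRUE, prob = lw)
  expr <- simulateExpression(genes, labels,
                             labelMedians = unlist(
                               config$expression$labelMedians),
                             sdLog = config$expression$sdLog,
                             zeroFraction = config$expression$zeroFraction,
                             seed = deriveSeed(seed, "expr"))
  writeGeneTable(genes, file.path(outDir, "genes.tsv"))
  writeExpressionTable(expr, file.path(outDir, "expression.tsv"))
  ann <- annotatePeaks(consensus, genes,
                       promoterWindow = unlist(
                         config$annotation$promoterWindow),
                       downstreamWindow = config$annotation$downstreamWindow)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(ann)), start = start(ann) - 1L,
               end = end(ann), category = ann$category,
               distanceToTSS = ann$distanceToTSS, geneId = ann$geneId),
    file.path(outDir, "annotation.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  dist <- normalizedFeatureDistribution(
    ann, study$genome, genes,
    promoterWindow = unlist(config$annotation$promoterWindow),
    downstreamWindow = config$annotation$downstreamWindow)
  utils::write.table(dist, file.path(outDir, "feature_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- tssMatrix(.meanTrack(tracks), genes,
                    flank = config$profile$flank, bin = config$profile$bin,
                    scale = if (is.null(config$profile$scale)) "none" else
                      config$profile$scale)
  utils::write.table(prof$profile, file.path(outDir, "tss_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("[quadtag] expression: structure x expression integration")
  tss <- geneTSS(genes)
  mkPeaks <- function(which) {
    g <- tss[labels %in% which]
    GRanges(seqnames(g), IRanges(pmax(1L, start(g) - 200L),
                                 start(g) + 200L))
  }
  integ <- structureByExpression(genes, mkPeaks(c("iM", "both")),
                                 mkPeaks(c("G4", "both")), expr,
                                 tssWindow = config$expression$tssWindow)
  utils::write.table(cbind(structure = rownames(integ$byStructure),
                           integ$byStructure),
                     file.path(outDir, "structure_by_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ext <- externalOverlap(ann, study$regions)

  files <- setdiff(list.files(outDir), "manifest.json")
  manifest <- list(
    config = config,
    seeds = list(root = seed,
                 regions = deriveSeed(seed, "regions"),
                 plants = deriveSeed(seed, "plants"),
                 fragments = vapply(seq_len(cfg@nReplicates), function(r)
                   deriveSeed(seed, paste0("fragments_rep", r)), integer(1)),
                 qc = deriveSeed(seed, "qc"),
                 enrichment = deriveSeed(seed, "enrichment"),
                 gc = deriveSeed(seed, "gc"),
                 genes = deriveSeed(seed, "genes"),
                 labels = deriveSeed(seed, "labels"),
                 expr = deriveSeed(seed, "expr")),
    parameters = list(threshold = config$peaks$threshold,
                      binSize = config$peaks$binSize,
                      nShuffles = config$enrichment$nShuffles,
                      promoterWindow = config$annotation$promoterWindow,
                      tssWindow = config$expression$tssWindow,
                      motifClasses = names(allMotifSpecs("C"))),
    gcEnrichment = gc[c("observed", "nullMean", "p")],
    externalOverlap = ext[c("shared", "fraction")],
    digests = as.list(tools::md5sum(file.path(outDir, files))))
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, tracks = tracks, peaks = peaks,
                 consensus = consensus, qc = qc, enrichment = enr,
                 annotation = ann, featureDistribution = dist,
                 profile = prof, genes = genes, expression = expr,
                 integration = integ, manifest = manifest))
}
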