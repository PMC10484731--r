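#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   letterFrequency subseq
#' @importFrom GenomicRanges GRanges granges strand strand<- mcols mcols<-
#' @importFrom IRanges IRanges Views RleList
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
#' @importFrom BiocGenerics start end width sort
NULL

## All files are 0-based half-open (BED convention); in-memory GRanges are
## 1-based closed. The conversion happens only here (rtracklayer handles it
## for BED/bedGraph; the gene-table reader/writer does it explicitly).

#' Read / write a genome FASTA
#'
#' Sequences are uppercased on read; characters outside \code{A,C,G,T,N}
#' and duplicate or empty headers are rejected.
#'
#' @param path FASTA file path.
#' @return \code{readGenomeFasta}: a named \code{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## pre-scan so illegal characters are reported with their line number
  ## (readDNAStringSet would accept any IUPAC code; this genome model
  ## admits only A, C, G, T, N)
  lines <- readLines(path)
  seqLine <- !startsWith(lines, ">")
  bad <- seqLine & grepl("[^ACGTNacgtn]", lines)
  if (any(bad)) {
    ln <- which(bad)[1L]
    ch <- regmatches(lines[ln], regexpr("[^ACGTNacgtn]", lines[ln]))
    stop("illegal character '", ch, "' on line ", ln, " of ", path)
  }
  gen <- readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (any(!nzchar(names(gen)))) stop("empty FASTA header")
  if (anyDuplicated(names(gen)))
    stop("duplicate FASTA header: ",
         names(gen)[anyDuplicated(names(gen))][1L])
  if (any(Biostrings::width(gen) == 0)) stop("empty sequence in FASTA")
  DNAStringSet(toupper(gen))
}

#' @rdname readGenomeFasta
#' @param genome Named \code{DNAStringSet}.
#' @export
writeGenomeFasta <- function(genome, path) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED3/BED6, tab-separated, 0-based half-open on disk.  When a genome (or
#' named length vector) is supplied, records on unknown chromosomes or out
#' of bounds are an error rather than being clipped; unbound reads pass
#' unknown chromosomes through.
#'
#' @param path BED file path.
#' @param genome Optional \code{DNAStringSet} or named length vector to
#'   bind coordinates against.
#' @return \code{readBed}: a \code{GRanges} (with \code{name}/\code{score}
#'   columns for BED6 input).
#' @export
readBed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(width(gr) < 1L)) stop("BED record with start >= end")
  if (!is.null(genome)) .checkBounds(gr, chromLengths(genome), "BED record")
  gr
}

#' @rdname readBed
#' @param intervals \code{GRanges} to write; \code{name}/\code{score}
#'   metadata columns are emitted as BED6 when present.
#' @export
writeBed <- function(intervals, path) {
  stopifnot(is(intervals, "GRanges"))
  if (any(width(intervals) < 1L)) stop("refusing to write empty interval")
  rtracklayer::export(intervals, path, format = "BED")
  invisible(path)
}

#' Read / write bedGraph signal tracks
#'
#' Runs are validated non-overlapping and non-negative, sorted, and padded
#' with zero runs to full chromosome length.  Zero-valued runs are dropped
#' on write; the per-base value function is unchanged by a round trip.
#'
#' @param path bedGraph file path.
#' @param genome \code{DNAStringSet} or named chromosome-length vector
#'   (required on read: bedGraphs may omit zero runs, so lengths cannot be
#'   inferred from the file).
#' @return \code{readBedGraph}: a \linkS4class{SignalTrack}.
#' @export
readBedGraph <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  lens <- chromLengths(genome)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(!is.finite(gr$score)) || any(gr$score < 0))
    stop("bedGraph values must be finite and >= 0")
  .checkBounds(gr, lens, "bedGraph run")
  gr <- BiocGenerics::sort(.withSeqlengths(gr, lens), ignore.strand = TRUE)
  rl <- lapply(names(lens), function(chr) {
    g <- gr[as.character(seqnames(gr)) == chr]
    if (length(g) > 1L && any(start(g)[-1L] <= end(g)[-length(g)]))
      stop("overlapping bedGraph runs on ", chr)
    v <- numeric(lens[[chr]])
    for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- g$score[i]
    S4Vectors::Rle(v)
  })
  names(rl) <- names(lens)
  SignalTrack(methods::as(rl, "RleList"))
}

#' @rdname readBedGraph
#' @param track \linkS4class{SignalTrack} to write.
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "SignalTrack"))
  sig <- trackValues(track)
  grl <- lapply(names(sig), function(chr) {
    r <- sig[[chr]]
    rs <- S4Vectors::runValue(r)
    ir <- IRanges(start = cumsum(c(1L, S4Vectors::runLength(r)))[
                    seq_along(rs)],
                  width = S4Vectors::runLength(r))
    keep <- rs > 0
    GRanges(chr, ir[keep], score = rs[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene models
## ---------------------------------------------------------------------------

#' Construct gene models
#'
#' Genes are a stranded \code{GRanges} with a \code{gene_id} column and
#' per-gene exon coordinates (\code{IRangesList} column \code{exons},
#' absolute coordinates).  The TSS is the 5' end: span start on \code{+},
#' span end on \code{-}.
#'
#' @param genes Stranded \code{GRanges} (strand \code{+} or \code{-}) with
#'   \code{mcols} column \code{gene_id}.
#' @param exons \code{IRangesList} (one element per gene) of exon spans in
#'   absolute chromosome coordinates; defaults to single-exon genes.
#' @return Validated gene-model \code{GRanges}.
#' @export
makeGeneModels <- function(genes, exons = NULL) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$gene_id))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (any(strand(genes) == "*")) stop("genes must be stranded (+/-)")
  if (any(GenomicRanges::countOverlaps(genes, genes,
                                       ignore.strand = FALSE) > 1L))
    stop("overlapping genes (within a strand) are not supported")
  if (is.null(exons))
    exons <- methods::as(lapply(seq_along(genes), function(i)
      IRanges(start(genes)[i], end(genes)[i])), "IRangesList")
  stopifnot(length(exons) == length(genes))
  for (i in seq_along(genes)) {
    e <- BiocGenerics::sort(exons[[i]])
    if (length(e) < 1L) stop("gene ", genes$gene_id[i], " has no exons")
    if (any(start(e) < start(genes)[i]) || any(end(e) > end(genes)[i]))
      stop("exon outside gene span for ", genes$gene_id[i])
    if (length(e) > 1L && any(start(e)[-1L] <= end(e)[-length(e)]))
      stop("overlapping exons in ", genes$gene_id[i])
    exons[[i]] <- e
  }
  mcols(genes)$exons <- exons
  genes
}

#' Transcription start sites of gene models
#'
#' @param genes Gene-model \code{GRanges} (see \code{\link{makeGeneModels}}).
#' @return Width-1 \code{GRanges} at each gene's TSS (strand-aware 5' end).
#' @export
geneTSS <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' Read / write the gene-model table
#'
#' Tab-separated with one \code{#}-prefixed header line; columns
#' \code{gene_id, chrom, start, end, strand, exon_starts, exon_ends}
#' (0-based half-open coordinates; exon columns are comma-separated lists).
#'
#' @param path File path.
#' @param genome Optional genome to bind coordinates against.
#' @return \code{readGeneTable}: gene-model \code{GRanges}.
#' @export
readGeneTable <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "chrom", "start", "end",
                                         "strand", "exon_starts", "exon_ends"))
  if (any(tab$start >= tab$end)) stop("gene with start >= end")
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
                strand = tab$strand, gene_id = tab$gene_id)
  exons <- methods::as(lapply(seq_len(nrow(tab)), function(i) {
    s <- as.integer(strsplit(tab$exon_starts[i], ",")[[1L]]) + 1L
    e <- as.integer(strsplit(tab$exon_ends[i], ",")[[1L]])
    IRanges(s, e)
  }), "IRangesList")
  gm <- makeGeneModels(gr, exons)
  if (!is.null(genome)) .checkBounds(gm, chromLengths(genome), "gene")
  gm
}

#' @rdname readGeneTable
#' @param genes Gene-model \code{GRanges} to write.
#' @export
writeGeneTable <- function(genes, path) {
  ex <- genes$exons
  lines <- c("#gene_id\tchrom\tstart\tend\tstrand\texon_starts\texon_ends",
    vapply(seq_along(genes), function(i) {
      paste(genes$gene_id[i], as.character(seqnames(genes))[i],
            start(genes)[i] - 1L, end(genes)[i],
            as.character(strand(genes))[i],
            paste(start(ex[[i]]) - 1L, collapse = ","),
            paste(end(ex[[i]]), collapse = ","), sep = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the expression table
#'
#' Tab-separated, one \code{#}-prefixed header line, columns
#' \code{gene_id, tpm}.
#'
#' @param path File path.
#' @return \code{readExpressionTable}: \code{data.frame(gene_id, tpm)}.
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "tpm"))
  if (any(!is.finite(tab$tpm)) || any(tab$tpm < 0))
    stop("TPM values must be finite and >= 0")
  tab
}

#' @rdname readExpressionTable
#' @param expression \code{data.frame} with columns \code{gene_id, tpm}.
#' @export
writeExpressionTable <- function(expression, path) {
  writeLines(c("#gene_id\ttpm",
               paste(expression$gene_id, expression$tpm, sep = "\t")), path)
  invisible(path)
}

#' Extract region sequences from a genome
#'
#' @param genome Named \code{DNAStringSet}.
#' @param regions \code{GRanges} within the genome.
#' @return \code{DNAStringSet}, one sequence per region.
#' @export
regionSequences <- function(genome, regions) {
  .checkBounds(regions, chromLengths(genome), "region")
  sn <- as.character(seqnames(regions))
  DNAStringSet(vapply(seq_along(regions), function(i)
    as.character(subseq(genome[[sn[i]]], start(regions)[i], end(regions)[i])),
    character(1)))
}
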