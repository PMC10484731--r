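#' Derive a reproducible sub-seed from a root seed and a stream label
#'
#' All stochastic stages draw their randomness from named sub-streams of a
#' single root seed, so that whole-pipeline runs are reproducible while the
#' stages stay independently re-runnable.
#'
#' @param seed Integer root seed.
#' @param label Character stream label (e.g. \code{"fragments_rep2"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1003853
  as.integer((abs(seed) + 99991 * h) %% 2147483646)
}

## round-half-up to integer (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

#' Chromosome lengths of a genome-like object
#'
#' @param x A \code{DNAStringSet} genome or an already-named numeric vector
#'   of chromosome lengths.
#' @return Named integer vector of chromosome lengths.
#' @export
chromLengths <- function(x) {
  if (is(x, "DNAStringSet")) {
    len <- setNames(Biostrings::width(x), names(x))
  } else if (is.numeric(x) && !is.null(names(x))) {
    len <- x
  } else {
    stop("'x' must be a DNAStringSet or a named numeric vector of lengths")
  }
  if (anyDuplicated(names(len)) || any(!nzchar(names(len))))
    stop("chromosome names must be unique and non-empty")
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  storage.mode(len) <- "integer"
  len
}

## validate that a GRanges fits within a set of chromosome lengths
.checkBounds <- function(gr, lengths, what = "interval") {
  sn <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(sn), names(lengths))
  if (length(unknown))
    stop(what, "s on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  bad <- BiocGenerics::start(gr) < 1L | BiocGenerics::end(gr) > lengths[sn]
  if (any(bad))
    stop(sum(bad), " ", what, "(s) out of chromosome bounds (first: ",
         sn[which(bad)[1L]], ":", BiocGenerics::start(gr)[which(bad)[1L]], "-",
         BiocGenerics::end(gr)[which(bad)[1L]], ")")
  invisible(gr)
}

## GRanges helper: attach seqlengths (required before coverage())
.withSeqlengths <- function(gr, lengths) {
  GenomeInfoDb::seqlevels(gr) <- names(lengths)
  GenomeInfoDb::seqlengths(gr) <- lengths
  gr
}

## strip seqinfo so that range arithmetic past chromosome ends (e.g.
## downstream flanks, later clipped) does not trigger out-of-bound warnings
.noSeqinfo <- function(gr) {
  GRanges(as.character(GenomeInfoDb::seqnames(gr)),
          IRanges::ranges(gr), strand = GenomicRanges::strand(gr))
}

## interpolated (type 7) quartiles, pinned once for the whole package
.quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
}
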