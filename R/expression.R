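#' Quartile-based expression categories
#'
#' Genes with TPM 0 are "no" (not expressed).  Expressed genes (TPM > 0)
#' are split at the interpolated quartiles of their TPM distribution:
#' high if TPM >= Q3 (checked first), low if TPM <= Q1, else medium.
#' Being rank-based, the categorization is invariant under monotone
#' rescaling of TPMs.
#'
#' @param expression \code{data.frame} with columns \code{gene_id},
#'   \code{tpm}.
#' @return The data.frame with an added \code{category} factor
#'   (\code{no < low < medium < high}); the quartile cutoffs are attached
#'   as \code{attr(, "cutoffs")}.
#' @examples
#' expressionCategories(data.frame(gene_id = letters[1:10], tpm = c(0, 0, 1:8)))
#' @export
expressionCategories <- function(expression) {
  stopifnot(all(c("gene_id", "tpm") %in% colnames(expression)))
  if (nrow(expression) == 0L) stop("empty expression table")
  if (any(expression$tpm < 0)) stop("negative TPM")
  tpm <- expression$tpm
  expressed <- tpm > 0
  lv <- c("no", "low", "medium", "high")
  if (!any(expressed)) {
    expression$category <- factor(rep("no", length(tpm)), levels = lv,
                                  ordered = TRUE)
    attr(expression, "cutoffs") <- c(Q1 = NA_real_, Q3 = NA_real_)
    return(expression)
  }
  q <- .quartiles(tpm[expressed])
  cat <- ifelse(!expressed, "no",
                ifelse(tpm >= q[2L], "high",
                       ifelse(tpm <= q[1L], "low", "medium")))
  expression$category <- factor(cat, levels = lv, ordered = TRUE)
  attr(expression, "cutoffs") <- c(Q1 = q[1L], Q3 = q[2L])
  expression
}

## two-sided 1.5 x IQR outlier exclusion, used only for distribution
## summaries (never for category assignment)
.dropOutliers <- function(x) {
  q <- .quartiles(x)
  iqr <- q[2L] - q[1L]
  x[x >= q[1L] - 1.5 * iqr & x <= q[2L] + 1.5 * iqr]
}

#' Structure-by-expression integration
#'
#' Each gene is labeled \code{both} / \code{<A>-only} / \code{<B>-only} /
#' \code{none} by the presence of at least one peak of each set within
#' \code{tssWindow} bp of its TSS.  The joint table is summarized in both
#' orientations (expression categories within each structure label, and
#' structure labels within each expression category), and per-label TPM
#' distributions are reported with two-sided 1.5 x IQR outliers excluded
#' (the exclusion applies to summaries only, never to categorization).
#'
#' @param genes Gene-model \code{GRanges}.
#' @param peaksA,peaksB Peak \code{GRanges} for the two structure assays
#'   (e.g. iM and G4).
#' @param expression \code{data.frame(gene_id, tpm)}; genes missing from
#'   it are categorized "no" with a warning.
#' @param tssWindow Half-window around the TSS (bp), default 3000.
#' @param structureNames Length-2 character naming the two assays.
#' @return List: \code{assignments} (per-gene structure, TPM, category),
#'   \code{byStructure} (rows = structure labels, columns = expression
#'   categories, rows sum to 100), \code{byExpression} (transposed
#'   orientation, rows sum to 100), \code{tpmSummary} (per structure:
#'   n, median, quartiles after outlier exclusion).
#' @export
structureByExpression <- function(genes, peaksA, peaksB, expression,
                                  tssWindow = 3000,
                                  structureNames = c("iM", "G4")) {
  stopifnot(tssWindow > 0, length(structureNames) == 2L)
  tss <- geneTSS(genes)
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(1L, start(tss) - as.integer(tssWindow)),
                         start(tss) + as.integer(tssWindow)))
  hasA <- IRanges::overlapsAny(win, peaksA, ignore.strand = TRUE)
  hasB <- IRanges::overlapsAny(win, peaksB, ignore.strand = TRUE)
  lvls <- c("none", paste0(structureNames[1L], "-only"),
            paste0(structureNames[2L], "-only"), "both")
  structure <- factor(ifelse(hasA & hasB, "both",
                      ifelse(hasA, lvls[2L],
                      ifelse(hasB, lvls[3L], "none"))), levels = lvls)
  cats <- expressionCategories(expression)
  idx <- match(genes$gene_id, cats$gene_id)
  if (any(is.na(idx)))
    warning(sum(is.na(idx)), " gene(s) absent from the expression table; ",
            "categorized 'no'")
  category <- factor(rep("no", length(genes)),
                     levels = levels(cats$category), ordered = TRUE)
  category[!is.na(idx)] <- cats$category[idx[!is.na(idx)]]
  tpm <- ifelse(is.na(idx), NA_real_, cats$tpm[idx])
  assignments <- data.frame(gene_id = genes$gene_id, structure = structure,
                            tpm = tpm, category = category)
  tab <- table(structure, category)
  present <- rowSums(tab) > 0
  byStructure <- 100 * prop.table(tab[present, , drop = FALSE], margin = 1L)
  tabE <- table(category, structure)
  presentE <- rowSums(tabE) > 0
  byExpression <- 100 * prop.table(tabE[presentE, , drop = FALSE],
                                   margin = 1L)
  tpmSummary <- do.call(rbind, lapply(levels(structure)[present],
    function(lv) {
      x <- tpm[structure == lv & !is.na(tpm)]
      kept <- if (length(x)) .dropOutliers(x) else numeric()
      data.frame(structure = lv, n = length(x),
                 nOutliersExcluded = length(x) - length(kept),
                 median = if (length(kept)) stats::median(kept) else NA_real_,
                 q1 = if (length(kept)) .quartiles(kept)[1L] else NA_real_,
                 q3 = if (length(kept)) .quartiles(kept)[2L] else NA_real_)
    }))
  list(assignments = assignments,
       byStructure = as.data.frame.matrix(byStructure),
       byExpression = as.data.frame.matrix(byExpression),
       tpmSummary = tpmSummary, tssWindow = tssWindow)
}

#' Overlap of peaks with an external interval set
#'
#' Peak-anchored >= 1 bp overlap counting (the same rule as
#' \code{\link{sharedUnique}}), e.g. against ATAC-seq open-chromatin or
#' R-loop peak sets.  When the peaks carry an annotation \code{category}
#' column, the fraction restricted to promoter-annotated peaks is also
#' reported.
#'
#' @param peaks Peak \code{GRanges} (optionally annotated).
#' @param external External \code{GRanges} on the same genome.
#' @return List: \code{shared}, \code{fraction}, \code{nPeaks},
#'   \code{promoterFraction} (NA when no annotation is attached).
#' @export
externalOverlap <- function(peaks, external) {
  lv <- union(GenomeInfoDb::seqlevels(peaks),
              GenomeInfoDb::seqlevels(external))
  GenomeInfoDb::seqlevels(peaks) <- lv
  GenomeInfoDb::seqlevels(external) <- lv
  ov <- IRanges::overlapsAny(peaks, external, ignore.strand = TRUE)
  promFrac <- NA_real_
  if (!is.null(peaks$category)) {
    isProm <- peaks$category == "Promoter"
    if (any(isProm)) promFrac <- mean(ov[isProm])
  }
  list(shared = sum(ov),
       fraction = if (length(peaks)) mean(ov) else 0,
       nPeaks = length(peaks), promoterFraction = promFrac)
}
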