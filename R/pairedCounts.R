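#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<- rowData rowData<- rowRanges
#' @importFrom BiocGenerics sizeFactors sizeFactors<-
NULL

#' PairedCountMatrix: per-feature counts over paired soma/dendrite samples
#'
#' A \code{SummarizedExperiment} whose columns are the sub-cellular samples
#' of a paired single-cell experiment: every cell contributes exactly one
#' soma and one dendrite sample. \code{colData} must carry \code{cell_id}
#' and \code{compartment} ("soma"/"dendrite"); the single assay
#' \code{counts} holds non-negative integer read counts per quantification
#' feature. Per-sample size factors (median-of-ratios) are stored in
#' \code{colData$size_factor} once estimated.
#'
#' @export
setClass("PairedCountMatrix", contains = "SummarizedExperiment")

setValidity("PairedCountMatrix", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("cell_id", "compartment") %in% colnames(cd)))
    return("colData must have cell_id and compartment columns")
  if (!all(cd$compartment %in% c("soma", "dendrite")))
    msg <- c(msg, "compartment must be 'soma' or 'dendrite'")
  tab <- table(cd$cell_id, cd$compartment)
  if (!all(tab == 1L))
    msg <- c(msg, "every cell_id must appear exactly once per compartment")
  k <- assay(object, "counts")
  if (any(k < 0) || any(k != round(k)))
    msg <- c(msg, "counts must be non-negative integers")
  if ("size_factor" %in% colnames(cd) && any(cd$size_factor <= 0))
    msg <- c(msg, "size factors must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedCountMatrix
#'
#' @param counts feature x sample integer matrix (rownames = feature ids).
#' @param sampleInfo data.frame with columns \code{sample_id},
#'   \code{cell_id}, \code{compartment}; rows match the columns of
#'   \code{counts}.
#' @param rowData optional \code{DataFrame} of per-feature annotation
#'   (e.g. \code{gene_id}, \code{kind}).
#' @return a \code{PairedCountMatrix}.
#' @export
pairedCountMatrix <- function(counts, sampleInfo, rowData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  colnames(counts) <- sampleInfo$sample_id
  cd <- DataFrame(cell_id = as.character(sampleInfo$cell_id),
                  compartment = as.character(sampleInfo$compartment),
                  row.names = sampleInfo$sample_id)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  methods::new("PairedCountMatrix", se)
}

#' @rdname PairedCountMatrix-class
#' @param object a \code{PairedCountMatrix}
#' @export
setGeneric("compartment", function(object) standardGeneric("compartment"))

#' @rdname PairedCountMatrix-class
#' @export
setMethod("compartment", "PairedCountMatrix",
          function(object) colData(object)$compartment)

#' @rdname PairedCountMatrix-class
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname PairedCountMatrix-class
#' @export
setMethod("cellId", "PairedCountMatrix",
          function(object) colData(object)$cell_id)

#' @rdname PairedCountMatrix-class
#' @export
setMethod("sizeFactors", "PairedCountMatrix", function(object) {
  colData(object)$size_factor
})

#' @rdname PairedCountMatrix-class
#' @param value numeric vector of positive per-sample size factors
#' @export
setReplaceMethod("sizeFactors", "PairedCountMatrix", function(object, value) {
  colData(object)$size_factor <- value
  methods::validObject(object)
  object
})

setMethod("show", "PairedCountMatrix", function(object) {
  cat("PairedCountMatrix:", nrow(object), "features x", ncol(object),
      "samples (", length(unique(cellId(object))), "cells )\n")
  cat(" compartments:", paste(names(table(compartment(object))),
      table(compartment(object)), collapse = ", "), "\n")
  if (!is.null(sizeFactors(object))) cat(" size factors estimated\n")
})

## ---------------------------------------------------------------------------

#' Count strand-specific reads over quantification features
#'
#' A read is assigned to a feature when it overlaps the feature by at least
#' one base on the same strand. Reads overlapping features of more than one
#' gene are discarded as ambiguous. Within a gene, a read overlapping
#' several isoform-window features is assigned to the single feature with
#' the larger overlap, ties broken in favour of the more 3' feature
#' (transcript orientation).
#'
#' @param features \code{GRanges} of feature intervals with metadata columns
#'   \code{feature_id} and \code{gene_id} (as produced by
#'   \code{\link{buildUnionUtr}} / \code{\link{buildIsoformWindows}}).
#' @param reads named \code{GRangesList}: one \code{GRanges} of aligned read
#'   intervals per sample (names = sample ids).
#' @param sampleInfo data.frame with \code{sample_id}, \code{cell_id},
#'   \code{compartment}; one row per element of \code{reads}.
#' @return a \code{PairedCountMatrix} over the distinct feature ids.
#' @export
countReads <- function(features, reads, sampleInfo) {
  fids <- unique(features$feature_id)
  counts <- matrix(0L, nrow = length(fids), ncol = length(reads),
                   dimnames = list(fids, names(reads)))
  for (s in seq_along(reads)) {
    rd <- reads[[s]]
    if (length(rd) == 0L) next
    hits <- findOverlaps(rd, features, ignore.strand = FALSE)
    if (length(hits) == 0L) next
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ov <- width(IRanges::pintersect(IRanges::ranges(rd)[qh],
                                    IRanges::ranges(features)[sh]))
    gene <- features$gene_id[sh]
    fid <- features$feature_id[sh]
    str <- as.character(strand(features))[sh]
    ## 3'-ness key of the overlapped interval, strand aware
    pos3 <- ifelse(str == "+", end(features)[sh], -start(features)[sh])
    ## drop reads touching >1 gene
    ngene <- vapply(split(gene, qh), function(g) length(unique(g)),
                    integer(1))
    ambiguous <- as.integer(names(ngene)[ngene > 1L])
    keep <- !(qh %in% ambiguous)
    if (!any(keep)) next
    df <- data.frame(read = qh[keep], fid = fid[keep], ov = ov[keep],
                     pos3 = pos3[keep])
    ## total overlap per (read, feature); feature intervals are disjoint so
    ## summing is the per-base overlap with the whole feature
    key <- paste(df$read, df$fid, sep = "\r")
    totOv <- tapply(df$ov, key, sum)
    maxPos <- tapply(df$pos3, key, max)
    parts <- strsplit(names(totOv), "\r", fixed = TRUE)
    agg <- data.frame(read = vapply(parts, `[`, "", 1L),
                      fid = vapply(parts, `[`, "", 2L),
                      ov = as.numeric(totOv), pos3 = as.numeric(maxPos))
    ## per read: larger overlap wins, ties to the more 3' feature
    picked <- vapply(split(seq_len(nrow(agg)), agg$read), function(ix) {
      sub <- agg[ix, , drop = FALSE]
      sub <- sub[order(-sub$ov, -sub$pos3), , drop = FALSE]
      sub$fid[1]
    }, character(1))
    tab <- table(picked)
    counts[names(tab), s] <- counts[names(tab), s] + as.integer(tab)
  }
  rd <- DataFrame(feature_id = fids,
                  gene_id = features$gene_id[match(fids,
                                                   features$feature_id)],
                  kind = features$kind[match(fids, features$feature_id)])
  pairedCountMatrix(counts, sampleInfo, rowData = rd)
}

## ---------------------------------------------------------------------------

#' Median-of-ratios size factors
#'
#' The library-size normalization of Anders & Huber: each sample's size
#' factor is the median, over features with all-positive counts, of the
#' ratio of the sample's count to the feature's geometric mean across
#' samples. When no feature is positive in every sample the total-count
#' ratio is used instead, with a warning.
#'
#' @param counts feature x sample count matrix (or a
#'   \code{PairedCountMatrix}).
#' @return numeric vector of positive size factors, one per sample.
#' @export
medianOfRatios <- function(counts) {
  if (methods::is(counts, "PairedCountMatrix"))
    counts <- assay(counts, "counts")
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  ok <- is.finite(logGeo)
  if (!any(ok)) {
    warning("no feature with positive counts in all samples; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts, 2, function(k) {
    exp(stats::median(log(k[ok]) - logGeo[ok]))
  })
}

#' Estimate and store size factors on a PairedCountMatrix
#'
#' Registers a \code{\link{medianOfRatios}} method on the shared
#' \code{BiocGenerics::estimateSizeFactors} generic.
#'
#' @param object a \code{PairedCountMatrix}.
#' @param ... ignored.
#' @return the object with \code{sizeFactors(object)} filled in.
#' @importFrom BiocGenerics estimateSizeFactors
#' @export estimateSizeFactors
#' @exportMethod estimateSizeFactors
#' @aliases estimateSizeFactors,PairedCountMatrix-method
#' @name estimateSizeFactors
NULL

setMethod("estimateSizeFactors", "PairedCountMatrix",
          function(object, ...) {
  sizeFactors(object) <- medianOfRatios(assay(object, "counts"))
  object
})

#' Size-factor-normalized counts
#'
#' @param object a \code{PairedCountMatrix} (size factors estimated on the
#'   fly if absent).
#' @return numeric matrix of counts divided by per-sample size factors.
#' @export
normalizedCounts <- function(object) {
  sf <- sizeFactors(object)
  if (is.null(sf)) sf <- medianOfRatios(assay(object, "counts"))
  sweep(assay(object, "counts"), 2, sf, "/")
}

## ---------------------------------------------------------------------------

#' Expression filter: detected in enough samples
#'
#' Retains genes with at least \code{minReads} reads in at least
#' \code{minSamples} samples (the gene-level input filter for the
#' differential localization test; with 32 paired samples the default asks
#' for detection in half of them).
#'
#' @param object \code{PairedCountMatrix} of gene-level (union 3'UTR)
#'   counts, rownames or rowData \code{gene_id} identifying genes.
#' @param minReads minimum reads per sample to count as detected (default 1).
#' @param minSamples minimum number of detected samples (default 16).
#' @return character vector of retained gene ids.
#' @export
filterExpressed <- function(object, minReads = 1L, minSamples = 16L) {
  k <- assay(object, "counts")
  ids <- .geneIdsOf(object)
  keep <- rowSums(k >= minReads) >= minSamples
  unique(ids[keep])
}

.geneIdsOf <- function(object) {
  rd <- rowData(object)
  if ("gene_id" %in% colnames(rd)) as.character(rd$gene_id)
  else rownames(object)
}

## ---------------------------------------------------------------------------

#' Paired differential localization test (deDend / deSoma)
#'
#' For each gene, the size-factor-normalized counts of the 16
#' dendrite/soma pairs are compared with an exact paired Wilcoxon
#' signed-rank test (\code{\link{wilcoxonSignedRank}}); p-values are
#' Benjamini-Hochberg adjusted over the tested genes. A gene is called
#' \code{deDend} when its adjusted p-value is at most \code{alphaFdr} and
#' the median paired difference (dendrite minus soma) is positive;
#' \code{deSoma} symmetrically. Genes with fewer than \code{minPairs}
#' complete pairs are marked untestable.
#'
#' @param object gene-level \code{PairedCountMatrix}.
#' @param alphaFdr FDR threshold (default 0.05).
#' @param genes optional subset of gene ids to test (e.g. the output of
#'   \code{\link{filterExpressed}}); default all rows.
#' @param minPairs minimum complete pairs per gene (default 6).
#' @return data.frame with one row per tested gene: \code{gene_id},
#'   \code{median_diff}, \code{statistic} (standardized signed-rank z, sign
#'   = direction of dendritic shift), \code{p_value}, \code{fdr_q},
#'   \code{set} ("deDend", "deSoma" or "ns"), \code{testable}.
#' @export
callDE <- function(object, alphaFdr = 0.05, genes = NULL, minPairs = 6L) {
  norm <- normalizedCounts(object)
  ids <- .geneIdsOf(object)
  if (!is.null(genes)) {
    keep <- ids %in% genes
    norm <- norm[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  cells <- unique(cellId(object))
  dIdx <- match(paste0(cells, ".dendrite"),
                paste0(cellId(object), ".", compartment(object)))
  sIdx <- match(paste0(cells, ".soma"),
                paste0(cellId(object), ".", compartment(object)))
  res <- lapply(seq_len(nrow(norm)), function(i) {
    d <- norm[i, dIdx]; s <- norm[i, sIdx]
    ok <- !is.na(d) & !is.na(s)
    if (sum(ok) < minPairs)
      return(data.frame(gene_id = ids[i], median_diff = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        testable = FALSE))
    wt <- wilcoxonSignedRank(d[ok] - s[ok])
    data.frame(gene_id = ids[i], median_diff = stats::median(d[ok] - s[ok]),
               statistic = wt$z, p_value = wt$p.value, testable = TRUE)
  })
  res <- do.call(rbind, res)
  res$fdr_q <- NA_real_
  res$fdr_q[res$testable] <- stats::p.adjust(res$p_value[res$testable],
                                             method = "BH")
  res$set <- "ns"
  res$set[res$testable & res$fdr_q <= alphaFdr & res$median_diff > 0] <-
    "deDend"
  res$set[res$testable & res$fdr_q <= alphaFdr & res$median_diff < 0] <-
    "deSoma"
  res
}

#' Constitutive dendritic genes (consDend)
#'
#' Genes detected (at least one read) in at least
#' \code{ceiling(minFraction * n_dendrite_samples)} of the dendrite samples
#' (with 16 cells and the default 90\%, that is 15 of 16 dendrites).
#'
#' @param object gene-level \code{PairedCountMatrix}.
#' @param minFraction fraction of dendrite samples required (default 0.9).
#' @return character vector of consDend gene ids.
#' @export
callConsDend <- function(object, minFraction = 0.9) {
  k <- assay(object, "counts")[, compartment(object) == "dendrite",
                               drop = FALSE]
  need <- ceiling(minFraction * ncol(k))
  ids <- .geneIdsOf(object)
  unique(ids[rowSums(k >= 1L) >= need])
}

## ---------------------------------------------------------------------------

#' Aggregate an isoform-level matrix to gene level
#'
#' Sums isoform-window counts over each gene, yielding the gene-level matrix
#' used by the expression filter and paired DE test.
#'
#' @param object isoform-level \code{PairedCountMatrix} with
#'   \code{rowData(object)$gene_id}.
#' @return gene-level \code{PairedCountMatrix}.
#' @export
aggregateToGene <- function(object) {
  k <- assay(object, "counts")
  g <- .geneIdsOf(object)
  agg <- rowsum(k, group = g)
  si <- data.frame(sample_id = colnames(object),
                   cell_id = cellId(object),
                   compartment = compartment(object))
  pcm <- pairedCountMatrix(agg, si,
                           rowData = DataFrame(gene_id = rownames(agg),
                                               kind = "gene"))
  if (!is.null(sizeFactors(object))) sizeFactors(pcm) <- sizeFactors(object)
  pcm
}
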