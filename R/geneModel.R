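#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList reduce strand seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings XStringSet
NULL

#' GeneModel: transcripts and 3'UTRs of one gene
#'
#' Holds, for a single gene, the 3'UTR intervals of each transcript and the
#' genomic position of each transcript's 3' terminus. All intervals live on
#' one chromosome and strand. The 3' terminus is the maximal end coordinate
#' on the plus strand and the minimal start coordinate on the minus strand
#' (1-based, closed intervals throughout, the GenomicRanges convention).
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand "+" or "-".
#' @slot utr3 \code{GRangesList}, one element per transcript (named by
#'   transcript id) holding its 3'UTR intervals.
#' @slot end3 named numeric, genomic 3'-terminus position per transcript.
#' @export
setClass("GeneModel",
  representation(geneId = "character", chrom = "character",
                 strand = "character", utr3 = "GRangesList",
                 end3 = "numeric"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@utr3) == 0L)
    msg <- c(msg, "at least one transcript with 3'UTR intervals required")
  gr <- unlist(object@utr3, use.names = FALSE)
  if (length(gr)) {
    if (!all(as.character(seqnames(gr)) == object@chrom))
      msg <- c(msg, "all intervals must be on the gene's chromosome")
    if (!all(as.character(strand(gr)) == object@strand))
      msg <- c(msg, "all intervals must be on the gene's strand")
  }
  if (!identical(sort(names(object@utr3)), sort(names(object@end3))))
    msg <- c(msg, "end3 must be named by the same transcripts as utr3")
  for (tx in names(object@utr3)) {
    u <- object@utr3[[tx]]
    if (length(u) == 0L) { msg <- c(msg, "empty 3'UTR"); next }
    e <- if (object@strand == "+") max(end(u)) else min(start(u))
    if (object@end3[[tx]] != e)
      msg <- c(msg, sprintf("end3 inconsistent for transcript %s", tx))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param utr3 named list of \code{GRanges} (or a \code{GRangesList}), one
#'   per transcript, each holding that transcript's 3'UTR intervals.
#' @return a \code{GeneModel}.
#' @examples
#' gm <- geneModel("g1", "chr1", "+",
#'   list(t1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(101, 600), "+")))
#' @export
geneModel <- function(geneId, chrom, strand, utr3) {
  if (!methods::is(utr3, "GRangesList")) {
    utr3 <- GRangesList(lapply(utr3, function(g) {
      GenomicRanges::sort(g, decreasing = FALSE)
    }))
  }
  end3 <- vapply(seq_along(utr3), function(i) {
    u <- utr3[[i]]
    if (strand == "+") max(end(u)) else min(start(u))
  }, numeric(1))
  names(end3) <- names(utr3)
  methods::new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
               utr3 = utr3, end3 = end3)
}

#' @describeIn GeneModel-class gene identifier accessor
#' @param object a \code{GeneModel}
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @rdname GeneModel-class
#' @export
setGeneric("utr3", function(object) standardGeneric("utr3"))

#' @rdname GeneModel-class
#' @export
setMethod("utr3", "GeneModel", function(object) object@utr3)

#' @rdname GeneModel-class
#' @export
setGeneric("end3", function(object) standardGeneric("end3"))

#' @rdname GeneModel-class
#' @export
setMethod("end3", "GeneModel", function(object) object@end3)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, sprintf("(%s%s)", object@chrom,
      object@strand), "with", length(object@utr3), "transcript(s);",
      "3' ends:", paste(sort(unique(object@end3)), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------

#' Load gene models from a GTF/GFF3 or BED12 annotation
#'
#' GTF/GFF3 files are expected to carry Ensembl-style
#' \code{three_prime_utr}/\code{three_prime_UTR} records annotated with
#' \code{gene_id} and \code{transcript_id}. BED12 files are interpreted as
#' one transcript per line; the 3'UTR is the part of the exon blocks
#' downstream of the thick (CDS) region, and the name field may be
#' \code{"gene|transcript"} (otherwise gene = transcript = name).
#' Transcripts without any 3'UTR are dropped with a warning.
#'
#' @param path annotation file.
#' @param format "auto" (by extension), "gtf", "gff3", or "bed".
#' @return named list of \code{GeneModel}, one per gene.
#' @export
loadGeneModels <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed",
                     stop("cannot infer annotation format from '", path, "'"))
  }
  if (format == "bed") {
    bed <- rtracklayer::import(path, format = "bed")
    utrTab <- .bed12ToUtr3(bed)
  } else {
    gr <- rtracklayer::import(path, format = format)
    keep <- tolower(as.character(gr$type)) %in%
      c("three_prime_utr", "3'utr", "three_prime_utr")
    gr <- gr[keep]
    if (length(gr) == 0L)
      stop("no three_prime_utr records found in '", path, "'")
    if (is.null(gr$gene_id) || is.null(gr$transcript_id))
      stop("annotation records must carry gene_id and transcript_id")
    utrTab <- data.frame(gene = as.character(gr$gene_id),
                         tx = as.character(gr$transcript_id),
                         chrom = as.character(seqnames(gr)),
                         strand = as.character(strand(gr)),
                         start = start(gr), end = end(gr))
  }
  .utrTabToModels(utrTab)
}

.bed12ToUtr3 <- function(bed) {
  blocks <- rtracklayer::blocks(bed)   # absolute genomic exon coords
  out <- vector("list", length(bed))
  for (i in seq_along(bed)) {
    nm <- bed$name[i]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    gene <- parts[1]
    tx <- if (length(parts) > 1) parts[2] else parts[1]
    str <- as.character(strand(bed)[i])
    thick <- bed$thick[i]
    ex <- blocks[[i]]
    ## the 3'UTR is the exonic region strictly 3' of the CDS (thick) block
    lo <- if (str == "+") end(thick) + 1L else min(start(ex))
    hi <- if (str == "+") max(end(ex)) else start(thick) - 1L
    if (hi < lo) {
      warning("transcript ", tx, " has no 3'UTR; dropped")
      next
    }
    u <- IRanges::intersect(IRanges::ranges(ex), IRanges(lo, hi))
    if (length(u) == 0L || sum(width(u)) == 0L) {
      warning("transcript ", tx, " has no 3'UTR; dropped")
      next
    }
    out[[i]] <- data.frame(gene = gene, tx = tx,
                           chrom = as.character(seqnames(bed)[i]),
                           strand = str, start = start(u), end = end(u))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.utrTabToModels <- function(utrTab) {
  dropped <- character()
  models <- list()
  for (g in unique(utrTab$gene)) {
    sub <- utrTab[utrTab$gene == g, , drop = FALSE]
    if (length(unique(sub$strand)) > 1L)
      stop("gene ", g, " has transcripts on mixed strands")
    utr <- lapply(split(sub, sub$tx), function(s) {
      GRanges(s$chrom[1], IRanges(s$start, s$end), s$strand[1])
    })
    models[[g]] <- geneModel(g, sub$chrom[1], sub$strand[1], utr)
  }
  models
}

## ---------------------------------------------------------------------------

#' Union 3'UTR quantification feature for a gene
#'
#' Takes the interval union of all transcripts' 3'UTR regions, the feature
#' over which gene-level read counts are computed.
#'
#' @param gm a \code{GeneModel}.
#' @return a \code{GRanges} (possibly several disjoint intervals) with
#'   metadata columns \code{feature_id}, \code{gene_id}, \code{kind}
#'   ("union_utr") and \code{member_end3s}.
#' @export
buildUnionUtr <- function(gm) {
  stopifnot(methods::is(gm, "GeneModel"))
  u <- reduce(unlist(gm@utr3, use.names = FALSE))
  mcols(u) <- DataFrame(
    feature_id = rep(paste0(gm@geneId, ":union"), length(u)),
    gene_id = rep(gm@geneId, length(u)),
    kind = rep("union_utr", length(u)),
    member_end3s = rep(paste(sort(unique(gm@end3)), collapse = ","),
                       length(u)))
  u
}

## terminal `window` nt of a transcript's 3'UTR, walked in transcript space
## (spliced coordinates) so windows crossing an exon junction stay correct
.terminalWindow <- function(utrGr, strand, window) {
  rs <- IRanges::ranges(utrGr)
  ord <- if (strand == "+") order(-end(rs)) else order(start(rs))
  remaining <- window
  keep <- list()
  for (k in ord) {
    if (remaining <= 0) break
    w <- min(remaining, width(rs)[k])
    piece <- if (strand == "+") {
      IRanges(end(rs)[k] - w + 1L, end(rs)[k])
    } else {
      IRanges(start(rs)[k], start(rs)[k] + w - 1L)
    }
    keep[[length(keep) + 1L]] <- piece
    remaining <- remaining - w
  }
  IRanges::reduce(do.call(c, keep))
}

#' Non-overlapping 3'-isoform terminal-window features for a gene
#'
#' Collects the distinct transcript 3'-end positions of a gene, merges ends
#' lying closer than \code{mergeDist} on the genome into a single
#' quantification feature, and represents every (merged) end by the terminal
#' \code{window} nt upstream of it in transcript orientation (walked in
#' spliced coordinates, clipped at the 3'UTR start). A merged feature is the
#' union of its member ends' windows. Adjacent features of the same gene are
#' then made non-overlapping by truncating the upstream (more 5') feature at
#' the downstream feature's boundary. Features are returned ordered 5' to 3'
#' in transcript orientation.
#'
#' @param gm a \code{GeneModel}.
#' @param window terminal window length in nt (default 500).
#' @param mergeDist 3' ends closer than this many nt are merged (default 500).
#' @return \code{GRanges} with metadata columns \code{feature_id},
#'   \code{gene_id}, \code{kind} ("isoform_window") and \code{member_end3s}.
#' @export
buildIsoformWindows <- function(gm, window = 500L, mergeDist = 500L) {
  stopifnot(methods::is(gm, "GeneModel"))
  if (mergeDist <= 0) stop("mergeDist must be positive")
  if (window <= 0) stop("window must be positive")
  str <- gm@strand
  ends <- sort(unique(gm@end3))
  ## chain-merge ends at genomic distance < mergeDist
  cluster <- cumsum(c(1, diff(ends) >= mergeDist))
  ## per end: union of windows of all transcripts terminating there
  windowsByEnd <- lapply(ends, function(e) {
    txs <- names(gm@end3)[gm@end3 == e]
    IRanges::reduce(do.call(c, lapply(txs, function(tx) {
      .terminalWindow(gm@utr3[[tx]], str, window)
    })))
  })
  featRanges <- lapply(split(seq_along(ends), cluster), function(ix) {
    IRanges::reduce(do.call(c, windowsByEnd[ix]))
  })
  featEnds <- split(ends, cluster)
  ## order features 5' -> 3' in transcript orientation
  key <- vapply(featRanges, function(r) {
    if (str == "+") max(end(r)) else -min(start(r))
  }, numeric(1))
  ord <- order(key)
  featRanges <- featRanges[ord]
  featEnds <- featEnds[ord]
  ## truncate the upstream feature at the downstream feature's boundary,
  ## working from the 3'-most pair backwards
  K <- length(featRanges)
  if (K > 1L) {
    hi <- max(vapply(featRanges, function(r) max(end(r)), numeric(1))) + 1L
    for (k in seq_len(K - 1L)) {
      dn <- featRanges[[k + 1L]]
      bound <- if (str == "+") min(start(dn)) else max(end(dn))
      cut <- if (str == "+") IRanges(bound, hi)
             else IRanges(1L, bound)
      featRanges[[k]] <- IRanges::setdiff(featRanges[[k]], cut)
    }
    keepF <- vapply(featRanges, function(r) sum(width(r)) > 0, logical(1))
    featRanges <- featRanges[keepF]
    featEnds <- featEnds[keepF]
    K <- length(featRanges)
  }
  out <- lapply(seq_len(K), function(k) {
    r <- featRanges[[k]]
    gr <- GRanges(gm@chrom, r, str)
    mcols(gr) <- DataFrame(
      feature_id = rep(sprintf("%s:iso%d", gm@geneId, k), length(r)),
      gene_id = rep(gm@geneId, length(r)),
      kind = rep("isoform_window", length(r)),
      member_end3s = rep(paste(sort(featEnds[[k]]), collapse = ","),
                         length(r)))
    gr
  })
  do.call(c, out)
}

#' Classify an isoform pair as ALE or tandem
#'
#' Two alternative 3' ends are "tandem" (alternative cleavage and
#' polyadenylation within one terminal exon) when their full-length 3'UTRs
#' overlap or directly abut, and "ALE" (alternative last exons) otherwise.
#'
#' @param proximalUtr \code{GRanges} of the proximal isoform's full-length
#'   3'UTR intervals.
#' @param distalUtr \code{GRanges} of the distal isoform's full-length 3'UTR
#'   intervals.
#' @return "tandem" or "ALE".
#' @export
classifyPair <- function(proximalUtr, distalUtr) {
  hits <- findOverlaps(proximalUtr, distalUtr, maxgap = 0L,
                       ignore.strand = FALSE)
  if (length(hits) > 0L) "tandem" else "ALE"
}
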