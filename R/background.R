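#' Build the ordered non-localized gene pool
#'
#' Background 3'UTRs for motif enrichment are drawn from genes
#' significantly higher in the soma, minus any gene on a localized or
#' previously annotated dendritic list, ordered by descending somatic
#' specificity (magnitude of the paired DE test statistic).
#'
#' @param deResults data.frame from \code{\link{callDE}}.
#' @param excludeLists list (or vector) of gene-id vectors to remove (e.g.
#'   consDend, isoDend, known dendritic genes).
#' @return character vector: pool gene ids, most soma-specific first.
#' @export
buildPool <- function(deResults, excludeLists = list()) {
  soma <- deResults[deResults$set == "deSoma", , drop = FALSE]
  soma <- soma[order(-abs(soma$statistic)), , drop = FALSE]
  excl <- unique(unlist(excludeLists))
  setdiff(soma$gene_id, excl)
}

#' Length-matched background set
#'
#' Greedy matcher: for each foreground gene, scan the pool in order (most
#' soma-specific first) and select the first pool gene whose 3'UTR length
#' is within \code{tol} nt of the foreground gene's; the selected gene is
#' removed from the pool. If no pool gene is within tolerance, the
#' remaining pool gene with the most similar length is taken (ties go to
#' the earlier pool position).
#'
#' @param fgLengths named numeric: foreground gene 3'UTR lengths.
#' @param poolLengths named numeric: pool gene lengths, in pool order.
#' @param tol length tolerance in nt (default 100).
#' @return data.frame: fg_gene, bg_gene, fg_len, bg_len, within_tol.
#' @export
matchBackground <- function(fgLengths, poolLengths, tol = 100L) {
  if (length(poolLengths) < length(fgLengths))
    stop("pool smaller than foreground set")
  poolIds <- names(poolLengths)
  avail <- rep(TRUE, length(poolLengths))
  rows <- vector("list", length(fgLengths))
  for (i in seq_along(fgLengths)) {
    L <- fgLengths[i]
    idx <- which(avail & abs(poolLengths - L) <= tol)
    if (length(idx) > 0L) {
      pick <- idx[1]
    } else {
      open <- which(avail)
      pick <- open[which.min(abs(poolLengths[open] - L))]
    }
    avail[pick] <- FALSE
    rows[[i]] <- data.frame(fg_gene = names(fgLengths)[i],
                            bg_gene = poolIds[pick],
                            fg_len = unname(L),
                            bg_len = unname(poolLengths[pick]),
                            within_tol = abs(poolLengths[pick] - L) <= tol)
  }
  do.call(rbind, rows)
}

#' One-match-per-gene Fisher enrichment
#'
#' Enrichment of a motif in a foreground gene set versus a matched
#' background: only one match is counted per gene, so the unit is
#' genes-with-a-hit. The fold is the ratio of hit fractions; the odds
#' ratio is the sample (cross-product) odds ratio of the 2x2 table (Inf
#' with a zero off-diagonal cell); the p-value is the two-sided Fisher
#' exact test.
#'
#' @param fgHits foreground genes with at least one hit.
#' @param fgTotal foreground genes in total.
#' @param bgHits background genes with at least one hit.
#' @param bgTotal background genes in total.
#' @param motifId optional label.
#' @return list: motif_id, fg_genes_hit, fg_genes_total, bg_genes_hit,
#'   bg_genes_total, fold, odds_ratio, p.
#' @export
fisherEnrichment <- function(fgHits, fgTotal, bgHits, bgTotal,
                             motifId = NA_character_) {
  stopifnot(fgHits <= fgTotal, bgHits <= bgTotal)
  tab <- matrix(c(fgHits, fgTotal - fgHits, bgHits, bgTotal - bgHits),
                nrow = 2, byrow = TRUE)
  fold <- (fgHits / fgTotal) / (bgHits / bgTotal)
  orNum <- fgHits * (bgTotal - bgHits)
  orDen <- (fgTotal - fgHits) * bgHits
  oddsRatio <- if (orDen == 0) {
    if (orNum == 0) NaN else Inf
  } else orNum / orDen
  p <- stats::fisher.test(tab)$p.value
  list(motif_id = motifId, fg_genes_hit = fgHits, fg_genes_total = fgTotal,
       bg_genes_hit = bgHits, bg_genes_total = bgTotal, fold = fold,
       odds_ratio = oddsRatio, p = p)
}
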