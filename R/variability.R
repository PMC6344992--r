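#' Dendritic read fraction
#'
#' For one gene in one cell: dendritic reads divided by the sum of
#' dendritic and somatic reads. Undefined (NA) when the cell has no reads
#' for the gene; cells below the caller's minimum total are excluded
#' upstream.
#'
#' @param d dendritic read count(s).
#' @param s somatic read count(s).
#' @return numeric in [0, 1], NA where d + s == 0.
#' @export
dendriticFraction <- function(d, s) {
  tot <- d + s
  ifelse(tot > 0, d / tot, NA_real_)
}

#' Per-cell dendritic read fractions for every gene
#'
#' @param object gene-level \code{PairedCountMatrix}.
#' @param minTotal minimum combined (dendrite + soma) raw reads for a cell
#'   to contribute a defined fraction (default 10).
#' @return list with \code{f} (genes x cells matrix of fractions, NA below
#'   threshold), \code{d} and \code{s} (the raw count matrices).
#' @export
fractionProfile <- function(object, minTotal = 10L) {
  k <- assay(object, "counts")
  cells <- unique(cellId(object))
  dIdx <- match(paste0(cells, ".dendrite"),
                paste0(cellId(object), ".", compartment(object)))
  sIdx <- match(paste0(cells, ".soma"),
                paste0(cellId(object), ".", compartment(object)))
  d <- k[, dIdx, drop = FALSE]; s <- k[, sIdx, drop = FALSE]
  colnames(d) <- colnames(s) <- cells
  f <- dendriticFraction(d, s)
  f[d + s < minTotal] <- NA_real_
  rownames(f) <- .geneIdsOf(object)
  list(f = f, d = d, s = s)
}

#' Cross-cell localization variance
#'
#' Sample variance of the dendritic read fraction across the cells where it
#' is defined. High variance marks genes whose localization differs
#' strongly from cell to cell ("all-or-nothing" profiles approach the
#' maximal 0.25); low variance marks constitutively localized genes.
#'
#' @param f numeric vector of per-cell dendritic read fractions (NAs
#'   ignored).
#' @return sample variance (NA with fewer than 2 defined cells).
#' @export
localizationVariance <- function(f) {
  f <- f[!is.na(f)]
  if (length(f) < 2L) return(NA_real_)
  stats::var(f)
}

#' Read-downsampling control for localization variance
#'
#' Expression level influences the variance of a read fraction, so
#' fractions of highly expressed genes are re-estimated at a fixed total of
#' \code{nDown} reads per cell: in every replicate, each cell's dendritic
#' read count is drawn Binomial(\code{nDown}, f_cell) — sampling reads from
#' either compartment in proportion to the original frequencies — the
#' fractions are recomputed and their cross-cell variance taken. The mean
#' and a nonparametric percentile interval over replicates are reported.
#' Cells with fewer than \code{nDown} total reads are excluded (the
#' binomial model is exact only at or above the target total).
#'
#' @param d per-cell dendritic read counts for one gene.
#' @param s per-cell somatic read counts.
#' @param nDown downsampled total per cell (default 10).
#' @param reps number of resampling replicates (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param ciProbs percentile bounds of the interval (default 2.5/97.5).
#' @return list with \code{mean_variance}, \code{ci} (length-2), \code{reps}
#'   (the per-replicate variances) and \code{n_cells}.
#' @export
downsampledVariance <- function(d, s, nDown = 10L, reps = 1000L,
                                seed = NULL, ciProbs = c(0.025, 0.975)) {
  if (reps < 1L) stop("reps must be >= 1")
  keep <- !is.na(d) & !is.na(s) & (d + s >= nDown)
  d <- d[keep]; s <- s[keep]
  n <- length(d)
  if (n < 2L)
    return(list(mean_variance = NA_real_, ci = c(NA_real_, NA_real_),
                reps = numeric(0), n_cells = n))
  f <- d / (d + s)
  if (!is.null(seed)) set.seed(seed)
  v <- vapply(seq_len(reps), function(r) {
    stats::var(stats::rbinom(n, nDown, f) / nDown)
  }, numeric(1))
  list(mean_variance = mean(v),
       ci = unname(stats::quantile(v, ciProbs)),
       reps = v, n_cells = n)
}

#' Localization variability table for a gene set
#'
#' Convenience wrapper computing, per gene, the number of contributing
#' cells, the raw cross-cell variance of the dendritic read fraction, and
#' the downsampled mean variance with its percentile interval.
#'
#' @param object gene-level \code{PairedCountMatrix}.
#' @param genes gene ids to summarize (default all).
#' @param minTotal minimum combined reads per cell (default 10).
#' @param nDown,reps,seed passed to \code{\link{downsampledVariance}}.
#' @return data.frame: gene, n_cells, variance, downsampled_mean, ci_lo,
#'   ci_hi.
#' @export
variabilityTable <- function(object, genes = NULL, minTotal = 10L,
                             nDown = 10L, reps = 1000L, seed = NULL) {
  prof <- fractionProfile(object, minTotal = minTotal)
  ids <- rownames(prof$f)
  if (is.null(genes)) genes <- ids
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(genes, function(g) {
    i <- match(g, ids)
    fv <- prof$f[i, ]
    ok <- !is.na(fv)
    ds <- downsampledVariance(prof$d[i, ok], prof$s[i, ok], nDown = nDown,
                              reps = reps, seed = NULL)
    data.frame(gene = g, n_cells = sum(ok),
               variance = localizationVariance(fv),
               downsampled_mean = ds$mean_variance,
               ci_lo = ds$ci[1], ci_hi = ds$ci[2])
  })
  do.call(rbind, rows)
}
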