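#' IsoformPairSet: per-gene proximal/distal records and distal fractions
#'
#' Result container of \code{\link{isoformRecords}}: a per-gene record table
#' together with the per-sample distal-fraction (DF) matrix and the per-cell
#' change in distal fraction (dDF = DF_dendrite - DF_soma).
#'
#' @slot records \code{DataFrame}: gene_id, proximal_id, distal_id, cls,
#'   n_valid_pairs, median_ddf, mean_ddf, p_wilcoxon, tested, isoDend,
#'   preferred, df_var_soma, df_var_dendrite.
#' @slot df genes x samples DF matrix (NA where undefined).
#' @slot ddf genes x cells dDF matrix (NA where either member undefined).
#' @slot sampleInfo \code{DataFrame} with sample_id, cell_id, compartment.
#' @export
setClass("IsoformPairSet",
  representation(records = "DataFrame", df = "matrix", ddf = "matrix",
                 sampleInfo = "DataFrame"))

#' @rdname IsoformPairSet-class
#' @param object an \code{IsoformPairSet}
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname IsoformPairSet-class
#' @export
setMethod("records", "IsoformPairSet", function(object) object@records)

#' @rdname IsoformPairSet-class
#' @export
setGeneric("distalFractions", function(object) standardGeneric("distalFractions"))

#' @rdname IsoformPairSet-class
#' @export
setMethod("distalFractions", "IsoformPairSet", function(object) object@df)

setMethod("show", "IsoformPairSet", function(object) {
  r <- object@records
  cat("IsoformPairSet:", nrow(r), "multi-isoform genes;",
      sum(r$tested), "tested;", sum(r$isoDend), "isoDend\n")
})

## ---------------------------------------------------------------------------

#' Select the top two 3' isoforms of a gene
#'
#' Per sample with at least \code{minReads} total gene reads, the read
#' fraction of every isoform is computed; fractions are summed across the
#' qualifying samples (each sample weighted equally) and the two isoforms
#' with the highest totals are kept. Ties are broken by larger total raw
#' reads, then by the more 3' feature. The more 5' of the two (transcript
#' orientation) is the proximal isoform, the more 3' the distal.
#'
#' @param counts isoforms x samples count matrix for one gene (rownames =
#'   feature ids).
#' @param key named numeric 5'-to-3' ordering key per feature (larger =
#'   more 3').
#' @param minReads minimum total gene reads for a sample to vote
#'   (default 10).
#' @return named character c(proximal, distal), or NULL if no sample
#'   reaches \code{minReads}.
#' @export
selectTopTwo <- function(counts, key, minReads = 10L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2L, !is.null(rownames(counts)))
  tot <- colSums(counts)
  use <- tot >= minReads
  if (!any(use)) return(NULL)
  frac <- sweep(counts[, use, drop = FALSE], 2, tot[use], "/")
  sumFrac <- rowSums(frac)
  raw <- rowSums(counts)
  k <- key[rownames(counts)]
  ord <- order(-sumFrac, -raw, -k)
  top <- rownames(counts)[ord[1:2]]
  if (k[top[1]] > k[top[2]]) top <- rev(top)
  c(proximal = top[1], distal = top[2])
}

#' Distal fraction
#'
#' Reads mapping to the distal isoform divided by the combined reads of the
#' distal and proximal isoforms; undefined (NA) when the combined total is
#' below \code{minReads}.
#'
#' @param distal distal-isoform read count(s).
#' @param proximal proximal-isoform read count(s).
#' @param minReads minimum combined reads (default 10).
#' @return numeric in [0, 1] or NA.
#' @export
distalFraction <- function(distal, proximal, minReads = 10L) {
  tot <- distal + proximal
  ifelse(tot >= minReads, distal / tot, NA_real_)
}

#' Paired consistency test for isoform-specific localization
#'
#' Two-sided exact Wilcoxon signed-rank test on a gene's per-cell dDF
#' values (zeros dropped, midranked ties, exact null enumeration for n <=
#' 25). The gene is isoDend when at least \code{minPairs} valid pairs exist
#' and p < \code{alpha}; the preferred isoform is distal when the median
#' dDF is positive, proximal when negative (ties broken by the mean).
#'
#' @param ddf numeric vector of per-cell dDF values (NAs dropped).
#' @param minPairs minimum valid soma-dendrite pairs (default 5).
#' @param alpha significance level (default 0.1).
#' @return list: n_valid_pairs, p_wilcoxon, tested, isoDend, preferred
#'   ("distal"/"proximal"/NA), median_ddf, mean_ddf.
#' @export
testIsoformLocalization <- function(ddf, minPairs = 5L, alpha = 0.1) {
  ddf <- ddf[!is.na(ddf)]
  n <- length(ddf)
  tested <- n >= minPairs
  if (!tested)
    return(list(n_valid_pairs = n, p_wilcoxon = NA_real_, tested = FALSE,
                isoDend = FALSE, preferred = NA_character_,
                median_ddf = if (n) stats::median(ddf) else NA_real_,
                mean_ddf = if (n) mean(ddf) else NA_real_))
  wt <- wilcoxonSignedRank(ddf)
  med <- stats::median(ddf); mn <- mean(ddf)
  dir <- if (med > 0) "distal" else if (med < 0) "proximal"
         else if (mn > 0) "distal" else if (mn < 0) "proximal"
         else NA_character_
  iso <- !is.na(wt$p.value) && wt$p.value < alpha && !is.na(dir)
  list(n_valid_pairs = n, p_wilcoxon = wt$p.value, tested = TRUE,
       isoDend = iso, preferred = if (iso || !is.na(dir)) dir else NA_character_,
       median_ddf = med, mean_ddf = mn)
}

## ---------------------------------------------------------------------------

#' Build per-gene isoform pair records from isoform-window counts
#'
#' For every gene with at least two expressed isoform-window features,
#' selects the top two isoforms, computes per-sample DF and per-cell dDF,
#' runs the paired consistency test, and records compartment-wise DF
#' variances. Optionally classifies each pair as ALE or tandem from the
#' full-length 3'UTR intervals.
#'
#' @param object isoform-level \code{PairedCountMatrix} with
#'   \code{rowData} columns \code{gene_id} (rownames = feature ids).
#' @param featureKey named numeric 5'-to-3' ordering key per feature;
#'   defaults to the \code{:iso<k>} suffix rank of the feature ids.
#' @param minReads minimum combined proximal+distal reads for a defined DF,
#'   and minimum total gene reads for top-two voting (default 10).
#' @param minPairs minimum valid pairs for testing (default 5).
#' @param alpha isoDend significance level (default 0.1).
#' @param utrByFeature optional named \code{GRangesList} of full-length
#'   3'UTR intervals per feature id, used for ALE/tandem classification.
#' @return an \code{\link{IsoformPairSet-class}} object.
#' @export
isoformRecords <- function(object, featureKey = NULL, minReads = 10L,
                           minPairs = 5L, alpha = 0.1,
                           utrByFeature = NULL) {
  k <- assay(object, "counts")
  gid <- .geneIdsOf(object)
  if (is.null(featureKey)) {
    idx <- suppressWarnings(as.numeric(sub(".*:iso", "", rownames(k))))
    if (any(is.na(idx)))
      stop("featureKey required when feature ids lack an :iso<k> suffix")
    featureKey <- stats::setNames(idx, rownames(k))
  }
  cells <- unique(cellId(object))
  sampTag <- paste0(cellId(object), ".", compartment(object))
  dIdx <- match(paste0(cells, ".dendrite"), sampTag)
  sIdx <- match(paste0(cells, ".soma"), sampTag)

  genes <- unique(gid)
  recRows <- list(); dfRows <- list(); ddfRows <- list()
  for (g in genes) {
    sub <- k[gid == g, , drop = FALSE]
    expressed <- rowSums(sub) > 0
    if (sum(expressed) < 2L) next
    sub <- sub[expressed, , drop = FALSE]
    top <- selectTopTwo(sub, featureKey, minReads = minReads)
    if (is.null(top)) next
    dfv <- distalFraction(sub[top["distal"], ], sub[top["proximal"], ],
                          minReads = minReads)
    ddf <- dfv[dIdx] - dfv[sIdx]
    tl <- testIsoformLocalization(ddf, minPairs = minPairs, alpha = alpha)
    cls <- NA_character_
    if (!is.null(utrByFeature) &&
        all(top %in% names(utrByFeature)))
      cls <- classifyPair(utrByFeature[[top["proximal"]]],
                          utrByFeature[[top["distal"]]])
    vS <- stats::var(dfv[sIdx], na.rm = TRUE)
    vD <- stats::var(dfv[dIdx], na.rm = TRUE)
    recRows[[g]] <- data.frame(
      gene_id = g, proximal_id = unname(top["proximal"]),
      distal_id = unname(top["distal"]), cls = cls,
      n_valid_pairs = tl$n_valid_pairs, median_ddf = tl$median_ddf,
      mean_ddf = tl$mean_ddf, p_wilcoxon = tl$p_wilcoxon,
      tested = tl$tested, isoDend = tl$isoDend,
      preferred = if (is.null(tl$preferred)) NA_character_ else tl$preferred,
      df_var_soma = vS, df_var_dendrite = vD)
    dfRows[[g]] <- dfv
    ddfRows[[g]] <- ddf
  }
  if (length(recRows) == 0L)
    stop("no gene with two expressed isoforms and sufficient reads")
  rec <- do.call(rbind, recRows)
  dfm <- do.call(rbind, dfRows)
  colnames(dfm) <- colnames(k)
  ddfm <- do.call(rbind, ddfRows)
  colnames(ddfm) <- cells
  si <- DataFrame(sample_id = colnames(object), cell_id = cellId(object),
                  compartment = compartment(object))
  methods::new("IsoformPairSet", records = DataFrame(rec), df = dfm,
               ddf = ddfm, sampleInfo = si)
}

## ---------------------------------------------------------------------------

#' Distal-preference summary: isoDend vs remaining tested genes
#'
#' Counts distal- versus proximal-preferred genes inside the isoDend set
#' and in the complement of the tested set (preference of a non-isoDend
#' gene is the sign of its mean dDF; genes with exactly zero mean are
#' excluded), and tests the association by Fisher's exact test. The odds
#' ratio reported is the sample (cross-product) odds ratio.
#'
#' @param ips an \code{IsoformPairSet} (or its records data.frame).
#' @return list: table (2x2), fraction_distal_isoDend,
#'   fraction_distal_rest, odds_ratio, p_value.
#' @export
preferenceSummary <- function(ips) {
  r <- if (methods::is(ips, "IsoformPairSet")) as.data.frame(records(ips))
       else as.data.frame(ips)
  r <- r[r$tested, , drop = FALSE]
  pref <- ifelse(r$isoDend, r$preferred,
                 ifelse(r$mean_ddf > 0, "distal",
                        ifelse(r$mean_ddf < 0, "proximal", NA)))
  ok <- !is.na(pref)
  iso <- r$isoDend[ok]; pref <- pref[ok]
  tab <- rbind(isoDend = c(distal = sum(iso & pref == "distal"),
                           proximal = sum(iso & pref == "proximal")),
               rest = c(distal = sum(!iso & pref == "distal"),
                        proximal = sum(!iso & pref == "proximal")))
  enr <- fisherEnrichment(tab[1, 1], sum(tab[1, ]), tab[2, 1],
                          sum(tab[2, ]))
  list(table = tab,
       fraction_distal_isoDend = tab[1, 1] / sum(tab[1, ]),
       fraction_distal_rest = tab[2, 1] / sum(tab[2, ]),
       odds_ratio = enr$odds_ratio, p_value = enr$p)
}

#' Compartment DF-variability comparison with soma downsampling
#'
#' For each gene, compares the variance of DF across soma samples with the
#' variance across dendrite samples, and summarizes how often the soma is
#' the more variable compartment among isoDend genes versus the full tested
#' set (sample odds ratio + Fisher p). Because somas carry more reads than
#' dendrites, the comparison is repeated with the soma DF re-estimated from
#' \code{nDown} binomially downsampled reads per sample, \code{reps} times;
#' the mean fraction of isoDend genes with soma-more-variable DF across
#' replicates is reported.
#'
#' @param ips an \code{IsoformPairSet}.
#' @param nDown downsampled read total per soma sample (default 10).
#' @param reps downsampling replicates (default 1000).
#' @param seed integer seed for reproducibility.
#' @return list: per_gene (data.frame gene_id, df_var_soma,
#'   df_var_dendrite, soma_more_variable), fraction_isoDend,
#'   fraction_tested, odds_ratio, p_value, downsampled_fraction_isoDend,
#'   downsampled_reps.
#' @export
dfVarianceComparison <- function(ips, nDown = 10L, reps = 1000L,
                                 seed = NULL) {
  stopifnot(methods::is(ips, "IsoformPairSet"))
  if (reps < 1L) stop("reps must be >= 1")
  r <- as.data.frame(records(ips))
  tested <- r$tested
  smv <- r$df_var_soma > r$df_var_dendrite
  perGene <- data.frame(gene_id = r$gene_id, df_var_soma = r$df_var_soma,
                        df_var_dendrite = r$df_var_dendrite,
                        soma_more_variable = smv)
  okT <- tested & !is.na(smv)
  okI <- okT & r$isoDend
  a <- sum(smv[okI]); b <- sum(!smv[okI])
  cc <- sum(smv[okT]); dd <- sum(!smv[okT])
  enr <- fisherEnrichment(a, a + b, cc, cc + dd)
  ## soma downsampling among isoDend genes
  somaCols <- ips@sampleInfo$compartment == "soma"
  dfSoma <- ips@df[r$gene_id[okI], somaCols, drop = FALSE]
  vDend <- r$df_var_dendrite[okI]
  if (!is.null(seed)) set.seed(seed)
  fracReps <- vapply(seq_len(reps), function(rp) {
    vS <- apply(dfSoma, 1, function(p) {
      p <- p[!is.na(p)]
      if (length(p) < 2L) return(NA_real_)
      stats::var(stats::rbinom(length(p), nDown, p) / nDown)
    })
    mean(vS > vDend, na.rm = TRUE)
  }, numeric(1))
  list(per_gene = perGene,
       fraction_isoDend = a / (a + b),
       fraction_tested = cc / (cc + dd),
       odds_ratio = enr$odds_ratio, p_value = enr$p,
       downsampled_fraction_isoDend = mean(fracReps),
       downsampled_reps = fracReps)
}

#' Paired length comparison of preferred vs non-preferred isoforms
#'
#' Among isoDend genes, tests whether the dendrite-preferred isoform's
#' full-length 3'UTR is longer than the non-preferred isoform's, with a
#' paired t-test computed separately for ALE and tandem pairs.
#'
#' @param ips an \code{IsoformPairSet} with \code{cls} filled in.
#' @param utrLengths named numeric: full-length 3'UTR length per feature id.
#' @return data.frame per class: cls, n_pairs, mean_diff (preferred minus
#'   non-preferred), t, p_value, testable.
#' @export
lengthComparison <- function(ips, utrLengths) {
  r <- as.data.frame(records(ips))
  r <- r[r$isoDend & !is.na(r$cls) & !is.na(r$preferred), , drop = FALSE]
  prefId <- ifelse(r$preferred == "distal", r$distal_id, r$proximal_id)
  otherId <- ifelse(r$preferred == "distal", r$proximal_id, r$distal_id)
  lp <- utrLengths[prefId]; lo <- utrLengths[otherId]
  out <- lapply(c("ALE", "tandem"), function(cl) {
    sel <- r$cls == cl & !is.na(lp) & !is.na(lo)
    n <- sum(sel)
    if (n < 2L)
      return(data.frame(cls = cl, n_pairs = n, mean_diff = NA_real_,
                        t = NA_real_, p_value = NA_real_,
                        testable = FALSE))
    d <- lp[sel] - lo[sel]
    if (stats::sd(d) == 0) {
      ## degenerate: all differences identical; t undefined unless all zero
      if (all(d == 0))
        return(data.frame(cls = cl, n_pairs = n, mean_diff = 0, t = 0,
                          p_value = 1, testable = TRUE))
      return(data.frame(cls = cl, n_pairs = n, mean_diff = mean(d),
                        t = Inf, p_value = 0, testable = TRUE))
    }
    tt <- stats::t.test(lp[sel], lo[sel], paired = TRUE)
    data.frame(cls = cl, n_pairs = n, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), p_value = tt$p.value,
               testable = TRUE)
  })
  do.call(rbind, out)
}
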