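#' SimScenario: parameters of the synthetic paired-compartment study
#'
#' Describes a synthetic experiment shaped like the real study design: 16
#' single neurons, each contributing one soma and one dendrite sample, with
#' multi-3'-isoform genes, negative-binomial counting noise, dropout, and
#' planted localization classes. Defaults are the study conditions: 16
#' cells, a 10x dendritic concentration ratio for gene-level localized
#' (deDend) genes, a distal-fraction shift of 0.3 for isoform-level
#' (isoDend) genes, and moderate single-cell noise (gene-level NB
#' dispersion 0.3, sparser and droppier dendrites than somas).
#'
#' @slot nCells number of neurons (default 16; 32 samples).
#' @slot nGenes number of genes (default 1000).
#' @slot classFractions named fractions for deDend, consDend (constitutive
#'   only), isoDend and nonlocalized genes (sum to 1).
#' @slot deDendRatio dendrite/soma concentration ratio of deDend genes.
#' @slot deltaDF planted DF_dendrite - DF_soma magnitude for isoDend genes.
#' @slot probDistal probability an isoDend gene prefers the distal isoform.
#' @slot nonlocSdLog lognormal sd of the per-gene dendrite/soma ratio of
#'   nonlocalized genes (0 = exact null).
#' @slot isoformCountProbs probabilities of 1..4 expressed 3' isoforms.
#' @slot dispersion NB dispersion (size = 1/dispersion).
#' @slot dropoutSoma per-gene-sample dropout probability in somas.
#' @slot dropoutDendrite dropout in dendrites (nonlocalized/isoDend genes).
#' @slot dropoutDendriteCons dropout in dendrites for consDend/deDend genes
#'   (constitutive presence).
#' @slot librarySpread lognormal sd of per-sample library factors.
#' @slot dendriteScale multiplicative depth of dendrite libraries relative
#'   to somas (dendrites yield fewer reads).
#' @slot baselineMeanLog,baselineSdLog lognormal baseline expression.
#' @slot aleFraction fraction of isoform pairs with ALE (vs tandem)
#'   geometry in simulated annotations.
#' @slot mergeNearRate fraction of adjacent 3' ends planted closer than the
#'   500-nt merge distance in simulated annotations.
#' @slot seed integer RNG seed; a fixed seed gives bit-identical output.
#' @export
setClass("SimScenario",
  representation(nCells = "integer", nGenes = "integer",
                 classFractions = "numeric", deDendRatio = "numeric",
                 deltaDF = "numeric", probDistal = "numeric",
                 nonlocSdLog = "numeric", isoformCountProbs = "numeric",
                 dispersion = "numeric", dropoutSoma = "numeric",
                 dropoutDendrite = "numeric",
                 dropoutDendriteCons = "numeric",
                 librarySpread = "numeric", dendriteScale = "numeric",
                 baselineMeanLog = "numeric", baselineSdLog = "numeric",
                 aleFraction = "numeric", mergeNearRate = "numeric",
                 seed = "integer"))

setValidity("SimScenario", function(object) {
  msg <- character()
  f <- object@classFractions
  if (!all(c("deDend", "consDend", "isoDend", "nonlocalized") %in% names(f)))
    msg <- c(msg, "classFractions must name deDend, consDend, isoDend, nonlocalized")
  if (abs(sum(f) - 1) > 1e-8) msg <- c(msg, "classFractions must sum to 1")
  if (object@deltaDF < 0 || object@deltaDF > 1)
    msg <- c(msg, "deltaDF must lie in [0, 1]")
  if (abs(sum(object@isoformCountProbs) - 1) > 1e-8)
    msg <- c(msg, "isoformCountProbs must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation scenario
#'
#' @param nCells,nGenes,classFractions,deDendRatio,deltaDF,probDistal
#'   see \code{\link{SimScenario-class}}.
#' @param nonlocSdLog,isoformCountProbs,dispersion,dropoutSoma see class.
#' @param dropoutDendrite,dropoutDendriteCons,librarySpread see class.
#' @param dendriteScale,baselineMeanLog,baselineSdLog see class.
#' @param aleFraction,mergeNearRate,seed see class.
#' @return a \code{SimScenario}.
#' @export
simScenario <- function(nCells = 16L, nGenes = 1000L,
                        classFractions = c(deDend = 0.10, consDend = 0.20,
                                           isoDend = 0.10,
                                           nonlocalized = 0.60),
                        deDendRatio = 10, deltaDF = 0.3, probDistal = 0.5,
                        nonlocSdLog = 0.4,
                        isoformCountProbs = c(0.30, 0.40, 0.20, 0.10),
                        dispersion = 0.3, dropoutSoma = 0.05,
                        dropoutDendrite = 0.25,
                        dropoutDendriteCons = 0.02,
                        librarySpread = 0.3, dendriteScale = 0.4,
                        baselineMeanLog = log(150), baselineSdLog = 1,
                        aleFraction = 0.85, mergeNearRate = 0.2,
                        seed = 1L) {
  methods::new("SimScenario", nCells = as.integer(nCells),
               nGenes = as.integer(nGenes),
               classFractions = classFractions, deDendRatio = deDendRatio,
               deltaDF = deltaDF, probDistal = probDistal,
               nonlocSdLog = nonlocSdLog,
               isoformCountProbs = isoformCountProbs,
               dispersion = dispersion, dropoutSoma = dropoutSoma,
               dropoutDendrite = dropoutDendrite,
               dropoutDendriteCons = dropoutDendriteCons,
               librarySpread = librarySpread,
               dendriteScale = dendriteScale,
               baselineMeanLog = baselineMeanLog,
               baselineSdLog = baselineSdLog, aleFraction = aleFraction,
               mergeNearRate = mergeNearRate, seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", object@nGenes, "genes x", object@nCells,
      "cells (paired soma/dendrite); classes:",
      paste(names(object@classFractions),
            round(object@classFractions * object@nGenes), collapse = ", "),
      "; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------

#' Simulate paired isoform-window counts with planted localization classes
#'
#' Per gene: a lognormal baseline, a class-specific dendrite/soma
#' concentration ratio (deDend genes enriched, nonlocalized genes spread
#' around 1, consDend genes at 1 but constitutively detected), Dirichlet
#' isoform proportions (isoDend genes get the distal share of their top
#' two isoforms shifted by deltaDF between compartments, consistently
#' across cells), NB counts per isoform thinned by class- and
#' compartment-specific dropout, and per-sample library factors.
#'
#' @param sc a \code{\link{SimScenario-class}}.
#' @param seed optional override of \code{sc@seed}.
#' @return list: \code{counts} (isoform-level
#'   \code{\link{PairedCountMatrix-class}}, feature ids
#'   \code{<gene>:iso<k>}), \code{truth} (data.frame: gene_id, class,
#'   n_isoforms, proximal_id, distal_id, true_df_soma, true_df_dendrite,
#'   preferred).
#' @export
simulateCounts <- function(sc, seed = NULL) {
  stopifnot(methods::is(sc, "SimScenario"))
  set.seed(if (is.null(seed)) sc@seed else seed)
  n <- sc@nGenes; nc <- sc@nCells
  cls <- rep(names(sc@classFractions),
             times = round(sc@classFractions * n))
  cls <- c(cls, rep("nonlocalized", n - length(cls)))[seq_len(n)]
  genes <- sprintf("g%04d", seq_len(n))

  nIso <- sample(seq_along(sc@isoformCountProbs), n, replace = TRUE,
                 prob = sc@isoformCountProbs)
  nIso[cls == "isoDend" & nIso < 2L] <- 2L

  baseline <- stats::rlnorm(n, sc@baselineMeanLog, sc@baselineSdLog)
  ratio <- rep(1, n)
  ratio[cls == "deDend"] <- sc@deDendRatio
  nl <- cls == "nonlocalized"
  ratio[nl] <- stats::rlnorm(sum(nl), 0, sc@nonlocSdLog)

  lib <- stats::rlnorm(2 * nc, 0, sc@librarySpread)
  sampleInfo <- data.frame(
    sample_id = c(paste0("c", seq_len(nc), ".soma"),
                  paste0("c", seq_len(nc), ".dendrite")),
    cell_id = rep(paste0("c", seq_len(nc)), 2),
    compartment = rep(c("soma", "dendrite"), each = nc))
  lib[sampleInfo$compartment == "dendrite"] <-
    lib[sampleInfo$compartment == "dendrite"] * sc@dendriteScale

  preferred <- ifelse(cls == "isoDend",
                      ifelse(stats::runif(n) < sc@probDistal, "distal",
                             "proximal"), NA)
  dfSoma <- ifelse(cls == "isoDend",
                   ifelse(preferred == "distal", 0.5 - sc@deltaDF / 2,
                          0.5 + sc@deltaDF / 2), NA)
  dfDend <- ifelse(cls == "isoDend", dfSoma +
                     ifelse(preferred == "distal", sc@deltaDF,
                            -sc@deltaDF), NA)

  counts <- matrix(0L, nrow = sum(nIso), ncol = 2 * nc)
  featIds <- unlist(lapply(seq_len(n), function(g) {
    sprintf("%s:iso%d", genes[g], seq_len(nIso[g]))
  }))
  rownames(counts) <- featIds
  geneOfFeat <- rep(genes, nIso)
  size <- 1 / sc@dispersion

  rowAt <- match(featIds, featIds)  # identity; rows located via offsets
  offset <- c(0L, cumsum(nIso))
  truthRows <- vector("list", n)
  for (g in seq_len(n)) {
    K <- nIso[g]
    ## base isoform proportions: first two dominant when multi-isoform
    alpha <- if (K == 1L) 1 else c(5, 5, rep(0.8, K - 2L))
    props <- as.numeric(stats::rgamma(K, alpha))
    props <- props / sum(props)
    propS <- propD <- props
    if (cls[g] == "isoDend") {
      topShare <- props[1] + props[2]
      propS[1:2] <- topShare * c(1 - dfSoma[g], dfSoma[g])
      propD[1:2] <- topShare * c(1 - dfDend[g], dfDend[g])
    }
    drD <- if (cls[g] %in% c("deDend", "consDend")) sc@dropoutDendriteCons
           else sc@dropoutDendrite
    for (s in seq_len(2 * nc)) {
      isDend <- sampleInfo$compartment[s] == "dendrite"
      mu <- baseline[g] * lib[s] * (if (isDend) ratio[g] else 1)
      pr <- if (isDend) propD else propS
      k <- stats::rnbinom(K, mu = mu * pr, size = size)
      if (stats::runif(1) < (if (isDend) drD else sc@dropoutSoma))
        k <- rep(0L, K)
      counts[(offset[g] + 1L):offset[g + 1L], s] <- k
    }
    truthRows[[g]] <- data.frame(
      gene_id = genes[g], class = cls[g], n_isoforms = K,
      proximal_id = sprintf("%s:iso1", genes[g]),
      distal_id = sprintf("%s:iso2", genes[g]),
      true_df_soma = dfSoma[g], true_df_dendrite = dfDend[g],
      preferred = preferred[g])
  }
  truth <- do.call(rbind, truthRows)
  pcm <- pairedCountMatrix(counts, sampleInfo,
                           rowData = DataFrame(feature_id = featIds,
                                               gene_id = geneOfFeat,
                                               kind = "isoform_window"))
  list(counts = pcm, truth = truth)
}

## ---------------------------------------------------------------------------

#' Simulate gene annotations exercising the feature-construction rules
#'
#' Genes with 1-4 transcripts on alternating strands; alternative 3' ends
#' are planted with ALE (disjoint last-exon 3'UTRs) or tandem
#' (shared-start, nested 3'UTRs) geometry at the configured rate, and a
#' configured fraction of adjacent 3' ends lies closer than 500 nt so the
#' merge rule is exercised.
#'
#' @param sc a \code{SimScenario}.
#' @param seed optional override of \code{sc@seed}.
#' @return list: \code{models} (named list of \code{GeneModel}),
#'   \code{truth} (data.frame: gene_id, n_tx, cls, near_pair).
#' @export
simulateAnnotation <- function(sc, seed = NULL) {
  stopifnot(methods::is(sc, "SimScenario"))
  set.seed(if (is.null(seed)) sc@seed else seed)
  n <- sc@nGenes
  genes <- sprintf("g%04d", seq_len(n))
  nTx <- sample(seq_along(sc@isoformCountProbs), n, replace = TRUE,
                prob = sc@isoformCountProbs)
  models <- list(); truthRows <- vector("list", n)
  for (g in seq_len(n)) {
    strand <- if (g %% 2L == 0L) "-" else "+"
    anchor <- 50000L * g
    K <- nTx[g]
    isAle <- K >= 2L && stats::runif(1) < sc@aleFraction
    near <- K >= 2L && stats::runif(1) < sc@mergeNearRate
    ## distance between the first two 3' ends; < 500 exercises merging
    endDist <- function(isNear) if (isNear) sample(150:450, 1)
                                else sample(600:2000, 1)
    d1 <- endDist(near)
    utr <- list()
    if (isAle || K == 1L) {
      ## disjoint UTR blocks, one per transcript, 5'->3'; the block gap
      ## shrinks when the planted end distance is small
      lens <- integer(K); gaps <- integer(K)
      for (t in seq_len(K)) {
        d <- if (t == 2L) d1 else endDist(FALSE)
        lens[t] <- if (t == 1L) sample(300:900, 1)
                   else sample(50:max(50L, min(900L, d - 50L)), 1)
        gaps[t] <- if (t == 1L) 0L else d - lens[t]
      }
      pos <- anchor
      for (t in seq_len(K)) {
        pos <- pos + (if (strand == "+") gaps[t] else -gaps[t])
        r <- if (strand == "+") IRanges(pos, pos + lens[t] - 1L)
             else IRanges(pos - lens[t] + 1L, pos)
        utr[[paste0(genes[g], ".t", t)]] <- GRanges("chrSim", r, strand)
        pos <- pos + (if (strand == "+") lens[t] else -lens[t])
      }
    } else {
      ## tandem: shared UTR start, successive ends further 3'
      len0 <- sample(300:900, 1)
      e <- if (strand == "+") anchor + len0 else anchor - len0
      for (t in seq_len(K)) {
        r <- if (strand == "+") IRanges(anchor, e)
             else IRanges(e, anchor)
        utr[[paste0(genes[g], ".t", t)]] <- GRanges("chrSim", r, strand)
        d <- if (t == 1L) d1 else endDist(FALSE)
        e <- e + (if (strand == "+") d else -d)
      }
    }
    models[[genes[g]]] <- geneModel(genes[g], "chrSim", strand, utr)
    truthRows[[g]] <- data.frame(
      gene_id = genes[g], n_tx = K,
      cls = if (K >= 2L) (if (isAle) "ALE" else "tandem") else NA,
      near_pair = if (K >= 2L) near else NA)
  }
  list(models = models, truth = do.call(rbind, truthRows))
}

## ---------------------------------------------------------------------------

#' Generate a random G-quadruplex instance
#'
#' Four runs of 3 guanines joined by three random 1-7 nt loops.
#' @param loopMax maximal loop length (default 7).
#' @return character G4 instance.
#' @export
randomG4 <- function(loopMax = 7L) {
  loops <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "T"), sample(1:loopMax, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  paste0("GGG", loops[1], "GGG", loops[2], "GGG", loops[3], "GGG")
}

#' Simulate 3'UTR sequences with planted motifs
#'
#' Background sequences drawn from a fixed base composition; instances of
#' the configured motifs (a G-quadruplex pattern, a PWM consensus, or a
#' verbatim structure exemplar) are inserted at random positions into the
#' localized and background sets at the configured per-gene rates.
#'
#' @param nLocalized,nBackground set sizes.
#' @param meanLength,sdLength lognormal-ish sequence length (normal
#'   rounded, floored at 200).
#' @param baseComp named probabilities for A/C/G/T.
#' @param plants list of plant specs: each
#'   \code{list(name, instance, fgRate, bgRate)} where \code{instance} is a
#'   string or a zero-argument generator function.
#' @param seed integer seed.
#' @return list: \code{seqs} (named character, localized genes first),
#'   \code{truth} (data.frame: gene_id, localized, motif, start; one row
#'   per planted instance plus one NA-motif row per unplanted gene).
#' @export
simulateSequences <- function(nLocalized = 50L, nBackground = 50L,
                              meanLength = 800, sdLength = 200,
                              baseComp = c(A = 0.28, C = 0.22, G = 0.22,
                                           T = 0.28),
                              plants = list(), seed = 1L) {
  set.seed(seed)
  nTot <- nLocalized + nBackground
  ids <- c(sprintf("loc%03d", seq_len(nLocalized)),
           sprintf("bg%03d", seq_len(nBackground)))
  lens <- pmax(200L, round(stats::rnorm(nTot, meanLength, sdLength)))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(baseComp), L, replace = TRUE, prob = baseComp),
          collapse = "")
  }, character(1))
  names(seqs) <- ids
  localized <- c(rep(TRUE, nLocalized), rep(FALSE, nBackground))
  truthRows <- list()
  for (pl in plants) {
    rate <- ifelse(localized, pl$fgRate, pl$bgRate)
    doPlant <- stats::runif(nTot) < rate
    for (i in which(doPlant)) {
      ins <- if (is.function(pl$instance)) pl$instance() else pl$instance
      L <- nchar(seqs[i])
      if (nchar(ins) >= L) next
      pos <- sample.int(L - nchar(ins), 1)
      seqs[i] <- paste0(substr(seqs[i], 1, pos - 1), ins,
                        substr(seqs[i], pos + nchar(ins), L))
      truthRows[[length(truthRows) + 1L]] <-
        data.frame(gene_id = ids[i], localized = localized[i],
                   motif = pl$name, start = pos)
    }
  }
  planted <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(gene_id = character(0), localized = logical(0),
               motif = character(0), start = integer(0))
  none <- !ids %in% planted$gene_id
  truth <- rbind(planted,
                 data.frame(gene_id = ids[none], localized = localized[none],
                            motif = NA_character_, start = NA_integer_))
  list(seqs = seqs, truth = truth)
}
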