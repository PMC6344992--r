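library(GenomicRanges)

mkGene <- function(id = "g1", strand = "+", utrs) {
  geneModel(id, "chr1", strand,
            lapply(utrs, function(u) GRanges("chr1", u, strand)))
}

test_that("union 3'UTR is the interval union over transcripts", {
  g1 <- mkGene(utrs = list(t1 = IRanges(101, 600)))
  u1 <- buildUnionUtr(g1)
  expect_equal(start(u1), 101)
  expect_equal(end(u1), 600)
  expect_equal(unique(u1$kind), "union_utr")

  g2 <- mkGene(utrs = list(t1 = IRanges(101, 600), t2 = IRanges(401, 900)))
  u2 <- buildUnionUtr(g2)
  expect_equal(length(u2), 1L)
  expect_equal(c(start(u2), end(u2)), c(101, 900))

  g3 <- mkGene(utrs = list(t1 = IRanges(101, 600), t2 = IRanges(2001, 2500)))
  u3 <- buildUnionUtr(g3)
  expect_equal(length(u3), 2L)
  expect_equal(sum(width(u3)), 1000L)

  ## brute-force base-set oracle on random multi-transcript genes
  set.seed(11)
  for (rep in 1:20) {
    utrs <- lapply(1:sample(2:4, 1), function(i) {
      s <- sample(1:3000, 1); IRanges(s, s + sample(50:800, 1))
    })
    names(utrs) <- paste0("t", seq_along(utrs))
    g <- mkGene(utrs = utrs)
    u <- buildUnionUtr(g)
    baseSet <- sort(unique(unlist(lapply(utrs, function(r) {
      seq(start(r), end(r))
    }))))
    got <- sort(unlist(mapply(seq, start(u), end(u), SIMPLIFY = FALSE)))
    expect_equal(got, baseSet)
    expect_gte(sum(width(u)), max(vapply(utrs, width, integer(1))))
    expect_lte(sum(width(u)), sum(vapply(utrs, width, integer(1))))
  }
})

test_that("isoform windows merge close 3' ends and never overlap", {
  ## ends 1000 and 1300 (300 nt apart, < 500) merge into one feature
  g <- mkGene(utrs = list(t1 = IRanges(201, 1000), t2 = IRanges(201, 1300)))
  w <- buildIsoformWindows(g)
  expect_equal(length(unique(w$feature_id)), 1L)
  expect_equal(unique(w$member_end3s), "1000,1300")
  expect_equal(c(min(start(w)), max(end(w))), c(501, 1300))

  ## ends 1000 and 1800 (800 apart) give two non-overlapping 500-nt windows
  g2 <- mkGene(utrs = list(t1 = IRanges(201, 1000), t2 = IRanges(201, 1800)))
  w2 <- buildIsoformWindows(g2)
  expect_equal(length(unique(w2$feature_id)), 2L)
  f1 <- w2[w2$feature_id == unique(w2$feature_id)[1]]
  f2 <- w2[w2$feature_id == unique(w2$feature_id)[2]]
  expect_equal(c(start(f1), end(f1)), c(501, 1000))
  expect_equal(c(start(f2), end(f2)), c(1301, 1800))

  ## short UTR clips the window at the UTR start
  g3 <- mkGene(utrs = list(t1 = IRanges(101, 400)))
  w3 <- buildIsoformWindows(g3)
  expect_lte(sum(width(w3)), 500L)
  expect_equal(c(start(w3), end(w3)), c(101, 400))

  expect_error(buildIsoformWindows(g3, mergeDist = 0), "positive")
})

test_that("windows cross exon junctions in spliced coordinates", {
  ## 3'UTR split 601-700 + 801-1000: terminal 500 nt = 200 + 300 spliced
  g <- mkGene(utrs = list(t1 = c(IRanges(601, 700), IRanges(801, 1000))))
  w <- buildIsoformWindows(g, window = 500)
  expect_equal(sum(width(w)), 300L)      # whole UTR is only 300 nt
  w2 <- buildIsoformWindows(g, window = 250)
  expect_equal(sum(width(w2)), 250L)
  expect_equal(sort(start(w2)), c(651, 801))  # 50 nt from the 5' exon
})

test_that("isoform window properties hold on randomized annotations", {
  sc <- simScenario(nGenes = 60L, seed = 5L)
  ann <- simulateAnnotation(sc)
  for (gm in ann$models) {
    w <- buildIsoformWindows(gm)
    feats <- split(w, w$feature_id)
    ## pairwise non-overlap
    if (length(feats) > 1L) {
      cmb <- utils::combn(length(feats), 2)
      for (k in seq_len(ncol(cmb))) {
        expect_equal(length(findOverlaps(feats[[cmb[1, k]]],
                                         feats[[cmb[2, k]]])), 0L)
      }
    }
    ## reducing merge distance can only split features, never merge more
    w250 <- buildIsoformWindows(gm, mergeDist = 250)
    expect_gte(length(unique(w250$feature_id)),
               length(unique(w$feature_id)))
  }
})

test_that("feature construction is strand symmetric", {
  ## mirror a plus-strand gene around a fixed point onto the minus strand
  M <- 100000L
  utrsP <- list(t1 = IRanges(201, 1000), t2 = IRanges(201, 1800))
  utrsM <- lapply(utrsP, function(r) IRanges(M - end(r), M - start(r)))
  gp <- mkGene(strand = "+", utrs = utrsP)
  gm <- mkGene(strand = "-", utrs = utrsM)
  wp <- buildIsoformWindows(gp)
  wm <- buildIsoformWindows(gm)
  expect_equal(length(wp), length(wm))
  ## widths per 5'->3' feature order agree
  expect_equal(unname(vapply(split(width(wp), wp$feature_id), sum,
                             integer(1))),
               unname(vapply(split(width(wm), wm$feature_id), sum,
                             integer(1))))
  ## mirrored coordinates agree exactly
  expect_equal(sort(M - end(wm)), sort(start(wp)))
})

test_that("ALE/tandem classification follows adjacency of full-length UTRs", {
  p <- GRanges("chr1", IRanges(101, 600), "+")
  expect_equal(classifyPair(p, GRanges("chr1", IRanges(101, 900), "+")),
               "tandem")                      # overlapping
  expect_equal(classifyPair(p, GRanges("chr1", IRanges(601, 900), "+")),
               "tandem")                      # directly abutting
  expect_equal(classifyPair(p, GRanges("chr1", IRanges(2001, 2500), "+")),
               "ALE")                         # gap > 0
})

test_that("GTF and BED12 encodings yield the same gene model", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttest\tthree_prime_utr\t601\t700\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttest\tthree_prime_utr\t801\t1000\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttest\tthree_prime_utr\t1501\t1900\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t2";')), gtf)
  bed <- tempfile(fileext = ".bed")
  ## same gene: t1 exons 101-700 + 801-1000 with CDS 101-600;
  ## t2 single exon 1201-1900 with CDS 1201-1500
  writeLines(c(
    "chr1\t100\t1000\tg1|t1\t0\t+\t100\t600\t0\t2\t600,200\t0,700",
    "chr1\t1200\t1900\tg1|t2\t0\t+\t1200\t1500\t0\t1\t700\t0"), bed)
  mg <- loadGeneModels(gtf)
  mb <- loadGeneModels(bed)
  expect_equal(names(mg), names(mb))
  g1 <- mg$g1; b1 <- mb$g1
  expect_equal(sort(names(utr3(g1))), sort(names(utr3(b1))))
  for (tx in names(utr3(g1))) {
    expect_equal(ranges(utr3(g1)[[tx]]), ranges(utr3(b1)[[tx]]),
                 ignore_attr = TRUE)
  }
  expect_equal(end3(g1)[sort(names(end3(g1)))],
               end3(b1)[sort(names(end3(b1)))])
  ## single-transcript / shared-gene grouping sanity
  expect_equal(length(utr3(g1)), 2L)
})
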