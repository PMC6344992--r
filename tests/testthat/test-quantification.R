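library(GenomicRanges)

simpleFeatures <- function() {
  c(GRanges("chr1", IRanges(101, 600), "+",
            feature_id = "gA:iso1", gene_id = "gA", kind = "isoform_window"),
    GRanges("chr1", IRanges(701, 1200), "+",
            feature_id = "gA:iso2", gene_id = "gA", kind = "isoform_window"),
    GRanges("chr1", IRanges(5001, 5500), "-",
            feature_id = "gB:iso1", gene_id = "gB", kind = "isoform_window"))
}

si2 <- data.frame(sample_id = c("c1.soma", "c1.dendrite"),
                  cell_id = "c1",
                  compartment = c("soma", "dendrite"))

test_that("read counting is strand-specific with larger-overlap/3' ties", {
  feats <- simpleFeatures()
  reads <- GRangesList(
    c1.soma = c(GRanges("chr1", IRanges(150, 200), "+"),   # inside gA:iso1
                GRanges("chr1", IRanges(150, 200), "-"),   # wrong strand
                GRanges("chr1", IRanges(580, 720), "+"),   # 21 vs 20 -> iso1
                GRanges("chr1", IRanges(581, 720), "+"),   # 20 vs 20 -> iso2
                GRanges("chr1", IRanges(5100, 5200), "-")),
    c1.dendrite = GRanges("chr1", IRanges(2000, 2100), "+")) # no feature
  pcm <- countReads(feats, reads, si2)
  k <- SummarizedExperiment::assay(pcm, "counts")
  expect_equal(k["gA:iso1", "c1.soma"], 2L)
  expect_equal(k["gA:iso2", "c1.soma"], 1L)
  expect_equal(k["gB:iso1", "c1.soma"], 1L)
  expect_equal(sum(k[, "c1.dendrite"]), 0L)
  ## never more assigned reads than input reads
  expect_lte(sum(k), sum(lengths(reads)))
})

test_that("counting matches the per-base brute-force oracle", {
  feats <- simpleFeatures()
  set.seed(21)
  starts <- sample(1:6000, 100, replace = TRUE)
  reads <- GRanges("chr1", IRanges(starts, starts + sample(30:150, 100,
                                                           replace = TRUE)),
                   sample(c("+", "-"), 100, replace = TRUE))
  got <- countReads(feats, GRangesList(c1.soma = reads,
                                       c1.dendrite = GRanges()), si2)
  want <- oracleCountReads(feats, reads)
  k <- SummarizedExperiment::assay(got, "counts")[names(want), "c1.soma"]
  expect_equal(unname(k), unname(as.integer(want)))
})

test_that("median-of-ratios size factors match closed forms and DESeq2", {
  k <- matrix(c(10, 20, 5, 10, 20, 5), nrow = 3)
  expect_equal(medianOfRatios(k), c(1, 1))

  ## one sample exactly twice the other: factors in ratio 2:1
  k2 <- matrix(c(20, 40, 10, 20), nrow = 2)
  sf <- medianOfRatios(k2)
  expect_equal(sf[1] / sf[2], 2)
  expect_equal(prod(sf), 1, tolerance = 1e-12)  # geometric centering

  set.seed(31)
  k3 <- matrix(rnbinom(120, mu = 50, size = 3), nrow = 20, ncol = 6)
  k3[1, ] <- k3[1, ] + 1L   # ensure an all-positive feature
  expect_equal(medianOfRatios(k3),
               unname(DESeq2::estimateSizeFactorsForMatrix(k3)),
               tolerance = 1e-10)

  expect_warning(medianOfRatios(matrix(c(0, 5, 5, 0), 2)), "falling back")
})

test_that("expression filter applies the detected-in-enough-samples rule", {
  nS <- 32L
  si <- data.frame(sample_id = paste0("c", rep(1:16, 2), ".",
                                      rep(c("soma", "dendrite"), each = 16)),
                   cell_id = paste0("c", rep(1:16, 2)),
                   compartment = rep(c("soma", "dendrite"), each = 16))
  k <- matrix(0L, nrow = 3, ncol = nS,
              dimnames = list(c("g16", "g15", "g32"), si$sample_id))
  k["g16", 1:16] <- 1L
  k["g15", 1:15] <- 1L
  k["g32", ] <- 7L
  pcm <- pairedCountMatrix(k, si)
  kept <- filterExpressed(pcm)
  expect_true(all(c("g16", "g32") %in% kept))
  expect_false("g15" %in% kept)

  ## brute-force row scan on a random matrix
  set.seed(41)
  kr <- matrix(rbinom(50 * nS, 1, 0.4), nrow = 50,
               dimnames = list(sprintf("g%02d", 1:50), si$sample_id))
  pr <- pairedCountMatrix(kr, si)
  want <- rownames(kr)[apply(kr, 1, function(x) sum(x >= 1) >= 16)]
  expect_setequal(filterExpressed(pr), want)
})

makePaired <- function(k, nCells = 16L) {
  si <- data.frame(sample_id = c(paste0("c", 1:nCells, ".soma"),
                                 paste0("c", 1:nCells, ".dendrite")),
                   cell_id = rep(paste0("c", 1:nCells), 2),
                   compartment = rep(c("soma", "dendrite"), each = nCells))
  pairedCountMatrix(k, si)
}

test_that("paired DE calls planted genes and nothing on flat profiles", {
  set.seed(51)
  nCells <- 16L
  nGenes <- 100L
  soma <- matrix(rnbinom(nGenes * nCells, mu = 50, size = 5), nrow = nGenes)
  dend <- matrix(rnbinom(nGenes * nCells, mu = 50, size = 5), nrow = nGenes)
  dend[1, ] <- rnbinom(nCells, mu = 500, size = 5)   # planted 10x gene
  k <- cbind(soma, dend)
  rownames(k) <- sprintf("g%03d", 1:nGenes)
  pcm <- makePaired(k)
  de <- callDE(pcm)
  expect_equal(de$set[de$gene_id == "g001"], "deDend")
  expect_lt(de$p_value[de$gene_id == "g001"], 1e-4)

  ## identical compartments: p = 1, nothing called
  k2 <- cbind(soma, soma)
  rownames(k2) <- rownames(k)
  de2 <- callDE(makePaired(k2))
  expect_true(all(de2$p_value == 1))
  expect_true(all(de2$set == "ns"))

  ## a gene with too few pairs is untestable
  de3 <- callDE(pcm, minPairs = 40L)
  expect_true(all(!de3$testable))
})

test_that("consDend detection threshold is ceiling(minFraction * n)", {
  k <- matrix(0L, nrow = 3, ncol = 32,
              dimnames = list(c("d15", "d14", "d16"), NULL))
  pcm <- makePaired(k)
  kd <- which(compartment(pcm) == "dendrite")
  k[,] <- 0L
  k["d15", kd[1:15]] <- 1L
  k["d14", kd[1:14]] <- 1L
  k["d16", kd] <- 1L
  pcm <- makePaired(k)
  cons <- callConsDend(pcm)
  expect_setequal(cons, c("d15", "d16"))
  ## degenerate parameter: every gene qualifies at minFraction = 0
  expect_setequal(callConsDend(pcm, minFraction = 0),
                  c("d14", "d15", "d16"))
})

test_that("DE is equivariant to per-sample scaling after normalization", {
  set.seed(61)
  k <- matrix(rnbinom(50 * 32, mu = 80, size = 5) + 1L, nrow = 50)
  rownames(k) <- sprintf("g%02d", 1:50)
  pcm1 <- makePaired(k)
  scale <- sample(1:4, 32, replace = TRUE)
  pcm2 <- makePaired(sweep(k, 2, scale, "*"))
  de1 <- callDE(pcm1)
  de2 <- callDE(pcm2)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-10)
  expect_equal(de1$set, de2$set)
})
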