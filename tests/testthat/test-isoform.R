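test_that("top-two isoform selection sums per-sample fractions", {
  ## 3 isoforms; sample C has < 10 reads and is skipped:
  ## summed fractions (1.0, 0.8, 0.2) pick isoforms 1 and 2
  counts <- rbind(i1 = c(16, 4, 3),
                  i2 = c(2, 14, 3),
                  i3 = c(2, 2, 3))
  colnames(counts) <- c("A", "B", "C")
  key <- c(i1 = 1, i2 = 2, i3 = 3)
  top <- selectTopTwo(counts, key)
  expect_equal(unname(top), c("i1", "i2"))
  expect_equal(names(top), c("proximal", "distal"))

  ## two-isoform gene: those two, ordered by position
  top2 <- selectTopTwo(counts[1:2, ], key)
  expect_equal(unname(top2), c("i1", "i2"))

  ## equal summed fractions: larger raw total wins, then more distal
  cEq <- rbind(i1 = c(10, 0), i2 = c(0, 10), i3 = c(10, 10))
  colnames(cEq) <- c("A", "B")
  topEq <- selectTopTwo(cEq, key)
  expect_equal(unname(topEq["distal"]), "i3")   # raw 20 beats raw 10

  ## no sample reaches the minimum: untestable
  expect_null(selectTopTwo(rbind(i1 = c(2, 1), i2 = c(1, 2)), key[1:2]))
})

test_that("distal fraction respects the combined-read minimum", {
  expect_equal(distalFraction(0, 12), 0)
  expect_equal(distalFraction(30, 10), 0.75)
  expect_true(is.na(distalFraction(4, 5)))       # 9 < 10 combined
  ## scale invariance
  expect_equal(distalFraction(30, 10), distalFraction(300, 100))
})

test_that("isoform localization test applies the consistency criteria", {
  r <- testIsoformLocalization(c(0.2, 0.3, 0.1, 0.25, 0.15))
  expect_equal(r$p_wilcoxon, 0.0625)
  expect_true(r$isoDend)
  expect_equal(r$preferred, "distal")

  r2 <- testIsoformLocalization(c(0.2, -0.2, 0.2, -0.2, 0.2))
  expect_false(r2$isoDend)
  expect_gt(r2$p_wilcoxon, 0.1)

  ## four valid pairs: untestable regardless of values
  r3 <- testIsoformLocalization(c(0.5, 0.5, 0.5, 0.5))
  expect_false(r3$tested)
  expect_false(r3$isoDend)

  ## all differences zero: p = 1, not called
  r4 <- testIsoformLocalization(rep(0, 8))
  expect_equal(r4$p_wilcoxon, 1)
  expect_false(r4$isoDend)

  ## consistent negative shift prefers the proximal isoform
  r5 <- testIsoformLocalization(-c(0.2, 0.3, 0.1, 0.25, 0.15, 0.3))
  expect_true(r5$isoDend)
  expect_equal(r5$preferred, "proximal")
})

test_that("wilcoxon caller equals sign-flip enumeration on dDF vectors", {
  set.seed(131)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    ddf <- round(runif(n, -0.5, 0.5), 2)
    got <- testIsoformLocalization(ddf, minPairs = 2L)
    expect_equal(got$p_wilcoxon, oracleSignedRankP(ddf), tolerance = 1e-12)
  }
})

test_that("isoform records pipeline recovers a hand-built gene", {
  nCells <- 8L
  si <- data.frame(sample_id = c(paste0("c", 1:nCells, ".soma"),
                                 paste0("c", 1:nCells, ".dendrite")),
                   cell_id = rep(paste0("c", 1:nCells), 2),
                   compartment = rep(c("soma", "dendrite"), each = nCells))
  ## soma DF 0.25 (15/60), dendrite DF 0.75 in every cell
  k <- rbind("gX:iso1" = c(rep(45L, nCells), rep(15L, nCells)),
             "gX:iso2" = c(rep(15L, nCells), rep(45L, nCells)),
             "gY:iso1" = rep(30L, 2 * nCells),
             "gY:iso2" = rep(30L, 2 * nCells))
  pcm <- pairedCountMatrix(k, si,
    rowData = S4Vectors::DataFrame(
      feature_id = rownames(k),
      gene_id = rep(c("gX", "gY"), each = 2),
      kind = "isoform_window"))
  ips <- isoformRecords(pcm)
  r <- as.data.frame(records(ips))
  rx <- r[r$gene_id == "gX", ]
  expect_true(rx$isoDend)
  expect_equal(rx$preferred, "distal")
  expect_equal(rx$median_ddf, 0.5)
  expect_equal(rx$n_valid_pairs, nCells)
  ry <- r[r$gene_id == "gY", ]
  expect_false(ry$isoDend)
  expect_equal(ry$p_wilcoxon, 1)
  ## DF matrix carries per-sample values
  expect_equal(unname(distalFractions(ips)["gX", "c1.soma"]), 0.25)
})

test_that("preference summary reproduces the cross-product odds ratio", {
  ## spec'd 2x2: [[191,107],[1410,1930]] -> OR 191*1930/(107*1410) = 2.44
  enr <- fisherEnrichment(191, 298, 1410, 3340)
  expect_equal(enr$odds_ratio, 191 * 1930 / (107 * 1410))
  expect_equal(round(enr$odds_ratio, 1), 2.4)
  ## identity table
  expect_equal(fisherEnrichment(10, 110, 10, 110)$odds_ratio, 1)
  ## zero cell convention
  expect_equal(fisherEnrichment(5, 5, 3, 10)$odds_ratio, Inf)
})

test_that("DF variance comparison is deterministic and noise-inflating", {
  set.seed(141)
  sc <- simScenario(nGenes = 120L, seed = 13L)
  sim <- simulateCounts(sc)
  ips <- isoformRecords(sim$counts)
  a <- dfVarianceComparison(ips, reps = 50L, seed = 7L)
  b <- dfVarianceComparison(ips, reps = 50L, seed = 7L)
  expect_identical(a$downsampled_reps, b$downsampled_reps)
  expect_identical(a$per_gene, b$per_gene)
  expect_true(a$downsampled_fraction_isoDend >= 0 &&
                a$downsampled_fraction_isoDend <= 1)
  ## soma DFs exactly constant across samples: soma not more variable
  r <- as.data.frame(records(ips))
  flat <- r$df_var_soma == 0 & r$df_var_dendrite > 0
  if (any(flat, na.rm = TRUE))
    expect_true(all(!a$per_gene$soma_more_variable[which(flat)]))
})

test_that("downsampled soma DF variance inflates over the raw variance", {
  ## high-count soma DFs around 0.5: raw variance tiny, downsampled to 10
  ## reads the binomial noise dominates
  set.seed(151)
  nCells <- 12L
  si <- data.frame(sample_id = c(paste0("c", 1:nCells, ".soma"),
                                 paste0("c", 1:nCells, ".dendrite")),
                   cell_id = rep(paste0("c", 1:nCells), 2),
                   compartment = rep(c("soma", "dendrite"), each = nCells))
  prox <- c(rpois(nCells, 500), rpois(nCells, 500))
  dist <- c(rpois(nCells, 500), round(rpois(nCells, 500) * 2.5))
  k <- rbind("gZ:iso1" = as.integer(prox), "gZ:iso2" = as.integer(dist))
  pcm <- pairedCountMatrix(k, si,
    rowData = S4Vectors::DataFrame(feature_id = rownames(k),
                                   gene_id = "gZ",
                                   kind = "isoform_window"))
  ips <- isoformRecords(pcm, minPairs = 2L)
  cmp <- dfVarianceComparison(ips, reps = 200L, seed = 8L)
  r <- as.data.frame(records(ips))
  ## raw soma variance is near zero; the downsampled comparison flips the
  ## gene to soma-more-variable in most replicates
  expect_lt(r$df_var_soma, 0.005)
  expect_gt(cmp$downsampled_fraction_isoDend, 0.5)
})

test_that("paired length comparison matches the closed-form t statistic", {
  mkIps <- function(rec) {
    methods::new("IsoformPairSet", records = S4Vectors::DataFrame(rec),
                 df = matrix(numeric(0), 0, 0),
                 ddf = matrix(numeric(0), 0, 0),
                 sampleInfo = S4Vectors::DataFrame())
  }
  rec <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    proximal_id = sprintf("g%d:iso1", 1:5),
    distal_id = sprintf("g%d:iso2", 1:5),
    cls = "ALE", n_valid_pairs = 8L, median_ddf = 0.3, mean_ddf = 0.3,
    p_wilcoxon = 0.05, tested = TRUE, isoDend = TRUE, preferred = "distal",
    df_var_soma = 0.1, df_var_dendrite = 0.05)
  diffs <- c(100, 120, 80, 110, 90)
  lens <- c(stats::setNames(1000 + diffs, sprintf("g%d:iso2", 1:5)),
            stats::setNames(rep(1000, 5), sprintf("g%d:iso1", 1:5)))
  out <- lengthComparison(mkIps(rec), lens)
  ale <- out[out$cls == "ALE", ]
  m <- mean(diffs); s <- sd(diffs)
  expect_equal(ale$t, m / (s / sqrt(5)), tolerance = 1e-12)
  expect_equal(ale$p_value,
               2 * pt(-abs(m / (s / sqrt(5))), df = 4), tolerance = 1e-12)
  ## all pairs equal length: t = 0, p = 1
  lens0 <- stats::setNames(rep(1000, 10),
                           c(sprintf("g%d:iso1", 1:5),
                             sprintf("g%d:iso2", 1:5)))
  out0 <- lengthComparison(mkIps(rec), lens0)
  expect_equal(out0$t[out0$cls == "ALE"], 0)
  expect_equal(out0$p_value[out0$cls == "ALE"], 1)
  ## a single pair is untestable
  out1 <- lengthComparison(mkIps(rec[1, ]), lens)
  expect_false(out1$testable[out1$cls == "ALE"])
})
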