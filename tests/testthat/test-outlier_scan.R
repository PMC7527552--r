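neutralIsland <- function() cached("neutralIsland", function() {
  d <- 4; N <- 3000; m <- 0.0015
  mig <- matrix(m / (d - 1), d, d); diag(mig) <- 0
  dem <- Demography(data.frame(label = sprintf("P%d", 1:4), size = N),
                    migration = mig)
  simulateGenotypes(dem, simConfig(
    nLoci = 2500, samplesPerDeme = c(P1 = 8, P2 = 8, P3 = 8, P4 = 8),
    seed = 404))
})

# plant a strongly diverged locus by pushing one deme's genotypes apart
plantOutlier <- function(snp, site = 1L) {
  gt <- genotypes(snp)
  pm <- popMap(snp)
  gt[site, pm == "P1"] <- 2L
  gt[site, pm != "P1"] <- 0L
  SummarizedExperiment::assay(snp, "GT") <- gt
  snp
}

test_that("FLK behaves like chi-square on neutral island data", {
  snp <- neutralIsland()
  f <- freqMatrix(snp)
  res <- flkTest(f)
  # mean of the statistic ~ npops - 1 under neutrality
  expect_equal(mean(res$T_FLK, na.rm = TRUE), 3, tolerance = 0.35)
  # raw type-I error at nominal 5% within generous binomial bounds
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.12)
  expect_gt(rate, 0.005)
  expect_error(flkTest(freqMatrix(snp, c("P1", "P2"))), ">= 3 populations")
})

test_that("FLK is invariant to population order and allele relabeling", {
  snp <- neutralIsland()
  f1 <- freqMatrix(snp, c("P1", "P2", "P3", "P4"))
  f2 <- freqMatrix(snp, c("P3", "P1", "P4", "P2"))
  r1 <- flkTest(f1); r2 <- flkTest(f2)
  expect_equal(r1$T_FLK, r2$T_FLK, tolerance = 1e-8)
  flip <- snp
  SummarizedExperiment::assay(flip, "GT") <- 2L - genotypes(snp)
  r3 <- flkTest(freqMatrix(flip))
  expect_equal(r1$T_FLK, r3$T_FLK, tolerance = 1e-8)
})

test_that("a planted divergent locus is the top FLK hit and beats the Fdist envelope", {
  snp <- plantOutlier(neutralIsland())
  f <- freqMatrix(snp)
  res <- flkTest(f)
  key <- paste(res$stack_id, res$pos)
  target <- paste(stackID(snp)[1L], rowData(snp)$pos[1L])
  expect_equal(key[which.min(res$p)], target)
  fd <- suppressWarnings(fdistTest(snp, nSimLoci = 4000, seed = 2))
  fdKey <- paste(fd$stack_id, fd$pos)
  # the planted locus has the top FST, sits at the empirical-p floor of
  # its heterozygosity bin, and is flagged by the envelope
  expect_equal(fd$fst[fdKey == target], max(fd$fst))
  expect_lte(fd$p[fdKey == target], 0.01)
  expect_true(fd$outlier[fdKey == target])
})

test_that("Fdist p-values are calibrated (conservative) on the island model's own data", {
  snp <- neutralIsland()
  fd <- cached("fdNeutral", function()
    suppressWarnings(fdistTest(snp, nSimLoci = 6000, seed = 3)))
  # single-SNP FST takes few discrete values, so empirical p-values carry
  # atoms and the envelope is conservative; type-I control must still hold
  # and the tail must not be degenerate
  for (a in c(0.05, 0.1)) {
    rate <- mean(fd$p <= a)
    expect_lte(rate, a + 2 * sqrt(a * (1 - a) / nrow(fd)) + 0.01)
    expect_gte(rate, a / 8)
  }
  # a locus matching the null's central FST is unremarkable
  medSim <- median(fd$fst[fd$p > 0.2 & fd$p < 0.8])
  expect_true(is.finite(medSim))
  # 99% envelope: at most ~1% of neutral loci flagged
  expect_lt(mean(fd$outlier), 0.03)
})

test_that("consensus intersects per-test outlier sets and is monotone", {
  tA <- data.frame(stack_id = c("L1", "L2", "L3"), pos = 1L,
                   outlier = c(TRUE, TRUE, FALSE))
  tB <- data.frame(stack_id = c("L1", "L2", "L3"), pos = 1L,
                   outlier = c(TRUE, FALSE, FALSE))
  cons <- consensusOutliers(list(A = tA, B = tB))
  expect_equal(cons$consensus, c(TRUE, FALSE, FALSE))
  consA <- consensusOutliers(list(A = tA))
  expect_true(all(cons$consensus <= consA$consensus))
  tC <- data.frame(stack_id = "LX", pos = 1L, outlier = TRUE)
  expect_error(consensusOutliers(list(tA, tC)), "misaligned")
})

test_that("planted outliers are recovered by the consensus with no false positives", {
  snp <- neutralIsland()
  gt <- genotypes(snp)
  pm <- popMap(snp)
  for (site in 1:3) {  # three planted strongly divergent loci
    gt[site, pm %in% c("P1", "P2")] <- 2L
    gt[site, !(pm %in% c("P1", "P2"))] <- 0L
  }
  SummarizedExperiment::assay(snp, "GT") <- gt
  f <- freqMatrix(snp)
  flk <- flkTest(f)
  fd <- fdistTest(snp, nSimLoci = 6000, seed = 5)
  cons <- consensusOutliers(list(flk = flk, fdist = fd))
  planted <- paste(stackID(snp)[1:3], rowData(snp)$pos[1:3])
  key <- paste(cons$stack_id, cons$pos)
  expect_gte(sum(cons$consensus[key %in% planted]), 2L)
  expect_equal(sum(cons$consensus[!key %in% planted]), 0L)
})

test_that("grouped selection scans run the two-stage published design", {
  snp <- neutralIsland()
  scheme <- list(
    species = list(SpA = c("P1", "P2"), SpB = c("P3", "P4")),
    withinA = list(P1 = "P1", P2 = "P2", P3 = "P3"))
  sc <- selectionScan(snp, scheme, nSimLoci = 2000, seed = 6)
  expect_named(sc, c("species", "withinA"))
  # two-group contrast: only the Fdist test applies
  expect_true("outlier_fdist" %in% names(sc$species))
  expect_false("outlier_flk" %in% names(sc$species))
  expect_true(all(c("outlier_flk", "outlier_fdist") %in% names(sc$withinA)))
})
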