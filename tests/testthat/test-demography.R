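smallM9Data <- function() cached("m9data", function() {
  m9 <- pepperModels("M9", fixed = list(Nw = 5000, Nanc = 5000))
  truth <- c(T = 1500, fold = 50)
  dem <- m9$build(truth, m9$fixed)
  snp <- simulateGenotypes(dem, simConfig(
    nLoci = 5000, samplesPerDeme = c(wild = 8, cult = 8), seed = 33))
  list(model = m9, truth = truth,
       obs = foldedSFS(snp, c("wild", "cult"), projections = c(16, 16)))
})

test_that("piecewise expected SFS: constant size and one-interval invariance", {
  n <- 10
  a <- expectedFoldedSFSPiecewise(0, 5000, n, nSims = 30000, seed = 1)
  i <- 1:5
  cf <- 1 / i + 1 / (n - i); cf[5] <- 1 / 5
  cf <- cf / sum(cf)
  expect_equal(as.vector(a@counts[2:6]), cf, tolerance = 0.05)
  expect_error(expectedFoldedSFSPiecewise(c(0, 100, 50), c(1, 2, 3) * 1e3, 10),
               "increasing")
  expect_error(expectedFoldedSFSPiecewise(0, 1e3, 3), "n >= 4")
})

test_that("an ancient expansion produces a singleton excess", {
  # 10x expansion 10,000 generations ago (recent size 20,000, ancestral
  # 2,000): star-like genealogies inflate the singleton class relative to
  # any constant-size history
  grow <- expectedFoldedSFSPiecewise(c(0, 10000), c(20000, 2000), 10,
                                     nSims = 30000, seed = 2)
  const <- expectedFoldedSFSPiecewise(0, 20000, 10, nSims = 30000, seed = 3)
  expect_gt(grow@counts[2L], const@counts[2L])
})

test_that("coalescent scaling identity: (c*N, c*t) leaves the SFS unchanged", {
  m9 <- pepperModels("M9")
  par <- c(T = 1360, fold = 200)
  base <- m9$build(par, m9$fixed)
  scaled <- pepperModels("M9", fixed = list(Nw = 1e5, Nanc = 1e5))$build(
    c(T = 13600, fold = 200), list(Nw = 1e5, Nanc = 1e5,
                                   pops = c("wild", "cult")))
  s1 <- expectedSFSMC(base, c(wild = 10, cult = 10), nSims = 5000, seed = 11,
                      haploids = TRUE)
  s2 <- expectedSFSMC(scaled, c(wild = 10, cult = 10), nSims = 5000, seed = 11,
                      haploids = TRUE)
  # identical RNG stream + exact time rescaling => identical probabilities
  expect_equal(s1@counts, s2@counts, tolerance = 1e-12)
})

test_that("multinomial composite likelihood peaks at the observed proportions", {
  counts <- c(50, 30, 12, 8)
  pHat <- counts / sum(counts)
  lnLhat <- zanpop:::.sfsLogLik(counts, pHat, 1e-12)
  set.seed(4)
  for (r in 1:25) {
    p <- runif(4); p <- p / sum(p)
    expect_lte(zanpop:::.sfsLogLik(counts, p, 1e-12), lnLhat + 1e-9)
  }
})

test_that("model fits expose consistent AIC and an extra free parameter costs exactly 2", {
  d <- smallM9Data()
  cfg <- fitConfig(nSims = 3000, starts = 2, maxCycles = 12, seed = 8,
                   refineSims = 6000, refineCycles = 3)
  fit <- fitModel(d$obs, d$model, cfg)
  expect_equal(fit@AIC, 2 * fit@k - 2 * fit@logLik, tolerance = 1e-9)
  # determinism: identical call, identical result
  fit2 <- fitModel(d$obs, d$model, cfg)
  expect_identical(fit@par, fit2@par)
  expect_identical(fit@logLik, fit2@logLik)
  # identical models evaluated at the same (pinned) parameter point:
  # identical lnL; a free-but-unused extra parameter costs AIC exactly 2
  pin <- function(m, extra = FALSE) {
    v <- c(T = 1500, fold = 50)
    m$lower <- v; m$upper <- v * (1 + 1e-9)
    if (extra) {
      m$paramNames <- c(m$paramNames, "unused")
      m$lower <- c(m$lower, unused = 1)
      m$upper <- c(m$upper, unused = 1 + 1e-9)
      m$scale <- c(m$scale, unused = "log")
      m$k <- 3L
    }
    m
  }
  cfg0 <- fitConfig(nSims = 3000, starts = 1, maxCycles = 1, seed = 8,
                    refineSims = 0, refineCycles = 0)
  fitA <- fitModel(d$obs, pin(d$model), cfg0)
  fitB <- fitModel(d$obs, pin(d$model, extra = TRUE), cfg0)
  expect_equal(fitB@logLik, fitA@logLik, tolerance = 1e-3)
  expect_equal(fitB@AIC - fitA@AIC, 2, tolerance = 1e-2)
  expect_equal(fitB@k - fitA@k, 1L)
})

test_that("model comparison: Akaike weights follow the closed form", {
  d <- smallM9Data()
  mkFit <- function(id, lnL, k) new("ModelFit", modelID = id,
    par = c(x = 1), logLik = lnL, k = as.integer(k),
    AIC = 2 * k - 2 * lnL, nSites = 100, trace = data.frame(),
    details = list(fingerprint = c(1, 2, 3)))
  f1 <- mkFit("a", -100, 2); f2 <- mkFit("b", -100, 2)
  cmp <- compareModels(list(f1, f2))
  expect_equal(cmp$weight, c(0.5, 0.5))
  f3 <- mkFit("c", -101, 2)  # dAIC = 2
  cmp2 <- compareModels(list(f1, f3))
  expect_equal(cmp2$dAIC, c(0, 2))
  expect_equal(cmp2$weight, c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-9)
  expect_equal(round(cmp2$weight, 3), c(0.731, 0.269))
  fOther <- mkFit("d", -50, 2)
  fOther@details$fingerprint <- c(9, 9, 9)
  expect_error(compareModels(list(f1, fOther)), "different observed SFS")
  expect_error(compareModels(list(f1)), "at least 2")
})

test_that("the generating model outranks a no-size-change model on its own data", {
  d <- smallM9Data()
  cfg <- fitConfig(nSims = 4000, starts = 3, maxCycles = 15, seed = 12,
                   refineSims = 10000, refineCycles = 4)
  fit9 <- fitModel(d$obs, d$model, cfg)
  mIso <- pepperModels("M1_iso", fixed = list(N1 = 5000, N2 = 5000,
                                              Nanc = 5000,
                                              pops = c("wild", "cult")))
  fitIso <- fitModel(d$obs, mIso, cfg)
  cmp <- compareModels(list(fit9, fitIso))
  expect_equal(cmp$model[1L], "M9")
  expect_gt(cmp$weight[1L], 0.9)
})

test_that("rescaling helpers convert generations to calendar years", {
  expect_equal(generationsToYears(1360, g = 4), 5440)
  expect_equal(yearsToGenerations(5440, g = 4), 1360)
})

test_that("stairway errors on degenerate input and recovers a flat history", {
  dem <- Demography(data.frame(label = "pop", size = 1e4))
  snp <- cached("stairConst", function()
    simulateGenotypes(dem, simConfig(nLoci = 6000, samplesPerDeme = c(pop = 10),
                                     seed = 55)))
  s <- foldedSFS(snp, "pop", projections = 20)
  bad <- s
  cnt <- bad@counts * 0; cnt[2L] <- 100
  bad@counts <- cnt
  expect_error(fitStairway(bad, config = stairwayConfig(totalSites = 1e6)),
               "degenerate")
  expect_error(fitStairway(s, config = stairwayConfig()), "totalSites")
  st <- fitStairway(s, config = stairwayConfig(
    totalSites = simInfo(snp)$impliedTotalSites))
  expect_lt(max(st@Ne) / min(st@Ne), 2)
  expect_equal(median(st@Ne), 1e4, tolerance = 0.35)
})
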