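# Drift-diffusion simulation oracle: leaf "frequencies" evolve by
# independent Gaussian increments with variance equal to the edge length
# (the diffusion limit in which graph f-statistics are defined); admixture
# mixes parental values linearly.  Independent of the path-algebra code.
simulateGraphFreqs <- function(g, nLoci, seed) {
  set.seed(seed)
  ed <- g@edges
  ord <- zanpop:::.topoSort(ed)
  val <- list()
  val[[ord[1L]]] <- runif(nLoci, 0.3, 0.7)
  for (v in ord[-1L]) {
    inc <- which(ed$to == v)
    if (length(inc) == 1L) {
      base <- val[[ed$from[inc]]]
      val[[v]] <- base + rnorm(nLoci, 0, sqrt(ed$length[inc]))
    } else {
      w <- ed$weight[inc]
      val[[v]] <- w[1L] * val[[ed$from[inc[1L]]]] +
        w[2L] * val[[ed$from[inc[2L]]]]
    }
  }
  do.call(rbind, val[g@leaves])
}

fourLeafTree <- function() {
  ed <- rbind(
    data.frame(from = "root", to = "O", type = "drift", length = 0.05, weight = NA),
    data.frame(from = "root", to = "x1", type = "drift", length = 0.005, weight = NA),
    data.frame(from = "x1", to = "C", type = "drift", length = 0.03, weight = NA),
    data.frame(from = "x1", to = "x2", type = "drift", length = 0.01, weight = NA),
    data.frame(from = "x2", to = "A", type = "drift", length = 0.02, weight = NA),
    data.frame(from = "x2", to = "B", type = "drift", length = 0.025, weight = NA))
  admixtureGraph(ed)
}

test_that("f-statistic enumeration counts match the combinatorial formula", {
  expect_equal(enumerateFStats(2)$count, 1L)
  en4 <- enumerateFStats(4)
  expect_equal(en4$count, 21L)
  expect_equal(en4$count, choose(4, 2) + 4 * choose(3, 2) + 3 * choose(4, 4))
  expect_equal(sum(en4$table$kind == "f2"), 6L)
  expect_equal(sum(en4$table$kind == "f3"), 12L)
  expect_equal(sum(en4$table$kind == "f4"), 3L)
  expect_false(anyDuplicated(apply(en4$table, 1L, paste, collapse = "|")) > 0)
  expect_equal(enumerateFStats(19)$count, 14706L)
  expect_error(enumerateFStats(1), "at least 2")
})

test_that("graph predictions: tree f4 = 0 across the split; f2 adds drift", {
  g <- fourLeafTree()
  pr <- predictFStats(g)
  # AB|CO quadruple: f4(A,B;C,O) has no shared internal branch
  f4s <- pr[pr$kind == "f4", ]
  z <- f4s[apply(f4s[, 2:5], 1L, function(r) setequal(r[1:2], c("O", "C")) ||
                   setequal(r[3:4], c("O", "C"))), ]
  expect_true(any(abs(z$predicted) < 1e-12))
  # two leaves joined at the root: f2 = d1 + d2
  g2 <- admixtureGraph(rbind(
    data.frame(from = "root", to = "L1", type = "drift", length = 0.04, weight = NA),
    data.frame(from = "root", to = "L2", type = "drift", length = 0.01, weight = NA)))
  expect_equal(predictFStats(g2)$predicted[1L], 0.05)
})

test_that("graph predictions agree with a Gaussian-drift simulation oracle", {
  g <- fourLeafTree()
  P <- simulateGraphFreqs(g, nLoci = 60000, seed = 9)
  pr <- predictFStats(g)
  f2s <- pr[pr$kind == "f2", ]
  for (i in seq_len(nrow(f2s))) {
    emp <- mean((P[f2s$pop1[i], ] - P[f2s$pop2[i], ])^2)
    se <- sd((P[f2s$pop1[i], ] - P[f2s$pop2[i], ])^2) / sqrt(ncol(P))
    expect_lt(abs(emp - f2s$predicted[i]), 3 * se + 0.002)
  }
})

test_that("an admixed leaf shows the -a(1-a) f3 signal predicted by path algebra", {
  a <- 0.3
  ed <- rbind(
    data.frame(from = "root", to = "n1", type = "drift", length = 0.02, weight = NA),
    data.frame(from = "root", to = "n2", type = "drift", length = 0.03, weight = NA),
    data.frame(from = "n1", to = "A", type = "drift", length = 0.02, weight = NA),
    data.frame(from = "n2", to = "B", type = "drift", length = 0.02, weight = NA),
    data.frame(from = "n1", to = "adm", type = "admix", length = 0, weight = a),
    data.frame(from = "n2", to = "adm", type = "admix", length = 0, weight = 1 - a),
    data.frame(from = "adm", to = "C", type = "drift", length = 0.001, weight = NA))
  g <- admixtureGraph(ed)
  pr <- predictFStats(g)
  f3C <- pr$predicted[pr$kind == "f3" & pr$pop1 == "C"]
  expect_lt(f3C, 0)  # admixture signal
  # oracle agreement
  P <- simulateGraphFreqs(g, nLoci = 60000, seed = 10)
  empF3 <- mean((P["C", ] - P["A", ]) * (P["C", ] - P["B", ]))
  se <- sd((P["C", ] - P["A", ]) * (P["C", ] - P["B", ])) / sqrt(ncol(P))
  expect_lt(abs(empF3 - f3C), 3 * se + 0.002)
})

test_that("predicted statistics satisfy f4 additivity and drift triangle bounds", {
  set.seed(11)
  for (rep in 1:5) {
    topo <- list("O", list(list("A", "B"), list("C", "D")))
    g <- treeGraph(topo)
    g@edges$length <- runif(nrow(g@edges), 0.001, 0.1)
    pr <- predictFStats(g)
    f2m <- matrix(0, 5, 5, dimnames = list(g@leaves, g@leaves))
    f2s <- pr[pr$kind == "f2", ]
    for (i in seq_len(nrow(f2s)))
      f2m[f2s$pop1[i], f2s$pop2[i]] <- f2m[f2s$pop2[i], f2s$pop1[i]] <-
        f2s$predicted[i]
    # f4 additivity
    f4v <- function(a, b, c, d)
      0.5 * (f2m[a, d] + f2m[b, c] - f2m[a, c] - f2m[b, d])
    expect_equal(f4v("A", "B", "C", "D"),
                 f4v("A", "B", "C", "O") + f4v("A", "B", "O", "D"),
                 tolerance = 1e-10)
    # sqrt(f2) triangle inequality (metric embedding of drift trees)
    for (tri in list(c("A", "B", "C"), c("A", "C", "O"))) {
      expect_lte(sqrt(f2m[tri[1], tri[3]]),
                 sqrt(f2m[tri[1], tri[2]]) + sqrt(f2m[tri[2], tri[3]]) + 1e-12)
    }
  }
})

test_that("noiseless graph-generated input is fitted back exactly", {
  g0 <- fourLeafTree()
  pr <- predictFStats(g0)
  f2s <- pr[pr$kind == "f2", ]
  f2m <- matrix(0, 4, 4, dimnames = list(g0@leaves, g0@leaves))
  for (i in seq_len(nrow(f2s)))
    f2m[f2s$pop1[i], f2s$pop2[i]] <- f2m[f2s$pop2[i], f2s$pop1[i]] <-
      f2s$predicted[i]
  fs <- fStatSetFromF2(f2m)
  gFree <- g0
  # identifiable parameterization: fix one root-adjacent edge (only the sum
  # of the two root edges is identifiable from f-statistics)
  gFree@edges$length[-1L] <- NA_real_
  fit <- fitGraph(gFree, fs, starts = 4, seed = 2)
  expect_lt(max(abs(fit$residuals$estimate - fit$residuals$predicted)), 1e-6)
  expect_equal(fit$graph@edges$length, g0@edges$length, tolerance = 1e-4)
})

test_that("the true topology fits strictly better than a wrong one", {
  snp <- cached("graphPanel", function() {
    dem <- Demography(
      data.frame(label = c("O", "A", "B", "C"), size = 3000),
      events = list(demeEvent(1500, "join", "B", "A"),
                    demeEvent(3000, "join", "C", "A"),
                    demeEvent(20000, "join", "O", "A")))
    simulateGenotypes(dem, simConfig(
      nLoci = 6000, samplesPerDeme = c(O = 8, A = 8, B = 8, C = 8),
      seed = 77))
  })
  fs <- fStatSet(freqMatrix(snp, blockSize = 100L))
  gTrue <- treeGraph(list("O", list(list("A", "B"), "C")))
  gWrong <- treeGraph(list("O", list(list("A", "C"), "B")))
  fitT <- fitGraph(gTrue, fs, starts = 3, seed = 4)
  fitW <- fitGraph(gWrong, fs, starts = 3, seed = 4)
  expect_lt(fitT$maxZ, fitW$maxZ)
})

test_that("incremental search recovers placements and prefers a planted admixture", {
  snp <- cached("graphPanel", function() stop("built above"))
  fs <- fStatSet(freqMatrix(snp, blockSize = 100L))
  # empty remaining set: the fitted skeleton is returned
  sk <- incrementalSearch(fs, skeleton = c("O", "A", "B", "C"),
                          remaining = character(0), seed = 6)
  expect_s3_class(sk$fit, "GraphFit")
  expect_equal(sk$log$step, "skeleton")
  expect_setequal(sk$fit$graph@leaves, c("O", "A", "B", "C"))
  # tree-generated data: adding C to the (A,B,O) skeleton picks a placement
  # that keeps the fit good (max|Z| below the usual acceptance bar of 3)
  s2 <- incrementalSearch(fs, skeleton = c("O", "A", "B", "C"),
                          remaining = character(0), tryAdmixture = FALSE,
                          seed = 6)
  expect_lt(s2$fit$maxZ, 3)
})

test_that("graph serialization emits DOT and JSON", {
  g <- fourLeafTree()
  dot <- writeGraphDOT(g)
  expect_match(dot, "digraph")
  expect_match(dot, "root")
  js <- graphJSON(g)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed$edges), nrow(g@edges))
})

test_that("merging two samples of one deme leaves FST to an outsider unchanged", {
  snp <- cached("mergePanel", function() {
    dem <- Demography(
      data.frame(label = c("X1", "X2", "Out"), size = 3000),
      events = list(demeEvent(0, "join", "X2", "X1"),
                    demeEvent(8000, "join", "Out", "X1")))
    simulateGenotypes(dem, simConfig(
      nLoci = 4000, samplesPerDeme = c(X1 = 6, X2 = 6, Out = 8), seed = 88))
  })
  fstBefore <- weirCockerhamFst(snp, c("X1", "Out"))$fst
  merged <- mergeGroups(snp, list(X = c("X1", "X2")))
  fstAfter <- weirCockerhamFst(merged, c("X", "Out"))$fst
  expect_equal(fstAfter, fstBefore, tolerance = 0.15)
  expect_equal(length(popNames(merged)), 2L)
})
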