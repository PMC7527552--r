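# brute-force oracles over a frequency table ---------------------------

bruteF3 <- function(p, target, a, b, k = NULL) {
  v <- 0
  for (s in seq_len(ncol(p))) {
    term <- (p[target, s] - p[a, s]) * (p[target, s] - p[b, s])
    if (!is.null(k)) {
      pc <- p[target, s]
      term <- term - pc * (1 - pc) * k / (k - 1) / k
    }
    v <- v + term
  }
  unname(v / ncol(p))
}

bruteD <- function(p, w, x, y, z) {
  num <- den <- 0
  for (s in seq_len(ncol(p))) {
    pw <- p[w, s]; px <- p[x, s]; py <- p[y, s]; pz <- p[z, s]
    num <- num + (pw - px) * (py - pz)
    den <- den + (pw + px - 2 * pw * px) * (py + pz - 2 * py * pz)
  }
  unname(num / den)
}

test_that("admixture-f3 is negative for an exactly intermediate target", {
  p <- rbind(A = rep(1, 10), B = rep(0, 10), C = rep(0.5, 10))
  f <- freqTable(p, k = 1000L)
  res <- f3(f, "C", "A", "B")
  # (c-a)(c-b) = -0.25 per site, minus a tiny bias term at k = 1000
  bias <- 0.5 * 0.5 * 1000 / 999 / 1000
  expect_equal(res$estimate, -0.25 - bias, tolerance = 1e-9)
  expect_lt(res$estimate, 0)
})

test_that("f3 vanishes when the target equals a source population's frequencies", {
  set.seed(1)
  pA <- runif(12)
  p <- rbind(A = pA, B = runif(12), C = pA)
  f <- freqTable(p, k = 1000L)
  res <- f3(f, "C", "A", "B", corrected = FALSE)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_error(f3(f, "A", "A", "B"), "differ")
})

test_that("f3 and D match independently coded brute-force oracles", {
  set.seed(2)
  p <- matrix(runif(4 * 6), 4, 6, dimnames = list(c("W", "X", "Y", "Z"), NULL))
  f <- freqTable(p, k = 500L)
  expect_equal(f3(f, "W", "X", "Y")$estimate,
               bruteF3(p, "W", "X", "Y", k = 500L), tolerance = 1e-12)
  expect_equal(f3(f, "W", "X", "Y", corrected = FALSE)$estimate,
               bruteF3(p, "W", "X", "Y"), tolerance = 1e-12)
  expect_equal(dStat(f, "W", "X", "Y", "Z")$estimate,
               unname(bruteD(p, "W", "X", "Y", "Z")), tolerance = 1e-12)
})

test_that("D statistic limits and symmetries", {
  pEq <- rbind(W = c(1, 0.2), X = c(0, 0.8), Y = c(0.3, 0.5), Z = c(0.3, 0.5))
  f <- freqTable(pEq)
  expect_equal(dStat(f, "W", "X", "Y", "Z")$estimate, 0, tolerance = 1e-12)
  pOne <- rbind(W = c(1, 1), X = c(0, 0), Y = c(1, 1), Z = c(0, 0))
  expect_equal(dStat(freqTable(pOne), "W", "X", "Y", "Z")$estimate, 1)
  set.seed(3)
  p <- matrix(runif(8), 4, 2, dimnames = list(c("W", "X", "Y", "Z"), NULL))
  f2t <- freqTable(p)
  expect_equal(dStat(f2t, "W", "X", "Y", "Z")$estimate,
               -dStat(f2t, "X", "W", "Y", "Z")$estimate, tolerance = 1e-12)
  expect_equal(dStat(f2t, "W", "X", "Y", "Z")$estimate,
               -dStat(f2t, "W", "X", "Z", "Y")$estimate, tolerance = 1e-12)
})

test_that("f-statistics are invariant under global allele relabeling", {
  set.seed(4)
  p <- matrix(runif(4 * 20), 4, 20, dimnames = list(c("W", "X", "Y", "Z"), NULL))
  f1 <- freqTable(p); f2t <- freqTable(1 - p)
  expect_equal(f3(f1, "W", "X", "Y")$estimate, f3(f2t, "W", "X", "Y")$estimate,
               tolerance = 1e-12)
  expect_equal(dStat(f1, "W", "X", "Y", "Z")$estimate,
               dStat(f2t, "W", "X", "Y", "Z")$estimate, tolerance = 1e-12)
  expect_equal(f2(f1, "W", "X")$estimate, f2(f2t, "W", "X")$estimate,
               tolerance = 1e-12)
})

test_that("f3 is symmetric in its sources; f4 additivity holds to 1e-10", {
  set.seed(5)
  p <- matrix(runif(5 * 30), 5, 30,
              dimnames = list(c("A", "B", "C", "D", "E"), NULL))
  f <- freqTable(p, k = 200L)
  expect_equal(f3(f, "A", "B", "C")$estimate, f3(f, "A", "C", "B")$estimate,
               tolerance = 1e-12)
  lhs <- f4(f, "A", "B", "C", "D")$estimate
  rhs <- f4(f, "A", "B", "C", "E")$estimate + f4(f, "A", "B", "E", "D")$estimate
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("block jackknife: exact SE behavior and textbook equivalence", {
  # identical per-block ratios -> SE = 0
  num <- rep(c(1, 2), each = 10)  # block ratio 1.5 everywhere when paired
  blocks <- rep(1:4, each = 5)
  numc <- rep(1.5, 20)
  jk <- blockJackknife(numc, blocks = blocks)
  expect_equal(jk$se, 0)
  # equal block sizes, mean statistic: matches delete-one jackknife formula
  set.seed(6)
  x <- rnorm(40)
  blocks2 <- rep(1:8, each = 5)
  jk2 <- blockJackknife(x, blocks = blocks2)
  thetaJ <- vapply(1:8, function(b) mean(x[blocks2 != b]), 0)
  g <- 8
  seRef <- sqrt((g - 1) / g * sum((thetaJ - mean(thetaJ))^2))
  expect_equal(jk2$estimate, mean(x), tolerance = 1e-12)
  expect_equal(jk2$se, seRef, tolerance = 1e-9)
  expect_error(blockJackknife(x, blocks = rep(1, 40)), "2 non-empty blocks")
  # halving block size on white noise leaves the SE stable
  jk4 <- blockJackknife(x, blocks = rep(1:16, each = 2.5)[1:40])
  expect_lt(abs(jk4$se - jk2$se) / jk2$se, 0.5)
})

test_that("outgroup-f3 ranks a clone of x highest and respects symmetry", {
  set.seed(7)
  nS <- 400
  pO <- runif(nS, 0.05, 0.95)
  drift <- function(p, s) pmin(pmax(p + rnorm(nS, 0, s), 0), 1)
  pX <- drift(pO, 0.15)
  p <- rbind(O = pO, X = pX, XClone = pX, Far = drift(pO, 0.3))
  f <- freqTable(p, k = 2000L, blockSize = 20L)
  cand <- c("XClone", "Far")
  vals <- vapply(cand, function(y) outgroupF3(f, "O", "X", y)$estimate, 0)
  expect_equal(names(which.max(vals)), "XClone")
})

test_that("f3 scan enumerates correctly, flags a planted admixture, and controls FDR", {
  set.seed(8)
  nS <- 600
  p0 <- runif(nS, 0.1, 0.9)
  drift <- function(p, s) pmin(pmax(p + rnorm(nS, 0, s), 0), 1)
  pA <- drift(p0, 0.12); pB <- drift(p0, 0.12); pC <- drift(p0, 0.12)
  pMix <- 0.5 * drift(pA, 0.02) + 0.5 * drift(pB, 0.02)
  p <- rbind(A = pA, B = pB, C = pC, M = pMix)
  f <- freqTable(p, k = 2000L, blockSize = 25L)
  sc <- f3Scan(f)
  # 4 pops: each target has C(3,2) = 3 source pairs
  expect_equal(nrow(sc), 12L)
  mrows <- sc[sc$pop1 == "M", ]
  best <- mrows[which.min(mrows$estimate), ]
  expect_true(best$significant)
  expect_setequal(c(best$pop2, best$pop3), c("A", "B"))
  expect_false(any(sc$significant[sc$pop1 %in% c("A", "B", "C")]))
  # 3 populations -> exactly 3 tests
  expect_equal(nrow(f3Scan(freqTable(p[1:3, ]))), 3L)
  m <- f3ScanMatrix(sc)
  expect_equal(dim(m), c(4L, 4L))
})
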