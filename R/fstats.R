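#' @include AllGenerics.R
NULL

#' Build the allele-frequency layer for f-statistics
#'
#' Computes per-population alternate-allele frequencies and observed
#' allele-copy counts per site, and assigns contiguous jackknife blocks of
#' roughly \code{blockSize} SNPs (block boundaries never split a GBS
#' stack; no chromosome map exists for this non-model genome, so stack
#' order stands in for genomic order).
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pops population labels (default all).
#' @param blockSize target SNPs per jackknife block (default 200).
#' @return A \linkS4class{FreqMatrix}.
#' @export
freqMatrix <- function(x, pops = popNames(x), blockSize = 200L) {
  pm <- popMap(x)
  gt <- genotypes(x)
  p <- k <- matrix(NA_real_, length(pops), nrow(x),
                   dimnames = list(pops, rownames(x)))
  for (i in seq_along(pops)) {
    sub <- gt[, pm == pops[i], drop = FALSE]
    kk <- 2 * rowSums(!is.na(sub))
    k[i, ] <- kk
    p[i, ] <- ifelse(kk > 0, rowSums(sub, na.rm = TRUE) / kk, NA_real_)
  }
  sid <- stackID(x)
  stackStart <- !duplicated(sid)
  nStack <- cumsum(stackStart)
  snpIdx <- seq_len(nrow(x))
  # block = run of consecutive stacks totalling ~blockSize SNPs
  blockOfStack <- integer(max(nStack))
  cnt <- 0L; b <- 1L
  stackSizes <- tabulate(nStack)
  for (s in seq_along(stackSizes)) {
    if (cnt >= blockSize) { b <- b + 1L; cnt <- 0L }
    blockOfStack[s] <- b
    cnt <- cnt + stackSizes[s]
  }
  storage.mode(k) <- "integer"
  new("FreqMatrix", p = p, k = k, blockID = blockOfStack[nStack],
      siteInfo = data.frame(stack_id = sid, pos = rowData(x)$pos))
}

#' Weighted block jackknife for ratio statistics
#'
#' Delete-one-block estimates of \code{sum(num)/sum(den)} with block-size
#' weighting (Busing-style weighted jackknife), as used for f-statistic
#' standard errors.
#'
#' @param num,den per-site numerator and denominator contributions
#'   (\code{den} defaults to 1 per site, giving a mean statistic).
#' @param blocks integer block id per site (>= 2 non-empty blocks).
#' @return List with \code{estimate}, \code{se}, \code{Z} and \code{nBlocks}.
#' @export
blockJackknife <- function(num, den = NULL, blocks) {
  if (is.null(den)) den <- rep(1, length(num))
  ok <- !is.na(num) & !is.na(den)
  num <- num[ok]; den <- den[ok]; blocks <- blocks[ok]
  ub <- unique(blocks)
  g <- length(ub)
  if (g < 2L) stop("block jackknife needs >= 2 non-empty blocks")
  numB <- vapply(split(num, blocks), sum, 0)
  denB <- vapply(split(den, blocks), sum, 0)
  mB <- vapply(split(num, blocks), length, 0L)
  nTot <- sum(mB)
  est <- sum(numB) / sum(denB)
  thetaJ <- (sum(numB) - numB) / (sum(denB) - denB)  # delete-one estimates
  h <- nTot / mB
  thetaTilde <- g * est - sum((1 - mB / nTot) * thetaJ)
  tau <- h * est - (h - 1) * thetaJ
  varJ <- sum((tau - thetaTilde)^2 / (h - 1)) / g
  se <- sqrt(varJ)
  list(estimate = est, se = se, Z = if (se > 0) est / se else NA_real_,
       nBlocks = g)
}

# internal: per-site bias-corrected squared frequency difference between
# two populations (the f2 site contribution); h/k terms remove sampling
# heterozygosity bias
.f2Site <- function(f, a, b) {
  pa <- f@p[a, ]; pb <- f@p[b, ]
  ka <- f@k[a, ]; kb <- f@k[b, ]
  ha <- pa * (1 - pa) * ka / (ka - 1)
  hb <- pb * (1 - pb) * kb / (kb - 1)
  (pa - pb)^2 - ha / ka - hb / kb
}

# internal: usable sites: all listed pops have >= 2 observed copies
.usableSites <- function(f, pops) {
  use <- rep(TRUE, ncol(f@p))
  for (p in pops) use <- use & !is.na(f@p[p, ]) & f@k[p, ] >= 2L
  use
}

.fstatRow <- function(kind, pops, jk, extra = NULL) {
  p4 <- c(pops, rep(NA_character_, 4 - length(pops)))
  df <- data.frame(stat = kind, pop1 = p4[1L], pop2 = p4[2L],
                   pop3 = p4[3L], pop4 = p4[4L],
                   estimate = jk$estimate, se = jk$se, Z = jk$Z,
                   nBlocks = jk$nBlocks)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

#' Three-population (admixture) f3 statistic
#'
#' \eqn{f3(C; A, B) = E[(c - a)(c - b)]} averaged over sites, with the
#' target's sampling-heterozygosity bias term \eqn{\hat h_C / k_C}
#' subtracted when \code{corrected} (needed for unbiasedness with finite
#' samples).  A significantly negative value signals that the target is
#' admixed between sources related to A and B.  Standard errors by
#' weighted block jackknife.
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param target,a,b population labels (target distinct from sources).
#' @param corrected subtract the target bias term (default TRUE).
#' @return A one-row data.frame (stat, pops, estimate, se, Z, nBlocks).
#' @export
f3 <- function(f, target, a, b, corrected = TRUE) {
  if (target == a || target == b)
    stop("target must differ from both source populations")
  use <- .usableSites(f, c(target, a, b))
  pc <- f@p[target, use]; pa <- f@p[a, use]; pb <- f@p[b, use]
  num <- (pc - pa) * (pc - pb)
  if (corrected) {
    kc <- f@k[target, use]
    num <- num - pc * (1 - pc) * kc / (kc - 1) / kc
  }
  .fstatRow("f3", c(target, a, b), blockJackknife(num, blocks = f@blockID[use]))
}

#' Outgroup f3: shared drift between two populations relative to an outgroup
#'
#' f3 with the outgroup as (uncorrected) target; larger values mean more
#' shared drift between \code{x} and \code{y} (a ranking statistic).
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param outgroup,x,y population labels.
#' @return A one-row data.frame.
#' @export
outgroupF3 <- function(f, outgroup, x, y) {
  out <- f3(f, outgroup, x, y, corrected = FALSE)
  out$stat <- "outgroup_f3"
  out
}

#' Four-population f4 statistic
#'
#' \eqn{f4(A, B; C, D) = E[(a - b)(c - d)]} over usable sites; no bias
#' correction is needed.  Block-jackknife SE.
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param a,b,c,d population labels.
#' @return A one-row data.frame.
#' @export
f4 <- function(f, a, b, c, d) {
  use <- .usableSites(f, c(a, b, c, d))
  num <- (f@p[a, use] - f@p[b, use]) * (f@p[c, use] - f@p[d, use])
  .fstatRow("f4", c(a, b, c, d), blockJackknife(num, blocks = f@blockID[use]))
}

#' Two-population f2 statistic (bias-corrected squared drift distance)
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param a,b population labels.
#' @return A one-row data.frame.
#' @export
f2 <- function(f, a, b) {
  use <- .usableSites(f, c(a, b))
  num <- .f2Site(f, a, b)[use]
  .fstatRow("f2", c(a, b), blockJackknife(num, blocks = f@blockID[use]))
}

#' D statistic (normalized ABBA-BABA)
#'
#' \eqn{D = \sum (w-x)(y-z) / \sum (w + x - 2wx)(y + z - 2yz)} over
#' usable sites, with block-jackknife SE/Z.  |Z| > 3 corresponds to
#' p ~ 0.001 for gene flow inconsistent with the tree ((w,x),(y,z)).
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param w,x,y,z population labels (4 distinct).
#' @return A one-row data.frame.
#' @export
dStat <- function(f, w, x, y, z) {
  pops <- c(w, x, y, z)
  if (anyDuplicated(pops)) stop("D statistic needs 4 distinct populations")
  use <- .usableSites(f, pops)
  pw <- f@p[w, use]; px <- f@p[x, use]
  py <- f@p[y, use]; pz <- f@p[z, use]
  num <- (pw - px) * (py - pz)
  den <- (pw + px - 2 * pw * px) * (py + pz - 2 * py * pz)
  if (sum(den) == 0) stop("no informative sites: D undefined")
  out <- .fstatRow("D", pops, blockJackknife(num, den, blocks = f@blockID[use]))
  out
}

#' Genome-wide admixture-f3 scan with FDR adjustment
#'
#' Runs all (target; A, B) admixture-f3 tests over the given targets,
#' computes one-sided p-values for negative Z (the admixture direction),
#' adjusts by Benjamini-Hochberg across the scan, and flags tests whose
#' adjusted significance corresponds to an adjusted Z-score at or below
#' -1.96.
#'
#' @param f a \linkS4class{FreqMatrix} with >= 3 populations.
#' @param targets targets to scan (default all populations).
#' @return data.frame of all tests with \code{p}, \code{q},
#'   \code{Z_adjusted} and \code{significant}.
#' @export
f3Scan <- function(f, targets = popNames(f)) {
  pops <- popNames(f)
  if (length(pops) < 3L) stop("f3 scan needs >= 3 populations")
  rows <- list()
  for (tg in targets) {
    src <- setdiff(pops, tg)
    prs <- combn(src, 2L)
    for (j in seq_len(ncol(prs)))
      rows[[length(rows) + 1L]] <- f3(f, tg, prs[1L, j], prs[2L, j])
  }
  out <- do.call(rbind, rows)
  out$p <- pnorm(out$Z)              # one-sided, negative direction
  out$q <- p.adjust(out$p, "BH")
  out$Z_adjusted <- qnorm(out$q)
  out$significant <- out$Z_adjusted <= -1.96
  out
}

#' Matrix view of an f3 scan (heat-map layout)
#'
#' Minimum f3 Z-score per (target, source) pairing: entry (t, s) is the
#' most negative adjusted Z over all tests f3(t; s, *).
#'
#' @param scan output of \code{\link{f3Scan}}.
#' @return numeric matrix targets x sources.
#' @export
f3ScanMatrix <- function(scan) {
  tg <- unique(scan$pop1)
  src <- unique(c(scan$pop2, scan$pop3))
  m <- matrix(NA_real_, length(tg), length(src), dimnames = list(tg, src))
  for (i in seq_len(nrow(scan))) {
    for (s in c(scan$pop2[i], scan$pop3[i])) {
      cur <- m[scan$pop1[i], s]
      v <- scan$Z_adjusted[i]
      m[scan$pop1[i], s] <- if (is.na(cur)) v else min(cur, v)
    }
  }
  m
}
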