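#' @include fstats.R diversity.R simulate.R
NULL

#' Reynolds coancestry distance matrix between populations
#'
#' Ratio-of-sums Reynolds distance from per-site allele frequencies over
#' sites usable in every population.
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @return Symmetric distance matrix.
#' @export
reynoldsDist <- function(f) {
  pops <- popNames(f)
  use <- .usableSites(f, pops)
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1L]) for (j in seq_len(i - 1L)) {
    pi <- f@p[pops[i], use]; pj <- f@p[pops[j], use]
    num <- (pi - pj)^2
    den <- 1 - pi * pj - (1 - pi) * (1 - pj)
    D[i, j] <- D[j, i] <- sum(num) / sum(den)
  }
  D
}

# internal: population kinship matrix from a rooted NJ tree of Reynolds
# distances: F[i, j] = shared branch length from the root.  The pairwise
# Reynolds coancestry converges to (f_i + f_j)/2 for independently drifting
# populations, so distances are doubled to put tip branches on the f scale
# the FLK covariance needs.
.kinshipFromTree <- function(D, outgroup = NULL) {
  tr <- ape::nj(stats::as.dist(2 * D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr <- if (!is.null(outgroup))
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  else phangorn::midpoint(tr)
  tr$edge.length <- pmax(tr$edge.length, 0)
  depth <- ape::node.depth.edgelength(tr)
  tips <- tr$tip.label
  mr <- ape::mrca(tr)
  Fm <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips)) for (j in seq_len(i)) {
    Fm[i, j] <- Fm[j, i] <- depth[mr[i, j]]
  }
  diag(Fm) <- depth[seq_along(tips)]
  list(F = Fm[rownames(D), rownames(D)], tree = tr)
}

#' FLK test for FST outliers with population kinship
#'
#' Extends the Lewontin-Krakauer test by a kinship matrix F derived from a
#' neighbor-joining tree of Reynolds distances (midpoint-rooted, or
#' outgroup-rooted if given).  Per locus,
#' \eqn{T = (p - \hat p_0 1)' V^{-1} (p - \hat p_0 1)} with
#' \eqn{V = \hat p_0 (1 - \hat p_0) F} and \eqn{\hat p_0} the GLS
#' (V-weighted) estimate of the ancestral frequency; p-values from a
#' chi-square with (number of populations - 1) degrees of freedom.
#' With a star phylogeny F is proportional to the identity and T reduces
#' to the classical Lewontin-Krakauer statistic.
#'
#' @param f a \linkS4class{FreqMatrix} with >= 3 populations.
#' @param outgroup optional population used to root the kinship tree.
#' @param qThreshold per-test outlier threshold on BH-adjusted p.
#' @return data.frame per usable locus: stack_id, pos, T, p, q, outlier;
#'   the kinship matrix and tree are attached as attributes.
#' @export
flkTest <- function(f, outgroup = NULL, qThreshold = 0.05) {
  pops <- popNames(f)
  if (length(pops) < 3L)
    stop("FLK needs >= 3 populations for a non-trivial kinship matrix")
  D <- reynoldsDist(f)
  kin <- .kinshipFromTree(D, outgroup)
  Fm <- kin$F
  Finv <- tryCatch(solve(Fm), error = function(e) {
    warning("singular kinship matrix; ridge-regularized")
    solve(Fm + diag(1e-6 * mean(diag(Fm)), nrow(Fm)))
  })
  use <- .usableSites(f, pops)
  P <- f@p[pops, use, drop = FALSE]
  one <- rep(1, length(pops))
  w <- as.vector(Finv %*% one) / sum(Finv)
  p0 <- as.vector(crossprod(w, P))
  poly <- p0 > 0 & p0 < 1
  Tstat <- rep(NA_real_, ncol(P))
  dev <- sweep(P[, poly, drop = FALSE], 2L, p0[poly], "-")
  Tstat[poly] <- colSums(dev * (Finv %*% dev)) / (p0[poly] * (1 - p0[poly]))
  pval <- pchisq(Tstat, df = length(pops) - 1L, lower.tail = FALSE)
  qval <- rep(NA_real_, length(pval))
  qval[!is.na(pval)] <- p.adjust(pval[!is.na(pval)], "BH")
  out <- data.frame(stack_id = f@siteInfo$stack_id[use],
                    pos = f@siteInfo$pos[use],
                    T_FLK = Tstat, p = pval, q = qval,
                    outlier = !is.na(qval) & qval < qThreshold)
  attr(out, "kinship") <- Fm
  attr(out, "tree") <- kin$tree
  out
}

#' Fdist-style FST outlier test with a coalescent island-model null
#'
#' Estimates the multi-locus neutral Weir-Cockerham FST, simulates
#' \code{nSimLoci} neutral loci under a symmetric island model matched to
#' that FST and to the observed sample sizes (island-model expectation
#' \eqn{F_{ST} = 1 / (1 + 4 N m (d/(d-1))^2)}), and computes per-locus
#' p-values as the proportion of simulated loci in the same
#' heterozygosity bin with FST at least as large.  BH-adjusted q-values.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pops >= 2 population labels (default all).
#' @param nSimLoci simulated neutral loci.
#' @param Nsim island-deme diploid size used in the null simulation.
#' @param nBins heterozygosity bins.
#' @param minPerBin minimum simulated loci per bin (bins are widened with
#'   a warning below this).
#' @param alpha per-locus envelope threshold for the outlier flag: a locus
#'   is flagged when its empirical p-value falls below \code{alpha} (the
#'   conventional reading of an Fdist simulation envelope; the empirical
#'   p-value floor of 1/(bin size + 1) makes genome-wide q-values
#'   unable to reach small thresholds at feasible simulation sizes, so
#'   q-values are reported but not used for the flag).
#' @param seed integer seed.
#' @return data.frame per locus: stack_id, pos, fst, het, p, q, outlier.
#' @export
fdistTest <- function(x, pops = popNames(x), nSimLoci = 10000L, Nsim = 5000,
                      nBins = 20L, minPerBin = 100L, alpha = 0.01,
                      seed = 1L) {
  if (length(pops) < 2L) stop("need >= 2 populations")
  wc <- weirCockerhamFst(x, pops)
  target <- max(wc$fst, 1e-4)
  d <- length(pops)
  pm <- popMap(x)
  nDip <- vapply(pops, function(p) sum(pm == p), 0L)
  # island-model null matched to the observed multi-locus FST.  Wright's
  # identity gives the starting Nm; two pilot rounds then calibrate the
  # migration rate empirically so the *realized* SNP-ascertained FST of
  # the null matches the observed one.
  Nm <- (1 / target - 1) / (4 * (d / (d - 1))^2)
  islandSim <- function(Nm, nLoci, tag) {
    m <- min(Nm / Nsim, 0.45)
    mig <- matrix(m / (d - 1), d, d); diag(mig) <- 0
    dem <- Demography(data.frame(label = pops, size = Nsim), migration = mig)
    simulateGenotypes(dem, simConfig(
      nLoci = nLoci, samplesPerDeme = setNames(nDip, pops),
      seed = deriveSeed(seed, tag)))
  }
  for (it in 1:2) {
    pilot <- weirCockerhamFst(islandSim(Nm, 2000L, paste0("pilot", it)),
                              pops)$fst
    Nm <- Nm * (1 / target - 1) / (1 / max(pilot, 1e-4) - 1)
  }
  sim <- islandSim(Nm, nSimLoci, "fdist")
  wcSim <- weirCockerhamFst(sim, pops)
  hetOf <- function(snp, res) {
    fq <- freqMatrix(snp, pops)
    key <- paste(res$perSite$stack_id, res$perSite$pos)
    all <- paste(fq@siteInfo$stack_id, fq@siteInfo$pos)
    idx <- match(key, all)
    kMat <- fq@k[, idx, drop = FALSE]
    pMat <- fq@p[, idx, drop = FALSE]
    pbar <- colSums(kMat * pMat) / colSums(kMat)
    2 * pbar * (1 - pbar)
  }
  hetSim <- hetOf(sim, wcSim)
  hetObs <- hetOf(x, wc)
  qs <- quantile(hetSim, probs = seq(0, 1, length.out = nBins + 1L))
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  binSim <- findInterval(hetSim, qs, rightmost.closed = TRUE)
  binObs <- findInterval(hetObs, qs, rightmost.closed = TRUE)
  binObs <- pmin(pmax(binObs, 1L), nBins)
  pval <- vapply(seq_along(binObs), function(i) {
    lo <- hi <- binObs[i]
    sel <- binSim == binObs[i]
    while (sum(sel) < minPerBin && (lo > 1L || hi < nBins)) {
      lo <- max(1L, lo - 1L); hi <- min(nBins, hi + 1L)
      sel <- binSim >= lo & binSim <= hi
    }
    (1 + sum(wcSim$perSite$fst[sel] >= wc$perSite$fst[i])) / (1 + sum(sel))
  }, 0)
  if (any(tabulate(binSim, nBins) < minPerBin))
    warning("some heterozygosity bins were widened to reach ", minPerBin,
            " simulated loci")
  qval <- p.adjust(pval, "BH")
  data.frame(stack_id = wc$perSite$stack_id, pos = wc$perSite$pos,
             fst = wc$perSite$fst, het = hetObs, p = pval, q = qval,
             outlier = pval < alpha)
}

#' Consensus of outlier tests
#'
#' Intersects the outlier flags of any number of aligned per-locus test
#' results (a locus is under putative selection only if every test flags
#' it), so externally computed tests can be merged in.
#'
#' @param results named list of per-locus data.frames, each with columns
#'   \code{stack_id}, \code{pos}, \code{outlier} (and optionally
#'   \code{q}).
#' @return data.frame with per-test flags and a \code{consensus} column.
#' @export
consensusOutliers <- function(results) {
  if (!length(results)) stop("need at least one test result")
  if (is.null(names(results)))
    names(results) <- sprintf("test%d", seq_along(results))
  keys <- lapply(results, function(r) paste(r$stack_id, r$pos))
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("test results share no loci (misaligned locus sets)")
  out <- data.frame(
    stack_id = sub(" .*", "", common),
    pos = as.integer(sub(".* ", "", common)))
  for (nm in names(results)) {
    r <- results[[nm]]
    out[[paste0("outlier_", nm)]] <- r$outlier[match(common, keys[[nm]])]
  }
  out$consensus <- Reduce(`&`, out[grep("^outlier_", names(out))])
  out
}

#' Grouped selection scans in the published design
#'
#' Runs the implemented outlier tests (FLK where >= 3 groups, the
#' Fdist-style test always) under a grouping scheme: first the
#' two-species contrast, then within-species contrasts (three geographic
#' clades of Z. bungeanum; wild vs cultivated Z. armatum), mirroring the
#' two-stage design of the source study.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param scheme named list: scan name -> named list mapping group label
#'   to population labels.
#' @param qThreshold per-test outlier threshold.
#' @param nSimLoci Fdist simulated loci.
#' @param seed integer seed.
#' @return Named list of consensus tables (one per scan).
#' @export
selectionScan <- function(x, scheme, qThreshold = 0.05, nSimLoci = 10000L,
                          seed = 1L) {
  res <- list()
  for (nm in names(scheme)) {
    gx <- mergeGroups(x, scheme[[nm]])
    gx <- gx[, popMap(gx) %in% names(scheme[[nm]])]
    pops <- unique(popMap(gx))
    tests <- list()
    if (length(pops) >= 3L)
      tests$flk <- flkTest(freqMatrix(gx, pops), qThreshold = qThreshold)
    tests$fdist <- fdistTest(gx, pops, nSimLoci = nSimLoci,
                             seed = deriveSeed(seed, nm))
    res[[nm]] <- consensusOutliers(tests)
  }
  res
}
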