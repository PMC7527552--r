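#' @include AllGenerics.R
NULL

# internal: per-site alt-allele count and observed copies for one population
.popCounts <- function(x, pop) {
  pm <- popMap(x)
  if (!pop %in% pm) stop(sprintf("population '%s' not in pop map", pop))
  sub <- genotypes(x)[, pm == pop, drop = FALSE]
  list(a = rowSums(sub, na.rm = TRUE),
       k = 2 * rowSums(!is.na(sub)),
       het = rowSums(sub == 1L, na.rm = TRUE),
       n = rowSums(!is.na(sub)))
}

#' Per-site nucleotide diversity within a population
#'
#' Per site, pi equals the average pairwise difference among the k observed
#' allele copies, \eqn{\pi = k/(k-1) \cdot 2 \hat p (1 - \hat p)}; sites
#' with fewer than 2 observed copies do not contribute.  Values are per
#' variant site (GBS panels carry no callable-site total); a total assayed
#' length can be supplied to express diversity per assayed site.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pop population label.
#' @param totalSites optional total number of assayed sites used as an
#'   alternative denominator for the mean.
#' @return List with \code{perSite} (named numeric), \code{mean} (over
#'   contributing variant sites), \code{sum} and \code{nSites}.
#' @export
nucleotideDiversity <- function(x, pop, totalSites = NULL) {
  pc <- .popCounts(x, pop)
  use <- pc$k >= 2
  p <- pc$a[use] / pc$k[use]
  k <- pc$k[use]
  pi <- 2 * p * (1 - p) * k / (k - 1)
  list(perSite = setNames(pi, rownames(x)[use]),
       mean = if (is.null(totalSites)) mean(pi) else sum(pi) / totalSites,
       sum = sum(pi), nSites = sum(use))
}

#' Observed heterozygosity per accession
#'
#' Fraction of non-missing genotypes that are heterozygous, per accession.
#' Accessions with no non-missing genotypes get \code{NA} with a warning.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @return Named numeric vector over accessions.
#' @export
heterozygosity <- function(x) {
  gt <- genotypes(x)
  nObs <- colSums(!is.na(gt))
  h <- colSums(gt == 1L, na.rm = TRUE) / nObs
  if (any(nObs == 0L)) {
    warning("accession(s) with no non-missing genotypes: ",
            paste(colnames(gt)[nObs == 0L], collapse = ", "))
    h[nObs == 0L] <- NA_real_
  }
  h
}

#' Weir-Cockerham fixation index
#'
#' Per-site variance components (a: among populations, b: among individuals
#' within populations, c: within individuals) of the Weir & Cockerham
#' ANOVA estimator, combined across sites as a ratio of sums
#' \eqn{\sum a / \sum (a+b+c)}.  Negative per-site components are retained
#' (not truncated) to preserve estimator unbiasedness; sites with zero
#' total variance, or where any population has no genotyped individual (or
#' the mean sample size is 1), are skipped.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pops two or more population labels (default: all).
#' @return List with \code{fst} (multi-locus estimate), \code{perSite}
#'   data.frame (stack_id, pos, a, abc, fst) and \code{nSites}.
#' @export
weirCockerhamFst <- function(x, pops = popNames(x)) {
  if (length(pops) < 2L) stop("need at least 2 populations")
  pcs <- lapply(pops, function(p) .popCounts(x, p))
  r <- length(pops)
  nMat <- matrix(vapply(pcs, `[[`, numeric(nrow(x)), "n"), ncol = r)
  pMat <- matrix(vapply(pcs, function(pc)
    ifelse(pc$k > 0, pc$a / pc$k, NA_real_), numeric(nrow(x))), ncol = r)
  hMat <- matrix(vapply(pcs, function(pc)
    ifelse(pc$n > 0, pc$het / pc$n, NA_real_), numeric(nrow(x))), ncol = r)
  ok <- rowSums(nMat > 0) == r
  nMat <- nMat[ok, , drop = FALSE]
  pMat <- pMat[ok, , drop = FALSE]
  hMat <- hMat[ok, , drop = FALSE]
  nbar <- rowMeans(nMat)
  nsum <- rowSums(nMat)
  nc <- (nsum - rowSums(nMat^2) / nsum) / (r - 1)
  pbar <- rowSums(nMat * pMat) / nsum
  s2 <- rowSums(nMat * (pMat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nMat * hMat) / nsum
  ok2 <- nbar > 1 & nc > 0
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  abc <- a + b + cc
  use <- ok2 & abs(abc) > .Machine$double.eps
  perSite <- data.frame(
    stack_id = stackID(x)[ok][use],
    pos = rowData(x)$pos[ok][use],
    a = a[use], abc = abc[use], fst = a[use] / abc[use])
  list(fst = sum(a[use]) / sum(abc[use]), perSite = perSite,
       nSites = sum(use))
}

#' Diversity and differentiation summary table
#'
#' Per population: mean and summed nucleotide diversity, expected
#' heterozygosity (unbiased, averaged over variant sites) and mean
#' observed accession heterozygosity.  Per population pair: multi-locus
#' Weir-Cockerham FST.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pops population labels (default: all).
#' @return List with \code{populations} (data.frame) and \code{fst}
#'   (symmetric matrix).
#' @export
diversityTable <- function(x, pops = popNames(x)) {
  hetObs <- heterozygosity(x)
  pm <- popMap(x)
  rows <- lapply(pops, function(p) {
    nd <- nucleotideDiversity(x, p)
    pc <- .popCounts(x, p)
    use <- pc$k >= 2
    pfr <- pc$a[use] / pc$k[use]
    he <- mean(2 * pfr * (1 - pfr) * pc$k[use] / (pc$k[use] - 1))
    data.frame(population = p, n = sum(pm == p),
               pi_mean = nd$mean, pi_sum = nd$sum, n_pi_sites = nd$nSites,
               het_expected = he,
               het_observed = mean(hetObs[pm == p], na.rm = TRUE))
  })
  fst <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  if (length(pops) >= 2L)
    for (i in seq_along(pops)[-1L]) for (j in seq_len(i - 1L)) {
      v <- weirCockerhamFst(x, c(pops[i], pops[j]))$fst
      fst[i, j] <- fst[j, i] <- v
    }
  diag(fst) <- 0
  list(populations = do.call(rbind, rows), fst = fst)
}
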