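#' @include demography-class.R
NULL

#' Simulate diploid genotypes under a structured-coalescent demography
#'
#' For each locus an independent genealogy of the sampled lineages is drawn
#' under the structured coalescent (piecewise-exponential deme sizes,
#' backward migration, joins), and one segregating site is placed uniformly
#' on the total branch length (infinite sites conditioned on segregating,
#' so \code{nLoci} equals the SNP count).  Haploid lineages are paired
#' within demes into diploid accessions.  Loci are grouped into GBS stacks
#' (grouping metadata only; loci stay unlinked) and genotypes are masked
#' missing independently at \code{missingRate}.  Fully reproducible from
#' the config seed.
#'
#' @param dem a \linkS4class{Demography}.
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{SNPMatrix}.
#' @export
simulateGenotypes <- function(dem, config) {
  validObject(dem)
  eng <- .demographyToEngine(dem)
  samples <- .sampleVector(dem, config$samplesPerDeme)
  sim <- coal_sim_sites(eng$nDemes, eng$N0, eng$growth0, eng$mig, eng$events,
                        samples, config$nLoci,
                        deriveSeed(config$seed, "genealogies"))
  hap <- sim$geno
  # pair consecutive haploids within demes into diploids (deme-major order)
  nDip <- samples %/% 2L
  gt <- hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE] +
        hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE]
  gt <- t(gt)  # sites x accessions
  labs <- rep(dem@demes$label, nDip)
  accIDs <- unlist(lapply(unique(labs), function(l)
    sprintf("%s_%02d", l, seq_len(sum(labs == l)))), use.names = FALSE)
  set.seed(deriveSeed(config$seed, "stacks"))
  # stack sizes drawn from the configured distribution until all loci used
  sizes <- sample.int(length(config$snpsPerStack),
                      size = config$nLoci, replace = TRUE,
                      prob = config$snpsPerStack)
  csum <- cumsum(sizes)
  nStacks <- which(csum >= config$nLoci)[1L]
  sizes <- sizes[seq_len(nStacks)]
  sizes[nStacks] <- sizes[nStacks] - (csum[nStacks] - config$nLoci)
  stackID <- rep(sprintf("locus%06d", seq_len(nStacks)), sizes)
  pos <- unlist(lapply(sizes, function(s)
    sort(sample.int(config$locusLength, s))), use.names = FALSE)
  alleles <- c("A", "C", "G", "T")
  refIdx <- sample.int(4L, config$nLoci, replace = TRUE)
  altIdx <- ((refIdx - 1L + sample.int(3L, config$nLoci, replace = TRUE)) %% 4L) + 1L
  if (config$missingRate > 0) {
    set.seed(deriveSeed(config$seed, "missing"))
    gt[runif(length(gt)) < config$missingRate] <- NA_integer_
  }
  out <- SNPMatrix(gt, stackID = stackID, pos = pos,
                   ref = alleles[refIdx], alt = alleles[altIdx],
                   populations = setNames(labs, accIDs))
  # bookkeeping for honest absolute-scale calibration downstream: loci are
  # conditioned on segregating, so the implied number of *assayed* loci is
  # nLoci / mean P(locus segregates | genealogy) under the mutation model
  muGen <- config$muPerYear * config$gYears
  pSeg <- mean(1 - exp(-muGen * config$locusLength * sim$totlen))
  metadata(out)$sim <- list(
    nLoci = config$nLoci, locusLength = config$locusLength,
    muPerYear = config$muPerYear, gYears = config$gYears,
    meanTreeLength = mean(sim$totlen), pSegregating = pSeg,
    impliedTotalSites = config$nLoci * config$locusLength / pSeg,
    seed = config$seed)
  out
}

#' Simulation bookkeeping attached to a synthetic SNPMatrix
#'
#' Returns the generator's bookkeeping (locus count and length, mutation
#' calibration, mean genealogy length, probability a locus segregates and
#' the implied number of assayed sites) or \code{NULL} for non-synthetic
#' data.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @return A list, or \code{NULL}.
#' @export
simInfo <- function(x) metadata(x)$sim

#' Monte-Carlo expected site-frequency spectrum
#'
#' Estimates the expected joint folded SFS of a demography from
#' \code{nSims} independent genealogies via branch-length contributions:
#' the expected length of branches subtending each joint
#' derived-allele-count class, normalized over segregating classes.  This
#' is the expected-SFS engine behind composite-likelihood model fitting.
#'
#' @param dem a \linkS4class{Demography}.
#' @param samplesPerDeme named integer vector of diploid sample sizes
#'   (demes absent or 0 are unsampled).
#' @param nSims number of simulated genealogies (>= 1).
#' @param seed integer seed (common random numbers: fixing the seed makes
#'   the estimate a smooth deterministic function of parameters).
#' @param fold fold over the global minor allele (default TRUE).
#' @param normalize return probabilities over segregating classes (TRUE)
#'   or raw expected branch lengths in generations (FALSE).
#' @param haploids interpret \code{samplesPerDeme} as haploid lineage
#'   counts instead of diploid individuals (used when matching an SFS
#'   projected to an odd haploid size).
#' @return A \linkS4class{FoldedSFS}.
#' @export
expectedSFSMC <- function(dem, samplesPerDeme, nSims = 10000L, seed = 1L,
                          fold = TRUE, normalize = TRUE, haploids = FALSE) {
  stopifnot(nSims >= 1)
  validObject(dem)
  eng <- .demographyToEngine(dem)
  samples <- if (haploids) {
    s <- integer(nrow(dem@demes))
    s[match(names(samplesPerDeme), dem@demes$label)] <- as.integer(samplesPerDeme)
    s
  } else .sampleVector(dem, samplesPerDeme)
  arr <- coal_expected_sfs(eng$nDemes, eng$N0, eng$growth0, eng$mig,
                           eng$events, samples, as.integer(nSims),
                           as.numeric(seed))
  dims <- samples[samples > 0L]
  pops <- dem@demes$label[samples > 0L]
  if (length(dims) == 1L) arr <- array(arr, dim = dims + 1L)
  sfs <- new("FoldedSFS", counts = arr,
             mask = array(TRUE, dim = dims + 1L),
             sampleSizes = as.integer(dims), pops = pops,
             nSites = NA_real_, folded = FALSE, isProbability = FALSE)
  if (fold) sfs <- foldSFS(sfs)
  if (normalize) sfs <- .normalizeSFS(sfs)
  sfs
}

# internal: convert to probabilities over segregating classes
.normalizeSFS <- function(sfs) {
  cnt <- sfs@counts
  seg <- .segregatingMask(sfs)
  tot <- sum(cnt[seg])
  cnt[seg] <- cnt[seg] / tot
  cnt[!seg] <- 0
  sfs@counts <- cnt
  sfs@isProbability <- TRUE
  sfs
}

# internal: logical array: cells that are segregating (not the monomorphic
# 0-cell or, unfolded, the all-derived cell) and, if folded, canonical
.segregatingMask <- function(sfs) {
  dims <- dim(sfs@counts)
  idx <- .cellCounts(dims)
  tot <- rowSums(idx)
  seg <- tot > 0 & tot < sum(sfs@sampleSizes)
  m <- array(seg, dim = dims)
  if (sfs@folded) m <- m & sfs@mask
  m
}

# internal: matrix of per-cell derived counts (cells x pops), column-major
.cellCounts <- function(dims) {
  as.matrix(do.call(expand.grid, lapply(dims, function(d) 0:(d - 1L))))
}

#' Generate the study-scale synthetic fixture
#'
#' Emits a VCF + popmap emulating the design of the real GBS panel: 112
#' accessions in 6 clades (four Z. bungeanum clades I-IV with 30/20/20/17
#' accessions, 12 wild and 13 cultivated Z. armatum) and ~38,395 biallelic
#' SNPs in stacks.  The generating demography composes the inferred
#' history: a species split 12 mya-equivalent (3e6 generations at g = 4),
#' Z. bungeanum clade splits at 221/219 kya-equivalents, a Clade IV split
#' set at 50 kya-equivalent (not dated by the source analyses; a declared
#' assumption), and a wild/cultivated Z. armatum split 5,440
#' yr-equivalent with a 200-fold exponential decline in the cultivated
#' deme.  Absolute sizes (50,000 diploids for Z. bungeanum demes, 10,000
#' for Z. armatum and ancestors) are declared assumptions, overridable.
#'
#' @param dir output directory.
#' @param seed integer seed; the same seed yields byte-identical files.
#' @param nLoci number of SNPs (default 38395).
#' @param sizes named numeric overrides for deme sizes.
#' @return List with paths \code{vcf} and \code{popmap}, plus the
#'   \code{demography} used.
#' @export
makeStudyFixture <- function(dir, seed = 1L, nLoci = 38395L, sizes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dem <- studyDemography(sizes)
  cfg <- simConfig(
    nLoci = nLoci,
    samplesPerDeme = c(cladeI = 30L, cladeII = 20L, cladeIII = 20L,
                       cladeIV = 17L, armWild = 12L, armCult = 13L),
    missingRate = 0.10, seed = seed)
  snp <- simulateGenotypes(dem, cfg)
  vcf <- file.path(dir, "study_fixture.vcf")
  pm <- file.path(dir, "study_fixture.popmap.tsv")
  writeVCF(snp, vcf, seed = seed)
  writePopmap(snp, pm)
  list(vcf = vcf, popmap = pm, demography = dem)
}

#' The composite study-scale demography used by the fixture
#'
#' @param sizes optional named numeric overrides of deme sizes.
#' @return A \linkS4class{Demography} with demes cladeI, cladeII, cladeIII,
#'   cladeIV, armWild, armCult.
#' @export
studyDemography <- function(sizes = NULL) {
  sz <- c(cladeI = 5e4, cladeII = 5e4, cladeIII = 5e4, cladeIV = 5e4,
          armWild = 1e4, armCult = 1e4 / 200)
  if (!is.null(sizes)) sz[names(sizes)] <- sizes
  tCult <- 5440 / 4      # wild/cultivated split, 5,440 yr at g = 4
  tIV <- 50000 / 4       # clade IV split (assumption, see docs)
  tII_III <- 219000 / 4  # 219 kya
  tI <- 221000 / 4       # 221 kya
  tSpecies <- 12e6 / 4   # 12 mya
  demes <- data.frame(
    label = names(sz), size = unname(sz),
    growth = c(0, 0, 0, 0, 0, log(sz[["armCult"]] / 1e4) / tCult))
  Demography(demes, events = list(
    demeEvent(tCult, "join", "armCult", "armWild"),
    demeEvent(tIV, "join", "cladeIV", "cladeI"),
    demeEvent(tII_III, "join", "cladeIII", "cladeII"),
    demeEvent(tI, "join", "cladeII", "cladeI"),
    demeEvent(tSpecies, "join", "armWild", "cladeI"),
    demeEvent(tSpecies, "size", "cladeI", size = 5e4)))
}
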