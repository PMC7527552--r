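#' @include sfs.R
NULL

#' Expected folded SFS under a piecewise-constant Ne history
#'
#' Computes the expected folded SFS of a single population whose diploid
#' effective size follows a piecewise-constant trajectory, via dense Monte
#' Carlo over coalescent genealogies (the same engine used for model
#' fitting; precision is the Monte-Carlo standard error implied by
#' \code{nSims}).  With a single interval this reduces to the
#' constant-size coalescent whose folded expectation is proportional to
#' 1/i + 1/(n-i).
#'
#' @param times interval start times in generations (ascending, first 0).
#' @param sizes diploid Ne per interval.
#' @param n haploid sample size (>= 4).
#' @param nSims Monte-Carlo genealogies.
#' @param seed integer seed.
#' @return A folded, normalized \linkS4class{FoldedSFS}.
#' @export
expectedFoldedSFSPiecewise <- function(times, sizes, n, nSims = 200000L,
                                       seed = 1L) {
  if (n < 4) stop("need haploid sample size n >= 4")
  if (times[1L] != 0) stop("first interval must start at time 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("interval start times must be strictly increasing")
  if (any(sizes <= 0)) stop("sizes must be positive")
  dem <- .piecewiseDemography(times, sizes)
  expectedSFSMC(dem, c(pop = n), nSims = nSims, seed = seed,
                fold = TRUE, normalize = TRUE, haploids = TRUE)
}

.piecewiseDemography <- function(times, sizes) {
  ev <- lapply(seq_along(times)[-1L], function(i)
    demeEvent(times[i], "size", 1L, size = sizes[i]))
  Demography(data.frame(label = "pop", size = sizes[1L], growth = 0),
             events = ev)
}

# internal: folded coefficient matrix mapping per-interval theta_k
# (k = 2..n ancestral lineages) to expected folded SFS class masses.
# Unfolded E[xi_i] = sum_k theta_k * P(branch subtends i | k) / (k - 1)
# with P(i | k) = C(n-i-1, k-2) / C(n-1, k-1)  (standard coalescent).
.stairCoef <- function(n) {
  A <- outer(seq_len(n - 1L), 2:n, function(i, k)
    choose(n - i - 1, k - 2) / choose(n - 1, k - 1) / (k - 1))
  m2 <- floor(n / 2)
  Af <- A[seq_len(m2), , drop = FALSE]
  for (i in seq_len(m2)) if (i != n - i) Af[i, ] <- A[i, ] + A[n - i, ]
  Af
}

#' Settings for stairway-style Ne trajectory estimation
#'
#' @param mu per-site per-year mutation rate (default 2.6e-9).
#' @param g generation time in years (default 4).
#' @param totalSites total assayed sequence length in bp (e.g. number of
#'   GBS loci x locus length); sets the absolute Ne scale via the
#'   per-site density of segregating sites.
#' @param candidateEpochs candidate numbers of free size epochs scored by
#'   the training/validation split.
#' @param trainFrac fraction of site counts assigned to training.
#' @param smooth ridge weight on adjacent log-size jumps between epochs
#'   (guards against degenerate near-zero epochs; 0 disables).
#' @param seed integer seed.
#' @return A \code{stairwayConfig} list.
#' @export
stairwayConfig <- function(mu = ZANTHOXYLUM_MU, g = ZANTHOXYLUM_G,
                           totalSites = NULL, candidateEpochs = 1:6,
                           trainFrac = 2 / 3, smooth = 1, seed = 1L) {
  structure(list(mu = mu, g = g, totalSites = totalSites,
                 candidateEpochs = candidateEpochs, trainFrac = trainFrac,
                 smooth = smooth, seed = as.integer(seed)),
            class = "stairwayConfig")
}

# internal: group k = 2..n into m contiguous epochs of near-equal size;
# returns integer group index per k (recent = high k = group 1)
# groups are log-spaced in (k - 1): coalescent intervals are geometrically
# spaced in time, so deep intervals (small k) get their own epochs instead
# of being absorbed into one recent-heavy group
.epochGroups <- function(n, m) {
  ks <- n:2  # recent (many lineages) to ancient
  g <- if (m == 1L) rep(1L, length(ks))
       else (m + 1L) - cut(log(ks - 1), breaks = m, labels = FALSE)
  g <- as.integer(factor(g))  # renumber contiguously, recent first
  setNames(g, ks)[as.character(2:n)]
}

# internal: maximize multinomial lnL of folded class counts over per-epoch
# log-theta, with a mild ridge on adjacent log-size jumps (guards against
# degenerate epochs with near-zero size, which compress the time axis);
# returns list(theta over k = 2..n, lnL)
.fitTheta <- function(counts, Af, groups, m, smooth = 1) {
  obj <- function(eta) {
    theta <- exp(eta)[groups]
    lam <- as.vector(Af %*% theta)
    p <- lam / sum(lam)
    pen <- if (m > 1L) smooth * sum(diff(eta)^2) else 0
    -sum(counts * log(pmax(p, 1e-300))) + pen
  }
  o <- optim(rep(0, m), obj, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-10))
  theta <- exp(o$par)[groups]
  lam <- as.vector(Af %*% theta)
  lnL <- sum(counts * log(pmax(lam / sum(lam), 1e-300)))
  list(theta = theta, lnL = lnL, eta = o$par)
}

#' Stairway-style effective-size trajectory from a folded SFS
#'
#' Fits per-coalescent-interval population sizes to a 1D folded SFS by
#' maximizing the multinomial composite likelihood, with the number of
#' free size epochs selected by a training/validation split of site
#' counts.  Bootstrap SFS replicates are refitted with the selected epoch
#' number to form median and 75\%/95\% envelopes.  Absolute scale is
#' calibrated from the per-site density of segregating sites
#' (\code{nSites / totalSites}), and times/sizes are rescaled through mu
#' and the generation time.
#'
#' @param sfs a 1D folded \linkS4class{FoldedSFS} of site counts
#'   (haploid size >= 4).
#' @param bootstraps list of bootstrap SFS replicates (from
#'   \code{\link{bootstrapSFS}}); may be empty.
#' @param config a \code{\link{stairwayConfig}} with \code{totalSites}
#'   set.
#' @return A \linkS4class{NeTrajectory}.
#' @export
fitStairway <- function(sfs, bootstraps = list(), config = stairwayConfig()) {
  stopifnot(is(sfs, "FoldedSFS"))
  if (!sfs@folded) sfs <- foldSFS(sfs)
  if (length(sfs@sampleSizes) != 1L) stop("stairway needs a 1D folded SFS")
  n <- sfs@sampleSizes
  if (n < 4L) stop("need haploid sample size >= 4")
  if (is.null(config$totalSites))
    stop("config$totalSites is required to set the absolute Ne scale")
  m2 <- floor(n / 2)
  counts <- sfs@counts[2:(m2 + 1L)]
  if (sum(counts > 0) < 2L)
    stop("degenerate SFS: all mass in one frequency class")
  Af <- .stairCoef(n)
  muGen <- config$mu * config$g  # per-site per-generation
  # epoch-number selection on a training/validation split of site counts
  set.seed(config$seed)
  train <- rbinom(length(counts), size = round(counts), prob = config$trainFrac)
  val <- round(counts) - train
  cand <- config$candidateEpochs[config$candidateEpochs <= n - 1L]
  valScore <- vapply(cand, function(m) {
    groups <- .epochGroups(n, m)
    ft <- .fitTheta(train, Af, groups, m, config$smooth)
    lam <- as.vector(Af %*% ft$theta)
    sum(val * log(pmax(lam / sum(lam), 1e-300)))
  }, 0)
  # parsimony rule: smallest epoch number within 2 lnL units of the best
  # validation score (guards against overfitting noisy singleton classes)
  mBest <- min(cand[valScore >= max(valScore) - 2])
  groups <- .epochGroups(n, mBest)
  refit <- function(cnt, nSitesUsed) {
    ft <- .fitTheta(cnt, Af, groups, mBest, config$smooth)
    # absolute calibration: E[S]/site = sum_k theta_k / (k - 1)
    sPerSite <- nSitesUsed / config$totalSites
    cal <- sPerSite / sum(ft$theta / (2:n - 1))
    thetaAbs <- ft$theta * cal         # 4 N_k mu_gen
    Nk <- thetaAbs / (4 * muGen)       # diploid Ne while k lineages
    Tk <- 4 * Nk / ((2:n) * (2:n - 1)) # expected interval durations
    # trajectory recent -> ancient: interval for k = n starts at 0
    ord <- rev(seq_along(Nk))          # k = n .. 2
    starts <- c(0, cumsum(Tk[ord]))[seq_along(ord)]
    list(times = starts, Ne = Nk[ord], lnL = ft$lnL)
  }
  full <- refit(counts, sfs@nSites)
  # collapse adjacent intervals belonging to the same epoch
  gOrd <- groups[as.character(rev(2:n))]
  keep <- c(TRUE, diff(as.integer(gOrd)) != 0)
  times <- full$times[keep]
  Ne <- full$Ne[keep]
  envelope <- data.frame()
  if (length(bootstraps)) {
    trajs <- lapply(bootstraps, function(b) {
      if (!b@folded) b <- foldSFS(b)
      cnt <- b@counts[2:(m2 + 1L)]
      refit(cnt, b@nSites)
    })
    grid <- sort(unique(unlist(lapply(trajs, `[[`, "times"))))
    evalNe <- function(tr, tg)
      tr$Ne[findInterval(tg, tr$times, rightmost.closed = FALSE)]
    mat <- vapply(trajs, evalNe, numeric(length(grid)), tg = grid)
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(grid))
    qs <- apply(mat, 1L, quantile, probs = c(0.5, 0.025, 0.975, 0.125, 0.875))
    envelope <- data.frame(
      time_gen = grid, time_years = grid * config$g,
      Ne_median = qs[1L, ], Ne_lo95 = qs[2L, ], Ne_hi95 = qs[3L, ],
      Ne_lo75 = qs[4L, ], Ne_hi75 = qs[5L, ])
  }
  new("NeTrajectory", times = times, Ne = Ne, envelope = envelope,
      mu = config$mu, g = config$g)
}

#' Tabulate an NeTrajectory with rescaled times
#'
#' @param traj a \linkS4class{NeTrajectory}.
#' @return data.frame with interval start times in generations and years,
#'   and diploid Ne.
#' @export
trajectoryTable <- function(traj)
  data.frame(time_gen = traj@times, time_years = traj@times * traj@g,
             Ne = traj@Ne)
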