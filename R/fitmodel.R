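#' @include models.R sfs.R
NULL

#' Settings for composite-likelihood model fitting
#'
#' Defaults follow the published protocol scaled to desk hardware:
#' 10,000 Monte-Carlo genealogies per expected-SFS evaluation (the
#' published analysis used 100,000), up to 50 cycles of coordinate-wise
#' Brent line search, and independent random restarts (published: 50;
#' desk default 10).  Common random numbers are used across likelihood
#' evaluations within one fit so the surface is a smooth deterministic
#' function of the parameters.
#'
#' @param nSims Monte-Carlo genealogies per expected-SFS evaluation.
#' @param maxCycles maximum Brent cycles (one line search per parameter
#'   per cycle).
#' @param starts number of independent random starts.
#' @param seed integer master seed.
#' @param tolLnL stop cycling when a full cycle improves the composite
#'   log-likelihood by less than this.
#' @param brentTol relative tolerance of each line search (fraction of the
#'   transformed parameter interval).
#' @param probFloor floor probability for expected-SFS classes that are
#'   empty in the Monte-Carlo estimate but observed in the data.
#' @param refineSims Monte-Carlo size for the final polishing stage (the
#'   best multi-start solution is re-optimized at this precision to remove
#'   most of the Monte-Carlo bias of the search stage); 0 disables.
#' @param refineCycles Brent cycles in the polishing stage.
#' @return A \code{fitConfig} list.
#' @export
fitConfig <- function(nSims = 10000L, maxCycles = 50L, starts = 10L,
                      seed = 1L, tolLnL = 1e-3, brentTol = 0.005,
                      probFloor = 1e-10, refineSims = 4L * nSims,
                      refineCycles = 8L) {
  structure(list(nSims = as.integer(nSims), maxCycles = as.integer(maxCycles),
                 starts = as.integer(starts), seed = as.integer(seed),
                 tolLnL = tolLnL, brentTol = brentTol,
                 probFloor = probFloor, refineSims = as.integer(refineSims),
                 refineCycles = as.integer(refineCycles)),
            class = "fitConfig")
}

# internal: transform parameters to/from optimization scale
.toOpt <- function(par, model)
  ifelse(model$scale == "log", log10(par), par)
.fromOpt <- function(v, model)
  setNames(ifelse(model$scale == "log", 10^v, v), model$paramNames)

# internal: composite multinomial log-likelihood of folded SFS counts
# against expected class probabilities (floored and renormalized)
.sfsLogLik <- function(counts, probs, floor) {
  p <- pmax(probs, floor)
  p <- p / sum(p)
  sum(counts * log(p))
}

#' Fit a demographic model to an observed joint folded SFS
#'
#' Maximizes the multinomial composite log-likelihood of the observed
#' folded SFS (segregating classes only; monomorphic classes carry no
#' information for SNP-only GBS data) against the model's Monte-Carlo
#' expected SFS.  Optimization is cycles of one-dimensional Brent line
#' searches over the free parameters (coordinate descent), repeated from
#' independent random starts; deterministic given the seed.
#'
#' @param obs a folded \linkS4class{FoldedSFS} of site counts whose
#'   dimensionality matches the model's deme count.
#' @param model a \code{DemographicModel} from \code{\link{pepperModels}}
#'   or \code{\link{demographicModel}}.
#' @param config a \code{\link{fitConfig}}.
#' @return A \linkS4class{ModelFit}.
#' @export
fitModel <- function(obs, model, config = fitConfig()) {
  stopifnot(is(obs, "FoldedSFS"))
  if (!obs@folded) obs <- foldSFS(obs)
  if (length(obs@sampleSizes) != model$nPops)
    stop(sprintf("observed SFS has %d dimensions but model '%s' has %d demes",
                 length(obs@sampleSizes), model$id, model$nPops))
  if (any(model$lower >= model$upper)) stop("infeasible parameter bounds")
  segMask <- .segregatingMask(obs)
  counts <- obs@counts[segMask]
  nSites <- sum(counts)
  hapSizes <- setNames(obs@sampleSizes, model$popLabels)
  crnSeed <- deriveSeed(config$seed, paste0("crn_", model$id))
  lnLfun <- function(par, nSims) {
    dem <- model$build(par, model$fixed)
    es <- expectedSFSMC(dem, hapSizes, nSims = nSims, seed = crnSeed,
                        fold = TRUE, normalize = TRUE, haploids = TRUE)
    .sfsLogLik(counts, es@counts[segMask], config$probFloor)
  }
  lo <- .toOpt(model$lower, model)
  hi <- .toOpt(model$upper, model)
  k <- model$k
  trace <- list()
  brentCycles <- function(v, cur, nSims, maxCycles, tag) {
    for (cycle in seq_len(maxCycles)) {
      prev <- cur
      for (j in seq_len(k)) {
        f <- function(z) {
          v2 <- v; v2[j] <- z
          -lnLfun(.fromOpt(v2, model), nSims)
        }
        o <- optimize(f, interval = c(lo[j], hi[j]),
                      tol = config$brentTol * (hi[j] - lo[j]))
        if (-o$objective > cur) { v[j] <- o$minimum; cur <- -o$objective }
      }
      trace[[length(trace) + 1L]] <<-
        data.frame(stage = tag, cycle = cycle, logLik = cur)
      if (cur - prev < config$tolLnL) break
    }
    list(v = v, lnL = cur)
  }
  best <- NULL
  for (s in seq_len(config$starts)) {
    set.seed(deriveSeed(config$seed, sprintf("start%d_%s", s, model$id)))
    v <- lo + runif(k) * (hi - lo)
    res <- brentCycles(v, lnLfun(.fromOpt(v, model), config$nSims),
                       config$nSims, config$maxCycles, sprintf("start%d", s))
    if (is.null(best) || res$lnL > best$lnL) best <- res
  }
  if (config$refineSims > config$nSims && config$refineCycles > 0L) {
    # joint polish on a fresh, higher-precision CRN surface: coordinate
    # descent crawls on correlated ridges (e.g. split time vs fold), so
    # the final stage uses a simplex search, then a short Brent pass
    crnSeed <- deriveSeed(config$seed, paste0("crn_refine_", model$id))
    objNM <- function(v) {
      v <- pmin(pmax(v, lo), hi)
      -lnLfun(.fromOpt(v, model), config$refineSims)
    }
    o <- if (k == 1L) {
      oo <- optimize(objNM, interval = c(lo, hi),
                     tol = 0.2 * config$brentTol * (hi - lo))
      list(par = oo$minimum, value = oo$objective)
    } else {
      optim(best$v, objNM, method = "Nelder-Mead",
            control = list(maxit = 150 * k, reltol = 1e-9))
    }
    vr <- pmin(pmax(o$par, lo), hi)
    trace[[length(trace) + 1L]] <-
      data.frame(stage = "refine_simplex", cycle = NA, logLik = -o$value)
    best <- brentCycles(vr, -o$value, config$refineSims,
                        config$refineCycles, "refine")
  }
  par <- .fromOpt(best$v, model)
  aic <- 2 * k - 2 * best$lnL
  new("ModelFit", modelID = model$id, par = par, logLik = best$lnL,
      k = as.integer(k), AIC = aic, nSites = nSites,
      trace = do.call(rbind, trace),
      details = list(config = config, bounds = cbind(lower = model$lower,
                                                     upper = model$upper),
                     fingerprint = .sfsFingerprint(obs),
                     popLabels = model$popLabels,
                     sampleSizes = obs@sampleSizes))
}

.sfsFingerprint <- function(sfs)
  c(dim(sfs@counts), round(sum(sfs@counts), 6),
    round(sum(sfs@counts * seq_along(sfs@counts)), 4))

#' Rank model fits by AIC and Akaike weight
#'
#' @param fits list of \linkS4class{ModelFit} objects fitted to the same
#'   observed SFS.
#' @return data.frame sorted by AIC with \code{dAIC} and Akaike weights
#'   \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}
#'   ("model probabilities").
#' @export
compareModels <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  fps <- lapply(fits, function(f) f@details$fingerprint)
  if (!all(vapply(fps, identical, TRUE, fps[[1L]])))
    stop("fits were made on different observed SFS data")
  df <- data.frame(
    model = vapply(fits, function(f) f@modelID, ""),
    k = vapply(fits, function(f) f@k, 0L),
    logLik = vapply(fits, function(f) f@logLik, 0),
    AIC = vapply(fits, function(f) f@AIC, 0))
  df <- df[order(df$AIC), ]
  df$dAIC <- df$AIC - df$AIC[1L]
  w <- exp(-df$dAIC / 2)
  df$weight <- w / sum(w)
  rownames(df) <- NULL
  df
}

#' Parametric-bootstrap confidence intervals for a model fit
#'
#' Simulates bootstrap SFS datasets from the fitted model (multinomial
#' draws of the fitted number of segregating sites from the fitted
#' expected SFS), refits each, and returns percentile intervals.
#'
#' @param fit a \linkS4class{ModelFit}.
#' @param model the \code{DemographicModel} that produced it.
#' @param B number of bootstrap replicates.
#' @param config refit settings (default: the fit's own settings with 2
#'   starts, halving compute).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return List with \code{estimates} (B x k matrix) and \code{ci}
#'   (2 x k matrix of percentile bounds).
#' @export
parametricBootstrap <- function(fit, model, B = 10L, config = NULL,
                                seed = 1L, level = 0.95) {
  if (is.null(config)) {
    config <- fit@details$config
    config$starts <- 2L
  }
  hapSizes <- setNames(fit@details$sampleSizes, model$popLabels)
  dem <- model$build(fit@par, model$fixed)
  es <- expectedSFSMC(dem, hapSizes,
                      nSims = max(fit@details$config$nSims, 20000L),
                      seed = deriveSeed(seed, "pboot_expected"),
                      fold = TRUE, normalize = TRUE, haploids = TRUE)
  segMask <- .segregatingMask(es)
  probs <- es@counts[segMask]
  ests <- matrix(NA_real_, B, model$k,
                 dimnames = list(NULL, model$paramNames))
  template <- es
  for (b in seq_len(B)) {
    set.seed(deriveSeed(seed, paste0("pboot", b)))
    cnt <- numeric(length(template@counts))
    cnt[segMask] <- rmultinom(1L, size = round(fit@nSites), prob = probs)
    template@counts <- array(cnt, dim = dim(template@counts))
    template@isProbability <- FALSE
    template@nSites <- fit@nSites
    cfg <- config
    cfg$seed <- deriveSeed(seed, paste0("pbootfit", b))
    bf <- fitModel(template, model, cfg)
    ests[b, ] <- bf@par
  }
  alpha <- (1 - level) / 2
  ci <- apply(ests, 2L, quantile, probs = c(alpha, 1 - alpha))
  list(estimates = ests, ci = ci)
}
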