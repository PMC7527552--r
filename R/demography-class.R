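#' @include AllClasses.R
NULL

#' Construct a Demography
#'
#' @param demes data.frame with columns \code{label} (character),
#'   \code{size} (present-day diploid Ne) and optionally \code{growth}
#'   (forward exponential growth rate per generation; default 0).
#' @param events list of events built with \code{\link{demeEvent}}.
#' @param migration deme x deme matrix of backward migration rates
#'   (fraction of lineages in the row deme moving to the column deme per
#'   generation); default none.
#' @return A \linkS4class{Demography}.
#' @examples
#' d <- Demography(data.frame(label = c("wild", "cult"),
#'                            size = c(1e4, 50),
#'                            growth = c(0, -log(200) / 1360)),
#'                 events = list(demeEvent(1360, "join", "cult", "wild")))
#' @export
Demography <- function(demes, events = list(), migration = NULL) {
  if (is.null(demes$growth)) demes$growth <- 0
  demes$label <- as.character(demes$label)
  nd <- nrow(demes)
  if (is.null(migration)) migration <- matrix(0, nd, nd)
  dimnames(migration) <- list(demes$label, demes$label)
  # resolve deme labels in events to indices
  events <- lapply(events, function(e) {
    for (f in c("d1", "d2")) {
      if (!is.null(e[[f]]) && is.character(e[[f]])) {
        i <- match(e[[f]], demes$label)
        if (is.na(i)) stop(sprintf("unknown deme '%s' in event", e[[f]]))
        e[[f]] <- i
      }
    }
    e
  })
  events <- events[order(vapply(events, function(e) e$time, 0))]
  new("Demography", demes = demes, events = events, migration = migration)
}

#' Build a demographic event
#'
#' Events act backward in time.  A \code{"join"} moves all lineages of deme
#' \code{d1} into deme \code{d2} (a forward-time split of \code{d1} from
#' \code{d2}); \code{"size"} resets the size and growth rate of \code{d1};
#' \code{"migration"} replaces the whole migration matrix.
#'
#' @param time time of the event in generations before present (>= 0).
#' @param type one of "join", "size", "migration".
#' @param d1,d2 deme labels (or indices).
#' @param size,growth new diploid size / forward growth rate (type "size").
#' @param mig new migration matrix (type "migration").
#' @return An event list for \code{\link{Demography}}.
#' @export
demeEvent <- function(time, type = c("join", "size", "migration"),
                      d1 = NULL, d2 = NULL, size = NULL, growth = 0,
                      mig = NULL) {
  type <- match.arg(type)
  e <- list(time = time, type = type, d1 = d1, d2 = d2,
            growth = growth)
  if (type == "size") {
    if (is.null(size) || size <= 0) stop("size event needs a positive size")
    e$size <- size
  }
  if (type == "migration") {
    if (is.null(mig)) stop("migration event needs a matrix")
    e$mig <- mig
  }
  e[!vapply(e, is.null, TRUE)]
}

#' Simulation configuration for the genotype generator
#'
#' @param nLoci number of independent SNP-bearing loci (one segregating
#'   site each).
#' @param samplesPerDeme named integer vector of diploid sample sizes per
#'   deme label.
#' @param snpsPerStack probability vector over stack sizes 1..K: how many
#'   consecutive loci are grouped into one GBS stack.  Default mimics short
#'   GBS stacks carrying one to four SNPs.
#' @param missingRate per-genotype missing probability
#'   (missing-completely-at-random), in [0, 1).
#' @param locusLength assayed length of one GBS locus in bp (used for
#'   mutation-rate bookkeeping downstream).
#' @param muPerYear per-site per-year mutation rate (default 2.6e-9).
#' @param gYears generation time in years (default 4).
#' @param seed integer seed.
#' @return A \code{SimConfig} list.
#' @export
simConfig <- function(nLoci, samplesPerDeme, snpsPerStack = c(0.45, 0.3, 0.15, 0.1),
                      missingRate = 0, locusLength = 150L,
                      muPerYear = ZANTHOXYLUM_MU, gYears = ZANTHOXYLUM_G,
                      seed = 1L) {
  stopifnot(nLoci > 0, all(samplesPerDeme >= 1))
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  structure(list(nLoci = as.integer(nLoci),
                 samplesPerDeme = samplesPerDeme,
                 snpsPerStack = snpsPerStack / sum(snpsPerStack),
                 missingRate = missingRate,
                 locusLength = as.integer(locusLength),
                 muPerYear = muPerYear, gYears = gYears,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# internal: flatten a Demography for the C++ engine
.demographyToEngine <- function(dem) {
  list(nDemes = nrow(dem@demes),
       N0 = dem@demes$size,
       growth0 = dem@demes$growth,
       mig = dem@migration,
       events = dem@events)
}

# internal: haploid sample counts aligned to deme order (input is diploids)
.sampleVector <- function(dem, samplesPerDeme) {
  labs <- dem@demes$label
  s <- integer(length(labs))
  if (is.null(names(samplesPerDeme))) {
    if (length(samplesPerDeme) != length(labs))
      stop("samplesPerDeme must be named or match the number of demes")
    s <- as.integer(samplesPerDeme)
  } else {
    if (!all(names(samplesPerDeme) %in% labs))
      stop("samplesPerDeme names must be deme labels")
    s[match(names(samplesPerDeme), labs)] <- as.integer(samplesPerDeme)
  }
  2L * s
}
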