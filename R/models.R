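#' @include simulate.R
NULL

#' Declare a parameterized demographic model
#'
#' A declarative model builder: a model is a function from free parameters
#' to a \linkS4class{Demography}, plus parameter names, bounds, scales and
#' fixed quantities.  The shipped library (\code{\link{pepperModels}})
#' covers the divergence-model families used for the two pepper species;
#' further topologies are expressed through this constructor.
#'
#' @param id model identifier.
#' @param popLabels sampled deme labels, in SFS dimension order.
#' @param paramNames names of free parameters.
#' @param lower,upper named bounds (natural scale).
#' @param scale per-parameter optimization scale, "log" or "lin".
#' @param fixed named list of fixed quantities available to \code{build}.
#' @param build \code{function(par, fixed)} returning a
#'   \linkS4class{Demography}.
#' @param description free-text description.
#' @return A \code{DemographicModel} (S3 list).
#' @export
demographicModel <- function(id, popLabels, paramNames, lower, upper,
                             build, scale = NULL, fixed = list(),
                             description = "") {
  if (is.null(scale)) scale <- setNames(rep("log", length(paramNames)),
                                        paramNames)
  stopifnot(length(lower) == length(paramNames),
            length(upper) == length(paramNames),
            all(lower < upper))
  structure(list(id = id, popLabels = popLabels, nPops = length(popLabels),
                 paramNames = paramNames,
                 lower = setNames(lower, paramNames),
                 upper = setNames(upper, paramNames),
                 scale = scale, fixed = fixed, build = build,
                 k = length(paramNames), description = description),
            class = "DemographicModel")
}

#' @export
print.DemographicModel <- function(x, ...) {
  cat(sprintf("DemographicModel '%s' (%d demes: %s)\n", x$id, x$nPops,
              paste(x$popLabels, collapse = ", ")))
  cat(sprintf("  free: %s\n  %s\n", paste(x$paramNames, collapse = ", "),
              x$description))
  invisible(x)
}

#' Library of divergence models for the pepper system
#'
#' Two-population models describe the wild/cultivated Z. armatum split (or,
#' with other sizes, the interspecies split); three-population models
#' describe the divergence of the three major Z. bungeanum genetic clades.
#' Time is in generations; sizes are diploid Ne.
#'
#' \describe{
#'   \item{M1_iso}{isolation, constant sizes; free: split time T.}
#'   \item{M2_im}{isolation with symmetric migration; free: T, m.}
#'   \item{M9}{isolation with exponential shrinkage in the cultivated
#'     deme; free: T and the fold-decline (N_ancestral / N_present).}
#'   \item{M11}{M9 plus asymmetric wild-cultivated migration; free: T,
#'     fold, m12, m21.}
#'   \item{M12}{exponential shrinkage in both demes, no gene flow; free:
#'     T, foldCult, foldWild.}
#'   \item{M13}{three clades: II and III split shortly after their common
#'     ancestor split from I; free: older split T1 and gap dT (younger
#'     split T2 = T1 - dT).}
#'   \item{M14, M15}{alternative three-clade join orders.}
#' }
#'
#' @param id model id (see Details).
#' @param fixed named list overriding fixed quantities (e.g. \code{Nw},
#'   \code{Nanc}, \code{N1}, \code{mSym}).
#' @return A \code{DemographicModel}.
#' @export
pepperModels <- function(id, fixed = list()) {
  fx <- function(defaults) {
    defaults[names(fixed)] <- fixed
    defaults
  }
  twoPopDemes <- function(labels, sizes, growth = c(0, 0))
    data.frame(label = labels, size = sizes, growth = growth)
  switch(
    id,
    M1_iso = {
      f <- fx(list(N1 = 5e4, N2 = 5e4, Nanc = 5e4, pops = c("p1", "p2")))
      demographicModel(
        id, f$pops, "T", lower = c(T = 50), upper = c(T = 2e7),
        fixed = f, description = "isolation, constant sizes, no migration",
        build = function(par, fixed) {
          Demography(twoPopDemes(fixed$pops, c(fixed$N1, fixed$N2)),
                     events = list(
                       demeEvent(par[["T"]], "join", 2L, 1L),
                       demeEvent(par[["T"]], "size", 1L, size = fixed$Nanc)))
        })
    },
    M2_im = {
      f <- fx(list(N1 = 5e4, N2 = 5e4, Nanc = 5e4, pops = c("p1", "p2")))
      demographicModel(
        id, f$pops, c("T", "m"),
        lower = c(T = 50, m = 1e-8), upper = c(T = 2e7, m = 1e-2),
        fixed = f, description = "isolation with symmetric migration",
        build = function(par, fixed) {
          mig <- matrix(c(0, par[["m"]], par[["m"]], 0), 2, 2, byrow = TRUE)
          Demography(twoPopDemes(fixed$pops, c(fixed$N1, fixed$N2)),
                     events = list(
                       demeEvent(par[["T"]], "join", 2L, 1L),
                       demeEvent(par[["T"]], "size", 1L, size = fixed$Nanc)),
                     migration = mig)
        })
    },
    M9 = {
      f <- fx(list(Nw = 1e4, Nanc = 1e4, pops = c("wild", "cult")))
      demographicModel(
        id, f$pops, c("T", "fold"),
        lower = c(T = 50, fold = 1.5), upper = c(T = 2e5, fold = 2000),
        fixed = f,
        description = "isolation; exponential shrinkage in the cultivated deme",
        build = function(par, fixed) {
          Tt <- par[["T"]]; fold <- par[["fold"]]
          Demography(twoPopDemes(fixed$pops,
                                 c(fixed$Nw, fixed$Nanc / fold),
                                 growth = c(0, log(1 / fold) / Tt)),
                     events = list(
                       demeEvent(Tt, "join", 2L, 1L),
                       demeEvent(Tt, "size", 1L, size = fixed$Nanc)))
        })
    },
    M11 = {
      f <- fx(list(Nw = 1e4, Nanc = 1e4, pops = c("wild", "cult")))
      demographicModel(
        id, f$pops, c("T", "fold", "m12", "m21"),
        lower = c(T = 50, fold = 1.5, m12 = 1e-8, m21 = 1e-8),
        upper = c(T = 2e5, fold = 2000, m12 = 1e-2, m21 = 1e-2),
        fixed = f,
        description = "cultivated shrinkage with asymmetric migration",
        build = function(par, fixed) {
          Tt <- par[["T"]]; fold <- par[["fold"]]
          mig <- matrix(c(0, par[["m12"]], par[["m21"]], 0), 2, 2,
                        byrow = TRUE)
          Demography(twoPopDemes(fixed$pops,
                                 c(fixed$Nw, fixed$Nanc / fold),
                                 growth = c(0, log(1 / fold) / Tt)),
                     events = list(
                       demeEvent(Tt, "join", 2L, 1L),
                       demeEvent(Tt, "size", 1L, size = fixed$Nanc)),
                     migration = mig)
        })
    },
    M12 = {
      f <- fx(list(Nanc = 1e4, pops = c("wild", "cult")))
      demographicModel(
        id, f$pops, c("T", "foldCult", "foldWild"),
        lower = c(T = 50, foldCult = 1.5, foldWild = 1.01),
        upper = c(T = 2e5, foldCult = 2000, foldWild = 2000),
        fixed = f,
        description = "exponential shrinkage in both demes, no gene flow",
        build = function(par, fixed) {
          Tt <- par[["T"]]
          fc <- par[["foldCult"]]; fw <- par[["foldWild"]]
          Demography(twoPopDemes(fixed$pops,
                                 c(fixed$Nanc / fw, fixed$Nanc / fc),
                                 growth = c(log(1 / fw) / Tt,
                                            log(1 / fc) / Tt)),
                     events = list(
                       demeEvent(Tt, "join", 2L, 1L),
                       demeEvent(Tt, "size", 1L, size = fixed$Nanc)))
        })
    },
    M13 = ,
    M14 = ,
    M15 = {
      # three-clade splits; M13: ((II,III),I); M14: ((I,II),III);
      # M15: ((I,III),II).  Young pair joins first, then into the odd one.
      pair <- switch(id, M13 = c(2L, 3L), M14 = c(1L, 2L), M15 = c(1L, 3L))
      f <- fx(list(N1 = 5e4, N2 = 5e4, N3 = 5e4, Nanc = 5e4, mSym = 0,
                   pops = c("cladeI", "cladeII", "cladeIII")))
      demographicModel(
        id, f$pops, c("T1", "dT"),
        lower = c(T1 = 5e3, dT = 1), upper = c(T1 = 5e5, dT = 5e3),
        fixed = f,
        description = "three-clade divergence; T1 older split, T2 = T1 - dT",
        build = function(par, fixed) {
          T1 <- par[["T1"]]; T2 <- T1 - par[["dT"]]
          odd <- setdiff(1:3, pair)
          mig <- matrix(fixed$mSym, 3, 3); diag(mig) <- 0
          Demography(
            data.frame(label = fixed$pops,
                       size = c(fixed$N1, fixed$N2, fixed$N3)),
            events = list(
              demeEvent(T2, "join", pair[2L], pair[1L]),
              demeEvent(T1, "join", pair[1L], odd),
              demeEvent(T1, "size", odd, size = fixed$Nanc)),
            migration = mig)
        })
    },
    stop(sprintf("unknown model id '%s'", id))
  )
}
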