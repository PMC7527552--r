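#' @include zanpop-package.R
NULL

MISSING_CODE <- NA_integer_

#' SNPMatrix: diploid genotype calls with GBS stack metadata
#'
#' An S4 container extending \linkS4class{SummarizedExperiment}. Rows are
#' SNP sites, columns are accessions.  The \code{"GT"} assay holds integer
#' alternate-allele dosages (0, 1, 2; \code{NA} = missing).  Per-site
#' metadata (\code{rowData}) carries the GBS stack (locus) identifier,
#' the position within the stack in bp, REF/ALT alleles, and the number of
#' alternate alleles seen in the source VCF.  \code{colData$population}
#' holds the population (cultivar/clade) label of each accession.
#'
#' @seealso \code{\link{readVCF}}, \code{\link{filterSites}},
#'   \code{\link{thinOneSNPPerLocus}}
#' @export
setClass("SNPMatrix", contains = "SummarizedExperiment")

setValidity("SNPMatrix", function(object) {
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    return("assay 'GT' is required")
  gt <- SummarizedExperiment::assay(object, "GT")
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    return("genotype codes must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("stack_id", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!"population" %in% colnames(cd))
    return("colData must contain a 'population' column")
  TRUE
})

#' FoldedSFS: a (joint) site-frequency spectrum
#'
#' Holds a 1D or joint (2D/3D) site-frequency spectrum over derived- or
#' minor-allele-count classes.  When \code{folded}, mass sits only in
#' canonical cells (global minor allele; exact-half classes counted once)
#' and \code{mask} marks those cells.  When \code{isProbability}, entries
#' over segregating classes sum to 1.
#'
#' @slot counts numeric array, one dimension per population, dimension
#'   \code{p} having extent \code{sampleSizes[p] + 1}.
#' @slot mask logical array marking canonical (folded) cells.
#' @slot sampleSizes integer haploid (projected) sample sizes.
#' @slot pops character population labels.
#' @slot nSites number of sites that contributed.
#' @slot folded logical.
#' @slot isProbability logical.
#' @export
setClass("FoldedSFS", representation(
  counts = "array", mask = "array", sampleSizes = "integer",
  pops = "character", nSites = "numeric", folded = "logical",
  isProbability = "logical"))

setValidity("FoldedSFS", function(object) {
  d <- dim(object@counts)
  if (is.null(d)) d <- length(object@counts)
  if (!identical(as.integer(d), object@sampleSizes + 1L))
    return("dim(counts) must equal sampleSizes + 1")
  if (length(object@pops) != length(object@sampleSizes))
    return("one population label per dimension required")
  if (any(object@counts < -1e-9, na.rm = TRUE))
    return("counts must be non-negative")
  TRUE
})

#' Demography: a multi-deme demographic model
#'
#' Describes demes with present-day diploid sizes and exponential growth
#' rates, a backward-time event list (joins, size changes, migration-matrix
#' changes) and a migration matrix.  Time is in generations, sizes are
#' diploid effective sizes, growth rates are forward per-generation
#' exponential rates, and migration rates are backward per-lineage
#' per-generation probabilities.
#'
#' @slot demes data.frame with columns \code{label}, \code{size},
#'   \code{growth}.
#' @slot events list of events from \code{\link{demeEvent}}.
#' @slot migration numeric matrix (deme x deme backward rates).
#' @export
setClass("Demography", representation(
  demes = "data.frame", events = "list", migration = "matrix"))

setValidity("Demography", function(object) {
  d <- object@demes
  if (!all(c("label", "size", "growth") %in% names(d)))
    return("demes needs columns label, size, growth")
  if (any(d$size <= 0)) return("deme sizes must be positive")
  if (anyDuplicated(d$label)) return("deme labels must be unique")
  nd <- nrow(d)
  if (!identical(dim(object@migration), c(nd, nd)))
    return("migration matrix must be nDemes x nDemes")
  if (any(object@migration < 0)) return("migration rates must be >= 0")
  tm <- vapply(object@events, function(e) e$time, 0)
  if (any(tm < 0)) return("event times must be non-negative")
  # connectivity: every deme must reach a single component through
  # migration (any epoch) or join events, else lineages never coalesce
  adj <- (object@migration > 0) | t(object@migration > 0)
  for (e in object@events) {
    if (e$type == "join") adj[e$d1, e$d2] <- adj[e$d2, e$d1] <- TRUE
    if (e$type == "migration") adj <- adj | (e$mig > 0) | t(e$mig > 0)
  }
  comp <- seq_len(nd)
  repeat {
    new <- comp
    for (i in seq_len(nd)) for (j in seq_len(nd))
      if (adj[i, j]) new[i] <- new[j] <- min(new[i], new[j])
    if (identical(new, comp)) break
    comp <- new
  }
  if (length(unique(comp)) > 1L)
    return("demography never coalesces to one ancestral deme (disconnected demes)")
  TRUE
})

#' FreqMatrix: per-population allele frequencies with jackknife blocks
#'
#' The frequency layer shared by all f-statistics: per population and site,
#' the observed alternate-allele frequency and the number of observed allele
#' copies, plus a contiguous jackknife block assignment per site.
#'
#' @slot p numeric matrix (populations x sites) of allele frequencies.
#' @slot k integer matrix of observed allele copies.
#' @slot blockID integer block per site (contiguous in site order).
#' @slot siteInfo data.frame with \code{stack_id} and \code{pos}.
#' @export
setClass("FreqMatrix", representation(
  p = "matrix", k = "matrix", blockID = "integer", siteInfo = "data.frame"))

setValidity("FreqMatrix", function(object) {
  if (!identical(dim(object@p), dim(object@k)))
    return("p and k must have identical dimensions")
  if (any(object@p < -1e-9 | object@p > 1 + 1e-9, na.rm = TRUE))
    return("frequencies must lie in [0, 1]")
  if (length(object@blockID) != ncol(object@p))
    return("one block id per site required")
  if (is.unsorted(object@blockID))
    return("block ids must be contiguous in site order")
  TRUE
})

#' AdmixtureGraph: a rooted admixture graph
#'
#' A rooted DAG whose leaves are populations.  Drift edges carry lengths in
#' f2 units (reported as 1000 x FST-scale drift units); admixture nodes have
#' exactly two parents via "admix" edges carrying mixture proportions that
#' sum to 1.  \code{NA} lengths/weights are free parameters to be fitted.
#'
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{type}
#'   ("drift" or "admix"), \code{length}, \code{weight}.
#' @slot leaves character leaf (population) labels.
#' @export
setClass("AdmixtureGraph",
         representation(edges = "data.frame", leaves = "character"))

setValidity("AdmixtureGraph", function(object) {
  ed <- object@edges
  need <- c("from", "to", "type", "length", "weight")
  if (!all(need %in% names(ed)))
    return(paste("edges needs columns:", paste(need, collapse = ", ")))
  nodes <- union(ed$from, ed$to)
  roots <- setdiff(nodes, ed$to)
  if (length(roots) != 1L) return("graph must have exactly one root")
  if (any(ed$length < 0, na.rm = TRUE)) return("drift lengths must be >= 0")
  # admixture nodes: exactly 2 admix parents, weights sum to 1 (or free)
  for (v in unique(ed$to)) {
    inc <- ed[ed$to == v, ]
    if (nrow(inc) > 1L) {
      if (nrow(inc) != 2L || !all(inc$type == "admix"))
        return(sprintf("node '%s': multiple parents must be 2 admix edges", v))
      w <- inc$weight
      if (!anyNA(w) && abs(sum(w) - 1) > 1e-8)
        return(sprintf("node '%s': admixture proportions must sum to 1", v))
      if (!anyNA(w) && any(w <= 0 | w >= 1))
        return(sprintf("node '%s': admixture proportions must be in (0,1)", v))
    }
  }
  # acyclicity via topological sort
  if (is.null(.topoSort(ed))) return("graph must be acyclic")
  if (!all(object@leaves %in% nodes)) return("all leaves must appear in edges")
  TRUE
})

# internal: topological order of nodes (NULL if cyclic)
.topoSort <- function(edges) {
  nodes <- union(edges$from, edges$to)
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  q <- names(indeg)[indeg == 0L]
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    out <- c(out, v)
    ch <- edges$to[edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) q <- c(q, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' NeTrajectory: a piecewise-constant effective-size history
#'
#' @slot times numeric interval start times (generations, ascending).
#' @slot Ne numeric diploid effective size per interval.
#' @slot envelope data.frame of bootstrap median/75\%/95\% bands on a
#'   common time grid (possibly empty).
#' @slot mu per-site per-year mutation rate used for calibration.
#' @slot g generation time in years.
#' @export
setClass("NeTrajectory", representation(
  times = "numeric", Ne = "numeric", envelope = "data.frame",
  mu = "numeric", g = "numeric"))

setValidity("NeTrajectory", function(object) {
  if (any(object@Ne <= 0)) return("Ne must be positive")
  if (is.unsorted(object@times, strictly = TRUE))
    return("interval start times must be strictly increasing")
  if (length(object@times) != length(object@Ne))
    return("times and Ne must have equal length")
  TRUE
})

#' ModelFit: a fitted demographic model
#'
#' @slot modelID model identifier.
#' @slot par named numeric parameter estimates.
#' @slot logLik maximum composite log-likelihood.
#' @slot k number of free parameters.
#' @slot AIC 2k - 2 lnL.
#' @slot nSites number of segregating sites in the fitted SFS.
#' @slot trace data.frame optimization trace (start, cycle, logLik).
#' @slot details list (bounds, seed, config, data fingerprint).
#' @export
setClass("ModelFit", representation(
  modelID = "character", par = "numeric", logLik = "numeric",
  k = "integer", AIC = "numeric", nSites = "numeric",
  trace = "data.frame", details = "list"))

setValidity("ModelFit", function(object) {
  if (abs(object@AIC - (2 * object@k - 2 * object@logLik)) > 1e-6)
    return("AIC inconsistent with logLik and k")
  TRUE
})
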