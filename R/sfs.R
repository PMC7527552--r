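#' @include simulate.R
NULL

#' Fold a site-frequency spectrum over the global minor allele
#'
#' Joint spectra are folded over the pooled (global) minor allele: cell
#' \code{c} and its complement \code{n - c} are merged into the canonical
#' cell (total derived count below half; exact-half ties resolved to the
#' lexicographically smaller cell, counted once).  Folding is idempotent.
#'
#' @param sfs a \linkS4class{FoldedSFS} (folded or not).
#' @return A folded \linkS4class{FoldedSFS}.
#' @export
foldSFS <- function(sfs) {
  if (sfs@folded) return(sfs)
  dims <- dim(sfs@counts)
  idx <- .cellCounts(dims)
  n <- sfs@sampleSizes
  ntot <- sum(n)
  tot <- rowSums(idx)
  comp <- sweep(-idx, 2L, n, "+")
  stride <- c(1, cumprod(dims)[-length(dims)])
  compLin <- as.vector(comp %*% stride) + 1L
  lexLess <- rep(FALSE, nrow(idx))
  undecided <- rep(TRUE, nrow(idx))
  for (j in seq_len(ncol(idx))) {
    lexLess[undecided & idx[, j] < comp[, j]] <- TRUE
    undecided <- undecided & idx[, j] == comp[, j]
  }
  canonical <- (2 * tot < ntot) | (2 * tot == ntot & (lexLess | undecided))
  target <- ifelse(canonical, seq_len(nrow(idx)), compLin)
  cnt <- as.vector(sfs@counts)
  folded <- numeric(length(cnt))
  agg <- rowsum(cnt, target)
  folded[as.integer(rownames(agg))] <- agg[, 1L]
  sfs@counts <- array(folded, dim = dims)
  sfs@mask <- array(canonical, dim = dims)
  sfs@folded <- TRUE
  sfs
}

# internal: per-population hypergeometric projection masses.
# Returns list(H = list of nSites x (proj+1) matrices, use = usable sites).
.sfsParts <- function(x, pops, projections) {
  gt <- genotypes(x)
  pm <- popMap(x)
  missingPops <- setdiff(pops, pm)
  if (length(missingPops))
    stop("populations not in pop map: ", paste(missingPops, collapse = ", "))
  nDip <- vapply(pops, function(p) sum(pm == p), 0L)
  if (is.null(projections))
    projections <- pmax(2L, as.integer(floor(0.9 * 2L * nDip)))
  projections <- as.integer(projections)
  if (any(projections <= 0L)) stop("projections must be positive")
  if (any(projections > 2L * nDip))
    stop("projection exceeds available allele copies (2 x diploids)")
  A <- K <- matrix(0L, nrow(gt), length(pops))
  for (i in seq_along(pops)) {
    sub <- gt[, pm == pops[i], drop = FALSE]
    K[, i] <- 2L * as.integer(rowSums(!is.na(sub)))
    A[, i] <- as.integer(rowSums(sub, na.rm = TRUE))
  }
  use <- rowSums(K >= rep(projections, each = nrow(gt))) == length(pops)
  H <- lapply(seq_along(pops), function(i) {
    a <- A[use, i]; k <- K[use, i]; pr <- projections[i]
    matrix(vapply(0:pr, function(j) dhyper(j, a, k - a, pr),
                  numeric(sum(use))), ncol = pr + 1L)
  })
  list(H = H, use = use, projections = projections,
       stacks = stackID(x)[use], pops = pops)
}

# internal: combine projection masses (optionally site-weighted) into an
# unfolded joint SFS array
.combineParts <- function(parts, w = NULL) {
  H <- parts$H
  if (!is.null(w)) H[[1L]] <- H[[1L]] * w
  if (length(H) == 1L) {
    arr <- array(colSums(H[[1L]]), dim = ncol(H[[1L]]))
  } else if (length(H) == 2L) {
    arr <- crossprod(H[[1L]], H[[2L]])
    arr <- array(arr, dim = dim(arr))
  } else if (length(H) == 3L) {
    d3 <- ncol(H[[3L]])
    arr <- array(0, dim = c(ncol(H[[1L]]), ncol(H[[2L]]), d3))
    for (j in seq_len(d3))
      arr[, , j] <- crossprod(H[[1L]] * H[[3L]][, j], H[[2L]])
  } else stop("joint SFS supported for up to 3 populations")
  arr
}

#' Build a folded (joint) site-frequency spectrum with projection
#'
#' Each usable site contributes its hypergeometric-projection mass over
#' derived-count classes, treating the observed allele copies as the urn
#' (deterministic fractional projection; sites with fewer observed copies
#' than the projection in any population are skipped).  The joint spectrum
#' is then folded over the global minor allele.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param pops character: 1-3 population labels.
#' @param projections haploid projection sizes per population (default 90\%
#'   of the available 2 x diploids, the convention used when the authors'
#'   settings are unknown).
#' @param fold fold the spectrum (default TRUE).
#' @return A \linkS4class{FoldedSFS} of site counts.
#' @export
foldedSFS <- function(x, pops, projections = NULL, fold = TRUE) {
  parts <- .sfsParts(x, pops, projections)
  arr <- .combineParts(parts)
  sfs <- new("FoldedSFS", counts = arr,
             mask = array(TRUE, dim = parts$projections + 1L),
             sampleSizes = parts$projections, pops = parts$pops,
             nSites = sum(parts$use), folded = FALSE, isProbability = FALSE)
  if (fold) foldSFS(sfs) else sfs
}

#' Bootstrap replicates of a folded SFS
#'
#' Resamples GBS stacks (not individual SNPs) with replacement, respecting
#' within-stack linkage as the exchangeable unit, and rebuilds the folded
#' SFS for each replicate.  Deterministic per seed.
#'
#' @inheritParams foldedSFS
#' @param nReps number of replicates (>= 1).
#' @param seed integer seed.
#' @param .resample internal test hook: a \code{function(nStacks)}
#'   returning stack indices (default: uniform resampling with
#'   replacement).
#' @return A list of \linkS4class{FoldedSFS}.
#' @export
bootstrapSFS <- function(x, pops, projections = NULL, nReps = 200L,
                         seed = 1L, .resample = NULL) {
  stopifnot(nReps >= 1)
  parts <- .sfsParts(x, pops, projections)
  ustacks <- unique(parts$stacks)
  siteStack <- match(parts$stacks, ustacks)
  set.seed(as.integer(seed))
  lapply(seq_len(nReps), function(r) {
    pick <- if (is.null(.resample))
      sample.int(length(ustacks), replace = TRUE) else .resample(length(ustacks))
    mult <- tabulate(pick, nbins = length(ustacks))
    w <- mult[siteStack]
    arr <- .combineParts(parts, w = w)
    sfs <- new("FoldedSFS", counts = arr,
               mask = array(TRUE, dim = parts$projections + 1L),
               sampleSizes = parts$projections, pops = parts$pops,
               nSites = sum(w), folded = FALSE, isProbability = FALSE)
    foldSFS(sfs)
  })
}

#' Marginalize an unfolded joint SFS over all but one population
#'
#' @param sfs an unfolded joint \linkS4class{FoldedSFS}.
#' @param pop population to keep.
#' @return A 1D unfolded \linkS4class{FoldedSFS}.
#' @export
marginalizeSFS <- function(sfs, pop) {
  if (sfs@folded)
    stop("marginalization is defined on the unfolded spectrum (fold after)")
  i <- match(pop, sfs@pops)
  if (is.na(i)) stop("population not in SFS")
  cnt <- apply(sfs@counts, i, sum)
  new("FoldedSFS", counts = array(cnt, dim = length(cnt)),
      mask = array(TRUE, dim = length(cnt)),
      sampleSizes = sfs@sampleSizes[i], pops = sfs@pops[i],
      nSites = sfs@nSites, folded = FALSE,
      isProbability = sfs@isProbability)
}

#' Write / read an SFS in flat dadi-style text
#'
#' Line 1: dimensions plus a "folded"/"unfolded" token and metadata; line
#' 2: counts in column-major order; line 3: the fold mask (1 = canonical).
#'
#' @param sfs a \linkS4class{FoldedSFS}.
#' @param path file path.
#' @export
writeSFS <- function(sfs, path) {
  hdr <- paste(c(dim(sfs@counts),
                 if (sfs@folded) "folded" else "unfolded",
                 paste0("pops=", paste(sfs@pops, collapse = ",")),
                 paste0("nSites=", format(sfs@nSites)),
                 paste0("prob=", sfs@isProbability)), collapse = " ")
  writeLines(c(hdr,
               paste(format(as.vector(sfs@counts), digits = 17), collapse = " "),
               paste(as.integer(as.vector(sfs@mask)), collapse = " ")), path)
  invisible(path)
}

#' @rdname writeSFS
#' @export
readSFS <- function(path) {
  ln <- readLines(path)
  tok <- strsplit(ln[1L], " +")[[1L]]
  nd <- max(which(!is.na(suppressWarnings(as.integer(tok)))))
  dims <- as.integer(tok[seq_len(nd)])
  folded <- "folded" %in% tok
  pops <- sub("pops=", "", tok[startsWith(tok, "pops=")])
  pops <- strsplit(pops, ",")[[1L]]
  nSites <- as.numeric(sub("nSites=", "", tok[startsWith(tok, "nSites=")]))
  prob <- as.logical(sub("prob=", "", tok[startsWith(tok, "prob=")]))
  cnt <- as.numeric(strsplit(ln[2L], " +")[[1L]])
  msk <- as.logical(as.integer(strsplit(ln[3L], " +")[[1L]]))
  new("FoldedSFS", counts = array(cnt, dim = dims),
      mask = array(msk, dim = dims), sampleSizes = dims - 1L,
      pops = pops, nSites = nSites, folded = folded,
      isProbability = isTRUE(prob))
}
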