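#' @include fstats.R
NULL

#' Construct an admixture graph
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{type} ("drift" or "admix"), \code{length} (drift length in f2
#'   units; \code{NA} = free), \code{weight} (mixture proportion for admix
#'   edges; \code{NA} = free).
#' @param leaves leaf labels (default: nodes with no outgoing edges).
#' @return An \linkS4class{AdmixtureGraph}.
#' @export
admixtureGraph <- function(edges, leaves = NULL) {
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$type)) edges$type <- "drift"
  if (is.null(edges$length)) edges$length <- NA_real_
  if (is.null(edges$weight)) edges$weight <- NA_real_
  if (is.null(leaves)) leaves <- setdiff(edges$to, edges$from)
  new("AdmixtureGraph", edges = edges, leaves = as.character(leaves))
}

#' Build a rooted tree graph from a nested list topology
#'
#' @param topology nested list / character structure, e.g.
#'   \code{list("outgroup", list(list("A", "B"), "C"))}.
#' @return An \linkS4class{AdmixtureGraph} with free edge lengths.
#' @export
treeGraph <- function(topology) {
  counter <- new.env(); counter$i <- 0L
  edges <- list()
  build <- function(node) {
    if (is.character(node)) return(node)
    counter$i <- counter$i + 1L
    me <- sprintf("n%d", counter$i)
    for (ch in node) {
      chName <- build(ch)
      edges[[length(edges) + 1L]] <<- data.frame(
        from = me, to = chName, type = "drift",
        length = NA_real_, weight = NA_real_)
    }
    me
  }
  root <- build(topology)
  ed <- do.call(rbind, edges)
  ed$from[ed$from == root] <- "root"
  admixtureGraph(ed)
}

#' Enumerate the complete f-statistic basis over n populations
#'
#' All distinct f2 (unordered pairs), f3 (ordered target with unordered
#' source pair) and f4 (unordered quadruples times three pairings)
#' statistics; the count is
#' \eqn{C(n,2) + n C(n-1,2) + 3 C(n,4)}.
#'
#' @param pops population labels, or a single integer n >= 2.
#' @return List with \code{count} and \code{table} (data.frame kind,
#'   pop1..pop4).
#' @export
enumerateFStats <- function(pops) {
  if (is.numeric(pops) && length(pops) == 1L)
    pops <- sprintf("P%d", seq_len(pops))
  n <- length(pops)
  if (n < 2L) stop("need at least 2 populations")
  rows <- list()
  prs <- combn(pops, 2L)
  for (j in seq_len(ncol(prs)))
    rows[[length(rows) + 1L]] <- c("f2", prs[1L, j], prs[2L, j], NA, NA)
  if (n >= 3L) for (tg in pops) {
    src <- combn(setdiff(pops, tg), 2L)
    for (j in seq_len(ncol(src)))
      rows[[length(rows) + 1L]] <- c("f3", tg, src[1L, j], src[2L, j], NA)
  }
  if (n >= 4L) {
    quads <- combn(pops, 4L)
    for (j in seq_len(ncol(quads))) {
      q <- quads[, j]
      # three pairings of a quadruple: (12|34), (13|24), (14|23)
      rows[[length(rows) + 1L]] <- c("f4", q[1L], q[2L], q[3L], q[4L])
      rows[[length(rows) + 1L]] <- c("f4", q[1L], q[3L], q[2L], q[4L])
      rows[[length(rows) + 1L]] <- c("f4", q[1L], q[4L], q[2L], q[3L])
    }
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c("kind", "pop1", "pop2", "pop3", "pop4")
  list(count = nrow(tab), table = tab)
}

# internal: leaf x edge traversal-probability matrix of a fully
# parameterized graph; rows ordered as g@leaves
.traversalMatrix <- function(g) {
  ed <- g@edges
  ord <- .topoSort(ed)           # root first
  mu <- matrix(0, length(g@leaves), nrow(ed),
               dimnames = list(g@leaves, NULL))
  for (li in seq_along(g@leaves)) {
    a <- setNames(numeric(length(ord)), ord)
    a[g@leaves[li]] <- 1
    for (v in rev(ord)) {        # leaves first
      if (a[v] == 0) next
      inc <- which(ed$to == v)
      for (e in inc) {
        w <- if (ed$type[e] == "admix") ed$weight[e] else 1
        mu[li, e] <- mu[li, e] + a[v] * w
        a[ed$from[e]] <- a[ed$from[e]] + a[v] * w
      }
    }
  }
  mu
}

#' Predict f-statistics from an admixture graph
#'
#' f2 between two leaves is the sum over drift edges of edge length times
#' the squared difference in expected traversal probability of the two
#' lineages (admixture nodes mix parental paths by their proportions);
#' f3 and f4 follow by the standard linear identities.
#'
#' @param g a fully parameterized \linkS4class{AdmixtureGraph} (no free
#'   lengths/weights).
#' @param stats data.frame as from \code{\link{enumerateFStats}}
#'   (default: the full basis over the graph's leaves).
#' @return The \code{stats} table with a \code{predicted} column.
#' @export
predictFStats <- function(g, stats = NULL) {
  ed <- g@edges
  if (anyNA(ed$length[ed$type == "drift"]) ||
      anyNA(ed$weight[ed$type == "admix"]))
    stop("graph has free parameters; fit it first")
  if (is.null(stats)) stats <- enumerateFStats(g@leaves)$table
  miss <- setdiff(unique(na.omit(unlist(stats[, -1L]))), g@leaves)
  if (length(miss))
    stop("populations not in graph: ", paste(miss, collapse = ", "))
  mu <- .traversalMatrix(g)
  len <- ifelse(ed$type == "drift", ed$length, 0)
  f2mat <- matrix(0, length(g@leaves), length(g@leaves),
                  dimnames = list(g@leaves, g@leaves))
  for (i in seq_along(g@leaves)) for (j in seq_len(i))
    f2mat[i, j] <- f2mat[j, i] <- sum(len * (mu[i, ] - mu[j, ])^2)
  stats$predicted <- .statFromF2(stats, f2mat)
  stats
}

# internal: evaluate f2/f3/f4 rows from an f2 matrix via linear identities
.statFromF2 <- function(stats, f2mat) {
  vapply(seq_len(nrow(stats)), function(i) {
    r <- stats[i, ]
    switch(r$kind,
      f2 = f2mat[r$pop1, r$pop2],
      f3 = 0.5 * (f2mat[r$pop1, r$pop2] + f2mat[r$pop1, r$pop3] -
                    f2mat[r$pop2, r$pop3]),
      f4 = 0.5 * (f2mat[r$pop1, r$pop4] + f2mat[r$pop2, r$pop3] -
                    f2mat[r$pop1, r$pop3] - f2mat[r$pop2, r$pop4]),
      stop("unknown statistic kind"))
  }, 0)
}

#' Precompute observed f-statistic block sums for graph fitting
#'
#' Computes, on the common set of sites usable in every population,
#' per-jackknife-block sums of bias-corrected squared frequency
#' differences for all population pairs.  Every f2/f3/f4 statistic is a
#' fixed linear combination of these pair sums, so estimates and
#' block-jackknife standard errors for arbitrarily many statistics cost
#' one matrix product.
#'
#' @param f a \linkS4class{FreqMatrix}.
#' @param pops populations to include (default all).
#' @return An \code{FStatSet} (S3).
#' @export
fStatSet <- function(f, pops = popNames(f)) {
  use <- .usableSites(f, pops)
  blocks <- f@blockID[use]
  ub <- sort(unique(blocks))
  bi <- match(blocks, ub)
  prs <- combn(pops, 2L)
  S2 <- matrix(0, ncol(prs), length(ub))
  for (j in seq_len(ncol(prs))) {
    v <- .f2Site(f, prs[1L, j], prs[2L, j])[use]
    S2[j, ] <- vapply(split(v, bi), sum, 0)
  }
  nB <- as.vector(table(bi))
  structure(list(S2 = S2, nB = nB, pops = pops,
                 pairs = t(prs),
                 pairKey = paste(pmin(prs[1L, ], prs[2L, ]),
                                 pmax(prs[1L, ], prs[2L, ]), sep = "|")),
            class = "FStatSet")
}

#' Build an FStatSet from an exact f2 matrix
#'
#' Constructs a pseudo observed set whose every block reproduces the given
#' f2 values exactly (jackknife SE ~ 0 up to the stated \code{se}); used
#' for noiseless round-trip tests and for fitting to externally computed
#' f2 tables.
#'
#' @param f2mat symmetric matrix of f2 values (dimnames = populations).
#' @param se standard error to attach to every statistic.
#' @return An \code{FStatSet}.
#' @export
fStatSetFromF2 <- function(f2mat, se = 1e-6) {
  pops <- rownames(f2mat)
  prs <- combn(pops, 2L)
  vals <- vapply(seq_len(ncol(prs)), function(j)
    f2mat[prs[1L, j], prs[2L, j]], 0)
  nB <- c(100L, 100L)
  S2 <- cbind(vals * nB[1L], vals * nB[2L])
  structure(list(S2 = S2, nB = nB, pops = pops, pairs = t(prs),
                 pairKey = paste(pmin(prs[1L, ], prs[2L, ]),
                                 pmax(prs[1L, ], prs[2L, ]), sep = "|"),
                 fixedSE = se),
            class = "FStatSet")
}

# internal: linear-combination matrix over pairs for a stats table
.lambdaMatrix <- function(stats, fs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  L <- matrix(0, nrow(stats), nrow(fs$pairs))
  idx <- function(a, b) match(key(a, b), fs$pairKey)
  for (i in seq_len(nrow(stats))) {
    r <- stats[i, ]
    if (r$kind == "f2") {
      L[i, idx(r$pop1, r$pop2)] <- 1
    } else if (r$kind == "f3") {
      L[i, idx(r$pop1, r$pop2)] <- L[i, idx(r$pop1, r$pop3)] <- 0.5
      L[i, idx(r$pop2, r$pop3)] <- -0.5
    } else if (r$kind == "f4") {
      L[i, idx(r$pop1, r$pop4)] <- L[i, idx(r$pop2, r$pop3)] <- 0.5
      L[i, idx(r$pop1, r$pop3)] <- L[i, idx(r$pop2, r$pop4)] <- -0.5
    }
  }
  L
}

#' Estimate f-statistics (with jackknife SE) from an FStatSet
#'
#' @param fs an \code{FStatSet}.
#' @param stats data.frame of statistics (kind, pop1..pop4); default all
#'   f2 pairs.
#' @return \code{stats} with \code{estimate}, \code{se} columns.
#' @export
estimateFStats <- function(fs, stats = NULL) {
  if (is.null(stats))
    stats <- data.frame(kind = "f2", pop1 = fs$pairs[, 1L],
                        pop2 = fs$pairs[, 2L], pop3 = NA, pop4 = NA)
  L <- .lambdaMatrix(stats, fs)
  tot <- rowSums(fs$S2)
  N <- sum(fs$nB)
  est <- as.vector(L %*% tot) / N
  # weighted delete-one-block jackknife, vectorized over statistics
  delNum <- sweep(-(L %*% fs$S2), 1L, as.vector(L %*% tot), "+")
  delEst <- sweep(delNum, 2L, N - fs$nB, "/")
  g <- length(fs$nB)
  h <- N / fs$nB
  thetaTilde <- g * est - as.vector(delEst %*% (1 - fs$nB / N))
  tau <- outer(est, h) - sweep(delEst, 2L, h - 1, "*")
  varJ <- as.vector(((tau - thetaTilde)^2) %*% (1 / (h - 1))) / g
  stats$estimate <- est
  stats$se <- if (is.null(fs$fixedSE)) sqrt(varJ) else
    rep(fs$fixedSE, length(est))
  stats
}

#' Fit an admixture graph to observed f-statistics
#'
#' Free drift lengths and admixture proportions are optimized to minimize
#' the weighted squared residuals of the spanning f2 basis (all leaf
#' pairs, weighted by jackknife SE), with box constraints (lengths >= 0,
#' proportions in (0,1)), from several seeded starts.  Residual Z-scores
#' are then reported for the full enumerated f2/f3/f4 set; the fit score
#' is the largest |Z|.  A rank check of the prediction Jacobian at a
#' random interior point warns about non-identifiable parameterizations.
#'
#' @param g an \linkS4class{AdmixtureGraph} (free parameters as NA).
#' @param fs an \code{FStatSet} covering the graph's leaves.
#' @param starts number of optimizer starts.
#' @param seed integer seed.
#' @return A \code{GraphFit} (S3): fitted graph, residual table, maxZ,
#'   worst statistic.
#' @export
fitGraph <- function(g, fs, starts = 5L, seed = 1L) {
  ed <- g@edges
  # only the sum of the two root-adjacent drift lengths is identifiable
  # from f-statistics: pin one of them to zero (standard convention)
  root <- setdiff(ed$from, ed$to)
  rootOut <- which(ed$from == root & ed$type == "drift")
  if (length(rootOut) == 2L && all(is.na(ed$length[rootOut])))
    ed$length[rootOut[2L]] <- 0
  freeLen <- which(ed$type == "drift" & is.na(ed$length))
  admNodes <- unique(ed$to[ed$type == "admix" & is.na(ed$weight)])
  nPar <- length(freeLen) + length(admNodes)
  obsF2 <- estimateFStats(fs)
  li <- match(g@leaves, fs$pops)
  if (anyNA(li)) stop("FStatSet does not cover all graph leaves")
  obsF2 <- obsF2[obsF2$pop1 %in% g@leaves & obsF2$pop2 %in% g@leaves, ]
  ub <- 5 * max(obsF2$estimate, 1e-6)
  assemble <- function(par) {
    ed2 <- ed
    ed2$length[freeLen] <- par[seq_along(freeLen)]
    for (i in seq_along(admNodes)) {
      w <- par[length(freeLen) + i]
      ai <- which(ed2$to == admNodes[i] & ed2$type == "admix")
      ed2$weight[ai] <- c(w, 1 - w)
    }
    g2 <- g; g2@edges <- ed2
    g2
  }
  predF2 <- function(par) {
    gg <- assemble(par)
    mu <- .traversalMatrix(gg)
    len <- ifelse(gg@edges$type == "drift", gg@edges$length, 0)
    vapply(seq_len(nrow(obsF2)), function(i) {
      a <- obsF2$pop1[i]; b <- obsF2$pop2[i]
      sum(len * (mu[a, ] - mu[b, ])^2)
    }, 0)
  }
  obj <- function(par)
    sum(((obsF2$estimate - predF2(par)) / pmax(obsF2$se, 1e-9))^2)
  lower <- c(rep(0, length(freeLen)), rep(0.02, length(admNodes)))
  upper <- c(rep(ub, length(freeLen)), rep(0.98, length(admNodes)))
  if (nPar == 0L) {
    best <- list(par = numeric(0), value = obj(numeric(0)))
  } else {
    # identifiability: Jacobian rank at a random interior point
    set.seed(deriveSeed(seed, "ident"))
    p0 <- lower + runif(nPar) * (upper - lower)
    eps <- 1e-6
    J <- vapply(seq_len(nPar), function(j) {
      pp <- p0; pp[j] <- pp[j] + eps
      (predF2(pp) - predF2(p0)) / eps
    }, numeric(nrow(obsF2)))
    if (qr(J)$rank < nPar)
      warning("graph parameterization appears non-identifiable (rank-deficient Jacobian); best-effort fit returned")
    best <- NULL
    for (s in seq_len(starts)) {
      set.seed(deriveSeed(seed, paste0("graphstart", s)))
      p0 <- lower + runif(nPar) * (upper - lower)
      o <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e7))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  gFit <- assemble(best$par)
  full <- enumerateFStats(g@leaves)$table
  obsFull <- estimateFStats(fs, full)
  pred <- predictFStats(gFit, full)
  resid <- obsFull
  resid$predicted <- pred$predicted
  resid$Z <- (resid$estimate - resid$predicted) / pmax(resid$se, 1e-12)
  worst <- which.max(abs(resid$Z))
  structure(list(graph = gFit, par = best$par, objective = best$value,
                 residuals = resid, maxZ = max(abs(resid$Z)),
                 worst = resid[worst, ]), class = "GraphFit")
}

#' @export
print.GraphFit <- function(x, ...) {
  cat(sprintf("GraphFit: max|Z| = %.3f over %d statistics (objective %.3f)\n",
              x$maxZ, nrow(x$residuals), x$objective))
  cat("  worst:", x$worst$kind,
      paste(na.omit(unlist(x$worst[paste0("pop", 1:4)])), collapse = ","),
      sprintf("Z = %.2f\n", x$worst$Z))
  invisible(x)
}

# internal: attach `leaf` to drift edge e by splitting it
.attachLeafToEdge <- function(g, leaf, e) {
  ed <- g@edges
  nn <- sprintf("n%d", max(0L, suppressWarnings(
    max(as.integer(sub("^n", "", grep("^n[0-9]+$", c(ed$from, ed$to),
                                      value = TRUE))), na.rm = TRUE))) + 1L)
  mid <- data.frame(from = c(ed$from[e], nn, nn), to = c(nn, ed$to[e], leaf),
                    type = "drift", length = NA_real_, weight = NA_real_)
  admixtureGraph(rbind(ed[-e, ], mid), leaves = c(g@leaves, leaf))
}

# internal: attach `leaf` as a 2-parent admixture child of edges e1, e2
.attachLeafAdmix <- function(g, leaf, e1, e2) {
  ed <- g@edges
  usedIds <- suppressWarnings(
    as.integer(sub("^n", "", grep("^n[0-9]+$", c(ed$from, ed$to), value = TRUE))))
  base <- max(0L, max(usedIds, na.rm = TRUE))
  n1 <- sprintf("n%d", base + 1L)
  n2 <- sprintf("n%d", base + 2L)
  am <- sprintf("n%d", base + 3L)
  new_edges <- rbind(
    data.frame(from = c(ed$from[e1], n1), to = c(n1, ed$to[e1]),
               type = "drift", length = NA_real_, weight = NA_real_),
    data.frame(from = c(ed$from[e2], n2), to = c(n2, ed$to[e2]),
               type = "drift", length = NA_real_, weight = NA_real_),
    data.frame(from = c(n1, n2), to = c(am, am), type = "admix",
               length = 0, weight = NA_real_),
    data.frame(from = am, to = leaf, type = "drift", length = NA_real_,
               weight = NA_real_))
  admixtureGraph(rbind(ed[-c(e1, e2), ], new_edges),
                 leaves = c(g@leaves, leaf))
}

#' Incremental admixture-graph search
#'
#' Starts from a skeleton tree of an outgroup plus three populations
#' (best of the three possible ingroup topologies), then adds the
#' remaining populations one at a time: each candidate placement (every
#' drift edge; optionally every pair of drift edges as a two-parent
#' admixture) is fitted and the placement with the smallest max|Z| is
#' retained.  Ties are broken by fewer admixture events, then by edge
#' order.  Deterministic per seed.
#'
#' @param fs an \code{FStatSet} covering all populations.
#' @param skeleton 4 labels: outgroup first, then three populations.
#' @param remaining further populations in addition order (default: the
#'   rest of \code{fs$pops}).
#' @param tryAdmixture also consider two-parent admixture placements.
#' @param starts optimizer starts per candidate fit.
#' @param seed integer seed.
#' @return List with \code{fit} (final \code{GraphFit}) and \code{log}
#'   (data.frame of per-step decisions).
#' @export
incrementalSearch <- function(fs, skeleton, remaining = NULL,
                              tryAdmixture = TRUE, starts = 3L, seed = 1L) {
  stopifnot(length(skeleton) == 4L)
  if (is.null(remaining)) remaining <- setdiff(fs$pops, skeleton)
  og <- skeleton[1L]; abc <- skeleton[-1L]
  topos <- list(
    list(og, list(list(abc[1L], abc[2L]), abc[3L])),
    list(og, list(list(abc[1L], abc[3L]), abc[2L])),
    list(og, list(list(abc[2L], abc[3L]), abc[1L])))
  fits <- lapply(topos, function(tp) fitGraph(treeGraph(tp), fs,
                                              starts = starts, seed = seed))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "maxZ"))]]
  log <- data.frame(step = "skeleton", pop = NA, placement = NA,
                    maxZ = best$maxZ)
  for (pop in remaining) {
    g <- best$graph
    # reset fitted values to free for refitting
    g@edges$length[g@edges$type == "drift"] <- NA_real_
    g@edges$weight[g@edges$type == "admix"] <- NA_real_
    drift <- which(g@edges$type == "drift")
    cands <- list()
    for (e in drift)
      cands[[length(cands) + 1L]] <-
        list(g = .attachLeafToEdge(g, pop, e), admix = FALSE,
             id = sprintf("edge%d", e))
    if (tryAdmixture && length(drift) >= 2L) {
      prs <- combn(drift, 2L)
      for (j in seq_len(ncol(prs)))
        cands[[length(cands) + 1L]] <-
          list(g = .attachLeafAdmix(g, pop, prs[1L, j], prs[2L, j]),
               admix = TRUE, id = sprintf("admix%d_%d", prs[1L, j], prs[2L, j]))
    }
    cfits <- lapply(cands, function(cd)
      fitGraph(cd$g, fs, starts = starts, seed = seed))
    mz <- vapply(cfits, `[[`, 0, "maxZ")
    nAdm <- vapply(cands, function(cd) cd$admix, TRUE)
    ord <- order(round(mz, 6), nAdm, seq_along(mz))
    best <- cfits[[ord[1L]]]
    log <- rbind(log, data.frame(step = "add", pop = pop,
                                 placement = cands[[ord[1L]]]$id,
                                 maxZ = best$maxZ))
  }
  list(fit = best, log = log)
}

#' Export an admixture graph as DOT text and JSON
#'
#' Drift edge labels are reported in drift units of 1000 x f2 (the
#' FST-proportional scale conventional for admixture-graph figures);
#' admixture edges are dotted and labelled with their percentage.
#'
#' @param g a fitted \linkS4class{AdmixtureGraph}.
#' @param path optional file path for the DOT text.
#' @return Invisibly, the DOT string.
#' @export
writeGraphDOT <- function(g, path = NULL) {
  ed <- g@edges
  lines <- c("digraph admixture_graph {",
             "  node [shape=plaintext];")
  for (i in seq_len(nrow(ed))) {
    if (ed$type[i] == "drift") {
      lab <- if (is.na(ed$length[i])) "?" else sprintf("%.0f", 1000 * ed$length[i])
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                                ed$from[i], ed$to[i], lab))
    } else {
      lab <- if (is.na(ed$weight[i])) "?" else sprintf("%.0f%%", 100 * ed$weight[i])
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [style=dotted, label=\"%s\"];",
        ed$from[i], ed$to[i], lab))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeGraphDOT
#' @export
graphJSON <- function(g, path = NULL) {
  js <- jsonlite::toJSON(list(leaves = g@leaves, edges = g@edges),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
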