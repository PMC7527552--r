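#' @include AllClasses.R
NULL

#' Extract the genotype dosage matrix
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @return Integer matrix (sites x accessions) of alternate-allele dosages.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Accession-to-population map
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @return Named character vector: accession id -> population label.
#' @export
setGeneric("popMap", function(x) standardGeneric("popMap"))

#' Population labels present in an object
#' @param x an object with population annotation.
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))

#' GBS stack (locus) identifier per site
#' @param x a \linkS4class{SNPMatrix}.
#' @export
setGeneric("stackID", function(x) standardGeneric("stackID"))

#' Accession identifiers
#' @param x a \linkS4class{SNPMatrix}.
#' @export
setGeneric("accessionIDs", function(x) standardGeneric("accessionIDs"))

#' @export
#' @rdname genotypes
setMethod("genotypes", "SNPMatrix",
          function(x) SummarizedExperiment::assay(x, "GT"))

#' @export
#' @rdname popMap
setMethod("popMap", "SNPMatrix", function(x)
  setNames(as.character(colData(x)$population), colnames(x)))

#' @export
#' @rdname popNames
setMethod("popNames", "SNPMatrix", function(x)
  unique(as.character(colData(x)$population)))

#' @export
#' @rdname popNames
setMethod("popNames", "FreqMatrix", function(x) rownames(x@p))

#' @export
#' @rdname stackID
setMethod("stackID", "SNPMatrix", function(x)
  as.character(rowData(x)$stack_id))

#' @export
#' @rdname accessionIDs
setMethod("accessionIDs", "SNPMatrix", function(x) colnames(x))

setMethod("show", "SNPMatrix", function(object) {
  cat(sprintf("SNPMatrix: %d sites x %d accessions\n",
              nrow(object), ncol(object)))
  pm <- popMap(object)
  tb <- table(pm)
  cat(sprintf("  %d stacks; populations: %s\n",
              length(unique(stackID(object))),
              paste(sprintf("%s (%d)", names(tb), tb), collapse = ", ")))
  gt <- genotypes(object)
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * mean(is.na(gt))))
})

setMethod("show", "FoldedSFS", function(object) {
  cat(sprintf("%s site-frequency spectrum (%s)\n",
              if (object@folded) "Folded" else "Unfolded",
              if (object@isProbability) "probabilities" else "counts"))
  cat(sprintf("  populations: %s; haploid sizes: %s; sites used: %s\n",
              paste(object@pops, collapse = ", "),
              paste(object@sampleSizes, collapse = ", "),
              format(object@nSites)))
})

setMethod("show", "Demography", function(object) {
  d <- object@demes
  cat(sprintf("Demography with %d deme(s):\n", nrow(d)))
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: N = %g diploids, growth = %g /gen\n",
                d$label[i], d$size[i], d$growth[i]))
  if (any(object@migration > 0)) cat("  migration matrix set\n")
  if (length(object@events))
    for (e in object@events)
      cat(sprintf("  t=%g: %s %s\n", e$time, e$type,
                  paste(d$label[c(e$d1, e$d2)], collapse = " -> ")))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s': lnL = %.2f, k = %d, AIC = %.2f (n = %g sites)\n",
              object@modelID, object@logLik, object@k, object@AIC,
              object@nSites))
  print(round(object@par, 4))
})

setMethod("show", "AdmixtureGraph", function(object) {
  ed <- object@edges
  nAdm <- sum(ed$type == "admix") / 2
  cat(sprintf("AdmixtureGraph: %d leaves, %d edges, %d admixture event(s)\n",
              length(object@leaves), nrow(ed), nAdm))
  cat("  leaves:", paste(object@leaves, collapse = ", "), "\n")
})

setMethod("show", "NeTrajectory", function(object) {
  cat(sprintf(
    "NeTrajectory: %d intervals, %.0f-%.0f generations (%.0f-%.0f years, g=%g)\n",
    length(object@Ne), min(object@times), max(object@times),
    min(object@times) * object@g, max(object@times) * object@g, object@g))
  cat(sprintf("  Ne range: %.0f - %.0f diploids\n",
              min(object@Ne), max(object@Ne)))
})
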