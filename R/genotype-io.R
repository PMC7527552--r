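#' @include AllGenerics.R
NULL

#' Construct a SNPMatrix from components
#'
#' @param genotypes integer matrix, sites x accessions, alternate-allele
#'   dosages 0/1/2 with \code{NA} for missing.
#' @param stackID character GBS stack (locus) id per site.
#' @param pos integer position of the SNP within its stack (bp).
#' @param ref,alt character alleles per site (multiallelic ALT joined by
#'   commas).
#' @param populations character population label per accession (or named by
#'   accession id).
#' @param nAlt integer number of ALT alleles per site (default parsed from
#'   \code{alt}).
#' @return A \linkS4class{SNPMatrix}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2)
#' snp <- SNPMatrix(g, stackID = c("L1", "L1"), pos = c(10L, 40L),
#'                  ref = c("A", "C"), alt = c("T", "G"),
#'                  populations = c(a1 = "P1", a2 = "P2"))
#' @export
SNPMatrix <- function(genotypes, stackID, pos, ref, alt, populations,
                      nAlt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- if (!is.null(names(populations)))
      names(populations) else sprintf("acc%03d", seq_len(ncol(genotypes)))
  }
  if (is.null(names(populations))) names(populations) <- colnames(genotypes)
  if (!all(colnames(genotypes) %in% names(populations)))
    stop("every accession must appear in the population map")
  if (is.null(nAlt)) nAlt <- lengths(strsplit(as.character(alt), ","))
  rd <- DataFrame(stack_id = as.character(stackID), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  nAlt = as.integer(nAlt))
  rownames(genotypes) <- sprintf("%s_%d", rd$stack_id, rd$pos)
  cd <- DataFrame(population = unname(populations[colnames(genotypes)]),
                  row.names = colnames(genotypes))
  new("SNPMatrix", SummarizedExperiment(
    assays = list(GT = genotypes), rowData = rd, colData = cd))
}

#' Read a VCF into a SNPMatrix
#'
#' Diploid GT fields are parsed to alternate-allele dosages (0/1/2);
#' \code{"./."} becomes missing.  Multiallelic sites are retained and
#' flagged (\code{nAlt > 1}) for removal by \code{\link{filterSites}}.
#' The CHROM column is taken as the GBS stack id and POS as the position
#' within the stack (the GBS dialect used throughout this package).
#'
#' @param path path to a VCF (v4.x) file with GT data for >= 1 sample.
#' @param popmap optional path to a two-column TSV (accession, population)
#'   or a named character vector; accessions without a label get
#'   \code{"unassigned"}.
#' @return A \linkS4class{SNPMatrix}.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "zanpop")
#' pm <- system.file("extdata", "toy.popmap.tsv", package = "zanpop")
#' snp <- readVCF(vcf, popmap = pm)
#' genotypes(snp)
#' filterSites(snp, maxMissing = 0.4)$report
#' @export
readVCF <- function(path, popmap = NULL) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) {
      # best effort: name the offending line for malformed input
      ln <- tryCatch({
        txt <- readLines(path)
        body <- which(!startsWith(txt, "#"))
        nf <- lengths(strsplit(txt[body], "\t", fixed = TRUE))
        if (length(body) && length(unique(nf)) > 1L)
          body[which(nf != nf[1L])[1L]] else NA_integer_
      }, error = function(e2) NA_integer_)
      stop(sprintf("malformed VCF '%s'%s: %s", path,
                   if (!is.na(ln)) sprintf(" (line %d)", ln) else "",
                   conditionMessage(e)), call. = FALSE)
    })
  gtc <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtc) || ncol(gtc) < 1L)
    stop("VCF has no GT field for any sample")
  ploidy <- lengths(regmatches(gtc, gregexpr("[/|]", gtc))) + 1L
  bad <- ploidy != 2L & gtc != "."
  if (any(bad))
    stop(sprintf("unsupported ploidy at %d genotype call(s); only diploid GT is supported",
                 sum(bad)))
  allele <- function(i) sub("^([^/|]*)[/|](.*)$", sprintf("\\%d", i), gtc)
  a1 <- allele(1); a2 <- allele(2)
  dose <- function(a) ifelse(a %in% c(".", ""), NA_integer_,
                             as.integer(a != "0"))
  gt <- matrix(dose(a1) + dose(a2), nrow(gtc), ncol(gtc),
               dimnames = dimnames(gtc))
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(altList, function(a) paste(as.character(a), collapse = ","), "")
  pops <- rep("unassigned", ncol(gt))
  names(pops) <- colnames(gt)
  if (!is.null(popmap)) {
    pm <- if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
      readPopmap(popmap) else popmap
    pops[names(pm)[names(pm) %in% names(pops)]] <-
      pm[names(pm) %in% names(pops)]
  }
  SNPMatrix(gt,
            stackID = as.character(GenomicRanges::seqnames(rr)),
            pos = GenomicRanges::start(rr),
            ref = as.character(VariantAnnotation::ref(vcf)),
            alt = alt, populations = pops,
            nAlt = lengths(altList))
}

#' Write a SNPMatrix as a VCF v4.2 file
#'
#' The writer is deliberately minimal and deterministic (no date stamps), so
#' fixtures written with a fixed seed are byte-identical across runs.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param path output file path.
#' @param seed optional integer recorded as a header line.
#' @return Invisibly, \code{path}.
#' @export
writeVCF <- function(x, path, seed = NULL) {
  rd <- rowData(x)
  gt <- genotypes(x)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtc <- matrix("./.", nrow(gt), ncol(gt))
  ok <- !is.na(gt)
  gtc[ok] <- code[as.character(gt[ok])]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=zanpop",
           if (!is.null(seed)) sprintf("##zanpopSeed=%d", as.integer(seed)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(rd$stack_id, rd$pos, ".", rd$ref, rd$alt, ".", "PASS", ".",
                "GT", sep = "\t")
  lines <- paste(body, apply(gtc, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read / write a two-column population map (TSV)
#'
#' @param path file path.
#' @return \code{readPopmap}: named character vector accession -> population.
#' @export
readPopmap <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("accession", "population"),
                   colClasses = "character")
  setNames(df$population, df$accession)
}

#' @rdname readPopmap
#' @param x a \linkS4class{SNPMatrix}.
#' @export
writePopmap <- function(x, path) {
  pm <- popMap(x)
  write.table(data.frame(names(pm), unname(pm)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Site filtering: biallelic sites with bounded missingness
#'
#' Retains sites that are biallelic among observed genotypes and missing in
#' at most \code{maxMissing} of accessions.  Removal reasons are assigned
#' with fixed priority (non-biallelic before missingness) so report counts
#' are well defined.  The default missingness threshold (0.4) reproduces,
#' at matrix level, a retain-if-genotyped-in->=60\%-of-accessions rule.
#' Sites monomorphic within the panel are biallelic carriers of SFS
#' information and are retained unless \code{dropMonomorphic}.
#'
#' @param x a \linkS4class{SNPMatrix} with >= 1 site.
#' @param maxMissing maximum tolerated missing fraction per site, in [0,1].
#' @param dropMonomorphic drop sites with a single observed allele.
#' @return A list with elements \code{snps} (filtered
#'   \linkS4class{SNPMatrix}) and \code{report} (a \code{FilterReport}
#'   list: n_in, n_non_biallelic, n_missingness_fail, n_out).
#' @export
filterSites <- function(x, maxMissing = 0.4, dropMonomorphic = FALSE) {
  if (nrow(x) == 0L) stop("empty SNPMatrix")
  .checkProportion(maxMissing, "maxMissing")
  gt <- genotypes(x)
  nAlt <- rowData(x)$nAlt
  if (is.null(nAlt)) nAlt <- rep(1L, nrow(x))
  nonBi <- nAlt > 1L
  if (dropMonomorphic) {
    mono <- apply(gt, 1L, function(g) {
      g <- g[!is.na(g)]
      length(g) == 0L || all(g == 0L) || all(g == 2L)
    })
    nonBi <- nonBi | mono
  }
  missFrac <- rowMeans(is.na(gt))
  missFail <- !nonBi & missFrac > maxMissing
  keep <- !nonBi & !missFail
  report <- structure(list(
    n_in = nrow(x), n_non_biallelic = sum(nonBi),
    n_missingness_fail = sum(missFail), n_out = sum(keep)),
    class = "FilterReport")
  list(snps = x[keep, ], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf(
    "FilterReport: %d sites in; removed %d non-biallelic, %d missingness; %d retained\n",
    x$n_in, x$n_non_biallelic, x$n_missingness_fail, x$n_out))
  invisible(x)
}

#' Serialize a FilterReport as JSON
#' @param report a FilterReport.
#' @param path optional output path.
#' @export
writeFilterReport <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Thin to one random SNP per GBS stack
#'
#' Keeps exactly one uniformly chosen SNP per distinct stack id, to avoid
#' carrying sets of tightly linked sites into structure-sensitive analyses.
#' Deterministic given \code{seed}; relative site order is preserved.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param seed integer seed.
#' @return A thinned \linkS4class{SNPMatrix}.
#' @export
thinOneSNPPerLocus <- function(x, seed) {
  sid <- stackID(x)
  idx <- seq_len(nrow(x))
  set.seed(as.integer(seed))
  sel <- vapply(split(idx, sid), function(i)
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)], 0L)
  x[sort(unname(sel)), ]
}

#' Merge populations into genetic groups
#'
#' Relabels accessions so that each listed group of populations becomes one
#' population; downstream frequencies are recomputed from the pooled
#' genotypes.  Groups must not overlap; unlisted populations keep their
#' labels.
#'
#' @param x a \linkS4class{SNPMatrix}.
#' @param groups named list: new label -> character vector of old labels.
#' @return A relabelled \linkS4class{SNPMatrix}.
#' @export
mergeGroups <- function(x, groups) {
  old <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(old)) stop("groups overlap: a population may appear in only one group")
  pm <- popMap(x)
  for (g in names(groups)) pm[pm %in% groups[[g]]] <- g
  colData(x)$population <- unname(pm)
  x
}
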