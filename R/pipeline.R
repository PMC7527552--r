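#' @include genotype-io.R diversity.R sfs.R stairway.R fitmodel.R outliers.R
NULL

.configDefaults <- function() list(
  vcf = NULL, popmap = NULL,
  synthetic = NULL,              # list(nLoci, samplesPerDeme, ...) or TRUE
  outDir = "zanpop_out",
  seed = 1L,
  maxMissing = 0.4,
  thin = FALSE,
  mu = ZANTHOXYLUM_MU,
  g = ZANTHOXYLUM_G,
  blockSize = 200L,
  stages = c("filter", "stats", "sfs"),
  sfsPops = NULL, projections = NULL,
  stairwayPop = NULL, stairwayBootstraps = 50L, totalSites = NULL,
  models = character(0), fitSettings = list(),
  fstatsPops = NULL,
  outlierScheme = NULL, qThreshold = 0.05)

#' Validate and normalize a pipeline configuration
#'
#' Injects documented defaults (including the mutation-rate and
#' generation-time calibration mu = 2.6e-9 /site/yr, g = 4 yr) and
#' rejects unknown keys, naming the offending key.
#'
#' @param cfg named list (possibly empty) or path to a JSON file.
#' @return Normalized configuration list.
#' @export
validateConfig <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1L)
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  defaults <- .configDefaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  out[names(cfg)] <- cfg
  .checkProportion(out$maxMissing, "maxMissing")
  out$seed <- as.integer(out$seed)
  bad <- setdiff(out$stages,
                 c("filter", "thin", "stats", "sfs", "stairway",
                   "fitmodels", "fstats", "outliers"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order (input/filter ->
#' diversity stats and SFS -> stairway / model fitting -> f-statistics ->
#' outlier scans), writes per-stage artifacts under \code{outDir}, and
#' returns (and writes) a machine-readable JSON report with seeds and
#' per-stage summaries.  Any stage failure aborts with a diagnostic
#' naming the stage.
#'
#' @param cfg configuration list (see \code{\link{validateConfig}}).
#' @return The run report (list), invisibly written to
#'   \code{outDir/report.json}.
#' @export
runPipeline <- function(cfg = list()) {
  cfg <- validateConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "zanpop",
                 version = as.character(utils::packageVersion("zanpop")),
                 seed = cfg$seed, config = cfg[!vapply(cfg, is.null, TRUE)],
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  # --- input ---------------------------------------------------------
  snp <- stage("input", {
    if (!is.null(cfg$vcf)) {
      readVCF(cfg$vcf, popmap = cfg$popmap)
    } else if (!is.null(cfg$synthetic)) {
      fx <- makeStudyFixture(file.path(cfg$outDir, "fixture"),
                             seed = deriveSeed(cfg$seed, "fixture"),
                             nLoci = if (is.list(cfg$synthetic) &&
                                         !is.null(cfg$synthetic$nLoci))
                               cfg$synthetic$nLoci else 38395L)
      readVCF(fx$vcf, popmap = fx$popmap)
    } else stop("config needs either 'vcf' or 'synthetic'")
  })
  report$stages$input <- list(nSites = nrow(snp), nAccessions = ncol(snp),
                              populations = popNames(snp))
  # --- filter --------------------------------------------------------
  if ("filter" %in% cfg$stages) {
    fl <- stage("filter", filterSites(snp, maxMissing = cfg$maxMissing))
    snp <- fl$snps
    report$stages$filter <- unclass(fl$report)
    writeFilterReport(fl$report, file.path(cfg$outDir, "filter_report.json"))
  }
  if ("thin" %in% cfg$stages || isTRUE(cfg$thin)) {
    snp <- stage("thin", thinOneSNPPerLocus(snp, deriveSeed(cfg$seed, "thin")))
    report$stages$thin <- list(nSites = nrow(snp))
  }
  # --- diversity stats ----------------------------------------------
  if ("stats" %in% cfg$stages) {
    dt <- stage("stats", diversityTable(snp))
    write.table(dt$populations, file.path(cfg$outDir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dt$fst, file.path(cfg$outDir, "fst_matrix.tsv"),
                sep = "\t", quote = FALSE)
    report$stages$stats <- list(
      pi = setNames(dt$populations$pi_mean, dt$populations$population),
      fstRange = range(dt$fst[upper.tri(dt$fst)]))
  }
  # --- SFS -----------------------------------------------------------
  sfsObj <- NULL
  if ("sfs" %in% cfg$stages) {
    pops <- if (is.null(cfg$sfsPops)) popNames(snp)[1L] else cfg$sfsPops
    sfsObj <- stage("sfs", foldedSFS(snp, pops, projections = cfg$projections))
    writeSFS(sfsObj, file.path(cfg$outDir, "sfs.txt"))
    report$stages$sfs <- list(pops = pops, dims = dim(sfsObj@counts),
                              nSites = sfsObj@nSites)
  }
  # --- stairway ------------------------------------------------------
  if ("stairway" %in% cfg$stages) {
    pop <- if (is.null(cfg$stairwayPop)) popNames(snp)[1L] else cfg$stairwayPop
    traj <- stage("stairway", {
      s1 <- foldedSFS(snp, pop, projections = cfg$projections)
      boots <- bootstrapSFS(snp, pop, projections = cfg$projections,
                            nReps = cfg$stairwayBootstraps,
                            seed = deriveSeed(cfg$seed, "boot"))
      ts <- cfg$totalSites
      if (is.null(ts) && !is.null(simInfo(snp)))
        ts <- simInfo(snp)$impliedTotalSites
      fitStairway(s1, boots, stairwayConfig(
        mu = cfg$mu, g = cfg$g, totalSites = ts,
        seed = deriveSeed(cfg$seed, "stairway")))
    })
    write.table(trajectoryTable(traj),
                file.path(cfg$outDir, sprintf("stairway_%s.tsv", pop)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$stairway <- list(pop = pop, NeRange = range(traj@Ne))
  }
  # --- model fitting -------------------------------------------------
  if ("fitmodels" %in% cfg$stages && length(cfg$models)) {
    fits <- stage("fitmodels", {
      stopifnot(!is.null(sfsObj))
      lapply(cfg$models, function(id) {
        fcfg <- do.call(fitConfig, c(cfg$fitSettings,
                                     list(seed = deriveSeed(cfg$seed, id))))
        fitModel(sfsObj, pepperModels(id), fcfg)
      })
    })
    cmp <- if (length(fits) >= 2L) compareModels(fits) else NULL
    report$stages$fitmodels <- list(
      models = lapply(fits, function(f)
        list(id = f@modelID, par = as.list(f@par), logLik = f@logLik,
             AIC = f@AIC)),
      ranking = cmp)
    jsonlite::write_json(report$stages$fitmodels,
                         file.path(cfg$outDir, "model_fits.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  # --- f-statistics --------------------------------------------------
  if ("fstats" %in% cfg$stages) {
    res <- stage("fstats", {
      pops <- if (is.null(cfg$fstatsPops)) popNames(snp) else cfg$fstatsPops
      fq <- freqMatrix(snp, pops, blockSize = cfg$blockSize)
      f3Scan(fq)
    })
    write.table(res, file.path(cfg$outDir, "f3_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$stages$fstats <- list(nTests = nrow(res),
                                 nSignificant = sum(res$significant))
  }
  # --- outlier scans -------------------------------------------------
  if ("outliers" %in% cfg$stages && !is.null(cfg$outlierScheme)) {
    sc <- stage("outliers", selectionScan(
      snp, cfg$outlierScheme, qThreshold = cfg$qThreshold,
      seed = deriveSeed(cfg$seed, "outliers")))
    for (nm in names(sc))
      write.table(sc[[nm]], file.path(cfg$outDir,
                                      sprintf("outliers_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$outliers <- lapply(sc, function(tb)
      list(nLoci = nrow(tb), nConsensus = sum(tb$consensus)))
  }
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}
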