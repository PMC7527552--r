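#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed; per-stage seeds
#' are derived deterministically so stages are independently reproducible.
#' Results stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483629 + 1)
}

#' Convert generations to years and back
#'
#' Calibration uses the generation time of Chinese pepper (default 4 years,
#' from field observations on cultivated trees).
#'
#' @param generations,years numeric times.
#' @param g generation time in years (default 4).
#' @return Numeric times in the other unit.
#' @export
generationsToYears <- function(generations, g = 4) generations * g

#' @rdname generationsToYears
#' @export
yearsToGenerations <- function(years, g = 4) years / g

#' Default per-year mutation rate
#'
#' Per-site per-year substitution rate used for time and size rescaling
#' (2.6e-9, a transcriptome-derived estimate for Zanthoxylum).
#' @export
ZANTHOXYLUM_MU <- 2.6e-9

#' Default generation time in years
#' @export
ZANTHOXYLUM_G <- 4

# internal: check scalar proportion
.checkProportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}
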