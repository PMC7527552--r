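# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a small two-deme panel with moderate divergence and some missingness
twoDemePanel <- function() cached("twoDeme", function() {
  dem <- Demography(data.frame(label = c("A", "B"), size = c(5000, 5000)),
                    events = list(demeEvent(4000, "join", "B", "A")))
  simulateGenotypes(dem, simConfig(nLoci = 2500,
                                   samplesPerDeme = c(A = 10, B = 10),
                                   missingRate = 0.1, seed = 101))
})

# a three-deme island-model panel at migration-drift equilibrium
islandPanel <- function() cached("island", function() {
  d <- 3; N <- 2000; m <- 0.002
  mig <- matrix(m / (d - 1), d, d); diag(mig) <- 0
  dem <- Demography(data.frame(label = c("P1", "P2", "P3"), size = N),
                    migration = mig)
  simulateGenotypes(dem, simConfig(nLoci = 4000,
                                   samplesPerDeme = c(P1 = 10, P2 = 10, P3 = 10),
                                   seed = 202))
})

# hand-built SNPMatrix: 5 accessions x 5 sites covering the filter cases
fiveSitePanel <- function() {
  g <- matrix(c(
    0L, 1L, 2L, 1L, 0L,   # biallelic, complete
    1L, 1L, 0L, 2L, 1L,   # triallelic site (flagged via nAlt)
    NA, NA, NA, 1L, 0L,   # 3/5 missing
    0L, 0L, 1L, 1L, 2L,   # biallelic, complete
    2L, 2L, 1L, 0L, 0L),  # biallelic, complete
    nrow = 5L, byrow = TRUE)
  SNPMatrix(g, stackID = c("L1", "L1", "L2", "L3", "L3"),
            pos = c(5L, 20L, 7L, 11L, 90L),
            ref = c("A", "C", "G", "T", "A"),
            alt = c("T", "G,T", "A", "C", "G"),
            populations = setNames(rep(c("X", "Y"), c(3, 2)),
                                   sprintf("acc%d", 1:5)))
}

# a FreqMatrix built directly from given frequency rows (large k)
freqTable <- function(p, k = 1000L, blockSize = 1L) {
  p <- as.matrix(p)
  kmat <- matrix(as.integer(k), nrow(p), ncol(p), dimnames = dimnames(p))
  blocks <- as.integer(ceiling(seq_len(ncol(p)) / blockSize))
  new("FreqMatrix", p = p, k = kmat, blockID = blocks,
      siteInfo = data.frame(stack_id = sprintf("s%d", seq_len(ncol(p))),
                            pos = seq_len(ncol(p))))
}
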