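# Small shared simulation configurations. Grids are kept small so the suite
# stays fast; the generator's statistical model is size-invariant.

tinyConfig <- function(seed = 1L, ...) {
  smearSimConfig(nX = 12L, nY = 12L, nRBC = 12L, nBackgroundPeaks = 60L,
                 seed = seed, ...)
}

calibConfig <- function(seed, ...) {
  smearSimConfig(nX = 14L, nY = 14L, nRBC = 14L, nullMode = TRUE,
                 seed = seed, ...)
}

# independent element masses for oracle sums (IUPAC values, typed in
# separately from the package's table)
ORACLE_MASS <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163, S = 31.972071,
                 Fe = 55.9349375, Na = 22.9897692809, K = 38.96370668,
                 Cl = 34.96885268, Se = 79.9165213, Mo = 97.9054082,
                 I = 126.904473)

suppressPackageStartupMessages(library(SummarizedExperiment))
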