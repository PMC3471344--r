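# Build a GenomePair from compact strings, e.g. pairFromStrings("1101","1111")
pairFromStrings <- function(gs, hs, offset = 0L) {
  GenomePair(g = as.integer(strsplit(gs, "")[[1]]),
             h = as.integer(strsplit(hs, "")[[1]]),
             offset = offset)
}

# Last-checkpoint RunStatistics of a fresh simulation
simFinalStats <- function(mu, phi, length = 100000L, stopTheta = 0.5,
                          seed = 1L, ...) {
  sim <- runSimulation(DeletionModel(mu, phi), length = length,
                       stopTheta = stopTheta, seed = seed, ...)
  sim@checkpointStats[[base::length(sim@checkpointStats)]]
}

runWidths <- function(stats) IRanges::width(runRanges(stats))
runR <- function(stats) S4Vectors::mcols(runRanges(stats))$r
runBoth <- function(stats) S4Vectors::mcols(runRanges(stats))$both
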