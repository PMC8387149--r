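# Shared test helpers: all fixtures are generated in code.

# memoized fixture suite (regenerating is cheap but not free)
fixtureSuiteDir <- local({
  cache <- new.env(parent = emptyenv())
  function(rootSeed = 20240101L) {
    key <- as.character(rootSeed)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("flyburst_fixture_", rootSeed))
      unlink(dir, recursive = TRUE)
      makeFixtureSuite(rootSeed, dir)
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

# random spike train with ISIs straddling the 100 ms burst boundary:
# mixture of short (in-burst), long (gap) and exactly-0.100 intervals
randomBoundaryTrain <- function(seed, maxSpikes = 50L) {
  set.seed(seed)
  n <- sample.int(maxSpikes, 1L)
  kind <- sample(c("short", "exact", "long"), n, replace = TRUE,
                 prob = c(0.5, 0.2, 0.3))
  isi <- ifelse(kind == "short", runif(n, 0.005, 0.09),
         ifelse(kind == "exact", 0.100, runif(n, 0.11, 0.6)))
  SpikeTrain(paste0("rnd", seed), cumsum(isi), duration = sum(isi) + 1)
}

# n simulated traces -> trace-summary data.frame
simSummaries <- function(n, cfg = spikeTrainSimConfig(), seedBase = 1000L,
                         genotype = "SIM") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    cfg$seed <- seedBase + i
    sim <- simulateSpikeTrain(cfg, sprintf("%s_%03d", genotype, i),
                              genotype = genotype)
    summarizeTrace(sim$train, detectBursts(sim$train))
  }))
}
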