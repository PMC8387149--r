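test_that("simulated trains are reproducible and detector-consistent", {
  cfg <- spikeTrainSimConfig(seed = 7)
  s1 <- simulateSpikeTrain(cfg, "a")
  s2 <- simulateSpikeTrain(cfg, "a")
  expect_identical(spikeTimes(s1$train), spikeTimes(s2$train))
  expect_identical(s1$bursts, s2$bursts)

  # ground truth recovered exactly, with and without noise spikes
  for (seed in 1:20) {
    sim <- simulateSpikeTrain(spikeTrainSimConfig(seed = seed), "t")
    expect_identical(detectBursts(sim$train), sim$bursts)
  }
  noNoise <- simulateSpikeTrain(
    spikeTrainSimConfig(noiseRateHz = 0, seed = 3), "t")
  expect_identical(detectBursts(noNoise$train), noNoise$bursts)
  # heavy noise still cannot corrupt ground-truth labels
  noisy <- simulateSpikeTrain(
    spikeTrainSimConfig(noiseRateHz = 0.2, seed = 3), "t")
  expect_identical(detectBursts(noisy$train), noisy$bursts)
  expect_gt(nSpikes(noisy$train), nSpikes(noNoise$train))
})

test_that("generator rejects configurations that cannot produce valid bursts", {
  expect_error(spikeTrainSimConfig(
    withinBurstISI = list(family = "gamma", mean = 0.2, sd = 0.05)),
    "config error")
  expect_error(spikeTrainSimConfig(
    withinBurstISI = list(family = "gamma", mean = 0.09, sd = 0.01),
    burstDuration = list(family = "lognormal", mean = 0.15, sd = 0.05)),
    "mean ISI x 2")
  expect_error(spikeTrainSimConfig(
    burstDuration = list(family = "weibull", mean = 0.2, sd = 0.1)),
    "family")
  expect_error(spikeTrainSimConfig(durationS = -1), "durationS")
})

test_that("ground-truth bursts always have >= 3 spikes and positive spans", {
  for (seed in 21:30) {
    sim <- simulateSpikeTrain(spikeTrainSimConfig(seed = seed), "t")
    expect_true(all(sim$bursts$n_spikes >= 3L))
    expect_true(all(sim$bursts$duration_s > 0))
    expect_true(all(diff(sim$bursts$start_s) > 0))
  }
})

test_that("behavior simulation is reproducible and order-insensitive", {
  groups <- data.frame(genotype = c("ctl", "mut"), assay = "vortex",
                       n = 10L, mean = c(10, 30), sd = c(3, 9))
  b1 <- simulateBehavior(behaviorSimConfig(groups, seed = 5))
  b2 <- simulateBehavior(behaviorSimConfig(groups, seed = 5))
  expect_identical(b1, b2)
  # per-group child seeds: reversing group order preserves each group's draw
  b3 <- simulateBehavior(behaviorSimConfig(groups[2:1, ], seed = 5))
  expect_equal(sort(b3$value[b3$genotype == "ctl"]),
               sort(b1$value[b1$genotype == "ctl"]))

  # scale -> 0 limit collapses onto the location
  b0 <- simulateBehavior(behaviorSimConfig(
    data.frame(genotype = "g", assay = "heat", n = 5L, mean = 42, sd = 0),
    seed = 1))
  expect_equal(b0$value, rep(42, 5))
})

test_that("a 3x location ratio recovers about +200% at large n", {
  groups <- data.frame(genotype = c("ctl", "mut"), assay = "eshock",
                       n = 4000L, mean = c(50, 150), sd = c(10, 30))
  b <- simulateBehavior(behaviorSimConfig(groups, seed = 11))
  pc <- percentChange(b$value[b$genotype == "mut"],
                      b$value[b$genotype == "ctl"])
  expect_equal(pc, 200, tolerance = 0.03)
})

test_that("heat-assay onsets are censored at the exposure window", {
  groups <- data.frame(genotype = "hs", assay = "heat", n = 500L,
                       mean = 70, sd = 25, onset_mean = 100, onset_sd = 60)
  b <- simulateBehavior(behaviorSimConfig(groups, censorTime = 120,
                                          seed = 2))
  expect_true(any(is.na(b$onset_time_s)))
  expect_true(all(b$onset_time_s <= 120, na.rm = TRUE))
})

test_that("fixture suite regenerates byte-identically from the same root seed", {
  d1 <- file.path(tempdir(), "suiteA"); d2 <- file.path(tempdir(), "suiteB")
  unlink(c(d1, d2), recursive = TRUE)
  makeFixtureSuite(424242L, d1)
  makeFixtureSuite(424242L, d2)
  for (f in c("spikes.tsv", "trace_meta.tsv", "behavior.tsv",
              "manifest.json", "run_config.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("elongated genotype shows a higher elongated fraction than wild-type-like", {
  fix <- fixtureSuiteDir()
  trains <- readSpikeTrains(file.path(fix, "spikes.tsv"),
                            file.path(fix, "trace_meta.tsv"))
  sums <- summarizeTraces(trains)
  band <- buildReferenceBand(sums, "WTL", 1.5)
  fr <- fractionElongated(classifyTraces(sums, band))
  expect_gt(fr$fraction_elongated[fr$genotype == "ELG"],
            fr$fraction_elongated[fr$genotype == "WTL"])
})
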