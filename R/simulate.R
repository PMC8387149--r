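#' Configure the synthetic spike-train generator
#'
#' The generator is an alternating renewal process — inter-burst gap, then
#' a burst of spikes — emulating the robust rhythmic bursting of larval
#' aCC/RP2 motor neurons, with isolated noise spikes superposed. It is a
#' statistical stand-in, not a biophysical central-pattern-generator model.
#'
#' Distribution specs are lists \code{list(family, mean, sd)} with family
#' \code{"exponential"} (mean only), \code{"gamma"} or \code{"lognormal"};
#' mean and sd are on the natural (seconds) scale and converted to family
#' parameters internally.
#'
#' Defaults describe a wild-type-like trace: 180 s duration, burst duration
#' lognormal with mean 175 ms and SD 91 ms, within-burst ISI gamma with
#' mean 13.5 ms (about 14 spikes per burst), inter-burst gaps exponential
#' with mean 1.95 s (about 0.47 bursts/s), and 0.01 Hz of isolated noise
#' spikes.
#'
#' Two constraints keep the ground truth exact under the detection rule:
#' within-burst ISIs are rejection-capped at \code{isiCapS} (strictly below
#' \code{maxISIS}), and inter-burst gaps below \code{maxISIS + 0.005} s are
#' redrawn, so generated bursts are detectable by construction and can
#' never merge.
#'
#' @param durationS trace duration, seconds.
#' @param interBurstInterval,burstDuration,withinBurstISI distribution
#'   specs (see Details).
#' @param noiseRateHz Poisson rate of isolated noise spikes.
#' @param maxISIS the downstream detection threshold the generator must
#'   respect (seconds).
#' @param isiCapS upper rejection bound for within-burst ISIs.
#' @param seed integer RNG seed.
#' @return a validated config (list of class \code{SpikeTrainSimConfig}).
#' @export
spikeTrainSimConfig <- function(durationS = 180,
    interBurstInterval = list(family = "exponential", mean = 1.95),
    burstDuration = list(family = "lognormal", mean = 0.175, sd = 0.0915),
    withinBurstISI = list(family = "gamma", mean = 0.0135, sd = 0.006),
    noiseRateHz = 0.01, maxISIS = 0.100, isiCapS = 0.095, seed = 1L) {
  cfg <- list(durationS = durationS, interBurstInterval = interBurstInterval,
              burstDuration = burstDuration, withinBurstISI = withinBurstISI,
              noiseRateHz = noiseRateHz, maxISIS = maxISIS,
              isiCapS = isiCapS, seed = as.integer(seed))
  class(cfg) <- "SpikeTrainSimConfig"
  .validateSpikeSimConfig(cfg)
  cfg
}

.validateSpikeSimConfig <- function(cfg) {
  if (cfg$durationS <= 0) stop("config error: durationS must be > 0")
  for (nm in c("interBurstInterval", "burstDuration", "withinBurstISI"))
    .validateDistSpec(cfg[[nm]], nm)
  if (cfg$noiseRateHz < 0) stop("config error: noiseRateHz must be >= 0")
  if (cfg$isiCapS >= cfg$maxISIS)
    stop("config error: isiCapS must be strictly below maxISIS")
  if (cfg$withinBurstISI$mean >= cfg$maxISIS)
    stop("config error: within-burst mean ISI must be below maxISIS")
  if (2 * cfg$withinBurstISI$mean > cfg$burstDuration$mean)
    stop("config error: mean ISI x 2 exceeds mean burst duration; ",
         "bursts of >= 3 spikes cannot be generated reliably")
  invisible(TRUE)
}

.validateDistSpec <- function(spec, what) {
  fam <- spec$family
  if (is.null(fam) || !(fam %in% c("exponential", "gamma", "lognormal")))
    stop("config error: '", what, "' family must be exponential, gamma ",
         "or lognormal")
  if (is.null(spec$mean) || spec$mean <= 0)
    stop("config error: '", what, "' mean must be > 0")
  if (fam != "exponential" && (is.null(spec$sd) || spec$sd <= 0))
    stop("config error: '", what, "' sd must be > 0")
  invisible(TRUE)
}

# draw n values from a natural-scale (mean, sd) distribution spec
.drawDist <- function(spec, n) {
  switch(spec$family,
    exponential = stats::rexp(n, rate = 1 / spec$mean),
    gamma = {
      shape <- (spec$mean / spec$sd)^2
      stats::rgamma(n, shape = shape, rate = shape / spec$mean)
    },
    lognormal = {
      sdlog2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - sdlog2 / 2,
                    sdlog = sqrt(sdlog2))
    })
}

#' Simulate one spike train with exact ground-truth bursts
#'
#' Alternates gap and burst draws until the trace duration is reached: each
#' burst's duration is drawn, then filled with spikes at the within-burst
#' ISI distribution (redrawn until at least three spikes fit). Noise spikes
#' are then superposed at the configured Poisson rate, rejecting any
#' candidate within \code{maxISIS} (+5 ms guard) of an already-accepted
#' spike so ground-truth burst labels stay exact. A burst that would
#' overrun the trace end is dropped.
#'
#' With zero noise the detector ([detectBursts()]) recovers the returned
#' ground truth exactly; with the default noise rate it still does, because
#' accepted noise spikes are isolated by construction.
#'
#' @param config a [spikeTrainSimConfig()].
#' @param traceId,genotype,cellType,groupRole metadata for the returned
#'   train.
#' @return list with \code{train} (a [SpikeTrain-class]) and \code{bursts}
#'   (ground-truth burst data.frame in the [detectBursts()] schema).
#' @examples
#' sim <- simulateSpikeTrain(spikeTrainSimConfig(seed = 7), "sim1")
#' identical(detectBursts(sim$train), sim$bursts)
#' @export
simulateSpikeTrain <- function(config, traceId = "sim",
                               genotype = NA_character_, cellType = "aCC",
                               groupRole = "control") {
  stopifnot(inherits(config, "SpikeTrainSimConfig"))
  .validateSpikeSimConfig(config)
  set.seed(config$seed)
  minGap <- config$maxISIS + 0.005
  spikes <- numeric(0)
  first <- integer(0); last <- integer(0)
  t <- 0
  repeat {
    gap <- .drawDist(config$interBurstInterval, 1L)
    tries <- 0L
    while (gap <= minGap && tries < 1000L) {
      gap <- .drawDist(config$interBurstInterval, 1L); tries <- tries + 1L
    }
    if (gap <= minGap) stop("config error: cannot draw a gap > maxISIS")
    start <- t + gap
    if (start >= config$durationS) break
    d <- .drawDist(config$burstDuration, 1L)
    bs <- .fillBurst(start, d, config)
    if (is.null(bs)) stop("config error: cannot fill bursts with >= 3 spikes")
    if (bs[length(bs)] > config$durationS) break
    first <- c(first, length(spikes) + 1L)
    last <- c(last, length(spikes) + length(bs))
    spikes <- c(spikes, bs)
    t <- bs[length(bs)]
  }
  truth <- .burstFrame(traceId, spikes, first, last)

  nNoise <- stats::rpois(1L, config$noiseRateHz * config$durationS)
  if (nNoise > 0L) {
    cand <- stats::runif(nNoise, 0, config$durationS)
    keepGuard <- config$maxISIS + 0.005
    accepted <- spikes
    noise <- numeric(0)
    for (x in cand) {
      if (!length(accepted) || min(abs(accepted - x)) > keepGuard) {
        noise <- c(noise, x)
        accepted <- c(accepted, x)
      }
    }
    spikes <- sort(c(spikes, noise))
  }
  train <- SpikeTrain(traceId, spikes, duration = config$durationS,
                      genotype = genotype, cellType = cellType,
                      groupRole = groupRole)
  list(train = train, bursts = truth)
}

# fill [start, start + d] with spikes at the within-burst ISI distribution;
# redraw whole fills until >= 3 spikes fit (NULL after 1000 failures)
.fillBurst <- function(start, d, config) {
  for (attempt in seq_len(1000L)) {
    times <- start
    repeat {
      isi <- .drawDist(config$withinBurstISI, 1L)
      tries <- 0L
      while ((isi >= config$isiCapS || isi <= 0) && tries < 1000L) {
        isi <- .drawDist(config$withinBurstISI, 1L); tries <- tries + 1L
      }
      nxt <- times[length(times)] + isi
      if (nxt > start + d) break
      times <- c(times, nxt)
    }
    if (length(times) >= 3L) return(times)
  }
  NULL
}

#' Configure the behavioral-assay simulator
#'
#' One row per genotype-assay group: the per-animal value (seizure duration
#' in s, or distance in mm) is drawn from a right-tailed nonnegative
#' distribution with the given natural-scale mean and SD. Heat-assay groups
#' may carry an onset distribution (\code{onset_mean}, \code{onset_sd});
#' onsets beyond \code{censorTime} are censored (recorded as missing),
#' emulating the fixed exposure window.
#'
#' @param groups data.frame with columns \code{genotype, assay, n, mean,
#'   sd} and optional \code{family} (default \code{"lognormal"}),
#'   \code{onset_mean}, \code{onset_sd}.
#' @param censorTime onset censoring time, seconds (default 120, the
#'   standard heat-exposure window).
#' @param seed integer RNG seed.
#' @return a validated config (list of class \code{BehaviorSimConfig}).
#' @export
behaviorSimConfig <- function(groups, censorTime = 120, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("genotype", "assay", "n", "mean", "sd") %in% names(groups)))
  if (!"family" %in% names(groups)) groups$family <- "lognormal"
  if (!"onset_mean" %in% names(groups)) groups$onset_mean <- NA_real_
  if (!"onset_sd" %in% names(groups)) groups$onset_sd <- NA_real_
  bad <- setdiff(unique(groups$assay), .ASSAYS)
  if (length(bad)) stop("config error: unknown assay '", bad[1L], "'")
  if (any(groups$n < 1)) stop("config error: n_animals must be >= 1")
  if (any(groups$mean <= 0) || any(groups$sd < 0))
    stop("config error: group means must be > 0 and sds >= 0")
  if (!all(groups$family %in% c("lognormal", "gamma")))
    stop("config error: behavior family must be lognormal or gamma")
  cfg <- list(groups = groups, censorTime = censorTime,
              seed = as.integer(seed))
  class(cfg) <- "BehaviorSimConfig"
  cfg
}

#' Simulate behavioral measurements
#'
#' Draws each genotype-assay group independently per its config row; group
#' order in the config does not affect other groups' draws (each group gets
#' a child seed derived from the config seed and its labels).
#'
#' @param config a [behaviorSimConfig()].
#' @return data.frame in the behavior-table schema: \code{animal_id,
#'   genotype, assay, value, onset_time_s} (onset \code{NA} when censored
#'   or not simulated).
#' @export
simulateBehavior <- function(config) {
  stopifnot(inherits(config, "BehaviorSimConfig"))
  g <- config$groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    r <- g[i, ]
    set.seed(deriveSeed(config$seed, "behavior", r$genotype, r$assay))
    spec <- list(family = r$family, mean = r$mean,
                 sd = if (r$sd > 0) r$sd else r$mean * 1e-9)
    vals <- if (r$sd > 0) .drawDist(spec, r$n) else rep(r$mean, r$n)
    onsets <- rep(NA_real_, r$n)
    if (is.finite(r$onset_mean)) {
      o <- .drawDist(list(family = r$family, mean = r$onset_mean,
                          sd = r$onset_sd), r$n)
      onsets <- ifelse(o <= config$censorTime, o, NA_real_)
    }
    data.frame(
      animal_id = sprintf("%s_%s_%03d", r$genotype, r$assay, seq_len(r$n)),
      genotype = r$genotype, assay = r$assay, value = vals,
      onset_time_s = onsets, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate the packaged synthetic fixture suite
#'
#' Writes a complete, deterministic synthetic dataset for end-to-end runs:
#' \itemize{
#'   \item 12 wild-type-like spike traces (genotype \code{WTL}, the
#'     reference) and 12 elongated-bursting traces (\code{ELG}, burst
#'     durations scaled 3x), as \code{spikes.tsv} + \code{trace_meta.tsv};
#'   \item behavioral measurements (\code{behavior.tsv}) for a mock
#'     bang-sensitive panel (\code{bsA < bsB < bsC} severity vs control
#'     \code{ctl}; vortex + electroshock) and two mock heat-sensitive lines
#'     (\code{hsA}, \code{hsB} vs matched controls \code{hsA_c},
#'     \code{hsB_c}; heat with onset times + electroshock), 20 animals per
#'     group;
#'   \item \code{manifest.json} recording every true generator parameter
#'     and per-trace ground-truth burst counts, for use as a test oracle;
#'   \item \code{run_config.yaml}, a ready-to-run [runPipeline()] config.
#' }
#' Regenerating with the same root seed gives byte-identical files.
#'
#' @param rootSeed integer root seed; all child seeds derive from it.
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
makeFixtureSuite <- function(rootSeed, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wtCfg <- function(seed) spikeTrainSimConfig(seed = seed)
  elCfg <- function(seed) spikeTrainSimConfig(
    burstDuration = list(family = "lognormal", mean = 0.525, sd = 0.27),
    interBurstInterval = list(family = "exponential", mean = 1.95),
    seed = seed)

  spikeRows <- list(); metaRows <- list(); truthCounts <- list()
  for (geno in c("WTL", "ELG")) {
    for (i in seq_len(12L)) {
      id <- sprintf("%s_%02d", geno, i)
      seed <- deriveSeed(rootSeed, "spike", geno, i)
      cfg <- if (geno == "WTL") wtCfg(seed) else elCfg(seed)
      sim <- simulateSpikeTrain(cfg, traceId = id, genotype = geno,
        cellType = if (i %% 2L) "aCC" else "RP2",
        groupRole = if (geno == "WTL") "wildtype_reference" else "mutant")
      spikeRows[[id]] <- data.frame(trace_id = id,
        spike_time_s = spikeTimes(sim$train), stringsAsFactors = FALSE)
      metaRows[[id]] <- data.frame(trace_id = id, genotype = geno,
        cell_type = cellType(sim$train), group_role = groupRole(sim$train),
        duration_s = traceDuration(sim$train), stringsAsFactors = FALSE)
      truthCounts[[id]] <- nrow(sim$bursts)
    }
  }
  spikePath <- file.path(outDir, "spikes.tsv")
  metaPath <- file.path(outDir, "trace_meta.tsv")
  writeResultTable(do.call(rbind, spikeRows), spikePath)
  writeResultTable(do.call(rbind, metaRows), metaPath)

  groups <- rbind(
    data.frame(genotype = c("ctl", "bsA", "bsB", "bsC"), assay = "vortex",
               n = 20L, mean = c(2, 15, 75, 168), sd = c(1, 5, 20, 40),
               onset_mean = NA_real_, onset_sd = NA_real_),
    data.frame(genotype = c("ctl", "bsA", "bsB", "bsC",
                            "hsA_c", "hsA", "hsB_c", "hsB"),
               assay = "eshock", n = 20L,
               mean = c(97, 153, 211, 334, 97, 214, 97, 166),
               sd = c(20, 35, 50, 80, 20, 50, 20, 40),
               onset_mean = NA_real_, onset_sd = NA_real_),
    data.frame(genotype = c("hsA_c", "hsA", "hsB_c", "hsB"), assay = "heat",
               n = 20L, mean = c(4, 72, 4, 431), sd = c(2, 25, 2, 150),
               onset_mean = c(NA, 40, NA, 55), onset_sd = c(NA, 30, NA, 35)))
  behav <- simulateBehavior(behaviorSimConfig(
    groups, censorTime = 120, seed = deriveSeed(rootSeed, "behavior")))
  behavPath <- file.path(outDir, "behavior.tsv")
  writeResultTable(behav, behavPath)

  cfgPath <- file.path(outDir, "run_config.yaml")
  runCfg <- list(
    spikes = "spikes.tsv", trace_meta = "trace_meta.tsv",
    behavior = "behavior.tsv",
    burst = list(max_isi_s = 0.1, min_spikes = 3L),
    classification = list(reference_genotype = "WTL", k = 1.5),
    comparisons = list(
      list(id = "bsA_vortex", group_a = "ctl", group_b = "bsA", assay = "vortex"),
      list(id = "bsB_vortex", group_a = "ctl", group_b = "bsB", assay = "vortex"),
      list(id = "bsC_vortex", group_a = "ctl", group_b = "bsC", assay = "vortex"),
      list(id = "bsA_eshock", group_a = "ctl", group_b = "bsA", assay = "eshock"),
      list(id = "bsB_eshock", group_a = "ctl", group_b = "bsB", assay = "eshock"),
      list(id = "bsC_eshock", group_a = "ctl", group_b = "bsC", assay = "eshock"),
      list(id = "hsA_heat", group_a = "hsA_c", group_b = "hsA", assay = "heat"),
      list(id = "hsB_heat", group_a = "hsB_c", group_b = "hsB", assay = "heat"),
      list(id = "hsA_eshock", group_a = "hsA_c", group_b = "hsA", assay = "eshock"),
      list(id = "hsB_eshock", group_a = "hsB_c", group_b = "hsB", assay = "eshock")),
    regression = list(x_assay = "eshock", n_boot = 1000L, points = list(
      list(genotype = "bsA", control = "ctl", y_assay = "vortex"),
      list(genotype = "bsB", control = "ctl", y_assay = "vortex"),
      list(genotype = "bsC", control = "ctl", y_assay = "vortex"),
      list(genotype = "hsA", control = "hsA_c", y_assay = "heat"),
      list(genotype = "hsB", control = "hsB_c", y_assay = "heat"))),
    bootstrap = list(n_boot = 5000L, ci_method = "bca",
                     seed = deriveSeed(rootSeed, "bootstrap")),
    heat_curve = list(genotypes = c("hsA", "hsB"), t_max_s = 120,
                      step_s = 10),
    out_dir = "results")
  yaml::write_yaml(runCfg, cfgPath)

  manifest <- list(
    root_seed = rootSeed,
    spike_presets = list(
      WTL = list(burst_duration_mean_s = 0.175, burst_duration_sd_s = 0.0915,
                 inter_burst_mean_s = 1.95, within_isi_mean_s = 0.0135,
                 noise_rate_hz = 0.01, duration_s = 180, n_traces = 12L),
      ELG = list(burst_duration_mean_s = 0.525, burst_duration_sd_s = 0.27,
                 inter_burst_mean_s = 1.95, within_isi_mean_s = 0.0135,
                 noise_rate_hz = 0.01, duration_s = 180, n_traces = 12L)),
    true_burst_counts = truthCounts,
    behavior_groups = groups,
    censor_time_s = 120)
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(spikes = spikePath, trace_meta = metaPath,
                 behavior = behavPath, config = cfgPath,
                 manifest = manifestPath))
}
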