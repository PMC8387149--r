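#' Read a run configuration
#'
#' Run configs are YAML with a flat, documented schema (see the fixture
#' suite's \code{run_config.yaml} for a complete example): input paths
#' (\code{spikes}, \code{trace_meta}, \code{behavior}), \code{burst}
#' parameters (\code{max_isi_s}, \code{min_spikes}), \code{classification}
#' (\code{reference_genotype}, \code{k}), a \code{comparisons} list
#' (\code{id}, \code{group_a}, \code{group_b}, \code{assay}), a
#' \code{regression} spec (\code{x_assay} plus per-genotype \code{points}
#' with their \code{control} and \code{y_assay}), \code{bootstrap}
#' parameters (\code{n_boot}, \code{ci_method}, root \code{seed}),
#' an optional \code{heat_curve} block, and \code{out_dir}. Relative paths
#' resolve against the config file's directory.
#'
#' @param path YAML config file.
#' @return config list with resolved paths.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: '", path, "'")
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p
                     else file.path(base, p)
  for (key in c("spikes", "trace_meta", "behavior"))
    cfg[[key]] <- rel(cfg[[key]])
  cfg$out_dir <- rel(cfg$out_dir)
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  for (key in c("spikes", "trace_meta", "behavior", "out_dir"))
    if (is.null(cfg[[key]])) stop("config error: missing key '", key, "'")
  for (cmp in cfg$comparisons) {
    if (is.null(cmp$group_a) || is.null(cmp$group_b) || is.null(cmp$assay))
      stop("config error: each comparison needs group_a, group_b, assay")
    if (identical(cmp$group_a, cmp$group_b))
      stop("config error: comparison groups must differ (",
           cmp$group_a, ")")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: spike/behavior ingestion, burst detection, per-trace
#' and per-genotype summaries, reference-band classification with
#' per-genotype elongated fractions, bootstrap effect sizes (mean
#' difference with 95\% CI, Cohen's d, percent change) for every configured
#' comparison, the cross-assay effect-size regression, and the heat-assay
#' cumulative seizing curve when onset data are present. Writes all result
#' tables (TSV) plus a plain-text run log with ISO timestamps into the
#' configured output directory. Each comparison draws its own child seed
#' from the root bootstrap seed and the comparison labels, so results are
#' reproducible and independent of comparison order.
#'
#' @param config a config list from [readRunConfig()] or a path to a YAML
#'   config.
#' @return invisibly, a named list of results (\code{traceSummaries},
#'   \code{genotypeSummaries}, \code{classifications}, \code{fractions},
#'   \code{effectSizes}, \code{regression}, \code{heatCurve},
#'   \code{files}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logf("flyburst %s pipeline start",
       as.character(utils::packageVersion("flyburst")))

  maxISI <- config$burst$max_isi_s %||% 0.100
  minSpikes <- config$burst$min_spikes %||% 3L
  params <- burstParams(maxISI, minSpikes)
  logf("burst params: max_isi_s=%g min_spikes=%d", maxISI, minSpikes)

  trains <- stage("spike_io",
                  readSpikeTrains(config$spikes, config$trace_meta))
  behav <- stage("spike_io", readBehavior(config$behavior))
  logf("read %d traces, %d behavioral records", length(trains), nrow(behav))

  bursts <- stage("bursts", detectBurstsAll(trains, params))
  logf("detected %d bursts", nrow(bursts))

  summaries <- stage("trace_stats", summarizeTraces(trains, params))
  genoSum <- stage("trace_stats", summarizeGenotype(summaries))
  logf("summarized %d traces into %d genotypes",
       nrow(summaries), nrow(genoSum))

  refGeno <- config$classification$reference_genotype %||% "CS"
  k <- config$classification$k %||% 1.5
  band <- stage("classify", buildReferenceBand(summaries, refGeno, k))
  labels <- stage("classify", classifyTraces(summaries, band))
  fractions <- stage("classify", fractionElongated(labels))
  logf("reference band (%s, k=%g): [%.4g, %.4g] s over %d traces",
       refGeno, k, bandLower(band), bandUpper(band), band@nTraces)

  nBoot <- config$bootstrap$n_boot %||% 5000L
  ciMethod <- config$bootstrap$ci_method %||% "bca"
  rootSeed <- config$bootstrap$seed %||% 1L
  effRows <- list()
  for (cmp in config$comparisons) {
    id <- cmp$id %||% paste(cmp$group_b, cmp$assay, sep = "_")
    a <- behav$value[behav$genotype == cmp$group_a & behav$assay == cmp$assay]
    b <- behav$value[behav$genotype == cmp$group_b & behav$assay == cmp$assay]
    es <- stage("effects", bootstrapMeanDifference(
      a, b, nBoot = nBoot,
      seed = deriveSeed(rootSeed, cmp$group_a, cmp$group_b, cmp$assay),
      ciMethod = ciMethod, groupA = cmp$group_a, groupB = cmp$group_b))
    row <- as.data.frame(es)
    row <- cbind(data.frame(comparison_id = id, assay = cmp$assay,
                            stringsAsFactors = FALSE), row)
    row$percent_change <- stage("effects", percentChange(b, a))
    effRows[[id]] <- row
    logf("comparison %s: diff %.4g [%.4g, %.4g], d=%.3g",
         id, meanDifference(es), confint95(es)[1L], confint95(es)[2L],
         effectD(es))
  }
  effects <- if (length(effRows)) do.call(rbind, effRows) else NULL

  regression <- NULL
  if (!is.null(config$regression) && length(config$regression$points) >= 2L) {
    xAssay <- config$regression$x_assay %||% "eshock"
    pts <- stage("effects", do.call(rbind, lapply(
      config$regression$points, function(p) {
        dOf <- function(assay) {
          a <- behav$value[behav$genotype == p$control & behav$assay == assay]
          b <- behav$value[behav$genotype == p$genotype & behav$assay == assay]
          cohensD(a, b)
        }
        data.frame(genotype = p$genotype, x = dOf(xAssay),
                   y = dOf(p$y_assay), stringsAsFactors = FALSE)
      })))
    reg <- stage("effects", fitEffectSizeRegression(
      pts$x, pts$y, nBoot = config$regression$n_boot %||% 0L,
      seed = deriveSeed(rootSeed, "regression")))
    regression <- data.frame(
      slope = reg@slope, intercept = reg@intercept,
      r_squared = reg@rSquared, n_points = reg@nPoints,
      r2_ci_low = reg@r2CiLow, r2_ci_high = reg@r2CiHigh)
    logf("regression: R^2 = %.4g over %d genotypes",
         reg@rSquared, reg@nPoints)
  }

  heatCurve <- NULL
  hc <- config$heat_curve
  if (!is.null(hc)) {
    cps <- seq(hc$step_s %||% 10, hc$t_max_s %||% 120,
               by = hc$step_s %||% 10)
    rows <- lapply(hc$genotypes, function(g) {
      on <- behav$onset_time_s[behav$genotype == g & behav$assay == "heat"]
      if (!length(on)) return(NULL)
      cbind(data.frame(genotype = g, stringsAsFactors = FALSE),
            cumulativeSeizingFraction(on, cps))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      heatCurve <- do.call(rbind, rows)
      logf("heat curve over %d genotypes", length(rows))
    }
  }

  files <- c(
    trace_summaries = "trace_summaries.tsv",
    genotype_summaries = "genotype_summaries.tsv",
    classifications = "classifications.tsv",
    elongated_fractions = "elongated_fractions.tsv",
    effect_sizes = "effect_sizes.tsv",
    regression = "regression.tsv",
    cumulative_seizing = "cumulative_seizing.tsv")
  out <- function(nm) file.path(config$out_dir, files[[nm]])
  writeResultTable(summaries, out("trace_summaries"))
  writeResultTable(genotypeSummaryTable(genoSum), out("genotype_summaries"))
  writeResultTable(labels, out("classifications"))
  writeResultTable(fractions, out("elongated_fractions"))
  if (!is.null(effects)) writeResultTable(effects, out("effect_sizes"))
  if (!is.null(regression)) writeResultTable(regression, out("regression"))
  if (!is.null(heatCurve))
    writeResultTable(heatCurve, out("cumulative_seizing"))
  logf("pipeline done; outputs in %s", config$out_dir)
  writeLines(logLines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(traceSummaries = summaries, genotypeSummaries = genoSum,
                 band = band, classifications = labels,
                 fractions = fractions, effectSizes = effects,
                 regression = regression, heatCurve = heatCurve,
                 files = file.path(config$out_dir,
                                   c(unlist(files), "run_log.txt"))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
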