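#' @import methods
NULL

.GROUP_ROLES <- c("wildtype_reference", "control", "mutant", "treated")
.ASSAYS <- c("vortex", "heat", "eshock", "locomotion_day",
             "locomotion_night", "larval_crawl")

#' SpikeTrain: one recorded or simulated trace
#'
#' Ordered spike times (seconds) from a single loose-patch recording of a
#' larval motor neuron (aCC or RP2), together with the declared recording
#' duration and trace metadata. Spike extraction from the raw voltage trace
#' is assumed to have happened upstream; this class starts from spike times.
#'
#' @slot traceId single character identifier, unique within a dataset.
#' @slot genotype genotype label (e.g. \code{"CS"}, \code{"jus"}).
#' @slot cellType recorded cell, typically \code{"aCC"} or \code{"RP2"}.
#' @slot groupRole one of \code{"wildtype_reference"}, \code{"control"},
#'   \code{"mutant"}, \code{"treated"}.
#' @slot duration recording duration in seconds (default protocol: 180 s).
#' @slot spikes strictly increasing spike times in seconds, all within
#'   \code{[0, duration]}.
#'
#' @seealso [SpikeTrain()] for the user-facing constructor,
#'   [detectBursts()] for burst segmentation.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    traceId   = "character",
    genotype  = "character",
    cellType  = "character",
    groupRole = "character",
    duration  = "numeric",
    spikes    = "numeric"
  ),
  prototype(
    traceId = NA_character_, genotype = NA_character_,
    cellType = NA_character_, groupRole = "control",
    duration = 180, spikes = numeric(0)
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@traceId) != 1L || is.na(object@traceId) ||
      !nzchar(object@traceId))
    msg <- c(msg, "'traceId' must be a single non-empty string")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "'duration' must be a single finite positive number")
  if (!(object@groupRole %in% .GROUP_ROLES))
    msg <- c(msg, sprintf("'groupRole' must be one of: %s",
                          paste(.GROUP_ROLES, collapse = ", ")))
  s <- object@spikes
  if (anyNA(s) || any(!is.finite(s)))
    msg <- c(msg, "spike times must be finite and non-missing")
  else {
    if (length(s) > 1L && any(diff(s) <= 0))
      msg <- c(msg, "spike times must be strictly increasing")
    if (length(s) && (s[1L] < 0 || s[length(s)] > object@duration))
      msg <- c(msg, "spike times must lie in [0, duration]")
  }
  if (length(msg)) msg else TRUE
})

#' BurstParams: parameters of the ISI-threshold burst rule
#'
#' A burst is a maximal run of at least \code{minSpikes} consecutive spikes
#' whose successive inter-spike intervals are all at most \code{maxISI}
#' seconds; the burst ends when no spike follows within \code{maxISI} of the
#' last spike. Defaults encode the standard rule for these recordings:
#' 100 ms maximum ISI, minimum three spikes.
#'
#' @slot maxISI maximum inter-spike interval inside a burst, seconds.
#' @slot minSpikes minimum number of spikes for a run to count as a burst.
#'
#' @seealso [burstParams()], [detectBursts()]
#' @exportClass BurstParams
setClass("BurstParams",
  representation(maxISI = "numeric", minSpikes = "integer"),
  prototype(maxISI = 0.100, minSpikes = 3L)
)

setValidity("BurstParams", function(object) {
  msg <- character(0)
  if (length(object@maxISI) != 1L || !is.finite(object@maxISI) ||
      object@maxISI <= 0)
    msg <- c(msg, "'maxISI' must be a single positive number (seconds)")
  if (length(object@minSpikes) != 1L || is.na(object@minSpikes) ||
      object@minSpikes < 2L)
    msg <- c(msg, "'minSpikes' must be an integer >= 2")
  if (length(msg)) msg else TRUE
})

#' ReferenceBand: wild-type normal range for trace classification
#'
#' The band mean +/- k*SD of per-trace mean burst durations across the
#' reference (wild-type) traces. A trace whose mean burst duration falls
#' above the band is called elongated, below it short, inside (bounds
#' inclusive) normal.
#'
#' @slot referenceGenotype genotype the band was built from (default "CS").
#' @slot mean mean of reference per-trace mean burst durations, seconds.
#' @slot sd sample SD of the same, seconds.
#' @slot k band half-width multiplier (default 1.5).
#' @slot lower,upper band bounds, \code{mean -/+ k*sd}, seconds.
#' @slot nTraces number of reference traces used (>= 2).
#'
#' @seealso [buildReferenceBand()], [classifyTraces()]
#' @exportClass ReferenceBand
setClass("ReferenceBand",
  representation(
    referenceGenotype = "character",
    mean = "numeric", sd = "numeric", k = "numeric",
    lower = "numeric", upper = "numeric", nTraces = "integer"
  )
)

setValidity("ReferenceBand", function(object) {
  msg <- character(0)
  if (!is.finite(object@sd) || object@sd < 0)
    msg <- c(msg, "'sd' must be finite and >= 0")
  if (!is.finite(object@k) || object@k < 0)
    msg <- c(msg, "'k' must be finite and >= 0")
  if (object@nTraces < 2L)
    msg <- c(msg, "a reference band needs >= 2 reference traces")
  if (is.finite(object@lower) && is.finite(object@upper) &&
      (object@lower > object@mean || object@upper < object@mean))
    msg <- c(msg, "band bounds must bracket the mean")
  if (length(msg)) msg else TRUE
})

#' EffectSize: bootstrap estimation statistics for one two-group comparison
#'
#' Holds the point estimate of the mean difference (group B minus group A),
#' its bootstrap 95\% confidence interval, and Cohen's d (pooled-SD
#' standardized mean difference). No p-values are computed anywhere in this
#' package: comparisons are reported as effect sizes with CIs.
#'
#' @slot groupA,groupB group labels; the difference is B - A.
#' @slot nA,nB group sizes.
#' @slot meanDifference mean(B) - mean(A).
#' @slot ciLow,ciHigh bootstrap 95\% CI of the mean difference.
#' @slot cohensD pooled-SD standardized mean difference.
#' @slot nBoot number of bootstrap resamples (default 5000).
#' @slot seed RNG seed used for the resampling.
#' @slot ciMethod \code{"bca"} or \code{"percentile"}; a BCa request that
#'   degenerates (undefined bias-correction or acceleration) is downgraded
#'   to percentile with a warning and recorded here.
#'
#' @seealso [bootstrapMeanDifference()], [cohensD()]
#' @exportClass EffectSize
setClass("EffectSize",
  representation(
    groupA = "character", groupB = "character",
    nA = "integer", nB = "integer",
    meanDifference = "numeric", ciLow = "numeric", ciHigh = "numeric",
    cohensD = "numeric", nBoot = "integer", seed = "integer",
    ciMethod = "character"
  )
)

setValidity("EffectSize", function(object) {
  msg <- character(0)
  if (object@nA < 2L || object@nB < 2L)
    msg <- c(msg, "both groups need n >= 2")
  if (object@nBoot < 1000L)
    msg <- c(msg, "'nBoot' must be >= 1000")
  if (!(object@ciMethod %in% c("bca", "percentile")))
    msg <- c(msg, "'ciMethod' must be 'bca' or 'percentile'")
  if (length(msg)) msg else TRUE
})

#' RegressionResult: least-squares fit of effect sizes across assays
#'
#' Ordinary least-squares line through per-genotype effect-size points
#' (e.g. larval electroshock Cohen's d on x vs adult-assay Cohen's d on y),
#' with R-squared and an optional bootstrap-over-points CI for R-squared.
#'
#' @slot slope,intercept OLS coefficients.
#' @slot rSquared squared Pearson correlation, in [0, 1].
#' @slot nPoints number of (x, y) points fitted.
#' @slot r2CiLow,r2CiHigh optional percentile bootstrap CI of R-squared
#'   (\code{NA} when not requested).
#'
#' @seealso [fitEffectSizeRegression()]
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(
    slope = "numeric", intercept = "numeric", rSquared = "numeric",
    nPoints = "integer", r2CiLow = "numeric", r2CiHigh = "numeric"
  ),
  prototype(r2CiLow = NA_real_, r2CiHigh = NA_real_)
)

setValidity("RegressionResult", function(object) {
  msg <- character(0)
  if (object@nPoints < 2L) msg <- c(msg, "'nPoints' must be >= 2")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
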