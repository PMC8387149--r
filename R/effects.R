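#' Bootstrap mean difference with BCa or percentile CI
#'
#' Estimation-statistics workhorse for two-group comparisons. The point
#' estimate is \code{mean(b) - mean(a)}; each group is resampled with
#' replacement at its own size \code{nBoot} times and the 95\% confidence
#' interval of the mean difference is taken from the bootstrap distribution.
#'
#' The default interval is bias-corrected and accelerated (BCa): the bias
#' correction \eqn{z_0} is the normal quantile of the fraction of bootstrap
#' replicates below the point estimate, and the acceleration \eqn{a} comes
#' from the grouped jackknife of the mean difference,
#' \eqn{a = \sum u_i^3 / (6 (\sum u_i^2)^{3/2})} with \eqn{u_i} the
#' deviations of the leave-one-out estimates from their mean. When either
#' quantity is undefined (all replicates identical, or zero jackknife
#' spread) the interval downgrades to the percentile method with a logged
#' message and the returned object records \code{ciMethod = "percentile"}.
#'
#' No p-value is computed; comparisons in this package are reported as
#' effect sizes with confidence intervals.
#'
#' @param a,b numeric samples (n >= 2 each, finite).
#' @param nBoot number of bootstrap resamples (default 5000).
#' @param seed RNG seed; identical seed and inputs give a bit-identical
#'   result.
#' @param ciMethod \code{"bca"} (default) or \code{"percentile"}.
#' @param groupA,groupB labels carried into the result.
#' @return an [EffectSize-class] object (also holding Cohen's d when
#'   defined, \code{NA} for two zero-variance groups).
#' @examples
#' es <- bootstrapMeanDifference(rnorm(20), rnorm(20, 1), seed = 7)
#' meanDifference(es); confint95(es)
#' @export
bootstrapMeanDifference <- function(a, b, nBoot = 5000L, seed = 1L,
                                    ciMethod = c("bca", "percentile"),
                                    groupA = "A", groupB = "B") {
  ciMethod <- match.arg(ciMethod)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2 (have ", length(a), " and ", length(b), ")")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input samples")
  nBoot <- as.integer(nBoot)
  if (nBoot < 1000L) stop("'nBoot' must be >= 1000")
  nA <- length(a); nB <- length(b)
  thetaHat <- mean(b) - mean(a)

  set.seed(as.integer(seed))
  ma <- rowMeans(matrix(sample(a, nA * nBoot, replace = TRUE), nrow = nBoot))
  mb <- rowMeans(matrix(sample(b, nB * nBoot, replace = TRUE), nrow = nBoot))
  thetaStar <- mb - ma

  usedMethod <- ciMethod
  ci <- NULL
  if (ciMethod == "bca") {
    ci <- .bcaInterval(thetaStar, thetaHat, a, b)
    if (is.null(ci)) {
      message("BCa interval undefined (degenerate bootstrap or jackknife); ",
              "falling back to percentile")
      usedMethod <- "percentile"
    }
  }
  if (is.null(ci))
    ci <- unname(stats::quantile(thetaStar, c(0.025, 0.975), type = 7))

  d <- tryCatch(cohensD(a, b), error = function(e) NA_real_)
  new("EffectSize", groupA = as.character(groupA),
      groupB = as.character(groupB), nA = nA, nB = nB,
      meanDifference = thetaHat, ciLow = ci[1L], ciHigh = ci[2L],
      cohensD = d, nBoot = nBoot, seed = as.integer(seed),
      ciMethod = usedMethod)
}

# BCa 95% interval, or NULL when bias-correction/acceleration is undefined
.bcaInterval <- function(thetaStar, thetaHat, a, b) {
  pBelow <- mean(thetaStar < thetaHat)
  if (pBelow <= 0 || pBelow >= 1) return(NULL)
  z0 <- stats::qnorm(pBelow)
  # grouped jackknife: leave one observation out of its own group
  nA <- length(a); nB <- length(b)
  jackA <- mean(b) - (sum(a) - a) / (nA - 1)
  jackB <- (sum(b) - b) / (nB - 1) - mean(a)
  jack <- c(jackA, jackB)
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  if (denom == 0) return(NULL)
  acc <- sum(u^3) / (6 * denom)
  zAlpha <- stats::qnorm(c(0.025, 0.975))
  adj <- stats::pnorm(z0 + (z0 + zAlpha) / (1 - acc * (z0 + zAlpha)))
  if (any(!is.finite(adj)) || any(adj <= 0) || any(adj >= 1)) return(NULL)
  unname(stats::quantile(thetaStar, adj, type = 7))
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' \deqn{d = \frac{\bar b - \bar a}{s_p}, \qquad
#'   s_p = \sqrt{\frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}}}
#' with sample variances. Used to compare seizure-severity effects measured
#' on different scales (e.g. larval electroshock vs adult vortex seizure
#' durations).
#'
#' @param a,b numeric samples, n >= 2 each.
#' @return the standardized mean difference \code{(mean(b) - mean(a)) / sp}.
#' @examples
#' cohensD(c(0, 2), c(1, 3))   # 1 / sqrt(2)
#' @export
cohensD <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input samples")
  nA <- length(a); nB <- length(b)
  sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) /
    (nA + nB - 2)
  if (sp2 == 0)
    stop("undefined effect: both groups have zero variance")
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Percent change of the treated-group mean relative to control
#'
#' \code{100 * (mean(treated) - mean(control)) / mean(control)}; the
#' conventional "seizure duration increased by X\%" report.
#'
#' @param treated,control numeric samples; \code{mean(control)} must be
#'   positive.
#' @return percent change (negative when the treated mean is lower).
#' @export
percentChange <- function(treated, control) {
  mc <- mean(as.numeric(control))
  if (!is.finite(mc) || mc <= 0)
    stop("control mean must be positive and finite")
  100 * (mean(as.numeric(treated)) - mc) / mc
}

#' Least-squares regression of effect sizes across assays
#'
#' Ordinary least-squares line through per-genotype effect-size points
#' (one point per genotype, e.g. larval electroshock Cohen's d on x, adult
#' assay Cohen's d on y), with \eqn{R^2} the squared Pearson correlation.
#' Optionally bootstraps over points (genotypes resampled with
#' replacement) for a percentile CI of \eqn{R^2}.
#'
#' @param x,y numeric effect sizes, equal length >= 2; x must not be
#'   constant.
#' @param nBoot bootstrap resamples over points for the R-squared CI; 0
#'   (default) skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @return a [RegressionResult-class].
#' @export
fitEffectSizeRegression <- function(x, y, nBoot = 0L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 2L) stop("need >= 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite effect sizes")
  if (stats::var(x) == 0)
    stop("degenerate design: all x values equal")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  # exactly collinear points must report R^2 = 1; squaring a correlation
  # a few ulps below one would otherwise leak round-off into the report
  if (1 - r2 < 1e-12) r2 <- 1
  r2 <- min(max(r2, 0), 1)
  lo <- hi <- NA_real_
  if (nBoot > 0L) {
    set.seed(as.integer(seed))
    n <- length(x)
    r2b <- replicate(nBoot, {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0 || stats::var(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])^2
    })
    q <- stats::quantile(r2b, c(0.025, 0.975), na.rm = TRUE, type = 7)
    lo <- unname(q[1L]); hi <- unname(q[2L])
  }
  new("RegressionResult", slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]), rSquared = r2,
      nPoints = length(x), r2CiLow = lo, r2CiHigh = hi)
}

#' Cumulative fraction of animals seizing over time
#'
#' Step curve for the heat-assay exposure window: at each checkpoint, the
#' fraction of the cohort whose seizure onset occurred at or before that
#' time. Censored animals (no onset before the cutoff, \code{NA} onset)
#' are never counted in the numerator but always in the denominator, so
#' the curve plateaus at the overall fraction that seized.
#'
#' @param onsets numeric onset times in seconds; \code{NA} = censored.
#' @param checkpoints increasing evaluation times (default every 10 s to
#'   120 s, the standard heat-assay window).
#' @return data.frame \code{time_s, fraction_seizing}; the curve is
#'   non-decreasing.
#' @export
cumulativeSeizingFraction <- function(onsets,
                                      checkpoints = seq(10, 120, by = 10)) {
  if (!length(onsets)) stop("empty cohort")
  if (any(onsets < 0, na.rm = TRUE)) stop("onset times must be >= 0")
  if (is.unsorted(checkpoints, strictly = TRUE))
    stop("'checkpoints' must be strictly increasing")
  frac <- vapply(checkpoints,
                 function(cp) sum(onsets <= cp, na.rm = TRUE) / length(onsets),
                 numeric(1))
  data.frame(time_s = checkpoints, fraction_seizing = frac)
}

#' Derive a reproducible child seed from a root seed and labels
#'
#' Comparisons get their own deterministic child seed from the run's root
#' seed and the comparison's group labels, so adding or reordering
#' comparisons never perturbs existing results.
#'
#' @param rootSeed integer root seed.
#' @param ... character labels identifying the consumer.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(rootSeed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- as.double(rootSeed) %% 2147483647
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Accessors for EffectSize objects
#'
#' @param x an [EffectSize-class].
#' @return \code{meanDifference}: the point estimate; \code{confint95}: a
#'   length-2 numeric (CI bounds); \code{effectD}: Cohen's d.
#' @name effectAccessors
NULL

#' @rdname effectAccessors
setMethod("meanDifference", "EffectSize", function(x) x@meanDifference)
#' @rdname effectAccessors
setMethod("confint95", "EffectSize", function(x) c(x@ciLow, x@ciHigh))
#' @rdname effectAccessors
setMethod("effectD", "EffectSize", function(x) x@cohensD)

setMethod("show", "EffectSize", function(object) {
  cat(sprintf(
    "EffectSize: %s vs %s (n = %d, %d)\n  mean difference %.4g [95%% CI %.4g, %.4g] (%s, %d resamples)\n  Cohen's d %.4g\n",
    object@groupA, object@groupB, object@nA, object@nB,
    object@meanDifference, object@ciLow, object@ciHigh, object@ciMethod,
    object@nBoot, object@cohensD))
})

#' Flatten an EffectSize into a one-row data.frame
#'
#' @param x an [EffectSize-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @return one-row data.frame matching the effect-size table schema.
#' @export
as.data.frame.EffectSize <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(group_a = x@groupA, group_b = x@groupB, n_a = x@nA,
             n_b = x@nB, mean_difference = x@meanDifference,
             ci_low = x@ciLow, ci_high = x@ciHigh, cohens_d = x@cohensD,
             n_boot = x@nBoot, seed = x@seed, ci_method = x@ciMethod,
             stringsAsFactors = FALSE)
}

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "RegressionResult: y = %.4g + %.4g x over %d points\n  R-squared %.4g%s\n",
    object@intercept, object@slope, object@nPoints, object@rSquared,
    if (is.finite(object@r2CiLow))
      sprintf(" [95%% CI %.4g, %.4g]", object@r2CiLow, object@r2CiHigh)
    else ""))
})
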