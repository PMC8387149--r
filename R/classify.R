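#' Build the wild-type reference band
#'
#' The reference statistic is the distribution of per-trace mean burst
#' durations across the reference-genotype traces (not the pooled
#' distribution of individual bursts): the band is their mean plus/minus
#' \code{k} sample standard deviations. Traces of the reference genotype
#' with no bursts are unclassifiable and are excluded, with a message.
#'
#' @param summaries trace-summary data.frame from [summarizeTraces()]
#'   (any mix of genotypes; filtered internally).
#' @param genotype the reference genotype (default \code{"CS"}).
#' @param k band half-width in SD units (default 1.5).
#' @return a [ReferenceBand-class] object.
#' @examples
#' s <- data.frame(trace_id = c("a", "b", "c"), genotype = "CS",
#'                 n_bursts = 5L, mean_burst_duration_s = c(0.1, 0.2, 0.3))
#' buildReferenceBand(s)   # band [0.05, 0.35]
#' @export
buildReferenceBand <- function(summaries, genotype = "CS", k = 1.5) {
  stopifnot(is.data.frame(summaries), is.numeric(k), k >= 0)
  s <- summaries[summaries$genotype %in% genotype, , drop = FALSE]
  if (!nrow(s))
    stop("no traces for reference genotype '", genotype, "'")
  drop <- s$n_bursts == 0L | is.na(s$mean_burst_duration_s)
  if (any(drop))
    message(sum(drop), " zero-burst reference trace(s) excluded from band")
  m <- s$mean_burst_duration_s[!drop]
  if (length(m) < 2L)
    stop("insufficient reference: need >= 2 classifiable traces for '",
         genotype, "', have ", length(m))
  mu <- mean(m); sdv <- stats::sd(m)
  new("ReferenceBand", referenceGenotype = genotype, mean = mu, sd = sdv,
      k = as.numeric(k), lower = mu - k * sdv, upper = mu + k * sdv,
      nTraces = length(m))
}

#' Accessors for ReferenceBand objects
#'
#' @param x a [ReferenceBand-class].
#' @return band bound/centre/scale in seconds.
#' @name bandAccessors
NULL

#' @rdname bandAccessors
setMethod("bandLower", "ReferenceBand", function(x) x@lower)
#' @rdname bandAccessors
setMethod("bandUpper", "ReferenceBand", function(x) x@upper)
#' @rdname bandAccessors
setMethod("bandMean", "ReferenceBand", function(x) x@mean)
#' @rdname bandAccessors
setMethod("bandSD", "ReferenceBand", function(x) x@sd)

setMethod("show", "ReferenceBand", function(object) {
  cat(sprintf(
    "ReferenceBand (%s, n = %d traces)\n  mean %.4g s, SD %.4g s, k = %g -> normal range [%.4g, %.4g] s\n",
    object@referenceGenotype, object@nTraces, object@mean, object@sd,
    object@k, object@lower, object@upper))
})

#' Classify traces against the reference band
#'
#' A trace is \emph{elongated} when its mean burst duration exceeds the
#' band's upper bound, \emph{short} when it falls below the lower bound,
#' \emph{normal} otherwise (bounds inclusive: a value exactly at a bound is
#' normal, since the band defines the normal range), and
#' \emph{unclassifiable} when the trace has no bursts.
#'
#' @param summaries trace-summary data.frame from [summarizeTraces()].
#' @param band a [ReferenceBand-class].
#' @return data.frame: \code{trace_id, genotype, mean_burst_duration_ms,
#'   label} with label in \code{normal/elongated/short/unclassifiable}.
#' @export
classifyTraces <- function(summaries, band) {
  stopifnot(is.data.frame(summaries), is(band, "ReferenceBand"))
  validObject(band)
  m <- summaries$mean_burst_duration_s
  # at-bound values are normal; the guard keeps that true when the bound
  # itself carries floating-point round-off from mean + k*sd
  eps <- 1e-12 * max(1, abs(band@upper), abs(band@lower))
  label <- ifelse(summaries$n_bursts == 0L | is.na(m), "unclassifiable",
           ifelse(m > band@upper + eps, "elongated",
           ifelse(m < band@lower - eps, "short", "normal")))
  data.frame(trace_id = summaries$trace_id,
             genotype = summaries$genotype,
             mean_burst_duration_ms = m * 1000,
             label = label, stringsAsFactors = FALSE)
}

#' Fraction of elongated bursting traces per genotype
#'
#' Elongated count over classifiable count (unclassifiable traces are
#' excluded from the denominator and reported separately). The fraction is
#' \code{NA} when a genotype has no classifiable traces.
#'
#' @param labels classification data.frame from [classifyTraces()].
#' @param by grouping column (default \code{"genotype"}).
#' @return data.frame: \code{genotype, n_classifiable, n_elongated,
#'   n_short, n_unclassifiable, fraction_elongated}.
#' @export
fractionElongated <- function(labels, by = "genotype") {
  stopifnot(is.data.frame(labels), "label" %in% names(labels),
            by %in% names(labels))
  groups <- unique(labels[[by]])
  out <- lapply(groups, function(g) {
    l <- labels$label[labels[[by]] == g]
    ncl <- sum(l != "unclassifiable")
    nel <- sum(l == "elongated")
    data.frame(genotype = g,
               n_classifiable = ncl,
               n_elongated = nel,
               n_short = sum(l == "short"),
               n_unclassifiable = sum(l == "unclassifiable"),
               fraction_elongated = if (ncl > 0L) nel / ncl else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res)[1L] <- by
  res
}
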