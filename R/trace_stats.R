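#' Per-trace burst statistics
#'
#' Computes the six summary statistics reported for each recorded trace:
#' mean and sample SD of burst duration, burst frequency, overall firing
#' rate, mean spike count per burst and mean AP frequency per burst.
#' Conventions:
#' \itemize{
#'   \item burst-duration SD is the sample SD (n - 1) over the trace's
#'     bursts, \code{NA} with fewer than two bursts;
#'   \item burst frequency and firing rate use the full declared recording
#'     duration as denominator (not the last-spike time);
#'   \item AP frequency per burst is the mean over bursts of
#'     \code{n_spikes / duration} of that burst (mean of ratios, the
#'     per-burst statistic), with zero-duration bursts excluded from this
#'     mean and a message logged;
#'   \item a zero-burst trace still gets its firing rate; all burst
#'     statistics are \code{NA} and the trace is flagged unclassifiable
#'     downstream.
#' }
#' Internally everything is seconds and Hz; use [genotypeSummaryTable()]
#' for the conventional report with durations in ms.
#'
#' @param train a [SpikeTrain-class].
#' @param bursts burst table for that train, as produced by
#'   [detectBursts()].
#' @return one-row data.frame: \code{trace_id, genotype, group_role,
#'   n_bursts, mean_burst_duration_s, sd_burst_duration_s,
#'   burst_frequency_hz, firing_rate_hz, mean_spikes_per_burst,
#'   mean_ap_frequency_per_burst_hz}.
#' @examples
#' st <- SpikeTrain("ex", c(0.00, 0.05, 0.10, 0.30, 0.35, 0.40, 0.45))
#' summarizeTrace(st, detectBursts(st))
#' @rdname summarizeTrace
#' @aliases summarizeTrace
#' @export summarizeTrace
setMethod("summarizeTrace", "SpikeTrain", function(train, bursts) {
  stopifnot(is.data.frame(bursts))
  if (nrow(bursts) && !all(bursts$trace_id == train@traceId))
    stop("burst table does not belong to trace '", train@traceId, "'")
  nb <- nrow(bursts)
  dur <- train@duration
  if (nb > 0L) {
    d <- bursts$duration_s
    posd <- d > 0
    if (!all(posd))
      message("trace '", train@traceId, "': ", sum(!posd),
              " zero-duration burst(s) excluded from AP-frequency mean")
    apf <- if (any(posd))
      mean(bursts$n_spikes[posd] / d[posd]) else NA_real_
    meanDur <- mean(d)
    sdDur <- if (nb >= 2L) stats::sd(d) else NA_real_
    spb <- mean(bursts$n_spikes)
  } else {
    meanDur <- sdDur <- spb <- apf <- NA_real_
  }
  data.frame(
    trace_id = train@traceId,
    genotype = train@genotype,
    group_role = train@groupRole,
    n_bursts = nb,
    mean_burst_duration_s = meanDur,
    sd_burst_duration_s = sdDur,
    burst_frequency_hz = nb / dur,
    firing_rate_hz = length(train@spikes) / dur,
    mean_spikes_per_burst = spb,
    mean_ap_frequency_per_burst_hz = apf,
    stringsAsFactors = FALSE)
})

#' Summarize a list of spike trains
#'
#' Runs [detectBursts()] and [summarizeTrace()] over each train.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param params a [BurstParams-class].
#' @return data.frame with one row per trace (see [summarizeTrace()]).
#' @export
summarizeTraces <- function(trains, params = burstParams()) {
  do.call(rbind, lapply(trains, function(tr)
    summarizeTrace(tr, detectBursts(tr, params))))
}

#' Per-genotype aggregation of trace summaries
#'
#' Unweighted means of the per-trace statistics over all traces of one
#' genotype. Traces with no bursts contribute to the trace count, the
#' burst-frequency mean and the firing-rate mean but are excluded from the
#' burst-statistic means (their values are undefined); the number excluded
#' is reported.
#'
#' @param summaries data.frame from [summarizeTraces()]; may contain many
#'   genotypes.
#' @param genotype genotype label(s) to aggregate; default all present.
#' @return data.frame with one row per genotype: \code{genotype, n_traces,
#'   n_zero_burst} plus the unweighted mean of every summary column.
#' @export
summarizeGenotype <- function(summaries,
                              genotype = unique(summaries$genotype)) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0L)
  out <- lapply(genotype, function(g) {
    s <- summaries[summaries$genotype %in% g, , drop = FALSE]
    if (!nrow(s)) stop("no traces for genotype '", g, "'")
    hasB <- s$n_bursts > 0L
    colMean <- function(x, idx = rep(TRUE, nrow(s)))
      if (any(idx)) mean(x[idx]) else NA_real_
    data.frame(
      genotype = g,
      n_traces = nrow(s),
      n_zero_burst = sum(!hasB),
      n_bursts = colMean(s$n_bursts),
      mean_burst_duration_s = colMean(s$mean_burst_duration_s, hasB),
      sd_burst_duration_s = colMean(s$sd_burst_duration_s,
                                    hasB & !is.na(s$sd_burst_duration_s)),
      burst_frequency_hz = colMean(s$burst_frequency_hz),
      firing_rate_hz = colMean(s$firing_rate_hz),
      mean_spikes_per_burst = colMean(s$mean_spikes_per_burst, hasB),
      mean_ap_frequency_per_burst_hz =
        colMean(s$mean_ap_frequency_per_burst_hz,
                hasB & !is.na(s$mean_ap_frequency_per_burst_hz)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genotype summary in conventional reporting units
#'
#' Reshapes a [summarizeGenotype()] table into the conventional column
#' order with burst durations in milliseconds (exact x1000 conversion) and
#' rates in Hz: genotype, N, burst duration (ms), burst duration SD (ms),
#' burst frequency (Hz), firing rate (AP/s), AP count per burst, AP
#' frequency per burst (Hz).
#'
#' @param genoSummary data.frame from [summarizeGenotype()].
#' @return data.frame in reporting units.
#' @export
genotypeSummaryTable <- function(genoSummary) {
  data.frame(
    genotype = genoSummary$genotype,
    n = genoSummary$n_traces,
    burst_duration_ms = genoSummary$mean_burst_duration_s * 1000,
    burst_duration_sd_ms = genoSummary$sd_burst_duration_s * 1000,
    burst_frequency_hz = genoSummary$burst_frequency_hz,
    firing_rate_ap_per_s = genoSummary$firing_rate_hz,
    ap_count_per_burst = genoSummary$mean_spikes_per_burst,
    ap_frequency_per_burst_hz = genoSummary$mean_ap_frequency_per_burst_hz,
    stringsAsFactors = FALSE)
}
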